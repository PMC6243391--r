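# build a block of valid trait-table rows, one per value
make_leaves <- function(values, trait = "SLA", species = "sp1",
                        genus = "G1", family = "F1", order = "O1",
                        site = "S1", plot_id = "S1-b1-C", block = "S1-b1",
                        treatment = "control", origin_site = site,
                        leaf_prefix = paste(plot_id, species, trait, sep = "-")) {
  n <- length(values)
  tibble::tibble(
    leaf_id = paste0(leaf_prefix, "-", seq_len(n)),
    species = species, genus = genus, family = family, order = order,
    site = site, plot_id = plot_id, block = block, treatment = treatment,
    origin_site = origin_site, trait = trait, value = values)
}

# one leaf measured for several traits (shared leaf_id)
make_leaf_panel <- function(leaf_id, traits, values, species = "sp1",
                            genus = "G1", family = "F1", order = "O1",
                            site = "S1", plot_id = "S1-b1-C",
                            block = "S1-b1", treatment = "control") {
  tibble::tibble(
    leaf_id = leaf_id, species = species, genus = genus, family = family,
    order = order, site = site, plot_id = plot_id, block = block,
    treatment = treatment, origin_site = site, trait = traits,
    value = values)
}

# simulate one study replicate and return the outcome x start-group G-test:
# the full chain exercised end to end (generator -> bootstrap community
# means -> home summaries -> classification -> G-test). Study conditions:
# communities that differ along the gradient (one community SD per site
# step), turf means resting on 10 leaves, one turf per population per
# direction (the G-test treats records as independent), and community
# means estimated precisely enough not to perturb the classification.
convergence_study_rep <- function(seed, pi_near, pi_far, B = 300,
                                  n_draws = 300) {
  cfg <- simulation_config(
    n_orders = 2, families_per_order = 2, genera_per_family = 2,
    species_per_genus = 2, n_sites = 4, leaves_per_species_site = 5,
    leaves_per_plot = 10, n_blocks = 1, site_trend = 1,
    plasticity_pi = c(near = pi_near, far = pi_far), seed = seed)
  sim <- simulate_dataset(cfg)
  cm <- bootstrap_all_communities(sim$communities, sim$traits,
                                  B = B, n_draws = n_draws, seed = seed)
  records <- classify_all_transplants(sim$traits, sim$design, cm)
  suppressWarnings(g_test(tabulate_outcomes(records, "start_group")))
}
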