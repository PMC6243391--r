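#' Configuration for the synthetic gradient + transplant generator
#'
#' Builds the parameter set for a simulated reciprocal turf-transplant study:
#' a balanced taxonomy, sites ordered along an elevation gradient (site 1 is
#' the lowest and warmest; adjacent sites differ by one ~1.5 degC step),
#' hierarchical trait variance at six nested levels, Dirichlet-structured
#' community biomass, and transplant-induced plastic shifts of tunable
#' magnitude toward the destination community mean.
#'
#' @param n_orders,families_per_order,genera_per_family,species_per_genus
#'   Counts defining the balanced taxonomy.
#' @param n_sites Number of sites along the gradient (default 4).
#' @param leaves_per_species_site Wild leaves sampled per species per site
#'   (default 5, one leaf from each of up to five individuals).
#' @param leaves_per_plot Leaves sampled per species in each experimental
#'   plot (default 5).
#' @param n_blocks Replicate blocks per site (default 7).
#' @param variance_components Named numeric vector of variances for levels
#'   `order`, `family`, `genus`, `species`, `population`, `within`.
#'   Defaults are proportions typical of alpine grassland leaf traits, with
#'   most variance at and below the species level.
#' @param trait_grand_mean Grand mean of the trait (latent scale for
#'   multiplicative traits).
#' @param traits Character vector of trait names to simulate (independent
#'   draws per trait). Multiplicative traits are generated on the log scale
#'   and exponentiated.
#' @param site_trend Directional shift added to population means per site
#'   step, in trait units. Default 0: community trait means along such
#'   gradients typically overlap broadly, with few directional shifts.
#' @param dirichlet_alpha Symmetric Dirichlet concentration for community
#'   biomass shares. Default 1 gives realistically uneven communities with a
#'   few dominants; large values approach even communities.
#' @param plot_total Total biomass per site community (g). Weights are
#'   relative, so the value is cosmetic.
#' @param plasticity_pi Named vector `c(near = , far = )` giving the
#'   interpolation fraction pi toward the destination community mean for
#'   species starting within (`near`) or beyond (`far`)
#'   `distance_threshold` community SDs of the destination mean. pi = 0 is
#'   no plasticity, pi = 1 full convergence; negative values model active
#'   divergence.
#' @param distance_threshold Start-distance class boundary in destination
#'   community SD units (default 1).
#' @param seed Integer seed; all generator randomness derives from it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_orders = 2, families_per_order = 2,
                              genera_per_family = 2, species_per_genus = 2,
                              n_sites = 4,
                              leaves_per_species_site = 5,
                              leaves_per_plot = 5,
                              n_blocks = 7,
                              variance_components = c(order = 0.15,
                                                      family = 0.10,
                                                      genus = 0.20,
                                                      species = 0.25,
                                                      population = 0.10,
                                                      within = 0.20),
                              trait_grand_mean = 10,
                              traits = "SLA",
                              site_trend = 0,
                              dirichlet_alpha = 1,
                              plot_total = 100,
                              plasticity_pi = c(near = 0.1, far = 0.8),
                              distance_threshold = 1,
                              seed = 1) {
  counts <- c(n_orders = n_orders, families_per_order = families_per_order,
              genera_per_family = genera_per_family,
              species_per_genus = species_per_genus, n_sites = n_sites,
              leaves_per_species_site = leaves_per_species_site,
              leaves_per_plot = leaves_per_plot, n_blocks = n_blocks)
  if (any(counts < 1)) stop("all counts must be >= 1", call. = FALSE)
  levels_needed <- c("order", "family", "genus", "species", "population", "within")
  if (!all(levels_needed %in% names(variance_components))) {
    stop("variance_components must name all of: ",
         paste(levels_needed, collapse = ", "), call. = FALSE)
  }
  variance_components <- variance_components[levels_needed]
  if (any(variance_components < 0)) stop("variances must be >= 0", call. = FALSE)
  if (!all(c("near", "far") %in% names(plasticity_pi))) {
    stop("plasticity_pi must name 'near' and 'far'", call. = FALSE)
  }
  if (any(plasticity_pi > 1) || any(plasticity_pi < -1)) {
    stop("plasticity_pi must lie in [-1, 1]", call. = FALSE)
  }
  stopifnot(dirichlet_alpha > 0, plot_total > 0, distance_threshold > 0,
            all(traits %in% trait_names))
  structure(list(n_orders = n_orders, families_per_order = families_per_order,
                 genera_per_family = genera_per_family,
                 species_per_genus = species_per_genus, n_sites = n_sites,
                 leaves_per_species_site = leaves_per_species_site,
                 leaves_per_plot = leaves_per_plot, n_blocks = n_blocks,
                 variance_components = variance_components,
                 trait_grand_mean = trait_grand_mean, traits = traits,
                 site_trend = site_trend, dirichlet_alpha = dirichlet_alpha,
                 plot_total = plot_total,
                 plasticity_pi = plasticity_pi,
                 distance_threshold = distance_threshold,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# deterministic per-stage sub-seed, kept inside 32-bit integer range
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + stage) %% 2147483647L)
}

site_labels <- function(n_sites) sprintf("S%d", seq_len(n_sites))

#' Generate a balanced taxonomy
#'
#' Species names encode their lineage (e.g. `O1.F2.G1.sp2`), guaranteeing
#' uniqueness and making nested grouping unambiguous.
#'
#' @param cfg A [simulation_config()].
#' @return A tibble with columns species, genus, family, order.
#' @export
simulate_taxonomy <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  orders <- sprintf("O%d", seq_len(cfg$n_orders))
  out <- tidyr::expand_grid(
    order = orders,
    f = seq_len(cfg$families_per_order),
    g = seq_len(cfg$genera_per_family),
    s = seq_len(cfg$species_per_genus)
  )
  out$family <- paste0(out$order, ".F", out$f)
  out$genus <- paste0(out$family, ".G", out$g)
  out$species <- paste0(out$genus, ".sp", out$s)
  tibble::as_tibble(out[, c("species", "genus", "family", "order")])
}

#' Simulate wild leaf trait data with known variance components
#'
#' Each leaf value is built as grand mean + order + family + genus + species
#' + population effects + within-population noise, every effect drawn
#' zero-mean Gaussian with its configured variance. The population level is
#' the species x site cell; an optional directional `site_trend` is added to
#' population means in elevation order. Multiplicative traits (LA, LT, LDMC)
#' are generated on the log scale and exponentiated.
#'
#' @param cfg A [simulation_config()].
#' @param taxonomy Output of [simulate_taxonomy()].
#' @return A list with `data` (wild-leaf trait table) and `truth`
#'   (a `simulation_truth` recording all drawn effects, population means on
#'   the analysis scale, and configured plus realized variance proportions).
#' @export
simulate_trait_data <- function(cfg, taxonomy) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(stage_seed(cfg$seed, 2L))
  vc <- cfg$variance_components
  sites <- site_labels(cfg$n_sites)
  n_species <- nrow(taxonomy)
  per_trait <- list()
  rows <- list()
  for (tr in cfg$traits) {
    b_order <- stats::rnorm(cfg$n_orders, 0, sqrt(vc[["order"]]))
    names(b_order) <- unique(taxonomy$order)
    fams <- unique(taxonomy$family)
    b_family <- stats::rnorm(length(fams), 0, sqrt(vc[["family"]]))
    names(b_family) <- fams
    gens <- unique(taxonomy$genus)
    b_genus <- stats::rnorm(length(gens), 0, sqrt(vc[["genus"]]))
    names(b_genus) <- gens
    b_species <- stats::rnorm(n_species, 0, sqrt(vc[["species"]]))
    names(b_species) <- taxonomy$species

    pops <- tidyr::expand_grid(species = taxonomy$species, site = sites)
    pops$site_index <- match(pops$site, sites)
    b_pop <- stats::rnorm(nrow(pops), 0, sqrt(vc[["population"]]))
    pop_dev <- b_pop + cfg$site_trend * (pops$site_index - 1)
    tax_idx <- match(pops$species, taxonomy$species)
    pops$mu <- cfg$trait_grand_mean +
      b_order[taxonomy$order[tax_idx]] +
      b_family[taxonomy$family[tax_idx]] +
      b_genus[taxonomy$genus[tax_idx]] +
      b_species[pops$species] +
      pop_dev

    n_leaf <- cfg$leaves_per_species_site
    leaves <- pops[rep(seq_len(nrow(pops)), each = n_leaf), ]
    leaves$leaf_num <- rep(seq_len(n_leaf), times = nrow(pops))
    eps <- stats::rnorm(nrow(leaves), 0, sqrt(vc[["within"]]))
    latent <- leaves$mu + eps
    value <- if (tr %in% multiplicative_traits) exp(latent) else latent

    tx <- match(leaves$species, taxonomy$species)
    rows[[tr]] <- tibble::tibble(
      leaf_id = sprintf("wild-%s-%s-%d", leaves$site, leaves$species,
                        leaves$leaf_num),
      species = leaves$species,
      genus = taxonomy$genus[tx],
      family = taxonomy$family[tx],
      order = taxonomy$order[tx],
      site = leaves$site,
      plot_id = paste0(leaves$site, "-wild"),
      block = NA_character_,
      treatment = "wild",
      origin_site = leaves$site,
      trait = tr,
      value = value
    )

    # realized component = pooled within-parent variance of the drawn
    # effects: the estimand a nested decomposition of this one dataset can
    # actually recover (group means absorb the luck of the parent draw)
    pooled_var <- function(b, parent) {
      k <- length(b) - length(unique(parent))
      if (k <= 0) return(0)
      sum((b - stats::ave(b, parent))^2) / k
    }
    fam_parent <- taxonomy$order[match(fams, taxonomy$family)]
    gen_parent <- taxonomy$family[match(gens, taxonomy$genus)]
    realized <- c(
      order = pooled_var(b_order, rep("all", length(b_order))),
      family = pooled_var(b_family, fam_parent),
      genus = pooled_var(b_genus, gen_parent),
      species = pooled_var(b_species, taxonomy$genus),
      population = pooled_var(pop_dev, pops$species),
      within = pooled_var(eps, paste(leaves$species, leaves$site)))
    per_trait[[tr]] <- list(
      grand_mean = cfg$trait_grand_mean,
      effects = list(order = b_order, family = b_family, genus = b_genus,
                     species = b_species,
                     population = stats::setNames(pop_dev,
                                                  paste(pops$species, pops$site))),
      population_means = pops[, c("species", "site", "mu")],
      configured_components = vc,
      configured_proportions = if (sum(vc) > 0) vc / sum(vc) else vc,
      realized_components = realized,
      realized_proportions = if (sum(realized) > 0) realized / sum(realized) else realized
    )
  }
  truth <- structure(list(config = cfg, taxonomy = taxonomy,
                          traits = per_trait),
                     class = "simulation_truth")
  list(data = validate_trait_table(dplyr::bind_rows(rows)), truth = truth)
}

#' Simulate site community biomass
#'
#' Per site, species biomass shares are drawn from a symmetric
#' Dirichlet(alpha) and scaled to a fixed community total. Every species is
#' present at every site (shares are strictly positive with probability 1).
#'
#' @inheritParams simulate_trait_data
#' @return A community table (site, plot_id, species, biomass), one pooled
#'   community plot per site.
#' @export
simulate_communities <- function(cfg, taxonomy) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(stage_seed(cfg$seed, 3L))
  sites <- site_labels(cfg$n_sites)
  n_species <- nrow(taxonomy)
  out <- lapply(sites, function(s) {
    g <- stats::rgamma(n_species, shape = cfg$dirichlet_alpha, rate = 1)
    share <- g / sum(g)
    tibble::tibble(site = s, plot_id = paste0(s, "-comm"),
                   species = taxonomy$species,
                   biomass = share * cfg$plot_total)
  })
  validate_community_table(dplyr::bind_rows(out))
}

# biomass-weighted community mean and SD of population means, per trait x site
community_truth <- function(truth, communities) {
  sites <- unique(communities$site)
  w_tab <- dplyr::summarise(dplyr::group_by(communities, .data$site, .data$species),
                            biomass = sum(.data$biomass), .groups = "drop")
  out <- list()
  for (tr in names(truth$traits)) {
    pops <- truth$traits[[tr]]$population_means
    m <- dplyr::inner_join(pops, w_tab, by = c("species", "site"))
    comm <- dplyr::summarise(
      dplyr::group_by(m, .data$site),
      mean = sum(.data$biomass * .data$mu) / sum(.data$biomass),
      sd = sqrt(sum(.data$biomass * (.data$mu - sum(.data$biomass * .data$mu) /
                                       sum(.data$biomass))^2) / sum(.data$biomass)),
      .groups = "drop")
    comm$trait <- tr
    out[[tr]] <- comm
  }
  dplyr::bind_rows(out)[, c("trait", "site", "mean", "sd")]
}

#' Simulate the reciprocal transplant experiment
#'
#' Builds the blocked experimental design and its leaves. Per site and block
#' there is one untouched control plot and one locally transplanted control
#' plot (distributionally identical, matching the finding that local
#' transplantation itself leaves traits unchanged). Warmed plots receive a
#' turf moved one site down the gradient (origin = next-higher site); cooled
#' plots one site up. A transplanted leaf's expectation is the linear
#' interpolation `(1 - pi) * mu_origin + pi * dest_community_mean`, with
#' within-population noise; pi depends on the species' start-distance class
#' (|mu_origin - destination community mean| relative to the destination
#' community SD of population means).
#'
#' @inheritParams simulate_trait_data
#' @param truth A `simulation_truth` from [simulate_trait_data()].
#' @param communities A community table from [simulate_communities()].
#' @return A list with `data` (experimental-leaf trait table), `design`
#'   (site, block, plot_id, treatment, origin_site, destination_site) and
#'   the `truth` updated with per-site community means/SDs and each
#'   transplanted population's true pi.
#' @export
simulate_transplant_experiment <- function(cfg, truth, communities) {
  stopifnot(inherits(cfg, "simulation_config"),
            inherits(truth, "simulation_truth"))
  if (cfg$n_sites < 2) {
    stop("transplant experiment needs n_sites >= 2", call. = FALSE)
  }
  set.seed(stage_seed(cfg$seed, 4L))
  sites <- site_labels(cfg$n_sites)
  taxonomy <- truth$taxonomy

  blocks <- tidyr::expand_grid(site = sites, b = seq_len(cfg$n_blocks))
  blocks$block <- sprintf("%s-b%d", blocks$site, blocks$b)
  controls <- dplyr::bind_rows(
    tibble::tibble(site = blocks$site, block = blocks$block,
                   plot_id = paste0(blocks$block, "-C"),
                   treatment = "control",
                   origin_site = blocks$site, destination_site = blocks$site),
    tibble::tibble(site = blocks$site, block = blocks$block,
                   plot_id = paste0(blocks$block, "-LT"),
                   treatment = "local_transplant",
                   origin_site = blocks$site, destination_site = blocks$site))
  transplants <- list()
  for (d in seq_len(cfg$n_sites)) {
    dest <- sites[d]
    if (d < cfg$n_sites) {   # warmed: turf moved down from the site above
      o <- sites[d + 1]
      ob <- sprintf("%s-b%d", o, seq_len(cfg$n_blocks))
      transplants[[length(transplants) + 1]] <- tibble::tibble(
        site = dest, block = ob,
        plot_id = paste0(ob, "-W"),
        treatment = "warmed", origin_site = o, destination_site = dest)
    }
    if (d > 1) {             # cooled: turf moved up from the site below
      o <- sites[d - 1]
      ob <- sprintf("%s-b%d", o, seq_len(cfg$n_blocks))
      transplants[[length(transplants) + 1]] <- tibble::tibble(
        site = dest, block = ob,
        plot_id = paste0(ob, "-K"),
        treatment = "cooled", origin_site = o, destination_site = dest)
    }
  }
  design <- dplyr::bind_rows(controls, dplyr::bind_rows(transplants))

  comm <- community_truth(truth, communities)
  sigma_w <- sqrt(cfg$variance_components[["within"]])
  rows <- list()
  plasticity_truth <- list()
  for (tr in names(truth$traits)) {
    pops <- truth$traits[[tr]]$population_means
    mu_lookup <- stats::setNames(pops$mu, paste(pops$species, pops$site))
    ctr <- comm[comm$trait == tr, ]
    cmean <- stats::setNames(ctr$mean, ctr$site)
    csd <- stats::setNames(ctr$sd, ctr$site)

    leaves <- tidyr::expand_grid(design, species = taxonomy$species,
                                 leaf = seq_len(cfg$leaves_per_plot))
    mu_origin <- mu_lookup[paste(leaves$species, leaves$origin_site)]
    is_moved <- leaves$treatment %in% c("warmed", "cooled")
    dist_sd <- abs(mu_origin - cmean[leaves$destination_site]) /
      csd[leaves$destination_site]
    # a degenerate community (zero SD) puts every species in the near class
    cls <- ifelse(is.finite(dist_sd) & dist_sd > cfg$distance_threshold,
                  "far", "near")
    pi_leaf <- ifelse(is_moved, cfg$plasticity_pi[cls], 0)
    target <- (1 - pi_leaf) * mu_origin +
      pi_leaf * cmean[leaves$destination_site]
    latent <- stats::rnorm(nrow(leaves), target, sigma_w)
    value <- if (tr %in% multiplicative_traits) exp(latent) else latent

    tx <- match(leaves$species, taxonomy$species)
    rows[[tr]] <- tibble::tibble(
      leaf_id = sprintf("exp-%s-%s-%d", leaves$plot_id, leaves$species,
                        leaves$leaf),
      species = leaves$species,
      genus = taxonomy$genus[tx],
      family = taxonomy$family[tx],
      order = taxonomy$order[tx],
      site = leaves$site,
      plot_id = leaves$plot_id,
      block = leaves$block,
      treatment = leaves$treatment,
      origin_site = leaves$origin_site,
      trait = tr,
      value = value
    )

    moved <- unique(leaves[is_moved, c("species", "origin_site",
                                       "destination_site")])
    mo <- mu_lookup[paste(moved$species, moved$origin_site)]
    dsd <- abs(mo - cmean[moved$destination_site]) / csd[moved$destination_site]
    mcls <- ifelse(is.finite(dsd) & dsd > cfg$distance_threshold, "far", "near")
    plasticity_truth[[tr]] <- tibble::tibble(
      trait = tr, species = moved$species, origin_site = moved$origin_site,
      destination_site = moved$destination_site, mu_origin = unname(mo),
      distance_sd = unname(dsd), class = unname(mcls),
      pi = unname(cfg$plasticity_pi[mcls]))
  }
  truth$community <- comm
  truth$plasticity <- dplyr::bind_rows(plasticity_truth)
  list(data = validate_trait_table(dplyr::bind_rows(rows)),
       design = design, truth = truth)
}

#' Simulate a complete gradient + transplant dataset
#'
#' Convenience wrapper running [simulate_taxonomy()],
#' [simulate_trait_data()], [simulate_communities()] and
#' [simulate_transplant_experiment()] in sequence.
#'
#' @param cfg A [simulation_config()].
#' @return A list with elements `taxonomy`, `wild`, `experimental`, `traits`
#'   (wild and experimental leaves combined), `communities`, `design` and
#'   `truth`.
#' @export
simulate_dataset <- function(cfg) {
  taxonomy <- simulate_taxonomy(cfg)
  wild <- simulate_trait_data(cfg, taxonomy)
  communities <- simulate_communities(cfg, taxonomy)
  exp <- simulate_transplant_experiment(cfg, wild$truth, communities)
  list(taxonomy = taxonomy,
       wild = wild$data,
       experimental = exp$data,
       traits = dplyr::bind_rows(wild$data, exp$data),
       communities = communities,
       design = exp$design,
       truth = exp$truth)
}
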