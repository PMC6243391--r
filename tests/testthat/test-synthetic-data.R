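test_that("taxonomy is a balanced tree with unique species", {
  cfg <- simulation_config(n_orders = 2, families_per_order = 2,
                           genera_per_family = 2, species_per_genus = 2)
  tax <- simulate_taxonomy(cfg)
  expect_equal(nrow(tax), 16)
  expect_equal(anyDuplicated(tax$species), 0L)
  expect_equal(length(unique(tax$genus)), 8)
  expect_equal(length(unique(tax$family)), 4)
  expect_equal(length(unique(tax$order)), 2)

  single <- simulate_taxonomy(simulation_config(1, 1, 1, 1))
  expect_equal(nrow(single), 1)
})

test_that("generator output is a pure function of config and seed", {
  cfg <- simulation_config(n_blocks = 2, seed = 99)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$traits, b$traits)
  expect_identical(a$communities, b$communities)
  expect_identical(a$design, b$design)
  c <- simulate_dataset(simulation_config(n_blocks = 2, seed = 100))
  expect_false(identical(a$traits$value, c$traits$value))
})

test_that("degenerate variances collapse every leaf to the grand mean", {
  cfg <- simulation_config(
    variance_components = c(order = 0, family = 0, genus = 0, species = 0,
                            population = 0, within = 0),
    trait_grand_mean = 7, site_trend = 0, seed = 5)
  sim <- simulate_trait_data(cfg, simulate_taxonomy(cfg))
  expect_true(all(sim$data$value == 7))
})

test_that("within-only variance matches configured sigma^2 at large n", {
  cfg <- simulation_config(
    n_orders = 1, families_per_order = 1, genera_per_family = 1,
    species_per_genus = 1, n_sites = 1, leaves_per_species_site = 10000,
    variance_components = c(order = 0, family = 0, genus = 0, species = 0,
                            population = 0, within = 1),
    seed = 21)
  sim <- simulate_trait_data(cfg, simulate_taxonomy(cfg))
  expect_equal(nrow(sim$data), 10000)
  expect_lt(abs(stats::var(sim$data$value) - 1), 0.05)
})

test_that("multiplicative traits are generated on the log scale", {
  cfg <- simulation_config(
    variance_components = c(order = 0, family = 0, genus = 0, species = 0,
                            population = 0, within = 0),
    trait_grand_mean = 2, traits = "LDMC", seed = 5)
  sim <- simulate_trait_data(cfg, simulate_taxonomy(cfg))
  expect_true(all(sim$data$value == exp(2)))
})

test_that("communities are Dirichlet-structured and normalized", {
  cfg <- simulation_config(dirichlet_alpha = 1e6, plot_total = 100, seed = 3)
  tax <- simulate_taxonomy(cfg)
  comm <- simulate_communities(cfg, tax)
  shares <- comm$biomass / 100
  # alpha -> infinity limit: near-equal shares
  expect_true(all(abs(shares - 1 / nrow(tax)) < 0.001))
  totals <- tapply(comm$biomass, comm$site, sum)
  expect_true(all(abs(totals - 100) < 1e-9))
  expect_identical(comm, simulate_communities(cfg, tax))
})

test_that("realized variance proportions track configured ones at scale", {
  cfg <- simulation_config(n_orders = 4, families_per_order = 3,
                           genera_per_family = 3, species_per_genus = 3,
                           n_sites = 4, leaves_per_species_site = 10,
                           seed = 17)
  sim <- simulate_trait_data(cfg, simulate_taxonomy(cfg))
  tr <- sim$truth$traits[["SLA"]]
  expect_equal(sum(tr$realized_proportions), 1, tolerance = 1e-12)
  expect_equal(unname(tr$configured_proportions[["within"]]), 0.2)
  expect_lt(abs(tr$realized_proportions[["within"]] -
                  tr$configured_proportions[["within"]]), 0.05)
})

test_that("transplanted leaves interpolate toward the destination mean", {
  zero_vc <- c(order = 0, family = 0, genus = 0, species = 0,
               population = 0, within = 0)
  base <- function(pi) {
    simulation_config(n_sites = 2, n_blocks = 1, leaves_per_plot = 2,
                      variance_components = zero_vc, trait_grand_mean = 10,
                      site_trend = 5,
                      plasticity_pi = c(near = pi, far = pi), seed = 2)
  }
  run <- function(pi) {
    sim <- simulate_dataset(base(pi))
    sim$traits[sim$traits$treatment == "warmed", ]
  }
  # S1 populations sit at 10, S2 at 15; warmed turfs move S2 plants to S1,
  # whose community mean is exactly 10 under zero variance
  expect_true(all(run(0)$value == 15))
  expect_true(all(run(1)$value == 10))
  expect_true(all(run(0.5)$value == 12.5))
})

test_that("controls and local transplants share the origin distribution", {
  cfg <- simulation_config(n_blocks = 4, seed = 31)
  sim <- simulate_dataset(cfg)
  ctl <- sim$traits[sim$traits$treatment == "control", ]
  lt <- sim$traits[sim$traits$treatment == "local_transplant", ]
  expect_equal(nrow(ctl), nrow(lt))
  expect_true(all(lt$origin_site == lt$site))
  # same generating distribution: pooled means agree within sampling noise
  expect_lt(abs(mean(ctl$value) - mean(lt$value)),
            4 * stats::sd(ctl$value) / sqrt(nrow(ctl)))
})

test_that("warmed turfs originate one site higher, cooled one lower", {
  cfg <- simulation_config(n_sites = 3, n_blocks = 1, seed = 1)
  sim <- simulate_dataset(cfg)
  d <- sim$design
  w <- d[d$treatment == "warmed", ]
  k <- d[d$treatment == "cooled", ]
  site_num <- function(s) as.integer(sub("S", "", s))
  expect_true(all(site_num(w$origin_site) == site_num(w$destination_site) + 1))
  expect_true(all(site_num(k$origin_site) == site_num(k$destination_site) - 1))
  expect_error(simulate_dataset(simulation_config(n_sites = 1)),
               "n_sites >= 2")
})

test_that("truth records community means as biomass-weighted averages", {
  cfg <- simulation_config(seed = 13)
  sim <- simulate_dataset(cfg)
  pops <- sim$truth$traits[["SLA"]]$population_means
  comm <- sim$truth$community
  for (s in unique(comm$site)) {
    w <- sim$communities[sim$communities$site == s, ]
    mu <- pops[pops$site == s, ]
    m <- merge(w, mu, by = "species")
    expect_equal(comm$mean[comm$site == s],
                 sum(m$biomass * m$mu) / sum(m$biomass), tolerance = 1e-12)
  }
})
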