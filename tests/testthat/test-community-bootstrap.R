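pool_fixture <- function() {
  dplyr::bind_rows(
    make_leaves(c(10, 11, 12, 13, 14), species = "sp1", genus = "G1",
                site = "S1", treatment = "wild", plot_id = "S1-wild",
                leaf_prefix = "a"),
    make_leaves(c(20, 21), species = "sp2", genus = "G1", site = "S1",
                treatment = "wild", plot_id = "S1-wild", leaf_prefix = "b"),
    make_leaves(c(30, 31, 32), species = "sp1", genus = "G1", site = "S2",
                treatment = "wild", plot_id = "S2-wild", leaf_prefix = "c"),
    make_leaves(c(40), species = "sp3", genus = "G2", site = "S2",
                treatment = "wild", plot_id = "S2-wild", leaf_prefix = "d"),
    # manipulated leaves must never enter pools
    make_leaves(c(99, 98), species = "sp1", genus = "G1", site = "S1",
                treatment = "warmed", origin_site = "S2",
                plot_id = "S1-b1-W", leaf_prefix = "e"))
}

test_that("trait pools follow the four-rung priority hierarchy", {
  x <- pool_fixture()
  p1 <- select_trait_pool("sp1", "S1", x, "SLA")
  expect_equal(p1$source_level, "species_at_site")
  expect_setequal(p1$values, c(10, 11, 12, 13, 14))

  # sp4 shares genus G1: genus rung at the focal site with 2 congeners
  tax <- tibble::tibble(species = "sp4", genus = "G1")
  p2 <- select_trait_pool("sp4", "S1", x, "SLA", taxonomy = tax)
  expect_equal(p2$source_level, "genus_at_site")
  expect_length(p2$congener_groups, 2)

  # sp3 is absent from S1 and its genus has no other members: species rung
  # anywhere
  p3 <- select_trait_pool("sp3", "S1", x, "SLA")
  expect_equal(p3$source_level, "species_anywhere")
  expect_equal(p3$values, 40)

  # genus anywhere as last resort
  tax5 <- tibble::tibble(species = "sp5", genus = "G2")
  p4 <- select_trait_pool("sp5", "S1", x, "SLA", taxonomy = tax5)
  expect_equal(p4$source_level, "genus_anywhere")

  expect_null(select_trait_pool("sp9", "S1", x, "SLA",
                                taxonomy = tibble::tibble(species = "sp9",
                                                          genus = "G9")))
})

test_that("congener rarefaction equalizes congener sampling probability", {
  x <- dplyr::bind_rows(
    make_leaves(rep(1, 100), species = "abundans", genus = "G1", site = "S1",
                treatment = "wild", plot_id = "S1-wild", leaf_prefix = "a"),
    make_leaves(2, species = "rarus", genus = "G1", site = "S1",
                treatment = "wild", plot_id = "S1-wild", leaf_prefix = "b"))
  tax <- tibble::tibble(species = "focalis", genus = "G1")
  pool <- select_trait_pool("focalis", "S1", x, "SLA", taxonomy = tax)
  expect_equal(pool$source_level, "genus_at_site")
  set.seed(42)
  draws <- draw_individual(pool, 3e5)
  expect_lt(abs(mean(draws == 2) - 0.5), 0.01)
})

test_that("species pools are sampled uniformly with replacement", {
  pool <- select_trait_pool("sp1", "S1",
                            make_leaves(c(1, 2, 3), treatment = "wild",
                                        plot_id = "S1-wild"),
                            "SLA")
  set.seed(7)
  draws <- draw_individual(pool, 3e5)
  freq <- table(draws) / 3e5
  expect_true(all(abs(freq - 1 / 3) < 0.01))
  single <- select_trait_pool("sp1", "S1", make_leaves(5, treatment = "wild"),
                              "SLA")
  expect_equal(draw_individual(single, 10), rep(5, 10))
})

test_that("degenerate pools force the exact weighted mean with zero width", {
  x <- dplyr::bind_rows(
    make_leaves(10, species = "a", treatment = "wild", plot_id = "S1-wild",
                leaf_prefix = "a"),
    make_leaves(2, species = "b", treatment = "wild", plot_id = "S1-wild",
                leaf_prefix = "b"))
  comm <- tibble::tibble(site = "S1", plot_id = "p", species = c("a", "b"),
                         biomass = c(3, 1))
  r <- bootstrap_community_distribution("S1", "SLA", comm, x, B = 50,
                                        n_draws = 200, seed = 1)
  expect_true(all(r$replicate_means == 8))
  s <- summarize_bootstrap(r)
  expect_equal(c(s$mean, s$ci_low, s$ci_high), c(8, 8, 8))
  expect_equal(s$coverage, 1)
})

test_that("a single-species community reduces to a plain bootstrap", {
  x <- make_leaves(c(4, 6, 8, 10), treatment = "wild", plot_id = "S1-wild")
  comm <- tibble::tibble(site = "S1", plot_id = "p", species = "sp1",
                         biomass = 5)
  r <- bootstrap_community_distribution("S1", "SLA", comm, x, B = 500,
                                        n_draws = 4, seed = 2)
  expect_true(all(r$replicate_means >= 4 & r$replicate_means <= 10))
  expect_gt(stats::sd(r$replicate_means), 0)
  expect_lt(abs(mean(r$replicate_means) - 7), 0.3)
})

test_that("uncovered species biomass is renormalized and reported", {
  x <- make_leaves(c(10, 12), species = "a", treatment = "wild",
                   plot_id = "S1-wild")
  comm <- tibble::tibble(site = "S1", plot_id = "p",
                         species = c("a", "ghost"), biomass = c(6, 2))
  r <- bootstrap_community_distribution("S1", "SLA", comm, x, B = 20,
                                        n_draws = 10, seed = 3)
  expect_equal(r$coverage, 0.75)
  expect_true(all(r$replicate_means >= 10 & r$replicate_means <= 12))

  none <- tibble::tibble(site = "S1", plot_id = "p", species = "ghost",
                         biomass = 2)
  expect_error(bootstrap_community_distribution("S1", "SLA", none, x),
               "S1.*SLA")
})

test_that("results are invariant to rescaling all biomass", {
  sim <- simulate_dataset(simulation_config(n_blocks = 1, seed = 8))
  comm2 <- sim$communities
  comm2$biomass <- comm2$biomass * 1000
  a <- bootstrap_community_distribution("S1", "SLA", sim$communities,
                                        sim$wild, B = 50, n_draws = 60,
                                        seed = 4)
  b <- bootstrap_community_distribution("S1", "SLA", comm2, sim$wild,
                                        B = 50, n_draws = 60, seed = 4)
  expect_equal(a$replicate_means, b$replicate_means)
})

test_that("the same seed reproduces replicate means exactly", {
  sim <- simulate_dataset(simulation_config(n_blocks = 1, seed = 9))
  a <- bootstrap_community_distribution("S2", "SLA", sim$communities,
                                        sim$wild, B = 30, n_draws = 50,
                                        seed = 11)
  b <- bootstrap_community_distribution("S2", "SLA", sim$communities,
                                        sim$wild, B = 30, n_draws = 50,
                                        seed = 11)
  expect_identical(a$replicate_means, b$replicate_means)
})

test_that("summaries use linear-interpolation percentile intervals", {
  r <- structure(list(site = "S1", trait = "SLA",
                      replicate_means = as.numeric(1:1000),
                      n_draws_per_replicate = 10, B = 1000, weighted = TRUE,
                      coverage = 1, source_levels = NULL, seed = NULL),
                 class = "bootstrap_result")
  s <- summarize_bootstrap(r, level = 0.95)
  expect_equal(s$ci_low, 25.975)
  expect_equal(s$ci_high, 975.025)
  expect_equal(s$mean, 500.5)

  s0 <- summarize_bootstrap(r, level = 0)
  expect_equal(s0$ci_low, s0$ci_high)
  expect_equal(s0$ci_low, stats::median(r$replicate_means))

  const <- r
  const$replicate_means <- rep(3.5, 100)
  sc <- summarize_bootstrap(const)
  expect_equal(c(sc$mean, sc$ci_low, sc$ci_high), c(3.5, 3.5, 3.5))
})

test_that("largest-remainder allocation is exact and deterministic", {
  alloc <- turftraits:::largest_remainder_allocation
  expect_equal(alloc(c(0.75, 0.25), 200), c(150L, 50L))
  w <- c(0.4, 0.35, 0.25)
  expect_equal(sum(alloc(w, 7)), 7L)
  expect_equal(alloc(w, 7), alloc(w, 7))
  # representation error is below one draw per species
  expect_true(all(abs(alloc(w, 7) - w * 7) < 1))
})
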