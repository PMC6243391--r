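design_fixture <- function() {
  tibble::tibble(
    site = c("S2", "S2", "S1", "S3"),
    block = c("S2-b1", "S2-b1", "S2-b1", "S2-b1"),
    plot_id = c("S2-b1-C", "S2-b1-LT", "S2-b1-W", "S2-b1-K"),
    treatment = c("control", "local_transplant", "warmed", "cooled"),
    origin_site = c("S2", "S2", "S2", "S2"),
    destination_site = c("S2", "S2", "S1", "S3"))
}

test_that("transplant plots pair with the control plots of their origin block", {
  pairs <- pair_plots(design_fixture())
  expect_equal(nrow(pairs), 2)
  w <- pairs[pairs$treatment == "warming", ]
  expect_equal(w$transplant_plot, "S2-b1-W")
  expect_setequal(w$home_plots[[1]], c("S2-b1-C", "S2-b1-LT"))
  expect_equal(pairs$treatment[pairs$transplant_plot == "S2-b1-K"],
               "cooling")
})

test_that("orphan transplant plots are dropped with a warning", {
  d <- design_fixture()[3, ]
  expect_warning(pairs <- pair_plots(d), "no control-type plot")
  expect_equal(nrow(pairs), 0)
  dup <- design_fixture()[c(1, 1), ]
  expect_error(pair_plots(dup), "duplicate")
})

test_that("a full blocked design yields one pair per transplanted turf", {
  sim <- simulate_dataset(simulation_config(n_sites = 4, n_blocks = 7,
                                            seed = 3))
  pairs <- pair_plots(sim$design)
  # 3 adjacent site pairs x 2 directions x 7 blocks
  expect_equal(nrow(pairs), 42)
  expect_true(all(lengths(pairs$home_plots) == 2))
})

test_that("the relative plasticity index follows its defining formula", {
  mk <- function(home_vals, turf_vals, trait = "SLA") {
    dplyr::bind_rows(
      make_leaves(home_vals, trait = trait, site = "S2",
                  plot_id = "S2-b1-C", block = "S2-b1",
                  treatment = "control", origin_site = "S2",
                  leaf_prefix = paste0("h", trait)),
      make_leaves(turf_vals, trait = trait, site = "S1",
                  plot_id = "S2-b1-W", block = "S2-b1",
                  treatment = "warmed", origin_site = "S2",
                  leaf_prefix = paste0("t", trait)))
  }
  pairs <- pair_plots(design_fixture())
  # H = 2, T = 1 -> 0.5
  r1 <- compute_plasticity(mk(2, 1), pairs)
  expect_equal(r1$P_R, 0.5)
  expect_equal(r1$H, 2)
  expect_equal(r1$T, 1)
  # H = T -> 0
  r2 <- compute_plasticity(mk(c(3, 5), c(3, 5)), pairs)
  expect_equal(r2$P_R, 0)
  # negative trait values (d13C-like): H = -28, T = -21 -> 0.25
  r3 <- compute_plasticity(mk(-28, -21, trait = "d13C"), pairs)
  expect_equal(r3$P_R, 0.25)
})

test_that("H = 0 yields an undefined-flagged record, not an error", {
  x <- dplyr::bind_rows(
    make_leaves(c(-1, 1), trait = "d15N", site = "S2", plot_id = "S2-b1-C",
                block = "S2-b1", treatment = "control", leaf_prefix = "h"),
    make_leaves(2, trait = "d15N", site = "S1", plot_id = "S2-b1-W",
                block = "S2-b1", treatment = "warmed", origin_site = "S2",
                leaf_prefix = "t"))
  r <- compute_plasticity(x, pair_plots(design_fixture()))
  expect_false(r$pr_defined)
  expect_true(is.na(r$P_R))
})

test_that("leaves are averaged to plot-level species means before the index", {
  # home plots: control mean 10, local-transplant mean 20 -> H = 15 (plot
  # means weighted equally, not leaf counts)
  x <- dplyr::bind_rows(
    make_leaves(c(10, 10, 10), site = "S2", plot_id = "S2-b1-C",
                block = "S2-b1", treatment = "control", leaf_prefix = "c"),
    make_leaves(20, site = "S2", plot_id = "S2-b1-LT", block = "S2-b1",
                treatment = "local_transplant", leaf_prefix = "lt"),
    make_leaves(c(30, 0), site = "S1", plot_id = "S2-b1-W", block = "S2-b1",
                treatment = "warmed", origin_site = "S2", leaf_prefix = "w"))
  r <- compute_plasticity(x, pair_plots(design_fixture()))
  expect_equal(r$H, 15)
  expect_equal(r$T, 15)
  expect_equal(r$P_R, 0)
  expect_equal(r$n_home, 4L)
  expect_equal(r$n_transplant, 2L)
})

test_that("P_R is scale invariant but not shift invariant", {
  sim <- simulate_dataset(simulation_config(n_blocks = 2, seed = 12))
  pairs <- pair_plots(sim$design)
  a <- compute_plasticity(sim$traits, pairs)
  scaled <- sim$traits
  scaled$value <- scaled$value * 12.5
  b <- compute_plasticity(scaled, pairs)
  expect_equal(b$P_R, a$P_R, tolerance = 1e-12)
  shifted <- sim$traits
  shifted$value <- shifted$value + 100
  c_ <- compute_plasticity(shifted, pairs)
  expect_gt(max(abs(c_$P_R - a$P_R)), 1e-4)
})

test_that("identical plasticity across arms gives p = 1", {
  records <- tibble::tibble(
    species = rep(c("a", "b"), each = 4),
    trait = "SLA",
    block = rep(c("b1", "b2"), 4),
    origin_site = "S2", destination_site = "S1",
    treatment = rep(c("warming", "cooling"), 4),
    transplant_plot = paste0("p", 1:8),
    H = 10, T = 12, P_R = 0.2,
    n_home = 3L, n_transplant = 3L, pr_defined = TRUE)
  res <- compare_plasticity(records, n_perm = 199, seed = 1)
  expect_equal(res$p_value, 1)
  expect_equal(res$statistic, 0)
})

test_that("permutation p values are deterministic given a seed", {
  sim <- simulate_dataset(simulation_config(n_blocks = 3, seed = 14))
  rec <- compute_plasticity(sim$traits, pair_plots(sim$design))
  a <- compare_plasticity(rec, n_perm = 199, seed = 77)
  b <- compare_plasticity(rec, n_perm = 199, seed = 77)
  expect_identical(a, b)
})

test_that("a one-armed trait is skipped with a warning", {
  records <- tibble::tibble(
    species = "a", trait = "SLA", block = c("b1", "b2"),
    origin_site = "S2", destination_site = "S1",
    treatment = "warming", transplant_plot = c("p1", "p2"),
    H = 10, T = 12, P_R = 0.2, n_home = 3L, n_transplant = 3L,
    pr_defined = TRUE)
  expect_warning(res <- compare_plasticity(records, n_perm = 49, seed = 1),
                 "skipped")
  expect_equal(nrow(res), 0)
})

test_that("null permutation p values are approximately uniform", {
  # no plasticity anywhere: the warming/cooling contrast is pure noise
  ps <- vapply(1:200, function(i) {
    cfg <- simulation_config(
      n_orders = 1, families_per_order = 1, genera_per_family = 2,
      species_per_genus = 2, n_sites = 3, leaves_per_plot = 3,
      n_blocks = 2, plasticity_pi = c(near = 0, far = 0), seed = 5000 + i)
    sim <- simulate_dataset(cfg)
    rec <- compute_plasticity(sim$traits, pair_plots(sim$design))
    compare_plasticity(rec, n_perm = 199, seed = i)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_gt(mean(ps <= 1), 1 - 1e-12)  # p in (0, 1]
  expect_true(all(ps > 0))
})

test_that("log display transform drops exact zeros with a count", {
  records <- tibble::tibble(
    species = "a", trait = "SLA", block = "b1", origin_site = "S2",
    destination_site = "S1", treatment = "warming",
    transplant_plot = c("p1", "p2"), H = c(10, 10), T = c(10, 12),
    P_R = c(0, 0.2), n_home = 2L, n_transplant = 2L,
    pr_defined = TRUE)
  lg <- log_plasticity(records)
  expect_equal(lg$n_zero_dropped, 1)
  expect_equal(lg$records$log_P_R, log(0.2))
})
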