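#' Home-site summary of a species' trait under unmanipulated conditions
#'
#' Mean, sample SD and exact central t-distribution confidence interval
#' (default 99%) of a species' trait at a site, over unmanipulated leaves.
#' A transplanted population whose mean falls outside this interval is
#' judged to have shown a significant plastic response.
#'
#' @param x A trait table; restricted internally to unmanipulated
#'   treatments.
#' @param species,site,trait The species x site x trait cell to summarize.
#' @param level Confidence level (default 0.99).
#' @return A `home_summary` list: species, site, trait, mean, sd, n,
#'   ci_low, ci_high, level.
#' @export
summarize_home <- function(x, species, site, trait, level = 0.99) {
  x <- unmanipulated(validate_trait_table(x))
  v <- x$value[x$species == species & x$site == site & x$trait == trait]
  n <- length(v)
  if (n < 2) {
    stop("insufficient data: need >= 2 unmanipulated leaves for ", species,
         " at ", site, " (", trait, "), got ", n, call. = FALSE)
  }
  m <- mean(v)
  s <- stats::sd(v)
  tq <- stats::qt(1 - (1 - level) / 2, df = n - 1)
  half <- tq * s / sqrt(n)
  structure(list(species = species, site = site, trait = trait,
                 mean = m, sd = s, n = n,
                 ci_low = m - half, ci_high = m + half, level = level),
            class = "home_summary")
}

#' Classify one transplant observation as converging, diverging or unchanged
#'
#' A transplanted population's mean `T_mean` is compared with its home-site
#' summary. Inside the home confidence interval the outcome is `no_change`
#' (no significant plastic response). Outside it, the population is
#' `converging` when it ends up closer to the destination community mean
#' than its home mean was, `diverging` otherwise (ties count as diverging).
#' The start group records whether the home mean lay closer to the home or
#' to the destination community mean before transplantation (ties count as
#' home).
#'
#' @param T_mean Mean trait value in the transplanted turf.
#' @param home A `home_summary` for the species at its origin site.
#' @param home_comm_mean,dest_comm_mean Community trait means (typically
#'   biomass-weighted bootstrap means) of the origin and destination sites.
#' @return A one-row tibble: outcome (`converging`/`diverging`/`no_change`),
#'   start_group (`home`/`destination`), T_mean, H_mean, home_comm_mean,
#'   dest_comm_mean.
#' @export
classify_transplant <- function(T_mean, home, home_comm_mean,
                                dest_comm_mean) {
  stopifnot(inherits(home, "home_summary"))
  if (!is.finite(home_comm_mean) || !is.finite(dest_comm_mean)) {
    stop("community means must be finite", call. = FALSE)
  }
  H_mean <- home$mean
  outcome <- if (T_mean >= home$ci_low && T_mean <= home$ci_high) {
    "no_change"
  } else if (abs(T_mean - dest_comm_mean) < abs(H_mean - dest_comm_mean)) {
    "converging"
  } else {
    "diverging"
  }
  start_group <- if (abs(H_mean - dest_comm_mean) <
                       abs(H_mean - home_comm_mean)) "destination" else "home"
  tibble::tibble(outcome = outcome, start_group = start_group,
                 T_mean = T_mean, H_mean = H_mean,
                 home_comm_mean = home_comm_mean,
                 dest_comm_mean = dest_comm_mean)
}

#' Classify every transplanted species x trait x turf observation
#'
#' Applies [summarize_home()] and [classify_transplant()] across a dataset:
#' for each warmed/cooled turf, each species x trait with at least one leaf
#' in the turf and at least two unmanipulated leaves at the origin site is
#' classified against the origin- and destination-site community means.
#'
#' @param x A trait table (experimental and unmanipulated leaves together).
#' @param design The experiment design table.
#' @param community_means A tibble with columns site, trait, mean — e.g.
#'   the output of [bootstrap_all_communities()].
#' @param level Confidence level for home intervals (default 0.99).
#' @return A tibble of convergence records: species, trait, turf,
#'   treatment (`warming`/`cooling`), start_group, outcome, T_mean, H_mean,
#'   home_comm_mean, dest_comm_mean, n_home, n_turf. Observations lacking a
#'   usable home summary or a community mean are skipped and counted in the
#'   `n_skipped` attribute.
#' @export
classify_all_transplants <- function(x, design, community_means,
                                     level = 0.99) {
  x <- validate_trait_table(x)
  design <- tibble::as_tibble(design)
  moved <- design[design$treatment %in% c("warmed", "cooled"), , drop = FALSE]
  unman <- unmanipulated(x)
  cm_key <- paste(community_means$site, community_means$trait)
  cm <- stats::setNames(community_means$mean, cm_key)

  # site-level home summaries for every species x origin-site x trait needed
  turf_leaves <- x[x$plot_id %in% moved$plot_id, , drop = FALSE]
  turf_means <- dplyr::summarise(
    dplyr::group_by(turf_leaves, .data$plot_id, .data$species, .data$trait),
    T_mean = mean(.data$value), n_turf = dplyr::n(), .groups = "drop")
  turf_means <- dplyr::left_join(
    turf_means,
    moved[, c("plot_id", "treatment", "origin_site", "destination_site")],
    by = "plot_id")

  home_stats <- dplyr::summarise(
    dplyr::group_by(unman, .data$species, .data$site, .data$trait),
    H_mean = mean(.data$value), H_sd = stats::sd(.data$value),
    n_home = dplyr::n(), .groups = "drop")

  m <- dplyr::left_join(
    turf_means, home_stats,
    by = c("species", "trait", "origin_site" = "site"))
  m$home_comm_mean <- unname(cm[paste(m$origin_site, m$trait)])
  m$dest_comm_mean <- unname(cm[paste(m$destination_site, m$trait)])

  usable <- !is.na(m$n_home) & m$n_home >= 2 &
    is.finite(m$home_comm_mean) & is.finite(m$dest_comm_mean)
  n_skipped <- sum(!usable)
  m <- m[usable, , drop = FALSE]
  tq <- stats::qt(1 - (1 - level) / 2, df = m$n_home - 1)
  half <- tq * m$H_sd / sqrt(m$n_home)
  inside <- m$T_mean >= m$H_mean - half & m$T_mean <= m$H_mean + half
  closer <- abs(m$T_mean - m$dest_comm_mean) < abs(m$H_mean - m$dest_comm_mean)
  out <- tibble::tibble(
    species = m$species, trait = m$trait, turf = m$plot_id,
    treatment = ifelse(m$treatment == "warmed", "warming", "cooling"),
    start_group = ifelse(abs(m$H_mean - m$dest_comm_mean) <
                           abs(m$H_mean - m$home_comm_mean),
                         "destination", "home"),
    outcome = ifelse(inside, "no_change",
                     ifelse(closer, "converging", "diverging")),
    T_mean = m$T_mean, H_mean = m$H_mean,
    home_comm_mean = m$home_comm_mean, dest_comm_mean = m$dest_comm_mean,
    n_home = m$n_home, n_turf = m$n_turf)
  attr(out, "n_skipped") <- n_skipped
  attr(out, "level") <- level
  out
}

outcome_levels <- c("converging", "diverging", "no_change")

#' Cross-tabulate convergence outcomes against a binary grouping
#'
#' Builds the 3 x 2 contingency table of outcome class (converging,
#' diverging, no_change) against either the start group (home/destination)
#' or the treatment (warming/cooling). Factor levels are fixed, so empty
#' cells are retained as zeros.
#'
#' @param records Output of [classify_all_transplants()].
#' @param column_factor `"start_group"` or `"treatment"`.
#' @return An integer matrix with outcome rows and factor-level columns.
#' @export
tabulate_outcomes <- function(records,
                              column_factor = c("start_group", "treatment")) {
  column_factor <- match.arg(column_factor)
  if (nrow(records) == 0) stop("no records to tabulate", call. = FALSE)
  cols <- switch(column_factor,
                 start_group = c("home", "destination"),
                 treatment = c("warming", "cooling"))
  tab <- table(factor(records$outcome, levels = outcome_levels),
               factor(records[[column_factor]], levels = cols))
  m <- matrix(as.integer(tab), nrow = length(outcome_levels),
              dimnames = list(outcome = outcome_levels,
                              group = cols))
  m
}

#' G-test (log-likelihood ratio test) of independence
#'
#' Computes G = 2 * sum O_ij * ln(O_ij / E_ij) with the convention
#' 0 * ln(0) = 0, expected counts E_ij = row total x column total / grand
#' total, df = (rows - 1)(cols - 1), and an upper-tail chi-square p-value.
#' All-zero rows or columns are dropped (with a warning) and df adjusted.
#'
#' @param tab A matrix of nonnegative counts.
#' @return A `g_test` list: statistic (G), df, p.value, observed, expected.
#' @export
g_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (sum(tab) == 0) stop("grand total must be > 0", call. = FALSE)
  zero_rows <- rowSums(tab) == 0
  zero_cols <- colSums(tab) == 0
  if (any(zero_rows) || any(zero_cols)) {
    warning("dropping ", sum(zero_rows), " all-zero row(s) and ",
            sum(zero_cols), " all-zero column(s)", call. = FALSE)
    tab <- tab[!zero_rows, !zero_cols, drop = FALSE]
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stop("independence is undefined for a 1 x k table", call. = FALSE)
  }
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  terms <- ifelse(tab > 0, tab * log(tab / E), 0)
  G <- 2 * sum(terms)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  structure(list(statistic = G, df = df,
                 p.value = stats::pchisq(G, df, lower.tail = FALSE),
                 observed = tab, expected = E),
            class = "g_test")
}

#' @export
print.g_test <- function(x, ...) {
  cat("G-test of independence\n")
  cat(sprintf("  G = %.4f, df = %d, p = %.4g\n", x$statistic, x$df,
              x$p.value))
  invisible(x)
}
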