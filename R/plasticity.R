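#' Pair transplanted turfs with their home control plots
#'
#' Comparisons are made only within blocks, so that microtopographic and
#' microclimatic variation does not masquerade as plasticity. Each warmed or
#' cooled turf is paired with the control and local-transplant plots of the
#' block it originated from (both plot types serve as controls). Transplant
#' plots whose origin block has no control-type plot are dropped with a
#' warning.
#'
#' @param design A design table with columns site, block, plot_id,
#'   treatment, origin_site, destination_site.
#' @return A tibble with one row per transplanted turf: transplant_plot,
#'   treatment (`warming`/`cooling`), block, origin_site, destination_site
#'   and a list-column `home_plots` of control-type plot ids.
#' @export
pair_plots <- function(design) {
  design <- tibble::as_tibble(design)
  needed <- c("site", "block", "plot_id", "treatment", "origin_site",
              "destination_site")
  missing_cols <- setdiff(needed, names(design))
  if (length(missing_cols) > 0) {
    stop("design table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(design$plot_id)) {
    stop("duplicate plot ids in design table", call. = FALSE)
  }
  controls <- design[design$treatment %in% c("control", "local_transplant"), ]
  moved <- design[design$treatment %in% c("warmed", "cooled"), ]
  if (nrow(moved) == 0) {
    return(tibble::tibble(transplant_plot = character(), treatment = character(),
                          block = character(), origin_site = character(),
                          destination_site = character(),
                          home_plots = list()))
  }
  home <- lapply(seq_len(nrow(moved)), function(i) {
    controls$plot_id[controls$block == moved$block[i] &
                       controls$site == moved$origin_site[i]]
  })
  n_home <- lengths(home)
  if (any(n_home == 0)) {
    warning(sum(n_home == 0),
            " transplant plot(s) dropped: no control-type plot in their ",
            "origin block", call. = FALSE)
  }
  keep <- n_home > 0
  tibble::tibble(
    transplant_plot = moved$plot_id[keep],
    treatment = ifelse(moved$treatment[keep] == "warmed", "warming", "cooling"),
    block = moved$block[keep],
    origin_site = moved$origin_site[keep],
    destination_site = moved$destination_site[keep],
    home_plots = home[keep]
  )
}

#' Relative plasticity of transplanted populations
#'
#' For every species x trait present both in a transplanted turf and in the
#' control plots of its origin block, computes the simplified relative
#' distance plasticity index
#' \deqn{P_R = \left| \frac{|H - T|}{H} \right|}
#' where `H` is the mean trait value of conspecifics in the home control
#' plots and `T` the mean in the transplanted turf. The inner absolute value
#' standardizes the direction of the shift; the outer one handles traits
#' with negative values (delta 13C). Leaves are first averaged to plot-level
#' species means; `H` averages those means across the block's control-type
#' plots.
#'
#' @param x A trait table containing the experimental leaves.
#' @param pairs Output of [pair_plots()].
#' @return A tibble of plasticity records: species, trait, block,
#'   origin_site, destination_site, treatment, H, T, P_R, n_home,
#'   n_transplant, pr_defined (FALSE where H = 0 leaves the index
#'   undefined).
#' @export
compute_plasticity <- function(x, pairs) {
  x <- validate_trait_table(x)
  recs <- lapply(seq_len(nrow(pairs)), function(i) {
    p <- pairs[i, ]
    home_leaves <- x[x$plot_id %in% p$home_plots[[1]], , drop = FALSE]
    turf_leaves <- x[x$plot_id == p$transplant_plot, , drop = FALSE]
    if (nrow(home_leaves) == 0 || nrow(turf_leaves) == 0) return(NULL)
    home_plot_means <- dplyr::summarise(
      dplyr::group_by(home_leaves, .data$species, .data$trait, .data$plot_id),
      m = mean(.data$value), n = dplyr::n(), .groups = "drop")
    home_means <- dplyr::summarise(
      dplyr::group_by(home_plot_means, .data$species, .data$trait),
      H = mean(.data$m), n_home = sum(.data$n), .groups = "drop")
    turf_means <- dplyr::summarise(
      dplyr::group_by(turf_leaves, .data$species, .data$trait),
      T = mean(.data$value), n_transplant = dplyr::n(), .groups = "drop")
    m <- dplyr::inner_join(home_means, turf_means, by = c("species", "trait"))
    if (nrow(m) == 0) return(NULL)
    m$block <- p$block
    m$origin_site <- p$origin_site
    m$destination_site <- p$destination_site
    m$treatment <- p$treatment
    m$transplant_plot <- p$transplant_plot
    m
  })
  out <- dplyr::bind_rows(recs)
  if (nrow(out) == 0) {
    return(tibble::tibble(species = character(), trait = character(),
                          block = character(), origin_site = character(),
                          destination_site = character(),
                          treatment = character(),
                          transplant_plot = character(),
                          H = numeric(), T = numeric(), P_R = numeric(),
                          n_home = integer(), n_transplant = integer(),
                          pr_defined = logical()))
  }
  out$pr_defined <- out$H != 0
  out$P_R <- ifelse(out$pr_defined, abs(abs(out$H - out$T) / out$H), NA_real_)
  out[, c("species", "trait", "block", "origin_site", "destination_site",
          "treatment", "transplant_plot", "H", "T", "P_R", "n_home",
          "n_transplant", "pr_defined")]
}

#' Compare plasticity between warming and cooling transplants
#'
#' Per trait, tests whether the mean relative plasticity differs between
#' cooling and warming transplants with a stratified permutation test:
#' treatment labels are shuffled within species x origin-site strata,
#' respecting the grouping structure under which repeated measures of the
#' same population arise. The observed statistic is
#' mean(P_R | cooling) - mean(P_R | warming), and
#' p = (1 + #\{|null| >= |observed|\}) / (1 + n_perm). Records with an
#' undefined index (H = 0) are excluded.
#'
#' @param records Output of [compute_plasticity()].
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed.
#' @return A tibble with one row per testable trait: trait,
#'   mean_PR_warming, mean_PR_cooling, statistic, p_value, n_warming,
#'   n_cooling, n_perm, seed. Traits with an empty arm are skipped with a
#'   warning.
#' @export
compare_plasticity <- function(records, n_perm = 999, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  records <- records[records$pr_defined, , drop = FALSE]
  out <- list()
  for (tr in unique(records$trait)) {
    r <- records[records$trait == tr, , drop = FALSE]
    n_w <- sum(r$treatment == "warming")
    n_c <- sum(r$treatment == "cooling")
    if (n_w < 2 || n_c < 2) {
      warning("trait ", tr, " skipped: fewer than 2 records per arm",
              call. = FALSE)
      next
    }
    obs <- mean(r$P_R[r$treatment == "cooling"]) -
      mean(r$P_R[r$treatment == "warming"])
    strata <- split(seq_len(nrow(r)), paste(r$species, r$origin_site))
    is_cooling <- r$treatment == "cooling"
    null_stats <- vapply(seq_len(n_perm), function(k) {
      perm <- logical(nrow(r))
      for (idx in strata) {
        perm[idx] <- is_cooling[idx][sample.int(length(idx))]
      }
      # a permutation may empty an arm; such draws carry no information
      if (!any(perm) || all(perm)) return(NA_real_)
      mean(r$P_R[perm]) - mean(r$P_R[!perm])
    }, numeric(1))
    null_stats <- null_stats[!is.na(null_stats)]
    p <- (1 + sum(abs(null_stats) >= abs(obs))) / (1 + length(null_stats))
    out[[tr]] <- tibble::tibble(
      trait = tr,
      mean_PR_warming = mean(r$P_R[r$treatment == "warming"]),
      mean_PR_cooling = mean(r$P_R[r$treatment == "cooling"]),
      statistic = obs, p_value = p,
      n_warming = n_w, n_cooling = n_c,
      n_perm = length(null_stats),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
  }
  if (length(out) == 0) {
    return(tibble::tibble(trait = character(), mean_PR_warming = numeric(),
                          mean_PR_cooling = numeric(), statistic = numeric(),
                          p_value = numeric(), n_warming = integer(),
                          n_cooling = integer(), n_perm = integer(),
                          seed = integer()))
  }
  dplyr::bind_rows(out)
}

#' Log-transformed plasticity values for display
#'
#' The index is displayed on the natural-log scale; exact zeros (no shift at
#' all) have no logarithm and are dropped, with their count reported.
#'
#' @param records Output of [compute_plasticity()].
#' @return A list with `records` (with a `log_P_R` column, zero-P_R rows
#'   removed) and `n_zero_dropped`.
#' @export
log_plasticity <- function(records) {
  records <- records[records$pr_defined, , drop = FALSE]
  zero <- records$P_R == 0
  kept <- records[!zero, , drop = FALSE]
  kept$log_P_R <- log(kept$P_R)
  list(records = kept, n_zero_dropped = sum(zero))
}
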