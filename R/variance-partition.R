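varpart_levels <- c("order", "family", "genus", "species", "population",
                    "within")

#' Partition trait variance across nested taxonomic levels
#'
#' Decomposes the variance of a trait among wild/unmanipulated leaves into
#' components at the order, family, genus, species, population
#' (species x site cell) and within-population levels, treating taxonomy as
#' a proxy phylogeny. Two estimators are available:
#'
#' * `"reml"` (default): a nested random-intercept model fitted by REML,
#'   robust to the strong imbalance of field data (singleton species,
#'   uneven site coverage).
#' * `"moments"`: a hierarchical method-of-moments estimator built from the
#'   sequential group-mean decomposition. At each level the mean square of
#'   group means around their parent-group means is formed, and components
#'   are recovered from differences of successive mean squares via the
#'   balanced expected-mean-squares relations (E[MS_j] = sigma^2_within +
#'   sum over levels l at or below j of m_l * sigma^2_l, with m_l the
#'   leaves per group). Intended for (near-)balanced designs, where it is
#'   unbiased; it serves as an independent cross-check of the REML fit.
#'
#' Negative component estimates are truncated to zero before proportions
#' are formed. Multiplicative traits should be log transformed first (see
#' [log_transform_multiplicative()]).
#'
#' @param x A trait table of leaves grown under unmanipulated conditions.
#' @param trait Which trait to partition.
#' @param estimator `"reml"` or `"moments"`.
#' @return A `variance_partition`: a tibble with one row per level
#'   (`level`, `variance`, `proportion`, `degenerate`), plus attributes
#'   `trait`, `n_leaves`, `estimator`. Levels realized with fewer than two
#'   groups (no estimable variance) are flagged `degenerate` and reported
#'   as proportion 0.
#' @export
partition_variance <- function(x, trait, estimator = c("reml", "moments")) {
  estimator <- match.arg(estimator)
  x <- validate_trait_table(x)
  x <- x[x$trait == trait, , drop = FALSE]
  if (nrow(x) < 2) {
    stop("insufficient data: need >= 2 leaves for trait ", trait,
         call. = FALSE)
  }
  tax_cols <- c("order", "family", "genus", "species", "site")
  if (anyNA(x[tax_cols])) {
    stop("taxonomy/site columns must be complete for variance partitioning",
         call. = FALSE)
  }
  # nested labels: identical child names under different parents stay distinct
  d <- data.frame(
    y = x$value,
    order = x$order,
    family = paste(x$order, x$family, sep = "/"),
    genus = paste(x$order, x$family, x$genus, sep = "/"),
    species = paste(x$order, x$family, x$genus, x$species, sep = "/"),
    stringsAsFactors = FALSE
  )
  d$population <- paste(d$species, x$site, sep = "@")

  comps <- switch(estimator,
                  reml = varpart_reml(d),
                  moments = varpart_moments(d))
  comps$variance <- pmax(comps$variance, 0)
  total <- sum(comps$variance)
  comps$proportion <- if (total > 0) comps$variance / total else
    rep(0, nrow(comps))
  out <- tibble::as_tibble(comps)
  attr(out, "trait") <- trait
  attr(out, "n_leaves") <- nrow(x)
  attr(out, "estimator") <- estimator
  class(out) <- c("variance_partition", class(out))
  out
}

varpart_reml <- function(d) {
  grp_levels <- vapply(d[varpart_levels[1:5]],
                       function(f) length(unique(f)), integer(1))
  usable <- names(grp_levels)[grp_levels >= 2 & grp_levels < nrow(d)]
  degenerate <- setdiff(varpart_levels[1:5], usable)
  if (length(degenerate) > 0) {
    warning("level(s) with a single realized group reported as 0: ",
            paste(degenerate, collapse = ", "), call. = FALSE)
  }
  vars <- stats::setNames(rep(0, 6), varpart_levels)
  if (length(usable) == 0) {
    vars[["within"]] <- stats::var(d$y)
  } else {
    form <- stats::as.formula(paste(
      "y ~ 1 +", paste(sprintf("(1 | %s)", usable), collapse = " + ")))
    fit <- suppressWarnings(suppressMessages(
      lme4::lmer(form, data = d, REML = TRUE,
                 control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                             check.nobs.vs.nRE = "ignore",
                                             calc.derivs = FALSE))))
    vc <- as.data.frame(lme4::VarCorr(fit))
    for (lv in usable) {
      vars[[lv]] <- vc$vcov[vc$grp == lv]
    }
    vars[["within"]] <- vc$vcov[vc$grp == "Residual"]
  }
  data.frame(level = varpart_levels, variance = unname(vars),
             degenerate = varpart_levels %in% degenerate,
             stringsAsFactors = FALSE)
}

varpart_moments <- function(d) {
  n <- nrow(d)
  grand <- mean(d$y)
  lev <- varpart_levels[1:5]
  # group means, sizes and parent means per level (parent of order = grand)
  ms <- numeric(5)
  df <- numeric(5)
  m_per_group <- numeric(5)
  parent_mean_of <- function(level_idx) {
    if (level_idx == 1) return(rep(grand, n))
    stats::ave(d$y, d[[lev[level_idx - 1]]])
  }
  for (j in seq_along(lev)) {
    gm <- stats::ave(d$y, d[[lev[j]]])
    pm <- parent_mean_of(j)
    groups <- unique(d[[lev[j]]])
    parents <- if (j == 1) 1L else length(unique(d[[lev[j - 1]]]))
    df[j] <- length(groups) - parents
    ss <- sum(tapply(seq_len(n), d[[lev[j]]], function(i) {
      length(i) * (gm[i][1] - pm[i][1])^2
    }))
    ms[j] <- if (df[j] > 0) ss / df[j] else NA_real_
    m_per_group[j] <- n / length(groups)
  }
  pop_mean <- stats::ave(d$y, d$population)
  df_within <- n - length(unique(d$population))
  ms_within <- if (df_within > 0) {
    sum((d$y - pop_mean)^2) / df_within
  } else NA_real_

  vars <- stats::setNames(rep(0, 6), varpart_levels)
  degenerate <- rep(FALSE, 6)
  # telescope from the bottom: sigma2_j = (MS_j - MS_{j+1}) / m_j, where the
  # next defined MS below is used when a level is degenerate
  ms_chain <- c(ms, ms_within)
  if (is.na(ms_within)) {
    degenerate[6] <- TRUE
  } else {
    vars[["within"]] <- ms_within
  }
  for (j in 5:1) {
    if (is.na(ms_chain[j]) || df[j] <= 0) {
      degenerate[j] <- TRUE
      next
    }
    below <- ms_chain[(j + 1):6]
    below <- below[!is.na(below)]
    ms_next <- if (length(below) > 0) below[1] else 0
    vars[[lev[j]]] <- (ms_chain[j] - ms_next) / m_per_group[j]
  }
  if (any(degenerate)) {
    warning("degenerate level(s) reported as 0: ",
            paste(varpart_levels[degenerate], collapse = ", "),
            call. = FALSE)
  }
  data.frame(level = varpart_levels, variance = unname(vars),
             degenerate = degenerate, stringsAsFactors = FALSE)
}

#' Partition variance for several traits at once
#'
#' @param x A trait table (unmanipulated leaves).
#' @param traits Traits to analyse; defaults to all traits present.
#' @param estimator Passed to [partition_variance()].
#' @return A tibble with columns trait, level, variance, proportion,
#'   degenerate, n_leaves, estimator (one row per trait x level), mirroring
#'   a stacked-bar presentation of the decomposition.
#' @export
partition_variance_all <- function(x, traits = NULL,
                                   estimator = c("reml", "moments")) {
  estimator <- match.arg(estimator)
  x <- validate_trait_table(x)
  if (is.null(traits)) traits <- intersect(trait_names, unique(x$trait))
  out <- lapply(traits, function(tr) {
    vp <- partition_variance(x, tr, estimator)
    tibble::tibble(trait = tr, level = vp$level, variance = vp$variance,
                   proportion = vp$proportion, degenerate = vp$degenerate,
                   n_leaves = attr(vp, "n_leaves"),
                   estimator = attr(vp, "estimator"))
  })
  dplyr::bind_rows(out)
}
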