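#' Select the trait-data pool for a species at a site
#'
#' Trait data are rarely complete for every species at every site, so pools
#' are filled from a fixed priority hierarchy of unmanipulated leaves:
#' (1) the focal species at the focal site, (2) the focal genus at the focal
#' site, (3) the focal species anywhere, (4) the focal genus anywhere. The
#' first non-empty rung wins. Genus-level pools carry a partition of values
#' by congener so that sampling can be rarefied to give each congener equal
#' probability regardless of how many leaves it contributed.
#'
#' @param species Focal species name.
#' @param site Focal site label.
#' @param x A trait table; restricted internally to unmanipulated
#'   treatments (wild, control, local_transplant) unless
#'   `restrict_unmanipulated = FALSE`.
#' @param trait Which trait the pool is for.
#' @param taxonomy Optional tibble with `species` and `genus` columns used
#'   to resolve the focal genus when the species has no rows in `x`;
#'   defaults to the genus column of `x`.
#' @param restrict_unmanipulated Filter `x` to unmanipulated treatments
#'   first (default TRUE).
#' @return A `trait_pool` (list with `species`, `site`, `trait`, `values`,
#'   `source_level`, `congener_groups`) or `NULL` when all four rungs are
#'   empty.
#' @export
select_trait_pool <- function(species, site, x, trait, taxonomy = NULL,
                              restrict_unmanipulated = TRUE) {
  x <- validate_trait_table(x)
  if (restrict_unmanipulated) x <- unmanipulated(x)
  x <- x[x$trait == trait, , drop = FALSE]
  genus <- resolve_genus(species, x, taxonomy)

  pool <- function(values, source_level, groups = NULL) {
    structure(list(species = species, site = site, trait = trait,
                   values = values, source_level = source_level,
                   congener_groups = groups),
              class = "trait_pool")
  }
  sp_site <- x$value[x$species == species & x$site == site]
  if (length(sp_site) > 0) return(pool(sp_site, "species_at_site"))
  if (!is.na(genus)) {
    g_site <- x[x$genus == genus & x$site == site, , drop = FALSE]
    if (nrow(g_site) > 0) {
      return(pool(g_site$value, "genus_at_site",
                  split(g_site$value, g_site$species)))
    }
  }
  sp_any <- x$value[x$species == species]
  if (length(sp_any) > 0) return(pool(sp_any, "species_anywhere"))
  if (!is.na(genus)) {
    g_any <- x[x$genus == genus, , drop = FALSE]
    if (nrow(g_any) > 0) {
      return(pool(g_any$value, "genus_anywhere",
                  split(g_any$value, g_any$species)))
    }
  }
  NULL
}

resolve_genus <- function(species, x, taxonomy) {
  if (!is.null(taxonomy) && species %in% taxonomy$species) {
    return(taxonomy$genus[match(species, taxonomy$species)])
  }
  hit <- x$genus[x$species == species]
  if (length(hit) > 0) hit[1] else NA_character_
}

#' Draw leaf values from a trait pool
#'
#' Species-level pools are sampled uniformly with replacement. Genus-level
#' pools are rarefied: a congener is first drawn uniformly, then a leaf
#' uniformly within that congener, so a congener with one leaf is as likely
#' to be represented as one with a hundred.
#'
#' @param pool A `trait_pool` from [select_trait_pool()].
#' @param n Number of draws (default 1).
#' @return Numeric vector of length `n`.
#' @export
draw_individual <- function(pool, n = 1) {
  stopifnot(inherits(pool, "trait_pool"), length(pool$values) > 0)
  if (is.null(pool$congener_groups)) {
    v <- pool$values
    return(v[sample.int(length(v), n, replace = TRUE)])
  }
  groups <- pool$congener_groups
  gi <- sample.int(length(groups), n, replace = TRUE)
  out <- numeric(n)
  for (g in unique(gi)) {
    idx <- which(gi == g)
    v <- groups[[g]]
    out[idx] <- v[sample.int(length(v), length(idx), replace = TRUE)]
  }
  out
}

#' Bootstrap the biomass-weighted community trait distribution of a site
#'
#' Per replicate, `n_draws` individual leaves are simulated and their
#' arithmetic mean taken; `B` replicates form the bootstrap distribution of
#' the community-weighted mean. Species are represented in proportion to
#' their relative site biomass (site-pooled across plots, renormalized over
#' species with an available trait pool): each replicate allocates the
#' `n_draws` individuals across species by largest-remainder proportional
#' allocation, then draws each individual's leaf value from its species'
#' pool via [draw_individual()] (uniform with replacement, congener-rarefied
#' for genus-level pools). The deterministic allocation keeps the replicate
#' mean an exactly biomass-weighted statistic — with single-value pools
#' every replicate equals the weighted community mean and the interval has
#' zero width — while the resampling of leaves within species propagates
#' trait-measurement uncertainty into the interval. For the interval to
#' approximate the sampling uncertainty of the community mean, `n_draws`
#' should be commensurate with the number of leaves actually measured at
#' the site (the default, 200, matches a typical site's leaf count).
#'
#' @param site Site label.
#' @param trait Trait name.
#' @param communities A community table (site, plot_id, species, biomass).
#' @param x A trait table providing the pools (unmanipulated leaves).
#' @param B Number of bootstrap replicates (default 1000).
#' @param n_draws Individuals drawn per replicate (default 200). Replicate
#'   means are invariant to `n_draws` in expectation; interval width is not.
#' @param seed Optional integer seed for reproducibility.
#' @param taxonomy Optional taxonomy passed to [select_trait_pool()].
#' @return A `bootstrap_result`: list with `site`, `trait`,
#'   `replicate_means` (length `B`), `n_draws_per_replicate`, `weighted`,
#'   `coverage` (fraction of site biomass belonging to species with a
#'   pool), `source_levels` (per covered species) and `seed`.
#' @export
bootstrap_community_distribution <- function(site, trait, communities, x,
                                             B = 1000, n_draws = 200,
                                             seed = NULL, taxonomy = NULL) {
  communities <- validate_community_table(communities)
  x <- validate_trait_table(x)
  x <- unmanipulated(x)
  if (!is.null(seed)) set.seed(as.integer(seed))
  site_comm <- communities[communities$site == site, , drop = FALSE]
  if (nrow(site_comm) == 0) {
    stop("no community data for site ", site, call. = FALSE)
  }
  w_tab <- dplyr::summarise(dplyr::group_by(site_comm, .data$species),
                            biomass = sum(.data$biomass), .groups = "drop")
  w_tab <- w_tab[w_tab$biomass > 0, , drop = FALSE]
  pools <- lapply(w_tab$species, select_trait_pool, site = site, x = x,
                  trait = trait, taxonomy = taxonomy,
                  restrict_unmanipulated = FALSE)
  covered <- !vapply(pools, is.null, logical(1))
  total_biomass <- sum(w_tab$biomass)
  coverage <- sum(w_tab$biomass[covered]) / total_biomass
  if (!any(covered)) {
    stop("no species with trait data at site ", site, " for trait ", trait,
         call. = FALSE)
  }
  w <- w_tab$biomass[covered] / sum(w_tab$biomass[covered])
  pools <- pools[covered]

  k <- largest_remainder_allocation(w, n_draws)
  replicate_sums <- numeric(B)
  for (s in seq_along(pools)) {
    if (k[s] == 0) next
    v <- draw_individual(pools[[s]], B * k[s])
    replicate_sums <- replicate_sums +
      rowSums(matrix(v, nrow = B, ncol = k[s]))
  }
  replicate_means <- replicate_sums / n_draws
  structure(list(site = site, trait = trait,
                 replicate_means = replicate_means,
                 n_draws_per_replicate = n_draws,
                 B = B, weighted = TRUE, coverage = coverage,
                 source_levels = stats::setNames(
                   vapply(pools, `[[`, character(1), "source_level"),
                   w_tab$species[covered]),
                 seed = seed),
            class = "bootstrap_result")
}

# deterministic proportional allocation of n draws to weights w (sum(w) = 1):
# floor(w * n) each, then +1 to the largest fractional remainders, ties
# broken by position
largest_remainder_allocation <- function(w, n) {
  base <- floor(w * n)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- w * n - base
    top <- order(frac, seq_along(w), decreasing = c(TRUE, FALSE),
                 method = "radix")[seq_len(rem)]
    base[top] <- base[top] + 1
  }
  as.integer(base)
}

#' Summarize a bootstrap distribution
#'
#' Mean of the replicate means plus a central percentile interval
#' (linear-interpolation quantiles, the default type 7).
#'
#' @param r A `bootstrap_result`.
#' @param level Confidence level (default 0.95). `level = 0` collapses to a
#'   zero-width interval at the median.
#' @return A one-row tibble: site, trait, mean, ci_low, ci_high, B,
#'   n_draws, coverage.
#' @export
summarize_bootstrap <- function(r, level = 0.95) {
  stopifnot(inherits(r, "bootstrap_result"), length(r$replicate_means) > 0,
            level >= 0, level <= 1)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci <- unname(stats::quantile(r$replicate_means, probs, type = 7))
  tibble::tibble(site = r$site, trait = r$trait,
                 mean = mean(r$replicate_means),
                 ci_low = ci[1], ci_high = ci[2],
                 B = r$B, n_draws = r$n_draws_per_replicate,
                 coverage = r$coverage)
}

#' Bootstrapped community trait summaries for all sites and traits
#'
#' @param communities A community table.
#' @param x A trait table (unmanipulated leaves are used).
#' @param traits Traits to summarize; defaults to all traits present.
#' @param sites Sites to summarize; defaults to all sites in `communities`.
#' @param level Confidence level for the percentile interval.
#' @inheritParams bootstrap_community_distribution
#' @return A tibble with one row per site x trait (site, trait, mean,
#'   ci_low, ci_high, B, n_draws, coverage, seed).
#' @export
bootstrap_all_communities <- function(communities, x, traits = NULL,
                                      sites = NULL, B = 1000, n_draws = 200,
                                      level = 0.95, seed = NULL,
                                      taxonomy = NULL) {
  communities <- validate_community_table(communities)
  x <- validate_trait_table(x)
  if (is.null(traits)) traits <- intersect(trait_names, unique(x$trait))
  if (is.null(sites)) sites <- unique(communities$site)
  if (!is.null(seed)) set.seed(as.integer(seed))
  grid <- tidyr::expand_grid(site = sites, trait = traits)
  out <- purrr::pmap(grid, function(site, trait) {
    r <- bootstrap_community_distribution(site, trait, communities, x,
                                          B = B, n_draws = n_draws,
                                          seed = NULL, taxonomy = taxonomy)
    summarize_bootstrap(r, level = level)
  })
  res <- dplyr::bind_rows(out)
  res$seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  res
}
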