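#' Canonical trait and treatment vocabularies
#'
#' The eleven leaf functional traits handled by the package, the subset
#' treated as multiplicative growth traits (analysed on the natural-log
#' scale), and the recognised plot treatments.
#'
#' Trait units: LA cm^2, LT mm, LDMC g/g, SLA cm^2/g, C/N/P %, CN and NP
#' unitless ratios, d13C and d15N per mil. The package never converts units;
#' callers supply values on these scales.
#'
#' @format Character vectors.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
trait_names <- c("LA", "LT", "LDMC", "SLA", "C", "N", "P",
                 "CN", "NP", "d13C", "d15N")

#' @rdname vocabularies
#' @export
multiplicative_traits <- c("LA", "LT", "LDMC")

#' @rdname vocabularies
#' @export
treatment_levels <- c("control", "local_transplant", "warmed", "cooled", "wild")

# treatments whose leaves represent unmanipulated growing conditions:
# local transplants were indistinguishable from untouched controls, so both
# plot types count as controls alongside wild-collected leaves
unmanipulated_treatments <- c("wild", "control", "local_transplant")

trait_table_columns <- c("leaf_id", "species", "genus", "family", "order",
                         "site", "plot_id", "block", "treatment",
                         "origin_site", "trait", "value")

community_table_columns <- c("site", "plot_id", "species", "biomass")

#' Validate a leaf-level trait table
#'
#' Checks the long-format trait table contract: all canonical columns
#' present, trait names drawn from [trait_names], treatments drawn from
#' [treatment_levels], and finite numeric values.
#'
#' @param x A data frame with the canonical columns (see [read_trait_table]).
#' @return The validated table as a tibble, invisibly unchanged.
#' @export
validate_trait_table <- function(x) {
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(trait_table_columns, names(x))
  if (length(missing_cols) > 0) {
    stop("trait table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(x$value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(x$value))) & !is.na(x$value))
    stop("trait table column 'value' is not numeric (first bad row: ",
         if (length(bad)) bad[1] else "?", ")", call. = FALSE)
  }
  bad_value <- which(!is.finite(x$value))
  if (length(bad_value) > 0) {
    stop("non-finite trait value at row ", bad_value[1], call. = FALSE)
  }
  unknown_traits <- setdiff(unique(x$trait), trait_names)
  if (length(unknown_traits) > 0) {
    stop("unknown trait name(s): ", paste(unknown_traits, collapse = ", "),
         "; expected one of ", paste(trait_names, collapse = ", "),
         call. = FALSE)
  }
  unknown_trt <- setdiff(unique(x$treatment), treatment_levels)
  if (length(unknown_trt) > 0) {
    stop("unknown treatment(s): ", paste(unknown_trt, collapse = ", "),
         call. = FALSE)
  }
  x
}

#' Read a leaf-level trait table from CSV
#'
#' Reads a long-format table with one row per leaf x trait. Columns may be
#' renamed on the way in through `schema`, a named character vector mapping
#' canonical names to the file's column names, e.g.
#' `c(species = "taxon", value = "trait_value")`.
#'
#' @param path Path to a UTF-8 CSV file with a header row and `.` decimals.
#' @param schema Optional named character vector; names are canonical column
#'   names, values are the column names used in the file.
#' @return A validated tibble with the canonical columns, rows in file order.
#' @seealso [write_trait_table()], [validate_trait_table()]
#' @export
read_trait_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  raw <- apply_schema(raw, schema)
  missing_cols <- setdiff(trait_table_columns, names(raw))
  if (length(missing_cols) > 0) {
    stop("trait table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  value_num <- suppressWarnings(as.numeric(raw$value))
  bad <- which(is.na(value_num) & !is.na(raw$value))
  if (length(bad) > 0) {
    stop("could not parse 'value' as a number at row ", bad[1],
         " (value '", raw$value[bad[1]], "')", call. = FALSE)
  }
  raw$value <- value_num
  validate_trait_table(raw[trait_table_columns])
}

#' Write a trait table to CSV
#'
#' @param x A trait table (validated first).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(x, path) {
  x <- validate_trait_table(x)
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' Read a community biomass table from CSV
#'
#' One row per site x plot x species with the species' standing biomass in
#' that plot (grams). Biomass is used downstream as a relative resampling
#' weight, so any consistent unit works.
#'
#' @inheritParams read_trait_table
#' @return A validated tibble with columns site, plot_id, species, biomass.
#' @export
read_community_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  raw <- apply_schema(raw, schema)
  missing_cols <- setdiff(community_table_columns, names(raw))
  if (length(missing_cols) > 0) {
    stop("community table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  biomass_num <- suppressWarnings(as.numeric(raw$biomass))
  bad <- which(is.na(biomass_num) & !is.na(raw$biomass))
  if (length(bad) > 0) {
    stop("could not parse 'biomass' as a number at row ", bad[1], call. = FALSE)
  }
  raw$biomass <- biomass_num
  validate_community_table(raw[community_table_columns])
}

#' @rdname read_community_table
#' @param x A data frame to validate.
#' @export
validate_community_table <- function(x) {
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(community_table_columns, names(x))
  if (length(missing_cols) > 0) {
    stop("community table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(x$biomass)) || any(x$biomass < 0)) {
    stop("biomass must be finite and >= 0", call. = FALSE)
  }
  key <- paste(x$site, x$plot_id, x$species, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (site, plot_id, species) rows in community table",
         call. = FALSE)
  }
  x
}

apply_schema <- function(x, schema) {
  if (is.null(schema)) return(x)
  stopifnot(is.character(schema), !is.null(names(schema)))
  for (canonical in names(schema)) {
    from <- schema[[canonical]]
    if (!from %in% names(x)) {
      stop("schema maps '", canonical, "' to column '", from,
           "', which is absent from the file", call. = FALSE)
    }
    names(x)[names(x) == from] <- canonical
  }
  x
}

#' Trait-cleaning thresholds for unrealistic leaf measurements
#'
#' Thresholds beyond which a leaf measurement is treated as a measurement
#' error: leaf dry matter content above 1 g/g is physically impossible
#' (dry mass exceeding fresh mass), specific leaf area outside 5-500 cm^2/g
#' is outside the plausible range for grassland leaves, and leaf nitrogen
#' above 6.4 % exceeds the highest published values for the genera involved.
#' Boundary values are retained: the rules are strict inequalities.
#'
#' @param ldmc_max Maximum admissible LDMC (g/g). Default 1.
#' @param sla_min,sla_max Admissible SLA range (cm^2/g). Defaults 5 and 500.
#' @param n_max Maximum admissible leaf N (%). Default 6.4.
#' @return An object of class `cleaning_rules`.
#' @export
cleaning_rules <- function(ldmc_max = 1, sla_min = 5, sla_max = 500,
                           n_max = 6.4) {
  stopifnot(ldmc_max > 0, sla_min > 0, sla_max > 0, n_max > 0,
            sla_min < sla_max)
  structure(list(ldmc_max = ldmc_max, sla_min = sla_min, sla_max = sla_max,
                 n_max = n_max),
            class = "cleaning_rules")
}

#' Remove leaves with unrealistic trait values
#'
#' Applies the cleaning thresholds at the leaf level: a leaf violating any
#' rule has all of its trait rows removed (a failed mass or area measurement
#' contaminates every derived trait of that leaf). Removed rows are
#' attributed to the first rule the leaf violates, in the fixed order
#' LDMC, SLA, N. Retained values are never altered, so the operation is
#' idempotent. Cleaning operates on original measurement scales and must
#' precede [log_transform_multiplicative()].
#'
#' @param x A trait table.
#' @param rules A [cleaning_rules()] object.
#' @return A list with elements `data` (the retained trait table) and
#'   `report`, a `cleaning_report` with `n_input`, `n_retained` and
#'   `n_removed_by_rule` (row counts per rule, names "LDMC", "SLA", "N").
#' @export
clean_traits <- function(x, rules = cleaning_rules()) {
  x <- validate_trait_table(x)
  n_input <- nrow(x)
  if (n_input == 0) {
    report <- structure(list(n_input = 0L, n_retained = 0L,
                             n_removed_by_rule = c(LDMC = 0L, SLA = 0L, N = 0L)),
                        class = "cleaning_report")
    return(list(data = x, report = report))
  }
  viol_ldmc <- x$trait == "LDMC" & x$value > rules$ldmc_max
  viol_sla  <- x$trait == "SLA" & (x$value < rules$sla_min | x$value > rules$sla_max)
  viol_n    <- x$trait == "N" & x$value > rules$n_max
  # first violated rule per leaf, in order LDMC -> SLA -> N
  leaf_rule <- rep(NA_character_, n_input)
  bad_n_leaves    <- unique(x$leaf_id[viol_n])
  bad_sla_leaves  <- unique(x$leaf_id[viol_sla])
  bad_ldmc_leaves <- unique(x$leaf_id[viol_ldmc])
  leaf_rule[x$leaf_id %in% bad_n_leaves] <- "N"
  leaf_rule[x$leaf_id %in% bad_sla_leaves] <- "SLA"
  leaf_rule[x$leaf_id %in% bad_ldmc_leaves] <- "LDMC"
  keep <- is.na(leaf_rule)
  removed <- leaf_rule[!keep]
  n_removed <- c(LDMC = sum(removed == "LDMC"),
                 SLA = sum(removed == "SLA"),
                 N = sum(removed == "N"))
  report <- structure(list(n_input = n_input,
                           n_retained = sum(keep),
                           n_removed_by_rule = n_removed),
                      class = "cleaning_report")
  list(data = x[keep, , drop = FALSE], report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Trait cleaning report\n")
  cat("  rows in:      ", x$n_input, "\n")
  cat("  rows retained:", x$n_retained, "\n")
  cat("  removed by rule: LDMC", x$n_removed_by_rule[["LDMC"]],
      "| SLA", x$n_removed_by_rule[["SLA"]],
      "| N", x$n_removed_by_rule[["N"]], "\n")
  invisible(x)
}

#' Natural-log transform of multiplicative growth traits
#'
#' Leaf area, leaf thickness and leaf dry matter content vary
#' multiplicatively, so variance analyses run on their natural-log scale.
#' The transform replaces values in place and records which traits were
#' transformed in the `log_transformed` attribute.
#'
#' @param x A trait table.
#' @param traits Traits to transform; defaults to [multiplicative_traits].
#' @return The trait table with transformed values.
#' @export
log_transform_multiplicative <- function(x, traits = multiplicative_traits) {
  x <- validate_trait_table(x)
  idx <- which(x$trait %in% traits)
  nonpos <- idx[x$value[idx] <= 0]
  if (length(nonpos) > 0) {
    stop("cannot log transform non-positive value at row ", nonpos[1],
         " (trait ", x$trait[nonpos[1]], ", value ", x$value[nonpos[1]], ")",
         call. = FALSE)
  }
  x$value[idx] <- log(x$value[idx])
  attr(x, "log_transformed") <- union(attr(x, "log_transformed"), traits)
  x
}

#' Restrict a trait table to unmanipulated growing conditions
#'
#' Keeps wild-collected leaves together with control and local-transplant
#' plot leaves; locally transplanted turfs showed no differences from
#' untouched controls, so both plot types serve as controls.
#'
#' @param x A trait table.
#' @return The filtered trait table.
#' @export
unmanipulated <- function(x) {
  x <- validate_trait_table(x)
  x[x$treatment %in% unmanipulated_treatments, , drop = FALSE]
}
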