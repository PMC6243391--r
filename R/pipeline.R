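config_error <- function(...) {
  rlang::abort(paste0(...), class = "turftraits_config_error")
}

#' Validate a pipeline configuration
#'
#' A configuration is a named list (or a YAML file holding one) with:
#'
#' * exactly one of `input` (paths `traits`, `communities`, `design`) or
#'   `simulate` (arguments for [simulation_config()]);
#' * optional `cleaning` (arguments for [cleaning_rules()]);
#' * optional `bootstrap` (`B`, `n_draws`, `seed`), `permutation`
#'   (`n_perm`, `seed`), `ci_level` (home-interval level, default 0.99);
#' * `output_dir` for the result bundle.
#'
#' All randomness in a run flows from the two named seeds (the simulation
#' seed inside `simulate`, and the inference seeds under `bootstrap` and
#' `permutation`), which are recorded in the manifest.
#'
#' @param x A named list or the path to a YAML file.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(x) {
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) config_error("config file not found: ", x)
    x <- yaml::read_yaml(x)
  }
  if (!is.list(x)) config_error("config must be a named list or YAML path")
  has_input <- !is.null(x$input)
  has_sim <- !is.null(x$simulate)
  if (has_input == has_sim) {
    config_error("config must contain exactly one of 'input' or 'simulate'")
  }
  if (has_input) {
    for (key in c("traits", "communities", "design")) {
      if (is.null(x$input[[key]])) {
        config_error("config key 'input$", key, "' is required")
      }
    }
  }
  if (is.null(x$output_dir)) config_error("config key 'output_dir' is required")
  defaults <- list(bootstrap = list(B = 1000, n_draws = 200, seed = 1),
                   permutation = list(n_perm = 999, seed = 1),
                   ci_level = 0.99, cleaning = list())
  for (key in names(defaults)) {
    if (is.null(x[[key]])) x[[key]] <- defaults[[key]]
    else if (key %in% c("bootstrap", "permutation")) {
      x[[key]] <- utils::modifyList(defaults[[key]], x[[key]])
    }
  }
  for (key in c("bootstrap", "permutation")) {
    s <- x[[key]]$seed
    if (!is.numeric(s) || s != round(s)) {
      config_error("config key '", key, "$seed' must be an integer")
    }
    x[[key]]$seed <- as.integer(s)
  }
  if (!is.numeric(x$ci_level) || x$ci_level <= 0 || x$ci_level >= 1) {
    config_error("config key 'ci_level' must be in (0, 1)")
  }
  structure(x, class = "pipeline_config")
}

atomic_write_csv <- function(x, path) {
  tmp <- paste0(path, ".tmp")
  readr::write_csv(x, tmp, progress = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order: load or simulate data, clean, log-transform
#' multiplicative traits, partition variance, bootstrap community trait
#' distributions, compute and test relative plasticity, classify
#' convergence and run G-tests. Results are written as CSV files plus a
#' JSON manifest (row counts, seeds, config hash, package version) in
#' `output_dir`; files are written atomically. Reruns with the same
#' configuration reproduce identical numeric content.
#'
#' @param cfg A [pipeline_config()] (or a list/YAML path accepted by it).
#' @param quiet Suppress per-stage progress messages (default TRUE).
#' @return Invisibly, the result bundle: a list with cleaning_report,
#'   variance_partition, community_summaries, plasticity_records,
#'   plasticity_tests, convergence_records, contingency_tables, g_tests,
#'   and manifest.
#' @export
run_pipeline <- function(cfg, quiet = TRUE) {
  if (!inherits(cfg, "pipeline_config")) cfg <- pipeline_config(cfg)
  say <- function(...) if (!quiet) message("[turftraits] ", ...)
  t0 <- Sys.time()

  say("loading data")
  dat <- run_stage("load", {
    if (!is.null(cfg$simulate)) {
      sim_cfg <- do.call(simulation_config, cfg$simulate)
      sim <- simulate_dataset(sim_cfg)
      list(traits = sim$traits, communities = sim$communities,
           design = sim$design, taxonomy = sim$taxonomy, truth = sim$truth)
    } else {
      design <- readr::read_csv(cfg$input$design,
                                col_types = readr::cols(.default = readr::col_character()),
                                progress = FALSE)
      list(traits = read_trait_table(cfg$input$traits),
           communities = read_community_table(cfg$input$communities),
           design = design, taxonomy = NULL, truth = NULL)
    }
  })

  say("cleaning traits")
  cleaned <- run_stage("clean", {
    clean_traits(dat$traits, do.call(cleaning_rules, cfg$cleaning))
  })

  say("log transforming multiplicative traits")
  transformed <- run_stage("transform", {
    present <- intersect(multiplicative_traits, unique(cleaned$data$trait))
    if (length(present) > 0) {
      log_transform_multiplicative(cleaned$data, present)
    } else cleaned$data
  })
  wild <- unmanipulated(transformed)

  say("partitioning variance")
  varpart <- run_stage("varpart", {
    suppressWarnings(partition_variance_all(wild))
  })

  say("bootstrapping community trait distributions")
  community <- run_stage("bootstrap", {
    bootstrap_all_communities(dat$communities, transformed,
                              B = cfg$bootstrap$B,
                              n_draws = cfg$bootstrap$n_draws,
                              seed = cfg$bootstrap$seed,
                              taxonomy = dat$taxonomy)
  })

  say("computing relative plasticity")
  plast <- run_stage("plasticity", {
    pairs <- pair_plots(dat$design)
    records <- compute_plasticity(transformed, pairs)
    tests <- suppressWarnings(
      compare_plasticity(records, n_perm = cfg$permutation$n_perm,
                         seed = cfg$permutation$seed))
    list(records = records, tests = tests)
  })

  say("classifying convergence")
  conv <- run_stage("convergence", {
    records <- classify_all_transplants(transformed, dat$design, community,
                                        level = cfg$ci_level)
    tabs <- list(start_group = tabulate_outcomes(records, "start_group"),
                 treatment = tabulate_outcomes(records, "treatment"))
    gt <- lapply(names(tabs), function(nm) {
      res <- tryCatch(suppressWarnings(g_test(tabs[[nm]])),
                      error = function(e) NULL)
      tibble::tibble(table = nm,
                     G = if (is.null(res)) NA_real_ else res$statistic,
                     df = if (is.null(res)) NA_integer_ else res$df,
                     p_value = if (is.null(res)) NA_real_ else res$p.value)
    })
    tabs_long <- dplyr::bind_rows(lapply(names(tabs), function(nm) {
      t <- tabs[[nm]]
      tidyr::expand_grid(table = nm, outcome = rownames(t),
                         group = colnames(t)) |>
        dplyr::mutate(count = as.integer(t[cbind(.data$outcome, .data$group)]))
    }))
    list(records = records, tables = tabs_long,
         g_tests = dplyr::bind_rows(gt))
  })

  say("writing result bundle")
  out_dir <- cfg$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report_df <- tibble::tibble(
    n_input = cleaned$report$n_input,
    n_retained = cleaned$report$n_retained,
    removed_LDMC = cleaned$report$n_removed_by_rule[["LDMC"]],
    removed_SLA = cleaned$report$n_removed_by_rule[["SLA"]],
    removed_N = cleaned$report$n_removed_by_rule[["N"]])
  files <- list(
    cleaning_report = report_df,
    variance_partition = varpart,
    community_summaries = community,
    plasticity_records = plast$records,
    plasticity_tests = plast$tests,
    convergence_records = conv$records,
    contingency_tables = conv$tables,
    g_tests = conv$g_tests)
  manifest_files <- list()
  for (nm in names(files)) {
    path <- file.path(out_dir, paste0(nm, ".csv"))
    atomic_write_csv(files[[nm]], path)
    manifest_files[[nm]] <- list(file = basename(path),
                                 rows = nrow(files[[nm]]))
  }
  manifest <- list(
    package = "turftraits",
    version = as.character(utils::packageVersion("turftraits")),
    # hash of the analysis configuration; output location excluded so that
    # the same analysis in a different directory hashes identically
    config_hash = rlang::hash(unclass(cfg)[setdiff(names(cfg), "output_dir")]),
    seeds = list(simulation = if (!is.null(cfg$simulate)) cfg$simulate$seed,
                 bootstrap = cfg$bootstrap$seed,
                 permutation = cfg$permutation$seed),
    elapsed_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    files = manifest_files)
  manifest_path <- file.path(out_dir, "manifest.json")
  tmp <- paste0(manifest_path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  file.rename(tmp, manifest_path)

  invisible(c(files, list(manifest = manifest,
                          report = cleaned$report,
                          truth = dat$truth)))
}

cli_usage <- function() {
  paste(
    "usage: turftraits <subcommand> [--config FILE] [--seed INT] [--out DIR]",
    "                  [--traits FILE] [--communities FILE] [--design FILE]",
    "subcommands:",
    "  run-all      run the full pipeline from a config file",
    "  simulate     generate a synthetic dataset (traits/communities/design CSVs)",
    "  clean        apply trait-cleaning rules to a trait CSV",
    "  varpart      variance partitioning of a trait CSV",
    "  bootstrap    bootstrapped community trait summaries",
    "  plasticity   relative plasticity records and permutation tests",
    "  convergence  convergence classification and G-tests",
    sep = "\n")
}

parse_cli_args <- function(args) {
  if (length(args) == 0) return(NULL)
  out <- list(subcommand = args[1], opts = list())
  i <- 2
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) config_error("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (i + 1 > length(args)) config_error("missing value for --", key)
    out$opts[[key]] <- args[i + 1]
    i <- i + 2
  }
  out
}

#' Command-line entry point
#'
#' Thin shell interface over the package functions; see
#' `inst/cli/turftraits.R` for a ready-to-run Rscript wrapper. Returns an
#' exit status instead of quitting so it can be tested in-process: 0 on
#' success, 2 for configuration errors, 3 for data errors.
#'
#' @param args Character vector of command-line arguments
#'   (subcommand first).
#' @return Integer exit status, invisibly.
#' @export
turftraits_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    parsed <- parse_cli_args(args)
    if (is.null(parsed)) {
      message(cli_usage())
      return(invisible(2L))
    }
    cli_dispatch(parsed$subcommand, parsed$opts)
    0L
  },
  turftraits_config_error = function(e) {
    message("config error: ", conditionMessage(e))
    2L
  },
  error = function(e) {
    message("error: ", conditionMessage(e))
    3L
  })
  invisible(status)
}

cli_load_config <- function(opts, required = TRUE) {
  if (is.null(opts$config)) {
    if (required) config_error("--config is required for this subcommand")
    return(NULL)
  }
  pipeline_config(opts$config)
}

cli_need <- function(opts, keys) {
  for (k in keys) {
    if (is.null(opts[[k]])) config_error("--", k, " is required")
  }
}

cli_dispatch <- function(subcommand, opts) {
  seed <- if (!is.null(opts$seed)) as.integer(opts$seed)
  switch(subcommand,
    "run-all" = {
      cfg <- cli_load_config(opts)
      if (!is.null(opts$out)) cfg$output_dir <- opts$out
      if (!is.null(seed)) {
        if (!is.null(cfg$simulate)) cfg$simulate$seed <- seed
        cfg$bootstrap$seed <- seed
        cfg$permutation$seed <- seed
      }
      run_pipeline(cfg, quiet = FALSE)
    },
    "simulate" = {
      cli_need(opts, "out")
      sim_args <- list()
      if (!is.null(opts$config)) {
        raw <- yaml::read_yaml(opts$config)
        sim_args <- if (!is.null(raw$simulate)) raw$simulate else raw
      }
      if (!is.null(seed)) sim_args$seed <- seed
      sim <- simulate_dataset(do.call(simulation_config, sim_args))
      dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
      atomic_write_csv(sim$traits, file.path(opts$out, "traits.csv"))
      atomic_write_csv(sim$communities,
                       file.path(opts$out, "communities.csv"))
      atomic_write_csv(sim$design, file.path(opts$out, "design.csv"))
    },
    "clean" = {
      cli_need(opts, c("traits", "out"))
      res <- clean_traits(read_trait_table(opts$traits))
      dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
      atomic_write_csv(res$data, file.path(opts$out, "traits_clean.csv"))
      jsonlite::write_json(
        list(n_input = res$report$n_input,
             n_retained = res$report$n_retained,
             n_removed_by_rule = as.list(res$report$n_removed_by_rule)),
        file.path(opts$out, "cleaning_report.json"), auto_unbox = TRUE)
    },
    "varpart" = {
      cli_need(opts, c("traits", "out"))
      x <- read_trait_table(opts$traits)
      present <- intersect(multiplicative_traits, unique(x$trait))
      if (length(present) > 0) x <- log_transform_multiplicative(x, present)
      res <- suppressWarnings(partition_variance_all(unmanipulated(x)))
      dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
      atomic_write_csv(res, file.path(opts$out, "variance_partition.csv"))
    },
    "bootstrap" = {
      cli_need(opts, c("traits", "communities", "out"))
      x <- read_trait_table(opts$traits)
      comm <- read_community_table(opts$communities)
      res <- bootstrap_all_communities(comm, x, seed = seed)
      dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
      atomic_write_csv(res, file.path(opts$out, "community_summaries.csv"))
    },
    "plasticity" = {
      cli_need(opts, c("traits", "design", "out"))
      x <- read_trait_table(opts$traits)
      design <- readr::read_csv(opts$design,
                                col_types = readr::cols(.default = readr::col_character()),
                                progress = FALSE)
      records <- compute_plasticity(x, pair_plots(design))
      tests <- suppressWarnings(compare_plasticity(records, seed = seed))
      dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
      atomic_write_csv(records, file.path(opts$out, "plasticity_records.csv"))
      atomic_write_csv(tests, file.path(opts$out, "plasticity_tests.csv"))
    },
    "convergence" = {
      cli_need(opts, c("traits", "design", "communities", "out"))
      x <- read_trait_table(opts$traits)
      design <- readr::read_csv(opts$design,
                                col_types = readr::cols(.default = readr::col_character()),
                                progress = FALSE)
      comm <- read_community_table(opts$communities)
      cm <- bootstrap_all_communities(comm, x, seed = seed)
      records <- classify_all_transplants(x, design, cm)
      dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
      atomic_write_csv(records, file.path(opts$out, "convergence_records.csv"))
      gt <- lapply(c("start_group", "treatment"), function(nm) {
        res <- tryCatch(suppressWarnings(g_test(tabulate_outcomes(records, nm))),
                        error = function(e) NULL)
        tibble::tibble(table = nm,
                       G = if (is.null(res)) NA_real_ else res$statistic,
                       df = if (is.null(res)) NA_integer_ else res$df,
                       p_value = if (is.null(res)) NA_real_ else res$p.value)
      })
      atomic_write_csv(dplyr::bind_rows(gt), file.path(opts$out, "g_tests.csv"))
    },
    {
      message(cli_usage())
      config_error("unknown subcommand: ", subcommand)
    }
  )
  invisible(NULL)
}
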