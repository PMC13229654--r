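## End-to-end orchestration: read cohort CSVs and a JSON configuration,
## fit every cohort, write familial-fitness and cohort-mean tables
## (before/after selection) and the partition table for each cohort pair.

#' Read a cohort CSV
#'
#' Expects the header `id, site, year, gen, sire, dam, block, pos, germ,
#' flower, total_pods, sample_pods, seeds` (the `flower` column is part of
#' the default graph; extra columns are carried along untouched). The file
#' is validated against the graph; violations are reported with row
#' numbers.
#'
#' @param file Path to a CSV file.
#' @param graph An `"lh_graph"` (default [default_fitness_graph()]).
#' @param site,year,gen Optional labels overriding the file's columns.
#' @return A validated cohort data frame.
#' @export
read_cohort_csv <- function(file, graph = default_fitness_graph(),
                            site = NULL, year = NULL, gen = NULL) {
  if (!file.exists(file)) stop("cohort file not found: ", file)
  dat <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!is.null(site)) dat$site <- site
  if (!is.null(year)) dat$year <- year
  if (!is.null(gen)) dat$gen <- gen
  validate_cohort(graph, dat)
  dat
}

#' @rdname read_cohort_csv
#' @param data A cohort data frame.
#' @export
write_cohort_csv <- function(data, file) {
  utils::write.csv(data, file, row.names = FALSE)
  invisible(file)
}

#' Analysis configuration
#'
#' @param cohorts A data frame (or list coercible to one) with columns
#'   `label`, `file`, and optionally `site`, `year`, `gen`.
#' @param pairs A list of named lists/vectors, each with elements `prev`,
#'   `par`, `off` referencing cohort labels.
#' @param graph Path to a graph JSON or an `"lh_graph"`; `NULL` for the
#'   default graph.
#' @param fixed Fixed-effect formula (string or formula) for every cohort
#'   fit.
#' @param random Named character vector for the random term, as in
#'   [aster_spec()].
#' @param output_dir Directory for report files.
#' @param seed RNG seed recorded in the run log.
#' @param conf Confidence level.
#' @return An object of class `"analysis_config"`.
#' @export
analysis_config <- function(cohorts, pairs, graph = NULL, fixed = ~1,
                            random = c(sire = "Seeds"),
                            output_dir = "asterpart-out", seed = 1,
                            conf = 0.95) {
  cohorts <- as.data.frame(cohorts, stringsAsFactors = FALSE)
  if (nrow(cohorts) == 0) stop("empty cohort list")
  if (!all(c("label", "file") %in% names(cohorts)))
    stop("cohorts need 'label' and 'file' columns")
  if (anyDuplicated(cohorts$label)) stop("duplicate cohort labels")
  for (pr in pairs) {
    need <- unlist(pr[c("prev", "par", "off")])
    miss <- setdiff(need, cohorts$label)
    if (length(miss) > 0)
      stop("pair references unknown cohorts: ", paste(miss, collapse = ", "))
  }
  stopifnot(conf > 0, conf < 1)
  if (is.character(fixed)) fixed <- stats::as.formula(fixed)
  if (is.character(graph)) graph <- read_graph_json(graph)
  if (is.null(graph)) graph <- default_fitness_graph()
  structure(list(cohorts = cohorts, pairs = pairs, graph = graph,
                 fixed = fixed, random = random, output_dir = output_dir,
                 seed = seed, conf = conf), class = "analysis_config")
}

#' Read an analysis configuration from JSON
#'
#' @param path Path to a JSON file with fields `cohorts`, `pairs`, and
#'   optionally `graph` (path), `fixed` (formula string), `random`,
#'   `output_dir`, `seed`, `conf`.
#' @return An `"analysis_config"`.
#' @export
read_config_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  coh <- as.data.frame(x$cohorts, stringsAsFactors = FALSE)
  rel <- !file.exists(coh$file) & file.exists(file.path(base, coh$file))
  coh$file[rel] <- file.path(base, coh$file[rel])
  pairs <- x$pairs
  if (is.data.frame(pairs)) pairs <- split(pairs, seq_len(nrow(pairs)))
  analysis_config(
    cohorts = coh, pairs = pairs,
    graph = if (!is.null(x$graph)) {
      g <- x$graph
      if (!file.exists(g) && file.exists(file.path(base, g)))
        g <- file.path(base, g)
      g
    },
    fixed = if (!is.null(x$fixed)) x$fixed else ~1,
    random = if (!is.null(x$random)) unlist(x$random) else c(sire = "Seeds"),
    output_dir = if (!is.null(x$output_dir)) x$output_dir else "asterpart-out",
    seed = if (!is.null(x$seed)) x$seed else 1,
    conf = if (!is.null(x$conf)) x$conf else 0.95)
}

.log_line <- function(...) message("[asterpart] ", ...)

#' Run the full analysis pipeline
#'
#' Reads and validates every cohort, fits the life-history mixed model to
#' each, writes per-cohort familial-fitness CSVs, a cohort table of mean
#' fitness before and after selection (with standard errors), and a
#' partition table per cohort pair, plus a JSON run log. A cohort whose fit
#' fails is reported and skipped; pairs referencing it are dropped rather
#' than aborting the run.
#'
#' @param config An `"analysis_config"` or a path to a JSON configuration.
#' @return Invisibly, a list with `fits`, `familial`, `cohort_table`,
#'   `partitions`, and the output file paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config_json(config)
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  graph <- config$graph
  spec <- aster_spec(fixed = config$fixed, random = config$random)
  fits <- list(); familial <- list()
  rows <- list()
  for (i in seq_len(nrow(config$cohorts))) {
    lab <- config$cohorts$label[i]
    .log_line("cohort ", lab, ": reading ", config$cohorts$file[i])
    res <- tryCatch({
      dat <- read_cohort_csv(config$cohorts$file[i], graph,
                             site = config$cohorts$site[i],
                             year = config$cohorts$year[i],
                             gen = config$cohorts$gen[i])
      fit <- fit_aster(graph, dat, spec)
      .log_line("cohort ", lab, ": fit ", if (fit$converged) "converged"
                else "DID NOT CONVERGE", ", loglik ", format(fit$loglik),
                ", sigma2 ", format(fit$sigma2), ", iterations ", fit$n_iter)
      ffs <- familial_fitness(fit)
      list(fit = fit, ffs = ffs)
    }, error = function(e) {
      .log_line("cohort ", lab, ": FAILED: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) next
    fits[[lab]] <- res$fit
    familial[[lab]] <- res$ffs
    ff_file <- file.path(config$output_dir,
                         paste0("familial_fitness_", lab, ".csv"))
    utils::write.csv(as.data.frame(res$ffs), ff_file, row.names = FALSE)
    before <- cohort_mean_fitness(res$ffs)
    after <- after_selection_mean(res$ffs$mu, attr(res$ffs, "cov"))
    rows[[lab]] <- data.frame(
      label = lab, site = res$fit$cohort$site[1],
      year = res$fit$cohort$year[1], gen = res$fit$cohort$gen[1],
      n_families = nrow(res$ffs),
      before = before$estimate, before_se = before$se,
      after = after$estimate, after_se = after$se)
  }
  cohort_table <- do.call(rbind, rows)
  ct_file <- file.path(config$output_dir, "cohort_mean_fitness.csv")
  if (!is.null(cohort_table))
    utils::write.csv(cohort_table, ct_file, row.names = FALSE)
  partitions <- list()
  for (pr in config$pairs) {
    labs <- unlist(pr[c("prev", "par", "off")])
    pid <- paste(labs, collapse = "__")
    if (!all(labs %in% names(familial))) {
      .log_line("pair ", pid, ": skipped (missing cohort fit)")
      next
    }
    pair <- cohort_pair(familial[[labs[1]]], familial[[labs[2]]],
                        familial[[labs[3]]])
    part <- partition_change(pair, conf = config$conf)
    partitions[[pid]] <- part
    utils::write.csv(as.data.frame(part),
                     file.path(config$output_dir,
                               paste0("partition_", pid, ".csv")),
                     row.names = FALSE)
    .log_line("pair ", pid, ": total ", format(part$estimate[1]),
              " = selection ", format(part$estimate[2]),
              " + environmental ", format(part$estimate[3]),
              " + residual ", format(part$estimate[4]))
  }
  log_file <- file.path(config$output_dir, "run_log.json")
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("asterpart")),
         r_version = R.version.string, seed = config$seed,
         conf = config$conf,
         cohorts_fitted = names(fits),
         pairs = names(partitions)),
    log_file, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(fits = fits, familial = familial,
                 cohort_table = cohort_table, partitions = partitions,
                 output_dir = config$output_dir))
}
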