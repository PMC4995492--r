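## End-to-end orchestration: simulate (or load) a cohort, filter every pair,
## run the concordance estimator, the mutation spectrum, the clinical
## associations and (optionally) the reference-standard validation, and
## consolidate everything into one report bundle.

#' Run the full analysis pipeline
#'
#' Deterministic given the seed carried by the configuration. Exactly one of
#' a simulation config or a pre-built input set must be supplied. Each stage
#' result in the bundle is the unmodified return value of the corresponding
#' stage function, so every reported number is recomputable stage by stage.
#'
#' @param config list with components:
#'   * `simulate`: a [cohort_config()] (or `NULL` when `inputs` is given);
#'   * `inputs`: list with `pairs` (list of [sample_pair()]s), `clinical`
#'     (a `clinical_table` or `NULL`) and `regions`;
#'   * `tissue_profile`, `plasma_profile`: [filter_profile()]s (defaults:
#'     the published thresholds);
#'   * `ci_method`: interval method for [concordance()];
#'   * `standards`: `NULL`, or a list of arguments for
#'     [simulate_reference_standards()] plus optional `rule`/`threshold`
#'     for [estimate_lod()];
#'   * `cfdna_floor`: quantification floor for the marker comparison.
#' @return object of class `ctdna_report`: list with `filtered_pairs`,
#'   `traces`, `concordance`, `spectrum`, `associations`, `markers`, `lod`
#'   (absent when no standards are configured), `seed` and `config_digest`.
#' @export
run_pipeline <- function(config) {
  has_sim <- !is.null(config$simulate)
  has_inp <- !is.null(config$inputs)
  if (has_sim == has_inp)
    stop("supply exactly one of config$simulate or config$inputs")
  tissue_profile <- config$tissue_profile %||% filter_profile("tissue")
  plasma_profile <- config$plasma_profile %||% filter_profile("plasma")
  ci_method <- config$ci_method %||% "wilson"
  if (has_sim) {
    cohort <- simulate_cohort(config$simulate)
    pairs <- cohort$pairs
    clinical <- cohort$clinical
    regions <- cohort$regions
    seed <- config$simulate$seed
  } else {
    pairs <- config$inputs$pairs
    clinical <- config$inputs$clinical
    regions <- config$inputs$regions
    seed <- config$inputs$seed %||% NA_integer_
  }
  filtered <- lapply(pairs, run_filter_pipeline,
                     tissue_profile = tissue_profile,
                     plasma_profile = plasma_profile, regions = regions)
  fpairs <- lapply(filtered, `[[`, "pair")
  traces <- lapply(filtered, `[[`, "traces")
  names(traces) <- vapply(fpairs, `[[`, character(1), "patient_id")
  report <- list(
    filtered_pairs = fpairs,
    traces = traces,
    concordance = concordance(fpairs, ci_method = ci_method),
    spectrum = mutation_spectrum(fpairs, clinical),
    associations = if (!is.null(clinical)) cfdna_feature_table(clinical),
    markers = if (!is.null(clinical))
      detection_comparison(clinical, config$cfdna_floor %||% 0),
    seed = seed)
  if (!is.null(config$standards)) {
    st <- config$standards
    runs <- simulate_reference_standards(
      fractions = st$fractions %||% c(0, 0.001, 0.005, 0.01),
      replicates = st$replicates %||% 12,
      depth = st$depth %||% 10000,
      error_rate = st$error_rate %||% 0,
      seed = st$seed %||% seed)
    report$lod <- estimate_lod(runs, rule = st$rule %||% "majority",
                               threshold = st$threshold %||% 0.5)
  }
  report$config_digest <- .config_digest(config)
  structure(report, class = "ctdna_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## small stable fingerprint of the configuration (stamped on the report)
.config_digest <- function(config) {
  txt <- paste(utils::capture.output(utils::str(config, give.attr = FALSE)),
               collapse = "\n")
  ints <- utf8ToInt(txt)
  sum(ints * (seq_along(ints) %% 97 + 1)) %% 1000000007
}

#' @export
print.ctdna_report <- function(x, ...) {
  cat(sprintf("ctDNA concordance report (seed %s, config digest %d)\n",
              format(x$seed), x$config_digest))
  print(x$concordance)
  print(x$spectrum)
  if (!is.null(x$markers)) print(x$markers)
  if (!is.null(x$lod)) print(x$lod)
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits `summary.json` (metrics, CIs, category counts, tallies, marker and
#' LoD blocks), `per_pair.tsv` (pair categories and fractional counts),
#' `associations.tsv`, and a per-sample mutation matrix
#' `mutation_matrix.tsv` (pairs x mutation keys, values `T`, `P`, `TP` or
#' empty).
#'
#' @param report a `ctdna_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cc <- report$concordance
  summ <- list(
    seed = report$seed,
    config_digest = report$config_digest,
    n_pairs = cc$summary$n_pairs,
    totals = as.list(cc$summary$totals),
    metrics = cc$summary$metrics,
    ci_method = cc$summary$ci_method,
    category_counts = as.list(cc$category_counts),
    tallies = report$spectrum$tallies)
  if (!is.null(report$markers)) summ$markers <- unclass(report$markers)
  if (!is.null(report$lod))
    summ$lod <- list(accuracy = report$lod$accuracy, lod = report$lod$lod,
                     rule = report$lod$rule,
                     mean_rates = as.list(report$lod$mean_rates))
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "null")
  utils::write.table(cc$per_pair, file.path(dir, "per_pair.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(report$associations))
    utils::write.table(report$associations, file.path(dir, "associations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(mutation_matrix(report$filtered_pairs),
                     file.path(dir, "mutation_matrix.tsv"), sep = "\t",
                     quote = FALSE, row.names = TRUE, col.names = NA)
  invisible(dir)
}

#' Per-sample mutation matrix
#'
#' Pairs as rows, distinct mutation keys as columns; cell values `"T"`
#' (tumor only), `"P"` (plasma only), `"TP"` (both) or `""`.
#'
#' @param pairs list of post-filter [sample_pair()]s.
#' @return character matrix.
#' @export
mutation_matrix <- function(pairs) {
  matches <- lapply(pairs, function(p) match_mutations(p$tumor, p$plasma))
  keys <- sort(unique(unlist(lapply(matches, unlist))))
  ids <- vapply(pairs, `[[`, character(1), "patient_id")
  m <- matrix("", nrow = length(pairs), ncol = length(keys),
              dimnames = list(ids, keys))
  for (i in seq_along(matches)) {
    m[i, matches[[i]]$concordant] <- "TP"
    m[i, matches[[i]]$tdna_only] <- "T"
    m[i, matches[[i]]$ctdna_only] <- "P"
  }
  m
}
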