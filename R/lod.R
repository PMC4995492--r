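## Reference-standard validation: call variants on dilution-series replicates
## with the plasma thresholds, estimate assay accuracy on the negative
## standards and the limit of detection across mixture fractions.

#' Call variants on one reference-standard run
#'
#' A control site is detected iff its read evidence passes the profile's
#' variant-coverage, VAF and p-value bounds (the sample-level mean-depth bound
#' is taken as met by design of the dilution experiment; strand-bias and
#' hotspot steps do not apply because the six control loci are the site
#' universe). The binomial p-value is computed at the run's own error rate,
#' or at `p_error` when supplied.
#'
#' @param run a `standard_run` from [simulate_reference_standards()].
#' @param profile a [filter_profile()], default the plasma profile without
#'   hotspot restriction.
#' @param p_error error rate for the p-value computation; default the run's
#'   simulated error rate.
#' @return logical vector over the run's sites, `TRUE` = detected.
#' @export
call_standard_run <- function(run,
                              profile = filter_profile("plasma",
                                                       apply_hotspot = FALSE),
                              p_error = NULL) {
  ev <- run$evidence
  if (is.null(p_error)) p_error <- run$error_rate
  vaf <- ifelse(ev$depth > 0, ev$alt_reads / ev$depth, NA_real_)
  pv <- variant_pvalue(ev$alt_reads, ev$depth, p_error)
  ge <- if (profile$inclusive) `>=` else `>`
  det <- ge(ev$alt_reads, profile$min_alt_reads) &
    !is.na(vaf) & ge(vaf, profile$min_vaf) & pv < profile$max_p
  stats::setNames(det, ev$site)
}

#' Estimate accuracy and limit of detection from dilution runs
#'
#' Per (fraction, site), the detection rate is the share of replicates in
#' which the site was called. Accuracy is the share of zero-fraction
#' replicates with no call at any site. The limit of detection is the lowest
#' tested positive fraction whose mean per-site detection rate satisfies the
#' rule: `"majority"` (mean rate >= `threshold`, default 0.5), `"all"` (every
#' site in every replicate) or `"any"` (at least one detection).
#'
#' @param runs list of `standard_run`s, including zero-fraction runs for the
#'   accuracy estimate (a warning is issued and accuracy is `NA` otherwise).
#' @param profile a [filter_profile()], see [call_standard_run()].
#' @param rule detection rule, one of `"majority"`, `"all"`, `"any"`.
#' @param threshold mean detection-rate threshold for the majority rule.
#' @param p_error see [call_standard_run()].
#' @return object of class `lod_estimate` with `detection_rates` (fraction x
#'   site matrix), `mean_rates`, `accuracy`, `lod` (numeric, or `NA` when not
#'   reached) and the rule used.
#' @export
estimate_lod <- function(runs, profile = filter_profile("plasma",
                                                        apply_hotspot = FALSE),
                         rule = c("majority", "all", "any"), threshold = 0.5,
                         p_error = NULL) {
  rule <- match.arg(rule)
  stopifnot(length(runs) > 0)
  fr <- vapply(runs, `[[`, numeric(1), "nominal_fraction")
  n_sites <- nrow(runs[[1]]$evidence)
  det <- matrix(unlist(lapply(runs, call_standard_run, profile = profile,
                              p_error = p_error)),
                nrow = length(runs), ncol = n_sites, byrow = TRUE,
                dimnames = list(NULL, runs[[1]]$evidence$site))
  fractions <- sort(unique(fr))
  rates <- matrix(unlist(lapply(fractions, function(f)
    colMeans(det[fr == f, , drop = FALSE]))),
    nrow = length(fractions), ncol = n_sites, byrow = TRUE,
    dimnames = list(as.character(fractions), colnames(det)))
  mean_rates <- rowMeans(rates)
  if (any(fr == 0)) {
    neg <- det[fr == 0, , drop = FALSE]
    accuracy <- mean(rowSums(neg) == 0)
  } else {
    warning("no zero-fraction runs; accuracy undefined")
    accuracy <- NA_real_
  }
  pos <- fractions[fractions > 0]
  hit <- vapply(pos, function(f) {
    sub <- det[fr == f, , drop = FALSE]
    switch(rule,
           majority = mean(sub) >= threshold,
           all = all(sub),
           any = any(sub))
  }, logical(1))
  lod <- if (any(hit)) min(pos[hit]) else NA_real_
  structure(list(detection_rates = rates, mean_rates = mean_rates,
                 accuracy = accuracy, lod = lod, rule = rule,
                 threshold = threshold), class = "lod_estimate")
}

#' @export
print.lod_estimate <- function(x, ...) {
  cat("Reference-standard validation\n")
  cat(sprintf("  accuracy on negative standards: %s\n",
              if (is.na(x$accuracy)) "undefined" else
                sprintf("%.1f%%", 100 * x$accuracy)))
  for (f in rownames(x$detection_rates))
    cat(sprintf("  fraction %-6s mean detection rate %.2f\n", f,
                x$mean_rates[[f]]))
  cat(sprintf("  limit of detection (%s rule): %s\n", x$rule,
              if (is.na(x$lod)) "not reached" else format(x$lod)))
  invisible(x)
}

#' Closed-form per-site detection probability
#'
#' Probability that a site at true fraction `f`, depth `D` and error rate `e`
#' passes the profile's bounds: `P[X >= x_min]` for
#' `X ~ Binomial(D, f + (1-f)e)` where `x_min` is the smallest read count
#' satisfying the coverage, VAF and p-value thresholds. Independent analytic
#' counterpart of the Monte-Carlo detection rate.
#'
#' @param fraction true mutant fraction.
#' @param depth sequencing depth.
#' @param error_rate simulation error rate.
#' @param profile a [filter_profile()].
#' @param p_error error rate used in the p-value bound (defaults to
#'   `error_rate`).
#' @return detection probability.
#' @export
detection_probability <- function(fraction, depth, error_rate = 0,
                                  profile = filter_profile("plasma",
                                                           apply_hotspot = FALSE),
                                  p_error = error_rate) {
  x <- 0:depth
  ge <- if (profile$inclusive) `>=` else `>`
  pass <- ge(x, profile$min_alt_reads) & ge(x / depth, profile$min_vaf) &
    variant_pvalue(x, depth, p_error) < profile$max_p
  x_min <- if (any(pass)) min(x[pass]) else depth + 1L
  p <- fraction + (1 - fraction) * error_rate
  stats::pbinom(x_min - 1, depth, p, lower.tail = FALSE)
}
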