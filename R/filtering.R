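## Three-step somatic variant filtering for tissue and plasma call sets:
## threshold filter (sample mean depth, variant coverage, VAF, p-value),
## Fisher strand-bias proxy, hotspot-panel restriction; plus germline
## subtraction against the matched WBC call set. All threshold comparisons are
## strict, matching the printed bounds (">1000", ">20", ">5%", "p < 0.01").

#' Filtering profile for one compartment
#'
#' Defaults encode the published bounds: tissue samples require sample mean
#' depth > 1000x, variant coverage > 20 reads, VAF > 5% and p < 0.01; plasma
#' samples require mean depth > 10000x, variant coverage > 10 reads,
#' VAF > 0.1% and p < 0.01. `inclusive = TRUE` relaxes the read-count and VAF
#' bounds to >=, the alternative reading of the printed inequalities relevant
#' at the detection limit (a 0.1% variant at 10000x has an expected coverage
#' of exactly 10 reads, which the strict reading rejects half the time).
#'
#' @param name `"tissue"` or `"plasma"` (selects the default thresholds).
#' @param min_mean_depth sample-level mean coverage bound (strict >).
#' @param min_alt_reads variant coverage bound (strict > unless `inclusive`).
#' @param min_vaf VAF bound as a fraction (strict > unless `inclusive`).
#' @param max_p p-value bound (strict <).
#' @param error_rate per-base error rate used to compute a binomial tail
#'   p-value for calls that carry none.
#' @param strand_bias_alpha Fisher-test level for the strand-bias step.
#' @param apply_hotspot whether the hotspot restriction step runs.
#' @param inclusive use >= / <= for the alt-read and VAF bounds.
#' @return object of class `filter_profile`.
#' @export
filter_profile <- function(name = c("tissue", "plasma"),
                           min_mean_depth = NULL, min_alt_reads = NULL,
                           min_vaf = NULL, max_p = 0.01, error_rate = 0.001,
                           strand_bias_alpha = 0.001, apply_hotspot = TRUE,
                           inclusive = FALSE) {
  name <- match.arg(name)
  def <- switch(name,
    tissue = list(depth = 1000, alt = 20, vaf = 0.05),
    plasma = list(depth = 10000, alt = 10, vaf = 0.001))
  p <- list(name = name,
            min_mean_depth = if (is.null(min_mean_depth)) def$depth else min_mean_depth,
            min_alt_reads = if (is.null(min_alt_reads)) def$alt else min_alt_reads,
            min_vaf = if (is.null(min_vaf)) def$vaf else min_vaf,
            max_p = max_p, error_rate = error_rate,
            strand_bias_alpha = strand_bias_alpha,
            apply_hotspot = apply_hotspot, inclusive = inclusive)
  stopifnot(p$min_mean_depth >= 0, p$min_alt_reads >= 0, p$min_vaf >= 0,
            p$max_p >= 0, p$max_p <= 1)
  structure(p, class = "filter_profile")
}

#' Binomial tail p-value for a variant call
#'
#' Upper-tail probability `P[X >= alt_reads]` for `X ~ Binomial(depth,
#' error_rate)`: the probability that sequencing error alone produces at least
#' the observed variant coverage. Stand-in for the (undisclosed) caller test;
#' computed exactly at any depth. `alt_reads = 0` gives 1 (the whole sample
#' space); `error_rate = 0` with `alt_reads > 0` gives 0 (errors impossible).
#'
#' @param alt_reads observed variant-supporting reads (vectorized).
#' @param depth total reads.
#' @param error_rate per-base substitution probability in `[0, 1)`.
#' @return p-value vector in `[0,1]`.
#' @export
variant_pvalue <- function(alt_reads, depth, error_rate) {
  stopifnot(all(alt_reads <= depth), error_rate >= 0, error_rate < 1)
  stats::pbinom(alt_reads - 1, depth, error_rate, lower.tail = FALSE)
}

.new_trace <- function(n = 0L) {
  data.frame(chrom = character(n), pos = integer(n), ref = character(n),
             alt = character(n), disposition = character(n),
             stringsAsFactors = FALSE)
}

.trace_rows <- function(calls, disposition) {
  if (nrow(calls) == 0L) return(.new_trace())
  data.frame(chrom = calls$chrom, pos = calls$pos, ref = calls$ref,
             alt = calls$alt, disposition = disposition,
             stringsAsFactors = FALSE)
}

#' Threshold filter (step one)
#'
#' If the sample-level mean depth fails its bound every call is removed with
#' disposition `mean_depth`. Otherwise a call survives iff its variant
#' coverage, VAF and p-value all pass; the first failing bound (in that order)
#' is recorded as the disposition. A zero-depth call has undefined VAF and is
#' removed with disposition `vaf`. Calls lacking a p-value get one from
#' [variant_pvalue()] at the profile's error rate.
#'
#' @param cs a [call_set()].
#' @param profile a [filter_profile()].
#' @return list with the filtered `call_set` and a `trace` data.frame holding
#'   one disposition per input call.
#' @export
apply_threshold_filter <- function(cs, profile) {
  calls <- cs$calls
  if (nrow(calls) == 0L)
    return(list(callset = cs, trace = .new_trace()))
  if (!(cs$mean_depth > profile$min_mean_depth)) {
    out <- call_set(empty_calls(), cs$sample_id, cs$sample_type, cs$mean_depth)
    return(list(callset = out, trace = .trace_rows(calls, "mean_depth")))
  }
  pv <- calls$p_value
  needs <- is.na(pv)
  pv[needs] <- variant_pvalue(calls$alt_reads[needs], calls$depth[needs],
                              profile$error_rate)
  vaf <- call_vaf(calls)
  ge <- if (profile$inclusive) `>=` else `>`
  pass_alt <- ge(calls$alt_reads, profile$min_alt_reads)
  pass_vaf <- !is.na(vaf) & ge(vaf, profile$min_vaf)
  pass_p <- pv < profile$max_p
  disposition <- ifelse(calls$depth == 0L, "vaf",  # VAF undefined = fail
                 ifelse(!pass_alt, "alt_reads",
                 ifelse(!pass_vaf, "vaf",
                 ifelse(!pass_p, "p_value", "kept"))))
  kept <- disposition == "kept"
  out_calls <- calls[kept, , drop = FALSE]
  out_calls$p_value <- pv[kept]
  rownames(out_calls) <- NULL
  list(callset = call_set(out_calls, cs$sample_id, cs$sample_type, cs$mean_depth),
       trace = .trace_rows(calls, disposition))
}

#' Strand-bias filter decision for one call (step two)
#'
#' Automated proxy for manual strand-artifact review: a two-sided Fisher exact
#' test on the 2x2 table of forward/reverse read-orientation counts for the
#' reference and alternate alleles. The call is dropped iff p < alpha. An
#' all-zero table carries no evidence and is kept.
#'
#' @param ref_fwd,ref_rev,alt_fwd,alt_rev strand counts (vectorized).
#' @param alpha test level, default 0.001 (conservative: only gross imbalance
#'   is removed).
#' @return logical vector, `TRUE` = keep.
#' @export
strand_bias_keep <- function(ref_fwd, ref_rev, alt_fwd, alt_rev, alpha = 0.001) {
  stopifnot(alpha > 0, alpha < 1)
  n <- length(ref_fwd)
  if (n == 0L) return(logical(0))
  vapply(seq_len(n), function(i) {
    tab <- matrix(c(ref_fwd[i], alt_fwd[i], ref_rev[i], alt_rev[i]), nrow = 2)
    if (sum(tab) == 0) return(TRUE)
    stats::fisher.test(tab)$p.value >= alpha
  }, logical(1))
}

#' Apply the strand-bias filter to a call set
#'
#' @param cs a [call_set()].
#' @param alpha Fisher-test level, see [strand_bias_keep()].
#' @return list of filtered `call_set` and `trace`.
#' @export
apply_strand_bias_filter <- function(cs, alpha = 0.001) {
  calls <- cs$calls
  if (nrow(calls) == 0L) return(list(callset = cs, trace = .new_trace()))
  keep <- strand_bias_keep(calls$ref_fwd, calls$ref_rev,
                           calls$alt_fwd, calls$alt_rev, alpha)
  out <- calls[keep, , drop = FALSE]; rownames(out) <- NULL
  list(callset = call_set(out, cs$sample_id, cs$sample_type, cs$mean_depth),
       trace = .trace_rows(calls, ifelse(keep, "kept", "strand_bias")))
}

#' Hotspot restriction (step three)
#'
#' A call survives iff its 1-based position falls inside at least one panel
#' region (see [positions_in_regions()] for the coordinate rule). An empty
#' region set therefore removes every call.
#'
#' @param cs a [call_set()].
#' @param regions a `hotspot_regions` object.
#' @return list of filtered `call_set` and `trace`.
#' @export
apply_hotspot_filter <- function(cs, regions) {
  calls <- cs$calls
  if (nrow(calls) == 0L) return(list(callset = cs, trace = .new_trace()))
  keep <- positions_in_regions(calls$chrom, calls$pos, regions)
  out <- calls[keep, , drop = FALSE]; rownames(out) <- NULL
  list(callset = call_set(out, cs$sample_id, cs$sample_type, cs$mean_depth),
       trace = .trace_rows(calls, ifelse(keep, "kept", "hotspot")))
}

#' Subtract germline variants seen in the matched WBC sample
#'
#' Removes any call whose normalized `(chrom, pos, ref, alt)` key appears in
#' the white-blood-cell call set. An empty WBC set is the identity.
#'
#' @param cs a [call_set()].
#' @param wbc the matched germline [call_set()] (type `"wbc"`).
#' @return list of filtered `call_set` and `trace`.
#' @export
subtract_germline <- function(cs, wbc) {
  calls <- cs$calls
  if (nrow(calls) == 0L) return(list(callset = cs, trace = .new_trace()))
  wbc_keys <- if (nrow(wbc$calls) > 0)
    mutation_key(wbc$calls$chrom, wbc$calls$pos, wbc$calls$ref, wbc$calls$alt)
  else character(0)
  keys <- mutation_key(calls$chrom, calls$pos, calls$ref, calls$alt)
  keep <- !(keys %in% wbc_keys)
  out <- calls[keep, , drop = FALSE]; rownames(out) <- NULL
  list(callset = call_set(out, cs$sample_id, cs$sample_type, cs$mean_depth),
       trace = .trace_rows(calls, ifelse(keep, "kept", "germline")))
}

.merge_traces <- function(...) {
  traces <- list(...)
  out <- NULL
  for (tr in traces) {
    if (is.null(out)) { out <- tr; next }
    # later stages only re-judge calls the earlier stage kept
    removed <- tr[tr$disposition != "kept", , drop = FALSE]
    if (nrow(removed) > 0) {
      key_out <- paste(out$chrom, out$pos, out$ref, out$alt)
      key_rm <- paste(removed$chrom, removed$pos, removed$ref, removed$alt)
      idx <- match(key_rm, key_out)
      out$disposition[idx] <- removed$disposition
    }
  }
  if (is.null(out)) out <- .new_trace()
  out
}

#' Filter one compartment through the full stage order
#'
#' Threshold filter, then strand-bias filter, then hotspot restriction, then
#' (when a WBC set is supplied) germline subtraction. Each filter is a pure
#' predicate on the call, so the surviving set does not depend on stage order;
#' the trace attributes each removal to the first stage (in this order) that
#' rejects it.
#'
#' @param cs a [call_set()].
#' @param profile a [filter_profile()].
#' @param regions hotspot panel; required when `profile$apply_hotspot`.
#' @param wbc optional germline [call_set()] for subtraction.
#' @return list of filtered `call_set` and consolidated `trace`.
#' @export
filter_callset <- function(cs, profile, regions = NULL, wbc = NULL) {
  s1 <- apply_threshold_filter(cs, profile)
  s2 <- apply_strand_bias_filter(s1$callset, profile$strand_bias_alpha)
  if (profile$apply_hotspot) {
    if (is.null(regions)) stop("profile requires hotspot regions")
    s3 <- apply_hotspot_filter(s2$callset, regions)
  } else s3 <- list(callset = s2$callset, trace = .new_trace())
  if (!is.null(wbc)) s4 <- subtract_germline(s3$callset, wbc)
  else s4 <- list(callset = s3$callset, trace = .new_trace())
  list(callset = s4$callset,
       trace = .merge_traces(s1$trace, s2$trace, s3$trace, s4$trace))
}

#' Run the complete filtering pipeline on one sample pair
#'
#' The WBC compartment passes threshold filtering only (it serves as the
#' germline reference, with the tissue profile's bounds relaxed to its own
#' depth regime by default); tumor and plasma compartments then run the full
#' stage order with germline subtraction against the filtered WBC calls.
#'
#' @param pair a [sample_pair()].
#' @param tissue_profile,plasma_profile [filter_profile()]s; defaults are the
#'   published tissue and plasma thresholds.
#' @param regions hotspot panel.
#' @param wbc_profile profile for the WBC threshold step; defaults to the
#'   tissue profile.
#' @return list with the filtered `pair` and per-compartment `traces`.
#' @export
run_filter_pipeline <- function(pair,
                                tissue_profile = filter_profile("tissue"),
                                plasma_profile = filter_profile("plasma"),
                                regions = NULL,
                                wbc_profile = tissue_profile) {
  wbc_f <- apply_threshold_filter(pair$wbc, wbc_profile)
  tum <- filter_callset(pair$tumor, tissue_profile, regions, wbc_f$callset)
  pla <- filter_callset(pair$plasma, plasma_profile, regions, wbc_f$callset)
  list(pair = sample_pair(pair$patient_id, tum$callset, pla$callset,
                          wbc_f$callset),
       traces = list(tumor = tum$trace, plasma = pla$trace, wbc = wbc_f$trace))
}
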