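## Per-pair mutation matching, fractional TP/FP/FN/TN allocation, and the
## aggregate concordance / sensitivity / specificity / plasma PPV estimator.
## Tumor tissue is the reference standard: a mutation present in both
## compartments is a true positive, plasma-only is a false positive,
## tumor-only a false negative, and a mutation-free pair a true negative.
## Pairs with several mutations contribute fractional pair-equivalents so the
## cohort total stays at n pairs.

#' Match mutations between the two compartments of a pair
#'
#' Compares normalized `(chrom, pos, ref, alt)` keys; VAFs are irrelevant to
#' matching. Duplicate keys within one compartment are collapsed with a
#' warning (matching is set-based).
#'
#' @param tumor_calls,plasma_calls post-filter call tables (or `call_set`s).
#' @return object of class `mutation_match`: list of disjoint key sets
#'   `concordant`, `tdna_only`, `ctdna_only`.
#' @export
match_mutations <- function(tumor_calls, plasma_calls) {
  keys <- function(x) {
    if (inherits(x, "call_set")) x <- x$calls
    if (nrow(x) == 0L) return(character(0))
    k <- mutation_key(x$chrom, x$pos, x$ref, x$alt)
    if (anyDuplicated(k)) {
      warning("duplicate mutation keys within one compartment collapsed")
      k <- unique(k)
    }
    k
  }
  tk <- keys(tumor_calls); pk <- keys(plasma_calls)
  structure(list(concordant = intersect(tk, pk),
                 tdna_only = setdiff(tk, pk),
                 ctdna_only = setdiff(pk, tk)),
            class = "mutation_match")
}

#' Categorize a pair by its mutation-match structure
#'
#' @param match a [match_mutations()] result.
#' @return one of `"none"` (no mutations in either compartment),
#'   `"concordant_only"`, `"concordant_plus_discordant"`, `"tdna_only"`,
#'   `"ctdna_only"`, `"discordant_both"`.
#' @export
classify_pair <- function(match) {
  nc <- length(match$concordant)
  nt <- length(match$tdna_only)
  np <- length(match$ctdna_only)
  if (nc == 0 && nt == 0 && np == 0) return("none")
  if (nc > 0) {
    if (nt == 0 && np == 0) return("concordant_only")
    return("concordant_plus_discordant")
  }
  if (nt > 0 && np > 0) return("discordant_both")
  if (nt > 0) return("tdna_only")
  "ctdna_only"
}

#' Fractional TP/FP/FN/TN allocation for one pair
#'
#' With C concordant, Fp plasma-only and Fn tumor-only mutations and
#' T = C + Fp + Fn, each mutation carries weight 1/T toward its group:
#' tp = C/T, fp = Fp/T, fn = Fn/T. A mutation-free pair is one whole true
#' negative. Every pair therefore contributes exactly one pair-equivalent
#' (tp + fp + fn + tn = 1), keeping the cohort total at n.
#'
#' @param match a [match_mutations()] result.
#' @return named numeric vector `c(tp, fp, fn, tn)` summing to 1.
#' @export
allocate_fractions <- function(match) {
  C <- length(match$concordant)
  Fp <- length(match$ctdna_only)
  Fn <- length(match$tdna_only)
  Tt <- C + Fp + Fn
  if (Tt == 0) return(c(tp = 0, fp = 0, fn = 0, tn = 1))
  # direct ratios (not 1/T times the count) so printed decimals are exact
  c(tp = C / Tt, fp = Fp / Tt, fn = Fn / Tt, tn = 0)
}

#' Confidence interval for a proportion with fractional counts
#'
#' Default is the Wilson score interval evaluated at `z = 1.959964` (95%),
#' which is well defined for non-integer effective numerators and
#' denominators; Wald and Clopper-Pearson (computed on rounded counts, via the
#' beta quantile form) are selectable.
#'
#' @param numerator effective successes, `>= 0` (may be fractional).
#' @param denominator effective trials, `> 0` (may be fractional).
#' @param method `"wilson"`, `"wald"` or `"clopper-pearson"`.
#' @param conf confidence level, default 0.95.
#' @return numeric `c(lo, hi)`; `c(NA, NA)` when the denominator is 0.
#' @export
proportion_ci <- function(numerator, denominator,
                          method = c("wilson", "wald", "clopper-pearson"),
                          conf = 0.95) {
  method <- match.arg(method)
  if (is.na(denominator) || denominator <= 0) return(c(lo = NA_real_, hi = NA_real_))
  stopifnot(numerator >= 0, numerator <= denominator)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  n <- denominator
  p <- numerator / denominator
  if (method == "wilson") {
    den <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / den
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    out <- c(centre - half, centre + half)
  } else if (method == "wald") {
    half <- z * sqrt(p * (1 - p) / n)
    out <- c(p - half, p + half)
  } else {
    x <- round(numerator); nn <- round(denominator)
    a <- (1 - conf) / 2
    lo <- if (x == 0) 0 else stats::qbeta(a, x, nn - x + 1)
    hi <- if (x == nn) 1 else stats::qbeta(1 - a, x + 1, nn - x)
    out <- c(lo, hi)
  }
  out <- pmin(pmax(out, 0), 1)
  names(out) <- c("lo", "hi")
  out
}

#' Aggregate fractional counts into cohort-level metrics
#'
#' Sums per-pair pair-equivalents and computes concordance
#' `(tp + tn) / n`, sensitivity `tp / (tp + fn)`, specificity
#' `tn / (tn + fp)` and plasma positive predictive value `tp / (tp + fp)`,
#' each with a [proportion_ci()] on its effective (possibly fractional)
#' counts. A metric whose denominator is 0 is reported as `NA` (undefined),
#' never silently 0.
#'
#' @param counts matrix or data.frame with columns `tp`, `fp`, `fn`, `tn`,
#'   one row per pair.
#' @param ci_method passed to [proportion_ci()].
#' @return object of class `concordance_summary`.
#' @export
aggregate_concordance <- function(counts, ci_method = "wilson") {
  counts <- as.data.frame(counts)
  n <- nrow(counts)
  if (n == 0L) stop("no pairs to aggregate")
  tot <- vapply(c("tp", "fp", "fn", "tn"), function(k) sum(counts[[k]]),
                numeric(1))
  ratio <- function(num, den) if (den > 0) unname(num / den) else NA_real_
  metric <- function(num, den) {
    est <- ratio(num, den)
    ci <- if (is.na(est)) c(lo = NA_real_, hi = NA_real_)
          else proportion_ci(num, den, method = ci_method)
    c(estimate = est, ci)
  }
  m <- rbind(
    concordance = metric(tot["tp"] + tot["tn"], n),
    sensitivity = metric(tot["tp"], tot["tp"] + tot["fn"]),
    specificity = metric(tot["tn"], tot["tn"] + tot["fp"]),
    ppv         = metric(tot["tp"], tot["tp"] + tot["fp"]))
  structure(list(n_pairs = n, totals = tot,
                 metrics = as.data.frame(m), ci_method = ci_method),
            class = "concordance_summary")
}

#' Concordance analysis of filtered sample pairs
#'
#' The top-level estimator: matches mutations within each pair, categorizes
#' the pair, allocates fractional pair-equivalents, and aggregates them into
#' cohort concordance, sensitivity, specificity and plasma PPV with
#' confidence intervals.
#'
#' @param pairs list of post-filter [sample_pair()]s.
#' @param ci_method interval method, see [proportion_ci()].
#' @return object of class `ctdna_concordance` with components `per_pair`
#'   (patient id, category and fractional counts), `summary`
#'   (a `concordance_summary`), and `category_counts`.
#' @seealso [coef.ctdna_concordance()], [confint.ctdna_concordance()]
#' @export
concordance <- function(pairs, ci_method = "wilson") {
  stopifnot(length(pairs) > 0)
  rows <- lapply(pairs, function(p) {
    m <- match_mutations(p$tumor, p$plasma)
    fr <- allocate_fractions(m)
    data.frame(patient_id = p$patient_id, category = classify_pair(m),
               n_concordant = length(m$concordant),
               n_tdna_only = length(m$tdna_only),
               n_ctdna_only = length(m$ctdna_only),
               tp = fr["tp"], fp = fr["fp"], fn = fr["fn"], tn = fr["tn"],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  per_pair <- do.call(rbind, rows)
  summ <- aggregate_concordance(per_pair[c("tp", "fp", "fn", "tn")], ci_method)
  cats <- c("concordant_only", "concordant_plus_discordant", "tdna_only",
            "ctdna_only", "discordant_both", "none")
  structure(list(per_pair = per_pair, summary = summ,
                 category_counts = table(factor(per_pair$category, cats)),
                 ci_method = ci_method),
            class = "ctdna_concordance")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf("Concordance over %d sample pairs (%s intervals)\n",
              x$n_pairs, x$ci_method))
  cat(sprintf("  totals: TP %.2f  FP %.2f  FN %.2f  TN %.2f\n",
              x$totals["tp"], x$totals["fp"], x$totals["fn"], x$totals["tn"]))
  for (nm in rownames(x$metrics)) {
    r <- x$metrics[nm, ]
    if (is.na(r$estimate)) cat(sprintf("  %-12s undefined\n", nm))
    else cat(sprintf("  %-12s %5.1f%%  (95%% CI %.1f%%-%.1f%%)\n",
                     nm, 100 * r$estimate, 100 * r$lo, 100 * r$hi))
  }
  invisible(x)
}

#' @export
print.ctdna_concordance <- function(x, ...) {
  print(x$summary)
  cat("  pair categories:\n")
  for (nm in names(x$category_counts))
    cat(sprintf("    %-27s %d\n", nm, x$category_counts[[nm]]))
  invisible(x)
}

#' @export
summary.ctdna_concordance <- function(object, ...) object$summary

#' Extract the four concordance metrics
#'
#' @param object a `ctdna_concordance` fit.
#' @param ... unused.
#' @return named numeric vector (`concordance`, `sensitivity`, `specificity`,
#'   `ppv`), `NA` for undefined metrics.
#' @export
coef.ctdna_concordance <- function(object, ...) {
  stats::setNames(object$summary$metrics$estimate,
                  rownames(object$summary$metrics))
}

#' Confidence intervals for the concordance metrics
#'
#' @param object a `ctdna_concordance` fit.
#' @param parm metrics to report (default all four).
#' @param level must match the fitted 0.95 level.
#' @param ... unused.
#' @return matrix with columns `lo`, `hi`.
#' @export
confint.ctdna_concordance <- function(object, parm = NULL, level = 0.95, ...) {
  m <- object$summary$metrics
  if (!is.null(parm)) m <- m[parm, , drop = FALSE]
  as.matrix(m[c("lo", "hi")])
}

#' Mutation spectrum of a filtered cohort
#'
#' Per-gene fraction of samples mutated per compartment, variant-class
#' proportions per compartment (and per histology when clinical data is
#' given), and the mutation tallies: compartment totals (a concordant
#' mutation counted in both), the distinct-mutation total (counted once), and
#' the average number of distinct mutations per mutation-positive pair.
#' Calls without a gene label fall in bucket `"unannotated"`.
#'
#' @param pairs list of post-filter [sample_pair()]s.
#' @param clinical optional `clinical_table` for the per-histology breakdown.
#' @return object of class `mutation_spectrum`.
#' @export
mutation_spectrum <- function(pairs, clinical = NULL) {
  n <- length(pairs)
  comp_calls <- function(p, comp) {
    x <- p[[comp]]$calls
    if (nrow(x) == 0L) return(x)
    x$gene[is.na(x$gene) | x$gene == ""] <- "unannotated"
    x$key <- mutation_key(x$chrom, x$pos, x$ref, x$alt)
    x[!duplicated(x$key), , drop = FALSE]
  }
  gene_rate <- function(comp) {
    hits <- lapply(pairs, function(p) unique(comp_calls(p, comp)$gene))
    genes <- sort(unique(unlist(hits)))
    vapply(genes, function(g)
      sum(vapply(hits, function(h) g %in% h, logical(1))) / max(n, 1),
      numeric(1))
  }
  class_prop <- function(comp, idx = seq_len(n)) {
    cls <- unlist(lapply(pairs[idx], function(p) comp_calls(p, comp)$variant_class))
    if (length(cls) == 0L)
      return(c(SNP = NA_real_, MNP = NA_real_, Indel = NA_real_))
    prop.table(table(factor(cls, c("SNP", "MNP", "Indel"))))
  }
  matches <- lapply(pairs, function(p) match_mutations(p$tumor, p$plasma))
  n_t <- sum(vapply(matches, function(m)
    length(m$concordant) + length(m$tdna_only), numeric(1)))
  n_p <- sum(vapply(matches, function(m)
    length(m$concordant) + length(m$ctdna_only), numeric(1)))
  n_c <- sum(vapply(matches, function(m) length(m$concordant), numeric(1)))
  positive <- vapply(matches, function(m) classify_pair(m) != "none", logical(1))
  tal <- mutation_tallies(n_t, n_p, n_c, sum(positive))
  by_hist <- NULL
  if (!is.null(clinical)) {
    ids <- vapply(pairs, `[[`, character(1), "patient_id")
    hist <- clinical$histology[match(ids, clinical$patient_id)]
    by_hist <- lapply(stats::setNames(nm = c("AC", "SCC")), function(h) {
      idx <- which(hist == h)
      list(tumor = class_prop("tumor", idx), plasma = class_prop("plasma", idx))
    })
  }
  structure(list(
    n_pairs = n,
    gene_rates = list(tumor = gene_rate("tumor"), plasma = gene_rate("plasma")),
    class_proportions = list(tumor = class_prop("tumor"),
                             plasma = class_prop("plasma")),
    class_by_histology = by_hist,
    tallies = tal), class = "mutation_spectrum")
}

#' Reconcile mutation tallies
#'
#' Given compartment totals (concordant mutations counted in each
#' compartment), the concordant count, and the number of mutation-positive
#' pairs, returns the combined double-counted total, the distinct-mutation
#' total `tdna + ctdna - concordant`, and the average number of distinct
#' mutations per positive pair.
#'
#' @param n_tdna,n_ctdna per-compartment mutation counts.
#' @param n_concordant mutations found in both compartments.
#' @param n_positive_pairs pairs with at least one mutation.
#' @return list with `total_calls`, `distinct`, `per_positive_pair`.
#' @export
mutation_tallies <- function(n_tdna, n_ctdna, n_concordant, n_positive_pairs) {
  stopifnot(n_concordant <= n_tdna, n_concordant <= n_ctdna)
  distinct <- n_tdna + n_ctdna - n_concordant
  list(total_calls = n_tdna + n_ctdna,
       distinct = distinct,
       n_tdna = n_tdna, n_ctdna = n_ctdna, n_concordant = n_concordant,
       n_positive_pairs = n_positive_pairs,
       per_positive_pair = if (n_positive_pairs > 0)
         distinct / n_positive_pairs else NA_real_)
}

#' @export
print.mutation_spectrum <- function(x, ...) {
  t <- x$tallies
  cat(sprintf("Mutation spectrum over %d pairs\n", x$n_pairs))
  cat(sprintf("  tDNA %d, ctDNA %d, concordant %d -> %d distinct (%.2f per positive pair)\n",
              t$n_tdna, t$n_ctdna, t$n_concordant, t$distinct,
              t$per_positive_pair))
  top <- sort(x$gene_rates$tumor, decreasing = TRUE)
  top <- utils::head(top, 5)
  if (length(top))
    cat("  top tDNA genes:",
        paste(sprintf("%s %.1f%%", names(top), 100 * top), collapse = ", "), "\n")
  invisible(x)
}
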