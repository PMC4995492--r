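## Clinical associations: cfDNA concentration versus dichotomous clinical
## features by Mann-Whitney U, and the cfDNA-versus-serum-tumor-marker
## detection comparison at the clinical assay cut-offs.

#' Mann-Whitney U test
#'
#' U computed from rank sums with midranks for ties
#' (`U = R_x - n_x(n_x+1)/2`); the two-sided p-value comes from
#' [stats::wilcox.test()] — exact enumeration for small untied samples
#' (pooled n <= 12), otherwise the normal approximation with tie and
#' continuity correction. Swapping the samples maps U to
#' `n_x * n_y - U` and leaves p unchanged.
#'
#' @param x,y non-empty numeric vectors.
#' @return list with `U`, `p`, `n_x`, `n_y`.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) + length(y) <= 12
  if (length(unique(c(x, y))) == 1L) {
    p <- 1  # all pooled values identical: rank variance 0, no evidence
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
  }
  list(U = U, p = p, n_x = length(x), n_y = length(y))
}

.default_features <- function() list(
  age = function(d) ifelse(d$age < 65, "<65", ">=65"),
  sex = function(d) d$sex,
  ggo = function(d) ifelse(d$ggo_dominant, "Y", "N"),
  differentiation = function(d) d$differentiation,
  vascular_invasion = function(d) ifelse(d$vascular_invasion, "Y", "N"),
  vpi = function(d) ifelse(d$vpi, "Y", "N"),
  histology = function(d) d$histology,
  stage = function(d) ifelse(d$stage == "IIA", "II", "I"))

#' cfDNA-concentration association table
#'
#' One row per clinical feature: each feature induces a two-group split (age
#' dichotomized at 65; stage I vs II; GGO-dominant — strictly > 50% GGO —
#' vs not; etc.), and the groups' cfDNA concentrations are summarized
#' (n, mean, SD, and median/IQR for the non-normal presentation) and compared
#' by [mann_whitney_u()]. A feature with an empty group gets an `NA` p-value
#' with a warning.
#'
#' @param records a `clinical_table`.
#' @param features named list of functions mapping the table to a group
#'   label per patient; default mirrors the standard clinical feature set.
#' @return data.frame of class `assoc_table`, two rows per feature (one per
#'   group) with columns `feature`, `group`, `n`, `mean`, `sd`, `median`,
#'   `iqr`, `U`, `p` (test statistics repeated on both rows).
#' @export
cfdna_feature_table <- function(records, features = .default_features()) {
  rows <- list()
  for (nm in names(features)) {
    g <- features[[nm]](records)
    lev <- sort(unique(g))
    if (length(lev) > 2)
      stop("feature ", nm, " induces more than two groups")
    split_vals <- lapply(lev, function(l) records$cfdna_conc[g == l])
    if (length(lev) < 2 || any(lengths(split_vals) == 0)) {
      warning("feature ", nm, ": a group is empty; p undefined")
      U <- NA_real_; p <- NA_real_
    } else {
      mw <- mann_whitney_u(split_vals[[1]], split_vals[[2]])
      U <- mw$U; p <- mw$p
    }
    for (k in seq_along(lev)) {
      v <- split_vals[[k]]
      rows[[length(rows) + 1L]] <- data.frame(
        feature = nm, group = lev[k], n = length(v),
        mean = mean(v), sd = stats::sd(v),
        median = stats::median(v), iqr = stats::IQR(v),
        U = U, p = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("assoc_table", "data.frame")
  out
}

.marker_cutoffs <- c(CA125 = 35, CA19_9 = 39, CEA = 4.7, CYFRA21_1 = 3.3,
                     NSE = 16.3)

#' Serum-marker and cfDNA positivity per patient
#'
#' A marker is positive iff its value is at or above the clinical cut-off
#' (CA125 35 U/ml, CA19-9 39 U/ml, CEA 4.7 ng/ml, CYFRA21-1 3.3 ng/ml, NSE
#' 16.3 ng/ml — negativity is defined by the strict `<`). `any_positive` is
#' the union over the five markers. cfDNA positivity means a quantifiable
#' concentration, strictly above `cfdna_floor`.
#'
#' @param records a `clinical_table`.
#' @param cfdna_floor quantification floor in ng/ml, default 0.
#' @return data.frame with one logical column per marker (`pos_<marker>`),
#'   `any_positive` and `cfdna_positive`.
#' @export
marker_positivity <- function(records, cfdna_floor = 0) {
  vals <- as.matrix(records[names(.marker_cutoffs)])
  if (any(vals < 0, na.rm = TRUE)) stop("negative serum marker value")
  miss <- is.na(vals)
  if (any(miss)) warning("missing marker values treated as not positive")
  pos <- sweep(vals, 2, .marker_cutoffs, `>=`)
  pos[miss] <- FALSE
  out <- as.data.frame(pos)
  names(out) <- paste0("pos_", names(.marker_cutoffs))
  out <- cbind(patient_id = records$patient_id, out)
  out$any_positive <- rowSums(pos) > 0
  out$cfdna_positive <- records$cfdna_conc > cfdna_floor
  out
}

#' cfDNA versus serum-tumor-marker detection comparison
#'
#' Counts and rates of marker-positive and cfDNA-positive patients. Every
#' record is a confirmed cancer patient, so the "positive predictive value"
#' of each modality reduces to its detection rate; the output is labelled
#' accordingly.
#'
#' @param records a `clinical_table`.
#' @param cfdna_floor see [marker_positivity()].
#' @return object of class `detection_comparison` with per-marker positive
#'   counts, the marker union count/rate and the cfDNA count/rate.
#' @export
detection_comparison <- function(records, cfdna_floor = 0) {
  pos <- marker_positivity(records, cfdna_floor)
  n <- nrow(records)
  per_marker <- colSums(pos[paste0("pos_", names(.marker_cutoffs))])
  names(per_marker) <- names(.marker_cutoffs)
  structure(list(
    n = n,
    per_marker_positive = per_marker,
    marker_positive = sum(pos$any_positive),
    marker_detection_rate = if (n > 0) mean(pos$any_positive) else NA_real_,
    cfdna_positive = sum(pos$cfdna_positive),
    cfdna_detection_rate = if (n > 0) mean(pos$cfdna_positive) else NA_real_),
    class = "detection_comparison")
}

#' @export
print.detection_comparison <- function(x, ...) {
  cat(sprintf("Detection in %d cancer patients (rates are detection rates;\n", x$n))
  cat("often reported as PPV since all patients are diseased)\n")
  for (m in names(x$per_marker_positive))
    cat(sprintf("  %-10s %d positive\n", m, x$per_marker_positive[[m]]))
  cat(sprintf("  any marker %d (%.1f%%)\n", x$marker_positive,
              100 * x$marker_detection_rate))
  cat(sprintf("  cfDNA      %d (%.1f%%)\n", x$cfdna_positive,
              100 * x$cfdna_detection_rate))
  invisible(x)
}
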