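#' @keywords internal
"_PACKAGE"

## Core domain containers. A variant call table is an ordinary data.frame with
## a fixed column set; a call set wraps one table with sample-level metadata;
## a sample pair groups the tumor / plasma / WBC call sets of one patient.

.call_cols <- c("chrom", "pos", "ref", "alt", "gene", "variant_class",
                "depth", "alt_reads", "alt_fwd", "alt_rev",
                "ref_fwd", "ref_rev", "p_value")

#' Empty variant-call table
#'
#' Zero-row data.frame with the canonical call columns and types. Every
#' function that returns calls returns this shape.
#'
#' @return data.frame with 0 rows and the canonical call columns.
#' @export
empty_calls <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), gene = character(), variant_class = character(),
             depth = integer(), alt_reads = integer(),
             alt_fwd = integer(), alt_rev = integer(),
             ref_fwd = integer(), ref_rev = integer(),
             p_value = double(), stringsAsFactors = FALSE)
}

#' Build a variant-call table
#'
#' Vectorized constructor validating the call invariants: `alt_reads <= depth`,
#' `alt_fwd + alt_rev == alt_reads`, and `variant_class` consistent with the
#' ref/alt length rule (equal length 1 = SNP, equal length >1 = MNP, unequal =
#' Indel). `variant_class` is derived when not supplied.
#'
#' @param chrom,pos,ref,alt locus and alleles (pos is 1-based).
#' @param gene optional gene symbol (annotation only, never used for identity).
#' @param depth,alt_reads total and variant-supporting read counts.
#' @param alt_fwd,alt_rev,ref_fwd,ref_rev per-strand read-orientation counts;
#'   alt strand counts default to an even split of `alt_reads`.
#' @param p_value caller p-value in `[0,1]`; `NA` means "compute downstream".
#' @param variant_class optional; derived from allele lengths when `NULL`.
#' @return data.frame of calls.
#' @export
variant_calls <- function(chrom, pos, ref, alt, gene = NA_character_,
                          depth, alt_reads,
                          alt_fwd = NULL, alt_rev = NULL,
                          ref_fwd = NULL, ref_rev = NULL,
                          p_value = NA_real_, variant_class = NULL) {
  n <- length(pos)
  if (n == 0L) return(empty_calls())
  if (is.null(alt_fwd)) alt_fwd <- alt_reads %/% 2L
  if (is.null(alt_rev)) alt_rev <- alt_reads - alt_fwd
  ref_reads <- depth - alt_reads
  if (is.null(ref_fwd)) ref_fwd <- ref_reads %/% 2L
  if (is.null(ref_rev)) ref_rev <- ref_reads - ref_fwd
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = as.character(ref), alt = as.character(alt),
                   gene = rep_len(as.character(gene), n),
                   variant_class = NA_character_,
                   depth = as.integer(depth), alt_reads = as.integer(alt_reads),
                   alt_fwd = as.integer(alt_fwd), alt_rev = as.integer(alt_rev),
                   ref_fwd = as.integer(ref_fwd), ref_rev = as.integer(ref_rev),
                   p_value = rep_len(as.numeric(p_value), n),
                   stringsAsFactors = FALSE)
  df$variant_class <- if (is.null(variant_class))
    variant_class_of(df$ref, df$alt) else rep_len(variant_class, n)
  bad <- df$alt_reads > df$depth
  if (any(bad))
    stop("alt_reads exceeds depth at row(s): ", paste(which(bad), collapse = ", "))
  if (any(df$alt_fwd + df$alt_rev != df$alt_reads))
    stop("alt strand counts must sum to alt_reads")
  df
}

#' Classify a variant by allele lengths
#'
#' Total function: equal lengths of 1 give "SNP", equal lengths >1 give "MNP",
#' unequal lengths give "Indel".
#'
#' @param ref,alt character vectors of alleles.
#' @return character vector in `c("SNP","MNP","Indel")`.
#' @export
variant_class_of <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  ifelse(lr != la, "Indel", ifelse(lr == 1L, "SNP", "MNP"))
}

#' Variant allele frequency
#'
#' `alt_reads / depth`; `NA` where depth is 0 (VAF undefined).
#'
#' @param calls a call table.
#' @return numeric vector in `[0,1]` or `NA`.
#' @export
call_vaf <- function(calls) {
  ifelse(calls$depth > 0, calls$alt_reads / calls$depth, NA_real_)
}

#' Canonical mutation identity key
#'
#' Mutation identity throughout the pipeline is `(chrom, pos, ref, alt)` after
#' representation normalization (common suffix then prefix trimming, keeping at
#' least one base and shifting `pos` past trimmed leading bases). Matching by
#' key makes comparisons immune to redundant padded indel representations such
#' as `GGT>GG` vs `GT>G`.
#'
#' @param chrom,pos,ref,alt vectors describing variants.
#' @return character key vector, e.g. `"chr7:55241707:C:T"`.
#' @export
mutation_key <- function(chrom, pos, ref, alt) {
  norm <- normalize_variant(pos, ref, alt)
  paste(chrom, norm$pos, norm$ref, norm$alt, sep = ":")
}

#' Trim redundant allele padding
#'
#' Removes the longest shared allele suffix, then the longest shared prefix
#' (keeping at least one base of each allele), advancing `pos` by the number of
#' leading bases trimmed. Pure string normalization; no reference genome used,
#' so fully left-aligning repeats is out of scope.
#'
#' @param pos,ref,alt parallel vectors.
#' @return list with components `pos`, `ref`, `alt`.
#' @export
normalize_variant <- function(pos, ref, alt) {
  pos <- as.integer(pos); ref <- as.character(ref); alt <- as.character(alt)
  for (i in seq_along(pos)) {
    r <- ref[i]; a <- alt[i]
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1L, nchar(r) - 1L)
      a <- substr(a, 1L, nchar(a) - 1L)
    }
    while (nchar(r) > 1L && nchar(a) > 1L && substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
      r <- substr(r, 2L, nchar(r)); a <- substr(a, 2L, nchar(a))
      pos[i] <- pos[i] + 1L
    }
    ref[i] <- r; alt[i] <- a
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Construct a sample call set
#'
#' One sequenced compartment of one patient: a call table plus the sample-level
#' mean amplicon coverage used by the QC depth bound.
#'
#' @param calls call table (see [variant_calls()]).
#' @param sample_id sample identifier.
#' @param sample_type one of `"tumor"`, `"plasma"`, `"wbc"`.
#' @param mean_depth sample-level average total coverage depth (reads); when
#'   `NULL`, the mean of the per-call depths (0 for an empty set).
#' @return object of class `call_set`.
#' @export
call_set <- function(calls = empty_calls(), sample_id = "sample",
                     sample_type = c("tumor", "plasma", "wbc"),
                     mean_depth = NULL) {
  sample_type <- match.arg(sample_type)
  if (is.null(mean_depth))
    mean_depth <- if (nrow(calls) > 0) mean(calls$depth) else 0
  stopifnot(mean_depth >= 0)
  structure(list(sample_id = sample_id, sample_type = sample_type,
                 mean_depth = mean_depth, calls = calls),
            class = "call_set")
}

#' @export
print.call_set <- function(x, ...) {
  cat(sprintf("<call_set> %s (%s): %d call(s), mean depth %.0fx\n",
              x$sample_id, x$sample_type, nrow(x$calls), x$mean_depth))
  invisible(x)
}

#' Pair the tumor, plasma and WBC call sets of one patient
#'
#' @param patient_id patient identifier.
#' @param tumor,plasma `call_set`s of the respective type.
#' @param wbc germline reference `call_set`; may be empty.
#' @return object of class `sample_pair`.
#' @export
sample_pair <- function(patient_id, tumor, plasma,
                        wbc = call_set(sample_type = "wbc")) {
  stopifnot(inherits(tumor, "call_set"), tumor$sample_type == "tumor",
            inherits(plasma, "call_set"), plasma$sample_type == "plasma",
            inherits(wbc, "call_set"), wbc$sample_type == "wbc")
  structure(list(patient_id = patient_id, tumor = tumor, plasma = plasma,
                 wbc = wbc), class = "sample_pair")
}

#' @export
print.sample_pair <- function(x, ...) {
  cat(sprintf("<sample_pair> %s: tumor %d, plasma %d, wbc %d call(s)\n",
              x$patient_id, nrow(x$tumor$calls), nrow(x$plasma$calls),
              nrow(x$wbc$calls)))
  invisible(x)
}
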