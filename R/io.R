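## Readers and writers for the formats the pipeline touches: VCF v4.2 call
## files (parsed with vcfR), BED3 hotspot panels, the clinical TSV, and the
## per-pair mutation manifest used to encode externally curated pair lists.

#' Read variant calls from a VCF file
#'
#' Parses a VCF v4.x file with [vcfR::read.vcfR()] and maps INFO fields to the
#' canonical call table. One call is emitted per ALT allele; multi-allelic
#' records are split, with comma-separated per-allele INFO values (AO, SAF,
#' SAR) distributed across the resulting calls.
#'
#' @param path VCF file.
#' @param sample_id sample identifier to stamp on the call set.
#' @param sample_type `"tumor"`, `"plasma"` or `"wbc"`.
#' @param fields named list mapping the required quantities to INFO keys;
#'   defaults: `depth = "DP"`, `alt_reads = "AO"`, `alt_fwd = "SAF"`,
#'   `alt_rev = "SAR"`, `p_value = "PVAL"` (PVAL optional), `gene = "GENE"`
#'   (optional).
#' @param mean_depth override for the sample-level mean coverage; default is
#'   the arithmetic mean of DP over records (0 for an empty body).
#' @return a [call_set()].
#' @export
read_vcf_calls <- function(path, sample_id, sample_type,
                           fields = list(depth = "DP", alt_reads = "AO",
                                         alt_fwd = "SAF", alt_rev = "SAR",
                                         p_value = "PVAL", gene = "GENE"),
                           mean_depth = NULL) {
  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcfR::getFIX(vcf)
  if (is.null(fix) || nrow(vcf@fix) == 0L)
    return(call_set(empty_calls(), sample_id, sample_type,
                    mean_depth = if (is.null(mean_depth)) 0 else mean_depth))
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  info_num <- function(key) suppressWarnings(
    as.numeric(vcfR::extract.info(vcf, element = key)))
  info_chr <- function(key) vcfR::extract.info(vcf, element = key)

  dp <- info_num(fields$depth)
  ao_raw <- info_chr(fields$alt_reads)
  saf_raw <- info_chr(fields$alt_fwd)
  sar_raw <- info_chr(fields$alt_rev)
  pv_raw <- info_chr(fields$p_value)
  gene_raw <- info_chr(fields$gene)
  if (all(is.na(dp)))
    stop("VCF ", path, ": required INFO field '", fields$depth, "' missing")
  if (all(is.na(ao_raw)))
    stop("VCF ", path, ": required INFO field '", fields$alt_reads, "' missing")

  split_num <- function(x, i, k) {
    if (is.na(x)) return(NA_real_)
    parts <- suppressWarnings(as.numeric(strsplit(x, ",", fixed = TRUE)[[1]]))
    if (length(parts) >= k) parts[k] else parts[1]
  }

  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    if (is.na(dp[i]))
      stop("VCF ", path, ": record ", fix$CHROM[i], ":", fix$POS[i],
           " lacks INFO/", fields$depth)
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    for (k in seq_along(alts)) {
      ao <- split_num(ao_raw[i], i, k)
      if (is.na(ao))
        stop("VCF ", path, ": record ", fix$CHROM[i], ":", fix$POS[i],
             " lacks INFO/", fields$alt_reads)
      saf <- split_num(saf_raw[i], i, k)
      sar <- split_num(sar_raw[i], i, k)
      if (is.na(saf) || is.na(sar)) { saf <- floor(ao / 2); sar <- ao - saf }
      pv <- if (length(pv_raw) >= i && !is.na(pv_raw[i]))
        suppressWarnings(as.numeric(pv_raw[i])) else NA_real_
      gn <- if (length(gene_raw) >= i) gene_raw[i] else NA_character_
      d <- dp[i]
      ref_reads <- max(d - ao, 0)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]), ref = fix$REF[i],
        alt = alts[k], gene = gn,
        variant_class = variant_class_of(fix$REF[i], alts[k]),
        depth = as.integer(d), alt_reads = as.integer(ao),
        alt_fwd = as.integer(saf), alt_rev = as.integer(sar),
        ref_fwd = as.integer(ref_reads %/% 2), ref_rev = as.integer(ref_reads - ref_reads %/% 2),
        p_value = pv, stringsAsFactors = FALSE)
    }
  }
  calls <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(calls)) calls <- empty_calls()
  if (is.null(mean_depth)) mean_depth <- mean(dp, na.rm = TRUE)
  call_set(calls, sample_id, sample_type, mean_depth = mean_depth)
}

#' Write a call set as a minimal VCF
#'
#' Emits a self-contained VCF v4.2 with INFO keys DP, AO, SAF, SAR, PVAL and
#' optionally GENE, the dialect [read_vcf_calls()] reads back. Round-trips
#' chrom/pos/ref/alt/DP/AO for every call.
#'
#' @param cs a [call_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf_calls <- function(cs, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=ctdnaconcord;sample=%s;type=%s;mean_depth=%g",
            cs$sample_id, cs$sample_type, cs$mean_depth),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    "##INFO=<ID=AO,Number=A,Type=Integer,Description=\"Alt observation count\">",
    "##INFO=<ID=SAF,Number=A,Type=Integer,Description=\"Alt reads forward\">",
    "##INFO=<ID=SAR,Number=A,Type=Integer,Description=\"Alt reads reverse\">",
    "##INFO=<ID=PVAL,Number=A,Type=Float,Description=\"Caller p-value\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- character(0)
  if (nrow(cs$calls) > 0) {
    x <- cs$calls
    info <- sprintf("DP=%d;AO=%d;SAF=%d;SAR=%d", x$depth, x$alt_reads,
                    x$alt_fwd, x$alt_rev)
    has_p <- !is.na(x$p_value)
    info[has_p] <- paste0(info[has_p], sprintf(";PVAL=%.6g", x$p_value[has_p]))
    has_g <- !is.na(x$gene)
    info[has_g] <- paste0(info[has_g], ";GENE=", x$gene[has_g])
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                    x$chrom, x$pos, x$ref, x$alt, info)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a hotspot panel from a BED file
#'
#' BED3+ with 0-based half-open intervals, preserved as such in file order; a
#' 1-based variant position p lies inside interval (start, end] exactly when
#' `start < p <= end` (see [positions_in_regions()], the single place the
#' coordinate conventions meet).
#'
#' @param path BED file (3+ whitespace-separated columns; an optional 4th
#'   column is kept as the region label).
#' @return object of class `hotspot_regions`: a data.frame with columns
#'   `chrom`, `start`, `end` and optionally `name`.
#' @export
read_bed_regions <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (length(lines) == 0L)
    return(hotspot_regions(character(), integer(), integer()))
  parts <- strsplit(lines, "\t| +")
  ncols <- vapply(parts, length, integer(1))
  if (any(ncols < 3L))
    stop("BED ", path, ": fewer than 3 columns at line ", which(ncols < 3L)[1])
  chrom <- vapply(parts, `[`, character(1), 1L)
  start <- as.integer(vapply(parts, `[`, character(1), 2L))
  end <- as.integer(vapply(parts, `[`, character(1), 3L))
  bad <- which(!(start < end))
  if (length(bad))
    stop("BED ", path, ": start >= end at line ", bad[1])
  name <- if (all(ncols >= 4L)) vapply(parts, `[`, character(1), 4L) else NULL
  hotspot_regions(chrom, start, end, name)
}

#' Construct a hotspot-region set
#'
#' @param chrom,start,end parallel vectors; 0-based half-open intervals.
#' @param name optional region labels.
#' @return object of class `hotspot_regions`.
#' @export
hotspot_regions <- function(chrom, start, end, name = NULL) {
  stopifnot(all(start < end))
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- as.character(name)
  structure(df, class = c("hotspot_regions", "data.frame"))
}

#' Test 1-based positions for hotspot membership
#'
#' The one function where the 1-based variant convention meets the 0-based
#' half-open BED convention: position p is inside (start, end] iff
#' `start < p` and `p <= end`.
#'
#' @param chrom,pos parallel vectors of 1-based variant positions.
#' @param regions a `hotspot_regions` object.
#' @return logical vector, `TRUE` where the position falls in >= 1 region.
#' @export
positions_in_regions <- function(chrom, pos, regions) {
  if (length(pos) == 0L) return(logical(0))
  if (nrow(regions) == 0L) return(rep(FALSE, length(pos)))
  vapply(seq_along(pos), function(i) {
    any(regions$chrom == chrom[i] & regions$start < pos[i] & pos[i] <= regions$end)
  }, logical(1))
}

.stages <- c(IA = "IA", IB = "IB", IIA = "IIA")
.marker_cols <- c("CA125", "CA19_9", "CEA", "CYFRA21_1", "NSE")

#' Read the clinical covariate table
#'
#' Tab-separated with a header; required columns: `patient_id`, `age`, `sex`
#' (M/F), `histology` (AC/SCC), `stage` (IA/IB/IIA), `smoker` (logical or
#' 0/1), `ggo_proportion` (fraction in `[0,1]`), `differentiation`
#' (`median_or_high`/`poor`), `vascular_invasion`, `vpi` (logical),
#' `cfdna_conc` (ng per ml plasma) and the serum markers `CA125`, `CA19_9`
#' (U/ml), `CEA`, `CYFRA21_1`, `NSE` (ng/ml). A derived logical
#' `ggo_dominant` (strictly > 50% GGO proportion) is appended.
#'
#' @param path TSV file.
#' @return data.frame of class `clinical_table`, one row per patient.
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_clinical_table(df)
}

#' Validate a clinical data.frame
#'
#' @param df data.frame with the columns documented in [read_clinical_table()].
#' @return the validated data.frame of class `clinical_table`.
#' @export
as_clinical_table <- function(df) {
  need <- c("patient_id", "age", "sex", "histology", "stage", "smoker",
            "ggo_proportion", "differentiation", "vascular_invasion", "vpi",
            "cfdna_conc", .marker_cols)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("clinical table is missing column(s): ", paste(miss, collapse = ", "))
  chk_enum <- function(col, allowed) {
    bad <- setdiff(unique(df[[col]]), allowed)
    if (length(bad))
      stop("clinical table: invalid ", col, " value(s) ",
           paste(bad, collapse = ", "), "; allowed: ",
           paste(allowed, collapse = ", "))
  }
  chk_enum("sex", c("M", "F"))
  chk_enum("histology", c("AC", "SCC"))
  chk_enum("stage", c("IA", "IB", "IIA"))
  chk_enum("differentiation", c("median_or_high", "poor"))
  for (col in c("smoker", "vascular_invasion", "vpi"))
    df[[col]] <- as.logical(df[[col]])
  stopifnot(all(df$ggo_proportion >= 0 & df$ggo_proportion <= 1),
            all(df$cfdna_conc >= 0))
  if (any(as.matrix(df[.marker_cols]) < 0, na.rm = TRUE))
    stop("clinical table: negative serum marker value")
  df$ggo_dominant <- df$ggo_proportion > 0.5
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Write a clinical table as TSV
#'
#' @param df `clinical_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(df, path) {
  out <- df[setdiff(names(df), "ggo_dominant")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Encode externally curated per-pair mutation lists
#'
#' Reads a long-format TSV of already-filtered mutations (one row per mutation
#' per compartment) into `sample_pair` objects, so that concordance can be run
#' on published per-pair tables. Columns: `patient_id`, `compartment`
#' (`tumor`/`plasma`), `chrom`, `pos`, `ref`, `alt`, and optionally `gene`,
#' `vaf`. Read-evidence columns are synthesized at a nominal depth because the
#' input is post-filter; only mutation identity matters downstream.
#'
#' @param path TSV manifest.
#' @param patients optional vector of patient ids to force into the output
#'   (patients absent from the manifest get mutation-free pairs), so that
#'   mutation-free true-negative pairs are retained.
#' @return list of [sample_pair()] objects.
#' @export
read_pair_manifest <- function(path, patients = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "compartment", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("pair manifest missing column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$compartment), c("tumor", "plasma"))
  if (length(bad))
    stop("pair manifest: unknown compartment ", paste(bad, collapse = ", "))
  ids <- unique(c(as.character(df$patient_id), as.character(patients)))
  lapply(ids, function(id) {
    mk <- function(comp, type) {
      sub <- df[df$patient_id == id & df$compartment == comp, , drop = FALSE]
      if (nrow(sub) == 0L) return(call_set(empty_calls(), id, type))
      depth <- 10000L
      ar <- if ("vaf" %in% names(sub)) pmax(1L, as.integer(round(sub$vaf * depth)))
            else rep(100L, nrow(sub))
      calls <- variant_calls(sub$chrom, sub$pos, sub$ref, sub$alt,
                             gene = if ("gene" %in% names(sub)) sub$gene else NA,
                             depth = depth, alt_reads = ar)
      call_set(calls, id, type)
    }
    sample_pair(id, mk("tumor", "tumor"), mk("plasma", "plasma"))
  })
}
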