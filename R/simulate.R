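## Synthetic-cohort generator. Emulates the statistical structure of a
## 58-patient early-stage NSCLC liquid-biopsy study: per-patient tumor
## mutations drawn from a 50-gene hotspot catalogue, stochastic shedding into
## plasma at log-normally distributed low VAFs, plasma-private mutations,
## planted germline variants shared across compartments, binomial read
## evidence at tissue (~1000x+) and plasma (~10000x+) depths, log-normal
## cfDNA concentrations with stage and GGO effects, and serum tumor markers
## calibrated to published positivity rates at the clinical cut-offs.

#' Default 50-gene hotspot panel catalogue
#'
#' Deterministically constructed synthetic panel: `n_sites` hotspot loci
#' spread over the 50 genes of a cancer hotspot panel, with per-site ref/alt
#' alleles, a variant class (Indels confined to EGFR, MNPs to KRAS, all other
#' sites SNPs), and a per-site sampling weight concentrating mutations in
#' EGFR, then TP53/PIK3CA/KRAS, mirroring the driver-gene landscape of
#' early-stage lung adenocarcinoma. Coordinates are synthetic (one contig per
#' gene), not genome-build positions.
#'
#' @param n_sites number of hotspot loci, default 739.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `variant_class`, `weight`; attribute `regions` holds the matching
#'   [hotspot_regions()] (each site padded to a 10 bp interval).
#' @export
default_panel <- function(n_sites = 739) {
  genes <- c("ABL1", "AKT1", "ALK", "APC", "ATM", "BRAF", "CDH1", "CDKN2A",
             "CSF1R", "CTNNB1", "EGFR", "ERBB2", "ERBB4", "EZH2", "FBXW7",
             "FGFR1", "FGFR2", "FGFR3", "FLT3", "GNA11", "GNAQ", "GNAS",
             "HNF1A", "HRAS", "IDH1", "IDH2", "JAK2", "JAK3", "KDR", "KIT",
             "KRAS", "MET", "MLH1", "MPL", "NOTCH1", "NPM1", "NRAS",
             "PDGFRA", "PIK3CA", "PTEN", "PTPN11", "RB1", "RET", "SMAD4",
             "SMARCB1", "SMO", "SRC", "STK11", "TP53", "VHL")
  gene_weight <- stats::setNames(rep(0.2, length(genes)), genes)
  gene_weight[c("TP53", "PIK3CA", "KRAS")] <- 2.5
  gene_weight["EGFR"] <- 8
  gene <- genes[(seq_len(n_sites) - 1L) %% length(genes) + 1L]
  idx_in_gene <- stats::ave(seq_len(n_sites), gene, FUN = seq_along)
  pos <- 100000L + idx_in_gene * 1000L
  bases <- c("A", "C", "G", "T")
  ref <- bases[(seq_len(n_sites) - 1L) %% 4L + 1L]
  alt <- bases[seq_len(n_sites) %% 4L + 1L]
  variant_class <- rep("SNP", n_sites)
  egfr <- which(gene == "EGFR")
  if (length(egfr) >= 4) {
    del <- egfr[seq_len(max(1L, length(egfr) %/% 4L))]
    ref[del] <- paste0(ref[del], "TGGC")   # small deletions
    variant_class[del] <- "Indel"
  }
  kras <- which(gene == "KRAS")
  if (length(kras) >= 2) {
    mnp <- kras[seq_len(max(1L, length(kras) %/% 6L))]
    ref[mnp] <- paste0(ref[mnp], "G")
    alt[mnp] <- paste0(alt[mnp], "T")
    variant_class[mnp] <- "MNP"
  }
  weight <- gene_weight[gene] / table(gene)[gene]
  panel <- data.frame(chrom = paste0("ctg_", gene), pos = pos, ref = ref,
                      alt = alt, gene = gene, variant_class = variant_class,
                      weight = as.numeric(weight / sum(weight)),
                      stringsAsFactors = FALSE)
  attr(panel, "regions") <- hotspot_regions(panel$chrom, panel$pos - 5L,
                                            panel$pos + 5L, panel$gene)
  panel
}

#' Cohort simulation configuration
#'
#' Defaults are fixed to the published cohort marginals: 58 patients staged
#' IA 30 / IB 16 / IIA 12, histology AC 51 / SCC 7, 33 male / 25 female, 22
#' smokers, 8 GGO-dominant tumors; tumor VAFs uniform on 5-60%; plasma VAFs
#' log-normal with median 0.9% and log-sd 1.25 (about 95% of draws inside
#' 0.1-16%); a tumor mutation is shed into plasma with probability 34/59; the
#' plasma-private rate is 42/58 mutations per patient and the tumor mutation
#' rate 59/58; cfDNA concentration is log-normal with base mean 4.57 ng/ml, a
#' stage-II multiplier of 14.28/4.57, a GGO-dominant multiplier of 0.66/7.53
#' and CV 1.5, and is non-quantifiable (0 ng/ml) with probability 6/58;
#' serum-marker positivity rates at the clinical cut-offs are 0/58 (CA125),
#' 2/58 (CA19-9), 8/58 (CEA), 16/58 (CYFRA21-1) and 4/58 (NSE). Depth means
#' are 2000x (tissue/WBC) and 12000x (plasma), clear of the sample-level QC
#' floors.
#'
#' @param n_patients cohort size.
#' @param stage_counts,histology_counts named integer vectors summing to
#'   `n_patients`.
#' @param n_male number of male patients.
#' @param smoker_fraction,ggo_dominant_fraction cohort fractions.
#' @param panel site catalogue from [default_panel()].
#' @param tumor_depth_mean,plasma_depth_mean mean amplicon coverages (reads).
#' @param tumor_vaf_range uniform range of tissue VAFs.
#' @param plasma_vaf_meanlog,plasma_vaf_sdlog log-normal parameters of plasma
#'   VAFs (natural-log scale).
#' @param tumor_mut_rate Poisson mean of tumor mutations per patient.
#' @param shed_probability probability a tumor mutation is detectable in
#'   plasma.
#' @param plasma_private_rate Poisson mean of plasma-only mutations.
#' @param n_germline germline variants planted per patient (VAF 0.5, present
#'   in all three compartments).
#' @param seq_error_rate per-base substitution error probability.
#' @param emit_error_calls also emit raw error-only calls at non-planted
#'   panel sites (slower; off by default).
#' @param cfdna_base_mean stage-I solid-dominant mean cfDNA (ng/ml).
#' @param cfdna_stage2_multiplier,cfdna_ggo_multiplier multiplicative effects
#'   on the cfDNA mean.
#' @param cfdna_cv coefficient of variation of cfDNA concentration (0 =
#'   deterministic group means).
#' @param cfdna_nonquant_rate probability cfDNA is below quantification.
#' @param marker_rates expected positivity rate per serum marker.
#' @param marker_sdlog log-sd of the marker log-normal distributions.
#' @param seed master seed; per-patient substreams are derived from it.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 58,
                          stage_counts = c(IA = 30, IB = 16, IIA = 12),
                          histology_counts = c(AC = 51, SCC = 7),
                          n_male = 33,
                          smoker_fraction = 22 / 58,
                          ggo_dominant_fraction = 8 / 58,
                          panel = default_panel(),
                          tumor_depth_mean = 2000,
                          plasma_depth_mean = 12000,
                          tumor_vaf_range = c(0.05, 0.60),
                          plasma_vaf_meanlog = log(0.009),
                          plasma_vaf_sdlog = 1.25,
                          tumor_mut_rate = 59 / 58,
                          shed_probability = 34 / 59,
                          plasma_private_rate = 42 / 58,
                          n_germline = 2,
                          seq_error_rate = 0.001,
                          emit_error_calls = FALSE,
                          cfdna_base_mean = 4.57,
                          cfdna_stage2_multiplier = 14.28 / 4.57,
                          cfdna_ggo_multiplier = 0.66 / 7.53,
                          cfdna_cv = 1.5,
                          cfdna_nonquant_rate = 6 / 58,
                          marker_rates = c(CA125 = 0.5 / 58, CA19_9 = 2 / 58,
                                           CEA = 8 / 58, CYFRA21_1 = 16 / 58,
                                           NSE = 4 / 58),
                          marker_sdlog = 0.6,
                          seed = 1L) {
  cfg <- as.list(environment())
  if (n_patients > 0) {
    if (sum(stage_counts) != n_patients)
      stop("stage_counts must sum to n_patients")
    if (sum(histology_counts) != n_patients)
      stop("histology_counts must sum to n_patients")
    if (n_male > n_patients) stop("n_male exceeds n_patients")
  }
  stopifnot(smoker_fraction >= 0, smoker_fraction <= 1,
            ggo_dominant_fraction >= 0, ggo_dominant_fraction <= 1,
            shed_probability >= 0, shed_probability <= 1,
            seq_error_rate >= 0, seq_error_rate < 1,
            cfdna_stage2_multiplier > 0, cfdna_ggo_multiplier > 0,
            cfdna_cv >= 0, all(marker_rates >= 0 & marker_rates <= 1))
  structure(cfg, class = "cohort_config")
}

#' Simulate read evidence at one locus
#'
#' `alt_reads ~ Binomial(depth, true_vaf + (1 - true_vaf) * error_rate)`
#' (error reads on top of the true allele fraction), with the forward-strand
#' split `Binomial(alt_reads, strand_prob)`. Degenerate inputs produce
#' degenerate outputs (depth 0 gives all-zero evidence). Vectorized.
#'
#' @param true_vaf true variant allele fraction(s) in `[0,1]`.
#' @param depth total read count(s).
#' @param error_rate per-base substitution probability.
#' @param strand_prob forward-strand probability for alt reads (0.5 unless a
#'   strand bias is injected).
#' @return data.frame with columns `depth`, `alt_reads`, `alt_fwd`,
#'   `alt_rev`, `ref_fwd`, `ref_rev`.
#' @export
simulate_read_evidence <- function(true_vaf, depth, error_rate = 0,
                                   strand_prob = 0.5) {
  n <- max(length(true_vaf), length(depth))
  true_vaf <- rep_len(true_vaf, n); depth <- rep_len(depth, n)
  stopifnot(all(true_vaf >= 0 & true_vaf <= 1), all(depth >= 0))
  p <- true_vaf + (1 - true_vaf) * error_rate
  alt <- stats::rbinom(n, depth, p)
  alt_fwd <- stats::rbinom(n, alt, strand_prob)
  ref <- depth - alt
  ref_fwd <- stats::rbinom(n, ref, 0.5)
  data.frame(depth = depth, alt_reads = alt, alt_fwd = alt_fwd,
             alt_rev = alt - alt_fwd, ref_fwd = ref_fwd,
             ref_rev = ref - ref_fwd)
}

## deterministic per-patient substream: reseed from the master seed and the
## patient index so results do not depend on iteration order
.substream <- function(seed, i) set.seed((seed + 7919L * i) %% .Machine$integer.max)

#' Simulate a paired tumor/plasma/WBC cohort
#'
#' Per patient: clinical covariates drawn with the exact configured category
#' counts; tumor mutations drawn from the panel catalogue at uniform tissue
#' VAFs; each shed into plasma with `shed_probability` at a log-normal plasma
#' VAF; plasma-private mutations added at `plasma_private_rate`; germline
#' variants planted identically (VAF 0.5) in tumor, plasma and WBC raw calls;
#' binomial read evidence simulated for every variant in every compartment;
#' cfDNA concentration drawn log-normally with stage-II and GGO-dominant
#' multiplicative effects; serum markers drawn log-normally at the configured
#' positivity rates. The truth table records every planted mutation with its
#' compartments and true VAFs.
#'
#' @param config a [cohort_config()].
#' @return object of class `ctdna_cohort`: list with `pairs` (raw, unfiltered
#'   [sample_pair()]s), `clinical` (a `clinical_table`), `truth` (data.frame),
#'   `regions` (the panel's [hotspot_regions()]) and `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  panel <- config$panel
  regions <- attr(panel, "regions")
  if (n == 0L)
    return(structure(list(pairs = list(), clinical = NULL,
                          truth = .empty_truth(), regions = regions,
                          config = config), class = "ctdna_cohort"))
  set.seed(config$seed)
  ids <- sprintf("P%03d", seq_len(n))
  stage <- sample(rep(names(config$stage_counts), config$stage_counts))
  histology <- sample(rep(names(config$histology_counts), config$histology_counts))
  sex <- sample(rep(c("M", "F"), c(config$n_male, n - config$n_male)))
  n_smoke <- round(config$smoker_fraction * n)
  smoker <- sample(rep(c(TRUE, FALSE), c(n_smoke, n - n_smoke)))
  n_ggo <- round(config$ggo_dominant_fraction * n)
  ggo_dom <- sample(rep(c(TRUE, FALSE), c(n_ggo, n - n_ggo)))
  age <- pmin(pmax(round(stats::rnorm(n, 64.5, 9.3)), 35), 90)
  differentiation <- sample(c("median_or_high", "poor"), n, replace = TRUE,
                            prob = c(44, 14))
  vascular_invasion <- stats::runif(n) < 7 / 58
  vpi <- stats::runif(n) < 10 / 58
  ggo_prop <- ifelse(ggo_dom, stats::runif(n, 0.55, 0.95),
                     stats::runif(n, 0, 0.45))

  sdlog_cf <- if (config$cfdna_cv > 0) sqrt(log(1 + config$cfdna_cv^2)) else 0
  marker_cut <- c(CA125 = 35, CA19_9 = 39, CEA = 4.7, CYFRA21_1 = 3.3,
                  NSE = 16.3)

  pairs <- vector("list", n)
  truth_rows <- list()
  clin_rows <- vector("list", n)
  for (i in seq_len(n)) {
    .substream(config$seed, i)
    id <- ids[i]

    ## planted somatic mutations
    n_tum <- stats::rpois(1, config$tumor_mut_rate)
    n_tum <- min(n_tum, nrow(panel))
    tum_idx <- if (n_tum > 0)
      sample(nrow(panel), n_tum, prob = panel$weight) else integer(0)
    shed <- if (n_tum > 0) stats::runif(n_tum) < config$shed_probability
            else logical(0)
    n_priv <- stats::rpois(1, config$plasma_private_rate)
    avail <- setdiff(seq_len(nrow(panel)), tum_idx)
    n_priv <- min(n_priv, length(avail))
    priv_idx <- if (n_priv > 0)
      sample(avail, n_priv, prob = panel$weight[avail]) else integer(0)
    germ_avail <- setdiff(avail, priv_idx)
    n_germ <- min(config$n_germline, length(germ_avail))
    germ_idx <- if (n_germ > 0) sample(germ_avail, n_germ) else integer(0)

    tum_vaf <- stats::runif(n_tum, config$tumor_vaf_range[1],
                            config$tumor_vaf_range[2])
    shed_vaf <- .rlnorm_trunc(sum(shed), config$plasma_vaf_meanlog,
                              config$plasma_vaf_sdlog)
    priv_vaf <- .rlnorm_trunc(n_priv, config$plasma_vaf_meanlog,
                              config$plasma_vaf_sdlog)

    mk_calls <- function(idx, vaf, depth_mean, extra_idx = integer(0),
                         extra_vaf = numeric(0)) {
      idx <- c(idx, extra_idx); vaf <- c(vaf, extra_vaf)
      if (length(idx) == 0L) return(empty_calls())
      depth <- stats::rpois(length(idx), depth_mean)
      ev <- simulate_read_evidence(vaf, depth, config$seq_error_rate)
      variant_calls(panel$chrom[idx], panel$pos[idx], panel$ref[idx],
                    panel$alt[idx], gene = panel$gene[idx],
                    depth = ev$depth, alt_reads = ev$alt_reads,
                    alt_fwd = ev$alt_fwd, alt_rev = ev$alt_rev,
                    ref_fwd = ev$ref_fwd, ref_rev = ev$ref_rev,
                    p_value = variant_pvalue(ev$alt_reads, pmax(ev$depth, ev$alt_reads),
                                             max(config$seq_error_rate, 1e-6)))
    }

    germ_vaf <- rep(0.5, n_germ)
    tumor_calls <- mk_calls(tum_idx, tum_vaf, config$tumor_depth_mean,
                            germ_idx, germ_vaf)
    plasma_idx <- c(tum_idx[shed], priv_idx)
    plasma_vaf <- c(shed_vaf, priv_vaf)
    plasma_calls <- mk_calls(plasma_idx, plasma_vaf, config$plasma_depth_mean,
                             germ_idx, germ_vaf)
    wbc_calls <- mk_calls(germ_idx, germ_vaf, config$tumor_depth_mean)

    if (config$emit_error_calls) {
      bg <- setdiff(seq_len(nrow(panel)), c(tum_idx, priv_idx, germ_idx))
      add_bg <- function(calls, depth_mean) {
        depth <- stats::rpois(length(bg), depth_mean)
        ev <- simulate_read_evidence(0, depth, config$seq_error_rate)
        nz <- ev$alt_reads > 0
        if (!any(nz)) return(calls)
        idx <- bg[nz]
        bgc <- variant_calls(panel$chrom[idx], panel$pos[idx], panel$ref[idx],
                             panel$alt[idx], gene = panel$gene[idx],
                             depth = ev$depth[nz], alt_reads = ev$alt_reads[nz],
                             alt_fwd = ev$alt_fwd[nz], alt_rev = ev$alt_rev[nz],
                             ref_fwd = ev$ref_fwd[nz], ref_rev = ev$ref_rev[nz],
                             p_value = variant_pvalue(ev$alt_reads[nz], ev$depth[nz],
                                                      max(config$seq_error_rate, 1e-6)))
        rbind(calls, bgc)
      }
      tumor_calls <- add_bg(tumor_calls, config$tumor_depth_mean)
      plasma_calls <- add_bg(plasma_calls, config$plasma_depth_mean)
    }

    pairs[[i]] <- sample_pair(
      id,
      call_set(tumor_calls, paste0(id, "_T"), "tumor",
               mean_depth = config$tumor_depth_mean),
      call_set(plasma_calls, paste0(id, "_P"), "plasma",
               mean_depth = config$plasma_depth_mean),
      call_set(wbc_calls, paste0(id, "_W"), "wbc",
               mean_depth = config$tumor_depth_mean))

    truth_rows[[i]] <- .truth_rows(panel, id, tum_idx, tum_vaf, shed,
                                   shed_vaf, priv_idx, priv_vaf, germ_idx)

    ## clinical covariates
    mult <- config$cfdna_base_mean *
      (if (stage[i] == "IIA") config$cfdna_stage2_multiplier else 1) *
      (if (ggo_dom[i]) config$cfdna_ggo_multiplier else 1)
    cf <- if (sdlog_cf > 0)
      stats::rlnorm(1, log(mult) - sdlog_cf^2 / 2, sdlog_cf) else mult
    if (stats::runif(1) < config$cfdna_nonquant_rate) cf <- 0
    markers <- vapply(names(marker_cut), function(m) {
      r <- config$marker_rates[[m]]
      ml <- log(marker_cut[[m]]) - stats::qnorm(1 - r) * config$marker_sdlog
      stats::rlnorm(1, ml, config$marker_sdlog)
    }, numeric(1))
    clin_rows[[i]] <- data.frame(
      patient_id = id, age = age[i], sex = sex[i], histology = histology[i],
      stage = stage[i], smoker = smoker[i], ggo_proportion = ggo_prop[i],
      differentiation = differentiation[i],
      vascular_invasion = vascular_invasion[i], vpi = vpi[i],
      cfdna_conc = cf, CA125 = markers[["CA125"]],
      CA19_9 = markers[["CA19_9"]], CEA = markers[["CEA"]],
      CYFRA21_1 = markers[["CYFRA21_1"]], NSE = markers[["NSE"]],
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, c(truth_rows[lengths(truth_rows) > 0],
                            list(.empty_truth())))
  rownames(truth) <- NULL
  structure(list(pairs = pairs,
                 clinical = as_clinical_table(do.call(rbind, clin_rows)),
                 truth = truth, regions = regions, config = config),
            class = "ctdna_cohort")
}

.rlnorm_trunc <- function(n, meanlog, sdlog, lo = 1e-4, hi = 0.2) {
  if (n == 0L) return(numeric(0))
  pmin(pmax(stats::rlnorm(n, meanlog, sdlog), lo), hi)
}

.empty_truth <- function() {
  data.frame(patient_id = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(), gene = character(),
             origin = character(), in_tumor = logical(), in_plasma = logical(),
             true_vaf_tumor = double(), true_vaf_plasma = double(),
             stringsAsFactors = FALSE)
}

.truth_rows <- function(panel, id, tum_idx, tum_vaf, shed, shed_vaf,
                        priv_idx, priv_vaf, germ_idx) {
  rows <- list()
  if (length(tum_idx)) {
    pv <- rep(NA_real_, length(tum_idx)); pv[shed] <- shed_vaf
    rows[[1]] <- data.frame(patient_id = id, chrom = panel$chrom[tum_idx],
                            pos = panel$pos[tum_idx], ref = panel$ref[tum_idx],
                            alt = panel$alt[tum_idx], gene = panel$gene[tum_idx],
                            origin = "somatic", in_tumor = TRUE, in_plasma = shed,
                            true_vaf_tumor = tum_vaf, true_vaf_plasma = pv,
                            stringsAsFactors = FALSE)
  }
  if (length(priv_idx)) {
    rows[[2]] <- data.frame(patient_id = id, chrom = panel$chrom[priv_idx],
                            pos = panel$pos[priv_idx], ref = panel$ref[priv_idx],
                            alt = panel$alt[priv_idx], gene = panel$gene[priv_idx],
                            origin = "somatic", in_tumor = FALSE, in_plasma = TRUE,
                            true_vaf_tumor = NA_real_, true_vaf_plasma = priv_vaf,
                            stringsAsFactors = FALSE)
  }
  if (length(germ_idx)) {
    rows[[3]] <- data.frame(patient_id = id, chrom = panel$chrom[germ_idx],
                            pos = panel$pos[germ_idx], ref = panel$ref[germ_idx],
                            alt = panel$alt[germ_idx], gene = panel$gene[germ_idx],
                            origin = "germline", in_tumor = TRUE, in_plasma = TRUE,
                            true_vaf_tumor = 0.5, true_vaf_plasma = 0.5,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows[lengths(rows) > 0])
}

#' @export
print.ctdna_cohort <- function(x, ...) {
  cat(sprintf("<ctdna_cohort> %d patient(s), %d planted variant record(s)\n",
              length(x$pairs), nrow(x$truth)))
  invisible(x)
}

#' Write a simulated cohort to disk as pipeline fixtures
#'
#' Emits per-sample VCFs (`<id>_tumor.vcf`, `<id>_plasma.vcf`,
#' `<id>_wbc.vcf`), the clinical TSV, the hotspot BED and the truth-table
#' TSV into `dir`.
#'
#' @param cohort a `ctdna_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in cohort$pairs) {
    write_vcf_calls(p$tumor, file.path(dir, paste0(p$patient_id, "_tumor.vcf")))
    write_vcf_calls(p$plasma, file.path(dir, paste0(p$patient_id, "_plasma.vcf")))
    write_vcf_calls(p$wbc, file.path(dir, paste0(p$patient_id, "_wbc.vcf")))
  }
  if (!is.null(cohort$clinical))
    write_clinical_table(cohort$clinical, file.path(dir, "clinical.tsv"))
  reg <- cohort$regions
  writeLines(sprintf("%s\t%d\t%d\t%s", reg$chrom, reg$start, reg$end,
                     if ("name" %in% names(reg)) reg$name else "."),
             file.path(dir, "hotspots.bed"))
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Simulate reference-standard dilution runs
#'
#' Mutant and wild-type plasmid mixtures at known mutant fractions, each
#' sequenced `replicates` times at the six control loci: per replicate and
#' site, read evidence with `true_vaf = nominal_fraction` (the wild-type
#' plasmid contributes only error reads).
#'
#' @param fractions nominal mutant fractions, default the tested dilution
#'   series `c(0, 0.001, 0.005, 0.01)`.
#' @param replicates runs per fraction, default 12.
#' @param depth sequencing depth per site, default 10000.
#' @param sites control-site table, default [control_sites()].
#' @param error_rate per-base error probability, default 0.
#' @param seed RNG seed.
#' @return list of `standard_run` objects (fields `replicate_id`,
#'   `nominal_fraction`, `error_rate`, `evidence`).
#' @export
simulate_reference_standards <- function(fractions = c(0, 0.001, 0.005, 0.01),
                                         replicates = 12, depth = 10000,
                                         sites = control_sites(),
                                         error_rate = 0, seed = 1L) {
  stopifnot(all(fractions >= 0 & fractions <= 1), replicates >= 0)
  set.seed(seed)
  runs <- list()
  for (f in fractions) {
    for (r in seq_len(replicates)) {
      ev <- simulate_read_evidence(rep(f, nrow(sites)), depth, error_rate)
      runs[[length(runs) + 1L]] <- structure(
        list(replicate_id = sprintf("f%g_r%02d", f, r), nominal_fraction = f,
             error_rate = error_rate, evidence = cbind(sites, ev)),
        class = "standard_run")
    }
  }
  runs
}

#' The six control mutations of the reference-standard plasmid
#'
#' KRAS G12C, PIK3CA E545K, PIK3CA H1047R, BRAF V600E, EGFR L858R and the
#' EGFR exon-19 deletion E746_A750del, at synthetic coordinates.
#'
#' @return data.frame with columns `site`, `chrom`, `pos`, `ref`, `alt`.
#' @export
control_sites <- function() {
  data.frame(
    site = c("KRAS_G12C", "PIK3CA_E545K", "PIK3CA_H1047R", "BRAF_V600E",
             "EGFR_L858R", "EGFR_E746_A750del"),
    chrom = c("ctg_KRAS", "ctg_PIK3CA", "ctg_PIK3CA", "ctg_BRAF",
              "ctg_EGFR", "ctg_EGFR"),
    pos = c(25245350L, 179218303L, 179234297L, 140753336L, 55191822L, 55174772L),
    ref = c("C", "G", "A", "A", "T", "TGGAATTAAGAGAAGCA"),
    alt = c("A", "A", "G", "T", "G", "TA"),
    stringsAsFactors = FALSE)
}
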