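# Three-step variant filtering: binomial p-value, strict thresholds, Fisher
# strand-bias proxy, hotspot restriction, germline subtraction, and the
# stage-order properties of the combined pipeline.

test_that("variant_pvalue is the exact binomial upper tail", {
  expect_equal(variant_pvalue(0, 10, 0.5), 1)        # whole sample space
  expect_equal(variant_pvalue(3, 10, 0.5), 0.9453125)
  expect_equal(variant_pvalue(7, 10, 0.5), 0.171875)
  expect_equal(variant_pvalue(11, 10000, 0.001), 0.4169602, tolerance = 1e-6)
  expect_equal(variant_pvalue(5, 100, 0), 0)         # errors impossible
  expect_equal(variant_pvalue(0, 100, 0), 1)
})

test_that("variant_pvalue matches the summation oracle to 1e-12", {
  set.seed(31)
  for (i in 1:60) {
    n <- sample(1:1000, 1)
    k <- sample(0:n, 1)
    p <- runif(1, 1e-4, 0.5)
    want <- binom_tail_oracle(k, n, p)
    got <- variant_pvalue(k, n, p)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("threshold comparisons are strict, as printed", {
  prof <- filter_profile("plasma")
  # variant coverage bound ">10": exactly 10 alt reads is removed
  at10 <- mk_set(mk_calls(1L, depth = 10000L, alt_reads = 10L, p_value = 0))
  r <- apply_threshold_filter(at10, prof)
  expect_equal(nrow(r$callset$calls), 0L)
  expect_identical(r$trace$disposition, "alt_reads")
  at11 <- mk_set(mk_calls(1L, depth = 9000L, alt_reads = 11L, p_value = 0))
  expect_equal(nrow(apply_threshold_filter(at11, prof)$callset$calls), 1L)

  # tissue VAF bound ">5%": VAF exactly 0.05 is removed
  tis <- filter_profile("tissue")
  v05 <- mk_set(mk_calls(1L, depth = 2000L, alt_reads = 100L, p_value = 0),
                "tumor")
  r <- apply_threshold_filter(v05, tis)
  expect_identical(r$trace$disposition, "vaf")
  v_above <- mk_set(mk_calls(1L, depth = 2000L, alt_reads = 101L, p_value = 0),
                    "tumor")
  expect_equal(nrow(apply_threshold_filter(v_above, tis)$callset$calls), 1L)

  # p bound "< 0.01": exactly 0.01 fails
  pb <- mk_set(mk_calls(1L, depth = 10000L, alt_reads = 50L, p_value = 0.01))
  expect_identical(apply_threshold_filter(pb, prof)$trace$disposition, "p_value")
})

test_that("sample-level mean-depth failure removes every call", {
  cs <- mk_set(mk_calls(1:3, depth = 10000L, alt_reads = 100L, p_value = 0),
               mean_depth = 10000)  # bound is strict >10000
  r <- apply_threshold_filter(cs, filter_profile("plasma"))
  expect_equal(nrow(r$callset$calls), 0L)
  expect_identical(r$trace$disposition, rep("mean_depth", 3))
})

test_that("zero-depth calls fail as undefined VAF; empty sets pass through", {
  cs <- mk_set(mk_calls(1L, depth = 0L, alt_reads = 0L, p_value = 0))
  r <- apply_threshold_filter(cs, filter_profile("plasma",
                                                 min_alt_reads = 0))
  expect_identical(r$trace$disposition, "vaf")
  empty <- mk_set(empty_calls())
  r <- apply_threshold_filter(empty, filter_profile("plasma"))
  expect_equal(nrow(r$callset$calls), 0L)
  expect_equal(nrow(r$trace), 0L)
})

test_that("strand-bias filter drops only gross imbalance", {
  # perfectly balanced: keep
  expect_true(strand_bias_keep(500L, 500L, 10L, 10L))
  # 20/0 alt on balanced ref: Fisher p ~ 1.7e-6 < 0.001 -> drop
  expect_false(strand_bias_keep(500L, 500L, 20L, 0L))
  # degenerate all-zero table: keep (no evidence)
  expect_true(strand_bias_keep(0L, 0L, 0L, 0L))
  # decisions agree with fisher.test at the configured alpha
  set.seed(41)
  for (i in 1:25) {
    tab <- matrix(sample(0:60, 4, TRUE), 2)
    keep <- strand_bias_keep(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    want <- sum(tab) == 0 || stats::fisher.test(tab)$p.value >= 0.001
    expect_identical(keep, want)
  }
})

test_that("hotspot restriction uses region containment; empty panel drops all", {
  reg <- tiny_regions()
  inside <- mk_set(mk_calls(55241705L, p_value = 0))
  out <- apply_hotspot_filter(inside, reg)
  expect_equal(nrow(out$callset$calls), 1L)
  at_start <- mk_set(mk_calls(55241700L, p_value = 0))
  expect_identical(apply_hotspot_filter(at_start, reg)$trace$disposition,
                   "hotspot")
  none <- hotspot_regions(character(), integer(), integer())
  expect_equal(nrow(apply_hotspot_filter(inside, none)$callset$calls), 0L)
})

test_that("germline subtraction removes WBC-matched keys only", {
  somatic <- mk_calls(100L)
  germ <- mk_calls(200L, ref = "G", alt = "A")
  cs <- mk_set(rbind(somatic, germ))
  wbc <- mk_set(germ, "wbc")
  r <- subtract_germline(cs, wbc)
  expect_equal(r$callset$calls$pos, 100L)
  expect_setequal(r$trace$disposition, c("kept", "germline"))
  # empty WBC set is the identity
  r0 <- subtract_germline(cs, mk_set(empty_calls(), "wbc"))
  expect_equal(nrow(r0$callset$calls), 2L)
})

test_that("pipeline traces attribute each removal to its stage", {
  reg <- tiny_regions()
  # passes every threshold but sits outside the panel
  off_panel <- mk_calls(99L, p_value = 0)
  pair <- sample_pair("P1",
                      mk_set(empty_calls(), "tumor"),
                      mk_set(off_panel, "plasma"))
  res <- run_filter_pipeline(pair, regions = reg)
  expect_identical(res$traces$plasma$disposition, "hotspot")

  # disposition partition: kept + removed = input size
  set.seed(51)
  calls <- mk_calls(sample(55241701:55241710, 6, TRUE),
                    depth = 12000L,
                    alt_reads = sample(c(5L, 30L, 600L), 6, TRUE))
  pair <- sample_pair("P2", mk_set(empty_calls(), "tumor"), mk_set(calls))
  res <- run_filter_pipeline(pair, regions = reg)
  expect_equal(nrow(res$traces$plasma), 6L)
  expect_equal(sum(res$traces$plasma$disposition == "kept"),
               nrow(res$pair$plasma$calls))
})

test_that("planted somatic survives both compartments, germline in neither", {
  reg <- tiny_regions()
  som <- mk_calls(55241705L, alt_reads = 500L)
  germ <- mk_calls(55241708L, ref = "G", alt = "A", alt_reads = 5000L)
  pair <- sample_pair(
    "P1",
    mk_set(rbind(mk_calls(55241705L, depth = 2000L, alt_reads = 300L),
                 mk_calls(55241708L, ref = "G", alt = "A", depth = 2000L,
                          alt_reads = 1000L)), "tumor"),
    mk_set(rbind(som, germ)),
    call_set(mk_calls(55241708L, ref = "G", alt = "A", depth = 2000L,
                      alt_reads = 1000L), "W", "wbc", mean_depth = 2000))
  res <- run_filter_pipeline(pair, regions = reg)
  expect_equal(res$pair$tumor$calls$pos, 55241705L)
  expect_equal(res$pair$plasma$calls$pos, 55241705L)
})

test_that("raising any threshold never increases the surviving count", {
  set.seed(61)
  reg <- hotspot_regions("chr7", 0L, 10000L)
  for (rep in 1:15) {
    n <- sample(3:12, 1)
    depth <- sample(8000:15000, n, TRUE)
    calls <- mk_calls(sample(1:10000, n), depth = depth,
                      alt_reads = vapply(depth, function(d)
                        sample(0:200, 1), integer(1)))
    cs <- mk_set(calls)
    base <- filter_profile("plasma")
    n0 <- nrow(filter_callset(cs, base, reg)$callset$calls)
    for (arg in c("min_alt_reads", "min_vaf")) {
      args <- list("plasma")
      args[[arg]] <- base[[arg]] * 2 + 1e-4
      stricter <- do.call(filter_profile, args)
      n1 <- nrow(filter_callset(cs, stricter, reg)$callset$calls)
      expect_lte(n1, n0)
    }
    tighter_p <- filter_profile("plasma", max_p = base$max_p / 10)
    expect_lte(nrow(filter_callset(cs, tighter_p, reg)$callset$calls), n0)
  }
})

test_that("the surviving set does not depend on stage order", {
  set.seed(71)
  reg <- hotspot_regions(c("chr7", "chr7"), c(0L, 6000L), c(3000L, 9000L))
  stages <- list(
    thresh = function(cs) apply_threshold_filter(cs, filter_profile("plasma"))$callset,
    strand = function(cs) apply_strand_bias_filter(cs, 0.001)$callset,
    hot = function(cs) apply_hotspot_filter(cs, reg)$callset)
  perms <- list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1), c(3, 2, 1))
  for (rep in 1:8) {
    n <- sample(4:10, 1)
    alt <- sample(0:400, n, TRUE)
    af <- vapply(alt, function(a) sample(0:a, 1), integer(1))
    calls <- mk_calls(sample(1:10000, n), depth = 12000L, alt_reads = alt,
                      alt_fwd = af, alt_rev = alt - af,
                      ref_fwd = 6000L, ref_rev = 6000L - alt + af)
    calls$ref_fwd <- as.integer(6000)
    calls$ref_rev <- as.integer(12000 - alt - 6000)
    cs <- mk_set(calls)
    keysets <- lapply(perms, function(p) {
      out <- cs
      for (s in stages[p]) out <- s(out)
      sort(mutation_key(out$calls$chrom, out$calls$pos, out$calls$ref,
                        out$calls$alt))
    })
    for (k in keysets[-1]) expect_identical(k, keysets[[1]])
  }
})
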