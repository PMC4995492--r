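# Mutation matching, pair categories, fractional allocation, aggregate
# metrics with intervals, and the mutation spectrum.

test_that("matching compares keys, ignores VAFs, collapses duplicates", {
  one <- mk_calls(100L, alt_reads = 500L)
  same_other_vaf <- mk_calls(100L, alt_reads = 13L)
  m <- match_mutations(one, same_other_vaf)
  expect_length(m$concordant, 1L)
  expect_length(m$tdna_only, 0L)
  expect_length(m$ctdna_only, 0L)

  m <- mk_match(0, 2, 3)
  expect_length(m$ctdna_only, 3L)
  expect_length(m$tdna_only, 2L)
  expect_length(m$concordant, 0L)

  m <- match_mutations(empty_calls(), empty_calls())
  expect_length(c(m$concordant, m$tdna_only, m$ctdna_only), 0L)

  dup <- rbind(one, one)
  expect_warning(m <- match_mutations(dup, one), "duplicate")
  expect_length(m$concordant, 1L)
})

test_that("pair categories cover the six match structures exactly", {
  expect_identical(classify_pair(mk_match(0, 0, 0)), "none")
  expect_identical(classify_pair(mk_match(1, 0, 0)), "concordant_only")
  expect_identical(classify_pair(mk_match(1, 0, 1)), "concordant_plus_discordant")
  expect_identical(classify_pair(mk_match(1, 2, 0)), "concordant_plus_discordant")
  expect_identical(classify_pair(mk_match(0, 2, 0)), "tdna_only")
  expect_identical(classify_pair(mk_match(0, 0, 3)), "ctdna_only")
  expect_identical(classify_pair(mk_match(0, 2, 3)), "discordant_both")
})

test_that("fractional allocation reproduces the worked mixed-pair example", {
  # three plasma-only + two tumor-only mutations: weight 1/5 each
  fr <- allocate_fractions(mk_match(0, 2, 3))
  expect_equal(fr[["fp"]], 0.6)
  expect_equal(fr[["fn"]], 0.4)
  expect_equal(fr[["tp"]], 0)
  expect_equal(fr[["tn"]], 0)

  expect_equal(allocate_fractions(mk_match(0, 0, 0)),
               c(tp = 0, fp = 0, fn = 0, tn = 1))
  expect_equal(allocate_fractions(mk_match(2, 0, 1)),
               c(tp = 2 / 3, fp = 1 / 3, fn = 0, tn = 0))
  # pure pairs are whole pair-equivalents
  expect_equal(allocate_fractions(mk_match(3, 0, 0))[["tp"]], 1)
  expect_equal(allocate_fractions(mk_match(0, 4, 0))[["fn"]], 1)
  expect_equal(allocate_fractions(mk_match(0, 0, 2))[["fp"]], 1)
})

test_that("allocation conserves one pair-equivalent and matches the oracle", {
  set.seed(81)
  for (i in 1:300) {
    m <- mk_match(sample(0:4, 1), sample(0:4, 1), sample(0:4, 1))
    fr <- allocate_fractions(m)
    expect_equal(sum(fr), 1, tolerance = 1e-12)
    expect_true(all(fr >= 0))
    expect_equal(fr, allocation_oracle(m), tolerance = 1e-12)
    # category/allocation coherence
    cat <- classify_pair(m)
    expect_identical(cat == "none", fr[["tn"]] == 1)
    expect_identical(cat == "concordant_only", fr[["tp"]] == 1)
  }
})

test_that("aggregation computes the four metrics with undefined denominators", {
  two <- rbind(c(tp = 1, fp = 0, fn = 0, tn = 0),
               c(tp = 0, fp = 0, fn = 0, tn = 1))
  s <- aggregate_concordance(two)
  expect_equal(s$metrics["concordance", "estimate"], 1)
  expect_equal(s$metrics["sensitivity", "estimate"], 1)
  expect_equal(s$metrics["specificity", "estimate"], 1)
  expect_equal(s$metrics["ppv", "estimate"], 1)

  # a lone fully discordant pair: every ratio 0
  lone <- t(allocate_fractions(mk_match(0, 2, 3)))
  s <- aggregate_concordance(lone)
  expect_equal(unname(s$metrics$estimate), c(0, 0, 0, 0))

  # all pairs mutation-free: sensitivity and PPV undefined, specificity 1
  tn_only <- rbind(c(tp = 0, fp = 0, fn = 0, tn = 1),
                   c(tp = 0, fp = 0, fn = 0, tn = 1))
  s <- aggregate_concordance(tn_only)
  expect_true(is.na(s$metrics["sensitivity", "estimate"]))
  expect_true(is.na(s$metrics["ppv", "estimate"]))
  expect_equal(s$metrics["specificity", "estimate"], 1)

  expect_error(aggregate_concordance(empty_calls()[0, 0]), "no pairs")
})

test_that("cohort conservation: pair-equivalents sum to n", {
  set.seed(91)
  counts <- t(vapply(1:50, function(i)
    allocate_fractions(mk_match(sample(0:3, 1), sample(0:3, 1),
                                sample(0:3, 1))), numeric(4)))
  s <- aggregate_concordance(counts)
  expect_equal(sum(s$totals), 50)
})

test_that("Wilson intervals accept fractional counts; boundaries behave", {
  ci <- proportion_ci(14, 26)
  expect_equal(unname(ci), c(0.3545794, 0.7124415), tolerance = 1e-5)
  expect_equal(proportion_ci(0, 10)[["lo"]], 0)
  expect_equal(proportion_ci(10, 10)[["hi"]], 1)
  # fractional effective counts are legal and bracket the point estimate
  ci <- proportion_ci(13.28, 27.55)
  expect_true(ci[["lo"]] < 13.28 / 27.55 && 13.28 / 27.55 < ci[["hi"]])
  expect_true(all(is.na(proportion_ci(0, 0))))
  # Clopper-Pearson agrees with binom.test on integer counts
  for (x in c(0, 3, 14, 26)) {
    want <- stats::binom.test(x, 26)$conf.int
    got <- proportion_ci(x, 26, method = "clopper-pearson")
    expect_equal(unname(got), as.numeric(want), tolerance = 1e-9)
  }
})

test_that("perfect plasma/tumor agreement gives concordance 1", {
  set.seed(101)
  pairs <- lapply(1:8, function(i) {
    n <- sample(0:4, 1)
    calls <- if (n > 0) mk_calls(sample(1:1e5, n)) else empty_calls()
    sample_pair(paste0("P", i), mk_set(calls, "tumor"), mk_set(calls))
  })
  fit <- concordance(pairs)
  expect_equal(coef(fit)[["concordance"]], 1)
  expect_true(all(fit$per_pair$fp == 0) && all(fit$per_pair$fn == 0))
})

test_that("the concordance fit exposes coef, confint and summary", {
  pairs <- list(
    sample_pair("A", mk_set(mk_calls(1:2), "tumor"), mk_set(mk_calls(2:3))),
    sample_pair("B", mk_set(empty_calls(), "tumor"), mk_set(empty_calls())))
  fit <- concordance(pairs)
  expect_s3_class(fit, "ctdna_concordance")
  # pair A: C=1, Fn=1, Fp=1 -> tp 1/3; pair B: tn 1
  expect_equal(coef(fit)[["concordance"]], (1 / 3 + 1) / 2)
  ci <- confint(fit)
  expect_equal(rownames(ci),
               c("concordance", "sensitivity", "specificity", "ppv"))
  expect_true(all(ci[, "lo"] <= ci[, "hi"], na.rm = TRUE))
  expect_s3_class(summary(fit), "concordance_summary")
  expect_identical(sum(fit$category_counts), 2L)
  expect_output(print(fit), "Concordance over 2 sample pairs")
})

test_that("mutation tallies reconcile compartment totals into distinct counts", {
  t <- mutation_tallies(59, 76, 34, 45)
  expect_equal(t$total_calls, 135)
  expect_equal(t$distinct, 101)
  expect_equal(t$per_positive_pair, 101 / 45)
  expect_equal(round(t$per_positive_pair, 2), 2.24)
  expect_true(is.na(mutation_tallies(0, 0, 0, 0)$per_positive_pair))
})

test_that("mutation spectrum reports gene rates, class mix and tallies", {
  egfr <- mk_calls(100L, gene = "EGFR")
  pairs <- list(
    sample_pair("A", mk_set(egfr, "tumor"), mk_set(empty_calls())),
    sample_pair("B", mk_set(empty_calls(), "tumor"), mk_set(empty_calls())))
  sp <- mutation_spectrum(pairs)
  expect_equal(sp$gene_rates$tumor[["EGFR"]], 0.5)
  expect_equal(sp$tallies$n_tdna, 1)
  expect_equal(sp$tallies$n_positive_pairs, 1)
  expect_equal(sp$tallies$per_positive_pair, 1)
  expect_equal(sp$class_proportions$tumor[["SNP"]], 1)

  # unannotated bucket
  anon <- mk_calls(200L)
  sp <- mutation_spectrum(list(sample_pair("C", mk_set(anon, "tumor"),
                                           mk_set(empty_calls()))))
  expect_true("unannotated" %in% names(sp$gene_rates$tumor))

  # no calls at all
  sp <- mutation_spectrum(list(sample_pair("D", mk_set(empty_calls(), "tumor"),
                                           mk_set(empty_calls()))))
  expect_equal(sp$tallies$distinct, 0)
})
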