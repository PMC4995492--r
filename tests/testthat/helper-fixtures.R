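# Shared fixtures: quick call builders, a tiny hotspot panel, random-match
# generators, and independent oracles used across test files.

mk_calls <- function(pos, ref = "C", alt = "T", chrom = "chr7",
                     depth = 10000L, alt_reads = 100L, gene = NA,
                     alt_fwd = NULL, alt_rev = NULL,
                     ref_fwd = NULL, ref_rev = NULL, p_value = NA_real_) {
  n <- length(pos)
  variant_calls(rep_len(chrom, n), pos, rep_len(ref, n), rep_len(alt, n),
                gene = gene, depth = rep_len(depth, n),
                alt_reads = rep_len(alt_reads, n),
                alt_fwd = alt_fwd, alt_rev = alt_rev,
                ref_fwd = ref_fwd, ref_rev = ref_rev, p_value = p_value)
}

mk_set <- function(calls, type = "plasma", mean_depth = NULL, id = "S1") {
  if (is.null(mean_depth))
    mean_depth <- if (type == "plasma") 12000 else 2000
  call_set(calls, id, type, mean_depth = mean_depth)
}

tiny_regions <- function() hotspot_regions("chr7", 55241700L, 55241710L)

# a mutation_match with given set sizes, built from real calls so keys go
# through the same normalization path as production code
mk_match <- function(n_conc, n_tdna, n_ctdna) {
  conc <- if (n_conc) mk_calls(1000L + seq_len(n_conc)) else empty_calls()
  tonly <- if (n_tdna) mk_calls(2000L + seq_len(n_tdna)) else empty_calls()
  ponly <- if (n_ctdna) mk_calls(3000L + seq_len(n_ctdna)) else empty_calls()
  match_mutations(rbind(conc, tonly), rbind(conc, ponly))
}

# independent binomial upper-tail oracle: direct term-by-term summation in
# log space, never calling pbinom
binom_tail_oracle <- function(k, n, p) {
  if (k <= 0) return(1)
  if (p == 0) return(0)
  ks <- k:n
  sum(exp(lchoose(n, ks) + ks * log(p) + (n - ks) * log1p(-p)))
}

# exhaustive Mann-Whitney permutation oracle (no ties): two-sided p as the
# share of label assignments whose U is at least as extreme as observed
mw_perm_oracle <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  n1 <- length(x); n <- length(pooled)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  ext_obs <- min(u_obs, n1 * (n - n1) - u_obs)
  sets <- utils::combn(n, n1)
  us <- apply(sets, 2, u_of)
  mean(pmin(us, n1 * (n - n1) - us) <= ext_obs)
}

# brute-force fractional allocation: assign each mutation weight 1/T and sum
# per statistical group, enumerating mutations one by one
allocation_oracle <- function(match) {
  muts <- c(rep("tp", length(match$concordant)),
            rep("fn", length(match$tdna_only)),
            rep("fp", length(match$ctdna_only)))
  if (length(muts) == 0) return(c(tp = 0, fp = 0, fn = 0, tn = 1))
  w <- 1 / length(muts)
  c(tp = sum(muts == "tp") * w, fp = sum(muts == "fp") * w,
    fn = sum(muts == "fn") * w, tn = 0)
}
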