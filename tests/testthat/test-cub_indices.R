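code <- load_code(1)

test_that("family homozygosity follows the pseudocount formula exactly", {
  # equal counts give F = 1/m for any count, including zero
  for (c0 in c(0, 1, 10, 1000)) {
    expect_equal(family_F(c(c0, c0))$F_cf, 0.5)
  }
  expect_equal(family_F(c(0, 0, 0, 0))$F_cf, 0.25)
  # direct substitution: counts (1, 0) -> (2/3)^2 + (1/3)^2 = 5/9
  expect_equal(family_F(c(1, 0))$F_cf, 5 / 9)
  # random six-fold families against the literal summation oracle
  set.seed(2)
  for (i in 1:20) {
    ni <- sample(0:50, 6, replace = TRUE)
    expect_equal(family_F(ni)$F_cf, oracle_family_F(ni))
  }
  expect_error(family_F(5, m = 1), "m must be >= 2")
  expect_error(family_F(c(-1, 2)), "negative")
})

test_that("ENc hits its analytic limits: 61 at uniformity, 20 at extreme bias", {
  expect_equal(enc(uniform_counts(code), code), 61)
  expect_equal(enc(uniform_counts(code, 1000L), code), 61)
  expect_lt(abs(enc(extreme_counts(code), code) - 20), 0.05)
})

test_that("ENc equals the brute-force family/class oracle on random genes", {
  set.seed(7)
  for (i in 1:10) {
    cc <- random_counts(code, sample(100:800, 1))
    expect_equal(enc(cc, code), oracle_enc(cc, code))
  }
})

test_that("ENc decreases as one codon's share within a family grows", {
  base <- uniform_counts(code, 50L)
  prev <- enc(base, code)
  cc <- base
  for (shift in c(10L, 25L, 45L)) {
    cc$counts[["GCT"]] <- 50L + shift
    cc$counts[["GCA"]] <- 50L - shift
    e <- enc(cc, code)
    expect_lt(e, prev)
    prev <- e
  }
})

test_that("ENc is asymptotically scale-invariant and RSCU exactly so", {
  set.seed(9)
  cc <- random_counts(code, 500)
  # pseudocounts vanish relative to large counts, so ENc converges as the
  # whole count vector is scaled up
  mid <- big <- cc
  mid$counts <- cc$counts * 100L
  big$counts <- cc$counts * 10000L
  expect_lt(abs(enc(big, code) - enc(mid, code)), 0.05)
  expect_equal(rscu(big, code)$rscu, rscu(cc, code)$rscu)
})

test_that("the expected-ENc curve matches its closed form pointwise", {
  expect_equal(enc_expected(0.5), 60.5)
  expect_equal(enc_expected(0), 31)
  expect_equal(enc_expected(1), 32)
  s <- seq(0, 1, length.out = 1000)
  expect_equal(enc_expected(s), 2 + s + 29 / (s^2 + (1 - s)^2))
  # peak of ~60.5 sits within a hundredth of s = 0.5
  expect_equal(s[which.max(enc_expected(s))], 0.5, tolerance = 0.01)
  expect_equal(max(enc_expected(s)), 60.5, tolerance = 5e-5)
  expect_error(enc_expected(1.2), "\\[0, 1\\]")
})

test_that("ENc ratio is the printed quotient", {
  expect_equal(enc_ratio(50, 40), 0.2)
  expect_equal(enc_ratio(47.3, 47.3), 0)
  expect_error(enc_ratio(0, 40), "> 0")
  # recomputation sweep: ratio consistent with its two inputs
  set.seed(3)
  for (i in 1:5) {
    cc <- random_counts(code, 400)
    gc3s <- composition_profile(cc, code)$gc3s
    ee <- enc_expected(gc3s); eo <- enc(cc, code)
    expect_equal(enc_ratio(ee, eo), (ee - eo) / ee)
  }
})

test_that("RSCU normalizes within families and classifies by thresholds", {
  tab <- rscu(make_counts(code, c(AAC = 2, AAT = 2)), code)
  expect_equal(tab$rscu[tab$codon %in% c("AAC", "AAT")], c(1, 1))
  expect_equal(tab$class[tab$codon == "AAC"], "unbiased")
  tab2 <- rscu(make_counts(code, c(AAC = 3, AAT = 1)), code)
  expect_equal(tab2$rscu[tab2$codon == "AAC"], 1.5)
  expect_equal(tab2$rscu[tab2$codon == "AAT"], 0.5)
  expect_equal(tab2$class[tab2$codon == "AAC"], "average-biased")
  expect_equal(tab2$class[tab2$codon == "AAT"], "under")
  tab3 <- rscu(make_counts(code, c(CTA = 30, CTC = 1, CTG = 1, CTT = 1,
                                   TTA = 1, TTG = 1)), code)
  expect_equal(tab3$class[tab3$codon == "CTA"], "over")
  # unobserved families are flagged NA, not NaN
  expect_true(all(is.na(tab$rscu[!tab$family_observed])))
  expect_false(any(is.nan(tab$rscu)))
})

test_that("RSCU family sums conserve degeneracy on random genes", {
  set.seed(13)
  for (i in 1:10) {
    cc <- random_counts(code, 400)
    tab <- rscu(cc, code)
    oracle <- oracle_rscu(cc, code)
    expect_equal(stats::setNames(tab$rscu, tab$codon), oracle)
    sums <- tapply(tab$rscu, tab$aa, sum)
    for (aa in names(sums)) {
      f <- code$families[[aa]]
      if (any(cc$counts[f$codons] > 0)) expect_equal(sums[[aa]], f$m)
    }
  }
})

test_that("CAI weights are ratio-to-family-max with pseudo-frequency floor", {
  ref <- make_counts(code, c(AAC = 10, AAT = 5))
  w <- cai_weights(ref, code, on_missing = "na")
  expect_equal(unname(w[c("AAC", "AAT")]), c(1, 0.5))
  # uniform reference: every weight 1
  wu <- cai_weights(uniform_counts(code), code)
  expect_true(all(wu == 1))
  # zero-count codon in an observed family gets 0.5 / max, never 0
  ref2 <- make_counts(code, c(GCT = 20))
  w2 <- cai_weights(ref2, code, on_missing = "na")
  expect_equal(unname(w2[["GCA"]]), 0.5 / 20)
  expect_true(all(w2[!is.na(w2)] > 0))
  # random reference against the ratio-to-max oracle
  set.seed(17)
  ref3 <- random_counts(code, 2000)
  w3 <- cai_weights(ref3, code)
  for (f in code$families) {
    if (f$m < 2L) next
    o <- as.numeric(ref3$counts[f$codons])
    o[o == 0] <- 0.5
    expect_equal(unname(w3[f$codons]), o / max(o))
  }
  expect_error(cai_weights(ref, code), "no codons for families")
})

test_that("CAI is the geometric mean of weights, in [0, 1]", {
  ref <- uniform_counts(code)
  w <- cai_weights(ref, code)
  expect_equal(cai(make_counts(code, c(GCT = 30, AAC = 20)), w), 1)
  # two codons with weights (1, 0.25) -> sqrt(0.25)
  ref2 <- make_counts(code, c(AAC = 8, AAT = 2))
  w2 <- cai_weights(ref2, code, on_missing = "na")
  expect_equal(cai(make_counts(code, c(AAC = 1, AAT = 1)), w2), 0.5)
  # random genes equal the literal exp-mean-log oracle and stay in [0, 1]
  set.seed(19)
  ref3 <- random_counts(code, 3000)
  w3 <- cai_weights(ref3, code)
  for (i in 1:10) {
    cc <- random_counts(code, 300)
    v <- cai(cc, w3)
    expect_equal(v, oracle_cai(cc, w3))
    expect_gte(v, 0); expect_lte(v, 1)
  }
  # length invariance at fixed codon proportions
  cc1 <- make_counts(code, c(AAC = 3, AAT = 1))
  cc2 <- make_counts(code, c(AAC = 30, AAT = 10))
  expect_equal(cai(cc1, w3), cai(cc2, w3))
})

test_that("gravy and aroma follow the residue tables", {
  expect_equal(gravy(make_counts(code, c(ATT = 50)), code), 4.5)
  expect_equal(gravy(make_counts(code, c(ATT = 10, AAT = 10)), code), 0.5)
  # hydrophilic-only gene is negative
  expect_lt(gravy(make_counts(code, c(AAA = 5, GAT = 5, CGT = 5)), code), 0)
  # F,Y,G residues -> 2/3 aromatic
  expect_equal(aroma(make_counts(code, c(TTT = 1, TAT = 1, GGG = 1)), code),
               2 / 3)
  expect_equal(aroma(make_counts(code, c(GCT = 9)), code), 0)
  # Trp (TGG) counts toward aroma though excluded from codon indices
  expect_equal(aroma(make_counts(code, c(TGG = 1, GCT = 3)), code), 0.25)
  # random gene against a residue tally oracle
  set.seed(29)
  cc <- random_counts(code, 500)
  aa <- rep(code$codon_to_aa[names(cc$counts)], cc$counts)
  aa <- aa[aa != "*"]
  expect_equal(aroma(cc, code), mean(aa %in% c("F", "Y", "W")))
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
          E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
          M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
          Y = -1.3, V = 4.2)
  aa_syn <- aa[!(aa %in% c("M", "W"))]
  expect_equal(gravy(cc, code), mean(kd[aa_syn]))
})

test_that("optimal codons are recovered when usage tracks bias strength", {
  spec <- synthetic_spec(n_genes = 40, length_range = c(120L, 250L),
                         gc3_target = 0.5, preference_strength = 1.5,
                         expression_gradient = 0.5, expression_amplify = 3,
                         seed = 101)
  corpus <- generate_corpus(spec)
  fit <- cub_analysis(corpus)
  planted <- corpus$truth$preferred_codons
  found <- stats::setNames(fit$optimal_codons$codon, fit$optimal_codons$aa)
  hits <- sum(found[names(planted)] == planted, na.rm = TRUE)
  expect_gte(hits / length(planted), 0.8)
})

test_that("optimal codon selection is silent on no-signal corpora and breaks ties", {
  # identical usage everywhere: no variance, no optimal codons
  recs <- do.call(rbind, lapply(1:12, function(i)
    gene_record(paste0("u", i), rep(c("GCT", "GCA", "AAC", "AAT"), 26))))
  fit <- cub_analysis(recs, dedupe = FALSE)
  expect_true(all(is.na(fit$optimal_codons$codon)))
  # constant columns are counted as skipped
  expect_true(all(fit$optimal_codons$n_skipped_constant >= 0))
})
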