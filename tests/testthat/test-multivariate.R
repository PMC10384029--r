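code <- load_code(1)

test_that("the RSCU matrix has one row per gene and 59 fixed columns", {
  set.seed(47)
  genes <- lapply(1:3, function(i) random_counts(code, 300, paste0("g", i)))
  mat <- build_rscu_matrix(genes, code)
  expect_equal(dim(mat), c(3L, 59L))
  expect_equal(rownames(mat), c("g1", "g2", "g3"))
  expect_equal(colnames(mat), code$analyzed_codons)  # lexicographic
  # rows reproduce the per-gene rscu values; family sums = degeneracy
  for (i in 1:3) {
    orc <- oracle_rscu(genes[[i]], code)
    orc[is.na(orc)] <- 0
    expect_equal(mat[i, ], orc[colnames(mat)])
  }
  expect_error(build_rscu_matrix(genes[1], code), ">= 2")
})

test_that("unobserved families are zero-imputed and flagged", {
  g1 <- make_counts(code, c(AAC = 3, AAT = 1), "only2fold")
  g2 <- random_counts(code, 200, "full")
  mat <- build_rscu_matrix(list(g1, g2), code)
  imp <- attr(mat, "imputed")
  expect_true(all(mat["only2fold", imp["only2fold", ]] == 0))
  expect_true(imp["only2fold", "GCT"])
  expect_false(imp["only2fold", "AAC"])
})

test_that("a rank-2 matrix yields one axis carrying all inertia", {
  mat <- rbind(a = c(4, 0, 1, 3), b = c(0, 4, 3, 1),
               a2 = c(4, 0, 1, 3) * 2)
  res <- correspondence_analysis(mat)
  expect_equal(length(res$inertia_fractions), 1L)
  expect_equal(res$inertia_fractions, 1)
  # identical row profiles -> zero inertia, degenerate error
  same <- rbind(x = c(1, 2, 3), y = c(2, 4, 6))
  expect_error(correspondence_analysis(same), "inertia")
  expect_error(correspondence_analysis(matrix(-1, 2, 2)), "negative")
})

test_that("CA reproduces an independent decomposition up to per-axis sign", {
  set.seed(53)
  genes <- lapply(1:10, function(i)
    random_counts(code, sample(200:500, 1), paste0("g", i)))
  mat <- build_rscu_matrix(genes, code)
  res <- correspondence_analysis(mat, n_axes = 4)
  # oracle: eigen-decomposition of the standardized residual cross-product
  P <- mat / sum(mat)
  r <- rowSums(P); cm <- colSums(P)
  S <- (P - outer(r, cm)) / sqrt(outer(r, cm))
  ev <- eigen(S %*% t(S))
  lam <- ev$values[ev$values > 1e-12]
  expect_equal(res$inertia[seq_along(lam)], lam, tolerance = 1e-8)
  # row principal coordinates from the oracle eigenvectors
  for (a in 1:4) {
    orc <- (ev$vectors[, a] / sqrt(r)) * sqrt(ev$values[a])
    got <- res$row_coords[, a]
    expect_true(isTRUE(all.equal(got, orc, tolerance = 1e-6,
                                 check.attributes = FALSE)) ||
                isTRUE(all.equal(got, -orc, tolerance = 1e-6,
                                 check.attributes = FALSE)))
  }
  # inertia fractions: non-increasing, sum to 1
  expect_true(all(diff(res$inertia_fractions) <= 1e-12))
  expect_equal(sum(res$inertia_fractions), 1, tolerance = 1e-9)
})

test_that("CA cross-checks against MASS::corresp and scalar invariance", {
  skip_if_not_installed("MASS")
  set.seed(59)
  genes <- lapply(1:8, function(i) random_counts(code, 300, paste0("g", i)))
  mat <- build_rscu_matrix(genes, code)
  res <- correspondence_analysis(mat, n_axes = 2)
  # corresp warns about non-integer RSCU entries; CA is defined for any
  # non-negative table, so the warning is expected and irrelevant here
  mc <- suppressWarnings(MASS::corresp(mat, nf = 2))
  # MASS returns standard coordinates; principal = standard * singular value
  for (a in 1:2) {
    orc <- mc$rscore[, a] * mc$cor[a]
    got <- res$row_coords[, a]
    agree <- min(max(abs(got - orc)), max(abs(got + orc)))
    expect_lt(agree, 1e-6)
  }
  # total inertia is invariant to positive scaling of the matrix
  res2 <- correspondence_analysis(mat * 7.3, n_axes = 2)
  expect_equal(res2$total_inertia, res$total_inertia, tolerance = 1e-10)
  expect_equal(res2$inertia_fractions, res$inertia_fractions,
               tolerance = 1e-9)
})

test_that("correlation wrapper matches closed forms and handles degeneracy", {
  x <- c(1, 2, 3, 4, 5)
  r <- correlation(x, 2 * x + 1, method = "pearson")
  expect_equal(r$coefficient, 1)
  r2 <- correlation(x, c(9, 7, 5, 3, 1), method = "spearman")
  expect_equal(r2$coefficient, -1)
  # textbook product-moment formula oracle
  set.seed(61)
  a <- rnorm(20); b <- 0.4 * a + rnorm(20)
  rp <- correlation(a, b, method = "pearson")
  orc <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(rp$coefficient, orc)
  expect_equal(rp$n, 20)
  # symmetry
  expect_equal(correlation(b, a, method = "pearson")$coefficient,
               rp$coefficient)
  # monotone-transform invariance of Spearman
  expect_equal(correlation(exp(a), b, method = "spearman")$coefficient,
               correlation(a, b, method = "spearman")$coefficient)
  # zero variance -> flagged NA, not an error
  z <- correlation(rep(1, 5), x)
  expect_true(z$zero_variance)
  expect_true(is.na(z$coefficient))
  expect_error(correlation(1:2, 1:2), ">= 3")
})

test_that("correlation panels cover the standard pairs with BH adjustment", {
  spec <- synthetic_spec(n_genes = 30, preference_strength = 1.5,
                         expression_gradient = 0.5, seed = 67)
  fit <- cub_analysis(generate_corpus(spec))
  pan <- fit$correlations
  expect_s3_class(pan, "correlation_panel")
  expect_equal(nrow(pan), 13L)
  expect_true(all(abs(pan$coefficient) <= 1, na.rm = TRUE))
  expect_true(all(pan$p_adjusted >= pan$p_value - 1e-12, na.rm = TRUE))
  # planted preference: high-CAI genes are the low-ENc genes
  cai_enc <- pan[pan$var1 == "cai" & pan$var2 == "enc", ]
  expect_lt(cai_enc$coefficient, 0)
  expect_error(correlation_panels(data.frame(enc = 1:5)), "missing columns")
})
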