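#' Build the gene-by-codon RSCU matrix
#'
#' One row per gene, one column per analyzed codon (59 under the standard
#' code) in fixed lexicographic order. RSCU entries of families unobserved
#' in a gene are imputed as 0 and flagged in the `"imputed"` attribute.
#'
#' @param counts_list List of `codon_counts` objects, length >= 2.
#' @param code A `genetic_code`.
#' @return Numeric matrix (genes x codons) with gene ids as rownames and an
#'   `"imputed"` logical matrix attribute marking zero-filled entries.
#' @export
build_rscu_matrix <- function(counts_list, code) {
  if (length(counts_list) < 2L) stop("build_rscu_matrix: need >= 2 genes")
  cods <- code$analyzed_codons
  mat <- matrix(0, nrow = length(counts_list), ncol = length(cods),
                dimnames = list(vapply(counts_list, `[[`, character(1),
                                       "gene_id"),
                                cods))
  imputed <- matrix(FALSE, nrow = nrow(mat), ncol = ncol(mat),
                    dimnames = dimnames(mat))
  for (i in seq_along(counts_list)) {
    tab <- rscu(counts_list[[i]], code)
    v <- stats::setNames(tab$rscu, tab$codon)[cods]
    miss <- is.na(v)
    v[miss] <- 0
    mat[i, ] <- v
    imputed[i, ] <- miss
  }
  attr(mat, "imputed") <- imputed
  mat
}

#' Correspondence analysis of a non-negative matrix
#'
#' Classical (simple) correspondence analysis: the matrix is normalized to
#' a correspondence table, centred by the outer product of row and column
#' masses, scaled to standardized residuals, and decomposed by SVD. Row and
#' column principal coordinates and per-axis inertia fractions are
#' returned. Applied here to the gene-by-codon RSCU matrix, axis 1 captures
#' the dominant trend in synonymous codon usage across genes.
#'
#' Axis signs are fixed deterministically: each axis is flipped, if needed,
#' so the column (codon) coordinate of the alphabetically first column with
#' a nonzero loading on that axis is positive.
#'
#' @param mat Non-negative numeric matrix with positive grand total (e.g.
#'   from [build_rscu_matrix()]). Rows that are all zero are dropped with a
#'   warning; all-zero columns are dropped silently from the decomposition.
#' @param n_axes Number of axes to retain (default 4, capped at the rank).
#' @return A list of class `ca_result`: `row_coords`, `col_coords`
#'   (principal coordinates, axes as columns), `inertia` (per-axis
#'   principal inertias), `inertia_fractions` (non-increasing, summing
#'   to 1), `total_inertia`, `n_axes`.
#' @export
correspondence_analysis <- function(mat, n_axes = 4L) {
  stopifnot(is.matrix(mat))
  if (any(mat < 0)) stop("correspondence_analysis: negative entries")
  zero_rows <- rowSums(mat) == 0
  if (any(zero_rows)) {
    warning("dropping ", sum(zero_rows), " all-zero row(s)")
    mat <- mat[!zero_rows, , drop = FALSE]
  }
  keep_cols <- colSums(mat) > 0
  mat <- mat[, keep_cols, drop = FALSE]
  total <- sum(mat)
  if (total <= 0 || nrow(mat) < 2L) {
    stop("correspondence_analysis: degenerate matrix (zero total or < 2 rows)")
  }
  P <- mat / total
  r <- rowSums(P)
  cm <- colSums(P)
  # standardized residuals S = D_r^{-1/2} (P - r c') D_c^{-1/2}
  S <- (P - outer(r, cm)) / sqrt(outer(r, cm))
  dec <- svd(S)
  tol <- max(dim(S)) * max(dec$d, 0) * .Machine$double.eps * 100
  pos <- dec$d > tol
  if (!any(pos)) {
    stop("correspondence_analysis: zero total inertia (all rows identical ",
         "profiles)")
  }
  d <- dec$d[pos]
  U <- dec$u[, pos, drop = FALSE]
  V <- dec$v[, pos, drop = FALSE]
  k <- min(n_axes, length(d))
  inertia <- d^2
  fr <- inertia / sum(inertia)
  row_co <- sweep(U, 1, sqrt(r), "/") %*% diag(d, length(d))
  col_co <- sweep(V, 1, sqrt(cm), "/") %*% diag(d, length(d))
  # deterministic sign: first column with nonzero loading gets a positive one
  for (a in seq_len(length(d))) {
    nz <- which(abs(col_co[, a]) > tol)
    if (length(nz) > 0 && col_co[nz[1L], a] < 0) {
      col_co[, a] <- -col_co[, a]
      row_co[, a] <- -row_co[, a]
    }
  }
  dimnames(row_co) <- list(rownames(mat), paste0("axis", seq_along(d)))
  dimnames(col_co) <- list(colnames(mat), paste0("axis", seq_along(d)))
  structure(list(row_coords = row_co[, seq_len(k), drop = FALSE],
                 col_coords = col_co[, seq_len(k), drop = FALSE],
                 inertia = inertia,
                 inertia_fractions = fr,
                 total_inertia = sum(inertia),
                 n_axes = k),
            class = "ca_result")
}

#' @export
print.ca_result <- function(x, ...) {
  k <- min(4L, length(x$inertia_fractions))
  cat("Correspondence analysis: ", nrow(x$row_coords), " rows x ",
      nrow(x$col_coords), " columns, total inertia ",
      format(x$total_inertia, digits = 5), "\n", sep = "")
  cat("Inertia fractions (first ", k, "): ",
      paste(sprintf("%.2f%%", 100 * x$inertia_fractions[seq_len(k)]),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Correlation between two per-gene quantities
#'
#' Complete-case correlation with a two-sided test; a thin, uniform wrapper
#' used by all correlation panels.
#'
#' @param x,y Numeric vectors of equal length.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return A list with `coefficient`, `p_value`, `n` (complete cases), and
#'   `method`; coefficient is `NA` with a flag when either side has zero
#'   variance.
#' @export
correlation <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("correlation: need >= 3 complete cases")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(coefficient = NA_real_, p_value = NA_real_,
                n = length(x), method = method, zero_variance = TRUE))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(coefficient = unname(ct$estimate), p_value = ct$p.value,
       n = length(x), method = method, zero_variance = FALSE)
}

# Variable pairs of the standard correlation panel.
panel_pairs <- list(
  c("enc", "gc3s"), c("axis1", "gc"), c("axis1", "gc3"), c("axis1", "cai"),
  c("axis1", "enc"), c("cai", "enc"), c("cai", "gc3"), c("gravy", "gc"),
  c("gravy", "enc"), c("aroma", "gc"), c("aroma", "enc"),
  c("length_nt", "gc"), c("length_nt", "enc"))

#' Standard correlation panel over the per-gene index table
#'
#' Computes the fixed panel of pairwise correlations used to diagnose the
#' drivers of codon usage: ENc vs GC3s, CA axis 1 vs composition / CAI /
#' ENc, CAI vs ENc and GC3, Gravy and Aroma vs GC and ENc, and gene length
#' vs GC and ENc. Raw p-values are reported alongside Benjamini–Hochberg
#' adjusted ones.
#'
#' @param index_table Per-gene data.frame containing columns `enc`, `gc`,
#'   `gc3`, `gc3s`, `cai`, `gravy`, `aroma`, `length_nt`, `axis1`.
#' @param method Correlation method passed to [correlation()].
#' @return A data.frame of class `correlation_panel`: `var1`, `var2`,
#'   `method`, `coefficient`, `p_value`, `p_adjusted`, `n`.
#' @export
correlation_panels <- function(index_table,
                               method = c("spearman", "pearson")) {
  method <- match.arg(method)
  need <- unique(unlist(panel_pairs))
  miss <- setdiff(need, names(index_table))
  if (length(miss) > 0) {
    stop("correlation_panels: missing columns: ", paste(miss, collapse = ", "))
  }
  rows <- lapply(panel_pairs, function(pr) {
    r <- correlation(index_table[[pr[1L]]], index_table[[pr[2L]]], method)
    data.frame(var1 = pr[1L], var2 = pr[2L], method = method,
               coefficient = r$coefficient, p_value = r$p_value,
               n = r$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[, c("var1", "var2", "method", "coefficient", "p_value",
                 "p_adjusted", "n")]
  class(out) <- c("correlation_panel", "data.frame")
  out
}
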