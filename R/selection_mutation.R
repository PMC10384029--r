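#' Parity-rule-2 (PR2) plot coordinates of a gene
#'
#' Tallies third-position bases over the two-, four- and six-fold degenerate
#' families only (the three-fold Ile family and single-codon families are
#' excluded by default) and returns the PR2-plot point
#' `x = G3/(G3 + C3)`, `y = A3/(A3 + T3)`. Under pure, symmetric mutation
#' pressure A = T and G = C at these positions, so genes cluster at
#' (0.5, 0.5); departures indicate strand- or selection-driven asymmetry.
#'
#' @param counts A `codon_counts` object.
#' @param code A `genetic_code`.
#' @param include_threefold Also count the three-fold family (Ile)?
#'   Default `FALSE`.
#' @return A list of class `pr2_point` with `x`, `y` (either is `NA` with a
#'   flag if its denominator is zero), the four base tallies `a3`, `t3`,
#'   `c3`, `g3`, and `defined` (logical: both coordinates defined).
#' @export
pr2_point <- function(counts, code, include_threefold = FALSE) {
  stopifnot(inherits(counts, "codon_counts"), inherits(code, "genetic_code"))
  degs <- if (include_threefold) c(2L, 3L, 4L, 6L) else c(2L, 4L, 6L)
  cd <- codons_of_degeneracy(code, degs)
  n <- counts$counts[cd]
  if (sum(n) == 0L) stop("pr2_point: no codons in qualifying families for ",
                         counts$gene_id)
  third <- substr(cd, 3L, 3L)
  tal <- vapply(c("A", "T", "C", "G"),
                function(b) sum(n[third == b]), numeric(1))
  at <- tal[["A"]] + tal[["T"]]
  gc <- tal[["G"]] + tal[["C"]]
  x <- if (gc > 0) tal[["G"]] / gc else NA_real_
  y <- if (at > 0) tal[["A"]] / at else NA_real_
  structure(list(x = x, y = y,
                 a3 = tal[["A"]], t3 = tal[["T"]],
                 c3 = tal[["C"]], g3 = tal[["G"]],
                 defined = !is.na(x) && !is.na(y)),
            class = "pr2_point")
}

# Third-base classification used by the P2 index.
p2_doublets_ww <- c("AA", "AT", "TA", "TT")
p2_doublets_ss <- c("CC", "CG", "GC", "GG")

#' P2 translational-selection index of a gene
#'
#' Classifies codons by their first two bases (W = A/T, S = C/G) and their
#' pyrimidine third base (Y = C/T), then computes
#' \deqn{P2 = \frac{WWC + SST}{WWY + SSY}}
#' the frequency with which codons starting with the doublets AA, AT, TA,
#' TT (WW) or CC, CG, GC, GG (SS) choose the translationally favoured
#' pyrimidine. Values above 0.5 indicate selection for codon–anticodon
#' interaction strength.
#'
#' @param counts A `codon_counts` object.
#' @return A list of class `p2_result` with raw tallies `wwc`, `wwt`,
#'   `wwy`, `ssc`, `sst`, `ssy` and the index `p2` (`NA` with
#'   `defined = FALSE` when no codon qualifies).
#' @export
p2_index <- function(counts) {
  stopifnot(inherits(counts, "codon_counts"))
  cd <- names(counts$counts)
  n <- as.numeric(counts$counts)
  d2 <- substr(cd, 1L, 2L)
  b3 <- substr(cd, 3L, 3L)
  ww <- d2 %in% p2_doublets_ww
  ss <- d2 %in% p2_doublets_ss
  wwc <- sum(n[ww & b3 == "C"]); wwt <- sum(n[ww & b3 == "T"])
  ssc <- sum(n[ss & b3 == "C"]); sst <- sum(n[ss & b3 == "T"])
  wwy <- wwc + wwt; ssy <- ssc + sst
  denom <- wwy + ssy
  structure(list(wwc = wwc, wwt = wwt, wwy = wwy,
                 ssc = ssc, sst = sst, ssy = ssy,
                 p2 = if (denom > 0) (wwc + sst) / denom else NA_real_,
                 defined = denom > 0),
            class = "p2_result")
}

#' Corpus-level P2 summary
#'
#' Reports both aggregation conventions: the unweighted mean of per-gene P2
#' values and P2 recomputed from the pooled tallies of all genes. The two
#' coincide only when genes contribute equal numbers of qualifying codons,
#' so both are printed rather than choosing silently.
#'
#' @param p2_list List of `p2_result` objects (one per gene).
#' @return A data.frame with one row: pooled tallies `wwc`..`ssy`,
#'   `p2_pooled`, `p2_mean`, `n_genes` (genes with defined P2).
#' @export
p2_summary <- function(p2_list) {
  ok <- vapply(p2_list, `[[`, logical(1), "defined")
  if (!any(ok)) stop("p2_summary: no gene has a defined P2")
  p2_list <- p2_list[ok]
  tot <- function(f) sum(vapply(p2_list, `[[`, numeric(1), f))
  wwc <- tot("wwc"); wwt <- tot("wwt"); ssc <- tot("ssc"); sst <- tot("sst")
  data.frame(wwc = wwc, wwt = wwt, wwy = wwc + wwt,
             ssc = ssc, sst = sst, ssy = ssc + sst,
             p2_pooled = (wwc + sst) / (wwc + wwt + ssc + sst),
             p2_mean = mean(vapply(p2_list, `[[`, numeric(1), "p2")),
             n_genes = length(p2_list))
}

#' Neutrality regression of GC12 on GC3
#'
#' Ordinary least-squares fit of per-gene GC12 on GC3 across a corpus. A
#' slope near 1 is read as mutation pressure dominating codon-position GC
#' content, a slope near 0 as selective constraint dominating, and 0.5 as
#' an even balance.
#'
#' @param gc12 Numeric vector of per-gene GC12 fractions.
#' @param gc3 Numeric vector of per-gene GC3 fractions, same length.
#' @return A list of class `neutrality_fit`: `slope`, `intercept`, `r`
#'   (Pearson correlation), `p_value` (two-sided, from the slope t-test),
#'   `n_genes`, `label` (mutation-dominated / balanced / selection-dominated
#'   reading of the slope), and `lm_fit` (the underlying [stats::lm] object).
#' @export
neutrality_fit <- function(gc12, gc3) {
  ok <- is.finite(gc12) & is.finite(gc3)
  gc12 <- gc12[ok]; gc3 <- gc3[ok]
  if (length(gc3) < 3L) stop("neutrality_fit: need at least 3 genes")
  if (stats::sd(gc3) == 0) {
    stop("neutrality_fit: zero variance in GC3, slope undefined")
  }
  fit <- stats::lm(gc12 ~ gc3)
  sl <- unname(stats::coef(fit)[2L])
  # suppress the "essentially perfect fit" warning on exact collinear input
  p <- suppressWarnings(summary(fit)$coefficients[2L, 4L])
  lbl <- if (abs(sl) >= 0.75) "mutation-dominated"
         else if (abs(sl) >= 0.25) "balanced"
         else "selection-dominated"
  structure(list(slope = sl,
                 intercept = unname(stats::coef(fit)[1L]),
                 # zero variance in gc12 (flat fit) makes r undefined, not fatal
                 r = suppressWarnings(stats::cor(gc3, gc12)),
                 p_value = p,
                 n_genes = length(gc3),
                 label = lbl,
                 lm_fit = fit),
            class = "neutrality_fit")
}

#' @export
print.neutrality_fit <- function(x, ...) {
  cat(sprintf(
    "Neutrality regression (GC12 on GC3, n = %d genes)\n  slope = %.4f  intercept = %.4f  r = %.4f  p = %.3g\n  reading: %s\n",
    x$n_genes, x$slope, x$intercept, x$r, x$p_value, x$label))
  invisible(x)
}
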