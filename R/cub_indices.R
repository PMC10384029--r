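#' Per-family codon homozygosity with pseudocounts
#'
#' For one synonymous family of degeneracy `m` with codon counts
#' `n_1, ..., n_m` (total `n`), computes
#' \deqn{F = \sum_{i=1}^{m} \left(\frac{n_i + 1}{n + m}\right)^2}
#' The `+1` pseudocounts keep `F` defined even for unobserved families
#' (`n = 0` gives `F = 1/m` exactly), and `F = 1/m` exactly whenever all
#' `m` codons are used equally. The family's effective codon number is
#' `1/F`.
#'
#' @param family_counts Numeric vector of per-codon counts for one family.
#' @param m Family degeneracy; must equal `length(family_counts)` and be
#'   at least 2.
#' @return A list with `F_cf`, `n` (family total), and `m`.
#' @export
family_F <- function(family_counts, m = length(family_counts)) {
  if (m < 2L) stop("family_F: degeneracy m must be >= 2 (single-codon ",
                   "families carry no synonymous choice)")
  if (length(family_counts) != m) stop("family_F: counts length != m")
  if (any(family_counts < 0)) stop("family_F: negative counts")
  n <- sum(family_counts)
  list(F_cf = sum(((family_counts + 1) / (n + m))^2), n = n, m = m)
}

#' Effective number of codons (ENc), codon-family formulation
#'
#' Computes ENc for one gene from its codon counts. Each synonymous family's
#' homozygosity `F` is computed with [family_F()] (pseudocount form); the
#' per-degeneracy-class means of `F` are then combined Wright-style. Under
#' the standard code:
#' \deqn{ENc = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6}
#' where the leading 2 counts the single-codon families (Met, Trp). ENc is
#' 61 exactly for perfectly even synonymous usage and approaches 20 when
#' each family uses a single codon. Values below 35 are conventionally read
#' as strong codon usage bias.
#'
#' @param counts A `codon_counts` object.
#' @param code A `genetic_code`.
#' @param drop_unobserved_families If `TRUE`, families with zero counts are
#'   dropped from their class mean instead of contributing `F = 1/m`;
#'   default `FALSE` (the pseudocount form is defined at `n = 0`).
#' @return ENc as a single numeric value.
#' @export
enc <- function(counts, code, drop_unobserved_families = FALSE) {
  stopifnot(inherits(counts, "codon_counts"), inherits(code, "genetic_code"))
  if (counts$n_codons_analyzed == 0L) {
    stop("no observed codons in any synonymous family for gene ",
         counts$gene_id)
  }
  fam_m <- vapply(code$families, function(f) f$m, integer(1))
  fam_F <- numeric(length(code$families))
  fam_n <- numeric(length(code$families))
  for (i in seq_along(code$families)) {
    f <- code$families[[i]]
    if (f$m >= 2L) {
      ff <- family_F(counts$counts[f$codons], f$m)
      fam_F[i] <- ff$F_cf
      fam_n[i] <- ff$n
    }
  }
  total <- sum(fam_m == 1L)  # singleton families each contribute 1 codon
  for (k in sort(unique(fam_m[fam_m >= 2L]))) {
    sel <- fam_m == k
    if (drop_unobserved_families) sel <- sel & fam_n > 0
    if (!any(sel)) next
    Fbar <- mean(fam_F[sel])
    total <- total + sum(fam_m == k) / Fbar
  }
  total
}

#' Expected ENc under GC mutation bias alone
#'
#' Wright's expected-ENc curve as a function of the GC content at
#' synonymous third positions:
#' \deqn{ENc_{exp}(s) = 2 + s + \frac{29}{s^2 + (1-s)^2}}
#' Its maximum over `[0, 1]` is 60.5 at `s = 0.5`.
#'
#' @param gc3s GC3s fraction(s) in `[0, 1]`; vectorized.
#' @return Expected ENc value(s).
#' @export
enc_expected <- function(gc3s) {
  if (any(gc3s < 0 | gc3s > 1, na.rm = TRUE)) {
    stop("enc_expected: gc3s must lie in [0, 1]")
  }
  2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)
}

#' Relative deviation of observed from expected ENc
#'
#' `(ENc_exp - ENc_obs) / ENc_exp`: positive when the gene is more biased
#' than GC composition alone predicts.
#'
#' @param enc_exp Expected ENc (must be positive); vectorized.
#' @param enc_obs Observed ENc.
#' @return The ENc ratio.
#' @export
enc_ratio <- function(enc_exp, enc_obs) {
  if (any(enc_exp <= 0, na.rm = TRUE)) stop("enc_ratio: enc_exp must be > 0")
  (enc_exp - enc_obs) / enc_exp
}

#' Relative synonymous codon usage (RSCU)
#'
#' RSCU of a codon is its observed count divided by the count expected if
#' all synonyms of its amino acid were used equally: within a family of
#' size `k` with counts `O_c`,
#' \deqn{RSCU_c = \frac{O_c}{\frac{1}{k}\sum_{c'} O_{c'}}}
#' Values sum to `k` within each observed family; 1 means unbiased use.
#' Codons are classed by the conventional thresholds: `over` (> 1.6),
#' `average-biased` ((1, 1.6]), `unbiased` ([0.6, 1]), `under` (< 0.6).
#' Families with zero total count get `NA` RSCU and are flagged, not
#' propagated as NaN.
#'
#' @param counts A `codon_counts` object (single gene or pooled corpus).
#' @param code A `genetic_code`.
#' @return A data.frame of class `rscu_table` with one row per analyzed
#'   codon: `codon`, `aa`, `count`, `rscu`, `class` (`NA` class for
#'   unobserved families), `family_observed`.
#' @export
rscu <- function(counts, code) {
  stopifnot(inherits(counts, "codon_counts"), inherits(code, "genetic_code"))
  rows <- lapply(code$families, function(f) {
    if (f$m < 2L) return(NULL)
    o <- as.numeric(counts$counts[f$codons])
    tot <- sum(o)
    val <- if (tot > 0) o / (tot / f$m) else rep(NA_real_, f$m)
    data.frame(codon = f$codons, aa = f$aa, count = o, rscu = val,
               family_observed = tot > 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$codon), ]
  rownames(out) <- NULL
  out$class <- ifelse(is.na(out$rscu), NA_character_,
               ifelse(out$rscu > 1.6, "over",
               ifelse(out$rscu > 1, "average-biased",
               ifelse(out$rscu >= 0.6, "unbiased", "under"))))
  class(out) <- c("rscu_table", "data.frame")
  out
}

#' Relative-adaptiveness weights for CAI
#'
#' Sharp–Li weights from a reference codon pool: each codon's frequency in
#' the reference divided by the frequency of the most used synonym in its
#' family, so the best codon of every family has weight 1. Codons absent
#' from the reference within an otherwise observed family receive a
#' pseudo-frequency (default 0.5) before the ratio, keeping `log(w)` finite.
#'
#' @param reference_counts Pooled `codon_counts` of the reference gene set
#'   (typically the whole filtered genome, or a highly expressed subset).
#' @param code A `genetic_code`.
#' @param zero_pseudofreq Pseudo-count assigned to reference-absent codons
#'   in observed families. Default 0.5.
#' @param on_missing What to do when an entire family is absent from the
#'   reference: `"error"` (default) or `"na"` (leave that family's weights
#'   `NA`; [cai()] then skips those codons). The `"na"` mode is what the
#'   pipeline uses with a self-referenced corpus, where any codon a gene
#'   uses is necessarily present in the pooled reference.
#' @return Named numeric vector of class `cai_weights`: one weight in
#'   `(0, 1]` (or `NA`) per analyzed codon.
#' @export
cai_weights <- function(reference_counts, code, zero_pseudofreq = 0.5,
                        on_missing = c("error", "na")) {
  on_missing <- match.arg(on_missing)
  stopifnot(inherits(reference_counts, "codon_counts"),
            inherits(code, "genetic_code"))
  w <- stats::setNames(rep(NA_real_, length(code$analyzed_codons)),
                       code$analyzed_codons)
  missing_fams <- character(0)
  for (f in code$families) {
    if (f$m < 2L) next
    o <- as.numeric(reference_counts$counts[f$codons])
    if (sum(o) == 0) {
      missing_fams <- c(missing_fams, f$aa)
      next
    }
    o[o == 0] <- zero_pseudofreq
    w[f$codons] <- o / max(o)
  }
  if (length(missing_fams) > 0 && on_missing == "error") {
    stop("cai_weights: reference set has no codons for families: ",
         paste(missing_fams, collapse = ", "))
  }
  class(w) <- "cai_weights"
  w
}

#' Codon adaptation index (CAI)
#'
#' Geometric mean of the relative-adaptiveness weights of a gene's analyzed
#' codons:
#' \deqn{CAI = \exp\left(\frac{1}{L}\sum_{k=1}^{L} \ln \omega_{c_k}\right)}
#' where `L` is the number of analyzed codons. CAI lies in `(0, 1]`; 1 means
#' the gene uses only each family's reference-preferred codon.
#'
#' @param counts A `codon_counts` object.
#' @param weights A `cai_weights` vector from [cai_weights()].
#' @return CAI as a single numeric value.
#' @export
cai <- function(counts, weights) {
  stopifnot(inherits(counts, "codon_counts"))
  ok <- !is.na(weights)
  codons <- names(weights)[ok]
  n <- as.numeric(counts$counts[codons])
  L <- sum(n)
  if (L < 1) stop("cai: gene has no analyzed codons with defined weights")
  exp(sum(n * log(as.numeric(weights)[ok])) / L)
}

#' Identify putative optimal codons
#'
#' The optimal codon of each amino-acid family is the codon whose per-gene
#' RSCU correlates most negatively with per-gene ENc across the corpus
#' (usage rising as bias strengthens), subject to two-sided p < `alpha`.
#' Zero-variance codon columns are skipped and flagged. Ties on the
#' correlation are broken by larger mean RSCU, then lexicographic codon
#' order.
#'
#' @param rscu_matrix Gene-by-codon RSCU matrix from [build_rscu_matrix()].
#' @param enc_per_gene Numeric vector of per-gene ENc values, aligned with
#'   the matrix rows.
#' @param code A `genetic_code`.
#' @param method Correlation method, `"spearman"` (default) or `"pearson"`.
#' @param alpha Two-sided significance level for the negative correlation
#'   (default 0.05).
#' @param min_genes Minimum number of genes required (default 10).
#' @return A data.frame of class `optimal_codons`: one row per multi-codon
#'   family with `aa`, `codon` (`NA` if no codon qualifies), `r`, `p_value`,
#'   `n_skipped_constant` (zero-variance codons in the family).
#' @export
optimal_codons <- function(rscu_matrix, enc_per_gene, code,
                           method = c("spearman", "pearson"),
                           alpha = 0.05, min_genes = 10L) {
  method <- match.arg(method)
  stopifnot(is.matrix(rscu_matrix),
            nrow(rscu_matrix) == length(enc_per_gene))
  if (nrow(rscu_matrix) < min_genes) {
    stop("optimal_codons: need at least ", min_genes, " genes")
  }
  rows <- lapply(code$families, function(f) {
    if (f$m < 2L) return(NULL)
    res <- lapply(f$codons, function(cd) {
      x <- rscu_matrix[, cd]
      ok <- is.finite(x) & is.finite(enc_per_gene)
      if (sum(ok) < 3L || stats::sd(x[ok]) == 0 ||
          stats::sd(enc_per_gene[ok]) == 0) {
        return(list(codon = cd, r = NA_real_, p = NA_real_,
                    mean_rscu = mean(x[ok]), constant = TRUE))
      }
      ct <- suppressWarnings(
        stats::cor.test(x[ok], enc_per_gene[ok], method = method))
      list(codon = cd, r = unname(ct$estimate), p = ct$p.value,
           mean_rscu = mean(x[ok]), constant = FALSE)
    })
    r <- vapply(res, `[[`, numeric(1), "r")
    p <- vapply(res, `[[`, numeric(1), "p")
    mr <- vapply(res, `[[`, numeric(1), "mean_rscu")
    cds <- vapply(res, `[[`, character(1), "codon")
    const <- vapply(res, `[[`, logical(1), "constant")
    cand <- which(!is.na(r) & r < 0 & !is.na(p) & p < alpha)
    if (length(cand) == 0L) {
      pick <- NA_integer_
    } else {
      # most negative r; ties -> larger mean RSCU -> lexicographic codon
      ord <- order(r[cand], -mr[cand], cds[cand])
      pick <- cand[ord[1L]]
    }
    data.frame(aa = f$aa,
               codon = if (is.na(pick)) NA_character_ else cds[pick],
               r = if (is.na(pick)) NA_real_ else r[pick],
               p_value = if (is.na(pick)) NA_real_ else p[pick],
               n_skipped_constant = sum(const),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("optimal_codons", "data.frame")
  out
}

# Kyte-Doolittle hydropathy index per residue (canonical published scale).
kyte_doolittle <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

#' Grand average of hydropathy (Gravy)
#'
#' Mean Kyte–Doolittle hydropathy over the residues encoded by the gene's
#' analyzed codons (single-codon families Met and Trp are excluded,
#' consistent with the codon exclusions of the other indices). Positive
#' values indicate hydrophobic products, negative hydrophilic ones.
#'
#' @param counts A `codon_counts` object.
#' @param code A `genetic_code`.
#' @return Gravy as a single numeric value.
#' @export
gravy <- function(counts, code) {
  stopifnot(inherits(counts, "codon_counts"), inherits(code, "genetic_code"))
  cd <- code$analyzed_codons
  n <- as.numeric(counts$counts[cd])
  if (sum(n) == 0) stop("gravy: empty translation for gene ", counts$gene_id)
  aa <- code$codon_to_aa[cd]
  sum(n * kyte_doolittle[aa]) / sum(n)
}

#' Aromaticity of the translated product
#'
#' Fraction of aromatic residues (Phe, Tyr, Trp) among all residues of the
#' translated gene product. Unlike the codon-usage indices, the denominator
#' includes Met and Trp residues — aromaticity is a property of the whole
#' protein, so Trp counts toward the numerator too.
#'
#' @param counts A `codon_counts` object.
#' @param code A `genetic_code`.
#' @return Aromatic-residue fraction in `[0, 1]`.
#' @export
aroma <- function(counts, code) {
  stopifnot(inherits(counts, "codon_counts"), inherits(code, "genetic_code"))
  sense <- setdiff(names(counts$counts), code$stop_codons)
  n <- as.numeric(counts$counts[sense])
  if (sum(n) == 0) stop("aroma: empty translation for gene ", counts$gene_id)
  aa <- code$codon_to_aa[sense]
  sum(n[aa %in% c("F", "Y", "W")]) / sum(n)
}
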