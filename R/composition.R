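#' Nucleotide-composition profile of a gene
#'
#' Computes the positional GC statistics and third-position base composition
#' used throughout the codon-usage diagnostics. `gc`, `gc1`, `gc2`, `gc3`
#' and `gc12 = (gc1 + gc2)/2` are computed over all sense codons of the gene
#' (the terminal stop codon is excluded; ATG and TGG are included, so these
#' describe the whole coding sequence). `gc3s` and the third-position base
#' fractions `a3`, `t3`, `c3`, `g3` are computed over synonymously variable
#' codons only (families of degeneracy >= 2), the codon set on which
#' synonymous choice exists.
#'
#' @param counts A `codon_counts` object from [count_codons()].
#' @param code A `genetic_code`.
#' @return A list of class `composition_profile` with fields `gc`, `gc1`,
#'   `gc2`, `gc3`, `gc12`, `gc3s`, `a3`, `t3`, `c3`, `g3` (fractions in
#'   `[0, 1]`) and `n_codons` (sense codons used for `gc*`).
#' @export
composition_profile <- function(counts, code) {
  stopifnot(inherits(counts, "codon_counts"), inherits(code, "genetic_code"))
  if (counts$n_codons_analyzed == 0L) {
    stop("no analyzed codons for gene ", counts$gene_id,
         ": composition profile undefined")
  }
  cts <- counts$counts
  sense <- setdiff(names(cts), code$stop_codons)
  sense_cts <- cts[sense]
  n_sense <- sum(sense_cts)

  pos_frac_gc <- function(codons, w, pos) {
    b <- substr(codons, pos, pos)
    sum(w[b %in% c("G", "C")]) / sum(w)
  }
  gc1 <- pos_frac_gc(sense, sense_cts, 1L)
  gc2 <- pos_frac_gc(sense, sense_cts, 2L)
  gc3 <- pos_frac_gc(sense, sense_cts, 3L)
  gc <- (gc1 + gc2 + gc3) / 3

  syn <- code$analyzed_codons
  syn_cts <- cts[syn]
  n_syn <- sum(syn_cts)
  third <- substr(syn, 3L, 3L)
  base3 <- vapply(c("A", "T", "C", "G"),
                  function(b) sum(syn_cts[third == b]) / n_syn, numeric(1))
  structure(
    list(gc = gc, gc1 = gc1, gc2 = gc2, gc3 = gc3,
         gc12 = (gc1 + gc2) / 2,
         gc3s = base3[["G"]] + base3[["C"]],
         a3 = base3[["A"]], t3 = base3[["T"]],
         c3 = base3[["C"]], g3 = base3[["G"]],
         n_codons = n_sense),
    class = "composition_profile")
}

#' Pool composition across genes
#'
#' Codon-count-weighted pooling: equivalent to concatenating the codons of
#' all genes and recomputing the profile, not an unweighted mean of per-gene
#' fractions. Order-invariant.
#'
#' @param counts_list List of `codon_counts` objects (one per gene).
#' @param code A `genetic_code`.
#' @return A `composition_profile` for the pooled corpus.
#' @export
pool_composition <- function(counts_list, code) {
  if (length(counts_list) == 0L) stop("pool_composition: empty input")
  composition_profile(pool_counts(counts_list, code), code)
}
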