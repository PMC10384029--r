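# Evaluate expr under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Specify a synthetic CDS corpus
#'
#' Parameters of the generative model used to produce coding sequences with
#' known mutational bias and selection-like codon preference. Amino acids
#' are drawn i.i.d. from `aa_frequencies`; the codon within each family is
#' drawn from third-position base probabilities tilted toward `gc3_target`
#' (the mutation knob), multiplied by `exp(preference)` on the family's
#' preferred codon (the selection knob) and renormalized. A fraction
#' `expression_gradient` of genes is treated as highly expressed and has
#' its preference amplified by `expression_amplify`, creating the CAI/ENc
#' gradient that optimal-codon detection needs.
#'
#' Defaults emulate a biased, AT-rich protist coding-sequence set: GC3
#' target 0.3, moderate preference, 100 genes of 100–400 codons.
#'
#' @param n_genes Number of genes (default 100).
#' @param length_range Min/max sense-codon count per gene, excluding start
#'   and stop (default `c(100, 400)`, so all genes pass the 300-nt filter).
#' @param gc3_target Target GC fraction at synonymous third positions
#'   (default 0.3).
#' @param preference_strength Log-scale weight added to each family's
#'   preferred codon; 0 = neutral (default 0).
#' @param preferred_codons Named character vector (amino acid -> codon); if
#'   `NULL`, one codon per multi-codon family is drawn under `seed` and
#'   recorded in the truth.
#' @param expression_gradient Fraction of genes treated as highly expressed
#'   (default 0).
#' @param expression_amplify Preference multiplier for highly expressed
#'   genes (default 3).
#' @param aa_frequencies Named sampling weights over amino acids; default
#'   uniform over the multi-codon families.
#' @param table_id Genetic code table (default 1).
#' @param seed Integer seed; the generator is fully deterministic given the
#'   spec.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 100L, length_range = c(100L, 400L),
                           gc3_target = 0.3, preference_strength = 0,
                           preferred_codons = NULL,
                           expression_gradient = 0,
                           expression_amplify = 3,
                           aa_frequencies = NULL,
                           table_id = 1L, seed = 1L) {
  stopifnot(n_genes >= 1L, length_range[1L] >= 100L,
            length_range[2L] >= length_range[1L],
            gc3_target >= 0, gc3_target <= 1,
            preference_strength >= 0,
            expression_gradient >= 0, expression_gradient <= 1)
  structure(list(n_genes = as.integer(n_genes),
                 length_range = as.integer(length_range),
                 gc3_target = gc3_target,
                 preference_strength = preference_strength,
                 preferred_codons = preferred_codons,
                 expression_gradient = expression_gradient,
                 expression_amplify = expression_amplify,
                 aa_frequencies = aa_frequencies,
                 table_id = as.integer(table_id),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Per-codon sampling probabilities for one family under GC3 tilt g and
# log-preference s on codon `pref` (NA for none).
family_codon_probs <- function(codons, g, s = 0, pref = NA_character_) {
  third <- substr(codons, 3L, 3L)
  w <- ifelse(third %in% c("G", "C"), g / 2, (1 - g) / 2)
  if (!is.na(pref) && s != 0) w[codons == pref] <- w[codons == pref] * exp(s)
  if (sum(w) <= 0) {
    stop("infeasible spec: no codon of family {",
         paste(codons, collapse = ","), "} has positive weight at gc3 = ", g)
  }
  w / sum(w)
}

#' Generate a synthetic CDS corpus with known ground truth
#'
#' @param spec A `synthetic_spec`.
#' @return A list of class `synthetic_corpus` with `records` (data.frame of
#'   `gene_id`, `sequence`, `length_nt`, ready for [qc_filter()]) and
#'   `truth` (the spec, the realized preferred-codon map, and a per-gene
#'   data.frame with `gene_id`, `length_codons`, `highly_expressed`,
#'   `preference`).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  code <- load_code(spec$table_id)
  fams <- Filter(function(f) f$m >= 2L, code$families)
  aa_freq <- spec$aa_frequencies
  if (is.null(aa_freq)) {
    aa_freq <- stats::setNames(rep(1, length(fams)), names(fams))
  }
  aa_freq <- aa_freq / sum(aa_freq)
  with_seed(spec$seed, {
    pref <- spec$preferred_codons
    if (is.null(pref)) {
      pref <- vapply(fams, function(f) sample(f$codons, 1L), character(1))
    }
    he <- stats::runif(spec$n_genes) < spec$expression_gradient
    pref_strength <- ifelse(he,
                            spec$preference_strength * spec$expression_amplify,
                            spec$preference_strength)
    # probability tables per family for the two expression classes
    probs_for <- function(s) {
      lapply(fams, function(f)
        family_codon_probs(f$codons, spec$gc3_target, s, pref[[f$aa]]))
    }
    lens <- sample(seq(spec$length_range[1L], spec$length_range[2L]),
                   spec$n_genes, replace = TRUE)
    seqs <- character(spec$n_genes)
    prob_cache <- list()
    for (i in seq_len(spec$n_genes)) {
      key <- as.character(pref_strength[i])
      if (is.null(prob_cache[[key]])) {
        prob_cache[[key]] <- probs_for(pref_strength[i])
      }
      pr <- prob_cache[[key]]
      aas <- sample(names(aa_freq), lens[i], replace = TRUE, prob = aa_freq)
      cods <- vapply(aas, function(a) {
        f <- fams[[a]]
        sample(f$codons, 1L, prob = pr[[a]])
      }, character(1), USE.NAMES = FALSE)
      stop_cd <- sample(code$stop_codons, 1L)
      seqs[i] <- paste0("ATG", paste(cods, collapse = ""), stop_cd)
    }
    records <- data.frame(gene_id = sprintf("synth_%04d", seq_len(spec$n_genes)),
                          sequence = seqs, length_nt = nchar(seqs),
                          stringsAsFactors = FALSE)
    truth <- list(spec = spec,
                  preferred_codons = pref,
                  genes = data.frame(gene_id = records$gene_id,
                                     length_codons = lens,
                                     highly_expressed = he,
                                     preference = pref_strength,
                                     stringsAsFactors = FALSE))
    structure(list(records = records, truth = truth),
              class = "synthetic_corpus")
  })
}

# Families used by the neutrality-corpus construction: first two positions
# entirely G/C (gc12 = 1) or entirely A/T (gc12 = 0), all with both GC- and
# AT-ending synonyms.
neutrality_gc_fams <- c(A = "GC", G = "GG", P = "CC")   # 4-fold
neutrality_at_fams <- list(K = c("AAG", "AAA"), N = c("AAC", "AAT"),
                           F = c("TTC", "TTT"))  # GC-ending synonym first

#' Generate a corpus with a prescribed neutrality-plot slope
#'
#' Builds genes whose GC3 spreads widely across the corpus while GC12
#' follows `beta * GC3 + (1 - beta) * baseline + noise`, so the ordinary
#' least-squares slope of GC12 on GC3 has expectation `beta` — the
#' mutation-pressure share of codon-position GC content. Compositions are
#' realized by exact codon-count construction (each gene gets exactly
#' `round(g * L)` GC-ending thirds and `round(target_gc12 * L)` codons from
#' GC-rich amino-acid families), so with `beta = 1` and `noise_sd = 0` the
#' fitted slope is exactly 1.
#'
#' @param beta Target slope in `[0, 1]`.
#' @param n_genes Number of genes (default 500; must be >= 10).
#' @param seed Integer seed.
#' @param length_codons Sense codons per gene (default 300).
#' @param gc_range Range of the per-gene latent mutational GC level
#'   (default `c(0.1, 0.9)`).
#' @param noise_sd Gaussian noise on the GC12 target (default 0.02).
#' @param baseline Selection-side GC12 anchor (default 0.5).
#' @return A `synthetic_corpus` whose truth records `beta` and the per-gene
#'   latent GC levels and realized codon counts.
#' @export
generate_neutrality_corpus <- function(beta, n_genes = 500L, seed = 1L,
                                       length_codons = 300L,
                                       gc_range = c(0.1, 0.9),
                                       noise_sd = 0.02, baseline = 0.5) {
  stopifnot(beta >= 0, beta <= 1)
  if (n_genes < 10L) stop("generate_neutrality_corpus: n_genes must be >= 10")
  L <- as.integer(length_codons)
  with_seed(seed, {
    g <- stats::runif(n_genes, gc_range[1L], gc_range[2L])
    t12 <- beta * g + (1 - beta) * baseline +
      stats::rnorm(n_genes, 0, noise_sd)
    t12 <- pmin(pmax(t12, 0), 1)
    k3 <- round(g * L)
    k12 <- round(t12 * L)
    gc_f <- names(neutrality_gc_fams)
    at_f <- names(neutrality_at_fams)
    seqs <- character(n_genes)
    for (i in seq_len(n_genes)) {
      aa_gc <- sample(c(rep(TRUE, k12[i]), rep(FALSE, L - k12[i])))
      third_gc <- sample(c(rep(TRUE, k3[i]), rep(FALSE, L - k3[i])))
      cods <- character(L)
      for (j in seq_len(L)) {
        if (aa_gc[j]) {
          stem <- neutrality_gc_fams[[sample(gc_f, 1L)]]
          b3 <- if (third_gc[j]) sample(c("G", "C"), 1L)
                else sample(c("A", "T"), 1L)
          cods[j] <- paste0(stem, b3)
        } else {
          fam <- neutrality_at_fams[[sample(at_f, 1L)]]
          # fam[1] is the C/G-ending synonym, fam[2] the A/T-ending one
          cods[j] <- if (third_gc[j]) fam[1L] else fam[2L]
        }
      }
      seqs[i] <- paste0("ATG", paste(cods, collapse = ""), "TAA")
    }
    records <- data.frame(gene_id = sprintf("neut_%04d", seq_len(n_genes)),
                          sequence = seqs, length_nt = nchar(seqs),
                          stringsAsFactors = FALSE)
    truth <- list(beta = beta, seed = as.integer(seed),
                  length_codons = L, baseline = baseline,
                  noise_sd = noise_sd,
                  genes = data.frame(gene_id = records$gene_id,
                                     gc_latent = g, target_gc12 = t12,
                                     k3 = k3, k12 = k12,
                                     stringsAsFactors = FALSE))
    structure(list(records = records, truth = truth),
              class = "synthetic_corpus")
  })
}

#' Hand-auditable five-gene micro corpus
#'
#' Five tiny genes whose composition, family homozygosity, RSCU, CAI (under
#' the corpus's own pooled reference weights), Gravy, Aroma, PR2 and P2
#' values were computed by hand from the defining formulas and frozen into
#' the returned expected table. Used to pin the whole pipeline end to end.
#'
#' @return A list with `records` (5-gene data.frame) and `expected`
#'   (per-gene data.frame of hand-computed index values).
#' @export
worked_micro_corpus <- function() {
  glue_gene <- function(id, codons) {
    s <- paste0("ATG", paste(codons, collapse = ""), "TAA")
    data.frame(gene_id = id, sequence = s, length_nt = nchar(s),
               stringsAsFactors = FALSE)
  }
  records <- rbind(
    glue_gene("mg1", rep("GCT", 100)),                          # pure Ala/GCT
    glue_gene("mg2", rep(c("AAC", "AAT"), 50)),                 # balanced Asn
    glue_gene("mg3", rep(c("AAC", "AAT", "CCT", "CCC"), 25)),   # P2 = 0.5
    glue_gene("mg4", c(rep("ATT", 80), rep("ATC", 20))),        # Ile, CAI<1
    glue_gene("mg5", rep(c("GCG", "TTC", "TAC"), 34)))          # aromatic
  expected <- data.frame(
    gene_id = c("mg1", "mg2", "mg3", "mg4", "mg5"),
    # whole-CDS composition (sense codons incl. the ATG start)
    gc1  = c(100 / 101, 0, 50 / 101, 0, 34 / 103),
    gc2  = c(100 / 101, 0, 50 / 101, 0, 34 / 103),
    gc3  = c(1 / 101, 51 / 101, 51 / 101, 21 / 101, 1),
    # synonymously variable codons only (the ATG start drops out)
    gc3s = c(0, 1 / 2, 1 / 2, 1 / 5, 1),
    a3   = c(0, 0, 0, 0, 0),
    t3   = c(1, 1 / 2, 1 / 2, 4 / 5, 0),
    c3   = c(0, 1 / 2, 1 / 2, 1 / 5, 2 / 3),
    g3   = c(0, 0, 0, 0, 1 / 3),
    # CAI under pooled self-reference weights (pooled family counts: Ala
    # GCT 100 / GCG 34, Asn 75/75, Pro CCT 25 / CCC 25, Ile ATT 80 / ATC 20,
    # Phe TTC 34, Tyr TAC 34; absent synonyms get pseudo-frequency 0.5):
    # mg4 = exp(20 ln 0.25 / 100); mg5 = exp(34 ln 0.34 / 102)
    cai  = c(1, 1, 1, 0.25^(1 / 5), 0.34^(1 / 3)),
    gravy = c(1.8, -3.5, (-3.5 - 1.6) / 2, 4.5, (1.8 + 2.8 - 1.3) / 3),
    aroma = c(0, 0, 0, 0, 68 / 103),
    # mg1 is all GC-doublet codons ending T (SST), mg5 all WWC among its
    # pyrimidine-ending codons
    p2   = c(1, 1 / 2, 1 / 2, 1 / 5, 1),
    stringsAsFactors = FALSE)
  expected$gc12 <- (expected$gc1 + expected$gc2) / 2
  expected$gc <- (expected$gc1 + expected$gc2 + expected$gc3) / 3
  list(records = records, expected = expected)
}

#' Write a corpus to FASTA (plus optional truth sidecar)
#'
#' Plain-text, byte-deterministic FASTA writer for generated corpora.
#'
#' @param corpus A `synthetic_corpus` (or any list with a `records`
#'   data.frame).
#' @param fasta Output FASTA path.
#' @param truth_tsv Optional path for the per-gene truth table.
#' @return Invisibly, the FASTA path.
#' @export
write_corpus <- function(corpus, fasta, truth_tsv = NULL) {
  rec <- corpus$records
  lines <- as.vector(rbind(paste0(">", rec$gene_id), rec$sequence))
  writeLines(lines, fasta)
  if (!is.null(truth_tsv) && !is.null(corpus$truth$genes)) {
    utils::write.table(corpus$truth$genes, truth_tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(fasta)
}
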