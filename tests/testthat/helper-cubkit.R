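# Shared fixtures and independent oracles. Oracles are deliberately written
# as straight-line re-implementations of the defining formulas, independent
# of the package internals they check.

all_codons <- function(code) sort(names(code$codon_to_aa))

# Build a codon_counts object directly from a (partial) named count vector.
make_counts <- function(code, counts, gene_id = "test") {
  full <- stats::setNames(rep(0L, 64), all_codons(code))
  full[names(counts)] <- as.integer(counts)
  structure(list(gene_id = gene_id, counts = full,
                 n_codons_analyzed = sum(full[code$analyzed_codons]),
                 length_nt = 3L * sum(full)),
            class = "codon_counts")
}

# Uniform counts across every multi-codon family.
uniform_counts <- function(code, per_codon = 5L) {
  cts <- stats::setNames(rep(0L, 0), character(0))
  for (f in code$families) if (f$m >= 2L) {
    cts[f$codons] <- per_codon
  }
  make_counts(code, cts, gene_id = "uniform")
}

# One codon per family at a large count (extreme bias).
extreme_counts <- function(code, per_family = 10000L) {
  cts <- stats::setNames(rep(0L, 0), character(0))
  for (f in code$families) if (f$m >= 2L) cts[f$codons[1L]] <- per_family
  make_counts(code, cts, gene_id = "extreme")
}

# Random counts over the analyzed codons.
random_counts <- function(code, n_codons = 300L, gene_id = "rand") {
  cd <- sample(code$analyzed_codons, n_codons, replace = TRUE)
  tab <- table(cd)
  make_counts(code, stats::setNames(as.integer(tab), names(tab)), gene_id)
}

# Records row for an explicit codon sequence (ATG + codons + stop).
gene_record <- function(id, codons, stop = "TAA") {
  s <- paste0("ATG", paste(codons, collapse = ""), stop)
  data.frame(gene_id = id, sequence = s, length_nt = nchar(s),
             stringsAsFactors = FALSE)
}

# --- oracles ---------------------------------------------------------------

# Literal summation of the pseudocount family-homozygosity formula.
oracle_family_F <- function(ni) {
  n <- sum(ni); m <- length(ni)
  acc <- 0
  for (i in seq_len(m)) acc <- acc + ((ni[i] + 1) / (n + m))^2
  acc
}

# Independent ENc: per-family F by literal summation, class-mean aggregation.
oracle_enc <- function(counts, code) {
  Fs <- c(); ms <- c()
  for (f in code$families) {
    if (f$m < 2L) next
    Fs <- c(Fs, oracle_family_F(as.numeric(counts$counts[f$codons])))
    ms <- c(ms, f$m)
  }
  n_single <- sum(vapply(code$families, function(f) f$m, integer(1)) == 1L)
  total <- n_single
  for (k in unique(ms)) {
    total <- total + sum(ms == k) / mean(Fs[ms == k])
  }
  total
}

# Brute-force RSCU by family normalization.
oracle_rscu <- function(counts, code) {
  out <- c()
  for (f in code$families) {
    if (f$m < 2L) next
    o <- as.numeric(counts$counts[f$codons])
    v <- if (sum(o) > 0) o / (sum(o) / f$m) else rep(NA_real_, f$m)
    out[f$codons] <- v
  }
  out[sort(names(out))]
}

# Literal exp-mean-log CAI over analyzed codons with defined weights.
oracle_cai <- function(counts, weights) {
  lw <- 0; L <- 0
  for (cd in names(weights)) {
    if (is.na(weights[[cd]])) next
    k <- counts$counts[[cd]]
    if (k > 0) { lw <- lw + k * log(weights[[cd]]); L <- L + k }
  }
  exp(lw / L)
}

# Character-tally composition oracle over an explicit codon vector.
oracle_positional_gc <- function(codons, pos) {
  mean(substr(codons, pos, pos) %in% c("G", "C"))
}

# PR2 tallies by explicit loop over 2-/4-/6-fold family codons.
oracle_pr2 <- function(counts, code) {
  tal <- c(A = 0, T = 0, C = 0, G = 0)
  for (f in code$families) {
    if (!(f$m %in% c(2L, 4L, 6L))) next
    for (cd in f$codons) {
      b <- substr(cd, 3L, 3L)
      tal[b] <- tal[b] + counts$counts[[cd]]
    }
  }
  list(x = tal[["G"]] / (tal[["G"]] + tal[["C"]]),
       y = tal[["A"]] / (tal[["A"]] + tal[["T"]]))
}

# P2 by explicit doublet classification of every codon string.
oracle_p2 <- function(counts) {
  ww <- c("AA", "AT", "TA", "TT"); ss <- c("CC", "CG", "GC", "GG")
  wwc <- wwt <- ssc <- sst <- 0
  for (cd in names(counts$counts)) {
    k <- counts$counts[[cd]]
    if (k == 0) next
    d <- substr(cd, 1, 2); b <- substr(cd, 3, 3)
    if (d %in% ww && b == "C") wwc <- wwc + k
    if (d %in% ww && b == "T") wwt <- wwt + k
    if (d %in% ss && b == "C") ssc <- ssc + k
    if (d %in% ss && b == "T") sst <- sst + k
  }
  (wwc + sst) / (wwc + wwt + ssc + sst)
}
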