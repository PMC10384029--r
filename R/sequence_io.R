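#' Read coding sequences from a FASTA file
#'
#' Reads a multi-record nucleotide FASTA of coding sequences (one CDS per
#' record). Sequences are upper-cased and RNA-style `U` is mapped to `T`;
#' no filtering happens here — see [qc_filter()].
#'
#' @param path Path to a FASTA file.
#' @return A data.frame of raw CDS records with columns `gene_id`,
#'   `sequence`, `length_nt`, in file order.
#' @export
read_cds_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  # read as BString set first: raw CDS files may contain ambiguity codes or U
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA input: ", path)
  sq <- toupper(as.character(seqs))
  sq <- gsub("U", "T", sq, fixed = TRUE)
  ids <- sub("\\s.*$", "", names(seqs))
  data.frame(gene_id = ids, sequence = unname(sq),
             length_nt = nchar(sq), stringsAsFactors = FALSE)
}

# QC rules in the order they are tested; the first failure is reported.
qc_rules <- c("ambiguous_base", "not_multiple_of_3", "too_short",
              "no_start_codon", "no_stop_codon", "internal_stop",
              "duplicate")

#' Quality-filter coding sequences
#'
#' Applies the CDS quality rules used throughout the package: only A/C/G/T
#' bases; length an exact multiple of three and strictly longer than
#' `min_len` nucleotides; an ATG start codon; a terminal codon in the code's
#' stop set; no internal stop codon; and (optionally) removal of exact
#' duplicate sequences. Failures are reported, never raised.
#'
#' @param records data.frame as returned by [read_cds_fasta()].
#' @param code A `genetic_code`; its stop set defines the stop rules.
#' @param dedupe Collapse exact full-sequence duplicates to the first
#'   occurrence? Default `TRUE`.
#' @param min_len Sequences must be strictly longer than this many
#'   nucleotides (default 300, i.e. minimum accepted length 303 given the
#'   frame constraint).
#' @return A list with `passed` (filtered records data.frame), `report`
#'   (one row per input record: `gene_id`, `status` = "pass"/"fail",
#'   `failed_rule`), and `rule_totals` (named counts per rule).
#' @export
qc_filter <- function(records, code, dedupe = TRUE, min_len = 300L) {
  stopifnot(is.data.frame(records), inherits(code, "genetic_code"))
  n <- nrow(records)
  failed_rule <- rep(NA_character_, n)
  seen <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    s <- records$sequence[i]
    len <- nchar(s)
    rule <- NA_character_
    if (grepl("[^ACGT]", s)) {
      rule <- "ambiguous_base"
    } else if (len %% 3L != 0L) {
      rule <- "not_multiple_of_3"
    } else if (len <= min_len) {
      rule <- "too_short"
    } else if (substr(s, 1L, 3L) != "ATG") {
      rule <- "no_start_codon"
    } else {
      codons <- substring(s, seq(1L, len - 2L, by = 3L), seq(3L, len, by = 3L))
      k <- length(codons)
      if (!(codons[k] %in% code$stop_codons)) {
        rule <- "no_stop_codon"
      } else if (any(codons[-k] %in% code$stop_codons)) {
        rule <- "internal_stop"
      } else if (dedupe) {
        if (!is.null(seen[[s]])) rule <- "duplicate" else seen[[s]] <- TRUE
      }
    }
    failed_rule[i] <- rule
  }
  pass <- is.na(failed_rule)
  report <- data.frame(gene_id = records$gene_id,
                       status = ifelse(pass, "pass", "fail"),
                       failed_rule = failed_rule,
                       stringsAsFactors = FALSE)
  totals <- table(factor(failed_rule, levels = qc_rules))
  list(passed = records[pass, , drop = FALSE],
       report = report,
       rule_totals = c(totals))
}

#' Count codons of a QC-passed coding sequence
#'
#' Reads the sequence in frame 0 as consecutive triplets and tallies all 64
#' codons. The terminal stop codon is included in the raw counts but never in
#' `n_codons_analyzed`, which counts only the synonymously variable codons
#' (families of degeneracy >= 2; 59 codons under the standard code).
#'
#' @param record One row of a QC-passed records data.frame (or any list with
#'   `gene_id` and `sequence`).
#' @param code A `genetic_code`.
#' @return A list of class `codon_counts`: `gene_id`, `counts` (named
#'   integer of length 64, lexicographic codon order), `n_codons_analyzed`,
#'   `length_nt`.
#' @export
count_codons <- function(record, code) {
  s <- record$sequence
  len <- nchar(s)
  if (len %% 3L != 0L) stop("sequence length not divisible by 3 for gene ",
                            record$gene_id)
  codons <- substring(s, seq(1L, len - 2L, by = 3L), seq(3L, len, by = 3L))
  all64 <- sort(names(code$codon_to_aa))
  counts <- table(factor(codons, levels = all64))
  counts <- stats::setNames(as.integer(counts), all64)
  structure(
    list(gene_id = record$gene_id,
         counts = counts,
         n_codons_analyzed = sum(counts[code$analyzed_codons]),
         length_nt = len),
    class = "codon_counts")
}

# Vectorized convenience: codon_counts for every row of a records data.frame.
count_codons_all <- function(records, code) {
  lapply(seq_len(nrow(records)),
         function(i) count_codons(records[i, ], code))
}

# Sum the 64-codon count vectors of a list of codon_counts objects.
pool_counts <- function(counts_list, code, gene_id = "pooled") {
  stopifnot(length(counts_list) >= 1L)
  total <- Reduce(`+`, lapply(counts_list, `[[`, "counts"))
  structure(
    list(gene_id = gene_id,
         counts = total,
         n_codons_analyzed = sum(total[code$analyzed_codons]),
         length_nt = 3L * sum(total)),
    class = "codon_counts")
}
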