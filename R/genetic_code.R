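#' Load a genetic code with its synonymous-family partition
#'
#' Builds the translation table used by every codon-usage statistic in the
#' package: the codon-to-amino-acid map, the stop-codon set, the partition of
#' sense codons into synonymous families with their degeneracies, and the set
#' of codons excluded from codon-usage-bias statistics (stop codons plus
#' single-codon families, which carry no synonymous choice).
#'
#' The family partition is always recomputed from the codon-to-amino-acid map,
#' so alternative tables (e.g. the ciliate nuclear code, in which TAA and TAG
#' encode glutamine and only TGA terminates) propagate consistently through
#' ENc, RSCU, CAI, PR2 and the composition statistics.
#'
#' @param table_id Integer id of an NCBI translation table. Supported: `1`
#'   (standard) and `6` (ciliate/dasycladacean/hexamita nuclear).
#' @return An object of class `genetic_code`: a list with elements
#'   `table_id`, `codon_to_aa` (named character of length 64), `stop_codons`,
#'   `families` (named list; each element has `aa`, `codons`, `m`),
#'   `degeneracy` (named integer per sense codon), `excluded_codons`, and
#'   `analyzed_codons` (lexicographically ordered codons of families with
#'   degeneracy >= 2; 59 codons under the standard code).
#' @examples
#' code <- load_code(1)
#' length(code$analyzed_codons)  # 59
#' degeneracy_class_counts(code) # 2 singletons, 9 two-fold, ...
#' @export
load_code <- function(table_id = 1) {
  supported <- c(1L, 6L)
  table_id <- as.integer(table_id)
  if (length(table_id) != 1L || is.na(table_id) || !(table_id %in% supported)) {
    stop("unsupported genetic code table id: ", deparse(substitute(table_id)),
         " (supported: ", paste(supported, collapse = ", "), ")")
  }
  map <- Biostrings::getGeneticCode(as.character(table_id))
  # Biostrings names codons over ACGT in TTT..GGG order; sort lexicographically
  map <- map[order(names(map))]
  stopifnot(length(map) == 64L)
  stops <- names(map)[map == "*"]
  sense <- names(map)[map != "*"]
  fams <- split(sense, map[sense])
  fams <- lapply(fams, sort)
  families <- lapply(names(fams), function(aa) {
    list(aa = aa, codons = fams[[aa]], m = length(fams[[aa]]))
  })
  names(families) <- names(fams)
  degeneracy <- integer(0)
  for (f in families) {
    degeneracy[f$codons] <- f$m
  }
  degeneracy <- degeneracy[sort(names(degeneracy))]
  singletons <- unlist(lapply(families, function(f) if (f$m == 1L) f$codons),
                       use.names = FALSE)
  excluded <- sort(c(singletons, stops))
  analyzed <- sort(setdiff(sense, singletons))
  structure(
    list(table_id = table_id,
         codon_to_aa = map,
         stop_codons = stops,
         families = families,
         degeneracy = degeneracy,
         excluded_codons = excluded,
         analyzed_codons = analyzed),
    class = "genetic_code")
}

#' @export
print.genetic_code <- function(x, ...) {
  cc <- degeneracy_class_counts(x)
  cat("Genetic code table ", x$table_id, ": ",
      length(x$codon_to_aa) - length(x$stop_codons), " sense codons, ",
      length(x$stop_codons), " stops (", paste(x$stop_codons, collapse = ","),
      "), ", length(x$analyzed_codons), " analyzed codons\n", sep = "")
  cat("Families per degeneracy class: ",
      paste(sprintf("%s-fold: %d", names(cc), cc), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Count synonymous families per degeneracy class
#'
#' @param code A `genetic_code` from [load_code()].
#' @return Named integer vector mapping degeneracy (as character "1","2",...)
#'   to the number of amino-acid families of that size. For the standard code
#'   this is `c("1" = 2, "2" = 9, "3" = 1, "4" = 5, "6" = 3)`.
#' @export
degeneracy_class_counts <- function(code) {
  stopifnot(inherits(code, "genetic_code"))
  m <- vapply(code$families, function(f) f$m, integer(1))
  tab <- table(m)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

# Codons of all families of a given degeneracy, in lexicographic order.
codons_of_degeneracy <- function(code, degs) {
  sort(names(code$degeneracy)[code$degeneracy %in% degs])
}
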