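#' Run the full codon-usage-bias analysis
#'
#' The central entry point of the package. Takes a CDS FASTA file (or an
#' already-read records data.frame, or a `synthetic_corpus`), quality-filters
#' the sequences, and computes every per-gene index — composition (GC,
#' GC1–GC3, GC12, GC3s, A3/T3/C3/G3), ENc with its expected value and ratio,
#' CAI, Gravy, Aroma, PR2 coordinates and P2 — plus the corpus-level
#' analyses: pooled composition and RSCU, correspondence analysis of the
#' gene-by-codon RSCU matrix, putative optimal codons, the neutrality
#' regression, the P2 summary and the standard correlation panel.
#'
#' @param x FASTA path, records data.frame (`gene_id`, `sequence`), or a
#'   `synthetic_corpus`.
#' @param table_id Genetic code table id (default 1, standard).
#' @param min_len Sequences must exceed this many nucleotides (default 300).
#' @param dedupe Collapse exact duplicate sequences (default `TRUE`).
#' @param cai_reference Reference for CAI weights: `NULL` (default) uses the
#'   filtered corpus itself; otherwise a FASTA path or records data.frame of
#'   highly expressed genes.
#' @param corr_method Correlation method for panels and optimal codons
#'   (`"spearman"` default, or `"pearson"`).
#' @param n_axes Correspondence-analysis axes to retain (default 4).
#' @param min_genes_optimal Minimum genes for optimal-codon detection
#'   (default 10; with fewer genes that component is `NULL`).
#' @param drop_unobserved_families Passed to [enc()].
#' @param label Corpus label used by [compare_genomes()] (default the file
#'   name or `"corpus"`).
#' @return An object of class `cub_analysis`; see [print.cub_analysis()],
#'   [summary.cub_analysis()], [plot.cub_analysis()],
#'   [write_cub_tables()].
#' @examples
#' corpus <- generate_corpus(synthetic_spec(n_genes = 20, seed = 42))
#' fit <- cub_analysis(corpus)
#' summary(fit)
#' @export
cub_analysis <- function(x, table_id = 1L, min_len = 300L, dedupe = TRUE,
                         cai_reference = NULL,
                         corr_method = c("spearman", "pearson"),
                         n_axes = 4L, min_genes_optimal = 10L,
                         drop_unobserved_families = FALSE,
                         label = NULL) {
  corr_method <- match.arg(corr_method)
  cl <- match.call()
  if (is.character(x) && length(x) == 1L) {
    if (is.null(label)) label <- basename(x)
    records <- read_cds_fasta(x)
  } else if (inherits(x, "synthetic_corpus")) {
    records <- x$records
  } else if (is.data.frame(x)) {
    records <- x
  } else {
    stop("cub_analysis: x must be a FASTA path, a records data.frame, ",
         "or a synthetic_corpus")
  }
  if (is.null(label)) label <- "corpus"
  code <- load_code(table_id)
  qc <- qc_filter(records, code, dedupe = dedupe, min_len = min_len)
  if (nrow(qc$passed) < 2L) {
    stop("cub_analysis: fewer than 2 genes passed QC (",
         nrow(qc$passed), " of ", nrow(records), ")")
  }
  counts_list <- count_codons_all(qc$passed, code)

  # CAI reference pool: the corpus itself, or a user-supplied gene set
  if (is.null(cai_reference)) {
    ref_counts <- pool_counts(counts_list, code, gene_id = "self_reference")
  } else {
    ref_rec <- if (is.character(cai_reference)) read_cds_fasta(cai_reference)
               else cai_reference
    ref_qc <- qc_filter(ref_rec, code, dedupe = dedupe, min_len = min_len)
    if (nrow(ref_qc$passed) < 1L) stop("cub_analysis: empty CAI reference")
    ref_counts <- pool_counts(count_codons_all(ref_qc$passed, code), code,
                              gene_id = "cai_reference")
  }
  weights <- cai_weights(ref_counts, code, on_missing = "na")

  n <- length(counts_list)
  genes <- data.frame(gene_id = qc$passed$gene_id,
                      length_nt = qc$passed$length_nt,
                      stringsAsFactors = FALSE)
  comp_fields <- c("gc", "gc1", "gc2", "gc3", "gc12", "gc3s",
                   "a3", "t3", "c3", "g3")
  for (f in comp_fields) genes[[f]] <- NA_real_
  genes$enc <- genes$enc_exp <- genes$enc_ratio <- genes$cai <- NA_real_
  genes$gravy <- genes$aroma <- NA_real_
  genes$pr2_x <- genes$pr2_y <- genes$p2 <- NA_real_
  p2_list <- vector("list", n)
  for (i in seq_len(n)) {
    ct <- counts_list[[i]]
    cp <- composition_profile(ct, code)
    for (f in comp_fields) genes[[f]][i] <- cp[[f]]
    genes$enc[i] <- enc(ct, code,
                        drop_unobserved_families = drop_unobserved_families)
    genes$enc_exp[i] <- enc_expected(cp$gc3s)
    genes$enc_ratio[i] <- enc_ratio(genes$enc_exp[i], genes$enc[i])
    genes$cai[i] <- cai(ct, weights)
    genes$gravy[i] <- gravy(ct, code)
    genes$aroma[i] <- aroma(ct, code)
    pr <- tryCatch(pr2_point(ct, code), error = function(e) NULL)
    if (!is.null(pr)) {
      genes$pr2_x[i] <- pr$x
      genes$pr2_y[i] <- pr$y
    }
    p2_list[[i]] <- p2_index(ct)
    genes$p2[i] <- p2_list[[i]]$p2
  }

  pooled <- pool_counts(counts_list, code)
  rscu_mat <- build_rscu_matrix(counts_list, code)
  ca <- tryCatch(correspondence_analysis(rscu_mat, n_axes = n_axes),
                 error = function(e) structure(list(message = conditionMessage(e)),
                                               class = "ca_degenerate"))
  for (a in seq_len(n_axes)) genes[[paste0("axis", a)]] <- NA_real_
  if (inherits(ca, "ca_result")) {
    k <- ncol(ca$row_coords)
    idx <- match(rownames(ca$row_coords), genes$gene_id)
    for (a in seq_len(min(k, n_axes))) {
      genes[[paste0("axis", a)]][idx] <- ca$row_coords[, a]
    }
  }
  opt <- if (n >= min_genes_optimal) {
    tryCatch(optimal_codons(rscu_mat, genes$enc, code, method = corr_method,
                            min_genes = min_genes_optimal),
             error = function(e) NULL)
  } else NULL
  neut <- tryCatch(neutrality_fit(genes$gc12, genes$gc3),
                   error = function(e) NULL)
  p2_sum <- tryCatch(p2_summary(p2_list), error = function(e) NULL)
  panels <- tryCatch(correlation_panels(genes, method = corr_method),
                     error = function(e) NULL)

  structure(
    list(call = cl,
         label = label,
         config = list(table_id = table_id, min_len = min_len,
                       dedupe = dedupe,
                       cai_reference = if (is.null(cai_reference)) "self"
                                       else "external",
                       corr_method = corr_method, n_axes = n_axes,
                       min_genes_optimal = min_genes_optimal,
                       drop_unobserved_families = drop_unobserved_families),
         code = code,
         qc_report = qc$report,
         qc_rule_totals = qc$rule_totals,
         genes = genes,
         counts = counts_list,
         pooled_counts = pooled,
         pooled_composition = composition_profile(pooled, code),
         rscu_pooled = rscu(pooled, code),
         rscu_matrix = rscu_mat,
         ca = ca,
         cai_weights = weights,
         optimal_codons = opt,
         neutrality = neut,
         p2 = p2_sum,
         correlations = panels),
    class = "cub_analysis")
}

# Per-index summary statistics of the per-gene table.
summary_indices <- c("gc", "gc1", "gc2", "gc3", "gc12", "gc3s",
                     "a3", "t3", "c3", "g3",
                     "enc", "enc_exp", "enc_ratio", "cai", "gravy", "aroma",
                     "pr2_x", "pr2_y", "p2", "length_nt")

#' @method summary cub_analysis
#' @export
summary.cub_analysis <- function(object, ...) {
  g <- object$genes
  rows <- lapply(summary_indices, function(f) {
    v <- g[[f]]
    v <- v[is.finite(v)]
    data.frame(index = f, n = length(v), mean = mean(v), sd = stats::sd(v),
               min = min(v), max = max(v), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "label") <- object$label
  class(out) <- c("summary.cub_analysis", "data.frame")
  out
}

#' @export
print.summary.cub_analysis <- function(x, ...) {
  cat("Per-genome summary (", attr(x, "label"), ")\n", sep = "")
  y <- x
  class(y) <- "data.frame"
  y$mean <- round(y$mean, 4); y$sd <- round(y$sd, 4)
  y$min <- round(y$min, 4); y$max <- round(y$max, 4)
  print(y, row.names = FALSE)
  invisible(x)
}

#' @export
print.cub_analysis <- function(x, ...) {
  g <- x$genes
  cat("Codon usage bias analysis: ", x$label, "\n", sep = "")
  cat("  genetic code table ", x$config$table_id, "; ",
      nrow(g), " genes passed QC (", nrow(x$qc_report), " input)\n", sep = "")
  cat(sprintf("  mean ENc %.4f (sd %.4f), mean GC3s %.2f%%, mean CAI %.4f\n",
              mean(g$enc), stats::sd(g$enc), 100 * mean(g$gc3s),
              mean(g$cai)))
  if (inherits(x$ca, "ca_result")) {
    k <- min(4L, length(x$ca$inertia_fractions))
    cat("  CA axis inertia: ",
        paste(sprintf("%.1f%%", 100 * x$ca$inertia_fractions[seq_len(k)]),
              collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$neutrality)) {
    cat(sprintf("  neutrality slope %.4f (%s)\n", x$neutrality$slope,
                x$neutrality$label))
  }
  invisible(x)
}

#' Diagnostic plots for a codon-usage analysis
#'
#' Draws the three classical diagnostics on the current device: the
#' ENc-vs-GC3s plot with the mutation-only expected curve, the PR2 plot
#' with its (0.5, 0.5) parity point, and the GC12-on-GC3 neutrality plot
#' with its fitted regression line.
#'
#' @param x A `cub_analysis` object.
#' @param which Subset of `c("enc", "pr2", "neutrality")`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @method plot cub_analysis
#' @export
plot.cub_analysis <- function(x, which = c("enc", "pr2", "neutrality"), ...) {
  g <- x$genes
  which <- match.arg(which, several.ok = TRUE)
  if ("enc" %in% which) {
    graphics::plot(100 * g$gc3s, g$enc, xlab = "GC3s (%)", ylab = "ENc",
                   xlim = c(0, 100), ylim = c(15, 65),
                   main = "ENc plot", ...)
    s <- seq(0, 1, length.out = 200)
    graphics::lines(100 * s, enc_expected(s), lty = 2)
  }
  if ("pr2" %in% which) {
    graphics::plot(g$pr2_x, g$pr2_y, xlim = c(0, 1), ylim = c(0, 1),
                   xlab = "G3/(G3+C3)", ylab = "A3/(A3+T3)",
                   main = "PR2 plot", ...)
    graphics::abline(h = 0.5, v = 0.5, lty = 3)
  }
  if ("neutrality" %in% which) {
    graphics::plot(g$gc3, g$gc12, xlab = "GC3", ylab = "GC12",
                   main = "Neutrality plot", ...)
    if (!is.null(x$neutrality)) {
      graphics::abline(x$neutrality$intercept, x$neutrality$slope)
    }
  }
  invisible(x)
}

# Format percentages to 2 decimals and indices to 4, per-table convention.
format_gene_table <- function(g) {
  out <- g
  pct <- intersect(c("gc", "gc1", "gc2", "gc3", "gc12", "gc3s",
                     "a3", "t3", "c3", "g3"), names(out))
  for (f in pct) out[[f]] <- sprintf("%.2f", 100 * out[[f]])
  num4 <- intersect(c("enc", "enc_exp", "enc_ratio", "cai", "gravy", "aroma",
                      "pr2_x", "pr2_y", "p2", "axis1", "axis2", "axis3",
                      "axis4"), names(out))
  for (f in num4) out[[f]] <- sprintf("%.4f", out[[f]])
  out
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write all analysis tables to a directory
#'
#' Emits the TSV outputs of a [cub_analysis()] run: the per-gene index
#' table (formatted: composition as percentages to 2 decimals, indices to
#' 4 decimals) plus a full-precision sidecar, the QC report, the pooled
#' RSCU table, the genome summary, coordinate files for the ENc / PR2 /
#' neutrality plots (with the expected-ENc curve sampled), CA gene and
#' codon coordinates with the inertia table, optimal codons, correlation
#' panels, the P2 summary and a config snapshot. Every figure-backing file
#' is reconstructible from the per-gene table.
#'
#' @param x A `cub_analysis` object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the directory path.
#' @export
write_cub_tables <- function(x, dir) {
  stopifnot(inherits(x, "cub_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_tsv(format_gene_table(x$genes), p("gene_indices.tsv"))
  write_tsv(x$genes, p("gene_indices_full.tsv"))
  write_tsv(x$qc_report, p("qc_report.tsv"))
  write_tsv(as.data.frame(x$rscu_pooled), p("rscu_pooled.tsv"))
  s <- summary(x)
  write_tsv(as.data.frame(s), p("genome_summary.tsv"))
  write_tsv(x$genes[, c("gene_id", "gc3s", "enc", "enc_exp", "enc_ratio")],
            p("enc_plot.tsv"))
  curve <- data.frame(gc3s = seq(0, 1, by = 0.001))
  curve$enc_exp <- enc_expected(curve$gc3s)
  write_tsv(curve, p("enc_expected_curve.tsv"))
  write_tsv(x$genes[, c("gene_id", "pr2_x", "pr2_y")], p("pr2_plot.tsv"))
  write_tsv(x$genes[, c("gene_id", "gc3", "gc12")], p("neutrality_plot.tsv"))
  if (!is.null(x$neutrality)) {
    write_tsv(data.frame(slope = x$neutrality$slope,
                         intercept = x$neutrality$intercept,
                         r = x$neutrality$r, p_value = x$neutrality$p_value,
                         n_genes = x$neutrality$n_genes),
              p("neutrality_fit.tsv"))
  }
  if (!is.null(x$p2)) write_tsv(x$p2, p("p2_summary.tsv"))
  if (inherits(x$ca, "ca_result")) {
    rc <- data.frame(gene_id = rownames(x$ca$row_coords), x$ca$row_coords)
    cc <- data.frame(codon = rownames(x$ca$col_coords), x$ca$col_coords)
    write_tsv(rc, p("ca_gene_coords.tsv"))
    write_tsv(cc, p("ca_codon_coords.tsv"))
    fr <- x$ca$inertia_fractions
    write_tsv(data.frame(axis = seq_along(fr), inertia = x$ca$inertia,
                         fraction = fr, cumulative = cumsum(fr)),
              p("ca_inertia.tsv"))
  }
  if (!is.null(x$optimal_codons)) {
    write_tsv(as.data.frame(x$optimal_codons), p("optimal_codons.tsv"))
  }
  if (!is.null(x$correlations)) {
    write_tsv(as.data.frame(x$correlations), p("correlations.tsv"))
  }
  cfg <- vapply(x$config, function(v) paste(as.character(v), collapse = ","),
                character(1))
  writeLines(paste0(names(cfg), "\t", cfg), p("config.tsv"))
  invisible(dir)
}

#' Cross-genome comparison table
#'
#' Binds the per-genome summaries of several analyses into one table with a
#' row per genome and a column per (index, statistic) pair.
#'
#' @param analyses List of `cub_analysis` objects with distinct labels.
#' @return A data.frame with one row per genome.
#' @export
compare_genomes <- function(analyses) {
  stopifnot(length(analyses) >= 1L)
  labels <- vapply(analyses, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("compare_genomes: duplicate genome labels")
  rows <- lapply(analyses, function(a) {
    s <- summary(a)
    wide <- stats::setNames(s$mean, paste0(s$index, "_mean"))
    sds <- stats::setNames(s$sd, paste0(s$index, "_sd"))
    data.frame(genome = a$label, n_genes = nrow(a$genes),
               as.list(wide), as.list(sds),
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
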