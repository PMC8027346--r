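#' @name cohort_summary
#' @title Cohort-level diagnostic-yield summarization
#'
#' @description
#' Aggregates per-proband classifications into the headline tables of a
#' diagnostic cohort: overall yield, dominant/recessive split, per-gene
#' counts and percentages by mode, the variant-class tally over distinct
#' variants, and the OPA1 exon/class/domain spectrum.
NULL

VARIANT_CLASSES <- c("missense", "nonsense", "frameshift", "splice")

pct2 <- function(n, d) round(100 * n / d, 2)

#' Summarize a cohort of case classifications
#'
#' Solved cases are those with a dominant or recessive assignment
#' (candidate-gene VUS cases carry a mode and are counted in their mode's
#' bucket, as diagnostic panels report candidate-gene families alongside
#' known-gene ones). Per-gene percentages are relative to the mode total;
#' the yield is relative to the cohort size. Distinct variants are
#' deduplicated on the normalized key.
#'
#' @param classifications table from [classify_cohort()] (one row per
#'   proband analysed; probands can outnumber rows only via `n_total`).
#' @param variant_table distinct-variant table with columns `chrom`,
#'   `pos`, `ref`, `alt`, `consequence` (e.g. annotated causal variants);
#'   may be NULL.
#' @param n_total cohort size (>= number of solved cases).
#' @return list of class `ion_cohort_summary`: `n_total`, `n_solved`,
#'   `n_dominant`, `n_recessive`, `yield_pct`, `dominant_pct`,
#'   `recessive_pct`, `gene_counts` (mode, gene, n, pct),
#'   `n_distinct_variants`, `class_tally` (variant_class, n, pct).
#' @export
summarize_cohort <- function(classifications, variant_table = NULL,
                             n_total = nrow(classifications)) {
  cl <- data.table::as.data.table(classifications)
  if ("sample_id" %in% names(cl) && anyDuplicated(cl$sample_id))
    stop_trailing("duplicate proband id in classifications")
  solved <- cl[status %in% c("solved_dominant", "solved_recessive",
                             "vus_candidate") & !is.na(mode)]
  if (n_total < nrow(solved))
    stop_trailing("cohort size smaller than solved count")
  n_dom <- solved[mode == "dominant", .N]
  n_rec <- solved[mode == "recessive", .N]
  n_solved <- n_dom + n_rec
  gene_counts <- solved[, .(n = .N), by = .(mode, gene)]
  gene_counts[, pct := pct2(n, ifelse(mode == "dominant", n_dom, n_rec))]
  data.table::setorder(gene_counts, mode, -n, gene)
  class_tally <- data.table::data.table(
    variant_class = VARIANT_CLASSES, n = 0L, pct = NA_real_)
  n_distinct <- 0L
  if (!is.null(variant_table) && nrow(variant_table)) {
    vt <- unique(data.table::as.data.table(variant_table),
                 by = c("chrom", "pos", "ref", "alt"))
    n_distinct <- nrow(vt)
    tally <- vt[, .(n = .N), by = .(variant_class = consequence)]
    class_tally <- merge(class_tally[, .(variant_class)], tally,
                         by = "variant_class", all.x = TRUE)
    class_tally[is.na(n), n := 0L]
    class_tally[, pct := pct2(n, n_distinct)]
    class_tally <- class_tally[match(VARIANT_CLASSES, variant_class)]
  }
  structure(list(
    n_total = n_total, n_solved = n_solved,
    n_dominant = n_dom, n_recessive = n_rec,
    yield_pct = pct2(n_solved, n_total),
    dominant_pct = pct2(n_dom, n_total),
    recessive_pct = pct2(n_rec, n_total),
    gene_counts = gene_counts[],
    n_distinct_variants = n_distinct,
    class_tally = class_tally[]),
    class = "ion_cohort_summary")
}

#' @export
print.ion_cohort_summary <- function(x, ...) {
  cat(sprintf(
    "ION cohort summary: %d probands, %d solved (%.2f%%)\n",
    x$n_total, x$n_solved, x$yield_pct))
  cat(sprintf("  dominant:  %d (%.2f%% of cohort)\n",
              x$n_dominant, x$dominant_pct))
  cat(sprintf("  recessive: %d (%.2f%% of cohort)\n",
              x$n_recessive, x$recessive_pct))
  cat(sprintf("  distinct variants: %d\n", x$n_distinct_variants))
  print(x$gene_counts)
  invisible(x)
}

#' Exon / class / domain spectrum of distinct OPA1 variants
#'
#' @param opa1_variants annotated distinct OPA1 variants (`chrom`, `pos`,
#'   `ref`, `alt`, `consequence`, `exon_number`, `protein_pos`).
#' @param domain_table OPA1 domain table ([ion_opa1_domains()]); protein
#'   positions outside every interval (or without a protein position,
#'   e.g. splice variants) are bucketed as `"other"`.
#' @return list with `exon_counts` (exon_number, n), `class_pct`
#'   (variant_class, n, pct over distinct OPA1 variants) and `domain_pct`
#'   (domain, n, pct).
#' @export
opa1_spectrum <- function(opa1_variants,
                          domain_table = ion_opa1_domains()) {
  v <- unique(data.table::as.data.table(opa1_variants),
              by = c("chrom", "pos", "ref", "alt"))
  if (nrow(v) == 0)
    return(list(exon_counts = data.table::data.table(
      exon_number = integer(), n = integer()),
      class_pct = data.table::data.table(
        variant_class = character(), n = integer(), pct = numeric()),
      domain_pct = data.table::data.table(
        domain = character(), n = integer(), pct = numeric())))
  exon_counts <- v[!is.na(exon_number), .(n = .N), by = exon_number]
  data.table::setorder(exon_counts, exon_number)
  class_pct <- v[, .(n = .N), by = .(variant_class = consequence)]
  class_pct[, pct := pct2(n, nrow(v))]
  data.table::setorder(class_pct, -n)
  dom <- vapply(v$protein_pos, function(p) {
    if (is.na(p)) return("other")
    w <- which(domain_table$aa_start <= p & p <= domain_table$aa_end)
    if (length(w)) domain_table$domain[w[1]] else "other"
  }, character(1))
  domain_pct <- data.table::data.table(domain = dom)[, .(n = .N),
                                                     by = domain]
  domain_pct[, pct := pct2(n, nrow(v))]
  data.table::setorder(domain_pct, -n)
  list(exon_counts = exon_counts[], class_pct = class_pct[],
       domain_pct = domain_pct[])
}

#' Bar chart of per-gene solved counts by mode
#'
#' Convenience plot mirroring the usual cohort-composition figure.
#' Requires ggplot2.
#'
#' @param summary an `ion_cohort_summary`.
#' @return a ggplot object.
#' @export
plot_cohort_summary <- function(summary) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_trailing("ggplot2 is required for plotting")
  gc <- summary$gene_counts
  ggplot2::ggplot(gc, ggplot2::aes(
    x = stats::reorder(gene, -n), y = n, fill = mode)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~mode, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "families",
                  title = sprintf("Diagnostic yield: %d/%d (%.1f%%)",
                                  summary$n_solved, summary$n_total,
                                  summary$yield_pct)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}
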