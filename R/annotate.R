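#' @name annotate
#' @title Variant annotation: gene, consequence, frequency, clinical status
#'
#' @description
#' A self-contained annotation stage: gene assignment by panel-region
#' overlap, a minimal transcript-model consequence engine (codon
#' translation for coding SNVs, frame arithmetic for coding indels,
#' canonical +/-2 bp splice-site window), population MAF lookup and
#' reported-clinical-significance lookup from packaged tables. Heavy
#' external annotators and live databases are out of scope by design; the
#' packaged tables play their role.
NULL

CONSEQUENCES <- c("missense", "nonsense", "synonymous", "frameshift",
                  "inframe_indel", "splice", "intronic", "intergenic")

#' Loss-of-function predicate
#'
#' LoF means stop-gain (nonsense), frameshift, or splice-disrupting.
#'
#' @param consequence character vector of consequence classes.
#' @return logical vector.
#' @export
is_lof <- function(consequence) {
  consequence %in% c("nonsense", "frameshift", "splice")
}

# transcription-order exon number of a genomic position's exon index
tx_exon_number <- function(tx, genomic_idx) {
  if (tx$strand == "+") genomic_idx
  else length(tx$exon_start) - genomic_idx + 1L
}

#' Classify the functional consequence of a normalized variant
#'
#' Coding SNVs are translated codon-wise with the standard genetic code
#' (stop gained = nonsense, amino-acid change = missense, silent =
#' synonymous; a lost stop codon is reported as missense). Coding indels
#' are frameshift when the net length change is not a multiple of 3, else
#' in-frame. Any variant touching the canonical splice window (the first
#' or last `splice_window` intronic bases of an intron) is `splice`,
#' overriding intronic. Everything else is intronic within the transcript
#' span (including untranslated exonic positions) or intergenic outside
#' it. Reverse-strand transcripts are handled by internal
#' reverse-complementation; inputs stay in genome coordinates.
#'
#' @param pos,ref,alt normalized variant (single alt) on `tx$chrom`.
#' @param tx transcript object ([transcript_list()]).
#' @param genome named contig vector.
#' @param splice_window intronic bases on each side of an exon-intron
#'   boundary counted as canonical splice region (default 2).
#' @return list with `consequence`, `protein_change` (simplified
#'   `p.<ref><codon><alt>` or NA), `protein_pos` (codon index or NA) and
#'   `exon_number` (transcription-order exon of / nearest to the variant,
#'   NA when intergenic).
#' @export
classify_consequence <- function(pos, ref, alt, tx, genome,
                                 splice_window = 2L) {
  contig <- genome[[tx$chrom]]
  if (is.null(contig))
    stop_trailing("contig %s not in genome", tx$chrom)
  if (pos + nchar(ref) - 1L > nchar(contig))
    stop_trailing("variant at %d outside contig %s", pos, tx$chrom)
  n_ex <- length(tx$exon_start)
  is_snv <- nchar(ref) == 1L && nchar(alt) == 1L
  net <- nchar(alt) - nchar(ref)

  # bases whose identity or context the edit touches
  affected <- if (is_snv) pos
    else if (nchar(ref) > 1L) (pos + 1L):(pos + nchar(ref) - 1L)
    else c(pos, pos + 1L)                      # pure insertion point

  # canonical splice window: first/last `splice_window` bases of introns
  in_splice <- FALSE
  if (n_ex > 1L && splice_window > 0L) {
    for (i in seq_len(n_ex - 1L)) {
      ilo <- tx$exon_end[i] + 1L; ihi <- tx$exon_start[i + 1L] - 1L
      if (ilo > ihi) next
      win <- c(ilo:min(ilo + splice_window - 1L, ihi),
               max(ihi - splice_window + 1L, ilo):ihi)
      if (any(affected %in% win)) { in_splice <- TRUE; break }
    }
  }

  in_exon_idx <- function(p) {
    w <- which(tx$exon_start <= p & p <= tx$exon_end)
    if (length(w)) w[1] else NA_integer_
  }
  nearest_exon_number <- function(p) {
    d <- pmax(tx$exon_start - p, 0L) + pmax(p - tx$exon_end, 0L)
    tx_exon_number(tx, which.min(d))
  }
  exon_number <- {
    hit <- Filter(Negate(is.na), lapply(affected, in_exon_idx))
    if (length(hit)) tx_exon_number(tx, hit[[1]])
    else nearest_exon_number(affected[1])
  }

  span_lo <- min(tx$exon_start); span_hi <- max(tx$exon_end)
  if (all(affected < span_lo) || all(affected > span_hi))
    return(list(consequence = "intergenic", protein_change = NA_character_,
                protein_pos = NA_integer_, exon_number = NA_integer_))
  if (in_splice)
    return(list(consequence = "splice", protein_change = NA_character_,
                protein_pos = NA_integer_, exon_number = exon_number))

  cdspos <- cds_positions(tx)
  if (is_snv) {
    i <- match(pos, cdspos)
    if (is.na(i))
      return(list(consequence = "intronic",
                  protein_change = NA_character_,
                  protein_pos = NA_integer_, exon_number = exon_number))
    codon_idx <- (i - 1L) %/% 3L + 1L
    off <- (codon_idx - 1L) * 3L + 1:3
    cod_pos <- cdspos[off]
    bases <- substring(contig, cod_pos, cod_pos)
    j <- i - (codon_idx - 1L) * 3L
    alt_bases <- bases
    alt_bases[j] <- alt
    if (tx$strand == "-") {
      bases <- complement(bases)
      alt_bases <- complement(alt_bases)
    }
    ref_cod <- paste(bases, collapse = "")
    alt_cod <- paste(alt_bases, collapse = "")
    aa_ref <- unname(Biostrings::GENETIC_CODE[ref_cod])
    aa_alt <- unname(Biostrings::GENETIC_CODE[alt_cod])
    csq <- if (aa_ref == aa_alt) "synonymous"
      else if (aa_alt == "*") "nonsense"
      else "missense"
    pc <- paste0("p.", sub("\\*", "X", aa_ref), codon_idx,
                 sub("\\*", "X", aa_alt))
    return(list(consequence = csq, protein_change = pc,
                protein_pos = codon_idx, exon_number = exon_number))
  }

  # indel / block substitution
  coding <- if (nchar(ref) > 1L) any(affected %in% cdspos)
    else all(c(pos, pos + 1L) %in% cdspos)
  if (coding) {
    csq <- if (net %% 3L != 0L) "frameshift" else "inframe_indel"
    first_cds <- affected[affected %in% cdspos]
    ppos <- if (length(first_cds))
      (match(if (tx$strand == "+") min(first_cds) else max(first_cds),
             cdspos) - 1L) %/% 3L + 1L
    else NA_integer_
    return(list(consequence = csq, protein_change = NA_character_,
                protein_pos = ppos, exon_number = exon_number))
  }
  list(consequence = "intronic", protein_change = NA_character_,
       protein_pos = NA_integer_, exon_number = exon_number)
}

#' Annotate unique variant keys against panel, tables and transcripts
#'
#' @param keys data.table with `chrom`, `pos`, `ref`, `alt` (normalized,
#'   one row per distinct variant).
#' @param panel panel gene table.
#' @param freq frequency table (or NULL for none).
#' @param clin clinical-significance table (or NULL for none).
#' @param tx named list of transcript objects.
#' @param genome named contig vector.
#' @param splice_window see [classify_consequence()].
#' @return `data.table`: keys plus `gene` (NA outside all panel regions),
#'   `ambiguous_gene`, `consequence`, `protein_change`, `protein_pos`,
#'   `exon_number`, `maf` (NA when absent from the table), `clinical`
#'   ("unreported" when absent).
#' @export
annotate_keys <- function(keys, panel, freq = NULL, clin = NULL,
                          tx = NULL, genome = NULL, splice_window = 2L) {
  dt <- unique(data.table::as.data.table(
    keys)[, .(chrom, pos, ref, alt)])
  regs <- panel_regions(panel)
  gr_reg <- GenomicRanges::GRanges(
    regs$chrom, IRanges::IRanges(regs$start, regs$end))
  gr_var <- GenomicRanges::GRanges(
    dt$chrom, IRanges::IRanges(dt$pos, dt$pos + nchar(dt$ref) - 1L))
  ov <- GenomicRanges::findOverlaps(gr_var, gr_reg)
  gene <- rep(NA_character_, nrow(dt))
  ambiguous <- rep(FALSE, nrow(dt))
  if (length(ov)) {
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    first <- !duplicated(qh)
    gene[qh[first]] <- regs$symbol[sh[first]]
    ambiguous[qh[duplicated(qh)]] <- TRUE
  }
  dt[, gene := gene]
  dt[, ambiguous_gene := ambiguous]
  ann <- lapply(seq_len(nrow(dt)), function(i) {
    g <- dt$gene[i]
    if (is.na(g) || is.null(tx[[g]]))
      return(list(consequence = "intergenic",
                  protein_change = NA_character_,
                  protein_pos = NA_integer_, exon_number = NA_integer_))
    classify_consequence(dt$pos[i], dt$ref[i], dt$alt[i], tx[[g]],
                         genome, splice_window)
  })
  dt[, consequence := vapply(ann, `[[`, "", "consequence")]
  dt[, protein_change := vapply(ann, function(a)
    a$protein_change %||% NA_character_, NA_character_)]
  dt[, protein_pos := vapply(ann, function(a)
    as.integer(a$protein_pos %||% NA), NA_integer_)]
  dt[, exon_number := vapply(ann, function(a)
    as.integer(a$exon_number %||% NA), NA_integer_)]
  dt[, maf := NA_real_]
  if (!is.null(freq) && nrow(freq))
    dt[freq, on = c("chrom", "pos", "ref", "alt"), maf := i.maf]
  dt[, clinical := "unreported"]
  if (!is.null(clin) && nrow(clin))
    dt[clin, on = c("chrom", "pos", "ref", "alt"),
       clinical := i.significance]
  dt[]
}

#' Annotate a consensus call table
#'
#' Annotation is a pure function of the variant key; distinct keys are
#' annotated once and merged back onto the (per-sample) call rows.
#'
#' @param calls consensus call table (e.g. [build_consensus_cohort()]
#'   output) with `chrom`, `pos`, `ref`, `alt` columns.
#' @inheritParams annotate_keys
#' @return the input with annotation columns appended.
#' @export
annotate_variants <- function(calls, panel, freq = NULL, clin = NULL,
                              tx = NULL, genome = NULL,
                              splice_window = 2L) {
  dt <- data.table::as.data.table(calls)
  ann <- annotate_keys(dt, panel, freq, clin, tx, genome,
                       splice_window)
  out <- merge(dt, ann, by = c("chrom", "pos", "ref", "alt"),
               all.x = TRUE, sort = FALSE)
  data.table::setcolorder(out, intersect(
    c("sample_id", "chrom", "pos", "ref", "alt"), names(out)))
  out[]
}
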