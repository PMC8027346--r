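#' @name toy_genome
#' @title Synthetic toy genome for the 22-gene ION panel
#'
#' @description
#' The pipeline is exercised against a fully synthetic miniature genome:
#' one short contig per panel gene (2-5 exons, a compact CDS with proper
#' start/stop codons and canonical GT..AG splice sites, UTRs, introns and
#' flanks). Real genomic loci are deliberately not used — the toy genome
#' keeps the whole test surface self-contained, fast and download-free
#' while preserving everything the consequence engine and normalizer need:
#' reading frames, exon-intron junctions, both strands, repetitive context.
#'
#' Construction is deterministic (internal fixed seed), so every session
#' sees byte-identical contigs, transcript models and panel regions.
NULL

#' The six-caller set, in reconciliation priority order
#'
#' Torrent Suite VariantCaller, GATK UnifiedGenotyper, VarScan2, SNVer,
#' LoFreq and Platypus. The listing order doubles as the fixed priority
#' used to break genotype-reconciliation ties.
#'
#' @return character vector of caller identifiers.
#' @export
ion_callers <- function() {
  c("torrent_vc", "gatk_ug", "varscan2", "snver", "lofreq", "platypus")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

all_codons <- function() {
  g <- expand.grid(a = DNA_BASES, b = DNA_BASES, c = DNA_BASES,
                   stringsAsFactors = FALSE)
  paste0(g$a, g$b, g$c)
}

# Panel composition: 15 named known genes plus 7 candidate placeholders
# (the study's novel candidate genes are unnamed). Both-mode genes are
# OPA1, WFS1, ACO2 and SPG7; the remainder are single-mode.
gene_metadata <- function() {
  data.table::data.table(
    symbol = c("OPA1", "WFS1", "ACO2", "SPG7",
               "OPA3", "MFN2", "AFG3L2", "DNM1L", "SSBP1", "MIEF1",
               "TMEM126A", "RTN4IP1", "SLC25A46", "NDUFS2", "MCAT",
               paste0("CAND", 1:7)),
    modes = c(rep("dominant,recessive", 4),
              rep("dominant", 6),
              rep("recessive", 5),
              rep("dominant", 7)),
    status = c(rep("known", 15), rep("candidate", 7)),
    n_exons = c(5L, 4L, 4L, 3L, rep(3L, 6), rep(3L, 5), rep(2L, 7)),
    n_codons = c(150L, 100L, 100L, 80L, rep(60L, 6), rep(60L, 5),
                 rep(50L, 7)),
    strand = rep(c("+", "-"), 11)
  )
}

# Build one gene contig in transcription-oriented space, then flip to
# genomic orientation for minus-strand genes.
build_gene_contig <- function(n_exons, n_codons, strand,
                              utr5 = 30L, utr3 = 30L, flank = 60L,
                              intron_len = 80L) {
  nonstop <- setdiff(all_codons(), STOP_CODONS)
  codons <- c("ATG",
              sample(nonstop, n_codons - 2L, replace = TRUE),
              "TAA")
  cds <- paste(codons, collapse = "")
  cds_len <- nchar(cds)
  per <- rep(cds_len %/% n_exons, n_exons)
  per[1] <- per[1] + cds_len - sum(per)
  if (n_exons > 1) {                      # misalign codons vs junctions
    per[1] <- per[1] - 1L
    per[n_exons] <- per[n_exons] + 1L
  }
  stopifnot(all(per >= 8L))
  pieces <- substring(cds, cumsum(c(0L, per[-n_exons])) + 1L, cumsum(per))
  exon_seq <- pieces
  rnd <- function(n) paste(sample(DNA_BASES, n, replace = TRUE),
                           collapse = "")
  exon_seq[1] <- paste0(rnd(utr5), exon_seq[1])
  exon_seq[n_exons] <- paste0(exon_seq[n_exons], rnd(utr3))
  introns <- replicate(max(n_exons - 1L, 0L), {
    mid <- rnd(intron_len - 4L)
    paste0("GT", mid, "AG")
  })
  seq_tx <- rnd(flank)
  ex_start <- integer(n_exons); ex_end <- integer(n_exons)
  for (i in seq_len(n_exons)) {
    ex_start[i] <- nchar(seq_tx) + 1L
    seq_tx <- paste0(seq_tx, exon_seq[i])
    ex_end[i] <- nchar(seq_tx)
    if (i < n_exons) seq_tx <- paste0(seq_tx, introns[i])
  }
  seq_tx <- paste0(seq_tx, rnd(flank))
  cds_start_tx <- ex_start[1] + utr5
  cds_end_tx <- ex_end[n_exons] - utr3
  L <- nchar(seq_tx)
  if (strand == "+") {
    list(seq = seq_tx, exon_start = ex_start, exon_end = ex_end,
         cds_start = cds_start_tx, cds_end = cds_end_tx)
  } else {
    flip <- function(x) L - x + 1L
    list(seq = revcomp(seq_tx),
         exon_start = rev(flip(ex_end)), exon_end = rev(flip(ex_start)),
         cds_start = flip(cds_end_tx), cds_end = flip(cds_start_tx))
  }
}

#' Build the deterministic toy panel genome
#'
#' @return a list with elements
#'   * `genome`: named character vector, one contig per gene;
#'   * `transcripts`: transcript-model table (serializable with
#'     [write_transcripts()]);
#'   * `tx`: list of transcript objects (one per gene) used by the
#'     consequence engine;
#'   * `panel`: panel gene table (exon span +/- 50 bp as the design
#'     region, serializable with [write_panel()]).
#' @export
ion_toy_genome <- function() {
  if (!is.null(.toy_cache$genome_obj)) return(.toy_cache$genome_obj)
  meta <- gene_metadata()
  with_seed(727001L, {
    contigs <- vector("list", nrow(meta))
    for (i in seq_len(nrow(meta))) {
      contigs[[i]] <- build_gene_contig(meta$n_exons[i], meta$n_codons[i],
                                        meta$strand[i])
    }
    genome <- setNames(vapply(contigs, `[[`, "", "seq"), meta$symbol)
    tx <- lapply(seq_len(nrow(meta)), function(i) {
      c <- contigs[[i]]
      list(gene = meta$symbol[i], chrom = meta$symbol[i],
           strand = meta$strand[i],
           exon_start = c$exon_start, exon_end = c$exon_end,
           cds_start = c$cds_start, cds_end = c$cds_end)
    })
    names(tx) <- meta$symbol
    transcripts <- data.table::data.table(
      gene = meta$symbol, chrom = meta$symbol, strand = meta$strand,
      exon_starts = vapply(tx, function(t)
        paste(t$exon_start, collapse = ","), ""),
      exon_ends = vapply(tx, function(t)
        paste(t$exon_end, collapse = ","), ""),
      cds_start = vapply(tx, function(t) t$cds_start, 1L),
      cds_end = vapply(tx, function(t) t$cds_end, 1L))
    panel <- data.table::data.table(
      symbol = meta$symbol, modes = meta$modes, status = meta$status,
      regions = vapply(seq_len(nrow(meta)), function(i) {
        t <- tx[[i]]
        lo <- max(1L, min(t$exon_start) - 50L)
        hi <- min(nchar(genome[[i]]), max(t$exon_end) + 50L)
        sprintf("%s:%d-%d", meta$symbol[i], lo, hi)
      }, ""))
    .toy_cache$genome_obj <-
      list(genome = genome, transcripts = transcripts, tx = tx,
           panel = panel)
    .toy_cache$genome_obj
  })
}

.toy_cache <- new.env(parent = emptyenv())

#' Convert a transcript table row set into transcript objects
#'
#' @param transcripts table as returned by [read_transcripts()].
#' @return named list of transcript objects.
#' @export
transcript_list <- function(transcripts) {
  tx <- lapply(seq_len(nrow(transcripts)), function(i) {
    list(gene = transcripts$gene[i], chrom = transcripts$chrom[i],
         strand = transcripts$strand[i],
         exon_start = as.integer(strsplit(
           transcripts$exon_starts[i], ",")[[1]]),
         exon_end = as.integer(strsplit(
           transcripts$exon_ends[i], ",")[[1]]),
         cds_start = as.integer(transcripts$cds_start[i]),
         cds_end = as.integer(transcripts$cds_end[i]))
  })
  names(tx) <- transcripts$gene
  tx
}

#' Genomic positions of CDS bases in transcription order
#'
#' @param tx transcript object.
#' @return integer vector (descending for minus-strand transcripts).
#' @keywords internal
cds_positions <- function(tx) {
  ov <- lapply(seq_along(tx$exon_start), function(i) {
    lo <- max(tx$exon_start[i], tx$cds_start)
    hi <- min(tx$exon_end[i], tx$cds_end)
    if (lo > hi) integer() else lo:hi
  })
  pos <- unlist(ov)
  if (tx$strand == "-") pos <- rev(pos)
  pos
}

#' Spliced CDS sequence of a transcript (transcription orientation)
#'
#' @param tx transcript object.
#' @param genome named contig vector.
#' @return character scalar.
#' @keywords internal
spliced_cds <- function(tx, genome) {
  pos <- cds_positions(tx)
  contig <- genome[[tx$chrom]]
  bases <- substring(contig, pos, pos)
  if (tx$strand == "-") bases <- complement(bases)
  paste(bases, collapse = "")
}

#' Approximate OPA1 protein-domain table, scaled to a protein length
#'
#' Human OPA1 carries an N-terminal targeting/coiled-coil region, the
#' central GTPase domain, a middle (central dynamin) domain and the
#' C-terminal GTPase effector domain (GED). Residue boundaries here are an
#' approximate, explicitly configurable stand-in scaled proportionally from
#' the canonical ~960-aa protein onto the toy protein length.
#'
#' @param n_aa protein length to scale onto (default: toy OPA1, 149 aa).
#' @return `data.table` with `domain`, `aa_start`, `aa_end`.
#' @export
ion_opa1_domains <- function(n_aa = 149L) {
  frac <- data.table::data.table(
    domain = c("N_terminal", "coiled_coil", "GTPase", "dynamin_central",
               "GED"),
    lo = c(0.00, 0.10, 0.29, 0.58, 0.87),
    hi = c(0.10, 0.29, 0.58, 0.77, 1.00))
  out <- frac[, .(domain,
                  aa_start = pmax(1L, as.integer(floor(lo * n_aa)) + 1L),
                  aa_end = pmin(n_aa, as.integer(floor(hi * n_aa))))]
  out
}

#' Default panel gene table for the toy genome
#'
#' @return panel `data.table` (symbol, modes, status, regions).
#' @export
ion_default_panel <- function() ion_toy_genome()$panel
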