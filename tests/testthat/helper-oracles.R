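# Independent brute-force oracles and small fixtures shared across tests.
# Each oracle re-derives its answer from first principles so it stays
# independent of the package code paths it is used to check.

library(data.table)

apply_edit <- function(seq, pos, ref, alt) {
  stopifnot(substr(seq, pos, pos + nchar(ref) - 1L) == ref)
  paste0(substr(seq, 1L, pos - 1L), alt,
         substr(seq, pos + nchar(ref), nchar(seq)))
}

# Enumerate every haplotype-equivalent (pos, ref, alt) triple within the
# window, keep the parsimonious ones (no shared trailing base; no shared
# leading base unless an allele has length 1), and choose minimal pos,
# then minimal allele length.
oracle_normalize <- function(seq, pos, ref, alt, max_len = 40L) {
  H <- apply_edit(seq, pos, ref, alt)
  net <- nchar(alt) - nchar(ref)
  best <- NULL
  for (p in seq_len(nchar(seq))) {
    for (rl in 1:max_len) {
      al <- rl + net
      if (al < 1L) next
      if (p + rl - 1L > nchar(seq) || p + al - 1L > nchar(H)) next
      rc <- substr(seq, p, p + rl - 1L)
      ac <- substr(H, p, p + al - 1L)
      if (rc == ac) next
      if (apply_edit(seq, p, rc, ac) != H) next
      # parsimony
      if (substr(rc, rl, rl) == substr(ac, al, al)) next
      if (rl > 1L && al > 1L &&
          substr(rc, 1, 1) == substr(ac, 1, 1)) next
      cand <- list(pos = p, ref = rc, alt = ac)
      if (is.null(best) || p < best$pos ||
          (p == best$pos && rl < nchar(best$ref)))
        best <- cand
    }
  }
  best
}

# random indel in a repetitive context
random_repeat_case <- function() {
  unit <- paste(sample(c("A", "C", "G", "T"),
                       sample(1:3, 1), replace = TRUE), collapse = "")
  nrep <- sample(3:8, 1)
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                  replace = TRUE), collapse = "")
  left <- pad(sample(5:15, 1))
  seq <- paste0(left, strrep(unit, nrep), pad(sample(5:15, 1)))
  seq <- substr(seq, 1, 60)
  # place an indel of 1..4 bases somewhere inside the repeat run
  run_lo <- nchar(left) + 1L
  run_hi <- nchar(left) + nchar(unit) * nrep
  p <- sample(run_lo:max(run_lo, run_hi - 5L), 1)
  len <- sample(1:4, 1)
  if (runif(1) < 0.5 && p + len <= nchar(seq)) {
    list(seq = seq, pos = p,
         ref = substr(seq, p, p + len), alt = substr(seq, p, p))
  } else {
    ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = "")
    list(seq = seq, pos = p, ref = substr(seq, p, p),
         alt = paste0(substr(seq, p, p), ins))
  }
}

# brute-force consensus: per-key distinct-caller counting
oracle_consensus_keys <- function(calls, m) {
  calls <- unique(calls[, c("chrom", "pos", "ref", "alt", "caller")])
  agg <- aggregate(caller ~ chrom + pos + ref + alt, data = calls,
                   FUN = function(x) length(unique(x)))
  agg <- agg[agg$caller >= m, ]
  sort(paste(agg$chrom, agg$pos, agg$ref, agg$alt, sep = ":"))
}

# ---- consequence oracle: rebuild the spliced CDS and translate --------

GENETIC_CODE <- Biostrings::GENETIC_CODE

oracle_translate <- function(nt) {
  codons <- substring(nt, seq(1, nchar(nt), 3), seq(3, nchar(nt), 3))
  codons <- codons[nchar(codons) == 3]
  paste(unname(GENETIC_CODE[codons]), collapse = "")
}

oracle_revcomp <- function(s)
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")

# independent CDS extraction from the transcript fields
oracle_cds <- function(tx, genome) {
  contig <- genome[[tx$chrom]]
  parts <- character()
  for (i in seq_along(tx$exon_start)) {
    lo <- max(tx$exon_start[i], tx$cds_start)
    hi <- min(tx$exon_end[i], tx$cds_end)
    if (lo <= hi) parts <- c(parts, substr(contig, lo, hi))
  }
  cds <- paste(parts, collapse = "")
  if (tx$strand == "-") oracle_revcomp(cds) else cds
}

# genomic position -> 1-based CDS coordinate (NA if not coding)
oracle_cds_coord <- function(tx, p) {
  coords <- integer()
  for (i in seq_along(tx$exon_start)) {
    lo <- max(tx$exon_start[i], tx$cds_start)
    hi <- min(tx$exon_end[i], tx$cds_end)
    if (lo <= hi) coords <- c(coords, lo:hi)
  }
  if (tx$strand == "-") coords <- rev(coords)
  match(p, coords)
}

# classify a coding SNV by full-protein comparison
oracle_snv_class <- function(tx, genome, p, alt) {
  i <- oracle_cds_coord(tx, p)
  if (is.na(i)) return(NA_character_)
  cds <- oracle_cds(tx, genome)
  b <- if (tx$strand == "-") chartr("ACGT", "TGCA", alt) else alt
  cds_alt <- paste0(substr(cds, 1, i - 1), b,
                    substr(cds, i + 1, nchar(cds)))
  p_ref <- oracle_translate(cds)
  p_alt <- oracle_translate(cds_alt)
  if (p_ref == p_alt) return("synonymous")
  d <- which(strsplit(p_ref, "")[[1]] != strsplit(p_alt, "")[[1]])[1]
  if (substr(p_alt, d, d) == "*") "nonsense" else "missense"
}

# ---- hand-built mini transcripts (plus and minus strand) --------------

# CDS: ATG AAA CGA TGG GAT CTC TAA split 10|11 over two exons, with the
# 4th codon spanning the junction. Coordinates are written out by hand.
mini_gene_plus <- function() {
  cds <- "ATGAAACGATGGGATCTCTAA"
  exon1 <- paste0("TT", substr(cds, 1, 10))
  exon2 <- paste0(substr(cds, 11, 21), "GG")
  seqv <- paste0("ACGTACGTAC", exon1, "GTAAAAAAAG", exon2, "ACGTACGTAC")
  list(genome = c(chrM1 = seqv),
       tx = list(gene = "MINI1", chrom = "chrM1", strand = "+",
                 exon_start = c(11L, 33L), exon_end = c(22L, 45L),
                 cds_start = 13L, cds_end = 43L))
}

mini_gene_minus <- function() {
  m <- mini_gene_plus()
  s <- m$genome[[1]]
  L <- nchar(s)
  flip <- function(x) L - x + 1L
  tx <- m$tx
  list(genome = c(chrM2 = oracle_revcomp(s)),
       tx = list(gene = "MINI2", chrom = "chrM2", strand = "-",
                 exon_start = rev(flip(tx$exon_end)),
                 exon_end = rev(flip(tx$exon_start)),
                 cds_start = flip(tx$cds_end),
                 cds_end = flip(tx$cds_start)))
}

# small annotated-variant row builder for prioritization tests
ann_row <- function(gene, consequence, gt_code, maf = NA_real_,
                    clinical = "unreported", pos = NULL, chrom = gene) {
  pos <- pos %||% sample.int(1000L, 1L)
  data.table(chrom = chrom, pos = pos, ref = "A", alt = "C",
             gt_code = gt_code, gene = gene, consequence = consequence,
             maf = maf, clinical = clinical)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
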