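#' @name coverage_qc
#' @title Panel coverage QC and Sanger-backfill regions
#'
#' @description
#' Per-base depth statistics over the panel design, and the list of
#' maximal under-covered intervals that would be backfilled by Sanger
#' sequencing, labeled with the overlapping gene and exon.
NULL

#' Fraction of design bases covered above depth thresholds
#'
#' @param depth depth table (`chrom`, `pos`, `depth`), restricted to
#'   design bases; must be nonempty.
#' @param thresholds depth cutoffs (default `c(25, 50, 100)`).
#' @param ge use `>=` instead of the default strict `>` ("coverage of
#'   >25x" is read as strictly greater).
#' @return named numeric vector, one fraction in \[0, 1\] per threshold;
#'   monotone non-increasing in the threshold.
#' @export
coverage_fractions <- function(depth, thresholds = c(25, 50, 100),
                               ge = FALSE) {
  dt <- data.table::as.data.table(depth)
  if (nrow(dt) == 0) stop_trailing("empty depth track")
  vapply(setNames(thresholds, paste0(">", thresholds, "x")),
         function(th) {
           if (ge) mean(dt$depth >= th) else mean(dt$depth > th)
         }, numeric(1))
}

#' Under-covered design intervals needing Sanger backfill
#'
#' Maximal merged runs of design bases with depth at or below `min_depth`,
#' labeled with the overlapping panel gene and (transcription-order) exon
#' numbers.
#'
#' @param depth depth table over the design.
#' @param tx named list of transcript objects (for exon labels); optional.
#' @param min_depth bases with `depth <= min_depth` are backfilled
#'   (default 25).
#' @return `data.table` with `chrom`, `start`, `end` (1-based inclusive),
#'   `gene`, `exons` (comma-joined exon numbers, "" when intronic or
#'   intergenic); writable with [write_bed()].
#' @export
backfill_regions <- function(depth, tx = NULL, min_depth = 25L) {
  if (min_depth < 1L) stop_trailing("min_depth must be >= 1")
  dt <- data.table::as.data.table(depth)[depth <= min_depth]
  if (nrow(dt) == 0)
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), gene = character(),
                                  exons = character()))
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    dt$chrom, IRanges::IRanges(dt$pos, dt$pos)))
  out <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr))
  out[, gene := chrom]                      # toy genome: contig == gene
  out[, exons := ""]
  if (!is.null(tx)) {
    for (i in seq_len(nrow(out))) {
      t <- tx[[out$chrom[i]]]
      if (is.null(t)) next
      hit <- which(t$exon_start <= out$end[i] &
                     t$exon_end >= out$start[i])
      if (length(hit))
        out[i, exons := paste(sort(vapply(hit, function(h)
          tx_exon_number(t, h), 1L)), collapse = ",")]
    }
  }
  data.table::setorder(out, chrom, start)
  out[]
}
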