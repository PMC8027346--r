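#' @name normalize
#' @title Allele normalization and multiallelic decomposition
#'
#' @description
#' Calls from different variant callers describe the same underlying edit
#' in different ways (multiallelic merging, right-shifted indels, padded
#' alleles). Before any cross-caller comparison, every called allele is
#' reduced to a unique canonical representation: multiallelic records are
#' decomposed into biallelic ones, then each allele pair is made
#' parsimonious (no shared trailing bases; no shared leading bases except a
#' single VCF-style anchor base for indels) and left-aligned (no
#' haplotype-equivalent representation exists at a smaller position).
#'
#' The algorithm is the standard iterative right-trim / left-extend /
#' left-trim procedure against the reference sequence; it is idempotent,
#' preserves haplotype equivalence, and maps every representation of the
#' same edit to one key `(chrom, pos, ref, alt)`.
NULL

#' Decompose multiallelic records into single-alt records
#'
#' One output record per alternate allele. A sample genotype that refers to
#' alternate allele *k* becomes het/hom in output *k*; alleles referring to
#' other alternates become reference in that output; missing stays missing.
#' Alt-allele counts are conserved across the decomposition.
#'
#' @param vcf an `ion_vcf` table ([read_vcf()]), possibly multiallelic.
#' @return a table of the same shape in which every row has a single `alt`.
#' @export
decompose <- function(vcf) {
  samples <- attr(vcf, "samples") %||% character()
  dt <- data.table::as.data.table(vcf)
  multi <- grepl(",", dt$alt, fixed = TRUE)
  if (!any(multi)) {
    out <- data.table::copy(dt)
  } else {
    rows <- vector("list", nrow(dt))
    for (i in seq_len(nrow(dt))) {
      if (!multi[i]) { rows[[i]] <- dt[i]; next }
      alts <- strsplit(dt$alt[i], ",", fixed = TRUE)[[1]]
      sub <- dt[rep(i, length(alts))]
      sub[, alt := alts]
      for (s in samples) {
        g <- dt[[s]][i]
        idx <- parse_gt(g)[1, ]
        ph <- gt_phased(g)
        sub[[s]] <- vapply(seq_along(alts), function(k) {
          mapped <- ifelse(is.na(idx), NA_integer_,
                           ifelse(idx == k, 1L, 0L))
          if (anyNA(mapped)) return("./.")
          if (!ph) mapped <- sort(mapped)   # unphased: canonical order
          paste(mapped, collapse = if (ph) "|" else "/")
        }, character(1))
      }
      rows[[i]] <- sub
    }
    out <- data.table::rbindlist(rows)
  }
  data.table::setattr(out, "samples", samples)
  out[]
}

#' Left-align and trim one single-alt variant
#'
#' Iteratively right-trims shared trailing bases (left-extending with the
#' preceding reference base whenever an allele would become empty), then
#' left-trims shared leading bases down to a single anchor base. The result
#' is the parsimonious, left-aligned representative of the variant's
#' haplotype-equivalence class.
#'
#' @param pos 1-based position of the first reference base.
#' @param ref,alt allele strings (nonempty, ACGT).
#' @param seq the contig sequence containing the variant.
#' @param max_shift maximum leftward shift in bp before erroring out
#'   (guards against pathological repeat expanses); default 1000.
#' @return list with `pos`, `ref`, `alt`.
#' @export
left_align_trim <- function(pos, ref, alt, seq, max_shift = 1000L) {
  if (substr(seq, pos, pos + nchar(ref) - 1L) != ref)
    stop_trailing(
      "reference mismatch at pos %d: REF '%s' vs reference '%s'",
      pos, ref, substr(seq, pos, pos + nchar(ref) - 1L))
  if (identical(ref, alt))
    stop_trailing("REF equals ALT at pos %d", pos)
  orig <- pos
  repeat {
    rl <- nchar(ref); al <- nchar(alt)
    if (rl > 0L && al > 0L &&
        substr(ref, rl, rl) == substr(alt, al, al)) {
      ref <- substr(ref, 1L, rl - 1L)
      alt <- substr(alt, 1L, al - 1L)
      if (nchar(ref) == 0L || nchar(alt) == 0L) {
        if (pos == 1L)
          stop_trailing("cannot left-extend past contig start")
        pos <- pos - 1L
        b <- substr(seq, pos, pos)
        ref <- paste0(b, ref)
        alt <- paste0(b, alt)
        if (orig - pos > max_shift)
          stop_trailing("left-alignment exceeded max_shift = %d", max_shift)
      }
    } else break
  }
  while (nchar(ref) >= 2L && nchar(alt) >= 2L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Normalize a table of single-alt calls against a reference genome
#'
#' SNVs are fixed points of normalization and pass through untouched;
#' distinct indel representations are normalized once each and the results
#' joined back, so cohort-scale call sets stay fast. Original
#' representations are retained in `orig_pos`, `orig_ref`, `orig_alt`
#' (caller provenance).
#'
#' @param calls data.table with `chrom`, `pos`, `ref`, `alt` (single
#'   allele per row) plus any other columns.
#' @param genome named character vector of contig sequences.
#' @param max_shift see [left_align_trim()].
#' @return the table with normalized `pos`, `ref`, `alt` and provenance
#'   columns appended.
#' @export
normalize_calls <- function(calls, genome, max_shift = 1000L) {
  dt <- data.table::as.data.table(calls)
  if (any(grepl(",", dt$alt, fixed = TRUE)))
    stop_trailing("normalize_calls expects decomposed (single-alt) input")
  dt[, `:=`(orig_pos = pos, orig_ref = ref, orig_alt = alt)]
  if (!nrow(dt)) return(dt[])
  needs <- !(nchar(dt$ref) == 1L & nchar(dt$alt) == 1L)
  if (any(needs)) {
    keys <- unique(dt[needs, .(chrom, pos, ref, alt)])
    norm <- keys[, {
      res <- left_align_trim(pos, ref, alt, genome[[chrom]], max_shift)
      list(new_pos = res$pos, new_ref = res$ref, new_alt = res$alt)
    }, by = .(chrom, pos, ref, alt)]
    dt[norm, on = c("chrom", "pos", "ref", "alt"),
       `:=`(pos = i.new_pos, ref = i.new_ref, alt = i.new_alt)]
  }
  dt[]
}

#' Check the normalized-variant invariants
#'
#' A variant is normalized iff it is parsimonious and left-aligned with
#' respect to the reference.
#'
#' @inheritParams left_align_trim
#' @return logical scalar.
#' @export
is_normalized <- function(pos, ref, alt, seq) {
  res <- tryCatch(left_align_trim(pos, ref, alt, seq),
                  error = function(e) NULL)
  !is.null(res) && res$pos == pos && res$ref == ref && res$alt == alt
}
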