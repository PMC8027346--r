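`%||%` <- function(x, y) if (is.null(x)) y else x

#' Run code with a temporary RNG seed, restoring caller RNG state
#'
#' All stochastic package internals route their sampling through this helper
#' so that library code never clobbers the user's random number stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Canonical variant key
#'
#' The normalized tuple (chrom, pos, ref, alt) identifies a variant
#' throughout the pipeline; distinct-variant tallies deduplicate on it.
#'
#' @param chrom,pos,ref,alt vectors of equal length.
#' @return character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# genotype helpers ------------------------------------------------------

#' Parse GT strings into allele index pairs
#'
#' @param gt character vector like "0/1", "1|1", "./.".
#' @return integer matrix with two columns (NA for missing alleles).
#' @export
parse_gt <- function(gt) {
  parts <- strsplit(gt, "[/|]")
  a <- vapply(parts, function(p) {
    p <- c(p, ".")[1:2]
    suppressWarnings(as.integer(ifelse(p == ".", NA, p)))
  }, integer(2))
  t(a)
}

#' Genotype dosage code for single-alt records
#'
#' 0 = hom-ref, 1 = het, 2 = hom-alt, NA = missing (any missing allele).
#'
#' @param gt character vector of GT strings over alleles {0, 1}.
#' @return integer vector.
#' @export
gt_code <- function(gt) {
  m <- parse_gt(gt)
  out <- m[, 1] + m[, 2]
  out[is.na(m[, 1]) | is.na(m[, 2])] <- NA_integer_
  as.integer(out)
}

gt_phased <- function(gt) grepl("|", gt, fixed = TRUE)

code_to_gt <- function(code, phased = FALSE) {
  sep <- ifelse(phased, "|", "/")
  out <- rep("./.", length(code))
  out[!is.na(code) & code == 0L] <- paste0("0", sep, "0")
  out[!is.na(code) & code == 1L] <- paste0("0", sep, "1")
  out[!is.na(code) & code == 2L] <- paste0("1", sep, "1")
  out
}

# sequence helpers ------------------------------------------------------

DNA_BASES <- c("A", "C", "G", "T")

revcomp <- function(x) {
  vapply(x, function(s) {
    if (nchar(s) == 0) return(s)
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

complement <- function(x) chartr("ACGT", "TGCA", x)

#' Translate a nucleotide string with the standard genetic code
#'
#' @param nt character scalar, length divisible by 3, ACGT alphabet.
#' @return character scalar of one-letter amino acids ("*" = stop).
#' @keywords internal
translate_cds <- function(nt) {
  stopifnot(nchar(nt) %% 3 == 0)
  if (nchar(nt) == 0) return("")
  codons <- substring(nt, seq(1, nchar(nt), 3), seq(3, nchar(nt), 3))
  paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
}

stop_trailing <- function(msg, ...) stop(sprintf(msg, ...), call. = FALSE)
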