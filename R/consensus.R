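#' @name consensus
#' @title Multi-caller consensus merging
#'
#' @description
#' The calling strategy is consensus-based: six callers (Torrent Suite
#' VariantCaller, GATK UnifiedGenotyper, VarScan2, SNVer, LoFreq, Platypus)
#' each produce a call set per sample, and a variant is retained when at
#' least `min_support` callers agree on its normalized key. Genotypes are
#' reconciled by majority vote among supporting callers, ties broken by
#' the fixed caller priority order ([ion_callers()]).
NULL

#' Reconcile genotypes from supporting callers
#'
#' Majority vote over het / hom-alt among non-missing, non-hom-ref votes;
#' ties go to the highest-priority caller. All-missing input yields a
#' missing genotype.
#'
#' @param codes integer dosage codes ([gt_code()]) from supporting callers.
#' @param callers caller ids aligned with `codes`.
#' @param priority caller priority order (default [ion_callers()]).
#' @return a single dosage code (1, 2, or NA).
#' @export
reconcile_genotype <- function(codes, callers,
                               priority = ion_callers()) {
  keep <- !is.na(codes) & codes > 0L
  codes <- codes[keep]; callers <- callers[keep]
  if (!length(codes)) return(NA_integer_)
  n_het <- sum(codes == 1L); n_hom <- sum(codes == 2L)
  if (n_het > n_hom) return(1L)
  if (n_hom > n_het) return(2L)
  ord <- match(callers, priority)
  codes[which.min(ord)]
}

#' Build the consensus call set for one sample
#'
#' @param calls normalized, decomposed call table for a single sample with
#'   columns `chrom`, `pos`, `ref`, `alt`, `caller`, `gt` (GT string) and
#'   optionally `quality_pass`.
#' @param min_support minimum number of supporting callers `m` (default 2).
#' @param callers_run the callers that produced output for this sample;
#'   callers that emitted no call set reduce the denominator rather than
#'   counting as absent votes.
#' @param count_nonpass count records whose FILTER failed (default FALSE:
#'   PASS-only).
#' @param genome optional named contig vector; when supplied, input keys
#'   are checked to be normalized and unnormalized input is an error.
#' @return `data.table` with one row per consensus variant: `chrom`,
#'   `pos`, `ref`, `alt`, `gt_code`, `n_support`, `support`
#'   (comma-joined caller ids), `n_callers_run`; ordered by
#'   (chrom, pos, ref, alt).
#' @export
build_consensus <- function(calls, min_support = 2L,
                            callers_run = ion_callers(),
                            count_nonpass = FALSE, genome = NULL) {
  dt <- data.table::as.data.table(calls)
  if (min_support < 1L || min_support > length(callers_run))
    stop_trailing("min_support must be in 1..%d", length(callers_run))
  if (nrow(dt) && !all(dt$caller %in% callers_run))
    stop_trailing("call set contains callers not in callers_run")
  if (!is.null(genome) && nrow(dt)) {
    u <- unique(dt[, .(chrom, pos, ref, alt)])
    ok <- vapply(seq_len(nrow(u)), function(i)
      is_normalized(u$pos[i], u$ref[i], u$alt[i], genome[[u$chrom[i]]]),
      logical(1))
    if (!all(ok))
      stop_trailing("unnormalized input key: %s",
                    variant_key(u$chrom[!ok][1], u$pos[!ok][1],
                                u$ref[!ok][1], u$alt[!ok][1]))
  }
  if (!count_nonpass && "quality_pass" %in% names(dt))
    dt <- dt[quality_pass == TRUE]
  if (!nrow(dt))
    return(data.table::data.table(
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), gt_code = integer(), n_support = integer(),
      support = character(), n_callers_run = integer()))
  dt <- unique(dt, by = c("chrom", "pos", "ref", "alt", "caller"))
  dt[, code := gt_code(gt)]
  out <- dt[, {
    ord <- order(match(caller, ion_callers()))
    list(gt_code = reconcile_genotype(code, caller),
         n_support = .N,
         support = paste(caller[ord], collapse = ","))
  }, by = .(chrom, pos, ref, alt)]
  out <- out[n_support >= min_support]
  out[, n_callers_run := length(callers_run)]
  data.table::setorder(out, chrom, pos, ref, alt)
  out[]
}

#' Consensus calling across a cohort
#'
#' Groups a multi-sample call table by `sample_id` and applies
#' [build_consensus()] per sample with shared settings. Vectorized
#' internally (single grouped pass) for cohort-scale inputs.
#'
#' @param calls normalized decomposed calls with columns `sample_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `caller`, `gt`, optionally
#'   `quality_pass`.
#' @inheritParams build_consensus
#' @return `data.table` keyed by `sample_id` with the [build_consensus()]
#'   columns.
#' @export
build_consensus_cohort <- function(calls, min_support = 2L,
                                   callers_run = ion_callers(),
                                   count_nonpass = FALSE) {
  dt <- data.table::as.data.table(calls)
  if (min_support < 1L || min_support > length(callers_run))
    stop_trailing("min_support must be in 1..%d", length(callers_run))
  if (!count_nonpass && "quality_pass" %in% names(dt))
    dt <- dt[quality_pass == TRUE]
  if (!nrow(dt))
    return(data.table::data.table(
      sample_id = character(), chrom = character(), pos = integer(),
      ref = character(), alt = character(), gt_code = integer(),
      n_support = integer(), support = character(),
      n_callers_run = integer()))
  dt <- unique(dt, by = c("sample_id", "chrom", "pos", "ref", "alt",
                          "caller"))
  dt[, code := gt_code(gt)]
  dt[, prio := match(caller, ion_callers())]
  data.table::setorder(dt, sample_id, chrom, pos, ref, alt, prio)
  out <- dt[, {
    list(gt_code = reconcile_genotype(code, caller),
         n_support = .N,
         support = paste(caller, collapse = ","))
  }, by = .(sample_id, chrom, pos, ref, alt)]
  out <- out[n_support >= min_support]
  out[, n_callers_run := length(callers_run)]
  data.table::setorder(out, sample_id, chrom, pos, ref, alt)
  out[]
}

#' Write a consensus call set as a VCF with support annotations
#'
#' Support is carried in INFO as `SUP=` (count) and `CALLERS=`
#' (comma-joined ids).
#'
#' @param consensus output of [build_consensus()].
#' @param sample_id sample name for the genotype column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_consensus_vcf <- function(consensus, sample_id, path) {
  dt <- data.table::as.data.table(consensus)
  vcf <- dt[, .(chrom, pos, id = ".", ref, alt, qual = ".",
                filter = "PASS",
                info = sprintf("SUP=%d;CALLERS=%s", n_support, support))]
  vcf[[sample_id]] <- code_to_gt(dt$gt_code)
  write_vcf(vcf, path, samples = sample_id,
            extra_header = c(
              "##INFO=<ID=SUP,Number=1,Type=Integer,Description=\"Supporting caller count\">",
              "##INFO=<ID=CALLERS,Number=.,Type=String,Description=\"Supporting callers\">"))
}
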