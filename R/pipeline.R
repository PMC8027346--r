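#' @name pipeline
#' @title End-to-end pipeline orchestration
#'
#' @description
#' Ties the stages together — simulate (or ingest) -> normalize ->
#' consensus -> annotate -> prioritize -> coverage QC -> summarize — under
#' a single validated configuration, with a JSON run manifest (config
#' hash, seed, per-stage row counts and content hashes) for
#' reproducibility: rerunning with the same configuration produces an
#' identical manifest.
NULL

#' Build and validate a pipeline run configuration
#'
#' @param seed RNG seed for the simulated cohort (mandatory).
#' @param n_probands cohort size.
#' @param min_support consensus support threshold m.
#' @param dominant_max,recessive_max MAF thresholds (see
#'   [maf_thresholds()]).
#' @param splice_window splice-region half-width in bp.
#' @param allow_unaffected_carriers dominant segregation relaxation.
#' @param min_depth backfill depth cutoff.
#' @param out_dir optional output directory for stage artifacts.
#' @param spec optional pre-built [cohort_spec()] (overrides `seed` /
#'   `n_probands`).
#' @return validated list of class `ion_run_config`.
#' @export
run_config <- function(seed, n_probands = 500L, min_support = 2L,
                       dominant_max = 1e-4, recessive_max = 5e-3,
                       splice_window = 2L,
                       allow_unaffected_carriers = FALSE,
                       min_depth = 25L, out_dir = NULL, spec = NULL) {
  thresholds <- maf_thresholds(dominant_max, recessive_max)
  if (min_support < 1L || min_support > length(ion_callers()))
    stop_trailing("min_support must be in 1..%d", length(ion_callers()))
  spec <- spec %||% cohort_spec(n_probands = n_probands, seed = seed)
  structure(list(spec = spec, min_support = as.integer(min_support),
                 thresholds = thresholds,
                 splice_window = as.integer(splice_window),
                 allow_unaffected_carriers = allow_unaffected_carriers,
                 min_depth = as.integer(min_depth), out_dir = out_dir),
            class = "ion_run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys mirror the [run_config()] arguments (plus any
#' [cohort_spec()] argument under `cohort:`); unknown keys are an error.
#'
#' @param path YAML file.
#' @return `ion_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("seed", "n_probands", "min_support", "dominant_max",
             "recessive_max", "splice_window",
             "allow_unaffected_carriers", "min_depth", "out_dir",
             "cohort")
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop_trailing("unknown config key(s): %s", paste(bad, collapse = ", "))
  if (is.null(y$seed)) stop_trailing("config requires a seed")
  spec <- NULL
  if (!is.null(y$cohort))
    spec <- do.call(cohort_spec,
                    c(y$cohort,
                      list(seed = y$seed),
                      if (!is.null(y$n_probands) &&
                          is.null(y$cohort$n_probands))
                        list(n_probands = y$n_probands)))
  args <- y[setdiff(names(y), "cohort")]
  do.call(run_config, c(args, list(spec = spec)))
}

#' Run the full pipeline on a (simulated or supplied) cohort
#'
#' @param config an [run_config()] object.
#' @param cohort optional pre-generated `ion_cohort` (ingest mode); when
#'   NULL one is simulated from `config$spec`.
#' @return list of class `ion_run`: `cohort`, `normalized`, `consensus`,
#'   `annotated`, `classifications`, `qc` (coverage fractions + backfill
#'   table), `summary`, and `manifest`.
#' @export
run_ion_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "ion_run_config"))
  stages <- list()
  note <- function(name, obj) {
    stages[[length(stages) + 1L]] <<- list(
      stage = name,
      n_rows = if (is.data.frame(obj)) nrow(obj) else length(obj),
      hash = rlang::hash(obj))
  }
  cohort <- cohort %||% generate_cohort(config$spec)
  note("simulate", cohort$calls)

  norm <- normalize_calls(cohort$calls, cohort$genome)
  note("normalize", norm)

  cons <- build_consensus_cohort(norm, min_support = config$min_support)
  note("consensus", cons)

  ann <- annotate_variants(cons, cohort$panel, cohort$freq_table,
                           cohort$clinical_table, cohort$tx,
                           cohort$genome,
                           splice_window = config$splice_window)
  note("annotate", ann)

  cls <- classify_cohort(
    ann, cohort$panel, pedigrees = cohort$pedigrees,
    relative_calls = cohort$relative_calls,
    thresholds = config$thresholds, sample_ids = cohort$ids,
    allow_unaffected_carriers = config$allow_unaffected_carriers)
  note("prioritize", cls)

  qc <- list(fractions = coverage_fractions(cohort$depth),
             backfill = backfill_regions(cohort$depth, cohort$tx,
                                         min_depth = config$min_depth))
  note("qc", qc$backfill)

  causal_ann <- ann[variant_key(chrom, pos, ref, alt) %in%
                      unlist(strsplit(cls$causal_keys[
                        !is.na(cls$causal_keys)], ","))]
  summ <- summarize_cohort(cls, causal_ann, n_total = length(cohort$ids))
  note("summarize", summ)

  manifest <- list(
    config_hash = rlang::hash(config),
    seed = config$spec$seed,
    n_probands = config$spec$n_probands,
    stages = stages)
  run <- structure(list(cohort = cohort, normalized = norm,
                        consensus = cons, annotated = ann,
                        classifications = cls, qc = qc, summary = summ,
                        manifest = manifest),
                   class = "ion_run")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(cls, file.path(config$out_dir,
                                      "classifications.tsv"), sep = "\t")
    jsonlite::write_json(summary_as_list(summ),
                         file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    write_bed(qc$backfill, file.path(config$out_dir, "backfill.bed"))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  run
}

summary_as_list <- function(s) {
  list(n_total = s$n_total, n_solved = s$n_solved,
       n_dominant = s$n_dominant, n_recessive = s$n_recessive,
       yield_pct = s$yield_pct, dominant_pct = s$dominant_pct,
       recessive_pct = s$recessive_pct,
       n_distinct_variants = s$n_distinct_variants,
       gene_counts = s$gene_counts, class_tally = s$class_tally)
}

#' @export
print.ion_run <- function(x, ...) {
  cat(sprintf("ION pipeline run (seed %d): %d probands, %d stages\n",
              x$manifest$seed, x$manifest$n_probands,
              length(x$manifest$stages)))
  print(x$summary)
  invisible(x)
}

#' Per-proband truth recovery of a pipeline run
#'
#' A solved truth proband is recovered when its classification carries the
#' same gene, mode and exact causal key set; an unsolved truth proband is
#' recovered when it is classified unsolved.
#'
#' @param run an `ion_run`.
#' @return list with `n_truth`, `n_recovered`, `recovery` (fraction over
#'   solved-truth probands), `false_solved` (background-only probands
#'   classified as solved or VUS).
#' @export
truth_recovery <- function(run) {
  truth <- run$cohort$truth
  cls <- run$classifications
  m <- merge(truth, cls, by = "sample_id", suffixes = c("_t", ""))
  sort_keys <- function(k) vapply(strsplit(k, ",", fixed = TRUE),
                                  function(x) paste(sort(x),
                                                    collapse = ","), "")
  ok <- m$gene_t == m$gene & m$mode_t == m$mode &
    !is.na(m$causal_keys) &
    sort_keys(m$causal_keys_t) == sort_keys(m$causal_keys)
  ok[is.na(ok)] <- FALSE
  bg_ids <- setdiff(run$cohort$ids, truth$sample_id)
  false_solved <- cls[sample_id %in% bg_ids &
                        status != "unsolved", .N]
  list(n_truth = nrow(truth), n_recovered = sum(ok),
       recovery = if (nrow(truth)) mean(ok) else NA_real_,
       false_solved = false_solved)
}
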