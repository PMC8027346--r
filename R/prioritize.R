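#' @name prioritize
#' @title Causative-variant prioritization cascade
#'
#' @description
#' Per-proband diagnostic logic: an mtDNA pre-screen for the three primary
#' LHON mutations, mode-specific rarity filtering (dominant MAF < 1e-4,
#' recessive MAF < 5e-3, absent-from-databases always passes), a tier
#' ladder (reported pathogenic in a known gene > novel loss-of-function in
#' a known gene > novel missense in a known gene > qualifying variant in a
#' candidate gene, reported as uncertain significance), biallelic /
#' compound-heterozygote detection, and pedigree segregation matching.
NULL

TIERS <- c("T1_reported_pathogenic", "T2_novel_lof", "T3_novel_missense",
           "T4_candidate_vus")

#' The three primary LHON mtDNA mutations
#'
#' m.3460G>A, m.11778G>A and m.14484T>C; samples carrying any of them are
#' excluded from the autosomal panel analysis.
#'
#' @return data.table with `pos`, `ref`, `alt`.
#' @export
lhon_primary_mutations <- function() {
  data.table::data.table(pos = c(3460L, 11778L, 14484L),
                         ref = c("G", "G", "T"),
                         alt = c("A", "A", "C"))
}

#' Screen a sample's mtDNA variants for primary LHON mutations
#'
#' Exact-allele matching on (position, ref, alt).
#'
#' @param mt_variants data.table with `pos`, `ref`, `alt` (mtDNA calls),
#'   possibly empty.
#' @return `"excluded"` if any primary mutation is present, else
#'   `"retained"`.
#' @export
lhon_screen <- function(mt_variants) {
  if (is.null(mt_variants) || nrow(mt_variants) == 0) return("retained")
  prim <- lhon_primary_mutations()
  hit <- merge(data.table::as.data.table(mt_variants)[, .(pos, ref, alt)],
               prim, by = c("pos", "ref", "alt"))
  if (nrow(hit)) "excluded" else "retained"
}

#' Mode-specific MAF thresholds
#'
#' Dominant candidate variants must be absent from population databases or
#' rarer than `dominant_max`; recessive candidates rarer than
#' `recessive_max`. Both comparisons are strict (`<`).
#'
#' @param dominant_max,recessive_max thresholds in (0, 1),
#'   `dominant_max <= recessive_max`. Defaults 1e-4 and 5e-3.
#' @return list of class `maf_thresholds`.
#' @export
maf_thresholds <- function(dominant_max = 1e-4, recessive_max = 5e-3) {
  if (!(dominant_max > 0 && dominant_max <= recessive_max &&
        recessive_max < 1))
    stop_trailing("need 0 < dominant_max <= recessive_max < 1")
  structure(list(dominant_max = dominant_max,
                 recessive_max = recessive_max),
            class = "maf_thresholds")
}

#' Mode-specific rarity filter
#'
#' @param maf numeric vector of population MAFs (NA = absent from public
#'   databases, which always passes).
#' @param mode `"dominant"` or `"recessive"`.
#' @param thresholds a [maf_thresholds()] object.
#' @return logical vector: TRUE = variant passes.
#' @export
maf_filter <- function(maf, mode, thresholds = maf_thresholds()) {
  mode <- match.arg(mode, VALID_MODES)
  cut <- if (mode == "dominant") thresholds$dominant_max
         else thresholds$recessive_max
  is.na(maf) | maf < cut
}

#' Assign the prioritization tier of an annotated variant
#'
#' Reported pathogenic / likely pathogenic in a known gene is tier 1; a
#' novel (unreported) LoF in a known gene tier 2; a novel missense in a
#' known gene tier 3; any qualifying (LoF or missense, non-benign) variant
#' in a candidate-status gene tier 4 (uncertain significance). Benign,
#' synonymous and non-splice intronic variants get no tier.
#'
#' @param consequence,clinical,gene_status vectors of equal length.
#' @return character vector of tiers (NA = not tier-qualifying).
#' @export
assign_tier <- function(consequence, clinical, gene_status) {
  qualifying <- is_lof(consequence) | consequence == "missense"
  reported_path <- clinical %in% c("pathogenic", "likely_pathogenic")
  novel <- clinical == "unreported"
  out <- rep(NA_character_, length(consequence))
  known <- gene_status == "known"
  out[known & reported_path] <- "T1_reported_pathogenic"
  out[known & is.na(out) & novel & is_lof(consequence)] <- "T2_novel_lof"
  out[known & is.na(out) & novel & consequence == "missense"] <-
    "T3_novel_missense"
  out[!known & qualifying & clinical != "benign"] <- "T4_candidate_vus"
  out[clinical == "benign"] <- NA_character_
  out
}

#' Detect the genotype pattern of one proband's variants in one gene
#'
#' @param gt_codes dosage codes of the (recessive-MAF-filtered) variants.
#' @return `"biallelic"` when a homozygous variant or two or more distinct
#'   heterozygous variants are present (presumed compound heterozygote;
#'   phase is unknown), else `"monoallelic_het"`.
#' @export
detect_genotype_pattern <- function(gt_codes) {
  gt_codes <- gt_codes[!is.na(gt_codes) & gt_codes > 0L]
  if (any(gt_codes == 2L) || sum(gt_codes == 1L) >= 2L) "biallelic"
  else "monoallelic_het"
}

#' Check segregation of candidate variant(s) in a pedigree
#'
#' Dominant: consistent iff every genotyped affected relative carries the
#' variant and (strict mode) no genotyped unaffected relative does;
#' `allow_unaffected_carriers = TRUE` relaxes the second clause (incomplete
#' penetrance). Recessive: every genotyped affected relative must be
#' biallelic and no genotyped unaffected relative may be; additionally,
#' a compound-heterozygous pair is inconsistent when one parent of the
#' proband carries both alleles (they would then be in cis).
#'
#' @param keys variant key(s) of the candidate genotype (1 for dominant or
#'   homozygous, 2 for compound het).
#' @param mode `"dominant"` or `"recessive"`.
#' @param pedigree `ion_pedigree` table (with `attr(,"proband")`).
#' @param relative_calls genotype table for family members with columns
#'   `sample_id`, `key`, `gt_code` (one row per genotyped relative and
#'   variant; 0 rows per relative = not genotyped).
#' @param allow_unaffected_carriers relax dominant strictness.
#' @return `"consistent"`, `"inconsistent"`, or `"untested"` (no genotyped
#'   non-proband relative).
#' @export
check_segregation <- function(keys, mode, pedigree, relative_calls,
                              allow_unaffected_carriers = FALSE) {
  mode <- match.arg(mode, VALID_MODES)
  if (is.null(pedigree) || is.null(relative_calls) ||
      nrow(relative_calls) == 0)
    return("untested")
  ped <- data.table::as.data.table(pedigree)
  pro <- attr(pedigree, "proband")
  rel <- data.table::as.data.table(relative_calls)
  rel <- rel[sample_id %in% setdiff(ped$id, pro)]
  if (!nrow(rel)) return("untested")
  genotyped <- unique(rel$sample_id)
  carries <- function(who, k) {
    g <- rel[sample_id == who & key == k, gt_code]
    length(g) > 0 && !is.na(g[1]) && g[1] > 0L
  }
  hom_for <- function(who, k) {
    g <- rel[sample_id == who & key == k, gt_code]
    length(g) > 0 && !is.na(g[1]) && g[1] == 2L
  }
  biallelic_rel <- function(who) {
    if (length(keys) == 1L) hom_for(who, keys)
    else all(vapply(keys, function(k) carries(who, k), logical(1)))
  }
  aff <- intersect(genotyped, ped[affected == "yes", id])
  unaff <- intersect(genotyped, ped[affected == "no", id])
  if (mode == "dominant") {
    k <- keys[1]
    if (length(aff) && !all(vapply(aff, carries, logical(1), k = k)))
      return("inconsistent")
    if (!allow_unaffected_carriers && length(unaff) &&
        any(vapply(unaff, carries, logical(1), k = k)))
      return("inconsistent")
    return("consistent")
  }
  # recessive
  if (length(keys) == 2L) {
    parents <- ped[id == pro, c(father, mother)]
    parents <- intersect(parents[parents != "0"], genotyped)
    for (p in parents)
      if (all(vapply(keys, function(k) carries(p, k), logical(1))))
        return("inconsistent")              # both alleles from one parent
  }
  if (length(aff) && !all(vapply(aff, biallelic_rel, logical(1))))
    return("inconsistent")
  if (length(unaff) && any(vapply(unaff, biallelic_rel, logical(1))))
    return("inconsistent")
  "consistent"
}

tier_rank <- function(tier) match(tier, TIERS)
seg_rank <- function(seg) match(seg, c("consistent", "untested",
                                       "inconsistent"))

#' Classify one proband from its annotated consensus variants
#'
#' Candidate diagnoses are constructed per panel gene — monoallelic
#' heterozygous for dominant-capable genes (dominant MAF filter), biallelic
#' for recessive-capable genes (recessive MAF filter) — and ranked by
#' (tier, segregation status, panel gene order). In a gene carrying both
#' inheritance modes, a constructible biallelic genotype beats a
#' monoallelic one. A best candidate of tier 1-3 solves the case
#' (dominant or recessive); tier 4 alone yields `vus_candidate`; nothing
#' qualifying yields `unsolved`. A proband failing the LHON pre-screen is
#' `excluded_lhon` and not analysed further.
#'
#' @param variants annotated consensus table for one proband (columns
#'   `chrom`, `pos`, `ref`, `alt`, `gt_code`, `gene`, `consequence`,
#'   `maf`, `clinical`).
#' @param panel panel gene table.
#' @param pedigree optional `ion_pedigree` for the proband's family.
#' @param relative_calls optional relative genotype table (see
#'   [check_segregation()]).
#' @param thresholds [maf_thresholds()].
#' @param mt_variants optional mtDNA calls for the LHON pre-screen.
#' @param allow_unaffected_carriers dominant segregation relaxation.
#' @return one-row `data.table`: `status`, `gene`, `mode`, `tier`,
#'   `segregation`, `causal_keys` (comma-joined), `n_causal`, `flags`.
#' @export
classify_case <- function(variants, panel, pedigree = NULL,
                          relative_calls = NULL,
                          thresholds = maf_thresholds(),
                          mt_variants = NULL,
                          allow_unaffected_carriers = FALSE) {
  empty <- function(status, flags = "") data.table::data.table(
    status = status, gene = NA_character_, mode = NA_character_,
    tier = NA_character_, segregation = NA_character_,
    causal_keys = NA_character_, n_causal = 0L, flags = flags)
  if (lhon_screen(mt_variants) == "excluded")
    return(empty("excluded_lhon"))
  v <- data.table::as.data.table(variants)
  flags <- character()
  if (nrow(v) == 0) return(empty("unsolved"))
  v <- v[!is.na(gene)]
  if (nrow(v) == 0) return(empty("unsolved"))
  pan <- data.table::as.data.table(panel)
  v[pan, on = c(gene = "symbol"), `:=`(gene_modes = i.modes,
                                       gene_status = i.status)]
  v[, key := variant_key(chrom, pos, ref, alt)]
  v[, tier := assign_tier(consequence, clinical, gene_status)]
  v <- v[!is.na(tier) & !is.na(gt_code) & gt_code > 0L]
  if (nrow(v) == 0) return(empty("unsolved"))

  gene_order <- pan$symbol
  cands <- list()
  for (g in unique(v$gene)) {
    vg <- v[gene == g]
    gmodes <- strsplit(vg$gene_modes[1], ",", fixed = TRUE)[[1]]
    dom_cand <- rec_cand <- NULL
    if ("recessive" %in% gmodes) {
      vr <- vg[maf_filter(maf, "recessive", thresholds)]
      if (nrow(vr) && detect_genotype_pattern(vr$gt_code) == "biallelic") {
        hom <- vr[gt_code == 2L][order(tier_rank(tier))]
        if (nrow(hom)) {
          pick <- hom[1]
          rec_cand <- list(gene = g, mode = "recessive",
                           tier = pick$tier, keys = pick$key,
                           codes = pick$gt_code)
        } else {
          hets <- vr[gt_code == 1L][order(tier_rank(tier),
                                          chrom, pos, ref, alt)]
          pair <- hets[1:2]
          rec_cand <- list(gene = g, mode = "recessive",
                           tier = TIERS[max(tier_rank(pair$tier))],
                           keys = pair$key, codes = pair$gt_code)
        }
      } else if (nrow(vr) && !("dominant" %in% gmodes)) {
        flags <- c(flags, sprintf("monoallelic_recessive_hit:%s", g))
      }
    }
    if ("dominant" %in% gmodes) {
      vd <- vg[maf_filter(maf, "dominant", thresholds) & gt_code == 1L]
      if (nrow(vd)) {
        pick <- vd[order(tier_rank(tier), chrom, pos, ref, alt)][1]
        dom_cand <- list(gene = g, mode = "dominant", tier = pick$tier,
                         keys = pick$key, codes = pick$gt_code)
      }
    }
    if (!is.null(rec_cand) && !is.null(dom_cand)) {
      flags <- c(flags, sprintf("both_modes_constructible:%s", g))
      cands <- c(cands, list(rec_cand))       # biallelic wins
    } else if (!is.null(rec_cand)) cands <- c(cands, list(rec_cand))
    else if (!is.null(dom_cand)) cands <- c(cands, list(dom_cand))
  }
  if (!length(cands))
    return(empty("unsolved", paste(unique(flags), collapse = ";")))

  for (i in seq_along(cands)) {
    cands[[i]]$segregation <- check_segregation(
      cands[[i]]$keys, cands[[i]]$mode, pedigree, relative_calls,
      allow_unaffected_carriers)
  }
  ord <- order(vapply(cands, function(c) tier_rank(c$tier), 1L),
               vapply(cands, function(c) seg_rank(c$segregation), 1L),
               vapply(cands, function(c) match(c$gene, gene_order), 1L))
  best <- cands[[ord[1]]]
  if (length(ord) > 1) {
    second <- cands[[ord[2]]]
    if (tier_rank(second$tier) == tier_rank(best$tier) &&
        seg_rank(second$segregation) == seg_rank(best$segregation))
      flags <- c(flags, sprintf("ambiguous_gene_tie:%s", second$gene))
  }
  status <- if (best$tier == "T4_candidate_vus") "vus_candidate"
    else if (best$mode == "dominant") "solved_dominant"
    else "solved_recessive"
  data.table::data.table(
    status = status, gene = best$gene, mode = best$mode, tier = best$tier,
    segregation = best$segregation,
    causal_keys = paste(best$keys, collapse = ","),
    n_causal = length(best$keys),
    flags = paste(unique(flags), collapse = ";"))
}

#' Classify every proband of a cohort
#'
#' @param consensus_annotated annotated consensus calls with `sample_id`.
#' @param panel panel table.
#' @param pedigrees named list of `ion_pedigree` (names irrelevant; the
#'   proband id links a pedigree to a sample).
#' @param relative_calls relative genotype table (all families).
#' @param thresholds [maf_thresholds()].
#' @param sample_ids probands to classify (defaults to those present in
#'   `consensus_annotated`); probands with no calls are `unsolved`.
#' @param mt_variants optional table of mtDNA calls with `sample_id`.
#' @param allow_unaffected_carriers dominant segregation relaxation.
#' @return `data.table`, one row per proband.
#' @export
classify_cohort <- function(consensus_annotated, panel, pedigrees = NULL,
                            relative_calls = NULL,
                            thresholds = maf_thresholds(),
                            sample_ids = NULL, mt_variants = NULL,
                            allow_unaffected_carriers = FALSE) {
  dt <- data.table::as.data.table(consensus_annotated)
  sample_ids <- sample_ids %||% sort(unique(dt$sample_id))
  ped_by_proband <- list()
  for (p in pedigrees %||% list()) {
    pro <- attr(p, "proband")
    if (!is.na(pro)) ped_by_proband[[pro]] <- p
  }
  rel <- if (!is.null(relative_calls))
    data.table::as.data.table(relative_calls) else NULL
  mt <- if (!is.null(mt_variants))
    data.table::as.data.table(mt_variants) else NULL
  split_v <- split(dt, by = "sample_id", keep.by = FALSE)
  out <- lapply(sample_ids, function(s) {
    cc <- classify_case(
      split_v[[s]] %||% dt[0],
      panel,
      pedigree = ped_by_proband[[s]],
      relative_calls = rel,
      thresholds = thresholds,
      mt_variants = if (!is.null(mt)) mt[sample_id == s] else NULL,
      allow_unaffected_carriers = allow_unaffected_carriers)
    cc[, sample_id := s]
    cc
  })
  res <- data.table::rbindlist(out)
  data.table::setcolorder(res, "sample_id")
  res[]
}
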