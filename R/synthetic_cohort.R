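#' @name synthetic_cohort
#' @title Seeded synthetic ION cohort generator
#'
#' @description
#' Generates a fully specified synthetic diagnostic cohort on the toy
#' panel genome: per-proband causal variants drawn by mode, gene and
#' functional class from configurable frequency vectors (defaults mirror a
#' large published ION cohort composition), benign background variants,
#' per-caller noisy call sets (per-call dropout, representation jitter on
#' indels, caller-specific false positives, genotype miscalls), pedigrees
#' with Sanger-style relative genotypes, a per-base depth track, and the
#' packaged frequency/clinical tables — plus the ground-truth table every
#' test needs. All sampling is routed through one seeded generator: the
#' same spec yields byte-identical output.
NULL

#' Default per-gene solved-case count vectors
#'
#' Dominant and recessive family counts by gene; the 27 dominant
#' candidate-gene families are spread over the seven placeholder candidate
#' genes.
#'
#' @return list with `dominant` and `recessive` named integer vectors.
#' @export
ion_default_gene_counts <- function() {
  list(
    dominant = c(OPA1 = 76L, ACO2 = 31L, WFS1 = 23L, MFN2 = 11L,
                 AFG3L2 = 8L, SPG7 = 6L, DNM1L = 2L, MIEF1 = 2L,
                 CAND1 = 5L, CAND2 = 4L, CAND3 = 4L, CAND4 = 4L,
                 CAND5 = 4L, CAND6 = 3L, CAND7 = 3L),
    recessive = c(WFS1 = 23L, ACO2 = 13L, RTN4IP1 = 9L, TMEM126A = 5L,
                  SPG7 = 5L, OPA1 = 3L, SLC25A46 = 1L))
}

#' Construct a cohort specification
#'
#' Defaults describe the emulated study conditions: 22.23% of probands
#' carry a causal variant (186:59 dominant:recessive), per-gene
#' frequencies follow [ion_default_gene_counts()], OPA1 dominant variants
#' follow the 36/26/24/14 splice/nonsense/missense/frameshift split and
#' all other genes the overall 120/22/20/28
#' missense/nonsense/frameshift/splice tally. Noise defaults are modest
#' and realistic for amplicon panels: 95% per-call caller sensitivity, 10%
#' indel representation jitter, one false positive per caller-sample on
#' average, 2% genotype miscalls.
#'
#' @param n_probands cohort size.
#' @param seed RNG seed (mandatory).
#' @param solved_fraction fraction of probands with a causal variant.
#' @param dominant_fraction fraction of solved cases that are dominant.
#' @param gene_counts list(dominant=, recessive=) named vectors
#'   (normalized internally to frequencies).
#' @param opa1_class_weights,default_class_weights named weights over
#'   missense/nonsense/frameshift/splice.
#' @param reported_fraction fraction of known-gene causal variants present
#'   in the clinical table as reported pathogenic (the rest are novel).
#' @param hom_fraction fraction of recessive cases homozygous (vs
#'   compound heterozygous).
#' @param sensitivity per-caller per-call detection probability (scalar or
#'   named vector over [ion_callers()]).
#' @param jitter_prob probability that a caller re-expresses an indel in a
#'   right-shifted or padded (unnormalized) form.
#' @param fp_rate mean false positives per caller per sample (Poisson);
#'   drawn from disjoint caller-specific artifact-site catalogs.
#' @param gt_error_rate probability a caller miscalls het as hom or vice
#'   versa.
#' @param background_rate mean benign background variants per proband
#'   (Poisson), drawn from a common-polymorphism catalog with MAFs above
#'   both mode thresholds.
#' @param pedigree_fraction fraction of solved probands with a genotyped
#'   family.
#' @param seg_inconsistency_rate fraction of generated families whose
#'   relative genotypes are deliberately made inconsistent with the truth
#'   mode (for negative tests).
#' @return list of class `ion_cohort_spec`.
#' @export
cohort_spec <- function(n_probands = 1102L,
                        seed,
                        solved_fraction = 245 / 1102,
                        dominant_fraction = 186 / 245,
                        gene_counts = ion_default_gene_counts(),
                        opa1_class_weights = c(splice = 0.36,
                                               nonsense = 0.26,
                                               missense = 0.24,
                                               frameshift = 0.14),
                        default_class_weights = c(missense = 120,
                                                  nonsense = 22,
                                                  frameshift = 20,
                                                  splice = 28) / 190,
                        reported_fraction = 0.6,
                        hom_fraction = 0.5,
                        sensitivity = 0.95,
                        jitter_prob = 0.1,
                        fp_rate = 1,
                        gt_error_rate = 0.02,
                        background_rate = 3,
                        pedigree_fraction = 0.3,
                        seg_inconsistency_rate = 0) {
  if (missing(seed)) stop_trailing("cohort_spec requires a seed")
  callers <- ion_callers()
  if (length(sensitivity) == 1L)
    sensitivity <- setNames(rep(sensitivity, length(callers)), callers)
  stopifnot(all(sensitivity >= 0 & sensitivity <= 1),
            jitter_prob >= 0, jitter_prob <= 1, fp_rate >= 0,
            pedigree_fraction >= 0, pedigree_fraction <= 1,
            solved_fraction >= 0, solved_fraction <= 1)
  norm <- function(x) x / sum(x)
  structure(list(
    n_probands = as.integer(n_probands), seed = as.integer(seed),
    solved_fraction = solved_fraction,
    dominant_fraction = dominant_fraction,
    dominant_gene_freq = norm(gene_counts$dominant),
    recessive_gene_freq = norm(gene_counts$recessive),
    opa1_class_weights = norm(opa1_class_weights),
    default_class_weights = norm(default_class_weights),
    reported_fraction = reported_fraction, hom_fraction = hom_fraction,
    sensitivity = sensitivity, jitter_prob = jitter_prob,
    fp_rate = fp_rate, gt_error_rate = gt_error_rate,
    background_rate = background_rate,
    pedigree_fraction = pedigree_fraction,
    seg_inconsistency_rate = seg_inconsistency_rate),
    class = "ion_cohort_spec")
}

# ---- per-gene causal-site catalogs -----------------------------------

# Enumerate coding SNV sites by class, splice-window SNV sites, and
# frameshift anchor positions for one gene. Cached: depends only on the
# deterministic toy genome.
gene_site_catalog <- function(gene, gobj) {
  cache_key <- paste0("sites_", gene)
  if (!is.null(.toy_cache[[cache_key]])) return(.toy_cache[[cache_key]])
  tx <- gobj$tx[[gene]]
  contig <- gobj$genome[[gene]]
  cdspos <- cds_positions(tx)
  inner <- cdspos[4:(length(cdspos) - 3L)]   # skip start/stop codons
  snv <- data.table::rbindlist(lapply(inner, function(p) {
    refb <- substr(contig, p, p)
    data.table::data.table(pos = p, ref = refb,
                           alt = setdiff(DNA_BASES, refb))
  }))
  cls <- vapply(seq_len(nrow(snv)), function(i)
    classify_consequence(snv$pos[i], snv$ref[i], snv$alt[i], tx,
                         gobj$genome)$consequence, character(1))
  snv[, consequence := cls]
  n_ex <- length(tx$exon_start)
  splice_pos <- integer()
  if (n_ex > 1) for (i in seq_len(n_ex - 1L)) {
    ilo <- tx$exon_end[i] + 1L; ihi <- tx$exon_start[i + 1L] - 1L
    splice_pos <- c(splice_pos, ilo, ilo + 1L, ihi - 1L, ihi)
  }
  splice <- data.table::rbindlist(lapply(splice_pos, function(p) {
    refb <- substr(contig, p, p)
    data.table::data.table(pos = p, ref = refb,
                           alt = setdiff(DNA_BASES, refb))
  }))
  # frameshift anchors: runs of CDS fully inside one exon, away from edges
  fs_anchor <- Filter(function(p) {
    all((p:(p + 3L)) %in% cdspos) &&
      any(tx$exon_start + 3L <= p & p + 3L <= tx$exon_end - 3L)
  }, as.list(inner))
  out <- list(missense = snv[consequence == "missense"],
              nonsense = snv[consequence == "nonsense"],
              splice = splice,
              fs_anchor = unlist(fs_anchor))
  .toy_cache[[cache_key]] <- out
  out
}

draw_causal_variant <- function(gene, class, gobj, forbidden_keys) {
  cat_ <- gene_site_catalog(gene, gobj)
  contig <- gobj$genome[[gene]]
  tx <- gobj$tx[[gene]]
  for (try in 1:50) {
    if (class %in% c("missense", "nonsense", "splice")) {
      tab <- cat_[[class]]
      if (nrow(tab) == 0)
        stop_trailing("no %s site available in toy gene %s", class, gene)
      i <- sample.int(nrow(tab), 1L)
      cand <- list(pos = tab$pos[i], ref = tab$ref[i], alt = tab$alt[i])
    } else if (class == "frameshift") {
      if (!length(cat_$fs_anchor))
        stop_trailing("no frameshift site available in toy gene %s", gene)
      p <- sample(cat_$fs_anchor, 1L)
      len <- sample(1:2, 1L)
      if (runif(1) < 0.5) {                   # deletion
        cand <- list(pos = p,
                     ref = substr(contig, p, p + len),
                     alt = substr(contig, p, p))
      } else {                                # insertion
        ins <- paste(sample(DNA_BASES, len, replace = TRUE),
                     collapse = "")
        cand <- list(pos = p, ref = substr(contig, p, p),
                     alt = paste0(substr(contig, p, p), ins))
      }
    } else stop_trailing("unknown variant class '%s'", class)
    nv <- left_align_trim(cand$pos, cand$ref, cand$alt, contig)
    k <- variant_key(gene, nv$pos, nv$ref, nv$alt)
    if (k %in% forbidden_keys) next
    got <- classify_consequence(nv$pos, nv$ref, nv$alt, tx,
                                gobj$genome)$consequence
    if (got == class)
      return(data.table::data.table(chrom = gene, pos = nv$pos,
                                    ref = nv$ref, alt = nv$alt,
                                    class = class))
  }
  stop_trailing("class/position constraints unsatisfiable in gene %s (%s)",
                gene, class)
}

# ---- representation jitter -------------------------------------------

# Re-express a normalized indel in an equivalent unnormalized form:
# right-shift within its repeat context when possible, otherwise pad with
# the following reference base. Haplotype equivalence is preserved.
jitter_rep <- function(pos, ref, alt, seq) {
  rl <- nchar(ref); al <- nchar(alt)
  pad <- function() {
    nxt <- pos + rl
    if (nxt > nchar(seq)) return(list(pos = pos, ref = ref, alt = alt))
    b <- substr(seq, nxt, nxt)
    list(pos = pos, ref = paste0(ref, b), alt = paste0(alt, b))
  }
  if (runif(1) < 0.5) return(pad())
  H <- paste0(substr(seq, 1L, pos - 1L), alt,
              substr(seq, pos + rl, nchar(seq)))
  best <- NULL
  for (p in (pos + 1L):(pos + 12L)) {
    if (p + rl - 1L > nchar(seq) || p + al - 1L > nchar(H)) break
    rc <- substr(seq, p, p + rl - 1L)
    ac <- substr(H, p, p + al - 1L)
    if (rc == ac) next
    if (substr(seq, 1L, p - 1L) == substr(H, 1L, p - 1L) &&
        substr(seq, p + rl, nchar(seq)) == substr(H, p + al, nchar(H)))
      best <- list(pos = p, ref = rc, alt = ac)
  }
  best %||% pad()
}

# ---- generator --------------------------------------------------------

#' Generate a synthetic cohort
#'
#' @param spec an [cohort_spec()] object.
#' @return list of class `ion_cohort` with elements `spec`, `truth`
#'   (per-proband ground truth), `causal_variants` (one row per causal
#'   allele), `true_calls` (all real variants per proband, causal +
#'   background), `calls` (the noisy per-caller call table), `pedigrees`
#'   (list of `ion_pedigree`), `relative_calls`, `freq_table`,
#'   `clinical_table`, `depth`, and the toy `genome`, `panel`,
#'   `transcripts`, `tx`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "ion_cohort_spec"))
  gobj <- ion_toy_genome()
  with_seed(spec$seed, {
    n <- spec$n_probands
    ids <- sprintf("P%05d", seq_len(n))
    callers <- ion_callers()

    # caller-specific artifact sites (disjoint) and background catalog
    all_pos <- data.table::rbindlist(lapply(names(gobj$genome),
      function(g) data.table::data.table(
        chrom = g, pos = seq_len(nchar(gobj$genome[[g]])))))
    art_idx <- sample.int(nrow(all_pos), 40L * length(callers) + 220L)
    take <- all_pos[art_idx]
    take[, ref := substring(gobj$genome[chrom], pos, pos),
         by = chrom]
    take[, alt := vapply(ref, function(r)
      sample(setdiff(DNA_BASES, r), 1L), "")]
    fp_catalog <- split(take[seq_len(40L * length(callers))],
                        rep(callers, each = 40L))
    bg_catalog <- take[(40L * length(callers) + 1L):nrow(take)]
    bg_catalog[, maf := runif(.N, 0.01, 0.05)]
    bg_catalog[, benign := runif(.N) < 0.2]
    forbidden <- variant_key(take$chrom, take$pos, take$ref, take$alt)

    # ---- truth assignment
    solved <- runif(n) < spec$solved_fraction
    truth_rows <- list(); causal_rows <- list()
    for (i in which(solved)) {
      mode <- if (runif(1) < spec$dominant_fraction) "dominant"
              else "recessive"
      freq <- if (mode == "dominant") spec$dominant_gene_freq
              else spec$recessive_gene_freq
      gene <- sample(names(freq), 1L, prob = freq)
      w <- if (gene == "OPA1" && mode == "dominant")
        spec$opa1_class_weights else spec$default_class_weights
      if (mode == "dominant") {
        v <- draw_causal_variant(gene, sample(names(w), 1L, prob = w),
                                 gobj, forbidden)
        v[, gt_code := 1L]
        zyg <- "het"
      } else if (runif(1) < spec$hom_fraction) {
        v <- draw_causal_variant(gene, sample(names(w), 1L, prob = w),
                                 gobj, forbidden)
        v[, gt_code := 2L]
        zyg <- "hom"
      } else {
        v1 <- draw_causal_variant(gene, sample(names(w), 1L, prob = w),
                                  gobj, forbidden)
        k1 <- variant_key(v1$chrom, v1$pos, v1$ref, v1$alt)
        repeat {
          v2 <- draw_causal_variant(gene, sample(names(w), 1L, prob = w),
                                    gobj, forbidden)
          if (variant_key(v2$chrom, v2$pos, v2$ref, v2$alt) != k1) break
        }
        v <- rbind(v1, v2)
        v[, gt_code := 1L]
        zyg <- "compound_het"
      }
      v[, `:=`(sample_id = ids[i], gene = gene, mode = mode,
               zygosity = zyg)]
      causal_rows[[length(causal_rows) + 1L]] <- v
      truth_rows[[length(truth_rows) + 1L]] <- data.table::data.table(
        sample_id = ids[i], gene = gene, mode = mode, zygosity = zyg,
        causal_keys = paste(sort(variant_key(v$chrom, v$pos, v$ref,
                                             v$alt)), collapse = ","))
    }
    causal <- if (length(causal_rows)) data.table::rbindlist(causal_rows)
      else data.table::data.table(
        chrom = character(), pos = integer(), ref = character(),
        alt = character(), class = character(), gt_code = integer(),
        sample_id = character(), gene = character(), mode = character(),
        zygosity = character())
    truth <- if (length(truth_rows)) data.table::rbindlist(truth_rows)
      else data.table::data.table(sample_id = character(),
                                  gene = character(), mode = character(),
                                  zygosity = character(),
                                  causal_keys = character())

    # ---- packaged tables: frequency + clinical
    ckeys <- unique(causal[, .(chrom, pos, ref, alt, gene)])
    pan <- gobj$panel
    known <- pan[status == "known", symbol]
    ckeys[, reported := gene %in% known &
             runif(.N) < spec$reported_fraction]
    freq_entries <- list(
      bg_catalog[, .(chrom, pos, ref, alt, maf)],
      data.table::rbindlist(lapply(callers, function(cl)
        fp_catalog[[cl]][, .(chrom, pos, ref, alt)]))[, maf := 0.02])
    rare <- ckeys[runif(nrow(ckeys)) < 0.5]   # half of causal: tiny MAF
    if (nrow(rare))
      freq_entries <- c(freq_entries,
                        list(rare[, .(chrom, pos, ref, alt,
                                      maf = runif(.N, 1e-6, 5e-5))]))
    freq_table <- unique(data.table::rbindlist(freq_entries),
                         by = c("chrom", "pos", "ref", "alt"))
    data.table::setkey(freq_table, chrom, pos, ref, alt)
    clin_entries <- list(
      ckeys[reported == TRUE,
            .(chrom, pos, ref, alt, significance = "pathogenic")],
      bg_catalog[benign == TRUE,
                 .(chrom, pos, ref, alt, significance = "benign")])
    clinical_table <- unique(data.table::rbindlist(clin_entries),
                             by = c("chrom", "pos", "ref", "alt"))
    data.table::setkey(clinical_table, chrom, pos, ref, alt)

    # ---- true per-proband call set (causal + background)
    n_bg <- rpois(n, spec$background_rate)
    bg_rows <- lapply(seq_len(n), function(i) {
      k <- min(n_bg[i], nrow(bg_catalog))
      if (k == 0L) return(NULL)
      b <- bg_catalog[sample.int(nrow(bg_catalog), k)]
      data.table::data.table(sample_id = ids[i], chrom = b$chrom,
                             pos = b$pos, ref = b$ref, alt = b$alt,
                             gt_code = ifelse(runif(k) < 0.1, 2L, 1L),
                             origin = "background")
    })
    true_calls <- data.table::rbindlist(c(
      list(causal[, .(sample_id, chrom, pos, ref, alt, gt_code,
                      origin = "causal")]),
      bg_rows))

    # ---- noisy per-caller call sets
    call_rows <- lapply(callers, function(cl) {
      keep <- runif(nrow(true_calls)) < spec$sensitivity[[cl]]
      cc <- true_calls[keep]
      if (nrow(cc)) {
        code <- cc$gt_code
        flip <- runif(nrow(cc)) < spec$gt_error_rate
        code[flip] <- 3L - code[flip]        # het <-> hom
        cc[, gt_code := code]
        is_indel <- nchar(cc$ref) != nchar(cc$alt)
        jit <- which(is_indel & runif(nrow(cc)) < spec$jitter_prob)
        for (j in jit) {
          r <- jitter_rep(cc$pos[j], cc$ref[j], cc$alt[j],
                          gobj$genome[[cc$chrom[j]]])
          data.table::set(cc, j, "pos", r$pos)
          data.table::set(cc, j, "ref", r$ref)
          data.table::set(cc, j, "alt", r$alt)
        }
      }
      n_fp <- rpois(n, spec$fp_rate)
      fp_rows <- lapply(which(n_fp > 0L), function(i) {
        k <- min(n_fp[i], nrow(fp_catalog[[cl]]))
        f <- fp_catalog[[cl]][sample.int(.N, k)]
        data.table::data.table(sample_id = ids[i], chrom = f$chrom,
                               pos = f$pos, ref = f$ref, alt = f$alt,
                               gt_code = 1L, origin = "fp")
      })
      out <- data.table::rbindlist(c(list(cc), fp_rows),
                                   use.names = TRUE, fill = TRUE)
      if (nrow(out)) {
        out[, caller := cl]
        out[, filter := ifelse(origin == "fp" & runif(.N) < 0.3,
                               "q20", "PASS")]
      }
      out
    })
    calls <- data.table::rbindlist(call_rows)
    if (nrow(calls)) {
      calls[, gt := code_to_gt(gt_code)]
      calls[, quality_pass := filter %in% c("PASS", ".")]
    } else {
      calls <- data.table::data.table(
        sample_id = character(), chrom = character(), pos = integer(),
        ref = character(), alt = character(), gt_code = integer(),
        origin = character(), caller = character(), filter = character(),
        gt = character(), quality_pass = logical())
    }

    # ---- pedigrees + relative genotypes
    ped <- make_pedigrees(truth, causal, spec$pedigree_fraction,
                          spec$seg_inconsistency_rate)

    # ---- depth track over the design
    depth <- make_depth_track(pan)

    structure(list(
      spec = spec, ids = ids, truth = truth, causal_variants = causal,
      true_calls = true_calls, calls = calls,
      pedigrees = ped$pedigrees, relative_calls = ped$relative_calls,
      freq_table = freq_table, clinical_table = clinical_table,
      depth = depth, genome = gobj$genome, panel = gobj$panel,
      transcripts = gobj$transcripts, tx = gobj$tx),
      class = "ion_cohort")
  })
}

#' Build pedigrees and relative genotypes for a fraction of solved cases
#'
#' Families are trios (optionally plus one sib). Dominant: the causal
#' variant is carried by one affected parent; recessive: both parents are
#' unaffected carriers (each carrying one allele of a compound-het pair).
#' `seg_inconsistency_rate` deliberately corrupts that structure (the
#' transmitting affected parent loses the variant, or an unaffected
#' parent becomes biallelic) so segregation checks can be tested
#' negatively.
#'
#' @param truth truth table from [generate_cohort()].
#' @param causal causal-variant table.
#' @param pedigree_fraction fraction of solved probands given a family.
#' @param seg_inconsistency_rate see above.
#' @return list with `pedigrees` (list of `ion_pedigree`) and
#'   `relative_calls` (`sample_id`, `key`, `gt_code`).
#' @export
make_pedigrees <- function(truth, causal, pedigree_fraction,
                           seg_inconsistency_rate = 0) {
  peds <- list(); rel_rows <- list()
  if (nrow(truth) == 0 || pedigree_fraction == 0)
    return(list(pedigrees = peds,
                relative_calls = data.table::data.table(
                  sample_id = character(), key = character(),
                  gt_code = integer())))
  pick <- which(runif(nrow(truth)) < pedigree_fraction)
  for (i in pick) {
    pro <- truth$sample_id[i]
    fam <- paste0("F_", pro)
    fid <- paste0(pro, "_fa"); mid <- paste0(pro, "_mo")
    sib <- if (runif(1) < 0.5) paste0(pro, "_sib") else NULL
    keys <- strsplit(truth$causal_keys[i], ",", fixed = TRUE)[[1]]
    mode <- truth$mode[i]
    inject <- runif(1) < seg_inconsistency_rate
    gt <- list()
    if (mode == "dominant") {
      transmitter <- sample(c(fid, mid), 1L)
      other <- setdiff(c(fid, mid), transmitter)
      gt[[transmitter]] <- setNames(rep(1L, length(keys)), keys)
      gt[[other]] <- setNames(rep(0L, length(keys)), keys)
      aff <- c(pro, transmitter)
      if (!is.null(sib)) {
        carries <- runif(1) < 0.5
        gt[[sib]] <- setNames(rep(as.integer(carries), length(keys)),
                              keys)
        if (carries) aff <- c(aff, sib)
      }
      if (inject) gt[[transmitter]][] <- 0L
    } else {
      if (length(keys) == 1L) {
        gt[[fid]] <- setNames(1L, keys)
        gt[[mid]] <- setNames(1L, keys)
        if (!is.null(sib)) {
          s <- sample(0:2, 1L, prob = c(.25, .5, .25))
          gt[[sib]] <- setNames(s, keys)
        }
      } else {
        gt[[fid]] <- setNames(c(1L, 0L), keys)
        gt[[mid]] <- setNames(c(0L, 1L), keys)
        if (!is.null(sib)) {
          from_fa <- runif(1) < 0.5; from_mo <- runif(1) < 0.5
          gt[[sib]] <- setNames(c(as.integer(from_fa),
                                  as.integer(from_mo)), keys)
        }
      }
      aff <- pro
      if (!is.null(sib) && all(gt[[sib]] >= 1L) &&
          (length(keys) == 2L || gt[[sib]][1] == 2L))
        aff <- c(aff, sib)
      if (inject) gt[[fid]][] <- 2L           # unaffected parent biallelic
    }
    members <- c(pro, fid, mid, sib)
    ped <- data.table::data.table(
      family = fam, id = members,
      father = c(fid, "0", "0", if (!is.null(sib)) fid),
      mother = c(mid, "0", "0", if (!is.null(sib)) mid),
      sex = c(sample(c("1", "2"), 1L), "1", "2",
              if (!is.null(sib)) sample(c("1", "2"), 1L)),
      affected = ifelse(members %in% aff, "yes", "no"))
    data.table::setattr(ped, "proband", pro)
    data.table::setattr(ped, "class", c("ion_pedigree", class(ped)))
    peds[[fam]] <- ped
    for (who in names(gt)) {
      rr <- data.table::data.table(sample_id = who,
                                   k = names(gt[[who]]),
                                   gt_code = unname(gt[[who]]))
      data.table::setnames(rr, "k", "key")
      rel_rows[[length(rel_rows) + 1L]] <- rr
    }
  }
  rel <- if (length(rel_rows)) data.table::rbindlist(rel_rows)
    else data.table::data.table(sample_id = character(),
                                key = character(), gt_code = integer())
  list(pedigrees = peds, relative_calls = rel)
}

#' Simulate a per-base depth track over the panel design
#'
#' Roughly 95% of design bases are deeply covered (> 100x) and ~5% fall
#' in short low-coverage runs (amplicon dropouts), mirroring typical
#' amplicon-panel behaviour.
#'
#' @param panel panel table.
#' @return depth table (`chrom`, `pos`, `depth`).
#' @export
make_depth_track <- function(panel) {
  regs <- panel_regions(panel)
  rows <- lapply(seq_len(nrow(regs)), function(i) {
    pos <- regs$start[i]:regs$end[i]
    np <- length(pos)
    low <- logical(np)
    state <- FALSE
    for (j in seq_len(np)) {
      state <- if (state) runif(1) > 1 / 20 else runif(1) < 0.0025
      low[j] <- state
    }
    depth <- ifelse(low, sample(0:20, np, replace = TRUE),
                    101L + rpois(np, 200))
    data.table::data.table(chrom = regs$chrom[i], pos = pos,
                           depth = as.integer(depth))
  })
  data.table::rbindlist(rows)
}

#' Write a generated cohort to disk in standard formats
#'
#' Per-caller single-sample VCFs (same-position records of one caller are
#' merged into multiallelic lines), a PED file, the truth table, frequency
#' and clinical TSVs, panel and transcript tables, the depth track and the
#' toy reference FASTA. Intended for small demonstration cohorts; analysis
#' at scale runs on the in-memory tables.
#'
#' @param cohort an `ion_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vcf_dir <- file.path(dir, "calls")
  dir.create(vcf_dir, showWarnings = FALSE)
  calls <- cohort$calls
  for (s in unique(calls$sample_id)) {
    sdir <- file.path(vcf_dir, s)
    dir.create(sdir, showWarnings = FALSE)
    for (cl in unique(calls[sample_id == s, caller])) {
      cc <- calls[sample_id == s & caller == cl]
      write_caller_vcf(cc, s, file.path(sdir, paste0(cl, ".vcf")))
    }
  }
  if (length(cohort$pedigrees))
    write_ped(cohort$pedigrees, file.path(dir, "families.ped"))
  data.table::fwrite(cohort$truth, file.path(dir, "truth.tsv"),
                     sep = "\t")
  write_freq_table(cohort$freq_table, file.path(dir, "freq_table.tsv"))
  write_clinical_table(cohort$clinical_table,
                       file.path(dir, "clinical_table.tsv"))
  write_panel(cohort$panel, file.path(dir, "panel_genes.tsv"))
  write_transcripts(cohort$transcripts,
                    file.path(dir, "transcripts.tsv"))
  write_depth(cohort$depth, file.path(dir, "depth.tsv"))
  write_reference_fasta(cohort$genome, file.path(dir, "reference.fasta"))
  write_opa1_domains(ion_opa1_domains(),
                     file.path(dir, "opa1_domains.tsv"))
  invisible(dir)
}

# Serialize one caller's calls for one sample, merging same-site records
# into multiallelic lines (as callers do), with GT indices rewritten.
write_caller_vcf <- function(cc, sample_id, path) {
  dt <- data.table::as.data.table(cc)
  recs <- dt[, {
    alts <- alt
    codes <- gt_code
    if (.N == 1L) {
      g <- code_to_gt(codes)
    } else {
      het <- which(codes >= 1L)
      g <- if (length(het) >= 2L) paste(het[1], het[2], sep = "/")
        else if (codes[het[1]] == 2L) paste(het[1], het[1], sep = "/")
        else paste(0, het[1], sep = "/")
    }
    list(alt = paste(alts, collapse = ","), gt = g,
         filter = filter[1])
  }, by = .(chrom, pos, ref)]
  vcf <- recs[, .(chrom, pos, id = ".", ref, alt, qual = ".", filter,
                  info = ".")]
  vcf[[sample_id]] <- recs$gt
  write_vcf(vcf, path, samples = sample_id)
}
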