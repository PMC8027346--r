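test_that("LHON pre-screen matches exact alleles only", {
  hit <- data.table(pos = c(100L, 11778L), ref = c("A", "G"),
                    alt = c("T", "A"))
  expect_equal(lhon_screen(hit), "excluded")
  expect_equal(lhon_screen(data.table(pos = integer(),
                                      ref = character(),
                                      alt = character())), "retained")
  near_miss <- data.table(pos = 11778L, ref = "G", alt = "C")
  expect_equal(lhon_screen(near_miss), "retained")
  expect_equal(lhon_screen(data.table(pos = c(3460L, 14484L),
                                      ref = c("G", "T"),
                                      alt = c("A", "C"))), "excluded")
})

test_that("MAF filter applies strict mode-specific thresholds", {
  th <- maf_thresholds()
  expect_false(maf_filter(0.01, "dominant", th))
  expect_true(maf_filter(NA_real_, "dominant", th))
  expect_true(maf_filter(NA_real_, "recessive", th))
  # straddles the two thresholds
  expect_false(maf_filter(0.001, "dominant", th))
  expect_true(maf_filter(0.001, "recessive", th))
  # boundary values are rejected (strict <)
  expect_false(maf_filter(1e-4, "dominant", th))
  expect_false(maf_filter(5e-3, "recessive", th))
  expect_true(maf_filter(9.99e-5, "dominant", th))
  expect_error(maf_thresholds(0.01, 0.001), "dominant_max")
})

test_that("tier ladder: reported > novel LoF > novel missense > candidate VUS", {
  expect_equal(assign_tier("missense", "pathogenic", "known"),
               "T1_reported_pathogenic")
  expect_equal(assign_tier("splice", "likely_pathogenic", "known"),
               "T1_reported_pathogenic")
  expect_equal(assign_tier("nonsense", "unreported", "known"),
               "T2_novel_lof")
  expect_equal(assign_tier("frameshift", "unreported", "known"),
               "T2_novel_lof")
  expect_equal(assign_tier("missense", "unreported", "known"),
               "T3_novel_missense")
  expect_equal(assign_tier("missense", "unreported", "candidate"),
               "T4_candidate_vus")
  expect_equal(assign_tier("nonsense", "unreported", "candidate"),
               "T4_candidate_vus")
  expect_true(is.na(assign_tier("missense", "benign", "known")))
  expect_true(is.na(assign_tier("synonymous", "unreported", "known")))
  expect_true(is.na(assign_tier("intronic", "unreported", "known")))
})

test_that("genotype pattern detection: hom, compound het, monoallelic", {
  expect_equal(detect_genotype_pattern(2L), "biallelic")
  expect_equal(detect_genotype_pattern(c(1L, 1L)), "biallelic")
  expect_equal(detect_genotype_pattern(1L), "monoallelic_het")
  expect_equal(detect_genotype_pattern(c(1L, NA_integer_)),
               "monoallelic_het")
})

make_trio <- function(aff_dad = "no") {
  ped <- data.table(family = "F1", id = c("kid", "dad", "mom"),
                    father = c("dad", "0", "0"),
                    mother = c("mom", "0", "0"),
                    sex = c("1", "1", "2"),
                    affected = c("yes", aff_dad, "no"))
  setattr(ped, "proband", "kid")
  ped
}

test_that("dominant segregation: carrier patterns decide consistency", {
  ped <- make_trio(aff_dad = "yes")
  k <- "OPA1:100:A:C"
  rel <- data.table(sample_id = c("dad", "mom"), gt_code = c(1L, 0L))
  rel[, key := k]
  expect_equal(check_segregation(k, "dominant", ped, rel), "consistent")
  # affected relative without the variant
  rel2 <- data.table(sample_id = c("dad", "mom"), gt_code = c(0L, 0L))
  rel2[, key := k]
  expect_equal(check_segregation(k, "dominant", ped, rel2),
               "inconsistent")
  # unaffected carrier: strict fails, relaxed accepts
  ped2 <- make_trio(aff_dad = "no")
  rel3 <- data.table(sample_id = c("dad", "mom"), gt_code = c(1L, 0L))
  rel3[, key := k]
  expect_equal(check_segregation(k, "dominant", ped2, rel3),
               "inconsistent")
  expect_equal(check_segregation(k, "dominant", ped2, rel3,
                                 allow_unaffected_carriers = TRUE),
               "consistent")
  # singleton / no genotyped relatives
  expect_equal(check_segregation(k, "dominant", ped, rel[0]),
               "untested")
  expect_equal(check_segregation(k, "dominant", NULL, NULL), "untested")
})

test_that("recessive segregation: carrier parents consistent, cis parent not", {
  ped <- make_trio()
  ks <- c("WFS1:10:A:C", "WFS1:90:G:T")
  rel <- rbindlist(list(
    data.table(sample_id = "dad", gt_code = c(1L, 0L)),
    data.table(sample_id = "mom", gt_code = c(0L, 1L))))
  rel[, key := rep(ks, 2)]
  expect_equal(check_segregation(ks, "recessive", ped, rel),
               "consistent")
  # one parent carries both alleles: presumed cis, inconsistent
  rel_cis <- rbindlist(list(
    data.table(sample_id = "dad", gt_code = c(1L, 1L)),
    data.table(sample_id = "mom", gt_code = c(0L, 0L))))
  rel_cis[, key := rep(ks, 2)]
  expect_equal(check_segregation(ks, "recessive", ped, rel_cis),
               "inconsistent")
  # unaffected relative biallelic for a homozygous causal variant
  relhom <- data.table(sample_id = "dad", gt_code = 2L)
  relhom[, key := ks[1]]
  expect_equal(check_segregation(ks[1], "recessive", ped, relhom),
               "inconsistent")
})

# classify_case scenario table: explicit expected outcomes for the
# tier x pattern x gene-mode factorial (probed through the public API)
test_that("classify_case resolves tiers, modes and both-mode genes", {
  panel <- ion_default_panel()
  run1 <- function(v) classify_case(v, panel)

  # T1 reported het in OPA1 -> solved dominant
  cc <- run1(ann_row("OPA1", "missense", 1L, clinical = "pathogenic",
                     pos = 100L))
  expect_equal(cc$status, "solved_dominant")
  expect_equal(cc$tier, "T1_reported_pathogenic")
  expect_equal(cc$gene, "OPA1")
  expect_equal(cc$segregation, "untested")

  # homozygous novel nonsense in TMEM126A -> solved recessive
  cc <- run1(ann_row("TMEM126A", "nonsense", 2L, pos = 55L))
  expect_equal(cc$status, "solved_recessive")
  expect_equal(cc$tier, "T2_novel_lof")
  expect_equal(cc$n_causal, 1L)

  # compound het in RTN4IP1 -> solved recessive with two causal keys
  v <- rbind(ann_row("RTN4IP1", "missense", 1L, pos = 10L),
             ann_row("RTN4IP1", "frameshift", 1L, pos = 90L))
  cc <- run1(v)
  expect_equal(cc$status, "solved_recessive")
  expect_equal(cc$n_causal, 2L)
  # pair tier is the weaker allele's tier
  expect_equal(cc$tier, "T3_novel_missense")

  # single het in a recessive-only gene -> unsolved, flagged
  cc <- run1(ann_row("RTN4IP1", "missense", 1L, pos = 10L))
  expect_equal(cc$status, "unsolved")
  expect_match(cc$flags, "monoallelic_recessive_hit:RTN4IP1")

  # candidate-gene variant -> VUS, not solved
  cc <- run1(ann_row("CAND2", "missense", 1L, pos = 33L))
  expect_equal(cc$status, "vus_candidate")
  expect_equal(cc$tier, "T4_candidate_vus")
  expect_equal(cc$mode, "dominant")

  # both-mode gene with dominant het AND biallelic pair: biallelic wins
  v <- rbind(ann_row("WFS1", "missense", 1L, clinical = "pathogenic",
                     pos = 10L),
             ann_row("WFS1", "nonsense", 1L, pos = 20L),
             ann_row("WFS1", "missense", 1L, pos = 30L))
  cc <- run1(v)
  expect_equal(cc$status, "solved_recessive")
  expect_match(cc$flags, "both_modes_constructible:WFS1")
  expect_equal(cc$n_causal, 2L)

  # T1 in one gene beats T2 in another
  v <- rbind(ann_row("OPA1", "nonsense", 1L, pos = 10L),
             ann_row("MFN2", "missense", 1L, clinical = "pathogenic",
                     pos = 20L))
  cc <- run1(v)
  expect_equal(cc$gene, "MFN2")
  expect_equal(cc$tier, "T1_reported_pathogenic")

  # MAF gates by mode: 0.001 fails dominant but passes recessive
  v <- ann_row("MFN2", "missense", 1L, maf = 0.001, pos = 40L)
  expect_equal(run1(v)$status, "unsolved")
  v <- rbind(ann_row("RTN4IP1", "missense", 1L, maf = 0.001, pos = 10L),
             ann_row("RTN4IP1", "missense", 1L, maf = 0.001, pos = 60L))
  expect_equal(run1(v)$status, "solved_recessive")

  # benign and synonymous variants never qualify
  v <- rbind(ann_row("OPA1", "missense", 1L, clinical = "benign",
                     pos = 10L),
             ann_row("OPA1", "synonymous", 1L, pos = 20L))
  expect_equal(run1(v)$status, "unsolved")

  # hom-ref / missing genotypes are ignored
  v <- ann_row("OPA1", "missense", 0L, clinical = "pathogenic",
               pos = 10L)
  expect_equal(run1(v)$status, "unsolved")

  # LHON-positive probands are excluded before any autosomal logic
  cc <- classify_case(ann_row("OPA1", "missense", 1L,
                              clinical = "pathogenic", pos = 10L),
                      panel,
                      mt_variants = data.table(pos = 11778L, ref = "G",
                                               alt = "A"))
  expect_equal(cc$status, "excluded_lhon")
})

test_that("adding a reported-pathogenic variant never lowers the tier", {
  panel <- ion_default_panel()
  t1 <- ann_row("AFG3L2", "missense", 1L, clinical = "pathogenic",
                pos = 200L)
  bases <- list(
    data.table(),                                      # unsolved
    ann_row("DNM1L", "missense", 1L, pos = 10L),       # T3 solved
    ann_row("CAND1", "missense", 1L, pos = 10L))       # T4 vus
  for (base in bases) {
    before <- classify_case(base, panel)
    after <- classify_case(rbind(base, t1, fill = TRUE), panel)
    expect_equal(after$tier, "T1_reported_pathogenic")
    rank_before <- match(before$tier, ionprior:::TIERS)
    expect_true(is.na(rank_before) ||
                  match(after$tier, ionprior:::TIERS) <= rank_before)
  }
})

test_that("segregation status orders candidates within a tier", {
  panel <- ion_default_panel()
  ped <- make_trio(aff_dad = "yes")
  # two T3 candidates in different dominant genes; one segregates,
  # the other is contradicted in the affected father
  v1 <- ann_row("MFN2", "missense", 1L, pos = 100L)
  v2 <- ann_row("SSBP1", "missense", 1L, pos = 200L)
  k1 <- variant_key(v1$chrom, v1$pos, v1$ref, v1$alt)
  k2 <- variant_key(v2$chrom, v2$pos, v2$ref, v2$alt)
  rel <- data.table(sample_id = c("dad", "dad"),
                    gt_code = c(0L, 1L))
  rel[, key := c(k1, k2)]
  cc <- classify_case(rbind(v1, v2), panel, pedigree = ped,
                      relative_calls = rel)
  expect_equal(cc$gene, "SSBP1")
  expect_equal(cc$segregation, "consistent")
})
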