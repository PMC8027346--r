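noise_free_spec <- function(n, seed, jitter_prob = 0, ...) {
  cohort_spec(n_probands = n, seed = seed, sensitivity = 1,
              jitter_prob = jitter_prob, fp_rate = 0,
              gt_error_rate = 0, ...)
}

test_that("the generator is deterministic given the seed", {
  a <- generate_cohort(cohort_spec(n_probands = 60, seed = 9))
  b <- generate_cohort(cohort_spec(n_probands = 60, seed = 9))
  expect_identical(a$calls, b$calls)
  expect_identical(a$truth, b$truth)
  expect_identical(a$relative_calls, b$relative_calls)
  expect_identical(a$freq_table, b$freq_table)
  d <- generate_cohort(cohort_spec(n_probands = 60, seed = 10))
  expect_false(identical(a$calls, d$calls))
})

test_that("noise-free cohorts give every caller exactly the truth set", {
  co <- generate_cohort(noise_free_spec(80, seed = 21))
  tc <- co$true_calls[, .(sample_id, chrom, pos, ref, alt, gt_code)]
  setorder(tc, sample_id, chrom, pos, ref, alt)
  for (cl in ion_callers()) {
    cc <- co$calls[caller == cl,
                   .(sample_id, chrom, pos, ref, alt, gt_code)]
    setorder(cc, sample_id, chrom, pos, ref, alt)
    expect_equal(cc, tc, info = cl)
  }
  expect_true(all(co$calls$quality_pass))
})

test_that("jitter changes raw indel keys but never normalized keys", {
  co <- generate_cohort(noise_free_spec(150, seed = 33, jitter_prob = 1))
  truth_keys <- co$true_calls[, variant_key(chrom, pos, ref, alt)]
  indel <- co$calls[nchar(ref) != nchar(alt) | nchar(ref) > 1]
  raw_keys <- indel[, variant_key(chrom, pos, ref, alt)]
  expect_gt(sum(!raw_keys %in% truth_keys), 0)  # jitter visibly applied
  norm <- normalize_calls(co$calls, co$genome)
  norm_keys <- norm[, variant_key(chrom, pos, ref, alt)]
  expect_true(all(norm_keys %in% truth_keys))
  # haplotype equivalence of every jittered representation
  jit <- co$calls[!variant_key(chrom, pos, ref, alt) %in% truth_keys]
  nj <- normalize_calls(jit, co$genome)
  for (i in seq_len(min(nrow(jit), 200))) {
    seqc <- co$genome[[jit$chrom[i]]]
    expect_equal(apply_edit(seqc, jit$pos[i], jit$ref[i], jit$alt[i]),
                 apply_edit(seqc, nj$pos[i], nj$ref[i], nj$alt[i]))
  }
})

test_that("causal variants carry the class, zygosity and tables they claim", {
  co <- generate_cohort(noise_free_spec(120, seed = 44))
  cv <- co$causal_variants
  expect_true(all(cv$class %in% c("missense", "nonsense", "frameshift",
                                  "splice")))
  for (i in seq_len(nrow(cv))) {
    got <- classify_consequence(cv$pos[i], cv$ref[i], cv$alt[i],
                                co$tx[[cv$gene[i]]],
                                co$genome)$consequence
    expect_equal(got, cv$class[i])
  }
  # recessive truths are biallelic, dominant het
  expect_true(all(co$truth[mode == "dominant", zygosity] == "het"))
  expect_true(all(co$truth[mode == "recessive", zygosity] %in%
                    c("hom", "compound_het")))
  # background variants are common (fail both mode filters)
  bg <- co$true_calls[origin == "background"]
  bg_ann <- merge(bg, co$freq_table,
                  by = c("chrom", "pos", "ref", "alt"))
  expect_true(all(bg_ann$maf > 5e-3))
  # causal keys never collide with the background/FP catalogs
  ck <- cv[, variant_key(chrom, pos, ref, alt)]
  expect_false(any(ck %in% bg[, variant_key(chrom, pos, ref, alt)]))
})

test_that("pedigrees encode the truth mode and can be broken on demand", {
  co <- generate_cohort(noise_free_spec(200, seed = 55,
                                        pedigree_fraction = 1))
  expect_gt(length(co$pedigrees), 0)
  for (fam in co$pedigrees) {
    pro <- attr(fam, "proband")
    tr <- co$truth[sample_id == pro]
    keys <- strsplit(tr$causal_keys, ",")[[1]]
    seg <- check_segregation(keys, tr$mode, fam, co$relative_calls)
    expect_equal(seg, "consistent",
                 info = paste(pro, tr$mode, tr$zygosity))
    # compound-het parents each carry exactly one allele
    if (tr$zygosity == "compound_het") {
      par_ids <- fam[id == pro, c(father, mother)]
      for (p in par_ids) {
        g <- co$relative_calls[sample_id == p & key %in% keys, gt_code]
        expect_equal(sum(g > 0), 1L)
      }
    }
  }
  # injected inconsistency flips every tested family
  co2 <- generate_cohort(noise_free_spec(200, seed = 55,
                                         pedigree_fraction = 1,
                                         seg_inconsistency_rate = 1))
  for (fam in co2$pedigrees) {
    pro <- attr(fam, "proband")
    tr <- co2$truth[sample_id == pro]
    keys <- strsplit(tr$causal_keys, ",")[[1]]
    expect_equal(check_segregation(keys, tr$mode, fam,
                                   co2$relative_calls),
                 "inconsistent")
  }
})

test_that("written cohorts round-trip through the standard formats", {
  co <- generate_cohort(cohort_spec(n_probands = 6, seed = 66))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "families.ped")) ||
                length(co$pedigrees) == 0)
  genome_back <- read_reference_fasta(file.path(dir, "reference.fasta"))
  expect_equal(genome_back, co$genome)
  tx_back <- transcript_list(read_transcripts(
    file.path(dir, "transcripts.tsv")))
  expect_equal(tx_back$OPA1, co$tx$OPA1)
  freq_back <- read_freq_table(file.path(dir, "freq_table.tsv"))
  expect_equal(freq_back, co$freq_table, ignore_attr = TRUE,
               tolerance = 1e-12)
  # per-caller VCFs parse back to the caller's call set (normalized keys)
  s <- co$ids[1]
  cl <- "gatk_ug"
  path <- file.path(dir, "calls", s, paste0(cl, ".vcf"))
  if (file.exists(path)) {
    v <- read_vcf(path, caller = cl)
    dec <- decompose(v)
    orig <- co$calls[sample_id == s & caller == cl]
    expect_setequal(variant_key(dec$chrom, dec$pos, dec$ref, dec$alt),
                    variant_key(orig$chrom, orig$pos, orig$ref,
                                orig$alt))
  }
})

test_that("cohort composition follows the configured frequencies at scale", {
  co <- generate_cohort(noise_free_spec(3000, seed = 77))
  frac_solved <- nrow(co$truth) / 3000
  expect_lt(abs(frac_solved - 245 / 1102), 3 * sqrt(0.22 * 0.78 / 3000))
  dom_frac <- co$truth[, mean(mode == "dominant")]
  expect_lt(abs(dom_frac - 186 / 245),
            3 * sqrt((186 / 245) * (59 / 245) / nrow(co$truth)))
})

test_that("spec validation rejects missing seeds and bad probabilities", {
  expect_error(cohort_spec(n_probands = 10), "seed")
  expect_error(cohort_spec(n_probands = 10, seed = 1, jitter_prob = 2))
})
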