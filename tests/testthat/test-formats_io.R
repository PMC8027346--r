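random_vcf_table <- function(n, samples = c("S1", "S2")) {
  dt <- data.table(
    chrom = sample(c("OPA1", "WFS1", "chr3"), n, replace = TRUE),
    pos = sample.int(5000L, n),
    id = ".",
    ref = replicate(n, paste(sample(c("A", "C", "G", "T"),
                                    sample(1:3, 1), replace = TRUE),
                             collapse = "")),
    qual = ".",
    filter = sample(c("PASS", ".", "q20"), n, replace = TRUE),
    info = ".")
  dt[, alt := vapply(ref, function(r) {
    alts <- replicate(sample(1:2, 1), {
      repeat {
        a <- paste(sample(c("A", "C", "G", "T"), sample(1:3, 1),
                          replace = TRUE), collapse = "")
        if (a != r) return(a)
      }
    })
    paste(unique(alts), collapse = ",")
  }, "")]
  for (s in samples) {
    dt[[s]] <- vapply(dt$alt, function(a) {
      k <- length(strsplit(a, ",")[[1]])
      paste(sample(0:k, 2, replace = TRUE), collapse = "/")
    }, "")
  }
  dt <- unique(dt, by = c("chrom", "pos", "ref", "alt"))
  dt
}

test_that("VCF read/write round-trips randomized records", {
  set.seed(41)
  samples <- c("S1", "S2")
  dt <- random_vcf_table(60, samples)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(dt, f, samples = samples)
  back <- read_vcf(f, caller = "varscan2")
  expect_equal(nrow(back), nrow(dt))
  expect_true(all(back$caller == "varscan2"))
  setorder(dt, chrom, pos, ref, alt)
  for (col in c("chrom", "pos", "ref", "alt", "filter", samples))
    expect_equal(back[[col]], dt[[col]], info = col)
  expect_equal(back$quality_pass, dt$filter %in% c("PASS", "."))
  # second round trip is the identity
  f2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("written VCFs agree with an independent parser (vcfR)", {
  skip_if_not_installed("vcfR")
  set.seed(42)
  dt <- random_vcf_table(40, "S1")
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(dt, f, samples = "S1")
  v <- suppressWarnings(vcfR::read.vcfR(f, verbose = FALSE))
  setorder(dt, chrom, pos, ref, alt)
  expect_equal(as.character(v@fix[, "CHROM"]), dt$chrom)
  expect_equal(as.integer(v@fix[, "POS"]), dt$pos)
  expect_equal(as.character(v@fix[, "REF"]), dt$ref)
  expect_equal(as.character(v@fix[, "ALT"]), dt$alt)
  expect_equal(unname(v@gt[, "S1"]), dt$S1)
})

test_that("VCF parsing: minimal record, multiallelic passthrough, errors", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT", "S1", sep = "\t"),
               "3\t100\t.\tA\tC\t50\tPASS\t.\tGT\t0/1",
               "3\t200\t.\tA\tC,G\t50\tPASS\t.\tGT\t1/2"), f)
  v <- read_vcf(f, caller = "lofreq")
  expect_equal(v$pos, c(100L, 200L))
  expect_equal(v$alt, c("C", "C,G"))     # decomposition happens later
  expect_equal(v$S1, c("0/1", "1/2"))
  expect_true(all(v$quality_pass))

  bad1 <- withr::local_tempfile()
  writeLines(c("##fileformat=VCFv4.2",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT", "S1", sep = "\t"),
               "3\t100\t.\tA\tC\t50\tPASS\t.\tGT\t0/1",
               "3\tnope\t.\tA\tC\t50\tPASS\t.\tGT\t0/1"), bad1)
  expect_error(read_vcf(bad1), "line 4")

  bad2 <- withr::local_tempfile()
  writeLines(c("##fileformat=VCFv4.2",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT", "S1", sep = "\t"),
               "3\t100\t.\tA\tC\t50\tPASS\t.\tDP\t13"), bad2)
  expect_error(read_vcf(bad2), "GT")

  bad3 <- withr::local_tempfile()
  writeLines(c("##fileformat=VCFv4.2",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT", "S1", sep = "\t"),
               "3\t100\t.\tA\tC\t50\tPASS\t.\tGT\t0/5"), bad3)
  expect_error(read_vcf(bad3), "alleles")
})

test_that("PED parsing: probands, singletons, multiple families, errors", {
  f <- withr::local_tempfile(fileext = ".ped")
  writeLines(c("F1\tkid\tdad\tmom\t1\t2",
               "F1\tdad\t0\t0\t1\t1",
               "F1\tmom\t0\t0\t2\t1",
               "F2\tsolo\t0\t0\t2\t2"), f)
  peds <- read_ped(f)
  expect_length(peds, 2)
  expect_equal(attr(peds$F1, "proband"), "kid")
  expect_equal(peds$F1[id == "kid", affected], "yes")
  expect_equal(peds$F1[id == "dad", affected], "no")
  expect_equal(nrow(peds$F2), 1)
  expect_equal(attr(peds$F2, "proband"), "solo")

  # round trip
  f2 <- withr::local_tempfile(fileext = ".ped")
  write_ped(peds, f2)
  expect_equal(read_ped(f2), peds, ignore_attr = "index")

  dangle <- withr::local_tempfile()
  writeLines("F1\tkid\tghost\t0\t1\t2", dangle)
  expect_error(read_ped(dangle), "dangling")

  noaff <- withr::local_tempfile()
  writeLines("F1\ta\t0\t0\t1\t1", noaff)
  expect_warning(p <- read_ped(noaff), "no affected")
  expect_true(is.na(attr(p$F1, "proband")))
})

test_that("panel/freq/clinical/domain tables round-trip and validate", {
  panel <- ion_default_panel()
  expect_true("dominant" %in% strsplit(
    panel[symbol == "OPA1", modes], ",")[[1]])
  expect_true("recessive" %in% strsplit(
    panel[symbol == "OPA1", modes], ",")[[1]])
  expect_equal(panel[symbol == "TMEM126A", modes], "recessive")
  expect_equal(sum(panel$status == "known"), 15)
  expect_equal(nrow(panel), 22)

  f <- withr::local_tempfile(fileext = ".tsv")
  write_panel(panel, f)
  expect_equal(read_panel(f), panel, ignore_attr = TRUE)

  dup <- copy(panel)[2, symbol := "OPA1"]
  write_panel(dup, f)
  expect_error(read_panel(f), "duplicate")

  badmode <- copy(panel)[1, modes := "x_linked"]
  write_panel(badmode, f)
  expect_error(read_panel(f), "mode")

  freq <- data.table(chrom = "OPA1", pos = c(10L, 20L),
                     ref = "A", alt = "C", maf = c(0.01, 2e-5))
  write_freq_table(freq, f)
  expect_equal(read_freq_table(f), freq, ignore_attr = TRUE)
  write_freq_table(data.table(chrom = "x", pos = 1L, ref = "A",
                              alt = "C", maf = 1.2), f)
  expect_error(read_freq_table(f), "MAF")

  clin <- data.table(chrom = "WFS1", pos = 5L, ref = "G", alt = "T",
                     significance = "pathogenic")
  write_clinical_table(clin, f)
  expect_equal(read_clinical_table(f), clin, ignore_attr = TRUE)

  dom <- ion_opa1_domains()
  write_opa1_domains(dom, f)
  expect_equal(read_opa1_domains(f), dom, ignore_attr = TRUE)
})

test_that("BED and depth I/O convert coordinates correctly", {
  bed <- data.table(chrom = c("OPA1", "WFS1"), start = c(1L, 101L),
                    end = c(50L, 200L), name = c("r1", "r2"))
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(bed, f)
  raw <- fread(f, header = FALSE)
  expect_equal(raw$V2, c(0L, 100L))     # 0-based half-open on disk
  expect_equal(raw$V3, c(50L, 200L))
  expect_equal(read_bed(f), bed)

  dp <- data.table(chrom = "OPA1", pos = 1:5,
                   depth = c(0L, 10L, 30L, 200L, 7L))
  fd <- withr::local_tempfile(fileext = ".tsv")
  write_depth(dp, fd)
  expect_equal(read_depth(fd), dp)
  # samtools-depth style (headerless) input
  writeLines(paste("OPA1", 1:3, c(5, 6, 7), sep = "\t"), fd)
  expect_equal(read_depth(fd)$depth, c(5L, 6L, 7L))
})

test_that("reference FASTA round-trips through Biostrings", {
  g <- ion_toy_genome()$genome
  f <- withr::local_tempfile(fileext = ".fasta")
  write_reference_fasta(g, f)
  expect_equal(read_reference_fasta(f), g)
})
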