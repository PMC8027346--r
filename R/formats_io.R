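#' @name formats_io
#' @title File formats used by the panel pipeline
#'
#' @description
#' Readers and writers for every external format the pipeline touches:
#' a VCFv4.2 subset (CHROM POS ID REF ALT QUAL FILTER INFO FORMAT + samples,
#' GT subfield required), 6-column PED pedigrees, BED panel designs,
#' samtools-depth style per-base depth tables, and the packaged TSV tables
#' (panel genes, population allele frequencies, clinical significance,
#' transcript models, OPA1 protein domains).
#'
#' Coordinates are 1-based inclusive in memory (VCF convention); BED files
#' are converted from/to 0-based half-open at the I/O boundary, and nowhere
#' else.
NULL

VALID_MODES <- c("dominant", "recessive")
VALID_STATUS <- c("known", "candidate")
VALID_SIGNIFICANCE <- c("pathogenic", "likely_pathogenic", "benign", "vus")

# ---- VCF (subset) -----------------------------------------------------

check_alleles <- function(ref, alts, line = NA) {
  where <- if (is.na(line)) "" else sprintf(" (line %d)", line)
  if (!grepl("^[ACGT]+$", ref))
    stop_trailing("invalid REF allele '%s'%s", ref, where)
  for (a in alts) {
    if (!grepl("^[ACGT]+$", a))
      stop_trailing("invalid ALT allele '%s'%s", a, where)
    if (identical(a, ref))
      stop_trailing("ALT equals REF ('%s')%s", a, where)
  }
  invisible(TRUE)
}

#' Read a VCF file (VCFv4.2 subset) into a variant table
#'
#' Only the fixed columns plus the GT subfield of each sample are retained.
#' Records whose FILTER is neither `PASS` nor `.` are kept with
#' `quality_pass = FALSE` rather than dropped, so downstream consensus can
#' optionally count them (default behaviour counts PASS-only).
#'
#' @param path path to an uncompressed VCF file.
#' @param caller identifier of the variant caller that produced the file;
#'   stored in the `caller` column (provenance for consensus merging).
#' @return a `data.table` of class `ion_vcf` with columns `chrom`, `pos`,
#'   `id`, `ref`, `alt` (comma-joined alternate alleles), `qual`, `filter`,
#'   `info`, `quality_pass`, `caller`, and one GT column per sample; sample
#'   names in `attr(, "samples")`.
#' @export
read_vcf <- function(path, caller = NA_character_) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1)
    stop_trailing("no #CHROM header line in %s", path)
  cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  if (length(cols) < 10)
    stop_trailing("VCF must have FORMAT and at least one sample: %s", path)
  samples <- cols[-(1:9)]
  body_idx <- seq_len(length(lines))
  body_idx <- body_idx[body_idx > hdr & nzchar(lines[body_idx])]
  recs <- vector("list", length(body_idx))
  for (i in seq_along(body_idx)) {
    ln <- body_idx[i]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(cols))
      stop_trailing("malformed VCF line %d: expected %d fields, got %d",
                    ln, length(cols), length(f))
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos) || pos < 1)
      stop_trailing("malformed VCF line %d: bad POS '%s'", ln, f[2])
    alts <- strsplit(f[5], ",", fixed = TRUE)[[1]]
    if (length(alts) == 0)
      stop_trailing("malformed VCF line %d: empty ALT", ln)
    check_alleles(f[4], alts, line = ln)
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    gt_i <- match("GT", fmt)
    if (is.na(gt_i))
      stop_trailing("VCF line %d: FORMAT lacks GT", ln)
    gts <- vapply(f[-(1:9)], function(s)
      strsplit(s, ":", fixed = TRUE)[[1]][gt_i], character(1),
      USE.NAMES = FALSE)
    n_alleles <- length(alts) + 1L
    for (g in gts) {
      idx <- parse_gt(g)
      bad <- idx[!is.na(idx)]
      if (any(bad < 0 | bad >= n_alleles))
        stop_trailing("VCF line %d: GT '%s' indexes outside alleles", ln, g)
    }
    recs[[i]] <- c(list(chrom = f[1], pos = pos, id = f[3], ref = f[4],
                        alt = f[5], qual = f[6], filter = f[7], info = f[8]),
                   as.list(setNames(gts, samples)))
  }
  out <- if (length(recs)) data.table::rbindlist(recs) else
    data.table::data.table(chrom = character(), pos = integer(),
                           id = character(), ref = character(),
                           alt = character(), qual = character(),
                           filter = character(), info = character())
  if (!length(recs)) for (s in samples) out[[s]] <- character()
  out[, quality_pass := filter %in% c("PASS", ".")]
  out[, caller := caller]
  data.table::setattr(out, "samples", samples)
  data.table::setattr(out, "class", c("ion_vcf", class(out)))
  out[]
}

#' Write a variant table as VCF
#'
#' Inverse of [read_vcf()]: `read_vcf(write_vcf(x, f))` recovers the
#' retained fields exactly.
#'
#' @param vcf an `ion_vcf` table (or any data.table with the same columns).
#' @param path output path.
#' @param samples sample column names; defaults to `attr(vcf, "samples")`.
#' @param extra_header character vector of additional `##` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vcf, path, samples = NULL, extra_header = NULL) {
  samples <- samples %||% attr(vcf, "samples")
  if (is.null(samples)) stop_trailing("sample names required to write VCF")
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           extra_header,
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  dt <- data.table::as.data.table(vcf)
  if (nrow(dt)) {
    data.table::setorder(dt, chrom, pos, ref, alt)
    body <- do.call(paste, c(
      list(dt$chrom, dt$pos,
           if ("id" %in% names(dt)) dt$id else ".",
           dt$ref, dt$alt,
           if ("qual" %in% names(dt)) dt$qual else ".",
           if ("filter" %in% names(dt)) dt$filter else "PASS",
           if ("info" %in% names(dt)) dt$info else ".",
           "GT"),
      lapply(samples, function(s) dt[[s]]),
      list(sep = "\t")))
  } else body <- character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---- PED --------------------------------------------------------------

#' Read a 6-column PED file into pedigree objects
#'
#' Phenotype coding follows the PED convention: 2 = affected,
#' 1 = unaffected, 0 or -9 = unknown. The proband of each family is the
#' first affected individual listed; a family without any affected member
#' raises a warning and leaves the proband unset.
#'
#' @param path PED file path.
#' @return named list (by family id) of `ion_pedigree` data.tables with
#'   columns `family`, `id`, `father`, `mother`, `sex`, `affected`
#'   (yes/no/unknown); the proband id is in `attr(, "proband")`.
#' @export
read_ped <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(list())
  f <- strsplit(lines, "[ \t]+")
  bad <- which(lengths(f) != 6)
  if (length(bad))
    stop_trailing("malformed PED line %d: expected 6 columns", bad[1])
  dt <- data.table::data.table(
    family = vapply(f, `[`, "", 1), id = vapply(f, `[`, "", 2),
    father = vapply(f, `[`, "", 3), mother = vapply(f, `[`, "", 4),
    sex = vapply(f, `[`, "", 5), pheno = vapply(f, `[`, "", 6))
  dt[, affected := data.table::fcase(pheno == "2", "yes",
                                     pheno == "1", "no",
                                     default = "unknown")]
  dt[, pheno := NULL]
  out <- lapply(split(dt, by = "family", keep.by = TRUE), function(fam) {
    for (col in c("father", "mother")) {
      p <- fam[[col]]
      dangle <- p != "0" & !(p %in% fam$id)
      if (any(dangle))
        stop_trailing("pedigree %s: dangling %s id '%s'",
                      fam$family[1], col, p[dangle][1])
    }
    aff <- fam$id[fam$affected == "yes"]
    if (!length(aff)) {
      warning(sprintf("pedigree %s has no affected member; proband unset",
                      fam$family[1]), call. = FALSE)
      pro <- NA_character_
    } else pro <- aff[1]
    data.table::setattr(fam, "proband", pro)
    data.table::setattr(fam, "class", c("ion_pedigree", class(fam)))
    fam
  })
  out[unique(dt$family)]
}

#' Write pedigrees to a PED file
#'
#' @param peds a single pedigree table or list of them (as from
#'   [read_ped()]), or one combined data.table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(peds, path) {
  if (is.data.frame(peds)) peds <- list(peds)
  dt <- data.table::rbindlist(lapply(peds, data.table::as.data.table),
                              use.names = TRUE, fill = TRUE)
  pheno <- data.table::fcase(dt$affected == "yes", "2",
                             dt$affected == "no", "1",
                             default = "0")
  writeLines(paste(dt$family, dt$id, dt$father, dt$mother, dt$sex, pheno,
                   sep = "\t"), path)
  invisible(path)
}

# ---- TSV tables -------------------------------------------------------

read_tsv_required <- function(path, required) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  for (col in intersect(c("chrom", "ref", "alt", "gene", "symbol"), names(dt)))
    data.table::set(dt, j = col, value = as.character(dt[[col]]))
  miss <- setdiff(required, names(dt))
  if (length(miss))
    stop_trailing("%s: missing column(s) %s", path,
                  paste(miss, collapse = ", "))
  dt
}

#' Read the panel gene table
#'
#' Tab-separated with header `symbol  modes  status  regions`; `modes` is a
#' comma-joined subset of dominant/recessive, `regions` a semicolon-joined
#' list of `chrom:start-end` intervals (1-based inclusive).
#'
#' @param path TSV path.
#' @return `data.table` with columns `symbol`, `modes`, `status`, `regions`.
#' @export
read_panel <- function(path) {
  dt <- read_tsv_required(path, c("symbol", "modes", "status", "regions"))
  if (anyDuplicated(dt$symbol))
    stop_trailing("duplicate gene symbol in panel: %s",
                  dt$symbol[duplicated(dt$symbol)][1])
  for (m in unlist(strsplit(dt$modes, ",")))
    if (!m %in% VALID_MODES)
      stop_trailing("unknown inheritance mode '%s'", m)
  if (any(!nzchar(dt$modes)))
    stop_trailing("panel gene with empty modes")
  if (any(!dt$status %in% VALID_STATUS))
    stop_trailing("unknown gene status '%s'",
                  dt$status[!dt$status %in% VALID_STATUS][1])
  dt
}

#' @rdname read_panel
#' @param panel panel table.
#' @export
write_panel <- function(panel, path) {
  data.table::fwrite(panel[, c("symbol", "modes", "status", "regions")],
                     path, sep = "\t")
  invisible(path)
}

#' Expand a panel table into one row per genomic region
#'
#' @param panel panel table from [read_panel()] or [ion_default_panel()].
#' @return `data.table` with `symbol`, `modes`, `status`, `chrom`, `start`,
#'   `end` (1-based inclusive).
#' @export
panel_regions <- function(panel) {
  out <- panel[, {
    regs <- strsplit(regions, ";", fixed = TRUE)[[1]]
    m <- regmatches(regs, regexec("^([^:]+):([0-9]+)-([0-9]+)$", regs))
    if (any(lengths(m) != 4))
      stop_trailing("bad region string for %s", symbol)
    list(chrom = vapply(m, `[`, "", 2),
         start = as.integer(vapply(m, `[`, "", 3)),
         end = as.integer(vapply(m, `[`, "", 4)))
  }, by = .(symbol, modes, status)]
  out
}

#' Read / write the population allele-frequency table
#'
#' Keys are normalized variants; absent keys mean "absent from public
#' databases" (treated as MAF unknown, which passes the rarity filters).
#'
#' @param path TSV path with columns `chrom pos ref alt maf`.
#' @return `data.table` keyed by (chrom, pos, ref, alt).
#' @export
read_freq_table <- function(path) {
  dt <- read_tsv_required(path, c("chrom", "pos", "ref", "alt", "maf"))
  if (any(dt$maf < 0 | dt$maf > 1))
    stop_trailing("MAF outside [0,1] in %s", path)
  data.table::setkey(dt, chrom, pos, ref, alt)
  dt
}

#' @rdname read_freq_table
#' @param freq frequency table.
#' @export
write_freq_table <- function(freq, path) {
  data.table::fwrite(freq[, c("chrom", "pos", "ref", "alt", "maf")],
                     path, sep = "\t")
  invisible(path)
}

#' Read / write the clinical-significance (reported pathogenic) table
#'
#' @param path TSV with columns `chrom pos ref alt significance`;
#'   significance one of pathogenic, likely_pathogenic, benign, vus.
#' @return keyed `data.table`.
#' @export
read_clinical_table <- function(path) {
  dt <- read_tsv_required(path, c("chrom", "pos", "ref", "alt",
                                  "significance"))
  bad <- !dt$significance %in% VALID_SIGNIFICANCE
  if (any(bad))
    stop_trailing("unknown clinical significance '%s'",
                  dt$significance[bad][1])
  data.table::setkey(dt, chrom, pos, ref, alt)
  dt
}

#' @rdname read_clinical_table
#' @param clin clinical table.
#' @export
write_clinical_table <- function(clin, path) {
  data.table::fwrite(clin[, c("chrom", "pos", "ref", "alt", "significance")],
                     path, sep = "\t")
  invisible(path)
}

#' Read / write transcript models
#'
#' TSV with columns `gene chrom strand exon_starts exon_ends cds_start
#' cds_end` (1-based inclusive, exon lists comma-joined in genomic order).
#'
#' @param path TSV path.
#' @return `data.table`, one row per transcript.
#' @export
read_transcripts <- function(path) {
  read_tsv_required(path, c("gene", "chrom", "strand", "exon_starts",
                            "exon_ends", "cds_start", "cds_end"))
}

#' @rdname read_transcripts
#' @param tx transcript table.
#' @export
write_transcripts <- function(tx, path) {
  data.table::fwrite(tx[, c("gene", "chrom", "strand", "exon_starts",
                            "exon_ends", "cds_start", "cds_end")],
                     path, sep = "\t")
  invisible(path)
}

#' Read / write the OPA1 protein-domain table
#'
#' Amino-acid intervals (1-based inclusive) for the dynamin-family domains
#' of OPA1 (GTPase, central dynamin, GED, ...). Residue boundaries are
#' configuration, not code, and the packaged defaults are approximate.
#'
#' @param path TSV with columns `domain aa_start aa_end`.
#' @return `data.table` ordered by `aa_start`.
#' @export
read_opa1_domains <- function(path) {
  dt <- read_tsv_required(path, c("domain", "aa_start", "aa_end"))
  data.table::setorder(dt, aa_start)
  if (nrow(dt) > 1 && any(dt$aa_start[-1] <= dt$aa_end[-nrow(dt)]))
    stop_trailing("overlapping domain intervals in %s", path)
  dt
}

#' @rdname read_opa1_domains
#' @param domains domain table.
#' @export
write_opa1_domains <- function(domains, path) {
  data.table::fwrite(domains[, c("domain", "aa_start", "aa_end")],
                     path, sep = "\t")
  invisible(path)
}

# ---- BED and depth ----------------------------------------------------

#' Read a BED file into 1-based inclusive intervals
#'
#' @param path BED path (0-based half-open on disk).
#' @return `data.table` with `chrom`, `start`, `end` (1-based inclusive)
#'   and `name` if present.
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 3) stop_trailing("BED needs >= 3 columns: %s", path)
  out <- data.table::data.table(chrom = as.character(dt[[1]]),
                                start = dt[[2]] + 1L, end = dt[[3]])
  if (ncol(dt) >= 4) out[, name := as.character(dt[[4]])]
  out
}

#' @rdname read_bed
#' @param bed interval table with 1-based inclusive `start`, `end`.
#' @export
write_bed <- function(bed, path) {
  dt <- data.table::as.data.table(bed)
  cols <- list(dt$chrom, dt$start - 1L, dt$end)
  if ("name" %in% names(dt)) cols <- c(cols, list(dt$name))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read / write a per-base depth table
#'
#' Three tab-separated columns chrom, pos (1-based), depth — the format of
#' `samtools depth` output (no header) or a headered TSV.
#'
#' @param path depth file path.
#' @return `data.table` with `chrom`, `pos`, `depth`.
#' @export
read_depth <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("chrom", first, fixed = TRUE)
  dt <- data.table::fread(path, header = has_header, sep = "\t")
  data.table::setnames(dt, 1:3, c("chrom", "pos", "depth"))
  dt[, chrom := as.character(chrom)]
  if (any(dt$depth < 0)) stop_trailing("negative depth in %s", path)
  dt[, .(chrom, pos = as.integer(pos), depth = as.integer(depth))]
}

#' @rdname read_depth
#' @param depth depth table.
#' @export
write_depth <- function(depth, path) {
  data.table::fwrite(depth[, c("chrom", "pos", "depth")], path, sep = "\t")
  invisible(path)
}

# ---- FASTA ------------------------------------------------------------

#' Read / write a reference FASTA as a named character vector
#'
#' @param path FASTA path.
#' @return named character vector of contig sequences (uppercase).
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' @rdname read_reference_fasta
#' @param genome named character vector of contig sequences.
#' @export
write_reference_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(unlist(genome))
  names(x) <- names(genome)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
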