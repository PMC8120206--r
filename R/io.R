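# Table readers/writers. All user-facing tables are TSV with a header row
# and 1-based inclusive genomic coordinates (MAF convention); segment ends
# are exclusive (SEG convention). Writers and readers round-trip exactly.

.readTsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.VARIANT_COLS <- c("sample_id", "patient_id", "variant_id", "gene",
                   "variant_class", "chrom", "pos", "ref", "alt",
                   "tumor_alt_reads", "tumor_ref_reads",
                   "normal_alt_reads", "normal_ref_reads", "vaf",
                   "in_copy_loss", "expressed", "fpkm",
                   "ccf_point", "ccf_lo", "ccf_hi", "is_neoantigenic")

.EPITOPE_COLS <- c("sample_id", "patient_id", "variant_id", "peptide",
                   "hla_allele", "netmhc_ic50", "netmhcpan_ic50",
                   "pickpocket_ic50", "stability_halflife", "fpkm")

#' Read / write a MAF-like somatic variant table
#'
#' Tab-separated, one row per variant per sample. Required columns:
#' `sample_id`, `variant_id`, `gene`, `variant_class` (MISSENSE /
#' FRAMESHIFT_INDEL / OTHER_NONSILENT / SILENT), `chrom`, `pos` (1-based),
#' `ref`, `alt`, the four tumor/normal read-count columns, `vaf`,
#' `in_copy_loss`, `expressed`, `fpkm`, `ccf_point`, `ccf_lo`, `ccf_hi`,
#' `is_neoantigenic`.
#'
#' @param path file path.
#' @return data.frame (reader) or the path, invisibly (writer).
#' @export
readVariants <- function(path) {
  df <- .readTsv(path)
  .checkCols(df, .VARIANT_COLS, basename(path))
  if (any(df$ccf_lo > df$ccf_hi)) .stopf("CCF interval with lo > hi")
  df$chrom <- as.character(df$chrom)
  df
}

#' @rdname readVariants
#' @param variants data.frame in the same dialect.
#' @export
writeVariants <- function(variants, path) {
  .checkCols(variants, .VARIANT_COLS, "variants")
  .writeTsv(variants, path)
}

#' Read / write a pVACseq-style neoepitope table
#'
#' Tab-separated, one row per predicted peptide-HLA pair per sample, with
#' per-predictor IC50 columns in nM, predicted pMHC half-life in hours and
#' transcript FPKM. Peptides must be 9- or 10-mers.
#'
#' @param path file path.
#' @return data.frame (reader) or the path, invisibly (writer).
#' @export
readEpitopes <- function(path) {
  df <- .readTsv(path)
  .checkCols(df, .EPITOPE_COLS, basename(path))
  bad <- which(!nchar(df$peptide) %in% c(9L, 10L))
  if (length(bad) > 0)
    .stopf("%s line %d: peptide %s is not a 9- or 10-mer",
           basename(path), bad[1] + 1L, df$peptide[bad[1]])
  df
}

#' @rdname readEpitopes
#' @param epitopes data.frame in the same dialect.
#' @export
writeEpitopes <- function(epitopes, path) {
  .checkCols(epitopes, .EPITOPE_COLS, "epitopes")
  .writeTsv(epitopes, path)
}

#' Read / write a SEG-like copy-number segment table
#'
#' Columns `sample_id`, `chrom`, `start` (1-based), `end` (exclusive),
#' `total_cn`, `loh`. Segments of one sample must not overlap within a
#' chromosome.
#'
#' @param path file path.
#' @return data.frame (reader) or the path, invisibly (writer).
#' @export
readSegments <- function(path) {
  df <- .readTsv(path)
  .checkCols(df, c("sample_id", "chrom", "start", "end", "total_cn"),
             basename(path))
  df$chrom <- as.character(df$chrom)
  if (any(df$end <= df$start)) .stopf("segment with end <= start")
  for (key in unique(paste(df$sample_id, df$chrom))) {
    i <- paste(df$sample_id, df$chrom) == key
    s <- df[i, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
      .stopf("overlapping segments: %s", key)
  }
  df
}

#' @rdname readSegments
#' @param segs data.frame in the same dialect.
#' @export
writeSegments <- function(segs, path) {
  .checkCols(segs, c("sample_id", "chrom", "start", "end", "total_cn"),
             "segments")
  .writeTsv(segs, path)
}

#' Read / write a log2(TPM+1) expression matrix
#'
#' TSV with genes in rows (first column `gene`) and one column per sample.
#' Genes with any missing value are dropped on read (with a message).
#'
#' @param path file path.
#' @return numeric matrix (reader) or the path, invisibly (writer).
#' @export
readExpression <- function(path) {
  df <- .readTsv(path)
  if (names(df)[1] != "gene") .stopf("first column must be 'gene'")
  if (anyDuplicated(df$gene)) .stopf("duplicate gene identifiers")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  ok <- rowSums(is.na(m)) == 0
  if (!all(ok)) {
    message("dropping ", sum(!ok), " gene(s) with missing values")
    m <- m[ok, , drop = FALSE]
  }
  m
}

#' @rdname readExpression
#' @param expr genes x samples matrix with dimnames.
#' @export
writeExpression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  .writeTsv(df, path)
}

#' Read / write an immune-cell fraction table
#'
#' TSV with samples in rows (first column `sample_id`) and one column per
#' cell type; rows must sum to 1 within 1e-6.
#'
#' @param path file path.
#' @return samples x cell-types matrix (reader) or the path (writer).
#' @export
readCellFractions <- function(path) {
  df <- .readTsv(path)
  if (names(df)[1] != "sample_id") .stopf("first column must be 'sample_id'")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample_id
  if (any(abs(rowSums(m) - 1) > 1e-6))
    .stopf("cell fractions must sum to 1 per sample")
  m
}

#' @rdname readCellFractions
#' @param fractions samples x cell-types matrix with dimnames.
#' @export
writeCellFractions <- function(fractions, path) {
  df <- data.frame(sample_id = rownames(fractions), fractions,
                   check.names = FALSE)
  .writeTsv(df, path)
}

#' Read / write a TCR clonotype table
#'
#' TSV with columns `sample_id`, `chain` (TRA/TRB), `cdr3`, `count`.
#'
#' @param path file path.
#' @return data.frame (reader) or the path, invisibly (writer).
#' @export
readClonotypes <- function(path) {
  df <- .readTsv(path)
  .checkCols(df, c("sample_id", "chain", "cdr3", "count"), basename(path))
  df
}

#' @rdname readClonotypes
#' @param clonotypes data.frame in the same dialect.
#' @export
writeClonotypes <- function(clonotypes, path) {
  .checkCols(clonotypes, c("sample_id", "chain", "cdr3", "count"),
             "clonotypes")
  .writeTsv(clonotypes, path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated, name / description /
#' member genes. Sets need at least 2 member genes.
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    genes <- unique(f[-(1:2)][nzchar(f[-(1:2)])])
    if (length(f) < 4 || length(genes) < 2)
      .stopf("%s line %d: gene set '%s' has fewer than 2 member genes",
             basename(path), i, f[1])
    stats::setNames(list(genes), f[1])
  })
  do.call(c, sets)
}

#' Read a minimal somatic VCF into the variant-table dialect
#'
#' Parses a plain-text VCF with CHROM/POS/REF/ALT and per-sample AD
#' (allelic depth, "ref,alt") fields for a tumor and a normal sample
#' column. INFO annotation beyond this is ignored. Returns a data.frame
#' with the read-count columns of the MAF-like dialect; analysis columns
#' not represented in a VCF (class, flags, CCF) are filled with NA.
#'
#' @param path file path.
#' @param tumorCol,normalCol names of the tumor and normal sample columns;
#'   defaults: the first two sample columns in order tumor, normal.
#' @return data.frame with `chrom`, `pos`, `ref`, `alt`,
#'   `tumor_alt_reads`, `tumor_ref_reads`, `normal_alt_reads`,
#'   `normal_ref_reads`, `vaf`.
#' @export
readVcfMinimal <- function(path, tumorCol = NULL, normalCol = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1) .stopf("no #CHROM header line in %s", basename(path))
  cols <- strsplit(sub("^#", "", lines[hdr]), "\t", fixed = TRUE)[[1]]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  if (length(body) == 0) .stopf("VCF has no records")
  rec <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  colnames(rec) <- cols
  sampleCols <- setdiff(cols, c("CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                                "FILTER", "INFO", "FORMAT"))
  if (length(sampleCols) < 2)
    .stopf("need a tumor and a normal sample column")
  if (is.null(tumorCol)) tumorCol <- sampleCols[1]
  if (is.null(normalCol)) normalCol <- sampleCols[2]
  adOf <- function(i, col) {
    fmt <- strsplit(rec[i, "FORMAT"], ":", fixed = TRUE)[[1]]
    adIdx <- match("AD", fmt)
    if (is.na(adIdx)) .stopf("record %d: FORMAT lacks AD", i)
    v <- strsplit(rec[i, col], ":", fixed = TRUE)[[1]][adIdx]
    as.integer(strsplit(v, ",", fixed = TRUE)[[1]][1:2])
  }
  n <- nrow(rec)
  tum <- t(vapply(seq_len(n), adOf, integer(2), col = tumorCol))
  nor <- t(vapply(seq_len(n), adOf, integer(2), col = normalCol))
  dp <- tum[, 1] + tum[, 2]
  data.frame(chrom = rec[, "CHROM"], pos = as.integer(rec[, "POS"]),
             ref = rec[, "REF"], alt = rec[, "ALT"],
             tumor_alt_reads = tum[, 2], tumor_ref_reads = tum[, 1],
             normal_alt_reads = nor[, 2], normal_ref_reads = nor[, 1],
             vaf = ifelse(dp > 0, tum[, 2] / dp, NA_real_),
             stringsAsFactors = FALSE)
}

#' Write all tables of a cohort to a directory
#'
#' Emits `variants.tsv`, `epitopes.tsv`, `expression.tsv`, `segments.tsv`,
#' `cell_fractions.tsv`, `tcr.tsv` and `samples.tsv` in the dialects of
#' the corresponding readers.
#'
#' @param cohort a [NeoCohort-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "NeoCohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .writeTsv(sampleInfo(cohort), file.path(dir, "samples.tsv"))
  writeVariants(variants(cohort), file.path(dir, "variants.tsv"))
  writeEpitopes(epitopes(cohort), file.path(dir, "epitopes.tsv"))
  writeExpression(exprMatrix(cohort), file.path(dir, "expression.tsv"))
  writeSegments(segments(cohort), file.path(dir, "segments.tsv"))
  writeCellFractions(cellFractions(cohort),
                     file.path(dir, "cell_fractions.tsv"))
  writeClonotypes(clonotypes(cohort), file.path(dir, "tcr.tsv"))
  invisible(dir)
}

#' Read a cohort written by [writeCohort()]
#'
#' @param dir directory holding the cohort tables.
#' @return a [NeoCohort-class] (without ground truth).
#' @export
readCohort <- function(dir) {
  new("NeoCohort",
      samples = .readTsv(file.path(dir, "samples.tsv")),
      variants = readVariants(file.path(dir, "variants.tsv")),
      epitopes = readEpitopes(file.path(dir, "epitopes.tsv")),
      expression = readExpression(file.path(dir, "expression.tsv")),
      segments = readSegments(file.path(dir, "segments.tsv")),
      cellFractions = readCellFractions(file.path(dir, "cell_fractions.tsv")),
      tcr = readClonotypes(file.path(dir, "tcr.tsv")),
      groundTruth = list())
}
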