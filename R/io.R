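#' Read a GMT gene-set file
#'
#' Parses the tab-delimited GMT format (set name, description, member
#' symbols) into a named list of character vectors.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list; each element is a character vector of gene symbols.
#' @seealso [write_gmt()]
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write a GMT gene-set file
#'
#' @param pathways Named list of character vectors of gene symbols.
#' @param path Output path.
#' @param description Description field (second GMT column); recycled.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(pathways, path, description = "na") {
  stopifnot(is.list(pathways), !is.null(names(pathways)))
  description <- rep_len(description, length(pathways))
  lines <- vapply(seq_along(pathways), function(i) {
    paste(c(names(pathways)[i], description[i], pathways[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write genotypes as PLINK bed/bim/fam
#'
#' Writes the SNP-major binary PLINK format (two bits per genotype) together
#' with the `.bim` variant table and `.fam` sample table.  Dosages are minor
#' allele counts; alleles are recorded as synthetic labels A (minor) and
#' B (major).  Case/control status is stored in the `.fam` phenotype column
#' as 2/1.
#'
#' @param geno A genotype dataset as produced by [sim_genotypes()]: a list
#'   with `genotypes` (samples x SNPs dosage matrix in 0/1/2/`NA`),
#'   `phenotype` (0/1 vector, 1 = case) and `snp_table`
#'   (`snp_id`, `chr`, `pos`).
#' @param prefix Output path prefix; `.bed`, `.bim` and `.fam` are appended.
#' @return `prefix`, invisibly.
#' @seealso [read_plink()], [write_geno_text()]
#' @export
write_plink <- function(geno, prefix) {
  g <- geno$genotypes
  n <- nrow(g); p <- ncol(g)
  # per-genotype 2-bit codes, PLINK convention: 00 hom A1 (dosage 2),
  # 01 missing, 10 het, 11 hom A2 (dosage 0)
  code <- matrix(3L, n, p)
  code[g == 2] <- 0L
  code[g == 1] <- 2L
  code[is.na(g)] <- 1L
  bytes_per_snp <- ceiling(n / 4)
  pad <- bytes_per_snp * 4 - n
  if (pad > 0) code <- rbind(code, matrix(0L, pad, p))
  # pack 4 samples per byte, first sample in the low-order bits
  idx <- seq(1, nrow(code), by = 4)
  packed <- code[idx, , drop = FALSE] +
    4L * code[idx + 1, , drop = FALSE] +
    16L * code[idx + 2, , drop = FALSE] +
    64L * code[idx + 3, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(packed)), con)

  st <- geno$snp_table
  bim <- data.frame(chr = st$chr, id = st$snp_id, cm = 0, pos = st$pos,
                    a1 = "A", a2 = "B")
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  ids <- rownames(g)
  if (is.null(ids)) ids <- sprintf("S%05d", seq_len(n))
  fam <- data.frame(fid = ids, iid = ids, pid = 0, mid = 0, sex = 0,
                    pheno = ifelse(geno$phenotype == 1, 2L, 1L))
  write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read genotypes from PLINK bed/bim/fam
#'
#' @param prefix Path prefix of a fileset written by [write_plink()] or any
#'   SNP-major PLINK 1 binary fileset.
#' @return A genotype dataset list (`genotypes`, `phenotype`, `snp_table`)
#'   as consumed by [run_scan()].
#' @export
read_plink <- function(prefix) {
  bim <- read.delim(paste0(prefix, ".bim"), header = FALSE,
                    col.names = c("chr", "id", "cm", "pos", "a1", "a2"),
                    colClasses = c("character", "character", "numeric",
                                   "integer", "character", "character"))
  fam <- read.delim(paste0(prefix, ".fam"), header = FALSE,
                    col.names = c("fid", "iid", "pid", "mid", "sex", "pheno"))
  n <- nrow(fam); p <- nrow(bim)
  con <- file(paste0(prefix, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L)))
    stop("not a SNP-major PLINK .bed file: ", prefix, ".bed")
  bytes_per_snp <- ceiling(n / 4)
  raw <- readBin(con, "raw", bytes_per_snp * p)
  b <- as.integer(raw)
  # unpack 2-bit fields, low-order bits first
  codes <- rbind(b %% 4L, (b %/% 4L) %% 4L, (b %/% 16L) %% 4L, b %/% 64L)
  dim(codes) <- c(bytes_per_snp * 4, p)
  codes <- codes[seq_len(n), , drop = FALSE]
  g <- matrix(NA_integer_, n, p)
  g[codes == 0L] <- 2L
  g[codes == 2L] <- 1L
  g[codes == 3L] <- 0L
  rownames(g) <- fam$iid
  colnames(g) <- bim$id
  list(genotypes = g,
       phenotype = ifelse(fam$pheno == 2, 1L, 0L),
       snp_table = data.frame(snp_id = bim$id, chr = bim$chr, pos = bim$pos,
                              stringsAsFactors = FALSE))
}

#' Write genotypes in the tab-delimited text dialect
#'
#' Two files are written: `<prefix>.geno.tsv` with one row per sample
#' (`sample_id`, `phenotype`, one dosage column per SNP, `NA` for missing)
#' and `<prefix>.snps.tsv` with the SNP table (`snp_id`, `chr`, `pos`).
#'
#' @inheritParams write_plink
#' @return `prefix`, invisibly.
#' @export
write_geno_text <- function(geno, prefix) {
  g <- geno$genotypes
  ids <- rownames(g)
  if (is.null(ids)) ids <- sprintf("S%05d", seq_len(nrow(g)))
  df <- data.frame(sample_id = ids, phenotype = geno$phenotype, g,
                   check.names = FALSE)
  colnames(df)[-(1:2)] <- geno$snp_table$snp_id
  write.table(df, paste0(prefix, ".geno.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(geno$snp_table, paste0(prefix, ".snps.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Read genotypes from the tab-delimited text dialect
#'
#' @param prefix Path prefix of a fileset written by [write_geno_text()].
#' @return A genotype dataset list (`genotypes`, `phenotype`, `snp_table`).
#' @export
read_geno_text <- function(prefix) {
  df <- read.delim(paste0(prefix, ".geno.tsv"), check.names = FALSE)
  st <- read.delim(paste0(prefix, ".snps.tsv"))
  st$snp_id <- as.character(st$snp_id)
  st$chr <- as.character(st$chr)
  st$pos <- as.integer(st$pos)
  g <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(g) <- "integer"
  rownames(g) <- df$sample_id
  list(genotypes = g, phenotype = as.integer(df$phenotype), snp_table = st)
}

#' Write a gene annotation table
#'
#' BED-like tab-delimited table (`chr`, `start`, `end`, `strand`,
#' `gene_symbol`).  Coordinates are 1-based and inclusive at both ends,
#' which is stated in a header comment.
#'
#' @param genes Gene annotation data frame from [sim_gene_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# gene annotation; coordinates 1-based, inclusive", con)
  write.table(genes[, c("chr", "start", "end", "strand", "gene_symbol")],
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table written by [write_gene_annotation()]
#'
#' @param path Path to the annotation file.
#' @return Gene annotation data frame.
#' @export
read_gene_annotation <- function(path) {
  g <- read.delim(path, comment.char = "#",
                  colClasses = c("character", "integer", "integer",
                                 "character", "character"))
  g[, c("gene_symbol", "chr", "start", "end", "strand")]
}

#' Write a data frame as a plain TSV
#'
#' Convenience wrapper used for all report tables (SNP statistics, gene
#' statistics, pathway results, prediction tables); no quoting, no row
#' names, so tables round-trip losslessly through [read_tsv()].
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plain TSV written by [write_tsv()]
#'
#' @param path Path to the file.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
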