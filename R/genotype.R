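#' Genotype matrix for inbred (haploid-coded) accessions
#'
#' A `genotype_matrix` stores allele dosages for fully homozygous accessions
#' as a samples x SNPs matrix of 0 (reference), 1 (alternate) or `NA`
#' (missing), together with per-SNP metadata (chromosome, 1-based position,
#' identifier, intergenic flag). Heterozygous diploid calls have no place in
#' a selfing panel and are recorded as missing by the readers.
#'
#' @param dosage numeric matrix, samples in rows (rownames = accession ids),
#'   SNPs in columns; entries in \{0, 1, NA\}.
#' @param snps data.frame with columns `chrom`, `pos`, `id`, `intergenic`
#'   (logical), one row per dosage column, positions strictly increasing
#'   within each chromosome.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage` and `snps`.
#' @export
genotype_matrix <- function(dosage, snps) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (is.null(rownames(dosage))) {
    stop("dosage must have sample identifiers as rownames")
  }
  if (anyDuplicated(rownames(dosage))) {
    stop("duplicate sample identifiers in dosage rownames")
  }
  stopifnot(is.data.frame(snps))
  req <- c("chrom", "pos", "id", "intergenic")
  if (!all(req %in% names(snps))) {
    stop("snps metadata must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(snps) != ncol(dosage)) {
    stop("snps metadata rows (", nrow(snps), ") do not match dosage columns (",
         ncol(dosage), ")")
  }
  snps$pos <- as.integer(snps$pos)
  snps$intergenic <- as.logical(snps$intergenic)
  bad <- !(dosage %in% c(0, 1) | is.na(dosage))
  if (any(bad)) stop("dosage values must be 0, 1 or NA")
  for (ch in unique(snps$chrom)) {
    p <- snps$pos[snps$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop("positions not strictly increasing on chromosome ", ch)
    }
  }
  colnames(dosage) <- snps$id
  structure(list(dosage = dosage, snps = snps), class = "genotype_matrix")
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "samples x", ncol(x$dosage),
      "SNPs on", length(unique(x$snps$chrom)), "chromosome(s);",
      sum(x$snps$intergenic, na.rm = TRUE), "intergenic;",
      sum(is.na(x$dosage)), "missing calls\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Read a genotype matrix from VCF or TSV
#'
#' VCF input must contain bi-allelic SNPs with diploid genotypes; homozygous
#' calls collapse to haploid dosages (0/0 -> 0, 1/1 -> 1) and heterozygous
#' calls become missing (their count is reported via [message()]), since the
#' accessions are treated as fully selfing. TSV input follows the package's
#' plain-text dialect: a tab-separated table with one row per sample (first
#' column = sample id, remaining columns = SNP dosages) plus a `snps.tsv`
#' sidecar holding columns `chrom`, `pos`, `id`, `intergenic` in \{0,1\}.
#'
#' @param path path to the genotype file.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @param snp_info path to the SNP metadata sidecar. Defaults to `snps.tsv`
#'   next to `path` for TSV input; optional for VCF (when absent, intergenic
#'   flags are `NA`).
#' @return A [genotype_matrix()].
#' @export
read_genotype_matrix <- function(path, format = c("auto", "vcf", "tsv"),
                                 snp_info = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (format == "vcf") .read_genotype_vcf(path, snp_info)
  else .read_genotype_tsv(path, snp_info)
}

.read_genotype_vcf <- function(path, snp_info) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)     # single-variant VCF
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT) | nchar(fix$REF) != 1L | nchar(fix$ALT) != 1L
  if (any(multi)) {
    stop("non-bi-allelic SNP record(s): ",
         paste(utils::head(ifelse(is.na(fix$ID[multi]) | fix$ID[multi] == ".",
                                  paste0(fix$CHROM[multi], ":", fix$POS[multi]),
                                  fix$ID[multi]), 5), collapse = ", "))
  }
  gt <- vcfR::extract.gt(v, element = "GT")        # variants x samples
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  dos <- matrix(NA_real_, nrow = nrow(gt), ncol = ncol(gt),
                dimnames = dimnames(gt))
  dos[a1 == "0" & a2 == "0"] <- 0
  dos[a1 == "1" & a2 == "1"] <- 1
  het <- !is.na(a1) & !is.na(a2) & a1 != a2 & a1 %in% c("0", "1") &
    a2 %in% c("0", "1")
  n_het <- sum(het)
  if (n_het > 0) {
    message("read_genotype_matrix: ", n_het,
            " heterozygous call(s) set to missing (",
            format(100 * n_het / length(gt), digits = 3), "% of calls)")
  }
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, "_", fix$POS), fix$ID)
  intergenic <- rep(NA, nrow(fix))
  if (!is.null(snp_info) && file.exists(snp_info)) {
    side <- utils::read.delim(snp_info, stringsAsFactors = FALSE)
    intergenic <- as.logical(side$intergenic[match(ids, side$id)])
  }
  snps <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                     id = ids, intergenic = intergenic,
                     stringsAsFactors = FALSE)
  genotype_matrix(t(dos), snps)
}

.read_genotype_tsv <- function(path, snp_info) {
  if (is.null(snp_info)) snp_info <- file.path(dirname(path), "snps.tsv")
  if (!file.exists(snp_info)) {
    stop("SNP metadata sidecar not found: ", snp_info)
  }
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  samples <- as.character(tab[[1]])
  dos <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(dos)) stop("non-numeric dosage value in ", path)
  rownames(dos) <- samples
  side <- utils::read.delim(snp_info, stringsAsFactors = FALSE)
  snps <- data.frame(chrom = side$chrom, pos = as.integer(side$pos),
                     id = as.character(side$id),
                     intergenic = as.logical(side$intergenic == 1 |
                                               side$intergenic == TRUE),
                     stringsAsFactors = FALSE)
  if (!identical(colnames(dos), snps$id)) {
    stop("SNP ids in ", path, " do not match sidecar ", snp_info)
  }
  genotype_matrix(dos, snps)
}

#' Write a genotype matrix in the TSV dialect
#'
#' Writes the dosage table and its `snps.tsv` sidecar so that
#' [read_genotype_matrix()] round-trips the object exactly.
#'
#' @param g a [genotype_matrix()].
#' @param path output path for the dosage table.
#' @param snp_info output path for the metadata sidecar (default: `snps.tsv`
#'   next to `path`).
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(g, path,
                               snp_info = file.path(dirname(path), "snps.tsv")) {
  stopifnot(inherits(g, "genotype_matrix"))
  tab <- data.frame(sample = rownames(g$dosage), g$dosage,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- g$snps
  side$intergenic <- as.integer(side$intergenic)
  utils::write.table(side, snp_info, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
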