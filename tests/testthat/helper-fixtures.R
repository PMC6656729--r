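# Shared fixtures: tiny genotype matrices, an independent ANOVA-based
# Weir-Cockerham oracle, and a writer for a minimal VCF.

# Genotype matrix from a plain dosage matrix; SNPs placed `spacing` bp apart
# on one chromosome unless positions are given.
toy_geno <- function(dosage, pos = NULL, chrom = NULL, intergenic = TRUE,
                     spacing = 1000) {
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("s%02d", seq_len(nrow(dosage)))
  }
  m <- ncol(dosage)
  if (is.null(pos)) pos <- seq_len(m) * spacing
  if (is.null(chrom)) chrom <- rep("chr1", m)
  genotype_matrix(dosage, data.frame(
    chrom = chrom, pos = pos, id = sprintf("snp%03d", seq_len(m)),
    intergenic = rep_len(intergenic, m), stringsAsFactors = FALSE))
}

# Genotype matrix + assignment realizing given per-population alternate
# allele counts at a single SNP.
geno_from_counts <- function(alt_counts, pop_sizes) {
  dos <- unlist(mapply(function(x, n) c(rep(1, x), rep(0, n - x)),
                       alt_counts, pop_sizes, SIMPLIFY = FALSE))
  g <- toy_geno(matrix(dos, ncol = 1))
  pa <- stats::setNames(rep(paste0("group_", seq_along(pop_sizes)),
                            pop_sizes), rownames(g$dosage))
  list(g = g, pa = pa)
}

# Independent Weir-Cockerham haploid oracle: one-way ANOVA of the 0/1
# allele indicators via stats::lm, then a/(a+b) with the unbalanced nc.
wc_theta_oracle <- function(alt_counts, pop_sizes) {
  if (sum(alt_counts) %in% c(0, sum(pop_sizes))) return(NA_real_)  # monomorphic
  y <- unlist(mapply(function(x, n) c(rep(1, x), rep(0, n - x)),
                     alt_counts, pop_sizes, SIMPLIFY = FALSE))
  f <- factor(rep(seq_along(pop_sizes), pop_sizes))
  # zero-residual tables (fixed differences) trigger lm's perfect-fit warning
  av <- suppressWarnings(stats::anova(stats::lm(y ~ f)))
  msb <- av$`Mean Sq`[1]
  msw <- av$`Mean Sq`[2]
  N <- sum(pop_sizes)
  r <- length(pop_sizes)
  nc <- (N - sum(pop_sizes^2) / N) / (r - 1)
  a <- (msb - msw) / nc
  if (a + msw == 0) return(NA_real_)
  a / (a + msw)
}

# Minimal VCF with diploid GT calls; `calls` is variants x samples of
# strings like "0/0", "1/1", "0/1", "./.".
write_toy_vcf <- function(path, calls, chrom = "1",
                          pos = seq_len(nrow(calls)) * 100,
                          ref = "A", alt = "T") {
  samples <- colnames(calls)
  if (is.null(samples)) samples <- sprintf("S%d", seq_len(ncol(calls)))
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=1>",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(calls)), function(i) {
    paste(c(chrom, pos[i], paste0("v", i), rep_len(ref, nrow(calls))[i],
            rep_len(alt, nrow(calls))[i], ".", "PASS", ".", "GT",
            calls[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}

# Balanced five-population assignment over n genotypes.
study_assignment <- function(n = 300, n_pops = 5) {
  stats::setNames(rep(paste0("group_", seq_len(n_pops)), each = n / n_pops),
                  sprintf("g%04d", seq_len(n)))
}
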