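#' @name fst
#' @title Weir-Cockerham F_ST for haploid-coded selfing accessions
#'
#' @description
#' Fully selfing accessions are treated as haploid genomes, so the
#' Weir-Cockerham (1984) variance components reduce to the one-way ANOVA of
#' per-sample allele indicators. For a SNP with populations
#' \eqn{i = 1..r}, non-missing sample sizes \eqn{n_i} (total \eqn{N}) and
#' sample allele frequencies \eqn{p_i}:
#' \deqn{MS_B = \sum_i n_i (p_i - \bar p)^2 / (r - 1), \quad
#'       MS_W = \sum_i n_i p_i (1 - p_i) / (N - r),}
#' with \eqn{\bar p} the weighted mean frequency and
#' \eqn{n_c = (N - \sum_i n_i^2 / N)/(r - 1)}. The among-population
#' component is \eqn{a = (MS_B - MS_W)/n_c}, the within component
#' \eqn{b = MS_W}, and \eqn{\hat\theta = a / (a + b)} (negative values are
#' retained, not clamped). SNPs that are monomorphic over all samples, or
#' have fewer than two populations with at least two non-missing calls, get
#' `NA` and are excluded from multilocus summaries.
NULL

# Per-population alternate-allele counts (ac) and non-missing call counts
# (an), pops x snps, for the non-admixed samples of pa present in g.
.fst_counts <- function(g, pa) {
  stopifnot(inherits(g, "genotype_matrix"))
  pa <- pa[names(pa) %in% rownames(g$dosage)]
  keep <- names(pa)[pa != "Admixed"]
  if (length(keep) < 4) stop("need >= 4 non-admixed samples with genotypes")
  lab <- pa[keep]
  pops <- sort(unique(lab))
  if (length(pops) < 2) stop("need >= 2 non-admixed populations")
  D <- g$dosage[keep, , drop = FALSE]
  P <- outer(lab, pops, "==") + 0            # samples x pops
  M <- (!is.na(D)) + 0
  D0 <- D
  D0[is.na(D0)] <- 0
  list(ac = crossprod(P, D0), an = crossprod(P, M), pops = pops,
       labels = lab, dosage = D, nonmiss = M, indicator = P)
}

# Vectorized WC84 haploid variance components from count matrices
# (pops x snps). Returns per-SNP a, b, theta.
.wc_components <- function(ac, an) {
  use <- an >= 2
  ac[!use] <- 0
  an[!use] <- 0
  r <- colSums(an > 0)
  N <- colSums(an)
  p <- ifelse(an > 0, ac / an, 0)
  pbar <- ifelse(N > 0, colSums(ac) / N, 0)
  ssb <- colSums(an * sweep(p, 2, pbar, "-")^2)
  ssw <- colSums(an * p * (1 - p))
  ok <- r >= 2 & (N - r) > 0
  msb <- ifelse(ok, ssb / (r - 1), NA_real_)
  msw <- ifelse(ok, ssw / (N - r), NA_real_)
  nc <- ifelse(ok, (N - colSums(an^2) / pmax(N, 1)) / (r - 1), NA_real_)
  a <- (msb - msw) / nc
  b <- msw
  theta <- ifelse(ok & (a + b) != 0, a / (a + b), NA_real_)
  list(a = a, b = b, theta = theta)
}

#' Per-SNP Weir-Cockerham theta
#'
#' @param g a [genotype_matrix()].
#' @param pa population assignment from [assign_populations()]; `"Admixed"`
#'   accessions are excluded.
#' @return data.frame with one row per SNP: `id`, `chrom`, `pos`,
#'   `intergenic`, variance components `a` and `b`, and `theta`
#'   (`NA` where undefined). See [fst] for the estimator.
#' @export
snp_fst <- function(g, pa) {
  cc <- .fst_counts(g, pa)
  comp <- .wc_components(cc$ac, cc$an)
  data.frame(g$snps[, c("id", "chrom", "pos", "intergenic")],
             a = comp$a, b = comp$b, theta = comp$theta,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Multilocus F_ST summaries
#'
#' Combines per-SNP Weir-Cockerham components into the ratio-of-sums
#' estimator \eqn{\sum a / \sum (a + b)} (the primary multilocus statistic)
#' and the unweighted mean of per-SNP theta (also reported because
#' genome-wide means are the common summary in the literature).
#'
#' @param per_snp per-SNP table from [snp_fst()].
#' @return list with `ratio_of_sums`, `mean_theta` and `n_snps` (number of
#'   SNPs with a defined estimate).
#' @export
multilocus_fst <- function(per_snp) {
  ok <- is.finite(per_snp$theta)
  if (!any(ok)) stop("no SNP with a defined theta estimate")
  list(ratio_of_sums = sum(per_snp$a[ok]) /
         sum(per_snp$a[ok] + per_snp$b[ok]),
       mean_theta = mean(per_snp$theta[ok]),
       n_snps = sum(ok))
}

#' Pairwise population F_ST
#'
#' Ratio-of-sums multilocus theta restricted to each pair of populations.
#'
#' @inheritParams snp_fst
#' @return data.frame with columns `pop1`, `pop2`, `theta`, `n_snps`.
#' @export
pairwise_fst <- function(g, pa) {
  pa <- pa[pa != "Admixed"]
  pops <- sort(unique(pa))
  pairs <- utils::combn(pops, 2)
  out <- apply(pairs, 2, function(pr) {
    sub <- pa[pa %in% pr]
    ml <- multilocus_fst(snp_fst(g, sub))
    c(theta = ml$ratio_of_sums, n_snps = ml$n_snps)
  })
  data.frame(pop1 = pairs[1, ], pop2 = pairs[2, ],
             theta = out["theta", ], n_snps = out["n_snps", ],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Permutation null and per-SNP significance for F_ST
#'
#' Population labels are permuted across accessions once per iteration,
#' jointly for all SNPs (preserving between-SNP dependence and the
#' per-population sample sizes), and per-SNP theta is recomputed. A SNP is
#' declared significant when its observed theta exceeds the `q` quantile of
#' its own permutation null.
#'
#' @inheritParams snp_fst
#' @param n_perm number of label permutations (default 1000; fewer than 100
#'   triggers a warning about quantile stability).
#' @param q null quantile used as the significance cut-off (default 0.95).
#' @param seed integer seed for the permutation stream.
#' @return the [snp_fst()] table with extra columns `null_q` (the per-SNP
#'   null quantile) and `significant`.
#' @export
fst_permutation_null <- function(g, pa, n_perm = 1000, q = 0.95,
                                 seed = NULL) {
  if (n_perm < 100) warning("n_perm < 100: null quantiles are unstable")
  cc <- .fst_counts(g, pa)
  obs <- .wc_components(cc$ac, cc$an)
  n <- nrow(cc$dosage)
  D0 <- cc$dosage
  D0[is.na(D0)] <- 0
  nullmat <- .with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      Pp <- cc$indicator[sample.int(n), , drop = FALSE]
      .wc_components(crossprod(Pp, D0), crossprod(Pp, cc$nonmiss))$theta
    }, numeric(ncol(D0)))
  })
  null_q <- apply(nullmat, 1, stats::quantile, probs = q, na.rm = TRUE,
                  names = FALSE)
  out <- data.frame(g$snps[, c("id", "chrom", "pos", "intergenic")],
                    a = obs$a, b = obs$b, theta = obs$theta,
                    null_q = null_q,
                    significant = !is.na(obs$theta) & obs$theta > null_q,
                    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Neutral F_ST benchmark
#'
#' The neutral differentiation benchmark is the median of per-SNP theta over
#' SNPs that are both intergenic and permutation-significant — intergenic
#' SNPs being the ones assumed to experience only neutral (demographic)
#' differentiation.
#'
#' @param scan per-SNP table from [fst_permutation_null()] (must carry
#'   `intergenic` and `significant` columns).
#' @return scalar neutral F_ST.
#' @export
neutral_fst <- function(scan) {
  stopifnot(all(c("theta", "intergenic", "significant") %in% names(scan)))
  sel <- scan$intergenic %in% TRUE & scan$significant %in% TRUE &
    is.finite(scan$theta)
  if (!any(sel)) {
    stop("no significant intergenic SNP: check the intergenic flags ",
         "and the permutation scan")
  }
  stats::median(scan$theta[sel])
}

#' Full F_ST scan
#'
#' Convenience wrapper running [fst_permutation_null()],
#' [multilocus_fst()], [pairwise_fst()] and [neutral_fst()] in one call.
#'
#' @inheritParams fst_permutation_null
#' @return list of class `fst_result` with elements `per_snp`,
#'   `multilocus`, `pairwise`, `neutral_fst`, `n_perm`, `q`, `seed`.
#' @export
fst_scan <- function(g, pa, n_perm = 1000, q = 0.95, seed = NULL) {
  per_snp <- fst_permutation_null(g, pa, n_perm = n_perm, q = q, seed = seed)
  structure(list(per_snp = per_snp,
                 multilocus = multilocus_fst(per_snp),
                 pairwise = pairwise_fst(g, pa),
                 neutral_fst = neutral_fst(per_snp),
                 n_perm = n_perm, q = q, seed = seed),
            class = "fst_result")
}

#' @exportS3Method base::print
print.fst_result <- function(x, ...) {
  cat("fst_result:", nrow(x$per_snp), "SNPs;",
      sum(x$per_snp$significant, na.rm = TRUE), "significant\n")
  cat("  multilocus theta (ratio-of-sums):",
      format(x$multilocus$ratio_of_sums, digits = 4),
      "| mean per-SNP theta:", format(x$multilocus$mean_theta, digits = 4),
      "\n  neutral Fst (median significant intergenic):",
      format(x$neutral_fst, digits = 4), "\n")
  invisible(x)
}

#' Greedy windowed LD pruning
#'
#' Scans each chromosome left to right in windows of `window_kb` kilobases
#' starting every `step_snps` SNPs. Within a window, a SNP is dropped when
#' its squared Pearson correlation (pairwise-complete dosages) with an
#' earlier retained SNP of the window reaches `r2_max`. Deterministic for a
#' fixed input order. Zero-variance SNPs are correlated with nothing and are
#' kept unless they exactly duplicate an earlier in-window column.
#'
#' @param g a [genotype_matrix()]; SNPs must be position-sorted (enforced by
#'   the class).
#' @param r2_max squared-correlation threshold (default 0.1).
#' @param window_kb window width in kb (default 50).
#' @param step_snps window step in SNPs (default 50).
#' @return integer vector of retained SNP column indices.
#' @export
ld_prune <- function(g, r2_max = 0.1, window_kb = 50, step_snps = 50) {
  stopifnot(inherits(g, "genotype_matrix"), r2_max > 0)
  D <- g$dosage
  keep <- rep(TRUE, ncol(D))
  for (ch in unique(g$snps$chrom)) {
    idx <- which(g$snps$chrom == ch)
    pos <- g$snps$pos[idx]
    starts <- seq(1, length(idx), by = step_snps)
    for (s in starts) {
      win <- idx[pos >= pos[s] & pos <= pos[s] + window_kb * 1000 &
                   seq_along(idx) >= s]
      win <- win[keep[win]]
      if (length(win) < 2) next
      for (j in seq_along(win)[-1]) {
        if (!keep[win[j]]) next
        earlier <- win[seq_len(j - 1)]
        earlier <- earlier[keep[earlier]]
        for (i in earlier) {
          if (.r2_cols(D[, i], D[, win[j]]) >= r2_max) {
            keep[win[j]] <- FALSE
            break
          }
        }
      }
    }
  }
  which(keep)
}

# Squared Pearson correlation of two dosage columns over shared non-missing
# entries; zero-variance columns correlate with nothing except an exact
# duplicate.
.r2_cols <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(0)
  x <- x[ok]
  y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(if (identical(x, y)) 1 else 0)
  }
  stats::cor(x, y)^2
}

#' Realized-relationship (kinship) matrix from SNPs
#'
#' Standardizes each SNP column to mean 0 and unit variance over its
#' non-missing calls and forms \eqn{K_{ij} = \sum_s z_{is} z_{js} / m_{ij}},
#' where \eqn{m_{ij}} is the number of SNPs non-missing in both samples —
#' the standard realized relationship matrix used as a covariance in
#' kinship-aware regressions.
#'
#' @param g a [genotype_matrix()].
#' @return symmetric samples x samples matrix; monomorphic SNPs are skipped.
#' @export
kinship_matrix <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  D <- g$dosage
  if (nrow(D) < 2) stop("need >= 2 samples")
  mu <- colMeans(D, na.rm = TRUE)
  sdv <- apply(D, 2, stats::sd, na.rm = TRUE)
  poly <- is.finite(sdv) & sdv > 0
  if (!any(poly)) stop("no polymorphic SNP")
  Z <- sweep(sweep(D[, poly, drop = FALSE], 2, mu[poly], "-"),
             2, sdv[poly], "/")
  Mna <- (!is.na(Z)) + 0
  Z[is.na(Z)] <- 0
  m <- tcrossprod(Mna)
  if (any(m == 0)) stop("sample pair with no shared non-missing SNP")
  K <- tcrossprod(Z) / m
  dimnames(K) <- list(rownames(D), rownames(D))
  K
}
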