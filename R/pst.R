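#' Between/within-population variance components of genotype means
#'
#' One-way random-effects decomposition (method of moments with the standard
#' unbalanced-design coefficient n0): `sigma2_W` is the pooled
#' within-population mean square of genotype means, `sigma2_B = (MS_between
#' - MS_within) / n0`, truncated at 0 when the moment estimate is negative
#' (flagged via the `truncated` field). Admixed accessions and populations
#' with a single genotype are excluded.
#'
#' @param means genotype-mean trait table ([genotype_means()] output) or any
#'   data.frame with `genotype_id`, `trait`, `value`.
#' @param pa population assignment from [assign_populations()].
#' @param trait which trait to decompose (default: the single trait
#'   present).
#' @return list of class `variance_components` with `sigma2_B`, `sigma2_W`,
#'   `n_pops`, `pop_sizes` (genotypes per population), `grand_mean`,
#'   `truncated`.
#' @export
variance_components <- function(means, pa, trait = NULL) {
  stopifnot(is.data.frame(means),
            all(c("genotype_id", "trait", "value") %in% names(means)))
  if (is.null(trait)) {
    trait <- unique(means$trait)
    if (length(trait) != 1) {
      stop("several traits present; pick one via the trait argument")
    }
  }
  m <- means[means$trait == trait, , drop = FALSE]
  lab <- pa[match(m$genotype_id, names(pa))]
  keep <- !is.na(lab) & lab != "Admixed"
  m <- m[keep, , drop = FALSE]
  lab <- lab[keep]
  sizes <- table(lab)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("population(s) with a single genotype dropped: ",
            paste(small, collapse = ", "))
    keep <- !(lab %in% small)
    m <- m[keep, , drop = FALSE]
    lab <- lab[keep]
    sizes <- table(lab)
  }
  if (length(sizes) < 2) stop("need >= 2 populations with >= 2 genotypes")
  an <- .anova1(m$value, factor(lab))
  sigma2_B <- (an$msb - an$msw) / an$n0
  truncated <- sigma2_B < 0
  structure(list(sigma2_B = max(0, sigma2_B), sigma2_W = an$msw,
                 n_pops = length(sizes),
                 pop_sizes = stats::setNames(as.integer(sizes),
                                             names(sizes)),
                 grand_mean = mean(m$value), truncated = truncated),
            class = "variance_components")
}

# One-way ANOVA pieces for a numeric vector and grouping factor.
.anova1 <- function(y, f) {
  ni <- tabulate(f)
  r <- nlevels(f)
  N <- length(y)
  mi <- tapply(y, f, mean)
  gm <- sum(ni * mi) / N
  msb <- sum(ni * (mi - gm)^2) / (r - 1)
  msw <- sum((y - mi[f])^2) / (N - r)
  n0 <- (N - sum(ni^2) / N) / (r - 1)
  list(msb = msb, msw = msw, n0 = n0, ni = ni, r = r, N = N)
}

#' Heritability from replicated measurements
#'
#' Genotype-level variance ratio from a one-way random-effects ANOVA of
#' replicates within genotypes: `h2 = sigma2_G / (sigma2_G + sigma2_E)`,
#' with `sigma2_G = (MS_genotype - MS_error) / r0` (r0 the unbalanced
#' coefficient) truncated at 0. In a fully homozygous selfing panel the
#' replicate design estimates broad-sense heritability, which coincides
#' with the narrow-sense value when all loci are homozygous.
#'
#' @param traits replicate-level trait table (columns `genotype_id`,
#'   `replicate_id`, `trait`, `value`).
#' @param trait trait name (default: the single trait present).
#' @return list with `h2`, `sigma2_G`, `sigma2_E`, `n_genotypes`,
#'   `mean_reps`.
#' @export
heritability <- function(traits, trait = NULL) {
  .check_trait_table(traits, replicated = TRUE)
  if (is.null(trait)) {
    trait <- unique(traits$trait)
    if (length(trait) != 1) {
      stop("several traits present; pick one via the trait argument")
    }
  }
  tt <- traits[traits$trait == trait, , drop = FALSE]
  f <- factor(tt$genotype_id)
  reps <- tabulate(f)
  if (mean(reps >= 2) < 0.5) {
    stop("need >= 2 replicates for at least half of the genotypes")
  }
  an <- .anova1(tt$value, f)
  sigma2_G <- max(0, (an$msb - an$msw) / an$n0)
  list(h2 = sigma2_G / (sigma2_G + an$msw), sigma2_G = sigma2_G,
       sigma2_E = an$msw, n_genotypes = nlevels(f), mean_reps = mean(reps))
}

#' P_ST point estimate for an autogamous species
#'
#' \deqn{P_{ST} = \frac{c\,\sigma^2_B}{c\,\sigma^2_B + h^2\,\sigma^2_W}}
#' where `c` is the among-population heritability (fraction of the
#' between-population variance that is genetic) and `h2` the heritability.
#' The within-population variance carries no factor 2: in a predominantly
#' selfing, fully homozygous species the within-population additive variance
#' is not halved by outcrossing. Under H0 (`c = h2 = 1`) the statistic
#' reduces exactly to `sigma2_B / (sigma2_B + sigma2_W)`.
#'
#' @param vc [variance_components()] object (or any list with `sigma2_B`,
#'   `sigma2_W`).
#' @param c among-population heritability in \[0, 1\].
#' @param h2 heritability in (0, 1\].
#' @return scalar P_ST in \[0, 1\].
#' @export
pst <- function(vc, c = 1, h2 = 1) {
  stopifnot(c >= 0, h2 >= 0, vc$sigma2_B >= 0, vc$sigma2_W >= 0)
  num <- c * vc$sigma2_B
  den <- num + h2 * vc$sigma2_W
  if (den == 0) {
    if (vc$sigma2_B == 0 && vc$sigma2_W > 0) return(0)
    stop("P_ST undefined: c * sigma2_B and h2 * sigma2_W are both zero")
  }
  num / den
}

# Parametric-bootstrap draws of (sigma2_B*, sigma2_W*) under the fitted
# normal-normal model and the observed design; vectorized over iterations.
.boot_components <- function(vc, n_iter) {
  ni <- as.integer(vc$pop_sizes)
  r <- length(ni)
  N <- sum(ni)
  n0 <- (N - sum(ni^2) / N) / (r - 1)
  pop <- rep(seq_len(r), ni)
  P <- outer(pop, seq_len(r), "==") + 0
  Y <- matrix(stats::rnorm(n_iter * N, 0, sqrt(vc$sigma2_W)), n_iter, N) +
    matrix(stats::rnorm(n_iter * r, 0, sqrt(vc$sigma2_B)),
           n_iter, r)[, pop, drop = FALSE]
  S <- Y %*% P
  M <- sweep(S, 2, ni, "/")
  gm <- rowSums(S) / N
  msb <- rowSums(sweep((M - gm)^2, 2, ni, "*")) / (r - 1)
  ssw <- rowSums(Y^2) - rowSums(sweep(M^2, 2, ni, "*"))
  msw <- ssw / (N - r)
  list(sigma2_B = pmax(0, (msb - msw) / n0), sigma2_W = msw)
}

#' Parametric-bootstrap confidence interval for P_ST
#'
#' Each iteration redraws population effects ~ Normal(0, `sigma2_B`) and
#' genotype deviations ~ Normal(0, `sigma2_W`) under the observed design
#' (population sizes), re-estimates the variance components by the same
#' method of moments, and recomputes P_ST at the supplied `c` and `h2`. The
#' interval is the percentile 2.5/97.5 range.
#'
#' @inheritParams pst
#' @param n_iter bootstrap iterations (default 10000; fewer than 1000
#'   triggers a warning).
#' @param seed integer seed.
#' @param probs interval probabilities (default `c(0.025, 0.975)`).
#' @return numeric vector `c(lower, upper)`.
#' @export
pst_bootstrap_ci <- function(vc, c = 1, h2 = 1, n_iter = 10000, seed = NULL,
                             probs = c(0.025, 0.975)) {
  stopifnot(inherits(vc, "variance_components"))
  if (n_iter < 1000) warning("n_iter < 1000: bootstrap CI is unstable")
  .with_seed(seed, {
    bc <- .boot_components(vc, n_iter)
    p <- ifelse(c * bc$sigma2_B + h2 * bc$sigma2_W == 0, 0,
                c * bc$sigma2_B / (c * bc$sigma2_B + h2 * bc$sigma2_W))
    stats::setNames(stats::quantile(p, probs, names = FALSE),
                    c("lower", "upper"))
  })
}

#' c/h2 sensitivity analysis for P_ST
#'
#' For each ratio rho on the grid, sets `c = rho * h2`, computes the P_ST
#' point estimate and its parametric-bootstrap CI (reusing one set of
#' bootstrap component draws across the grid, which is valid because only
#' the c multiplier changes). The critical ratio is the smallest rho whose
#' CI lower bound exceeds `neutral_fst` — low values mean the
#' diversifying-selection verdict is robust to optimistic assumptions about
#' c and h2.
#'
#' @inheritParams pst_bootstrap_ci
#' @param neutral_fst neutral differentiation benchmark in \[0, 1).
#' @param ratio_grid grid of c/h2 ratios (default 0.05 to 2 by 0.05).
#' @return list of class `pst_sensitivity` with `curve` (data.frame: ratio,
#'   pst, ci_lower, ci_upper), `critical_ratio` (`NA` when no grid point
#'   qualifies), `h2`, `neutral_fst`.
#' @export
pst_sensitivity <- function(vc, h2, neutral_fst,
                            ratio_grid = seq(0.05, 2, by = 0.05),
                            n_iter = 10000, seed = NULL) {
  stopifnot(inherits(vc, "variance_components"),
            neutral_fst >= 0, neutral_fst < 1)
  if (!length(ratio_grid)) stop("empty ratio grid")
  ratio_grid <- sort(ratio_grid)
  bc <- .with_seed(seed, .boot_components(vc, n_iter))
  rows <- lapply(ratio_grid, function(rho) {
    cc <- rho * h2
    point <- pst(vc, c = cc, h2 = h2)
    den <- cc * bc$sigma2_B + h2 * bc$sigma2_W
    p <- ifelse(den == 0, 0, cc * bc$sigma2_B / den)
    ci <- stats::quantile(p, c(0.025, 0.975), names = FALSE)
    data.frame(ratio = rho, pst = point, ci_lower = ci[1], ci_upper = ci[2])
  })
  curve <- do.call(rbind, rows)
  crit <- curve$ratio[curve$ci_lower > neutral_fst]
  structure(list(curve = curve,
                 critical_ratio = if (length(crit)) min(crit) else NA_real_,
                 h2 = h2, neutral_fst = neutral_fst),
            class = "pst_sensitivity")
}

#' @exportS3Method base::print
print.pst_sensitivity <- function(x, ...) {
  cat("pst_sensitivity:", nrow(x$curve), "grid points; critical c/h2 =",
      format(x$critical_ratio, digits = 3),
      "at neutral Fst =", format(x$neutral_fst, digits = 3), "\n")
  invisible(x)
}

#' P_ST vs neutral F_ST verdict
#'
#' Declares diversifying selection when the lower bound of the H0
#' (`c = h2 = 1`) confidence interval exceeds the neutral F_ST benchmark;
#' otherwise the phenotypic differentiation is not distinguishable from
#' drift.
#'
#' @param ci length-2 vector (lower, upper) of the H0 bootstrap CI.
#' @param neutral_fst neutral benchmark.
#' @return `"diversifying"` or `"not-distinguishable"`.
#' @export
pst_fst_test <- function(ci, neutral_fst) {
  stopifnot(length(ci) == 2)
  if (ci[1] > neutral_fst) "diversifying" else "not-distinguishable"
}

#' Full P_ST analysis of one trait
#'
#' Runs [variance_components()], the H0 point estimate and bootstrap CI,
#' [pst_sensitivity()] and [pst_fst_test()], and (when replicate-level data
#' are supplied) [heritability()].
#'
#' @param means genotype-mean trait table.
#' @param pa population assignment.
#' @param neutral_fst neutral benchmark from [neutral_fst()].
#' @param trait trait name.
#' @param replicates optional replicate-level table for heritability.
#' @param n_iter bootstrap iterations.
#' @param ratio_grid sensitivity grid.
#' @param seed integer seed.
#' @return list of class `pst_result` with fields `trait`, `vc`, `pst`
#'   (H0 point estimate), `ci`, `h2` (`NA` without replicates),
#'   `sensitivity`, `critical_ratio`, `neutral_fst`, `verdict`.
#' @export
pst_analysis <- function(means, pa, neutral_fst, trait = NULL,
                         replicates = NULL, n_iter = 10000,
                         ratio_grid = seq(0.05, 2, by = 0.05), seed = NULL) {
  vc <- variance_components(means, pa, trait = trait)
  point <- pst(vc)
  ci <- pst_bootstrap_ci(vc, n_iter = n_iter, seed = seed)
  h2 <- if (!is.null(replicates)) heritability(replicates, trait = trait)$h2
        else NA_real_
  sens <- pst_sensitivity(vc, h2 = if (is.na(h2)) 1 else h2,
                          neutral_fst = neutral_fst,
                          ratio_grid = ratio_grid, n_iter = n_iter,
                          seed = seed)
  structure(list(trait = if (is.null(trait)) unique(means$trait) else trait,
                 vc = vc, pst = point, ci = ci, h2 = h2,
                 sensitivity = sens$curve,
                 critical_ratio = sens$critical_ratio,
                 neutral_fst = neutral_fst,
                 verdict = pst_fst_test(ci, neutral_fst)),
            class = "pst_result")
}

#' @exportS3Method base::print
print.pst_result <- function(x, ...) {
  cat("pst_result [", x$trait, "]: P_ST(H0) =", format(x$pst, digits = 3),
      "CI [", format(x$ci[1], digits = 3), ";",
      format(x$ci[2], digits = 3), "] vs neutral Fst",
      format(x$neutral_fst, digits = 3), "->", x$verdict, "\n")
  cat("  h2 =", format(x$h2, digits = 3), "| critical c/h2 =",
      format(x$critical_ratio, digits = 3), "\n")
  invisible(x)
}
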