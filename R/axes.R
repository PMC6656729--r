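#' Trait axis by correlation-matrix PCA
#'
#' Builds the leaf-economics or slow-fast axis: genotype-mean traits are
#' log10-transformed (all but the traits named in `log10_all_but` — RGR is
#' already a relative rate and stays on its natural scale), standardized,
#' and the first principal component of the correlation matrix gives each
#' genotype a score. The axis is oriented so that the loading of
#' `orient_trait` (by default the first trait whose name contains "LMA",
#' else the first trait) is positive: high scores = conservative/slow
#' phenotypes. Genotypes with any missing trait are dropped (complete-case
#' PCA) and reported via [message()].
#'
#' @param means genotype-mean trait table ([genotype_means()] output).
#' @param traits character vector (length >= 2) of trait names entering the
#'   axis.
#' @param axis_name label stored with the result (e.g. `"LES"`, `"SFC"`).
#' @param log10_all_but traits kept on their raw scale (default `"RGR"`).
#' @param orient_trait trait whose loading is pinned positive.
#' @return list of class `axis_scores` with `axis_name`, `loadings`
#'   (unit-norm named vector), `scores` (named by genotype),
#'   `var_explained` (fraction of variance on PC1), `n_dropped`.
#' @export
pca_axis <- function(means, traits, axis_name = "axis",
                     log10_all_but = "RGR", orient_trait = NULL) {
  stopifnot(length(traits) >= 2)
  m <- means[means$trait %in% traits, , drop = FALSE]
  wide <- stats::reshape(m[, c("genotype_id", "trait", "value")],
                         idvar = "genotype_id", timevar = "trait",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  miss <- setdiff(traits, names(wide))
  if (length(miss)) stop("trait(s) absent from table: ",
                         paste(miss, collapse = ", "))
  X <- as.matrix(wide[, traits, drop = FALSE])
  rownames(X) <- wide$genotype_id
  cc <- stats::complete.cases(X)
  n_dropped <- sum(!cc)
  if (n_dropped > 0) {
    message("pca_axis: ", n_dropped, " genotype(s) dropped (missing traits)")
  }
  X <- X[cc, , drop = FALSE]
  if (nrow(X) < 3) stop("need >= 3 complete-case genotypes")
  for (tr in setdiff(traits, log10_all_but)) {
    if (any(X[, tr] <= 0)) {
      stop("trait ", tr, " has non-positive values; cannot log10-transform")
    }
    X[, tr] <- log10(X[, tr])
  }
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant trait: ", paste(traits[sds == 0], collapse = ", "))
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  load1 <- pc$rotation[, 1]
  scores <- pc$x[, 1]
  if (is.null(orient_trait)) {
    hit <- grep("LMA", traits, value = TRUE)
    orient_trait <- if (length(hit)) hit[1] else traits[1]
  }
  if (load1[orient_trait] < 0) {
    load1 <- -load1
    scores <- -scores
  }
  structure(list(axis_name = axis_name,
                 loadings = load1,
                 scores = stats::setNames(scores, rownames(X)),
                 var_explained = pc$sdev[1]^2 / sum(pc$sdev^2),
                 n_dropped = n_dropped),
            class = "axis_scores")
}

#' @exportS3Method base::print
print.axis_scores <- function(x, ...) {
  cat("axis_scores [", x$axis_name, "]:", length(x$scores), "genotypes;",
      format(100 * x$var_explained, digits = 3),
      "% of trait covariation on PC1\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' Standardized major axis (SMA) regression
#'
#' Symmetric line fitting for trait-scaling relationships: the slope is
#' `sign(r) * s_y / s_x` and the intercept passes through the means. The
#' 95% slope interval follows the standard correlation-based construction
#' (Warton et al. 2006): with `B = F(0.95; 1, n-2) * (1 - r^2) / (n - 2)`,
#' the interval is `slope * (sqrt(B + 1) +/- sqrt(B))`, so it degenerates to
#' the point estimate when |r| = 1 and is symmetric on the log scale (the
#' SMA slope of y on x is the reciprocal of that of x on y).
#'
#' @param x,y numeric vectors (n >= 3, both with positive variance).
#' @return list of class `sma_fit` with `slope`, `intercept`, `r`,
#'   `p_value` (correlation test), `slope_ci`, `n`, and
#'   `slope_differs_from_1` (whether 1 lies outside the CI).
#' @export
sma_fit <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  stopifnot(n >= 3)
  sx <- stats::sd(x)
  sy <- stats::sd(y)
  if (sx == 0 || sy == 0) stop("zero variance in x or y")
  r <- stats::cor(x, y)
  slope <- (if (r < 0) -1 else 1) * sy / sx
  intercept <- mean(y) - slope * mean(x)
  B <- stats::qf(0.95, 1, n - 2) * (1 - r^2) / (n - 2)
  ci <- slope * c(sqrt(B + 1) - sqrt(B), sqrt(B + 1) + sqrt(B))
  ci <- sort(ci)
  p <- stats::cor.test(x, y)$p.value
  structure(list(slope = slope, intercept = intercept, r = r, p_value = p,
                 slope_ci = stats::setNames(ci, c("lower", "upper")), n = n,
                 slope_differs_from_1 = (1 < ci[1] || 1 > ci[2])),
            class = "sma_fit")
}

#' @exportS3Method base::print
print.sma_fit <- function(x, ...) {
  cat("sma_fit: slope =", format(x$slope, digits = 4),
      "[", format(x$slope_ci[1], digits = 4), ";",
      format(x$slope_ci[2], digits = 4), "], r =",
      format(x$r, digits = 3), ", n =", x$n, "\n")
  invisible(x)
}

#' Kinship-aware generalized least squares slope
#'
#' Fits `y ~ x` by GLS with residual covariance proportional to the realized
#' relationship matrix `K` (a small ridge is added, and escalated, until the
#' Cholesky factorization succeeds; the jitter used is reported). The
#' kinship-corrected slope is compared with the OLS slope via
#' `|b_GLS - b_OLS| / sqrt(se_GLS^2 + se_OLS^2)`, flagging whether
#' accounting for relatedness changes the relationship.
#'
#' @param y,x numeric vectors, aligned with `K`'s rows.
#' @param K kinship matrix from [kinship_matrix()] restricted to the
#'   analyzed samples.
#' @param jitter initial ridge proportion of the mean diagonal
#'   (default 1e-8).
#' @return list with `slope`, `se`, `intercept`, `ols_slope`, `ols_se`,
#'   `z_diff`, `differs` (|z| > 1.96), `jitter_used`.
#' @export
gls_kinship_fit <- function(y, x, K, jitter = 1e-8) {
  n <- length(y)
  stopifnot(length(x) == n, nrow(K) == n, ncol(K) == n)
  V <- as.matrix(K)
  scale <- mean(diag(V))
  eps <- jitter * scale
  R <- NULL
  for (i in 1:12) {
    R <- tryCatch(chol(V + diag(eps, n)), error = function(e) NULL)
    if (!is.null(R)) break
    eps <- eps * 10
  }
  if (is.null(R)) stop("kinship covariance singular even after ridge jitter")
  X <- cbind(1, x)
  Xw <- backsolve(R, X, transpose = TRUE)
  yw <- backsolve(R, y, transpose = TRUE)
  XtX <- crossprod(Xw)
  beta <- drop(solve(XtX, crossprod(Xw, yw)))
  res <- yw - Xw %*% beta
  s2 <- sum(res^2) / (n - 2)
  se <- sqrt(diag(s2 * solve(XtX)))
  ols <- stats::lm(y ~ x)
  bo <- stats::coef(summary(ols))
  z <- (beta[2] - bo[2, 1]) / sqrt(se[2]^2 + bo[2, 2]^2)
  list(slope = unname(beta[2]), se = unname(se[2]),
       intercept = unname(beta[1]),
       ols_slope = unname(bo[2, 1]), ols_se = unname(bo[2, 2]),
       z_diff = unname(z), differs = abs(z) > 1.96,
       jitter_used = eps / scale)
}
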