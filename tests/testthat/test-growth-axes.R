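test_that("noiseless logistic is recovered to 1e-6 relative", {
  day <- 1:35
  area <- 2000 / (1 + exp(-0.25 * (day - 20)))
  fit <- fit_logistic_growth(day, area)
  expect_true(fit$converged)
  expect_equal(fit$K, 2000, tolerance = 1e-6)
  expect_equal(fit$r, 0.25, tolerance = 1e-6)
  expect_equal(fit$t0, 20, tolerance = 1e-6)
})

test_that("a plateau-free series is flagged unconverged", {
  day <- 1:20
  expect_warning(fit <- fit_logistic_growth(day, 5 * day), "unconverged")
  expect_false(fit$converged)
  expect_error(rgr_at_inflection(fit), "converged")
})

test_that("RGR equals r/2 and matches numeric differentiation", {
  fit <- fit_logistic_growth(1:35, 1500 / (1 + exp(-0.2 * (1:35 - 17))))
  expect_equal(rgr_at_inflection(fit), 0.1, tolerance = 1e-8)
  # finite-difference (dA/dt)/A at the inflection
  A <- function(t) fit$K / (1 + exp(-fit$r * (t - fit$t0)))
  h <- 1e-5
  num <- (A(fit$t0 + h) - A(fit$t0 - h)) / (2 * h) / A(fit$t0)
  expect_equal(rgr_at_inflection(fit), num, tolerance = 1e-8)
})

test_that("RGR is invariant to rescaling the areas", {
  gs <- simulate_growth_series(n_plants = 1, noise_sd = 0.01, seed = 33)
  f1 <- fit_logistic_growth(gs$day, gs$area)
  f2 <- fit_logistic_growth(gs$day, gs$area * 17.3)
  expect_equal(rgr_at_inflection(f1), rgr_at_inflection(f2),
               tolerance = 1e-6)
})

test_that("noisy growth series recover the rate parameter", {
  gs <- simulate_growth_series(n_plants = 50, K = 2000, r = 0.25, t0 = 20,
                               noise_sd = 0.02, n_days = 30, seed = 44)
  fits <- fit_growth_table(gs)
  expect_true(all(fits$converged))
  expect_lt(stats::median(abs(fits$r - 0.25) / 0.25), 0.05)
})

# --- trait axes ---------------------------------------------------------

make_axis_table <- function(n = 120, noise = 0.15, seed = 50) {
  withr::with_seed(seed, {
    latent <- rnorm(n)                       # conservative = high latent
    g <- sprintf("g%03d", seq_len(n))
    vals <- list(
      LMA = 10^(1.5 + 0.2 * latent + rnorm(n, 0, noise * 0.2)),
      LLS = 10^(1.4 + 0.15 * latent + rnorm(n, 0, noise * 0.15)),
      A_mass = 10^(2.3 - 0.25 * latent + rnorm(n, 0, noise * 0.25)))
    tt <- do.call(rbind, lapply(names(vals), function(tr) {
      data.frame(genotype_id = g, site_id = g, trait = tr,
                 value = vals[[tr]], stringsAsFactors = FALSE)
    }))
    list(tt = tt, latent = stats::setNames(latent, g))
  })
}

test_that("axis orientation pins the LMA loading positive and
           anti-correlates assimilation", {
  ax <- make_axis_table()
  res <- pca_axis(ax$tt, c("A_mass", "LMA", "LLS"), axis_name = "LES")
  expect_gt(res$loadings["LMA"], 0)
  expect_lt(res$loadings["A_mass"], 0)
  expect_equal(sum(res$loadings^2), 1)
  expect_gt(res$var_explained, 0.5)
  # high score = conservative side (high latent)
  expect_gt(cor(res$scores, ax$latent[names(res$scores)]), 0.8)
})

test_that("two perfectly correlated traits load equally on a single axis", {
  g <- sprintf("g%02d", 1:20)
  x <- 10^seq(1, 2, length.out = 20)
  tt <- rbind(data.frame(genotype_id = g, site_id = g, trait = "LMA",
                         value = x),
              data.frame(genotype_id = g, site_id = g, trait = "plant_LMA",
                         value = x^2))
  res <- pca_axis(tt, c("LMA", "plant_LMA"))
  expect_equal(res$var_explained, 1)
  expect_equal(abs(unname(res$loadings)), rep(sqrt(0.5), 2))
})

test_that("axis scores are invariant to trait order; constant traits error", {
  ax <- make_axis_table()
  a <- pca_axis(ax$tt, c("A_mass", "LMA", "LLS"))
  b <- pca_axis(ax$tt, c("LLS", "A_mass", "LMA"))
  expect_equal(a$scores, b$scores, tolerance = 1e-12)
  cst <- ax$tt
  cst$value[cst$trait == "LLS"] <- 30
  expect_error(pca_axis(cst, c("A_mass", "LMA", "LLS")), "LLS")
})

test_that("independent traits spread variance near 1/p", {
  withr::with_seed(61, {
    g <- sprintf("g%04d", 1:2000)
    tt <- do.call(rbind, lapply(c("t1", "t2", "t3", "t4"), function(tr) {
      data.frame(genotype_id = g, site_id = g, trait = tr,
                 value = 10^rnorm(2000), stringsAsFactors = FALSE)
    }))
    res <- pca_axis(tt, c("t1", "t2", "t3", "t4"), orient_trait = "t1")
    expect_lt(abs(res$var_explained - 0.25), 0.05)
  })
})

test_that("SMA slope arithmetic, symmetry and degenerate identity", {
  withr::with_seed(70, {
    x <- rnorm(200)
    y <- -0.5 * x + rnorm(200, 0, sqrt(1 - 0.25))
    y <- (y / sd(y)) * 2 * sd(x)          # force s_y / s_x = 2
    f <- sma_fit(x, y)
    expect_equal(f$slope, sign(cor(x, y)) * 2, tolerance = 1e-12)
    # symmetry: b_xy * b_yx = 1 in absolute value
    g <- sma_fit(y, x)
    expect_equal(abs(f$slope * g$slope), 1, tolerance = 1e-12)
  })
  idf <- sma_fit(1:10, 1:10)
  expect_equal(idf$slope, 1)
  expect_equal(unname(idf$slope_ci), c(1, 1), tolerance = 1e-6)
  expect_false(idf$slope_differs_from_1)
  expect_error(sma_fit(rep(1, 5), 1:5), "variance")
})

test_that("kinship GLS reduces to OLS under identity covariance", {
  withr::with_seed(80, {
    x <- rnorm(50)
    y <- 1 + 2 * x + rnorm(50)
    K <- diag(50)
    fit <- gls_kinship_fit(y, x, K)
    ols <- stats::lm(y ~ x)
    expect_equal(fit$slope, unname(coef(ols)[2]), tolerance = 1e-10)
    expect_equal(fit$se, summary(ols)$coefficients[2, 2],
                 tolerance = 1e-10)
    expect_false(fit$differs)
  })
})

test_that("block-diagonal kinship shrinks a group-confounded slope toward
           the within-group slope", {
  withr::with_seed(81, {
    n <- 60
    grp <- rep(0:1, each = n / 2)
    x <- rnorm(n) + 4 * grp          # group means confound the slope
    y <- 0.5 * x + 6 * grp + rnorm(n, 0, 0.5)
    rho <- 0.9
    K <- outer(grp, grp, function(a, b) ifelse(a == b, rho, 0))
    diag(K) <- 1
    fit <- gls_kinship_fit(y, x, K)
    ols_all <- unname(coef(stats::lm(y ~ x))[2])
    within <- unname(coef(stats::lm(y ~ x + factor(grp)))[2])
    # GLS discounts the between-group contrast
    expect_lt(abs(fit$slope - within), abs(ols_all - within))
  })
})

test_that("kinship GLS does not spuriously shift unconfounded slopes", {
  withr::with_seed(82, {
    hits <- 0
    for (i in 1:20) {
      sim <- simulate_genotypes(n_pops = 2, pop_sizes = 20, n_snps = 300,
                                fst = 0.05)
      K <- kinship_matrix(sim$genotypes)
      x <- rnorm(40)
      y <- 1.5 * x + rnorm(40)
      fit <- gls_kinship_fit(y, x, K)
      if (!fit$differs) hits <- hits + 1
    }
    expect_gte(hits / 20, 0.9)
  })
})

test_that("LES and slow-fast axes agree when driven by one latent factor", {
  withr::with_seed(90, {
    n <- 200
    latent <- rnorm(n)
    g <- sprintf("g%03d", seq_len(n))
    mk <- function(tr, b0, b, s, raw = FALSE) {
      v <- b0 + b * latent + rnorm(n, 0, s)
      data.frame(genotype_id = g, site_id = g, trait = tr,
                 value = if (raw) v else 10^v, stringsAsFactors = FALSE)
    }
    tt <- rbind(mk("A_mass", 2.3, -0.25, 0.1), mk("LMA", 1.5, 0.2, 0.08),
                mk("LLS", 1.4, 0.15, 0.08),
                mk("plant_A_mass", 2.2, -0.22, 0.1),
                mk("plant_LMA", 1.5, 0.18, 0.08),
                mk("AM", 1.6, 0.2, 0.1),
                mk("RGR", 0.11, -0.015, 0.006, raw = TRUE))
    les <- pca_axis(tt, c("A_mass", "LMA", "LLS"), axis_name = "LES")
    sfc <- pca_axis(tt, c("plant_A_mass", "plant_LMA", "AM", "RGR"),
                    axis_name = "SFC", orient_trait = "plant_LMA")
    expect_gt(cor(les$scores, sfc$scores[names(les$scores)]), 0.8)
  })
})
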