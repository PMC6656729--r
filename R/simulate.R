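#' Simulate island-model genotypes for a selfing panel
#'
#' Draws haploid-coded genotypes under the Balding-Nichols island model: for
#' each SNP an ancestral frequency is drawn uniformly from
#' `ancestral_range`, each population's frequency is Beta-distributed around
#' it with the spread set by `fst`, and accession dosages are Bernoulli draws
#' from the population frequency. Admixed accessions draw every SNP from an
#' equal two-population mixture, so their true ancestry rows (0.5/0.5) fall
#' at the boundary of the majority rule and [assign_populations()] labels
#' them `"Admixed"`.
#'
#' @param n_pops number of differentiated populations.
#' @param pop_sizes accessions per population (recycled to `n_pops`).
#' @param n_snps number of bi-allelic SNPs.
#' @param fst target differentiation F in (0, 1); values below 1e-12 take
#'   the undifferentiated limit (population frequency = ancestral frequency).
#' @param ancestral_range range of ancestral allele frequencies.
#' @param frac_intergenic fraction of SNPs flagged intergenic.
#' @param frac_admixed fraction of the final panel that is admixed; the
#'   admixed count is `round(frac_admixed / (1 - frac_admixed) *
#'   sum(pop_sizes))` so admixed accessions make up `frac_admixed` of all
#'   accessions.
#' @param n_chrom number of chromosomes the SNPs are spread over.
#' @param seed integer seed; when non-NULL the draw is reproducible and the
#'   caller's RNG state is untouched.
#' @return list with elements `genotypes` (a [genotype_matrix()]), `q`
#'   (ancestry-fraction matrix, rows = accessions) and `truth` (list of true
#'   population labels and per-population allele frequencies).
#' @export
simulate_genotypes <- function(n_pops = 5, pop_sizes = 60, n_snps = 5000,
                               fst = 0.1, ancestral_range = c(0.1, 0.9),
                               frac_intergenic = 0.5, frac_admixed = 0,
                               n_chrom = 5, seed = NULL) {
  stopifnot(n_pops >= 1, fst >= 0, fst < 1,
            frac_admixed >= 0, frac_admixed < 1)
  pop_sizes <- rep_len(pop_sizes, n_pops)
  stopifnot(all(pop_sizes >= 2))
  .with_seed(seed, {
    n_pure <- sum(pop_sizes)
    n_adm <- round(frac_admixed / (1 - frac_admixed) * n_pure)
    n <- n_pure + n_adm
    p_anc <- stats::runif(n_snps, ancestral_range[1], ancestral_range[2])
    if (fst < 1e-12) {
      pf <- matrix(p_anc, n_pops, n_snps, byrow = TRUE)
    } else {
      shape <- (1 - fst) / fst
      pf <- matrix(stats::rbeta(n_pops * n_snps,
                                rep(p_anc * shape, each = n_pops),
                                rep((1 - p_anc) * shape, each = n_pops)),
                   n_pops, n_snps)
    }
    pop <- rep(seq_len(n_pops), pop_sizes)
    dos <- matrix(0, n, n_snps)
    dos[seq_len(n_pure), ] <-
      (matrix(stats::runif(n_pure * n_snps), n_pure) < pf[pop, ]) + 0
    qmat <- matrix(0, n, n_pops)
    qmat[cbind(seq_len(n_pure), pop)] <- 1
    if (n_adm > 0) {
      for (i in seq_len(n_adm)) {
        par <- sample.int(n_pops, 2)
        mix <- 0.5 * pf[par[1], ] + 0.5 * pf[par[2], ]
        dos[n_pure + i, ] <- (stats::runif(n_snps) < mix) + 0
        qmat[n_pure + i, par] <- 0.5
      }
    }
    ids <- sprintf("acc_%04d", seq_len(n))
    rownames(dos) <- ids
    rownames(qmat) <- ids
    colnames(qmat) <- paste0("cluster_", seq_len(n_pops))
    chrom <- sort(rep_len(seq_len(n_chrom), n_snps))
    pos <- unlist(lapply(split(seq_len(n_snps), chrom), function(ix) {
      cumsum(sample(200:1800, length(ix), replace = TRUE))
    }), use.names = FALSE)
    snps <- data.frame(
      chrom = paste0("chr", chrom), pos = pos,
      id = sprintf("snp_%05d", seq_len(n_snps)),
      intergenic = stats::runif(n_snps) < frac_intergenic,
      stringsAsFactors = FALSE)
    list(genotypes = genotype_matrix(dos, snps),
         q = qmat,
         truth = list(pop = stats::setNames(
           c(paste0("group_", pop), rep("Admixed", n_adm)), ids),
           pop_freq = pf, p_anc = p_anc))
  })
}

#' Simulate phenotypes with a set variance decomposition
#'
#' Builds genotype values as population effect + within-population deviation
#' and adds replicate-level noise. The population effect has variance
#' `sigma2_B`, split into a genetic part (`c_true * sigma2_B`) and an
#' environmental part; the within-population deviation has variance
#' `sigma2_W`, split by `h2_true`. Replicate noise is scaled so that the
#' replicate-level repeatability (one-way ANOVA across genotypes) targets
#' `h2_true`: its variance is `(sigma2_B + sigma2_W) * (1 - h2_true) /
#' h2_true`. Admixed accessions receive a population effect of 0 (the
#' ancestral mean).
#'
#' @param pa population assignment as returned by [assign_populations()].
#' @param sigma2_B between-population variance of genotype values
#'   (trait units squared).
#' @param sigma2_W within-population variance of genotype values.
#' @param c_true fraction of `sigma2_B` that is genetic.
#' @param h2_true heritability in (0, 1]; also the targeted replicate-level
#'   repeatability.
#' @param n_reps replicates per genotype; must be >= 2 unless `h2_true = 1`.
#' @param trait trait name written to the table.
#' @param seed integer seed (see [simulate_genotypes()]).
#' @return Trait table (data.frame with `genotype_id`, `replicate_id`,
#'   `site_id`, `trait`, `value`); attribute `"genotype_values"` carries the
#'   noise-free genotype values.
#' @export
simulate_phenotypes <- function(pa, sigma2_B = 1, sigma2_W = 1, c_true = 1,
                                h2_true = 1, n_reps = 4, trait = "trait",
                                seed = NULL) {
  stopifnot(sigma2_B >= 0, sigma2_W >= 0, c_true >= 0, c_true <= 1,
            h2_true > 0, h2_true <= 1, n_reps >= 1)
  pops <- setdiff(unique(pa), "Admixed")
  if (length(pops) < 2) stop("need >= 2 non-admixed populations")
  if (n_reps < 2 && h2_true < 1) {
    stop("h2_true < 1 requires n_reps >= 2 (heritability not estimable)")
  }
  .with_seed(seed, {
    n <- length(pa)
    b <- stats::rnorm(length(pops), 0, sqrt(c_true * sigma2_B)) +
      stats::rnorm(length(pops), 0, sqrt((1 - c_true) * sigma2_B))
    names(b) <- pops
    popeff <- ifelse(pa == "Admixed", 0, b[pa])
    dev <- stats::rnorm(n, 0, sqrt(h2_true * sigma2_W)) +
      stats::rnorm(n, 0, sqrt((1 - h2_true) * sigma2_W))
    gval <- popeff + dev
    sd_e <- sqrt((sigma2_B + sigma2_W) * (1 - h2_true) / h2_true)
    tt <- data.frame(
      genotype_id = rep(names(pa), each = n_reps),
      replicate_id = rep(seq_len(n_reps), n),
      site_id = rep(names(pa), each = n_reps),
      trait = trait,
      value = rep(gval, each = n_reps) +
        stats::rnorm(n * n_reps, 0, sd_e),
      stringsAsFactors = FALSE)
    attr(tt, "genotype_values") <- stats::setNames(gval, names(pa))
    tt
  })
}

#' Simulate logistic rosette-growth series
#'
#' Daily rosette areas follow `K / (1 + exp(-r (t - t0)))` with additive
#' Gaussian measurement noise of standard deviation `noise_sd * K`,
#' truncated at 0 (areas cannot be negative, so the noise tail is not
#' exactly Gaussian near germination).
#'
#' @param n_plants number of plants.
#' @param K asymptotic rosette area (mm^2).
#' @param r logistic rate (d^-1).
#' @param t0 inflection time (d); must lie within the observation window.
#' @param noise_sd measurement noise as a fraction of `K`.
#' @param n_days length of the daily series.
#' @param seed integer seed.
#' @return data.frame with columns `plant`, `day`, `area`.
#' @export
simulate_growth_series <- function(n_plants = 1, K = 2000, r = 0.25, t0 = 20,
                                   noise_sd = 0.02, n_days = 35, seed = NULL) {
  stopifnot(K > 0, r > 0, t0 > 0, t0 < n_days, noise_sd >= 0)
  .with_seed(seed, {
    day <- seq_len(n_days)
    mu <- K / (1 + exp(-r * (day - t0)))
    out <- do.call(rbind, lapply(seq_len(n_plants), function(i) {
      area <- pmax(0, mu + stats::rnorm(n_days, 0, noise_sd * K))
      data.frame(plant = sprintf("plant_%03d", i), day = day, area = area,
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
}

#' Simulate a climate table coupled to a trait score
#'
#' One "causal" climate variable is a linear function of the supplied
#' slow-fast scores plus Gaussian noise; the remaining variables are
#' independent standard normal deviates, giving a null background against
#' which correlation screening and model selection can be calibrated.
#'
#' @param scores named numeric vector of per-genotype axis scores; names
#'   become `site_id` (one collecting site per genotype).
#' @param coupling slope of the causal variable per unit score. Ignored when
#'   `target_r` is given.
#' @param target_r optional population-level Pearson correlation between
#'   score and the causal variable; the coupling slope is derived from it as
#'   `sign(target_r) * sqrt(r^2 / (1 - r^2)) * noise_sd / sd(scores)`.
#' @param noise_sd noise standard deviation of the causal variable.
#' @param n_vars total number of climate variables (>= 2); the first two are
#'   named `MAT` and `MAR`.
#' @param causal name of the causal column (default `"MAR"`).
#' @param seed integer seed.
#' @return data.frame with `site_id` plus `n_vars` numeric columns.
#' @export
simulate_climate <- function(scores, coupling = 0, target_r = NULL,
                             noise_sd = 1, n_vars = 19, causal = "MAR",
                             seed = NULL) {
  stopifnot(all(is.finite(scores)), n_vars >= 2, !is.null(names(scores)))
  vars <- c("MAT", "MAR",
            if (n_vars > 2) sprintf("bio%02d", seq_len(n_vars - 2) + 2))
  if (!causal %in% vars) stop("causal variable must be one of the columns")
  if (!is.null(target_r)) {
    stopifnot(abs(target_r) < 1)
    coupling <- sign(target_r) * sqrt(target_r^2 / (1 - target_r^2)) *
      noise_sd / stats::sd(scores)
  }
  .with_seed(seed, {
    n <- length(scores)
    cl <- as.data.frame(matrix(stats::rnorm(n * n_vars), n, n_vars,
                               dimnames = list(NULL, vars)))
    cl[[causal]] <- coupling * as.numeric(scores) +
      stats::rnorm(n, 0, noise_sd)
    cbind(site_id = names(scores), cl, stringsAsFactors = FALSE)
  })
}

# Evaluate expr under a fixed seed without disturbing the caller's RNG;
# NULL seed = use the current RNG stream.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}
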