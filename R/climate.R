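#' Trait-climate correlation screen
#'
#' Pearson correlation (and its two-sided test) between an axis score and
#' every climate variable, one row per variable. No multiplicity correction
#' is applied — the screen mirrors the exploratory per-variable tables of
#' trait-climate studies; the count of variables significant at 0.05 is
#' attached as the attribute `"n_significant"`. Genotypes without a matching
#' climate site are dropped and their count reported via [message()].
#'
#' @param scores [pca_axis()] result, or a named numeric vector of scores
#'   whose names match `climate$site_id` (one collecting site per genotype).
#' @param climate climate table: data.frame with `site_id` plus numeric
#'   variable columns.
#' @return data.frame with columns `variable`, `r`, `p`, `significant`.
#' @export
climate_correlations <- function(scores, climate) {
  s <- if (inherits(scores, "axis_scores")) scores$scores else scores
  stopifnot(!is.null(names(s)), "site_id" %in% names(climate))
  idx <- match(names(s), climate$site_id)
  drop <- sum(is.na(idx))
  if (drop > 0) {
    message("climate_correlations: ", drop, " genotype(s) without climate")
  }
  s <- s[!is.na(idx)]
  cl <- climate[idx[!is.na(idx)], , drop = FALSE]
  if (length(s) < 10) stop("need >= 10 matched genotype-site pairs")
  vars <- setdiff(names(cl), "site_id")
  out <- do.call(rbind, lapply(vars, function(v) {
    ct <- stats::cor.test(s, cl[[v]])
    data.frame(variable = v, r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  }))
  out$significant <- out$p < 0.05
  attr(out, "n_significant") <- sum(out$significant)
  rownames(out) <- NULL
  out
}

# Score/climate merge shared by the model-selection functions.
.climate_frame <- function(scores, climate) {
  s <- if (inherits(scores, "axis_scores")) scores$scores else scores
  idx <- match(names(s), climate$site_id)
  keep <- !is.na(idx)
  df <- climate[idx[keep], setdiff(names(climate), "site_id"),
                drop = FALSE]
  df$score <- as.numeric(s[keep])
  rownames(df) <- names(s)[keep]
  df
}

#' Stepwise AIC selection of a climate model
#'
#' Bidirectional stepwise selection by AIC, starting from the full model
#' with all candidate climate variables (the "formal" model) and free to
#' drop or re-add terms. Exactly collinear (aliased) columns are removed
#' before selection with a warning. If the stepwise path somehow ends above
#' the intercept-only model's AIC, the intercept-only model is returned
#' instead, so the selected model never has higher AIC than either extreme.
#'
#' @inheritParams climate_correlations
#' @param candidates candidate variable names (default: all climate
#'   columns).
#' @return list of class `climate_model` with `selected_vars`,
#'   `coefficients`, `aic`, `aic_full`, `model` (the fitted [stats::lm()]),
#'   `training_ranges` (per-variable min/max for extrapolation flagging).
#' @export
stepwise_aic <- function(scores, climate, candidates = NULL) {
  df <- .climate_frame(scores, climate)
  if (is.null(candidates)) candidates <- setdiff(names(df), "score")
  stopifnot(length(candidates) >= 1, all(candidates %in% names(df)))
  if (nrow(df) <= 3 * length(candidates)) {
    stop("need n > 3 x candidate variables")
  }
  full <- stats::lm(stats::reformulate(candidates, response = "score"),
                    data = df)
  alias <- names(which(is.na(stats::coef(full))))
  if (length(alias)) {
    warning("collinear variable(s) dropped: ", paste(alias, collapse = ", "))
    candidates <- setdiff(candidates, alias)
    full <- stats::lm(stats::reformulate(candidates, response = "score"),
                      data = df)
  }
  null <- stats::lm(score ~ 1, data = df)
  sel <- stats::step(full, direction = "both",
                     scope = list(lower = stats::formula(null),
                                  upper = stats::formula(full)),
                     trace = 0)
  if (stats::AIC(sel) > stats::AIC(null)) sel <- null
  vars <- setdiff(all.vars(stats::formula(sel)), "score")
  structure(list(selected_vars = vars,
                 coefficients = stats::coef(sel),
                 aic = stats::AIC(sel), aic_full = stats::AIC(full),
                 model = sel,
                 training_ranges = if (length(vars))
                   vapply(df[vars], range, numeric(2)) else NULL),
            class = "climate_model")
}

#' @exportS3Method base::print
print.climate_model <- function(x, ...) {
  cat("climate_model:", length(x$selected_vars), "variable(s) selected (",
      paste(x$selected_vars, collapse = ", "), "); AIC",
      format(x$aic, digits = 5), "vs full", format(x$aic_full, digits = 5),
      "\n")
  invisible(x)
}

#' Repeated k-fold cross-validated predictive r-squared
#'
#' Splits the data into `k` folds, `reps` times with different random
#' partitions; per repetition, out-of-fold predictions are pooled and
#' scored against the observations. When `spec = "stepwise"` the variable
#' selection is re-run inside every training fold, so the reported accuracy
#' carries no selection leakage. Two metrics are returned: the squared
#' Pearson correlation of pooled predictions vs observations (`cv_r2`, the
#' primary metric; defined as 0 when the predictions are constant) and the
#' pooled `1 - SSE/SST` (`cv_r2_sse`).
#'
#' @inheritParams stepwise_aic
#' @param spec `"stepwise"` (in-fold selection), `"full"` (all candidates),
#'   or a fixed right-hand-side formula such as `~ MAT + MAR`.
#' @param k folds (default 10).
#' @param reps repetitions (default 10).
#' @param seed integer seed for the fold partitions.
#' @return list with `cv_r2`, `cv_r2_sse`, `per_rep` (data.frame of both
#'   metrics per repetition), `k`, `reps`.
#' @export
repeated_cv_r2 <- function(scores, climate, spec = "stepwise",
                           candidates = NULL, k = 10, reps = 10,
                           seed = NULL) {
  df <- .climate_frame(scores, climate)
  if (is.null(candidates)) candidates <- setdiff(names(df), "score")
  n <- nrow(df)
  stopifnot(n >= 2 * k)
  .with_seed(seed, {
    per_rep <- vapply(seq_len(reps), function(rep) {
      fold <- sample(rep_len(seq_len(k), n))
      pred <- rep(NA_real_, n)
      for (f in seq_len(k)) {
        tr <- df[fold != f, , drop = FALSE]
        te <- df[fold == f, , drop = FALSE]
        if (stats::sd(tr$score) == 0) {
          message("repeated_cv_r2: constant response in a training fold; ",
                  "fold skipped")
          next
        }
        fit <- if (identical(spec, "stepwise")) {
          cl_tr <- cbind(site_id = rownames(tr), tr)
          stepwise_aic(stats::setNames(tr$score, rownames(tr)), cl_tr,
                       candidates = candidates)$model
        } else if (identical(spec, "full")) {
          stats::lm(stats::reformulate(candidates, response = "score"),
                    data = tr)
        } else {
          stats::lm(stats::update(stats::as.formula(spec), score ~ .),
                    data = tr)
        }
        pred[fold == f] <- stats::predict(fit, newdata = te)
      }
      ok <- !is.na(pred)
      r2 <- if (stats::sd(pred[ok]) == 0) 0
            else stats::cor(pred[ok], df$score[ok])^2
      sse <- sum((df$score[ok] - pred[ok])^2)
      sst <- sum((df$score[ok] - mean(df$score[ok]))^2)
      c(r2 = r2, r2_sse = 1 - sse / sst)
    }, numeric(2))
    list(cv_r2 = mean(per_rep["r2", ]),
         cv_r2_sse = mean(per_rep["r2_sse", ]),
         per_rep = data.frame(rep = seq_len(reps), r2 = per_rep["r2", ],
                              r2_sse = per_rep["r2_sse", ]),
         k = k, reps = reps)
  })
}

#' Predict axis scores over a climate grid
#'
#' Applies the selected linear climate model row-wise to a new climate
#' table (e.g. a spatial grid of climate normals). Rows where any selected
#' variable falls outside its training range are flagged as extrapolation.
#'
#' @param model [stepwise_aic()] result.
#' @param grid climate table containing at least the selected variables
#'   (plus any identifier columns, passed through).
#' @return data.frame: the grid's identifier columns, `predicted_score`,
#'   `extrapolation`.
#' @export
predict_grid <- function(model, grid) {
  stopifnot(inherits(model, "climate_model"))
  miss <- setdiff(model$selected_vars, names(grid))
  if (length(miss)) {
    stop("grid lacks selected variable(s): ", paste(miss, collapse = ", "))
  }
  pred <- stats::predict(model$model, newdata = grid)
  extra <- rep(FALSE, nrow(grid))
  for (v in model$selected_vars) {
    rg <- model$training_ranges[, v]
    extra <- extra | grid[[v]] < rg[1] | grid[[v]] > rg[2]
  }
  idcols <- intersect(c("site_id", "lon", "lat"), names(grid))
  out <- cbind(grid[, idcols, drop = FALSE],
               predicted_score = as.numeric(pred),
               extrapolation = extra)
  rownames(out) <- NULL
  out
}
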