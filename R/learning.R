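# Regression on log10 KD: standardization, the four regressors, feature
# selection by importance elimination and correlation pruning, 10-fold
# cross-validation and the shuffled-label control.
#
# Feature data are a plain numeric matrix `x` (rows = variants, named
# columns = feature ids) and response `y` = log10 KD at pH 7.0.

.ALGORITHMS <- c("MLR", "SVR", "RFR", "MLP")

#' Fit a feature scaler
#'
#' Columns are centered and scaled to unit variance on the data given
#' (training portion only, in cross-validation); constant columns cannot
#' be scaled and are dropped with a warning.
#'
#' @param x numeric feature matrix with column names.
#' @return a `fc_scaler` (centers, scales, kept column names).
#' @export
fit_scaler <- function(x) {
  x <- as.matrix(x)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  const <- scl < 1e-12 | !is.finite(scl)
  if (any(const))
    warning("dropping ", sum(const), " constant feature column(s): ",
            paste(utils::head(colnames(x)[const], 5), collapse = ", "),
            if (sum(const) > 5) ", ...")
  structure(list(center = ctr[!const], scale = scl[!const],
                 keep = colnames(x)[!const]),
            class = "fc_scaler")
}

#' Apply a fitted scaler
#' @param scaler a `fc_scaler`.
#' @param x feature matrix (must contain the scaler's columns).
#' @return scaled matrix restricted to the scaler's columns.
#' @export
apply_scaler <- function(scaler, x) {
  stopifnot(inherits(scaler, "fc_scaler"))
  x <- as.matrix(x)[, scaler$keep, drop = FALSE]
  scale(x, center = scaler$center, scale = scaler$scale)[, , drop = FALSE]
}

#' Fit one of the four regressors
#'
#' Hyperparameters follow the defaults used throughout the package:
#' \describe{
#'   \item{MLR}{ordinary least squares with intercept.}
#'   \item{SVR}{radial-basis kernel, `C = 1`, epsilon-tube 0.1,
#'     tolerance 1e-3, `gamma = 1/p`.}
#'   \item{RFR}{random forest, maximum tree depth 10, impurity importance,
#'     otherwise \pkg{ranger} defaults.}
#'   \item{MLP}{hidden layers (20, 2), tanh, L2 penalty 20, full-batch
#'     BFGS, up to 4000 iterations, tolerance 1e-5, fixed init seed.}
#' }
#' Features are assumed already standardized (see [fit_scaler()]).
#'
#' @param x standardized feature matrix.
#' @param y numeric response (log10 KD).
#' @param algorithm one of `"MLR"`, `"SVR"`, `"RFR"`, `"MLP"`.
#' @param seed integer seed for the stochastic fitters (RFR bootstrap, MLP
#'   initialization).
#' @return a `fc_regressor`.
#' @export
fit_regressor <- function(x, y, algorithm = c("MLR", "SVR", "RFR", "MLP"),
                          seed = 1L) {
  algorithm <- match.arg(algorithm)
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y))
  df <- data.frame(x, check.names = FALSE)
  fit <- switch(algorithm,
    MLR = stats::lm(y ~ ., data = cbind(df, y = y)),
    SVR = e1071::svm(x, y, type = "eps-regression", kernel = "radial",
                     cost = 1, epsilon = 0.1, tolerance = 1e-3,
                     gamma = 1 / ncol(x), scale = FALSE, fitted = FALSE),
    RFR = ranger::ranger(y = y, x = df, max.depth = 10,
                         importance = "impurity", seed = seed,
                         num.threads = 1),
    MLP = .mlp_fit(x, y, seed = seed))
  structure(list(algorithm = algorithm, fit = fit,
                 features = colnames(x), seed = seed,
                 # an epsilon-SVR whose training residuals all fall inside
                 # the tube has no support vectors; predict falls back to
                 # the training mean (which is inside the tube of every y)
                 fallback = mean(y)),
            class = "fc_regressor")
}

#' @export
predict.fc_regressor <- function(object, newdata, ...) {
  x <- as.matrix(newdata)[, object$features, drop = FALSE]
  df <- data.frame(x, check.names = FALSE)
  switch(object$algorithm,
    MLR = unname(stats::predict(object$fit, newdata = df)),
    SVR = if (object$fit$tot.nSV == 0) rep(object$fallback, nrow(x))
      else unname(stats::predict(object$fit, x)),
    RFR = unname(stats::predict(object$fit, data = df,
                                num.threads = 1)$predictions),
    MLP = unname(.mlp_predict(object$fit, x)))
}

.r2 <- function(y, pred) {
  ss_tot <- sum((y - mean(y))^2)
  1 - sum((y - pred)^2) / ss_tot
}

#' Rank features by importance
#'
#' Model-appropriate importances, normalized to sum 1: impurity importance
#' for the random forest, absolute standardized coefficients for the linear
#' model, and permutation importance (mean R-squared drop over `n_perm`
#' seeded permutations) for SVR and MLP, floored at zero before
#' normalization.
#'
#' @param model a `fc_regressor`.
#' @param x,y the (standardized) data the model was fitted on.
#' @param n_perm permutations per feature for the permutation importance.
#' @param seed permutation seed.
#' @return named numeric vector summing to 1.
#' @export
importance_rank <- function(model, x, y, n_perm = 10L, seed = 1L) {
  stopifnot(inherits(model, "fc_regressor"))
  x <- as.matrix(x)[, model$features, drop = FALSE]
  raw <- switch(model$algorithm,
    MLR = abs(stats::coef(model$fit)[-1]),
    RFR = ranger::importance(model$fit),
    .permutation_importance(model, x, y, n_perm, seed))
  raw <- stats::setNames(as.numeric(raw), model$features)
  raw[is.na(raw)] <- 0
  raw <- pmax(raw, 0)
  if (sum(raw) <= 0) return(stats::setNames(rep(1 / length(raw),
                                                length(raw)),
                                            names(raw)))
  raw / sum(raw)
}

.permutation_importance <- function(model, x, y, n_perm, seed) {
  base <- .r2(y, stats::predict(model, x))
  p <- ncol(x)
  drops <- numeric(p)
  for (j in seq_len(p)) {
    set.seed(seed * 1000L + j)
    d <- 0
    for (r in seq_len(n_perm)) {
      xp <- x
      xp[, j] <- sample(xp[, j])
      d <- d + (base - .r2(y, stats::predict(model, xp)))
    }
    drops[j] <- d / n_perm
  }
  stats::setNames(drops, colnames(x))
}

.fold_assign <- function(n, k, seed) {
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

#' 10-fold cross-validation of a regressor
#'
#' Shuffled k-fold split (seeded). The scaler is refitted on each training
#' fold and applied to the held-out fold, so held-out data never influence
#' standardization. Reports per-fold and mean R-squared (coefficient of
#' determination against the held-out mean, may be negative), MAE and MSE
#' on log10 KD.
#'
#' @param x raw (unscaled) feature matrix.
#' @param y response.
#' @param algorithm regressor name.
#' @param k number of folds (default 10).
#' @param seed fold-shuffling and fitting seed.
#' @return a `cv_report`.
#' @export
cross_validate <- function(x, y, algorithm = "MLR", k = 10L, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(n == length(y), k >= 2, n >= k)
  fold <- .fold_assign(n, k, seed)
  per <- data.frame(fold = seq_len(k), r2 = NA_real_, mae = NA_real_,
                    mse = NA_real_)
  for (f in seq_len(k)) {
    tr <- fold != f
    scaler <- suppressWarnings(fit_scaler(x[tr, , drop = FALSE]))
    xt <- apply_scaler(scaler, x[tr, , drop = FALSE])
    xh <- apply_scaler(scaler, x[!tr, , drop = FALSE])
    m <- fit_regressor(xt, y[tr], algorithm, seed = seed + f)
    pred <- stats::predict(m, xh)
    per$r2[f] <- .r2(y[!tr], pred)
    per$mae[f] <- mean(abs(y[!tr] - pred))
    per$mse[f] <- mean((y[!tr] - pred)^2)
  }
  structure(list(algorithm = algorithm, k = k, seed = seed,
                 folds = per,
                 mean_r2 = mean(per$r2), mean_mae = mean(per$mae),
                 mean_mse = mean(per$mse),
                 features = colnames(x)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report %s (k=%d, seed=%d): R2=%.3f MAE=%.3f MSE=%.3f\n",
              x$algorithm, x$k, x$seed, x$mean_r2, x$mean_mae, x$mean_mse))
  invisible(x)
}

#' Shuffled-label control
#'
#' Permutes the responses (seeded) and reruns [cross_validate()]. A model
#' learning real structure should collapse (mean R-squared near or below
#' zero) under shuffling.
#'
#' @inheritParams cross_validate
#' @param permutation optional explicit permutation of `seq_along(y)`
#'   (identity permutation reproduces the unshuffled result).
#' @return a `cv_report` on the shuffled responses.
#' @export
shuffled_control <- function(x, y, algorithm = "MLR", k = 10L, seed = 1L,
                             permutation = NULL) {
  if (is.null(permutation)) {
    set.seed(seed + 7919L)
    permutation <- sample(seq_along(y))
  }
  stopifnot(length(permutation) == length(y))
  cross_validate(x, y[permutation], algorithm, k = k, seed = seed)
}

#' Iterative importance-based feature elimination
#'
#' Starting from the full feature set, repeatedly drops the feature with
#' the lowest importance (fitted on the standardized full set). A drop is
#' accepted while the mean k-fold cross-validated R-squared stays within
#' `tol` of the initial model's; the first rejected drop stops the
#' procedure and the corresponding feature is restored.
#'
#' @inheritParams cross_validate
#' @param tol accepted R-squared degradation relative to the initial model
#'   (default 0.01; `Inf` removes all but one feature).
#' @param quiet suppress per-step messages.
#' @return character vector of selected feature ids (original order).
#' @export
eliminate_features <- function(x, y, algorithm = "MLR", k = 10L, seed = 1L,
                               tol = 0.01, quiet = TRUE) {
  x <- as.matrix(x)
  stopifnot(ncol(x) >= 2)
  current <- colnames(x)
  baseline <- cross_validate(x, y, algorithm, k, seed)$mean_r2
  while (length(current) > 1L) {
    scaler <- suppressWarnings(fit_scaler(x[, current, drop = FALSE]))
    xs <- apply_scaler(scaler, x)
    m <- fit_regressor(xs, y, algorithm, seed = seed)
    imp <- importance_rank(m, xs, y, seed = seed)
    drop_id <- names(imp)[order(imp, names(imp))][1]
    trial <- setdiff(current, drop_id)
    r2 <- cross_validate(x[, trial, drop = FALSE], y, algorithm, k,
                         seed)$mean_r2
    if (baseline - r2 < tol) {
      current <- trial
      if (!quiet)
        message("eliminate_features: dropped ", drop_id,
                sprintf(" (CV R2 %.3f vs baseline %.3f)", r2, baseline))
    } else {
      break
    }
  }
  colnames(x)[colnames(x) %in% current]
}

#' Correlation pruning
#'
#' Computes pairwise Pearson correlations and, for every pair with
#' `|r| >= threshold` (considered in descending `|r|`, ties broken by
#' feature id), drops the member with the lower importance (ties drop the
#' later feature id). Idempotent.
#'
#' @param x feature matrix.
#' @param threshold absolute correlation threshold (default 0.9).
#' @param importance optional named importance vector; equal importances
#'   assumed when absent.
#' @return character vector of retained feature ids (original order).
#' @export
correlation_prune <- function(x, threshold = 0.9, importance = NULL) {
  x <- as.matrix(x)
  ids <- colnames(x)
  if (is.null(importance)) importance <- stats::setNames(rep(1, ncol(x)), ids)
  cm <- suppressWarnings(stats::cor(x))
  cm[!is.finite(cm)] <- 0
  pairs <- which(upper.tri(cm) & abs(cm) >= threshold, arr.ind = TRUE)
  if (!nrow(pairs)) return(ids)
  ord <- order(-abs(cm[pairs]), ids[pairs[, 1]], ids[pairs[, 2]])
  pairs <- pairs[ord, , drop = FALSE]
  alive <- stats::setNames(rep(TRUE, ncol(x)), ids)
  for (r in seq_len(nrow(pairs))) {
    a <- ids[pairs[r, 1]]; b <- ids[pairs[r, 2]]
    if (!alive[a] || !alive[b]) next
    drop_id <- if (importance[a] < importance[b]) a
      else if (importance[b] < importance[a]) b
      else max(a, b)
    alive[drop_id] <- FALSE
  }
  ids[alive]
}

#' Train an end-to-end affinity prediction pipeline
#'
#' Bundles the reference complex, feature catalog, scaler (fitted on the
#' training features) and a fitted regressor into one object that predicts
#' log10 KD at pH 7.0 for new variants from their mutation strings.
#'
#' @param x raw feature matrix of the training variants.
#' @param y training log10 KD.
#' @param reference the reference `fc_complex` used to model variants.
#' @param catalog the `feature_catalog` the features came from.
#' @param algorithm regressor name.
#' @param seed fitting seed.
#' @param n_points SASA quadrature points used at prediction time.
#' @return a `fc_pipeline`.
#' @export
train_pipeline <- function(x, y, reference, catalog, algorithm = "RFR",
                           seed = 1L, n_points = 960L) {
  scaler <- suppressWarnings(fit_scaler(x))
  xs <- apply_scaler(scaler, x)
  model <- fit_regressor(xs, y, algorithm, seed = seed)
  structure(list(scaler = scaler, model = model, reference = reference,
                 catalog = catalog, algorithm = algorithm,
                 n_points = n_points),
            class = "fc_pipeline")
}

#' Predict log10 KD for variants
#'
#' Models each variant on the pipeline's reference complex (only mutations
#' at catalog Fc positions alter the features; others are dropped via the
#' effective signature), extracts features, applies the stored scaler and
#' regressor. Deterministic given the pipeline.
#'
#' @param pipeline a `fc_pipeline`.
#' @param specs list of `variant_spec`s or character vector of mutation
#'   strings.
#' @return numeric vector of predicted log10 KD at pH 7.0.
#' @export
predict_variants <- function(pipeline, specs) {
  stopifnot(inherits(pipeline, "fc_pipeline"))
  x <- variant_features(specs, pipeline$reference, pipeline$catalog,
                        n_points = pipeline$n_points)
  stats::predict(pipeline$model, apply_scaler(pipeline$scaler, x))
}

#' Feature matrix for a set of variants
#'
#' Applies each variant's effective mutations (catalog Fc positions only)
#' to the reference complex and extracts the catalog features.
#'
#' @param specs list of `variant_spec`s or character vector of mutation
#'   strings.
#' @param reference reference `fc_complex`.
#' @param catalog `feature_catalog`.
#' @param n_points SASA quadrature points.
#' @return numeric matrix, one row per variant.
#' @export
variant_features <- function(specs, reference, catalog, n_points = 960L) {
  if (is.character(specs)) specs <- lapply(specs, parse_mutations)
  fc_pos <- unique(catalog$eu[catalog$role %in% "FC"])
  rows <- vector("list", length(specs))
  cache <- new.env(parent = emptyenv())
  for (i in seq_along(specs)) {
    sig <- effective_signature(specs[[i]], fc_pos)
    if (!is.null(cache[[sig]])) {
      rows[[i]] <- cache[[sig]]
      next
    }
    eff <- parse_mutations(sig)
    mdl <- if (nrow(eff$mutations)) apply_mutations(reference, eff)
      else reference
    v <- extract_features(mdl, catalog, n_points = n_points)
    cache[[sig]] <- v
    rows[[i]] <- v
  }
  out <- do.call(rbind, rows)
  rownames(out) <- vapply(specs, mutation_string, "")
  out
}
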