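#' Fit an empirical-Bayes location/scale batch harmonization model
#'
#' ComBat-style harmonization with a reference batch: per feature, rows
#' are standardized against the reference batch's mean and (population)
#' variance after removing designated covariate effects; per-batch
#' location and scale deviations are estimated and shrunk towards
#' moment-matched pooled priors (normal for locations, inverse-gamma for
#' scales) by the standard iterative empirical-Bayes solution. The
#' reference batch maps to the identity, so harmonizing an external test
#' batch "towards" a training batch leaves the training data untouched.
#'
#' @param z data.frame of (already z-scored) feature values.
#' @param batch vector of batch labels, one per row (>= 2 batches, >= 3
#'   rows each; a single batch yields an identity model with a warning).
#' @param features feature columns to harmonize (default: all numeric
#'   columns). sNfL and other non-MRI columns should be excluded by the
#'   caller; [harmonized_feature_default()] helps.
#' @param covariates optional data.frame of covariates whose effects are
#'   estimated and preserved (default none).
#' @param ref_batch reference batch label (default: first level).
#' @param eb if `FALSE`, use the raw per-batch estimates without
#'   empirical-Bayes shrinkage.
#' @return object of class `harmonization_model`.
#' @export
fit_harmonization <- function(z, batch, features = NULL, covariates = NULL,
                              ref_batch = NULL, eb = TRUE) {
  if (is.null(features))
    features <- names(z)[vapply(z, is.numeric, logical(1))]
  if (!all(features %in% names(z)))
    stop("unknown feature columns", call. = FALSE)
  batch <- as.character(batch)
  if (length(batch) != nrow(z))
    stop("one batch label per row required", call. = FALSE)
  levels_b <- unique(batch)
  if (is.null(ref_batch)) ref_batch <- levels_b[1L]
  if (!ref_batch %in% levels_b)
    stop("ref_batch not among batch labels", call. = FALSE)
  nb <- table(batch)
  if (length(levels_b) == 1L) {
    warning("single batch: harmonization model is the identity")
  } else if (any(nb < 3L)) {
    stop("insufficient batch: every batch needs at least 3 rows",
         call. = FALSE)
  }
  X <- as.matrix(z[, features, drop = FALSE])
  n <- nrow(X)

  # covariate design (effects preserved, never removed)
  beta <- NULL
  Cmat <- NULL
  if (!is.null(covariates)) {
    Cmat <- stats::model.matrix(~ ., data = as.data.frame(covariates))[, -1,
                                                                       drop = FALSE]
  }

  # per-feature: reference-batch location/scale after covariate removal
  ref_rows <- batch == ref_batch
  stand_mean <- numeric(length(features))
  pooled_var <- numeric(length(features))
  names(stand_mean) <- names(pooled_var) <- features
  if (!is.null(Cmat)) beta <- matrix(0, ncol(Cmat), length(features),
                                     dimnames = list(colnames(Cmat),
                                                     features))
  resid <- X
  for (j in seq_along(features)) {
    y <- X[, j]
    if (!is.null(Cmat)) {
      # batch-aware regression so covariate effects are not confounded
      # with batch shifts
      D <- cbind(stats::model.matrix(~ 0 + factor(batch,
                                                  levels = levels_b)), Cmat)
      fit <- stats::lm.fit(D, y)
      bcoef <- fit$coefficients[-seq_along(levels_b)]
      bcoef[is.na(bcoef)] <- 0
      beta[, j] <- bcoef
      y <- y - Cmat %*% bcoef
    }
    stand_mean[j] <- mean(y[ref_rows])
    pooled_var[j] <- mean((y[ref_rows] - stand_mean[j])^2)
    if (pooled_var[j] <= 0)
      stop("degenerate reference batch variance in '", features[j], "'",
           call. = FALSE)
    resid[, j] <- (y - stand_mean[j]) / sqrt(pooled_var[j])
  }

  # per-batch location (gamma) and scale (delta^2) on the standardized
  # scale, with parametric EB shrinkage
  gamma_star <- delta2_star <- matrix(NA_real_, length(levels_b),
                                      length(features),
                                      dimnames = list(levels_b, features))
  for (b in levels_b) {
    rows <- batch == b
    g_hat <- colMeans(resid[rows, , drop = FALSE])
    d_hat <- apply(resid[rows, , drop = FALSE], 2L, stats::var)
    if (b == ref_batch || length(levels_b) == 1L || !eb ||
        length(features) < 2L) {
      if (b == ref_batch) {
        gamma_star[b, ] <- 0
        delta2_star[b, ] <- 1
      } else {
        gamma_star[b, ] <- g_hat
        delta2_star[b, ] <- d_hat
      }
      next
    }
    eb_fit <- .eb_shrink(resid[rows, , drop = FALSE], g_hat, d_hat)
    gamma_star[b, ] <- eb_fit$gamma
    delta2_star[b, ] <- eb_fit$delta2
  }

  structure(list(features = features, batches = levels_b,
                 ref_batch = ref_batch, stand_mean = stand_mean,
                 pooled_var = pooled_var, gamma_star = gamma_star,
                 delta2_star = delta2_star, beta = beta,
                 covariate_names = if (is.null(Cmat)) NULL else
                   colnames(Cmat), eb = eb),
            class = "harmonization_model")
}

# iterative EB posterior estimates (parametric normal / inverse-gamma
# priors, moment-matched across features)
.eb_shrink <- function(Zb, g_hat, d_hat, conv = 1e-4, max_iter = 1000L) {
  n <- nrow(Zb)
  g_bar <- mean(g_hat)
  t2 <- stats::var(g_hat)
  m <- mean(d_hat); s2 <- stats::var(d_hat)
  a_prior <- (2 * s2 + m^2) / s2
  b_prior <- (m * s2 + m^3) / s2
  g_new <- g_hat; d_new <- d_hat
  for (i in seq_len(max_iter)) {
    g_old <- g_new; d_old <- d_new
    g_new <- (n * t2 * g_hat + d_new * g_bar) / (n * t2 + d_new)
    sum2 <- colSums((Zb - matrix(g_new, n, length(g_new),
                                 byrow = TRUE))^2)
    d_new <- (0.5 * sum2 + b_prior) / (n / 2 + a_prior - 1)
    change <- max(abs(g_new - g_old) / abs(g_old),
                  abs(d_new - d_old) / abs(d_old))
    if (is.finite(change) && change < conv) break
  }
  list(gamma = g_new, delta2 = d_new)
}

#' Apply a fitted harmonization model to a z-score table
#'
#' Rows from the reference batch are returned unchanged; rows from other
#' known batches get the location/scale adjustment
#' `(z - mean - gamma*) / delta* * sd + mean` on the standardized scale
#' (covariate effects, if modelled, are removed before and restored
#' after). Only the model's feature columns are touched; sNfL and other
#' columns pass through.
#'
#' @param z data.frame containing the model's features.
#' @param model a [fit_harmonization()] model.
#' @param batch batch labels per row.
#' @param covariates covariate data.frame if the model was fitted with
#'   one.
#' @param unknown_as_reference treat unknown batch labels as the
#'   reference batch (identity) instead of erroring.
#' @return data.frame with harmonized feature columns.
#' @export
apply_harmonization <- function(z, model, batch,
                                covariates = NULL,
                                unknown_as_reference = FALSE) {
  batch <- as.character(batch)
  if (length(batch) != nrow(z))
    stop("one batch label per row required", call. = FALSE)
  unknown <- !batch %in% model$batches
  if (any(unknown)) {
    if (!unknown_as_reference)
      stop("unknown batch label(s): ",
           paste(unique(batch[unknown]), collapse = ", "), call. = FALSE)
    batch[unknown] <- model$ref_batch
  }
  cov_term <- NULL
  if (!is.null(model$beta)) {
    if (is.null(covariates))
      stop("model was fitted with covariates; supply them", call. = FALSE)
    Cmat <- stats::model.matrix(~ ., data = as.data.frame(covariates))[, -1,
                                                                       drop = FALSE]
    Cmat <- Cmat[, model$covariate_names, drop = FALSE]
    cov_term <- Cmat %*% model$beta
  }
  out <- z
  for (j in seq_along(model$features)) {
    f <- model$features[j]
    y <- z[[f]]
    if (!is.null(cov_term)) y <- y - cov_term[, j]
    s <- (y - model$stand_mean[j]) / sqrt(model$pooled_var[j])
    g <- model$gamma_star[batch, j]
    d <- sqrt(model$delta2_star[batch, j])
    s <- (s - g) / d
    y <- s * sqrt(model$pooled_var[j]) + model$stand_mean[j]
    if (!is.null(cov_term)) y <- y + cov_term[, j]
    out[[f]] <- y
  }
  out
}

#' Default harmonized feature set
#'
#' Volumes and T1/T2-ratio variables are harmonized; lesion volume is
#' optional (off by default) and sNfL is never harmonized.
#'
#' @param features candidate feature names.
#' @param snfl_cols sNfL column names to exclude.
#' @param lesion_cols lesion-volume columns.
#' @param include_lesion include lesion columns (default `FALSE`).
#' @return character vector of features to harmonize.
#' @export
harmonized_feature_default <- function(features, snfl_cols = "snfl",
                                       lesion_cols = "lesion_volume",
                                       include_lesion = FALSE) {
  out <- setdiff(features, snfl_cols)
  if (!include_lesion) out <- setdiff(out, lesion_cols)
  out
}

#' @export
print.harmonization_model <- function(x, ...) {
  cat("Harmonization model:", length(x$features), "features,",
      length(x$batches), "batch(es); reference batch '", x$ref_batch,
      "'\n", sep = "")
  invisible(x)
}
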