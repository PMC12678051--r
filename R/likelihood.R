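#' Expected abnormality z-score along a subtype trajectory
#'
#' The trajectory of each biomarker is piecewise linear through the
#' control points (stage 0, z = 0), (position of each of the
#' biomarker's events, its threshold) and (stage N, z_max), evaluated at
#' integer stages. A subject at stage k is modelled as Gaussian noise
#' around these expected values.
#'
#' @param sequence integer event-index vector (see [validate_sequence()]).
#' @param stage integer stage(s) in `0..N`.
#' @param biomarker biomarker name.
#' @param config an [event_config()].
#' @return numeric expected z-score(s).
#' @examples
#' cfg <- event_config(c("a", "b"), thresholds = 1:3, z_max = 5)
#' s <- c(1, 4, 2, 5, 3, 6)  # alternate a and b
#' expected_value(s, 0, "a", cfg)  # 0
#' @export
expected_value <- function(sequence, stage, biomarker, config) {
  if (!biomarker %in% config$biomarkers)
    stop("unknown biomarker '", biomarker, "'", call. = FALSE)
  N <- config$n_events
  if (any(stage < 0 | stage > N))
    stop("stage out of range 0..", N, call. = FALSE)
  E <- expected_matrix(sequence, config)
  E[biomarker, stage + 1L]
}

#' Matrix of expected z-scores for every biomarker and stage
#'
#' @inheritParams expected_value
#' @return numeric matrix, biomarkers x stages `0..N` (columns named
#'   `"0"..."N"`).
#' @export
expected_matrix <- function(sequence, config) {
  N <- config$n_events
  ev <- config$events
  pos <- event_positions(sequence)
  E <- matrix(0, nrow = length(config$biomarkers), ncol = N + 1L,
              dimnames = list(config$biomarkers, 0:N))
  k <- 0:N
  for (bi in seq_along(config$biomarkers)) {
    b <- config$biomarkers[bi]
    idx <- which(ev$biomarker == b)
    xp <- c(0, pos[idx], N)
    yp <- c(0, ev$threshold[idx], config$z_max[[b]])
    # if the biomarker's last event sits at stage N, its threshold (not
    # the ceiling) is the stage-N value: stage k means k events occurred
    np <- length(xp)
    if (xp[np] == xp[np - 1L]) { xp <- xp[-np]; yp <- yp[-np]; np <- np - 1L }
    j <- pmin.int(findInterval(k, xp), np - 1L)
    E[bi, ] <- yp[j] + (k - xp[j]) * (yp[j + 1L] - yp[j]) /
      (xp[j + 1L] - xp[j])
  }
  E
}

#' Per-stage likelihoods of a biomarker profile
#'
#' Evaluates P(x | stage k, sequence) for k = 0..N as a product of
#' independent Gaussian densities around the stage-k expected values.
#'
#' @param z complete numeric vector of abnormality z-scores, named by
#'   biomarker (or ordered as `config$biomarkers`).
#' @inheritParams expected_value
#' @return numeric vector of length N + 1 (stages 0..N).
#' @export
stage_likelihoods <- function(z, sequence, config) {
  z <- .as_z_matrix(z, config)
  exp(.stage_loglik_matrix(z, sequence, config))[1L, ]
}

.as_z_matrix <- function(z, config) {
  if (is.data.frame(z)) z <- as.matrix(z[, config$biomarkers, drop = FALSE])
  if (!is.matrix(z)) {
    if (!is.null(names(z))) z <- z[config$biomarkers]
    z <- matrix(z, nrow = 1L, dimnames = list(NULL, config$biomarkers))
  }
  if (!all(config$biomarkers %in% colnames(z)))
    stop("z table lacks modelled biomarker columns", call. = FALSE)
  z <- z[, config$biomarkers, drop = FALSE]
  if (!is.numeric(z)) stop("z values must be numeric", call. = FALSE)
  if (anyNA(z) || any(!is.finite(z)))
    stop("incomplete biomarker profile: the model requires complete, ",
         "finite z-scores (no imputation)", call. = FALSE)
  z
}

# n x (N+1) matrix of log P(x_i | stage k, sequence); the Gaussian
# quadratic form is expanded so the stage dimension is one matrix
# multiply.
.stage_loglik_matrix <- function(z, sequence, config) {
  E <- expected_matrix(sequence, config)          # B x (N+1)
  sig <- config$sigma[config$biomarkers]
  iv <- 1 / sig^2
  const <- -sum(log(sig)) - length(sig) * 0.5 * log(2 * pi)
  q1 <- drop((z^2) %*% iv)                        # n
  q2 <- (z * rep(iv, each = nrow(z))) %*% E       # n x (N+1)
  q3 <- drop(crossprod(iv, E^2))                  # N+1
  ll <- -0.5 * (outer(q1, q3, `+`) - 2 * q2) + const
  dimnames(ll) <- list(rownames(z), colnames(E))
  ll
}

# log( mean_k exp(ll_k) ) per row, guarded against underflow
.row_log_mean_exp <- function(ll) .row_log_mean_exp_cpp(ll)

# --- fast evaluation context -----------------------------------------
# The greedy/EM/MCMC inner loops score thousands of candidate sequences
# against a fixed z table. The Gaussian quadratic form splits into a
# per-row term (sequence-independent) and a term linear in the
# trajectory matrix, so candidate scoring reduces to one matrix
# multiply: M = [Z*iv, 1] %*% rbind(E, -q3/2), whose row log-mean-exp
# differs from the exact per-row log-likelihood only by the cached
# per-row constant `row_const`.
.make_ctx <- function(zm, config) {
  iv <- 1 / config$sigma[config$biomarkers]^2
  const <- -sum(log(config$sigma)) -
    length(config$sigma) * 0.5 * log(2 * pi)
  list(A = cbind(sweep(zm, 2L, iv, `*`), 1),
       row_const = -0.5 * drop((zm^2) %*% iv) + const,
       config = config, n = nrow(zm))
}

# relative per-row log mean_k P(x|k,S): exact value minus row_const
.ctx_lme <- function(ctx, sequence) {
  E <- expected_matrix(sequence, ctx$config)
  iv <- 1 / ctx$config$sigma[ctx$config$biomarkers]^2
  q3 <- drop(crossprod(E^2, iv))
  .row_log_mean_exp_cpp(ctx$A %*% rbind(E, -0.5 * q3))
}

# exact total mixture log-likelihood from relative per-subtype columns
.ctx_model_ll <- function(ctx, Lc_rel, fractions) {
  lf <- sweep(Lc_rel, 2L, log(fractions), `+`)
  mx <- do.call(pmax, as.data.frame(lf))
  sum(mx + log(rowSums(exp(lf - mx))) + ctx$row_const)
}

#' Total log-likelihood of a z table under a fitted model
#'
#' Per subject the stage is marginalized with a uniform prior over
#' stages 0..N and subtypes are mixed with the model's fractions:
#' `log sum_c f_c (N+1)^-1 sum_k P(x | k, S_c)`, summed over rows.
#'
#' @param z data.frame or matrix of abnormality z-scores containing the
#'   model's biomarker columns; one row per subject(-visit).
#' @param model a [sustain_fit()] model.
#' @return total log-likelihood (scalar).
#' @export
model_loglik <- function(z, model) {
  sum(.subject_logliks(z, model)$marginal)
}

# list(marginal = n-vector log f-mixture likelihood,
#      by_subtype = n x C matrix of log (N+1)^-1 sum_k P(x|k,S_c))
.subject_logliks <- function(z, model) {
  cfg <- model$config
  zm <- .as_z_matrix(z, cfg)
  if (nrow(zm) == 0L) stop("empty z table", call. = FALSE)
  Lc <- vapply(model$sequences, function(s)
    .row_log_mean_exp(.stage_loglik_matrix(zm, s, cfg)),
    numeric(nrow(zm)))
  Lc <- matrix(Lc, nrow = nrow(zm))
  lf <- sweep(Lc, 2L, log(model$fractions), `+`)
  mx <- apply(lf, 1L, max)
  list(marginal = mx + log(rowSums(exp(lf - mx))), by_subtype = Lc)
}
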