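# Independent brute-force oracles for the event model. These mirror the
# model definition directly (explicit segment search, dnorm products,
# full enumeration) and share no code with the package internals.

# expected z of one biomarker at one integer stage, by explicit
# piecewise-linear segment search through the control points
oracle_expected <- function(positions, thresholds, z_max, N, stage) {
  xs <- c(0, positions, N)
  ys <- c(0, thresholds, z_max)
  # event control points take precedence at a collision with the ceiling
  if (positions[length(positions)] == N) {
    xs <- xs[-length(xs)]; ys <- ys[-length(ys)]
  }
  if (stage <= xs[1]) return(ys[1])
  for (i in seq_len(length(xs) - 1)) {
    if (stage <= xs[i + 1]) {
      return(ys[i] + (stage - xs[i]) * (ys[i + 1] - ys[i]) /
               (xs[i + 1] - xs[i]))
    }
  }
  ys[length(ys)]
}

# P(x | stage k, sequence) for k = 0..N by direct density evaluation
oracle_stage_lik <- function(z, sequence, config) {
  N <- config$n_events
  ev <- config$events
  pos_of <- order(sequence)
  sapply(0:N, function(k) {
    lik <- 1
    for (bi in seq_along(config$biomarkers)) {
      b <- config$biomarkers[bi]
      idx <- which(ev$biomarker == b)
      mu <- oracle_expected(pos_of[idx], ev$threshold[idx],
                            config$z_max[[b]], N, k)
      lik <- lik * dnorm(z[[b]], mu, config$sigma[[b]])
    }
    lik
  })
}

oracle_model_loglik <- function(Z, sequences, fractions, config) {
  N <- config$n_events
  sum(apply(Z, 1, function(z) {
    z <- as.list(setNames(z, colnames(Z)))
    log(sum(vapply(seq_along(sequences), function(cc) {
      fractions[cc] * mean(oracle_stage_lik(z, sequences[[cc]], config))
    }, numeric(1))))
  }))
}

# all admissible sequences by filtering full permutations (tiny N only)
oracle_all_sequences <- function(config) {
  N <- config$n_events
  ev <- config$events
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  ok <- function(s) {
    pos <- order(s)
    for (b in unique(ev$biomarker)) {
      idx <- which(ev$biomarker == b)
      if (is.unsorted(pos[idx], strictly = TRUE)) return(FALSE)
    }
    TRUE
  }
  Filter(ok, perms(seq_len(N)))
}

# Cox partial log-likelihood for one numeric covariate, distinct event
# times (no ties)
oracle_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# small helpers ---------------------------------------------------------

toy_config_2x2 <- function()
  event_config(c("a", "b"), thresholds = c(1, 2), z_max = 4)

# data drawn on a planted trajectory with noise
draw_on_trajectory <- function(sequence, config, n, sd, seed,
                               stages = NULL) {
  set.seed(seed)
  N <- config$n_events
  E <- expected_matrix(sequence, config)
  st <- if (is.null(stages)) sample(0:N, n, replace = TRUE) else stages
  n <- length(st)
  Z <- t(E[, st + 1, drop = FALSE]) +
    matrix(rnorm(n * length(config$biomarkers), 0, sd),
           nrow = n)
  colnames(Z) <- config$biomarkers
  list(z = Z, stages = st)
}

# match fitted subtype indices to planted ones by assignment agreement
best_subtype_mapping <- function(fitted, truth) {
  stopifnot(length(fitted) == length(truth))
  if (mean(fitted == truth) >= mean((3 - fitted) == truth))
    c(1, 2) else c(2, 1)
}
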