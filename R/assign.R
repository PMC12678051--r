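#' Assign subtype and stage posteriors to subject-visits
#'
#' Every row of `z` is assigned independently. Subtype membership
#' probabilities are `p_c` proportional to `f_c (N+1)^-1 sum_k
#' P(x | k, S_c)` (uniform stage prior); the reported stage is the
#' maximum a posteriori stage under the maximum-probability subtype,
#' with ties broken towards the lower stage (and towards the lower
#' subtype index).
#'
#' @param z data.frame or matrix of abnormality z-scores. If a
#'   data.frame carries `subject` / `month` columns they are passed
#'   through to the output.
#' @param model a [sustain_fit()] model.
#' @return data.frame of class `sustain_posterior`: one row per input
#'   row with subtype probability columns `p1..pC`, `ml_subtype`,
#'   `ml_stage`, `confidence` (max subtype probability) and, attached as
#'   the `"stage_posterior"` attribute, a list of per-row stage
#'   posterior matrices (subtype x stage).
#' @export
sustain_assign <- function(z, model) {
  cfg <- model$config
  zm <- .as_z_matrix(z, cfg)
  n <- nrow(zm)
  C <- length(model$sequences)
  N <- cfg$n_events
  ll_stage <- lapply(model$sequences, function(s)
    .stage_loglik_matrix(zm, s, cfg))        # C matrices n x (N+1)
  Lc <- vapply(ll_stage, .row_log_mean_exp, numeric(n))
  Lc <- matrix(Lc, nrow = n)
  lf <- sweep(Lc, 2L, log(model$fractions), `+`)
  mx <- apply(lf, 1L, max)
  p <- exp(lf - mx)
  p <- p / rowSums(p)
  ml_subtype <- max.col(p, ties.method = "first")  # ties -> lower index
  ml_stage <- integer(n)
  stage_post <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- vapply(seq_len(C), function(cc) {
      v <- ll_stage[[cc]][i, ]
      v <- exp(v - max(v)); v / sum(v)
    }, numeric(N + 1L))
    stage_post[[i]] <- t(sp)
    ml_stage[i] <- which.max(stage_post[[i]][ml_subtype[i], ]) - 1L
  }
  out <- data.frame(matrix(p, ncol = C,
                           dimnames = list(NULL, paste0("p", seq_len(C)))))
  out$ml_subtype <- ml_subtype
  out$ml_stage <- ml_stage
  out$confidence <- apply(p, 1L, max)
  if (is.data.frame(z)) {
    keep <- intersect(c("subject", "month", "arm", "batch"), names(z))
    if (length(keep)) out <- cbind(z[, keep, drop = FALSE], out)
  }
  attr(out, "stage_posterior") <- stage_post
  class(out) <- c("sustain_posterior", "data.frame")
  out
}

#' MCMC positional variance of the event ordering
#'
#' Samples event sequences per subtype with Metropolis-Hastings
#' (proposal: relocate a uniformly chosen event to a uniformly chosen
#' admissible position; the proposal is symmetric because an event's
#' admissible window length is unchanged by its own relocation), holding
#' the other subtypes' sequences and the mixture fractions fixed at
#' their fitted values. The positional-variance matrix gives, per event,
#' the posterior probability of occupying each position — the
#' uncertainty display of the fitted orderings.
#'
#' @param z z-score table used for the fit.
#' @param model fitted [sustain_fit()] model.
#' @param n_iters MCMC iterations per subtype (>= 100; the package
#'   default of 10000 is deliberately desk-scale).
#' @param seed integer seed.
#' @param burn_in fraction of initial samples discarded.
#' @param average_assignments if `TRUE`, additionally returns subject
#'   subtype probabilities averaged over thinned posterior sequence
#'   samples.
#' @param keep_samples if `TRUE`, return the thinned sequence samples
#'   (list per subtype); used for posterior-predictive held-out
#'   evaluation in [sustain_cv()].
#' @return list of class `positional_variance` with per-subtype
#'   `variance` matrices (event x position, rows sum to 1),
#'   `acceptance_rate`, `map_sequences` (modal sampled sequence), and
#'   optionally `averaged_assignments` and `samples`.
#' @export
mcmc_positional_variance <- function(z, model, n_iters = 10000L, seed = 1L,
                                     burn_in = 0.1,
                                     average_assignments = FALSE,
                                     keep_samples = FALSE) {
  if (n_iters < 100L) stop("n_iters must be at least 100", call. = FALSE)
  cfg <- model$config
  zm <- .as_z_matrix(z, cfg)
  N <- cfg$n_events
  C <- length(model$sequences)
  labs <- event_labels(cfg)
  set.seed(seed)
  keep_from <- floor(burn_in * n_iters) + 1L
  res_var <- vector("list", C)
  acc_rate <- numeric(C)
  thin_samples <- vector("list", C)
  cur <- model$sequences

  ctx <- .make_ctx(zm, cfg)
  lf_sum <- function(Lc) .ctx_model_ll(ctx, Lc, model$fractions)
  seq_col <- function(s) .ctx_lme(ctx, s)
  Lc_cur <- .Lc_rel(ctx, cur)
  for (cc in seq_len(C)) {
    counts <- matrix(0L, N, N, dimnames = list(labs, seq_len(N)))
    ll <- lf_sum(Lc_cur)
    acc <- 0L
    thin_at <- unique(pmax(keep_from,
                           round(seq(keep_from, n_iters, length.out = 50))))
    thinned <- list()
    for (it in seq_len(n_iters)) {
      s <- cur[[cc]]
      from <- sample.int(N, 1L)
      win <- .admissible_window(s, from, cfg)
      to <- if (win[1L] == win[2L]) from else
        sample(seq.int(win[1L], win[2L]), 1L)
      if (to != from) {
        s_prop <- .relocate(s, from, to)
        col_prop <- seq_col(s_prop)
        Lc_prop <- Lc_cur
        Lc_prop[, cc] <- col_prop
        ll_prop <- lf_sum(Lc_prop)
        if (log(stats::runif(1L)) < ll_prop - ll) {
          cur[[cc]] <- s_prop; Lc_cur <- Lc_prop; ll <- ll_prop
          acc <- acc + 1L
        }
      }
      if (it >= keep_from) {
        pos <- event_positions(cur[[cc]])
        counts[cbind(seq_len(N), pos)] <- counts[cbind(seq_len(N), pos)] + 1L
        if ((average_assignments || keep_samples) && it %in% thin_at)
          thinned[[length(thinned) + 1L]] <- cur[[cc]]
      }
    }
    res_var[[cc]] <- counts / rowSums(counts)
    acc_rate[cc] <- acc / n_iters
    thin_samples[[cc]] <- thinned
  }
  out <- list(variance = res_var, acceptance_rate = acc_rate,
              map_sequences = cur, n_iters = n_iters, seed = seed)
  if (keep_samples) out$samples <- thin_samples
  if (average_assignments) {
    n_thin <- length(thin_samples[[1L]])
    pbar <- 0
    for (j in seq_len(n_thin)) {
      seqs <- lapply(seq_len(C), function(cc) thin_samples[[cc]][[j]])
      m_j <- list(config = cfg, sequences = seqs,
                  fractions = model$fractions)
      pj <- sustain_assign(zm, m_j)
      pbar <- pbar + as.matrix(pj[, paste0("p", seq_len(C))]) / n_thin
    }
    out$averaged_assignments <- pbar
  }
  class(out) <- "positional_variance"
  out
}

#' @export
print.positional_variance <- function(x, ...) {
  cat("Positional variance over", length(x$variance), "subtype(s),",
      x$n_iters, "MCMC iterations; acceptance",
      paste(sprintf("%.2f", x$acceptance_rate), collapse = ", "), "\n")
  invisible(x)
}

#' Cross-validated selection of the number of subtypes
#'
#' Subject-level K-fold cross-validation: for every candidate subtype
#' count C the model is fitted on the training folds and the held-out
#' log-likelihood accumulated; `CVIC(C) = -2 * sum(out-of-fold
#' log-likelihood)` (lower is better). The selected C is the smallest
#' candidate whose CVIC lies within `parsimony_margin` of the minimum —
#' a parsimony rule that prefers the simpler model when the criterion
#' difference is small.
#'
#' By default (`mcmc_iters > 0`) the out-of-fold log-likelihood is the
#' posterior-predictive one: held-out likelihood averaged over thinned
#' MCMC samples of the per-fold sequence posterior, following the
#' original cross-validation information criterion. This matters for
#' the comparison: a maximum-likelihood plug-in evaluation lets a
#' redundant extra subtype act as a free model average (hedging
#' sequence uncertainty) and so systematically flatters larger C on
#' single-subtype data, while posterior averaging gives every candidate
#' the same hedge. `mcmc_iters = 0` falls back to the plug-in
#' evaluation.
#'
#' @param z z-score table (one row per subject).
#' @param config an [event_config()].
#' @param candidates integer vector of subtype counts to compare.
#' @param folds number of folds (>= 2; `folds = nrow(z)` is
#'   leave-one-out).
#' @param seed integer seed (fold split uses `seed`; the fit of fold j
#'   for candidate C uses `seed + 100 * C + j`).
#' @param restarts,em_iters,split_tries passed to [sustain_fit()];
#'   the defaults are lighter than [sustain_fit()]'s because each
#'   candidate is refit `folds` times.
#' @param mcmc_iters MCMC iterations per fold for the
#'   posterior-predictive out-of-fold evaluation; `0` switches to the
#'   maximum-likelihood plug-in evaluation.
#' @param parsimony_margin CVIC slack within which the smaller C wins
#'   (default 6).
#' @return list of class `sustain_cv`: data.frame `table` (columns
#'   `n_subtypes`, `oof_loglik`, `cvic`), `chosen`, `fold_logliks`.
#' @export
sustain_cv <- function(z, config, candidates = 1:3, folds = 5L, seed = 1L,
                       restarts = 10L, em_iters = 50L, split_tries = 2L,
                       mcmc_iters = 400L, parsimony_margin = 6) {
  zm <- .as_z_matrix(z, config)
  n <- nrow(zm)
  if (folds < 2L || folds > n) stop("folds must be in 2..n", call. = FALSE)
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), n))
  if (any(tabulate(fold_id, folds) == 0L))
    stop("a fold has zero subjects", call. = FALSE)
  fold_ll <- matrix(NA_real_, folds, length(candidates),
                    dimnames = list(NULL, candidates))
  for (ci in seq_along(candidates)) {
    C <- candidates[ci]
    for (j in seq_len(folds)) {
      ztr <- zm[fold_id != j, , drop = FALSE]
      zte <- zm[fold_id == j, , drop = FALSE]
      fit <- sustain_fit(ztr, config, n_subtypes = C,
                         restarts = restarts, em_iters = em_iters,
                         split_tries = split_tries,
                         seed = seed + 100L * C + j)
      fold_ll[j, ci] <- if (mcmc_iters > 0L)
        .posterior_predictive_loglik(ztr, zte, fit, mcmc_iters,
                                     seed + 100L * C + j)
      else model_loglik(zte, fit)
    }
  }
  oof <- colSums(fold_ll)
  cvic <- -2 * oof
  within <- which(cvic <= min(cvic) + parsimony_margin)
  chosen <- candidates[min(within)]
  structure(list(table = data.frame(n_subtypes = candidates,
                                    oof_loglik = oof, cvic = cvic),
                 chosen = chosen, fold_logliks = fold_ll,
                 parsimony_margin = parsimony_margin, seed = seed),
            class = "sustain_cv")
}

# held-out log-likelihood averaged over thinned posterior sequence
# samples: sum_i log( (1/S) sum_s P(x_i | model_s) ), with fractions
# held at the fitted values and samples paired across subtype chains
.posterior_predictive_loglik <- function(ztr, zte, fit, mcmc_iters,
                                         seed) {
  pv <- mcmc_positional_variance(ztr, fit, n_iters = mcmc_iters,
                                 seed = seed, keep_samples = TRUE)
  S <- min(lengths(pv$samples))
  C <- length(fit$sequences)
  cfg <- fit$config
  ll_mat <- vapply(seq_len(S), function(s) {
    m_s <- list(config = cfg,
                sequences = lapply(seq_len(C),
                                   function(cc) pv$samples[[cc]][[s]]),
                fractions = fit$fractions)
    .subject_logliks(zte, m_s)$marginal
  }, numeric(nrow(zte)))
  ll_mat <- matrix(ll_mat, nrow = nrow(zte))
  sum(.row_log_mean_exp(ll_mat))
}

#' @export
print.sustain_cv <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat("chosen number of subtypes:", x$chosen,
      sprintf("(parsimony margin %.1f)\n", x$parsimony_margin))
  invisible(x)
}
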