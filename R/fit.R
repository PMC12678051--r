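#' Fit a subtype-and-stage model by maximum likelihood
#'
#' For a single subtype the most likely event sequence is found by
#' seeded random restarts of greedy coordinate ascent: each event in
#' turn is relocated to its likelihood-maximizing admissible position
#' (respecting within-biomarker level order) until a full sweep makes no
#' improvement. For `C > 1` subtypes the model is built hierarchically:
#' the largest-membership subtype of the `C - 1` solution is split into
#' two (several seeded random splits are tried, each briefly polished,
#' and the best kept), then the full mixture is refined by
#' expectation-maximisation — responsibility-weighted sequence refits
#' with mixture fractions set to mean responsibilities — until the
#' log-likelihood gain falls below `tol`. The EM log-likelihood is
#' monotone non-decreasing by construction and asserted to be so;
#' fractions stay on the simplex.
#'
#' Ties during greedy relocation keep the incumbent position. All
#' randomness derives from `seed`: restart r of the C = 1 fit uses
#' `seed + r - 1`, and split attempt t at level c uses
#' `seed + 1000 * c + 10 * t`.
#'
#' @param z data.frame or matrix of abnormality z-scores (rows:
#'   subjects; typically first visits only — longitudinal visits are
#'   staged afterwards with [sustain_assign()]).
#' @param config an [event_config()].
#' @param n_subtypes number of subtypes C (>= 1).
#' @param restarts random restarts of the greedy ascent (default 25).
#' @param em_iters maximum EM iterations.
#' @param tol EM convergence tolerance on the total log-likelihood.
#' @param split_tries random split initializations per hierarchy level.
#' @param seed integer seed.
#' @return `sustain_model`: list with `config`, `sequences` (list of C
#'   event-index vectors), `fractions`, `loglik`, `n_subtypes`,
#'   `em_trace` and the fitting parameters.
#' @export
sustain_fit <- function(z, config, n_subtypes = 1L, restarts = 25L,
                        em_iters = 100L, tol = 1e-6, split_tries = 4L,
                        seed = 1L) {
  zm <- .as_z_matrix(z, config)
  if (n_subtypes < 1L) stop("n_subtypes must be >= 1", call. = FALSE)
  if (nrow(unique(zm)) < n_subtypes)
    stop("degenerate fit: fewer distinct rows than subtypes",
         call. = FALSE)
  if (nrow(zm) < config$n_events)
    warning("fewer rows than events; the sequence is weakly identified")
  ctx <- .make_ctx(zm, config)
  model <- .fit_c1(ctx, restarts, seed)
  em_trace <- model$loglik
  if (n_subtypes > 1L) {
    for (cc in 2L:n_subtypes) {
      best <- NULL
      for (tr in seq_len(split_tries)) {
        cand <- .split_largest(ctx, model, restarts,
                               seed + 1000L * cc + 10L * tr)
        cand <- .em_polish(ctx, cand, em_iters = 5L, tol = tol)
        if (is.null(best) || cand$loglik > best$loglik) best <- cand
      }
      model <- .em_polish(ctx, best, em_iters = em_iters, tol = tol)
      em_trace <- c(em_trace, model$em_trace)
    }
  }
  structure(list(config = config,
                 sequences = model$sequences,
                 fractions = model$fractions,
                 loglik = model$loglik,
                 n_subtypes = n_subtypes,
                 em_trace = em_trace,
                 restarts = restarts,
                 seed = seed),
            class = "sustain_model")
}

# one greedy ascent from a given start sequence; objective is the
# (weighted) relative log-likelihood sum(w * .ctx_lme)
.greedy_ascent <- function(ctx, sequence, w = NULL) {
  config <- ctx$config
  obj_of <- function(s) {
    lme <- .ctx_lme(ctx, s)
    if (is.null(w)) sum(lme) else sum(w * lme)
  }
  obj <- obj_of(sequence)
  N <- config$n_events
  repeat {
    improved <- FALSE
    for (e in seq_len(N)) {
      from <- which(sequence == e)
      win <- .admissible_window(sequence, from, config)
      cand <- setdiff(seq.int(win[1L], win[2L]), from)
      if (!length(cand)) next
      best <- obj; best_seq <- NULL
      for (to in cand) {
        s2 <- .relocate(sequence, from, to)
        o2 <- obj_of(s2)
        if (o2 > best) { best <- o2; best_seq <- s2 }
      }
      if (!is.null(best_seq)) {  # strict improvement only (ties stay)
        sequence <- best_seq; obj <- best; improved <- TRUE
      }
    }
    if (!improved) break
  }
  list(sequence = sequence, objective = obj)
}

.fit_c1 <- function(ctx, restarts, seed, w = NULL) {
  best <- NULL
  for (r in seq_len(restarts)) {
    set.seed(seed + r - 1L)
    fit <- .greedy_ascent(ctx, random_sequence(ctx$config), w)
    if (is.null(best) || fit$objective > best$objective) best <- fit
  }
  rc <- if (is.null(w)) sum(ctx$row_const) else sum(w * ctx$row_const)
  list(sequences = list(best$sequence), fractions = 1,
       loglik = best$objective + rc, em_trace = NULL)
}

# E-step responsibilities r_ic from relative per-subtype columns
.responsibilities_rel <- function(Lc_rel, fractions) {
  lf <- sweep(Lc_rel, 2L, log(fractions), `+`)
  mx <- do.call(pmax, as.data.frame(lf))
  r <- exp(lf - mx)
  r / rowSums(r)
}

.Lc_rel <- function(ctx, sequences) {
  out <- vapply(sequences, function(s) .ctx_lme(ctx, s), numeric(ctx$n))
  matrix(out, nrow = ctx$n)
}

# split the largest-membership subtype of `model` into two random
# halves and refit each half with a reduced number of restarts
.split_largest <- function(ctx, model, restarts, seed) {
  C <- length(model$sequences)
  Lc <- .Lc_rel(ctx, model$sequences)
  resp <- .responsibilities_rel(Lc, model$fractions)
  target <- which.max(colSums(resp))
  members <- which(max.col(resp, ties.method = "first") == target)
  if (length(members) < 4L) members <- seq_len(ctx$n)
  set.seed(seed)
  half <- sample(c(TRUE, FALSE), length(members), replace = TRUE)
  if (all(half) || all(!half)) half[1L] <- !half[1L]
  r_split <- max(2L, restarts %/% 5L)
  w1 <- w2 <- rep(0, ctx$n)
  w1[members[half]] <- 1
  w2[members[!half]] <- 1
  f1 <- .fit_c1(ctx, r_split, seed + 1L, w = w1)
  f2 <- .fit_c1(ctx, r_split, seed + 2L, w = w2)
  seqs <- model$sequences
  fr <- model$fractions
  seqs[[target]] <- f1$sequences[[1L]]
  seqs[[C + 1L]] <- f2$sequences[[1L]]
  fr <- c(fr, 0)
  fr[C + 1L] <- fr[target] * mean(!half)
  fr[target] <- fr[target] * mean(half)
  fr <- fr / sum(fr)
  list(sequences = seqs, fractions = fr)
}

.em_polish <- function(ctx, model, em_iters, tol) {
  seqs <- model$sequences
  fr <- model$fractions
  Lc <- .Lc_rel(ctx, seqs)
  ll <- .ctx_model_ll(ctx, Lc, fr)
  trace <- ll
  for (it in seq_len(em_iters)) {
    r <- .responsibilities_rel(Lc, fr)
    fr <- pmax(colMeans(r), 1e-12)
    fr <- fr / sum(fr)
    for (cc in seq_along(seqs)) {
      seqs[[cc]] <- .greedy_ascent(ctx, seqs[[cc]], w = r[, cc])$sequence
    }
    Lc <- .Lc_rel(ctx, seqs)
    ll_new <- .ctx_model_ll(ctx, Lc, fr)
    stopifnot("EM log-likelihood decreased" = ll_new >= ll - 1e-8)
    trace <- c(trace, ll_new)
    if (ll_new - ll < tol) { ll <- ll_new; break }
    ll <- ll_new
  }
  list(sequences = seqs, fractions = fr, loglik = ll, em_trace = trace)
}

#' @export
print.sustain_model <- function(x, ...) {
  cat("Subtype-and-stage model:", x$n_subtypes, "subtype(s),",
      x$config$n_events, "events, log-likelihood",
      format(x$loglik, digits = 7), "\n")
  labs <- event_labels(x$config)
  for (cc in seq_along(x$sequences)) {
    cat(sprintf("  subtype %d (f = %.3f): %s\n", cc, x$fractions[cc],
                paste(labs[x$sequences[[cc]]], collapse = " > ")))
  }
  invisible(x)
}
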