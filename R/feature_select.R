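#' Rank candidate features by rank correlation with EDSS
#'
#' First stage of the EDSS-anchored variable selection: every candidate
#' is scored by the absolute Spearman correlation of its values with
#' EDSS, and the top `k` are kept. Constant features (undefined
#' correlation) are excluded with a warning; ties are broken
#' alphabetically for determinism.
#'
#' @param features data.frame of candidate feature columns.
#' @param edss numeric EDSS per row.
#' @param k number of features to retain (default 10).
#' @return data.frame `feature`, `rho`, `p` sorted by decreasing
#'   `|rho|`, truncated to `k` rows.
#' @export
rank_by_edss_correlation <- function(features, edss, k = 10L) {
  stopifnot(nrow(features) == length(edss))
  rows <- lapply(names(features), function(f) {
    x <- features[[f]]
    if (stats::sd(x) == 0) {
      warning("feature '", f, "' is constant; correlation undefined, ",
              "excluded")
      return(NULL)
    }
    ct <- suppressWarnings(stats::cor.test(x, edss, method = "spearman",
                                           exact = FALSE))
    data.frame(feature = f, rho = unname(ct$estimate),
               p = ct$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L)
    stop("no usable features", call. = FALSE)
  out <- out[order(-abs(out$rho), out$feature), ]
  rownames(out) <- NULL
  utils::head(out, k)
}

#' Recursive feature elimination against the stage-EDSS correlation
#'
#' Second selection stage: starting from the top-ranked working set,
#' each round drops the feature whose removal maximizes the Spearman
#' correlation between the stages of a refit single-subtype model and
#' EDSS, until `target` features remain. Refits use a reduced number of
#' greedy restarts for speed; EDSS enters only through this objective,
#' never through the event model itself (which keeps the pipeline
#' honest about being "not entirely unsupervised").
#'
#' Ties remove the alphabetically-last candidate. Round r refits use
#' seed `seed + r`, recorded in the trace so every objective value is
#' reproducible.
#'
#' @param z data.frame of abnormality z-scores containing the start set.
#' @param edss numeric EDSS per row.
#' @param start character vector: the working feature set.
#' @param target final feature-set size (default 5).
#' @param thresholds,z_max event-model settings used for the refits.
#' @param restarts greedy restarts per refit (default 5).
#' @param seed integer seed.
#' @return object of class `selection_trace`: list with `rounds`
#'   (data.frame `round`, `removed`, `rho`, `seed`), `final` (character
#'   vector) and `start`.
#' @export
recursive_eliminate <- function(z, edss, start, target = 5L,
                                thresholds = c(1, 2, 3), z_max = 5,
                                restarts = 5L, seed = 1L) {
  if (!all(start %in% names(z)))
    stop("start set not contained in the table", call. = FALSE)
  if (target > length(start))
    stop("target larger than the start set", call. = FALSE)
  working <- sort(start)
  rounds <- data.frame(round = integer(), removed = character(),
                       rho = numeric(), seed = integer(),
                       stringsAsFactors = FALSE)
  r <- 0L
  while (length(working) > target) {
    r <- r + 1L
    round_seed <- seed + r
    best_rho <- -Inf; best_drop <- NULL
    for (f in working) {
      keep <- setdiff(working, f)
      rho <- tryCatch(
        .stage_edss_rho(z, edss, keep, thresholds, z_max, restarts,
                        round_seed),
        error = function(e) stop("engine fit failed while evaluating ",
                                 "removal of '", f, "': ",
                                 conditionMessage(e), call. = FALSE))
      # ties: remove the alphabetically-last candidate (working is
      # sorted, so >= keeps the later name)
      if (rho >= best_rho) { best_rho <- rho; best_drop <- f }
    }
    working <- setdiff(working, best_drop)
    rounds <- rbind(rounds,
                    data.frame(round = r, removed = best_drop,
                               rho = best_rho, seed = round_seed,
                               stringsAsFactors = FALSE))
  }
  structure(list(start = sort(start), rounds = rounds, final = working,
                 target = target, restarts = restarts, seed = seed),
            class = "selection_trace")
}

.stage_edss_rho <- function(z, edss, feats, thresholds, z_max, restarts,
                            seed) {
  cfg <- event_config(feats, thresholds = thresholds, z_max = z_max)
  fit <- sustain_fit(z[, feats, drop = FALSE], cfg, n_subtypes = 1L,
                     restarts = restarts, seed = seed)
  stage <- sustain_assign(z[, feats, drop = FALSE], fit)$ml_stage
  suppressWarnings(stats::cor(stage, edss, method = "spearman"))
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("Recursive feature elimination:", length(x$start), "->",
      length(x$final), "features\n")
  if (nrow(x$rounds)) print(x$rounds, row.names = FALSE)
  cat("final set:", paste(x$final, collapse = ", "), "\n")
  invisible(x)
}
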