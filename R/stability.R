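#' Per-visit subtype/stage labels from a posterior table
#'
#' Reduces a [sustain_assign()] table to one labelled row per
#' subject-visit: maximum-probability subtype, MAP stage and the
#' assignment confidence (the maximum subtype probability; equal
#' probabilities resolve to the lower subtype index).
#'
#' @param posterior a `sustain_posterior` data.frame with `subject` and
#'   `month` columns.
#' @return data.frame `subject`, `month`, `subtype`, `stage`,
#'   `confidence`.
#' @export
label_visits <- function(posterior) {
  need <- c("subject", "month", "ml_subtype", "ml_stage", "confidence")
  if (!all(need %in% names(posterior)))
    stop("posterior table must carry subject/month keys and labels",
         call. = FALSE)
  if (anyDuplicated(posterior[, c("subject", "month")]))
    stop("duplicate (subject, month) keys", call. = FALSE)
  out <- data.frame(subject = posterior$subject,
                    month = posterior$month,
                    subtype = posterior$ml_subtype,
                    stage = posterior$ml_stage,
                    confidence = posterior$confidence)
  out[order(out$subject, out$month), ]
}

#' Subtype-switching stability across confidence thresholds
#'
#' A subject "switches" if the maximum-probability subtype at any later
#' visit differs from the baseline (earliest-visit) subtype. For each
#' confidence threshold tau, only subjects whose baseline confidence is
#' `>= tau` are retained, and the switch fraction is computed over them.
#' Raising the threshold never increases the switch set, so the reported
#' fraction tends to fall as tau rises — the stability pattern the
#' sensitivity analysis at 80/85/90% confidence probes.
#'
#' @param labels a [label_visits()] table.
#' @param thresholds confidence thresholds (default 0.80, 0.85, 0.90).
#' @param anchor `"baseline"` (default; switch = any later visit differs
#'   from baseline) or `"consecutive"` (any visit differs from its
#'   predecessor).
#' @return data.frame of class `stability_report`: `threshold`,
#'   `n_retained`, `n_switched`, `switch_fraction`.
#' @export
switching_analysis <- function(labels, thresholds = c(0.80, 0.85, 0.90),
                               anchor = c("baseline", "consecutive")) {
  anchor <- match.arg(anchor)
  labels <- labels[order(labels$subject, labels$month), ]
  by_subj <- split(labels, labels$subject)
  multi <- vapply(by_subj, nrow, integer(1)) >= 2L
  if (!any(multi)) {
    warning("no subject has more than one visit; empty report")
    out <- data.frame(threshold = thresholds, n_retained = 0L,
                      n_switched = 0L, switch_fraction = NA_real_)
    class(out) <- c("stability_report", "data.frame")
    return(out)
  }
  base_conf <- vapply(by_subj, function(d) d$confidence[1L], numeric(1))
  switches <- vapply(by_subj, function(d) {
    if (nrow(d) < 2L) return(FALSE)
    if (anchor == "baseline") any(d$subtype[-1L] != d$subtype[1L])
    else any(diff(d$subtype) != 0)
  }, logical(1))
  out <- do.call(rbind, lapply(thresholds, function(tau) {
    keep <- base_conf >= tau
    data.frame(threshold = tau, n_retained = sum(keep),
               n_switched = sum(switches & keep),
               switch_fraction = if (any(keep))
                 sum(switches & keep) / sum(keep) else NA_real_)
  }))
  class(out) <- c("stability_report", "data.frame")
  out
}
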