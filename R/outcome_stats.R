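#' Spearman rank correlation with strength label
#'
#' Midrank-tied Spearman correlation with an asymptotic two-tailed
#' p-value, labelled by the conventional strength bins on `|rho|`:
#' 0.10-0.39 weak, 0.40-0.69 moderate, 0.70-0.89 strong, 0.90-1.00 very
#' strong; `|rho| < 0.10` is labelled "negligible".
#'
#' @param x,y paired numeric vectors (n >= 4, finite).
#' @return list of class `correlation_result`: `rho`, `p`, `n`, `label`.
#' @export
spearman_with_p <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  rho <- unname(ct$estimate)
  structure(list(rho = rho, p = ct$p.value, n = n,
                 label = correlation_strength(rho)),
            class = "correlation_result")
}

#' @rdname spearman_with_p
#' @param rho a correlation coefficient.
#' @export
correlation_strength <- function(rho) {
  a <- abs(rho)
  if (a > 1) stop("|rho| > 1", call. = FALSE)
  if (a < 0.10) "negligible"
  else if (a < 0.40) "weak"
  else if (a < 0.70) "moderate"
  else if (a < 0.90) "strong"
  else "very strong"
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f (%s), p = %.4g, n = %d\n",
              x$rho, x$label, x$p, x$n))
  invisible(x)
}

#' Fisher z comparison of two independent correlations
#'
#' `z = (atanh(rho1) - atanh(rho2)) / sqrt(1/(n1-3) + 1/(n2-3))` with a
#' two-tailed normal p-value. Assumes the two correlations come from
#' independent samples.
#'
#' @param rho1,rho2 correlation coefficients (|rho| < 1).
#' @param n1,n2 sample sizes (> 3).
#' @return list with `z` and `p`.
#' @export
fisher_z_compare <- function(rho1, n1, rho2, n2) {
  if (n1 <= 3 || n2 <= 3) stop("sample sizes must exceed 3", call. = FALSE)
  if (abs(rho1) >= 1 || abs(rho2) >= 1)
    stop("|rho| must be < 1", call. = FALSE)
  z <- (atanh(rho1) - atanh(rho2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Annual outcome slopes from random-intercept mixed models
#'
#' Fits, separately per group (per subtype, or per subtype x treatment
#' arm), `outcome ~ years + (1 | subject)` by REML and reports the fixed
#' time slope in outcome units per year with its Wald 95% CI and
#' Satterthwaite p-value. Groups without repeated measures are reported
#' as non-estimable.
#'
#' @param visits long data.frame with `subject`, `month` and the outcome
#'   and grouping columns.
#' @param outcome outcome column name.
#' @param grouping `"subtype"` or `"subtype_arm"`.
#' @param subtype_col,arm_col grouping column names.
#' @return data.frame of class `slope_result`: one row per group with
#'   `group`, `beta`, `ci_lo`, `ci_hi`, `p`, `n_subjects`, `n_visits`.
#' @export
mixed_slope <- function(visits, outcome,
                        grouping = c("subtype", "subtype_arm"),
                        subtype_col = "subtype", arm_col = "arm") {
  grouping <- match.arg(grouping)
  stopifnot(all(c("subject", "month", outcome, subtype_col) %in%
                  names(visits)))
  g <- as.character(visits[[subtype_col]])
  if (grouping == "subtype_arm")
    g <- paste(g, visits[[arm_col]], sep = ":")
  rows <- lapply(sort(unique(g)), function(grp) {
    d <- visits[g == grp, , drop = FALSE]
    d$years <- d$month / 12
    d$y <- d[[outcome]]
    n_subj <- length(unique(d$subject))
    if (!any(duplicated(d$subject)) || length(unique(d$years)) < 2L)
      return(data.frame(group = grp, beta = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_, p = NA_real_,
                        n_subjects = n_subj, n_visits = nrow(d),
                        note = "non-estimable: no repeated measures"))
    fit <- suppressMessages(suppressWarnings(
      lmerTest::lmer(y ~ years + (1 | subject), data = d, REML = TRUE)))
    co <- stats::coef(summary(fit))["years", ]
    ci <- suppressWarnings(stats::confint(fit, parm = "years",
                                          method = "Wald"))
    data.frame(group = grp, beta = unname(co["Estimate"]),
               ci_lo = ci[1L], ci_hi = ci[2L],
               p = unname(co["Pr(>|t|)"]),
               n_subjects = n_subj, n_visits = nrow(d), note = "")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("slope_result", "data.frame")
  out
}

#' Time to first new gadolinium-enhancing lesion
#'
#' Per subject, an increase in lesion count at any follow-up visit
#' relative to the previous visit is an event at that visit; otherwise
#' the subject is censored at the last visit. Time is months from
#' baseline (the earliest visit).
#'
#' @param visits long data.frame with `subject`, `month` and lesion
#'   counts.
#' @param lesion_col lesion-count column (default `"gad_count"`).
#' @return data.frame `subject`, `time` (months), `event` (0/1), plus
#'   any of `subtype`, `arm`, `batch` carried from the baseline row.
#' @export
time_to_new_lesion <- function(visits, lesion_col = "gad_count") {
  stopifnot(all(c("subject", "month", lesion_col) %in% names(visits)))
  carry <- intersect(c("subtype", "arm", "batch"), names(visits))
  rows <- lapply(split(visits, visits$subject), function(d) {
    d <- d[order(d$month), ]
    cnt <- d[[lesion_col]]
    base <- d$month[1L]
    out <- data.frame(subject = d$subject[1L], time = NA_real_,
                      event = 0L)
    if (nrow(d) == 1L) {
      warning("subject ", d$subject[1L],
              " has only a baseline visit; censored at time 0")
      out$time <- 0
    } else {
      inc <- which(diff(cnt) > 0)
      if (length(inc)) {
        out$time <- d$month[inc[1L] + 1L] - base
        out$event <- 1L
      } else {
        out$time <- d$month[nrow(d)] - base
      }
    }
    for (cl in carry) out[[cl]] <- d[[cl]][1L]
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cox proportional-hazards fit for new-lesion risk
#'
#' Partial-likelihood fit with the Efron tie correction (visit-grid
#' event times are heavily tied). Covariates default to subtype and
#' treatment arm.
#'
#' @param surv a [time_to_new_lesion()]-style data.frame with `time`,
#'   `event` and covariate columns.
#' @param covariates character vector of covariate columns.
#' @return list of class `cox_result`: data.frame `table` (`term`, `hr`,
#'   `ci_lo`, `ci_hi`, `p`), `n_events`, and the underlying
#'   `survival::coxph` fit.
#' @export
cox_fit <- function(surv, covariates = c("subtype", "arm")) {
  stopifnot(all(c("time", "event", covariates) %in% names(surv)))
  if (sum(surv$event) == 0L)
    stop("no events: cannot fit a proportional-hazards model",
         call. = FALSE)
  for (cl in covariates) {
    if (length(unique(surv[[cl]])) < 2L)
      stop("covariate '", cl, "' is constant", call. = FALSE)
    if (!is.numeric(surv[[cl]])) surv[[cl]] <- factor(surv[[cl]])
  }
  f <- stats::as.formula(paste("survival::Surv(time, event) ~",
                               paste(covariates, collapse = " + ")))
  fit <- survival::coxph(f, data = surv, ties = "efron")
  s <- summary(fit)
  tab <- data.frame(term = rownames(s$coefficients),
                    hr = s$conf.int[, "exp(coef)"],
                    ci_lo = s$conf.int[, "lower .95"],
                    ci_hi = s$conf.int[, "upper .95"],
                    p = s$coefficients[, "Pr(>|z|)"],
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, n_events = sum(surv$event), fit = fit),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat("Cox proportional hazards (Efron ties),", x$n_events, "events\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimates, exported as a step-function table suitable
#' for plotting or further bookkeeping.
#'
#' @param surv data.frame with `time`, `event` and the grouping column.
#' @param group grouping column name (groups with no rows are skipped
#'   with a warning).
#' @return data.frame `group`, `time`, `n_risk`, `n_event`, `surv`.
#' @export
km_curve <- function(surv, group = "subtype") {
  stopifnot(all(c("time", "event", group) %in% names(surv)))
  g <- surv[[group]]
  rows <- lapply(unique(g), function(grp) {
    d <- surv[g == grp, , drop = FALSE]
    if (nrow(d) == 0L) {
      warning("empty group '", grp, "' skipped")
      return(NULL)
    }
    sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
    data.frame(group = grp, time = sf$time, n_risk = sf$n.risk,
               n_event = sf$n.event, surv = sf$surv)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Annualized brain-volume-change contrasts between subtypes
#'
#' Annualizes each subject's total percentage brain volume change by the
#' actual inter-scan interval in years, summarizes per group and runs
#' Welch two-sample t-tests between subtypes — overall and within each
#' treatment arm.
#'
#' @param pbvc data.frame with per-subject `pbvc` (total % change),
#'   `years` (inter-scan interval), `subtype` and optionally `arm`.
#'   Zero or missing intervals are excluded with a message.
#' @return list of class `pbvc_result`: `groups` (data.frame `arm`,
#'   `subtype`, `mean`, `sd`, `n`), `tests` (data.frame `arm`, `t`, `p`).
#' @export
pbvc_contrast <- function(pbvc) {
  stopifnot(all(c("pbvc", "years", "subtype") %in% names(pbvc)))
  bad <- !is.finite(pbvc$years) | pbvc$years <= 0
  if (any(bad)) {
    message(sum(bad), " subject(s) excluded: zero or missing interval")
    pbvc <- pbvc[!bad, , drop = FALSE]
  }
  pbvc$annual <- pbvc$pbvc / pbvc$years
  arms <- if ("arm" %in% names(pbvc))
    c("all", sort(unique(as.character(pbvc$arm)))) else "all"
  groups <- list(); tests <- list()
  for (a in arms) {
    d <- if (a == "all") pbvc else pbvc[pbvc$arm == a, , drop = FALSE]
    for (st in sort(unique(as.character(d$subtype)))) {
      v <- d$annual[d$subtype == st]
      groups[[length(groups) + 1L]] <-
        data.frame(arm = a, subtype = st, mean = mean(v),
                   sd = stats::sd(v), n = length(v))
    }
    sts <- sort(unique(as.character(d$subtype)))
    if (length(sts) == 2L) {
      v1 <- d$annual[d$subtype == sts[1L]]
      v2 <- d$annual[d$subtype == sts[2L]]
      tt <- if (stats::sd(c(v1, v2)) == 0 ||
                (stats::sd(v1) == 0 && stats::sd(v2) == 0 &&
                 mean(v1) == mean(v2)))
        list(statistic = c(t = 0), p.value = 1)
      else stats::t.test(v1, v2)
      tests[[length(tests) + 1L]] <-
        data.frame(arm = a, t = unname(tt$statistic), p = tt$p.value)
    }
  }
  structure(list(groups = do.call(rbind, groups),
                 tests = do.call(rbind, tests)),
            class = "pbvc_result")
}

#' @export
print.pbvc_result <- function(x, ...) {
  cat("Annualized PBVC by group:\n")
  print(x$groups, row.names = FALSE)
  if (!is.null(x$tests)) {
    cat("Welch t-tests between subtypes:\n")
    print(x$tests, row.names = FALSE)
  }
  invisible(x)
}

#' Truncate control-arm records at the crossover month
#'
#' External-design emulation helper: control-arm visits after the
#' crossover month (default 24) are dropped, matching designs in which
#' the control arm switches to active treatment in an extension phase.
#'
#' @param visits long visit data.frame with `month` and the arm column.
#' @param arm_col treatment-arm column (values `"control"` are
#'   truncated).
#' @param crossover_month last control month retained (default 24).
#' @return filtered data.frame.
#' @export
truncate_control_crossover <- function(visits, arm_col = "arm",
                                       crossover_month = 24) {
  keep <- visits[[arm_col]] != "control" |
    visits$month <= crossover_month
  visits[keep, , drop = FALSE]
}
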