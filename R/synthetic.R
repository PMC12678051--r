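#' Default six-biomarker panel and planted subtype sequences
#'
#' The default synthetic panel mirrors the combined MRI + serum model:
#' three regional volumes (limbic cortex, deep grey matter, parietal
#' cortex), total T2 lesion volume, corpus callosum T1/T2 ratio and the
#' sNfL z-score. Two planted orderings give the subtypes their
#' character: in the "early-sNfL" sequence the sNfL, corpus-callosum
#' T1/T2 and lesion events come first; in the "late-sNfL" sequence
#' limbic and deep-grey-matter volume loss lead and sNfL rises late.
#'
#' @return `ms_biomarker_panel()`: character vector of the six biomarker
#'   names. `default_true_sequences(config)`: list of the two planted
#'   event sequences for a 3-threshold [event_config()] over that panel.
#' @export
ms_biomarker_panel <- function() {
  c("limbic_volume", "dgm_volume", "parietal_volume",
    "lesion_volume", "cc_t1t2", "snfl")
}

#' @rdname ms_biomarker_panel
#' @param config an [event_config()] over [ms_biomarker_panel()] with
#'   three thresholds per biomarker.
#' @export
default_true_sequences <- function(config) {
  stopifnot(identical(config$biomarkers, ms_biomarker_panel()),
            config$n_events == 18L)
  early <- c(16L, 13L, 10L, 17L, 14L, 11L, 7L, 1L, 4L,
             18L, 15L, 12L, 2L, 5L, 8L, 3L, 6L, 9L)
  late <- c(1L, 4L, 7L, 2L, 5L, 8L, 13L, 10L, 3L,
            6L, 9L, 14L, 11L, 16L, 15L, 12L, 17L, 18L)
  validate_sequence(early, config)
  validate_sequence(late, config)
  list(early_snfl = early, late_snfl = late)
}

#' Configuration for the synthetic longitudinal cohort generator
#'
#' Defines the study conditions a generated cohort emulates: a
#' relapse-onset MS trial structure with screening plus follow-up visits
#' at months 3, 4, 5, 6 and 12, two latent subtypes with distinct event
#' orderings over six biomarkers (prevalences 44/56% as in the training
#' cohort), uniform baseline stages over 0..N, stage-linked EDSS on the
#' 0-10 half-point grid, subtype/treatment-dependent Poisson lesion
#' counts, subtype-dependent annualized brain-volume-change, and an
#' optional batch (scanner/study) shift for harmonization testing.
#'
#' No canonical generative magnitudes exist for the outcome links; the
#' defaults are fixed once to reproduce the qualitative patterns seen
#' in relapse-onset MS trials (moderate stage-EDSS rank correlation,
#' low gadolinium-enhancing lesion counts, faster atrophy in the
#' early-sNfL subtype) and are documented in the methods vignette.
#'
#' @param n_subjects number of subjects.
#' @param visit_months strictly increasing visit grid in months.
#' @param config [event_config()] shared by the planted sequences.
#' @param true_sequences list of planted event sequences, one per
#'   subtype.
#' @param subtype_fractions subtype prevalences (sum to 1).
#' @param stage_distribution baseline-stage probabilities over 0..N
#'   (default uniform).
#' @param noise_sd per-biomarker Gaussian noise sd (> 0); scalar or
#'   named vector.
#' @param edss_link list `intercept`, `slope` (EDSS points per stage),
#'   `sd`; EDSS is clipped to the 0-10 half-point grid.
#' @param lesion_link list `base_rate` (Poisson rate per subtype),
#'   `treatment_rr` (rate ratio under treatment), `time_coef` (log-rate
#'   per year).
#' @param pbvc_link list `annual_mean` (annualized % change per
#'   subtype), `sd`.
#' @param progression_rate stages per year, per subtype (subjects never
#'   regress).
#' @param treatment_fraction probability of assignment to the treatment
#'   arm.
#' @param batch_effects `NULL` (single batch "A") or list with `labels`,
#'   `probs`, `shift` (batch x biomarker additive matrix) and `scale`
#'   (multiplicative matrix).
#' @param seed integer seed; identical config + seed gives byte-identical
#'   tables.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 200L,
                          visit_months = c(0, 3, 4, 5, 6, 12),
                          config = event_config(ms_biomarker_panel()),
                          true_sequences = default_true_sequences(config),
                          subtype_fractions = c(0.44, 0.56),
                          stage_distribution = NULL,
                          noise_sd = 1,
                          edss_link = list(intercept = 1.5, slope = 0.15,
                                           sd = 1.5),
                          lesion_link = list(base_rate = c(0.8, 0.4),
                                             treatment_rr = 0.3,
                                             time_coef = 0),
                          pbvc_link = list(annual_mean = c(-0.46, -0.31),
                                           sd = 0.42),
                          progression_rate = c(1.2, 0.8),
                          treatment_fraction = 0.5,
                          batch_effects = NULL,
                          seed = 1L) {
  if (n_subjects < 1L) stop("n_subjects must be positive", call. = FALSE)
  if (length(visit_months) < 1L ||
      is.unsorted(visit_months, strictly = TRUE))
    stop("visit_months must be strictly increasing", call. = FALSE)
  if (abs(sum(subtype_fractions) - 1) > 1e-8 ||
      any(subtype_fractions <= 0))
    stop("subtype_fractions must be positive and sum to 1",
         call. = FALSE)
  C <- length(subtype_fractions)
  if (length(true_sequences) != C)
    stop("need one true sequence per subtype", call. = FALSE)
  for (s in true_sequences) validate_sequence(s, config)
  N <- config$n_events
  if (is.null(stage_distribution))
    stage_distribution <- rep(1 / (N + 1), N + 1)
  if (length(stage_distribution) != N + 1 ||
      any(stage_distribution < 0) ||
      abs(sum(stage_distribution) - 1) > 1e-8)
    stop("stage_distribution must be probabilities over 0..N",
         call. = FALSE)
  # noise_sd = 0 is admitted for noiseless trajectory checks
  noise_sd <- .per_biomarker(noise_sd, config$biomarkers, "noise_sd")
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0", call. = FALSE)
  if (length(progression_rate) == 1L)
    progression_rate <- rep(progression_rate, C)
  if (length(lesion_link$base_rate) == 1L)
    lesion_link$base_rate <- rep(lesion_link$base_rate, C)
  if (length(pbvc_link$annual_mean) == 1L)
    pbvc_link$annual_mean <- rep(pbvc_link$annual_mean, C)
  if (any(lesion_link$base_rate <= 0) || lesion_link$treatment_rr <= 0)
    stop("lesion rates must be positive", call. = FALSE)
  if (!is.null(batch_effects)) {
    be <- batch_effects
    if (!all(c("labels", "probs", "shift", "scale") %in% names(be)))
      stop("batch_effects needs labels, probs, shift, scale",
           call. = FALSE)
    if (length(be$labels) != length(be$probs) ||
        abs(sum(be$probs) - 1) > 1e-8)
      stop("batch probs must match labels and sum to 1", call. = FALSE)
    if (!all(dim(be$shift) == c(length(be$labels),
                                length(config$biomarkers))) ||
        !all(dim(be$scale) == dim(be$shift)))
      stop("batch shift/scale must be batch x biomarker matrices",
           call. = FALSE)
    if (any(be$scale <= 0))
      stop("batch scales must be positive", call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 visit_months = visit_months, config = config,
                 true_sequences = true_sequences,
                 subtype_fractions = subtype_fractions,
                 stage_distribution = stage_distribution,
                 noise_sd = noise_sd, edss_link = edss_link,
                 lesion_link = lesion_link, pbvc_link = pbvc_link,
                 progression_rate = progression_rate,
                 treatment_fraction = treatment_fraction,
                 batch_effects = batch_effects,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a reference (healthy-control-like) biomarker cohort
#'
#' Draws `n` rows of raw biomarker values from independent normal
#' distributions — the stand-in for an external normative dataset
#' against which patient values are z-scored.
#'
#' @param n number of reference subjects (>= 2).
#' @param means named numeric vector of biomarker means.
#' @param sds named numeric vector of standard deviations (> 0).
#' @param seed integer seed.
#' @return data.frame with one column per biomarker.
#' @export
generate_reference_cohort <- function(n, means, sds, seed = 1L) {
  if (n < 2L) stop("invalid config: n must be at least 2", call. = FALSE)
  if (is.null(names(means))) stop("means must be named", call. = FALSE)
  sds <- .per_biomarker(sds, names(means), "sds")
  if (any(sds <= 0))
    stop("invalid config: sds must be positive", call. = FALSE)
  set.seed(seed)
  out <- as.data.frame(lapply(names(means), function(b)
    stats::rnorm(n, means[[b]], sds[[b]])))
  names(out) <- names(means)
  out
}

#' Generate a synthetic longitudinal cohort with planted ground truth
#'
#' Subjects get a fixed latent subtype, a baseline stage drawn from the
#' configured stage distribution and a deterministic (rounded,
#' non-regressing) stage trajectory across visits. Biomarker z-scores
#' equal the planted subtype trajectory's expected value at the true
#' stage plus Gaussian noise; EDSS, lesion counts and per-subject PBVC
#' follow the configured links; batch shifts are applied last.
#'
#' @param cfg a [cohort_config()].
#' @return list of class `ms_cohort` with `visits` (one row per
#'   subject-visit: `subject`, `month`, `arm`, `batch`, the biomarker
#'   z-columns, `edss`, `gad_count`) and `truth` (per visit: `subject`,
#'   `month`, `subtype`, `true_stage`, `arm`, `batch`, plus per-subject
#'   `pbvc` and `pbvc_years` on the final-visit row).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  ec <- cfg$config
  N <- ec$n_events
  B <- ec$biomarkers
  n <- cfg$n_subjects
  months <- cfg$visit_months
  V <- length(months)
  C <- length(cfg$subtype_fractions)

  subtype <- sample.int(C, n, replace = TRUE,
                        prob = cfg$subtype_fractions)
  arm <- ifelse(stats::runif(n) < cfg$treatment_fraction,
                "treatment", "control")
  batch <- if (is.null(cfg$batch_effects)) rep("A", n) else
    sample(cfg$batch_effects$labels, n, replace = TRUE,
           prob = cfg$batch_effects$probs)
  k0 <- sample.int(N + 1L, n, replace = TRUE,
                   prob = cfg$stage_distribution) - 1L

  E <- lapply(cfg$true_sequences, expected_matrix, config = ec)

  years <- (months - months[1L]) / 12
  subj_id <- sprintf("S%04d", seq_len(n))
  rows_v <- vector("list", n)
  rows_t <- vector("list", n)
  for (i in seq_len(n)) {
    st <- as.integer(pmin(N, cummax(round(k0[i] +
      cfg$progression_rate[subtype[i]] * years))))
    Z <- t(E[[subtype[i]]][, st + 1L, drop = FALSE])
    noise <- matrix(stats::rnorm(V * length(B), 0,
                                 rep(cfg$noise_sd, each = V)), V)
    Z <- Z + noise
    colnames(Z) <- B
    edss_raw <- cfg$edss_link$intercept + cfg$edss_link$slope * st +
      stats::rnorm(V, 0, cfg$edss_link$sd)
    edss <- pmin(10, pmax(0, round(edss_raw * 2) / 2))
    treated <- (arm[i] == "treatment") & (months > months[1L])
    log_rate <- log(cfg$lesion_link$base_rate[subtype[i]]) +
      log(cfg$lesion_link$treatment_rr) * treated +
      cfg$lesion_link$time_coef * years
    gad <- stats::rpois(V, exp(log_rate))
    if (!is.null(cfg$batch_effects)) {
      bi <- match(batch[i], cfg$batch_effects$labels)
      Z <- sweep(Z, 2L, cfg$batch_effects$scale[bi, ], `*`)
      Z <- sweep(Z, 2L, cfg$batch_effects$shift[bi, ], `+`)
    }
    pbvc_years <- years[V]
    pbvc_rate <- cfg$pbvc_link$annual_mean[subtype[i]] +
      stats::rnorm(1L, 0, cfg$pbvc_link$sd)
    rows_v[[i]] <- data.frame(subject = subj_id[i], month = months,
                              arm = arm[i], batch = batch[i],
                              as.data.frame(Z), edss = edss,
                              gad_count = gad,
                              stringsAsFactors = FALSE)
    rows_t[[i]] <- data.frame(subject = subj_id[i], month = months,
                              subtype = subtype[i], true_stage = st,
                              arm = arm[i], batch = batch[i],
                              pbvc = c(rep(NA_real_, V - 1L),
                                       pbvc_rate * pbvc_years),
                              pbvc_years = c(rep(NA_real_, V - 1L),
                                             pbvc_years),
                              stringsAsFactors = FALSE)
  }
  visits <- do.call(rbind, rows_v)
  truth <- do.call(rbind, rows_t)
  rownames(visits) <- rownames(truth) <- NULL
  structure(list(visits = visits, truth = truth, config = cfg),
            class = "ms_cohort")
}

#' @export
print.ms_cohort <- function(x, ...) {
  cat("Synthetic MS cohort:", x$config$n_subjects, "subjects x",
      length(x$config$visit_months), "visits,",
      length(x$config$subtype_fractions), "planted subtypes\n")
  invisible(x)
}

#' Plant exponential time-to-new-lesion outcomes on a cohort
#'
#' Simulates a latent exponential first-event time per subject under
#' proportional hazards (subtype 1 carries `hazard_ratio_subtype`
#' relative to the others; the treatment arm carries
#' `hazard_ratio_treatment`), then discretizes onto the visit grid: the
#' event is recorded at the first follow-up visit at or after the latent
#' time, otherwise the subject is censored at the last visit.
#'
#' @param cohort an [generate_cohort()] result.
#' @param hazard_ratio_subtype hazard ratio of subtype 1 vs the rest
#'   (> 0).
#' @param hazard_ratio_treatment hazard ratio of treatment vs control
#'   (> 0).
#' @param base_hazard control-group baseline hazard per month.
#' @param seed integer seed.
#' @return data.frame `subject`, `time` (months from baseline), `event`,
#'   `subtype`, `arm`.
#' @export
generate_survival_truth <- function(cohort, hazard_ratio_subtype = 2.44,
                                    hazard_ratio_treatment = 0.5,
                                    base_hazard = 0.04, seed = 1L) {
  stopifnot(inherits(cohort, "ms_cohort"))
  if (hazard_ratio_subtype <= 0 || hazard_ratio_treatment <= 0 ||
      base_hazard <= 0)
    stop("hazards must be positive", call. = FALSE)
  months <- cohort$config$visit_months
  if (length(months) < 2L)
    stop("invalid config: need follow-up visits beyond baseline",
         call. = FALSE)
  fup <- months[-1L] - months[1L]
  base <- cohort$truth[!duplicated(cohort$truth$subject),
                       c("subject", "subtype", "arm")]
  set.seed(seed)
  lambda <- base_hazard *
    ifelse(base$subtype == 1L, hazard_ratio_subtype, 1) *
    ifelse(base$arm == "treatment", hazard_ratio_treatment, 1)
  t_lat <- stats::rexp(nrow(base), rate = lambda)
  idx <- vapply(t_lat, function(tt) {
    hit <- which(fup >= tt)
    if (length(hit)) hit[1L] else NA_integer_
  }, integer(1))
  data.frame(subject = base$subject,
             time = ifelse(is.na(idx), fup[length(fup)], fup[idx]),
             event = as.integer(!is.na(idx)),
             subtype = base$subtype, arm = base$arm,
             stringsAsFactors = FALSE)
}

#' Plausible reference-distribution parameters for the default panel
#'
#' Normative means/sds on the raw scale for the six-biomarker panel
#' (volumes in cubic millimetres, T1/T2 ratio unitless, lesion volume in
#' cubic millimetres, sNfL already a z-score). Used when a raw-scale
#' pipeline exercise is wanted; all synthetic modelling happens on the
#' z scale.
#'
#' @return list with `means` and `sds` named vectors (sNfL excluded —
#'   it needs no reference scaling).
#' @export
ms_reference_defaults <- function() {
  list(means = c(limbic_volume = 12000, dgm_volume = 40000,
                 parietal_volume = 55000, lesion_volume = 2000,
                 cc_t1t2 = 1.40),
       sds = c(limbic_volume = 1200, dgm_volume = 3500,
               parietal_volume = 5000, lesion_volume = 400,
               cc_t1t2 = 0.10))
}
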