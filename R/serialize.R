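#' Serialize and restore fitted objects as structured text
#'
#' Models, reference statistics and harmonization models round-trip
#' through versioned YAML documents so fits can be audited and reapplied
#' without binary artifacts.
#'
#' @param model a `sustain_model`.
#' @param path file path.
#' @return `write_*` return `path` invisibly; `read_*` return the
#'   restored object.
#' @name serialization
NULL

.schema_version <- "1"

#' @rdname serialization
#' @export
write_sustain_model <- function(model, path) {
  stopifnot(inherits(model, "sustain_model"))
  cfg <- model$config
  doc <- list(schema = "sustainms/model", version = .schema_version,
              biomarkers = cfg$biomarkers,
              thresholds = cfg$thresholds,
              z_max = as.list(cfg$z_max),
              sigma = as.list(cfg$sigma),
              n_subtypes = model$n_subtypes,
              sequences = lapply(model$sequences, as.integer),
              fractions = as.numeric(model$fractions),
              loglik = model$loglik,
              seed = model$seed, restarts = model$restarts)
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' @rdname serialization
#' @export
read_sustain_model <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!identical(doc$schema, "sustainms/model"))
    stop("not a serialized model file", call. = FALSE)
  cfg <- event_config(unlist(doc$biomarkers),
                      thresholds = lapply(doc$thresholds, as.numeric),
                      z_max = unlist(doc$z_max),
                      sigma = unlist(doc$sigma))
  structure(list(config = cfg,
                 sequences = lapply(doc$sequences, as.integer),
                 fractions = as.numeric(doc$fractions),
                 loglik = doc$loglik,
                 n_subtypes = doc$n_subtypes,
                 em_trace = NULL, restarts = doc$restarts,
                 seed = doc$seed),
            class = "sustain_model")
}

#' @rdname serialization
#' @param stats a `reference_stats` object.
#' @export
write_reference_stats <- function(stats, path) {
  stopifnot(inherits(stats, "reference_stats"))
  doc <- list(schema = "sustainms/reference_stats",
              version = .schema_version,
              stats = lapply(seq_len(nrow(stats)), function(i)
                as.list(stats[i, , drop = FALSE])))
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' @rdname serialization
#' @export
read_reference_stats <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!identical(doc$schema, "sustainms/reference_stats"))
    stop("not a serialized reference-stats file", call. = FALSE)
  out <- do.call(rbind, lapply(doc$stats, as.data.frame))
  class(out) <- c("reference_stats", "data.frame")
  out
}

#' @rdname serialization
#' @param hm a `harmonization_model`.
#' @export
write_harmonization <- function(hm, path) {
  stopifnot(inherits(hm, "harmonization_model"))
  doc <- list(schema = "sustainms/harmonization",
              version = .schema_version,
              features = hm$features, batches = hm$batches,
              ref_batch = hm$ref_batch,
              stand_mean = as.list(hm$stand_mean),
              pooled_var = as.list(hm$pooled_var),
              gamma_star = apply(hm$gamma_star, 1L, as.list,
                                 simplify = FALSE),
              delta2_star = apply(hm$delta2_star, 1L, as.list,
                                  simplify = FALSE),
              covariate_names = hm$covariate_names,
              beta = if (is.null(hm$beta)) NULL else
                apply(hm$beta, 1L, as.list, simplify = FALSE),
              eb = hm$eb)
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' @rdname serialization
#' @export
read_harmonization <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!identical(doc$schema, "sustainms/harmonization"))
    stop("not a serialized harmonization file", call. = FALSE)
  feats <- unlist(doc$features)
  batches <- unlist(doc$batches)
  as_mat <- function(x, rn) {
    m <- do.call(rbind, lapply(x, function(r) unlist(r)[feats]))
    rownames(m) <- rn
    m
  }
  beta <- NULL
  if (!is.null(doc$beta))
    beta <- as_mat(doc$beta, unlist(doc$covariate_names))
  structure(list(features = feats, batches = batches,
                 ref_batch = doc$ref_batch,
                 stand_mean = unlist(doc$stand_mean)[feats],
                 pooled_var = unlist(doc$pooled_var)[feats],
                 gamma_star = as_mat(doc$gamma_star, batches),
                 delta2_star = as_mat(doc$delta2_star, batches),
                 beta = beta,
                 covariate_names = if (is.null(doc$covariate_names))
                   NULL else unlist(doc$covariate_names),
                 eb = doc$eb),
            class = "harmonization_model")
}

#' Write and read cohort tables as delimited text
#'
#' @param cohort an `ms_cohort`.
#' @param dir output directory (created if needed); writes `visits.csv`,
#'   `truth.csv` and the generating configuration as `config.yaml`.
#' @rdname serialization
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ms_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$visits, file.path(dir, "visits.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  cfg <- cohort$config
  doc <- list(schema = "sustainms/cohort_config",
              version = .schema_version,
              n_subjects = cfg$n_subjects,
              visit_months = cfg$visit_months,
              biomarkers = cfg$config$biomarkers,
              thresholds = cfg$config$thresholds,
              z_max = as.list(cfg$config$z_max),
              subtype_fractions = cfg$subtype_fractions,
              true_sequences = lapply(cfg$true_sequences, as.integer),
              noise_sd = as.list(cfg$noise_sd),
              edss_link = cfg$edss_link,
              lesion_link = cfg$lesion_link,
              pbvc_link = cfg$pbvc_link,
              progression_rate = cfg$progression_rate,
              treatment_fraction = cfg$treatment_fraction,
              seed = cfg$seed)
  yaml::write_yaml(doc, file.path(dir, "config.yaml"), precision = 15L)
  invisible(dir)
}
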