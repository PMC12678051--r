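test_that("generation is byte-identical under a fixed config and seed", {
  cc <- cohort_config(n_subjects = 40, seed = 60)
  c1 <- generate_cohort(cc)
  c2 <- generate_cohort(cc)
  expect_identical(c1$visits, c2$visits)
  expect_identical(c1$truth, c2$truth)
})

test_that("the reference generator honours its moments and rejects bad configs", {
  ref <- generate_reference_cohort(1000, c(v = 100), c(v = 10), seed = 1)
  expect_lt(abs(mean(ref$v) - 100), 1)
  expect_lt(abs(sd(ref$v) - 10), 0.7)
  expect_identical(ref,
                   generate_reference_cohort(1000, c(v = 100), c(v = 10),
                                             seed = 1))
  expect_error(generate_reference_cohort(1000, c(v = 100), c(v = 0)),
               "positive")
  expect_error(generate_reference_cohort(1, c(v = 100), c(v = 1)),
               "at least 2")
})

test_that("invalid cohort configurations are rejected", {
  expect_error(cohort_config(subtype_fractions = c(0.7, 0.7)), "sum to 1")
  expect_error(cohort_config(visit_months = c(0, 3, 3)), "increasing")
  expect_error(cohort_config(noise_sd = -1), ">= 0")
  cfg <- event_config(ms_biomarker_panel())
  expect_error(cohort_config(true_sequences =
                               list(default_true_sequences(cfg)[[1]])),
               "one true sequence per subtype")
})

test_that("subtype prevalences respect binomial sampling bounds", {
  cc <- cohort_config(n_subjects = 400, subtype_fractions = c(0.5, 0.5),
                      visit_months = 0, seed = 61)
  coh <- generate_cohort(cc)
  n1 <- sum(coh$truth$subtype == 1)
  bounds <- qbinom(c(0.005, 0.995), 400, 0.5)
  expect_gte(n1, bounds[1])
  expect_lte(n1, bounds[2])
})

test_that("noiseless cohorts sit exactly on the planted trajectories", {
  cfg <- event_config(ms_biomarker_panel())
  N <- cfg$n_events
  # all subjects at stage 0, no progression, no noise -> all z are 0
  cc0 <- cohort_config(n_subjects = 20, noise_sd = 0,
                       stage_distribution = c(1, rep(0, N)),
                       progression_rate = c(0, 0), seed = 62)
  v0 <- generate_cohort(cc0)$visits
  expect_true(all(as.matrix(v0[, ms_biomarker_panel()]) == 0))
  # all subjects at the final stage -> values at the trajectory endpoint
  ccN <- cohort_config(n_subjects = 10, noise_sd = 0,
                       stage_distribution = c(rep(0, N), 1),
                       progression_rate = c(0, 0), seed = 63)
  cohN <- generate_cohort(ccN)
  for (i in seq_len(10)) {
    st <- cohN$truth$subtype[cohN$truth$subject ==
                               cohN$visits$subject[i * 6]][1]
    E <- expected_matrix(ccN$true_sequences[[st]], cfg)
    row <- as.numeric(cohN$visits[i * 6, ms_biomarker_panel()])
    expect_equal(row, unname(E[, N + 1]))
    # biomarkers whose last event precedes stage N are at their ceiling
    pos <- order(ccN$true_sequences[[st]])
    last_pos <- tapply(pos, cfg$events$biomarker, max)
    at_ceiling <- names(last_pos)[last_pos < N]
    expect_equal(unname(E[at_ceiling, N + 1]),
                 unname(cfg$z_max[at_ceiling]))
  }
})

test_that("noiseless visits staged with the true model recover true stages", {
  cc <- cohort_config(n_subjects = 30, noise_sd = 0, seed = 64)
  coh <- generate_cohort(cc)
  model <- list(config = cc$config, sequences = cc$true_sequences,
                fractions = cc$subtype_fractions)
  post <- sustain_assign(coh$visits, model)
  expect_identical(post$ml_stage, coh$truth$true_stage)
})

test_that("stages never regress and subtypes are fixed within subject", {
  cc <- cohort_config(n_subjects = 80, seed = 65)
  truth <- generate_cohort(cc)$truth
  for (d in split(truth, truth$subject)) {
    expect_true(all(diff(d$true_stage[order(d$month)]) >= 0))
    expect_identical(length(unique(d$subtype)), 1L)
  }
})

test_that("the baseline stage histogram matches the target distribution", {
  cc <- cohort_config(n_subjects = 5000, visit_months = 0, seed = 66)
  truth <- generate_cohort(cc)$truth
  obs <- tabulate(truth$true_stage + 1L, nbins = 19)
  gof <- chisq.test(obs, p = cc$stage_distribution)
  expect_gt(gof$p.value, 0.01)
})

test_that("batch effects shift and scale the recorded biomarkers", {
  be <- list(labels = c("A", "B"), probs = c(0.5, 0.5),
             shift = rbind(rep(0, 6), rep(2, 6)),
             scale = rbind(rep(1, 6), rep(1, 6)))
  cc <- cohort_config(n_subjects = 300, visit_months = 0,
                      batch_effects = be, seed = 67)
  coh <- generate_cohort(cc)
  v <- coh$visits
  gap <- mean(as.matrix(v[v$batch == "B", ms_biomarker_panel()])) -
    mean(as.matrix(v[v$batch == "A", ms_biomarker_panel()]))
  expect_equal(gap, 2, tolerance = 0.25)
})

test_that("EDSS stays on the half-point grid and tracks stage", {
  cc <- cohort_config(n_subjects = 300, visit_months = 0, seed = 68)
  coh <- generate_cohort(cc)
  e <- coh$visits$edss
  expect_true(all(e >= 0 & e <= 10))
  expect_true(all(abs(e * 2 - round(e * 2)) < 1e-12))
  rho <- cor(coh$truth$true_stage, e, method = "spearman")
  expect_gt(rho, 0.25)  # moderate stage-disability link by design
})

test_that("null survival hazards produce exchangeable subtype curves", {
  cc <- cohort_config(n_subjects = 200, visit_months = c(0, 3, 6, 12),
                      seed = 69)
  coh <- generate_cohort(cc)
  pvals <- vapply(1:20, function(r) {
    sv <- generate_survival_truth(coh, hazard_ratio_subtype = 1,
                                  hazard_ratio_treatment = 1, seed = r)
    survival::survdiff(survival::Surv(time, event) ~ subtype,
                       data = sv)$pvalue
  }, numeric(1))
  expect_lte(mean(pvals < 0.05), 0.25)
  # degenerate: hazards so small that nothing is observed
  sv0 <- generate_survival_truth(coh, base_hazard = 1e-9, seed = 1)
  expect_true(all(sv0$event == 0))
  expect_true(all(sv0$time == 12))
})

test_that("cohort tables round-trip through delimited text", {
  cc <- cohort_config(n_subjects = 10, seed = 70)
  coh <- generate_cohort(cc)
  dir <- tempfile()
  write_cohort(coh, dir)
  v <- read.csv(file.path(dir, "visits.csv"))
  expect_equal(nrow(v), nrow(coh$visits))
  expect_equal(v$snfl, coh$visits$snfl, tolerance = 1e-12)
})
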