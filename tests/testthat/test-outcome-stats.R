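test_that("Spearman correlation is rank-invariant and matches a manual midrank computation", {
  x <- c(1, 4, 2, 8, 5, 7)
  expect_equal(spearman_with_p(x, x)$rho, 1)
  expect_identical(spearman_with_p(x, x)$label, "very strong")
  expect_equal(spearman_with_p(x, x^3)$rho, 1)  # monotone transform
  # tied fixture vs the Pearson correlation of midranks
  y <- c(2, 2, 5, 9, 5, 1)
  res <- spearman_with_p(x, y)
  expect_equal(res$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
  expect_identical(res$n, 6L)
  expect_error(spearman_with_p(c(1, 1, 1, 1), 1:4), "constant")
  expect_error(spearman_with_p(1:3, 1:3), "at least 4")
})

test_that("strength labels partition the magnitude axis exactly", {
  expect_identical(correlation_strength(0.05), "negligible")
  expect_identical(correlation_strength(0.10), "weak")
  expect_identical(correlation_strength(-0.39), "weak")
  expect_identical(correlation_strength(0.40), "moderate")
  expect_identical(correlation_strength(0.69), "moderate")
  expect_identical(correlation_strength(0.70), "strong")
  expect_identical(correlation_strength(-0.89), "strong")
  expect_identical(correlation_strength(0.90), "very strong")
  expect_identical(correlation_strength(1.00), "very strong")
  expect_error(correlation_strength(1.2), "rho")
})

test_that("Fisher z comparison matches its closed form and is antisymmetric", {
  expect_equal(fisher_z_compare(0.3, 50, 0.3, 80)$z, 0)
  expect_equal(fisher_z_compare(0.3, 50, 0.3, 80)$p, 1)
  got <- fisher_z_compare(0.5, 103, 0, 103)
  expect_equal(got$z, atanh(0.5) / sqrt(2 / 100), tolerance = 1e-12)
  swapped <- fisher_z_compare(0, 103, 0.5, 103)
  expect_equal(swapped$z, -got$z, tolerance = 1e-12)
  expect_equal(swapped$p, got$p, tolerance = 1e-12)
  expect_error(fisher_z_compare(0.5, 3, 0.2, 50), "exceed 3")
  expect_error(fisher_z_compare(1, 50, 0.2, 50), "< 1")
})

test_that("mixed slopes recover a deterministic trend exactly and ignore row order", {
  subj <- rep(sprintf("p%02d", 1:20), each = 4)
  month <- rep(c(0, 6, 12, 24), 20)
  offs <- rep(rnorm(20), each = 4)
  d <- data.frame(subject = subj, month = month, subtype = 1L,
                  y = 0.5 * month / 12 + offs)
  res <- mixed_slope(d, "y")
  expect_equal(res$beta, 0.5, tolerance = 1e-6)
  expect_lt(res$ci_hi - res$ci_lo, 1e-4)
  set.seed(50)
  res2 <- mixed_slope(d[sample(nrow(d)), ], "y")
  expect_equal(res2$beta, res$beta, tolerance = 1e-10)
})

test_that("without between-subject variance the mixed slope reduces to OLS", {
  set.seed(51)
  d <- data.frame(subject = rep(sprintf("p%02d", 1:30), each = 3),
                  month = rep(c(0, 6, 12), 30), subtype = 1L)
  d$y <- -0.8 * d$month / 12 + rnorm(nrow(d), 0, 0.4)
  res <- mixed_slope(d, "y")
  ols <- unname(coef(lm(y ~ I(month / 12), data = d))[2])
  expect_equal(res$beta, ols, tolerance = 1e-6)
})

test_that("groups without repeated measures are flagged non-estimable", {
  d <- data.frame(subject = c("a", "b", "c"), month = c(0, 0, 0),
                  subtype = 1L, y = 1:3)
  res <- mixed_slope(d, "y")
  expect_true(is.na(res$beta))
  expect_match(res$note, "non-estimable")
})

test_that("new-lesion event times follow the first-increase rule", {
  mk <- function(counts, months = c(0, 3, 6))
    data.frame(subject = "s", month = months, gad_count = counts)
  expect_equal(time_to_new_lesion(mk(c(2, 2, 2)))[, c("time", "event")],
               data.frame(time = 6, event = 0L))
  expect_equal(time_to_new_lesion(mk(c(0, 1, 0)))[, c("time", "event")],
               data.frame(time = 3, event = 1L))
  # a drop then a rise: the event is the increase at month 6
  expect_equal(time_to_new_lesion(mk(c(3, 1, 2)))[, c("time", "event")],
               data.frame(time = 6, event = 1L))
  expect_warning(res <- time_to_new_lesion(mk(2, months = 0)),
                 "only a baseline")
  expect_equal(res$time, 0)
  # inserting a no-change visit does not move the event
  with_extra <- time_to_new_lesion(mk(c(3, 1, 1, 2),
                                      months = c(0, 3, 4, 6)))
  expect_equal(with_extra[, c("time", "event")],
               data.frame(time = 6, event = 1L))
})

test_that("Cox fits match a hand partial-likelihood oracle and its invariances", {
  surv <- data.frame(time = c(1, 2, 3, 4, 5, 6),
                     event = c(1, 1, 0, 1, 1, 0),
                     x = c(1, 0, 1, 0, 1, 0))
  fit <- cox_fit(surv, covariates = "x")
  beta_hat <- log(fit$table$hr)
  oracle <- optimize(function(b)
    -oracle_cox_loglik(b, surv$time, surv$event, surv$x),
    c(-5, 5))$minimum
  expect_equal(beta_hat, oracle, tolerance = 1e-4)
  # doubling all times leaves the partial likelihood unchanged
  surv2 <- transform(surv, time = 2 * time)
  expect_equal(cox_fit(surv2, covariates = "x")$table$hr,
               fit$table$hr, tolerance = 1e-10)
  # identical event patterns in both groups give HR = 1
  same <- data.frame(time = rep(c(1, 2, 3), 2),
                     event = rep(c(1, 1, 0), 2),
                     x = rep(c(0, 1), each = 3))
  expect_equal(cox_fit(same, covariates = "x")$table$hr, 1,
               tolerance = 1e-8)
  expect_error(cox_fit(transform(surv, event = 0), covariates = "x"),
               "no events")
  expect_error(cox_fit(transform(surv, x = 1), covariates = "x"),
               "constant")
})

test_that("Kaplan-Meier estimates match the hand product-limit computation", {
  surv <- data.frame(time = c(1, 1.5, 2, 3),
                     event = c(1, 0, 1, 0),
                     subtype = 1L)
  km <- km_curve(surv)
  # t=1: 4 at risk, 1 event -> 3/4 ; t=2: 2 at risk, 1 event -> 0.375
  expect_equal(km$surv[km$time == 1], 0.75)
  expect_equal(km$surv[km$time == 2], 0.375)
  # no events: survival stays at 1
  none <- transform(surv, event = 0)
  expect_true(all(km_curve(none)$surv == 1))
  # all events at one time: single step to 0
  all1 <- data.frame(time = rep(2, 3), event = 1, subtype = 1L)
  expect_equal(km_curve(all1)$surv, 0)
})

test_that("PBVC contrasts annualize by the actual interval and handle identical groups", {
  d <- data.frame(pbvc = c(-1, -1), years = c(2, 2),
                  subtype = c(1, 2))
  res <- pbvc_contrast(d)
  expect_equal(res$groups$mean, c(-0.5, -0.5))
  expect_equal(res$tests$t, 0)
  expect_equal(res$tests$p, 1)
  # identical non-constant groups: t = 0, p = 1
  d2 <- data.frame(pbvc = c(-1, -2, -1, -2), years = 1,
                   subtype = rep(1:2, each = 2))
  res2 <- pbvc_contrast(d2)
  expect_equal(res2$tests$t, 0)
  expect_equal(res2$tests$p, 1)
  # zero intervals are excluded
  d3 <- rbind(d2, data.frame(pbvc = -9, years = 0, subtype = 1))
  expect_message(res3 <- pbvc_contrast(d3), "excluded")
  expect_equal(res3$groups$n, c(2L, 2L))
})

test_that("control-arm records are truncated at the crossover month", {
  v <- data.frame(subject = rep(c("a", "b"), each = 3),
                  month = rep(c(0, 24, 36), 2),
                  arm = rep(c("control", "treatment"), each = 3))
  out <- truncate_control_crossover(v)
  expect_equal(nrow(out), 5L)
  expect_false(any(out$arm == "control" & out$month > 24))
})
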