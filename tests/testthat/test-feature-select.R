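test_that("EDSS-correlation ranking puts perfect correlates first", {
  set.seed(30)
  edss <- sample(seq(0, 6, 0.5), 50, replace = TRUE)
  feats <- data.frame(same = edss,
                      anti = -edss,
                      noise = rnorm(50))
  rk <- rank_by_edss_correlation(feats, edss, k = 3)
  # both perfect correlates share |rho| = 1; alphabetical tie-break
  expect_equal(rk$feature[1:2], c("anti", "same"))
  expect_equal(abs(rk$rho[1:2]), c(1, 1))
  expect_identical(rk$feature[3], "noise")
})

test_that("constant features are excluded with a warning", {
  edss <- c(1, 2, 3, 4, 5)
  feats <- data.frame(flat = rep(2, 5), ok = c(5, 4, 3, 2, 1))
  expect_warning(rk <- rank_by_edss_correlation(feats, edss, k = 5),
                 "constant")
  expect_identical(rk$feature, "ok")
})

test_that("a target equal to the start size is an identity trace", {
  set.seed(31)
  z <- as.data.frame(matrix(rnorm(40 * 3), ncol = 3))
  names(z) <- c("a", "b", "c")
  tr <- recursive_eliminate(z, rnorm(40), start = names(z), target = 3,
                            restarts = 2, seed = 1)
  expect_identical(nrow(tr$rounds), 0L)
  expect_identical(tr$final, c("a", "b", "c"))
})

test_that("an exact duplicate is eliminated first", {
  cfg <- event_config(c("u", "v", "w"), thresholds = c(1, 2), z_max = 4)
  set.seed(32)
  truth <- random_sequence(cfg)
  d <- draw_on_trajectory(truth, cfg, 90, 0.7, seed = 5)
  z <- as.data.frame(d$z)
  edss <- pmin(10, pmax(0, round((1 + 0.4 * d$stages +
                                    rnorm(90, 0, 0.8)) * 2) / 2))
  z$u_copy <- z$u  # exact duplicate carries no information
  tr <- recursive_eliminate(z, edss, start = names(z), target = 3,
                            restarts = 3, seed = 2)
  expect_true(tr$rounds$removed[1] %in% c("u", "u_copy"))
  expect_false(all(c("u", "u_copy") %in% tr$final))
})

test_that("stage-driving features outrank and outlive pure-noise decoys", {
  cfg <- event_config(c("s1", "s2", "s3"), thresholds = c(1, 2), z_max = 4)
  keep_signal <- c("s1", "s2", "s3")
  hits_rank <- 0; hits_rfe <- 0
  for (rep in 1:3) {
    set.seed(100 + rep)
    truth <- random_sequence(cfg)
    d <- draw_on_trajectory(truth, cfg, 120, 0.8, seed = 200 + rep)
    z <- as.data.frame(d$z)
    z$n1 <- rnorm(120); z$n2 <- rnorm(120)
    edss <- pmin(10, pmax(0, round((1 + 0.5 * d$stages +
                                      rnorm(120)) * 2) / 2))
    rk <- rank_by_edss_correlation(z, edss, k = 3)
    hits_rank <- hits_rank + sum(rk$feature %in% keep_signal)
    tr <- recursive_eliminate(z, edss, start = names(z), target = 3,
                              restarts = 3, seed = 300 + rep)
    hits_rfe <- hits_rfe + sum(tr$final %in% keep_signal)
  }
  expect_gte(hits_rank, 8)  # >= 8/9 ranked slots are signal features
  expect_gte(hits_rfe, 7)   # >= 7/9 surviving features are signal
})

test_that("selection traces are deterministic and reproducible from logged seeds", {
  cfg <- event_config(c("p", "q"), thresholds = c(1, 2), z_max = 4)
  set.seed(33)
  d <- draw_on_trajectory(random_sequence(cfg), cfg, 60, 1, seed = 6)
  z <- as.data.frame(d$z)
  z$junk <- rnorm(60)
  edss <- d$stages * 0.3 + rnorm(60, 0, 0.5)
  tr1 <- recursive_eliminate(z, edss, start = names(z), target = 2,
                             restarts = 2, seed = 9)
  tr2 <- recursive_eliminate(z, edss, start = names(z), target = 2,
                             restarts = 2, seed = 9)
  expect_identical(tr1$rounds, tr2$rounds)
  expect_identical(tr1$final, tr2$final)
  # the logged objective is the stage-EDSS rank correlation of a refit
  # with the logged seed
  kept <- setdiff(sort(names(z)), tr1$rounds$removed[1])
  rho <- sustainms:::.stage_edss_rho(z, edss, kept, c(1, 2, 3), 5,
                                     restarts = 2,
                                     seed = tr1$rounds$seed[1])
  expect_equal(rho, tr1$rounds$rho[1])
})
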