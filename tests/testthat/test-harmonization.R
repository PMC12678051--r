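test_that("a single batch yields an identity transform with a warning", {
  set.seed(20)
  z <- data.frame(f1 = rnorm(30), f2 = rnorm(30))
  expect_warning(hm <- fit_harmonization(z, rep("A", 30)), "single batch")
  adj <- apply_harmonization(z, hm, rep("A", 30))
  expect_equal(adj, z, tolerance = 1e-12)
})

test_that("a pure location shift is removed exactly without shrinkage", {
  set.seed(21)
  base <- matrix(rnorm(800 * 4), ncol = 4)
  colnames(base) <- paste0("f", 1:4)
  delta <- c(2, -1.5, 0.8, 3)
  z <- as.data.frame(rbind(base[1:400, ],
                           sweep(base[401:800, ], 2, delta, `+`)))
  batch <- rep(c("train", "test"), each = 400)
  hm <- fit_harmonization(z, batch, ref_batch = "train", eb = FALSE)
  adj <- apply_harmonization(z, hm, batch)
  gap <- colMeans(adj[batch == "test", ]) - colMeans(adj[batch == "train", ])
  expect_true(all(abs(gap) < 1e-6 * abs(delta)))
  # training (reference) rows are untouched
  expect_equal(adj[batch == "train", ], z[batch == "train", ],
               tolerance = 1e-12)
})

test_that("a planted scale ratio is equalized within tolerance", {
  set.seed(22)
  base <- matrix(rnorm(1000 * 4), ncol = 4)
  colnames(base) <- paste0("f", 1:4)
  z <- as.data.frame(rbind(base[1:500, ], 2 * base[501:1000, ]))
  batch <- rep(c("train", "test"), each = 500)
  hm <- fit_harmonization(z, batch, ref_batch = "train")
  adj <- apply_harmonization(z, hm, batch)
  vr <- apply(adj[batch == "test", ], 2, var) /
    apply(adj[batch == "train", ], 2, var)
  expect_true(all(vr > 0.9 & vr < 1.1))
})

test_that("the empirical-Bayes adjustment matches the reference ComBat implementation", {
  library(sva)
  set.seed(23)
  n <- 150
  z <- as.data.frame(matrix(rnorm(n * 5), ncol = 5))
  names(z) <- paste0("f", 1:5)
  batch <- rep(c("train", "testA"), times = c(90, 60))
  idx <- batch == "testA"
  z[idx, ] <- sweep(sweep(as.matrix(z[idx, ]), 2,
                          c(1.4, 0.7, 1.1, 2, 0.9), `*`),
                    2, c(0.5, -0.3, 0, 1.2, -0.8), `+`)
  hm <- fit_harmonization(z, batch, ref_batch = "train")
  adj <- apply_harmonization(z, hm, batch)
  ref <- t(sva::ComBat(t(as.matrix(z)), batch = batch,
                       ref.batch = "train"))
  expect_equal(as.matrix(adj), ref, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("unknown batches error unless mapped to the reference", {
  set.seed(24)
  z <- data.frame(f1 = rnorm(40), f2 = rnorm(40))
  batch <- rep(c("A", "B"), each = 20)
  hm <- fit_harmonization(z, batch, ref_batch = "A")
  expect_error(apply_harmonization(z[1:3, ], hm, rep("C", 3)),
               "unknown batch")
  adj <- apply_harmonization(z[1:3, ], hm, rep("C", 3),
                             unknown_as_reference = TRUE)
  expect_equal(adj, z[1:3, ], tolerance = 1e-12)
  # batches need enough rows to estimate location and scale
  expect_error(fit_harmonization(z[c(1:20, 21:22), ],
                                 c(rep("A", 20), "B", "B")),
               "insufficient batch")
})

test_that("preserved covariate effects survive harmonization", {
  set.seed(25)
  n <- 600
  age <- runif(n, 20, 60)
  batch <- rep(c("train", "test"), each = n / 2)
  f1 <- 0.05 * age + rnorm(n) + ifelse(batch == "test", 1.5, 0)
  f2 <- -0.03 * age + rnorm(n) + ifelse(batch == "test", -0.7, 0)
  z <- data.frame(f1, f2)
  hm <- fit_harmonization(z, batch, covariates = data.frame(age = age),
                          ref_batch = "train")
  adj <- apply_harmonization(z, hm, batch,
                             covariates = data.frame(age = age))
  # batch means equalized...
  gap <- colMeans(adj[batch == "test", ]) -
    colMeans(adj[batch == "train", ])
  expect_true(all(abs(gap) < 0.2))
  # ...while the age slopes stay at their planted values
  expect_lt(abs(coef(lm(adj$f1 ~ age))[2] - 0.05), 0.01)
  expect_lt(abs(coef(lm(adj$f2 ~ age))[2] + 0.03), 0.01)
})

test_that("harmonization models round-trip through structured text", {
  set.seed(26)
  z <- data.frame(f1 = rnorm(60), f2 = rnorm(60))
  batch <- rep(c("A", "B"), each = 30)
  z[batch == "B", ] <- z[batch == "B", ] + 1
  hm <- fit_harmonization(z, batch)
  path <- tempfile(fileext = ".yaml")
  write_harmonization(hm, path)
  hm2 <- read_harmonization(path)
  expect_equal(apply_harmonization(z, hm2, batch),
               apply_harmonization(z, hm, batch), tolerance = 1e-12)
})
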