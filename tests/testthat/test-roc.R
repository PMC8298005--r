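test_that("hand examples and degenerate limits are exact", {
  r <- roc_auc(c(0.9, 0.7, 0.8, 0.3, 0.1), c(1, 1, 0, 0, 0))
  expect_equal(r$auc, 5 / 6, tolerance = 1e-12)

  expect_equal(roc_auc(rep(0.4, 10), rep(c(1, 0), 5))$auc, 0.5)

  sep <- roc_auc(c(5, 6, 1, 2), c(1, 1, 0, 0))
  expect_equal(sep$auc, 1)
  expect_equal(sep$se, 0)
  expect_equal(c(sep$ci_low, sep$ci_high), c(1, 1))
})

test_that("AUC equals brute-force pairwise counting on random instances", {
  set.seed(3)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    lab <- c(1, 0, rbinom(n - 2, 1, 0.4))
    sc <- round(rnorm(n), sample(0:2, 1)) # induce ties sometimes
    expect_identical(roc_auc(sc, lab)$auc, oracle_auc(sc, lab))
  }
})

test_that("negating scores complements the AUC (no ties)", {
  set.seed(4)
  lab <- rbinom(60, 1, 0.4)
  lab[1:2] <- c(0, 1)
  sc <- rnorm(60)
  expect_equal(roc_auc(-sc, lab)$auc, 1 - roc_auc(sc, lab)$auc,
               tolerance = 1e-12)
})

test_that("DeLong SE and paired test agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(5)
  lab <- c(rep(1, 30), rep(0, 50))
  s1 <- rnorm(80) + lab
  s2 <- 0.7 * s1 + rnorm(80, sd = 0.5)
  mine <- roc_auc(s1, lab)
  pr <- pROC::roc(lab, s1, quiet = TRUE, direction = "<")
  expect_equal(mine$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  expect_equal(mine$se^2, as.numeric(pROC::var(pr)), tolerance = 1e-9)

  cmp <- compare_paired_auc(s1, s2, lab)
  pt <- pROC::roc.test(pROC::roc(lab, s1, quiet = TRUE, direction = "<"),
                       pROC::roc(lab, s2, quiet = TRUE, direction = "<"),
                       method = "delong", paired = TRUE)
  expect_equal(cmp$p_value, as.numeric(pt$p.value), tolerance = 1e-9)
  expect_equal(cmp$delta_auc,
               abs(as.numeric(pt$estimate[1]) - as.numeric(pt$estimate[2])),
               tolerance = 1e-12)
})

test_that("identical or rank-identical score vectors give delta 0 and p 1", {
  set.seed(6)
  lab <- rbinom(40, 1, 0.5)
  lab[1:2] <- c(0, 1)
  sc <- rnorm(40)
  same <- compare_paired_auc(sc, sc, lab)
  expect_equal(same$delta_auc, 0)
  expect_equal(same$p_value, 1)
  mono <- compare_paired_auc(sc, plogis(2 * sc + 1), lab)
  expect_equal(mono$delta_auc, 0, tolerance = 1e-12)
})

test_that("Hanley-McNeil SE is available and sane", {
  set.seed(7)
  lab <- c(rep(1, 40), rep(0, 60))
  sc <- rnorm(100) + lab
  hm <- roc_auc(sc, lab, se_method = "hanley")
  dl <- roc_auc(sc, lab)
  expect_gt(hm$se, 0)
  expect_lt(abs(hm$se - dl$se) / dl$se, 0.5)
})

test_that("SE shrinks as the sample grows", {
  set.seed(8)
  mean_se <- function(n) {
    mean(replicate(40, {
      lab <- rep(c(1, 0), each = n)
      roc_auc(c(rnorm(n, 1), rnorm(n)), lab)$se
    }))
  }
  expect_lt(mean_se(100), mean_se(50))
})

test_that("DeLong p-values are uniform under the null", {
  set.seed(9)
  pvals <- replicate(500, {
    lab <- rep(c(1, 0), c(40, 60))
    base <- rnorm(100) + 0.8 * lab
    compare_paired_auc(base + rnorm(100, sd = 0.6),
                       base + rnorm(100, sd = 0.6), lab)$p_value
  })
  # discrete AUC differences can tie a few p-values; the KS statistic is
  # still the right summary
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif")$p.value), 0.01)
})

test_that("invalid ROC inputs are rejected", {
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
  expect_error(roc_auc(1:3, c(1, 0)), "length")
  expect_error(compare_paired_auc(1:3, 1:4, c(1, 0, 1)), "length")
})
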