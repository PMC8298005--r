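test_that("fitted priors and smoothed conditionals match hand computation", {
  # 2 malignant all margin=1, 2 benign all margin=0, alpha=1, binary space:
  # P(1|M) = (2+1)/(2+2) = 3/4, P(1|B) = (0+1)/(2+2) = 1/4
  sch <- binary_schema("margin2")
  co <- tiny_cohort(c("malignant", "malignant", "benign", "benign"),
                    list(margin2 = c("1", "1", "0", "0")))
  fit <- fit_bayes(co, schema = sch, alpha = 1)
  expect_equal(fit$prior_malignant, 0.5, tolerance = 1e-12)
  expect_equal(fit$conditional_tables$margin2["malignant", "1"], 3 / 4,
               tolerance = 1e-12)
  expect_equal(fit$conditional_tables$margin2["benign", "1"], 1 / 4,
               tolerance = 1e-12)
  expect_equal(unname(rowSums(fit$conditional_tables$margin2)), c(1, 1),
               tolerance = 1e-12)
})

test_that("the study composition yields prior P(M) = 85/264", {
  co <- generate_cohort(cohort_config(n_lesions = 264, prevalence = 85 / 264,
                                      seed = 1))
  fit <- fit_bayes(co)
  expect_equal(fit$prior_malignant, 85 / 264, tolerance = 1e-12)
  expect_equal(fit$prior_malignant + fit$prior_benign, 1, tolerance = 1e-12)
})

test_that("alpha = 0 reproduces literal count ratios and warns on zero cells", {
  sch <- binary_schema("f")
  co <- tiny_cohort(c("malignant", "malignant", "benign", "benign"),
                    list(f = c("1", "1", "0", "0")))
  expect_warning(fit <- fit_bayes(co, schema = sch, alpha = 0), "saturate")
  expect_identical(fit$conditional_tables$f["malignant", "0"], 0)
  expect_identical(fit$conditional_tables$f["malignant", "1"], 1)
})

test_that("single-class training sets are rejected", {
  sch <- binary_schema("f")
  co <- tiny_cohort(rep("benign", 4), list(f = c("0", "1", "0", "1")))
  expect_error(fit_bayes(co, schema = sch), "degenerate training set")
})

test_that("posterior follows the two-class Bayes rule on a hand example", {
  sch <- binary_schema("margin2")
  co <- tiny_cohort(c("malignant", "malignant", "benign", "benign"),
                    list(margin2 = c("1", "1", "0", "0")))
  fit <- fit_bayes(co, schema = sch, alpha = 1)
  # 0.5 * 0.75 / (0.5 * 0.75 + 0.5 * 0.25) = 0.75
  expect_equal(posterior(fit, list(margin2 = "1"))$probability_malignant,
               0.75, tolerance = 1e-12)
  # no evidence returns the prior
  expect_equal(posterior(fit, list())$probability_malignant,
               fit$prior_malignant, tolerance = 1e-12)
  # two-class normalization is exact
  p1 <- posterior(fit, list(margin2 = "1"))$probability_malignant
  fit_sw <- fit
  fit_sw$prior_malignant <- fit$prior_benign
  fit_sw$prior_benign <- fit$prior_malignant
  fit_sw$conditional_tables$margin2 <-
    fit$conditional_tables$margin2[c("benign", "malignant"), ]
  rownames(fit_sw$conditional_tables$margin2) <- c("malignant", "benign")
  expect_equal(p1 + posterior(fit_sw, list(margin2 = "1"))$probability_malignant,
               1, tolerance = 1e-12)
})

test_that("posterior rejects unknown features and categories by name", {
  co <- generate_cohort(cohort_config(n_lesions = 40, seed = 2))
  fit <- fit_bayes(co)
  expect_error(posterior(fit, list(margin = "fuzzy")), "margin.*fuzzy")
  expect_error(posterior(fit, list(nonfeature = "x")), "nonfeature")
})

test_that("posterior is invariant to feature multiplication order", {
  co <- generate_cohort(cohort_config(n_lesions = 80, seed = 3))
  fit <- fit_bayes(co, alpha = 1)
  fv <- list(shape = "oval", margin = "spiculated", echo_pattern = "hypoechoic")
  expect_equal(posterior(fit, fv)$probability_malignant,
               posterior(fit, rev(fv))$probability_malignant,
               tolerance = 1e-12)
})

test_that("raising P(F=v|M) never decreases the posterior of a case showing v", {
  co <- generate_cohort(cohort_config(n_lesions = 80, seed = 4))
  fit <- fit_bayes(co, alpha = 1)
  fv <- list(margin = "spiculated", echo_pattern = "hypoechoic")
  p0 <- posterior(fit, fv)$probability_malignant
  fit$conditional_tables$margin["malignant", "spiculated"] <-
    min(1, fit$conditional_tables$margin["malignant", "spiculated"] * 1.2)
  expect_gte(posterior(fit, fv)$probability_malignant, p0)
})

test_that("LOOCV reproduces the hand-worked four-case example", {
  # held-out malignant case: fold prior 1/3, P(1|M) = 2/3, P(1|B) = 1/4
  # => posterior = (1/3 * 2/3) / (1/3 * 2/3 + 2/3 * 1/4) = 4/7
  sch <- binary_schema("f")
  co <- tiny_cohort(c("malignant", "malignant", "benign", "benign"),
                    list(f = c("1", "1", "0", "0")))
  p <- loocv_posteriors(co, schema = sch, alpha = 1)
  expect_equal(p$probability_malignant[1], 4 / 7, tolerance = 1e-12)
  expect_identical(p$lesion_id, co$lesion_id)
})

test_that("downdated LOOCV equals naive refitting on every fold", {
  co <- generate_cohort(cohort_config(n_lesions = 30, seed = 5))
  ob <- generate_observation(co, observation_config(fidelity = 0.8, seed = 1))
  sch <- birads_schema()
  for (age in c(FALSE, TRUE)) {
    fast <- loocv_posteriors(co, ob, sch, alpha = 1, include_age = age)
    slow <- naive_loocv(co, ob, sch, alpha = 1, include_age = age)
    expect_equal(fast$probability_malignant, slow, tolerance = 1e-10)
  }
})

test_that("LOOCV respects input order and permutes with it", {
  co <- generate_cohort(cohort_config(n_lesions = 40, seed = 6))
  p <- loocv_posteriors(co, alpha = 1)
  perm <- sample(nrow(co))
  p2 <- loocv_posteriors(co[perm, ], alpha = 1)
  expect_identical(p2$lesion_id, co$lesion_id[perm])
  expect_equal(p2$probability_malignant, p$probability_malignant[perm],
               tolerance = 1e-12)
})

test_that("perfectly separating features give a perfect ranking", {
  sch <- binary_schema("f")
  n <- 264
  lab <- rep(c("malignant", "benign"), c(85, 179))
  co <- tiny_cohort(lab, list(f = ifelse(lab == "malignant", "1", "0")))
  p <- loocv_posteriors(co, schema = sch, alpha = 1)
  r <- roc_auc(p$probability_malignant, p$label)
  expect_equal(r$auc, 1)
})

test_that("LOOCV posteriors converge to full-fit posteriors as the cohort grows", {
  # the gap is dominated by rare categories (e.g. anechoic malignant masses,
  # expected count ~n/200), so the maximum shrinks roughly like 1/n
  gap <- function(n) {
    co <- generate_cohort(cohort_config(n_lesions = n, seed = 7))
    loo <- loocv_posteriors(co, alpha = 1)
    fit <- fit_bayes(co, alpha = 1)
    full <- vapply(seq_len(nrow(co)), function(i) {
      posterior(fit, as.list(as.data.frame(co)[i, names(birads_schema())]))$probability_malignant
    }, numeric(1))
    abs(loo$probability_malignant - full)
  }
  g1000 <- gap(1000)
  g4000 <- gap(4000)
  expect_lt(max(g4000), 0.02)
  expect_lt(max(g4000), max(g1000))
  expect_lt(stats::quantile(g1000, 0.99), 0.02)
})

test_that("LOOCV guards its preconditions", {
  sch <- binary_schema("f")
  expect_error(loocv_posteriors(
    tiny_cohort(c("malignant", "benign"), list(f = c("1", "0"))),
    schema = sch), "at least 3")
  expect_error(loocv_posteriors(
    tiny_cohort(c("malignant", "benign", "benign"), list(f = c("1", "0", "0"))),
    schema = sch), "single-class")
})
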