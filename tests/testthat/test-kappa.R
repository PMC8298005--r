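test_that("hand-computed kappa values are exact", {
  k <- cohen_kappa(c(1, 1, 0, 0), c(1, 0, 0, 0))
  expect_equal(k$p_observed, 0.75, tolerance = 1e-12)
  expect_equal(k$p_expected, 0.5, tolerance = 1e-12)
  expect_equal(k$kappa, 0.5, tolerance = 1e-12)
  expect_identical(k$label, "moderate")
})

test_that("complete agreement gives kappa 1; chance gives kappa near 0", {
  a <- c("a", "b", "c", "a", "b")
  expect_equal(cohen_kappa(a, a)$kappa, 1)
  set.seed(42)
  x <- sample(letters[1:4], 10000, replace = TRUE)
  y <- sample(letters[1:4], 10000, replace = TRUE)
  expect_lt(abs(cohen_kappa(x, y)$kappa), 0.03)
})

test_that("kappa matches an independent confusion-matrix oracle on random instances", {
  skip_if_not_installed("e1071")
  set.seed(1)
  for (i in 1:200) {
    n <- sample(2:30, 1)
    k <- sample(2:5, 1)
    a <- sample(letters[1:k], n, replace = TRUE)
    b <- sample(letters[1:k], n, replace = TRUE)
    mine <- cohen_kappa(a, b)$kappa
    if (is.nan(mine)) next
    expect_equal(mine, oracle_kappa(a, b), tolerance = 1e-12)
    # second, external oracle
    lev <- sort(unique(c(a, b)))
    ext <- e1071::classAgreement(table(factor(a, lev), factor(b, lev)))$kappa
    expect_equal(mine, ext, tolerance = 1e-12)
    expect_gte(mine, -1 - 1e-12)
    expect_lte(mine, 1 + 1e-12)
  }
})

test_that("kappa is symmetric and permutation invariant", {
  set.seed(2)
  a <- sample(letters[1:3], 50, replace = TRUE)
  b <- sample(letters[1:3], 50, replace = TRUE)
  expect_identical(cohen_kappa(a, b)$kappa, cohen_kappa(b, a)$kappa)
  perm <- sample(50)
  expect_equal(cohen_kappa(a[perm], b[perm])$kappa, cohen_kappa(a, b)$kappa,
               tolerance = 1e-15)
})

test_that("degenerate and malformed inputs are handled", {
  expect_error(cohen_kappa(c(1, 2), c(1, 2, 3)), "length")
  expect_error(cohen_kappa(character(0), character(0)), "empty")
  # both raters constant and equal: p_e = 1, complete agreement
  k <- cohen_kappa(c("a", "a"), c("a", "a"))
  expect_identical(k$kappa, 1)
})

test_that("pooled kappa reproduces a hand-built two-feature example", {
  # feature fA: agree on 1 of 2 items, p_e = 0.5; feature fB: identical,
  # p_e = 0.5; pooled p_o = 0.75, pooled p_e = 0.5 => kappa = 0.5
  sch <- two_feature_schema()
  oa <- data.frame(lesion_id = c("L1", "L2"), fA = c("1", "1"), fB = c("0", "1"),
                   stringsAsFactors = FALSE)
  ob <- data.frame(lesion_id = c("L1", "L2"), fA = c("1", "0"), fB = c("0", "1"),
                   stringsAsFactors = FALSE)
  ov <- overall_kappa(oa, ob, sch)
  expect_equal(ov$p_observed, 0.75, tolerance = 1e-12)
  expect_equal(ov$p_expected, 0.5, tolerance = 1e-12)
  expect_equal(ov$kappa, 0.5, tolerance = 1e-12)
})

test_that("pooled kappa is 1 for identical observations and reduces to Cohen's kappa for one feature", {
  co <- generate_cohort(cohort_config(n_lesions = 30, seed = 5))
  ob <- generate_observation(co, observation_config(fidelity = 0.7, seed = 1))
  expect_equal(overall_kappa(ob, ob)$kappa, 1)

  sch1 <- structure(list(margin = birads_schema()$margin),
                    class = "birads_schema")
  ob2 <- generate_observation(co, observation_config(fidelity = 0.7, seed = 2))
  expect_equal(overall_kappa(ob, ob2, sch1)$kappa,
               cohen_kappa(ob$margin, ob2$margin,
                           categories = sch1$margin)$kappa,
               tolerance = 1e-12)
})

test_that("mean-of-features pooling is exposed as an option", {
  co <- generate_cohort(cohort_config(n_lesions = 50, seed = 6))
  oa <- generate_observation(co, observation_config(fidelity = 0.6, seed = 3))
  ob <- generate_observation(co, observation_config(fidelity = 0.6, seed = 4))
  mv <- overall_kappa(oa, ob, method = "mean")
  per <- vapply(mv$per_feature, function(k) k$kappa, numeric(1))
  expect_equal(mv$kappa, mean(per), tolerance = 1e-12)
})

test_that("observation sets over different lesions are rejected", {
  co <- generate_cohort(cohort_config(n_lesions = 10, seed = 7))
  oa <- generate_observation(co, observation_config(fidelity = 1, seed = 1))
  ob <- oa
  ob$lesion_id[1] <- "Lxxx"
  expect_error(overall_kappa(oa, ob), "lesion_id")
})

test_that("Landis-Koch labels follow the five-scale system with gap closure", {
  expect_identical(landis_koch_label(0.77), "substantial")
  expect_identical(landis_koch_label(0.56), "moderate")
  expect_identical(landis_koch_label(0.95), "almost perfect")
  expect_identical(landis_koch_label(0.30), "fair")
  expect_identical(landis_koch_label(0.005), "slight")
  expect_identical(landis_koch_label(0), "poor (chance or worse)")
  expect_identical(landis_koch_label(-0.2), "poor (chance or worse)")
  expect_identical(landis_koch_label(1), "almost perfect")
  expect_error(landis_koch_label(1.1), "exceed")
})

test_that("agreement_table has the feature rows, overall row and pair columns", {
  co <- generate_cohort(cohort_config(n_lesions = 40, seed = 8))
  obs <- list(
    o1 = generate_observation(co, observation_config(0.9, seed = 1)),
    o2 = generate_observation(co, observation_config(0.9, seed = 2)),
    o3 = generate_observation(co, observation_config(0.9, seed = 3))
  )
  tab <- agreement_table(obs)
  expect_identical(tab$feature, c(names(birads_schema()), "overall"))
  expect_true(all(c("kappa_o1_vs_o2", "kappa_o2_vs_o3", "kappa_o1_vs_o3")
                  %in% names(tab)))
  expect_true(all(c("label_o1_vs_o2") %in% names(tab)))
})
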