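# Independent oracle implementations and small fixture builders.
# These deliberately re-derive each statistic by a different route than the
# package (brute-force enumeration, confusion-matrix arithmetic, naive
# refitting) so agreement is evidence, not tautology.

# AUC by brute-force enumeration of all positive-negative pairs, ties at 1/2
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1 | labels == TRUE | labels == "malignant"]
  neg <- scores[!(labels == 1 | labels == TRUE | labels == "malignant")]
  total <- 0
  for (x in pos) for (y in neg) {
    total <- total + (x > y) + 0.5 * (x == y)
  }
  total / (length(pos) * length(neg))
}

# Cohen's kappa from an explicit confusion matrix
oracle_kappa <- function(a, b) {
  lev <- sort(unique(c(a, b)))
  cm <- table(factor(a, lev), factor(b, lev))
  n <- sum(cm)
  p_o <- sum(diag(cm)) / n
  p_e <- sum(rowSums(cm) * colSums(cm)) / n^2
  (p_o - p_e) / (1 - p_e)
}

# single binary-feature schema for hand-computable Bayes examples
binary_schema <- function(feature = "f") {
  structure(stats::setNames(list(c("0", "1")), feature),
            class = "birads_schema")
}

two_feature_schema <- function() {
  structure(list(fA = c("0", "1"), fB = c("0", "1")),
            class = "birads_schema")
}

tiny_cohort <- function(labels, features, ages = NULL) {
  n <- length(labels)
  df <- data.frame(
    lesion_id = sprintf("L%02d", seq_len(n)),
    label = labels,
    age = if (is.null(ages)) rep(50, n) else ages,
    stringsAsFactors = FALSE
  )
  for (f in names(features)) df[[f]] <- as.character(features[[f]])
  df
}

# LOOCV by literally refitting on every fold via fit_bayes()/posterior()
naive_loocv <- function(cohort, observation = NULL, schema, alpha = 1,
                        include_age = FALSE) {
  feats <- if (is.null(observation)) {
    as.data.frame(cohort)[, names(schema), drop = FALSE]
  } else {
    obs <- observation[match(cohort$lesion_id, observation$lesion_id), ]
    as.data.frame(obs)[, names(schema), drop = FALSE]
  }
  sapply(seq_len(nrow(cohort)), function(i) {
    train <- cohort[-i, ]
    train_obs <- if (is.null(observation)) NULL else {
      observation[observation$lesion_id != cohort$lesion_id[i], ]
    }
    fit <- fit_bayes(train, train_obs, schema, alpha = alpha,
                     include_age = include_age)
    fv <- as.list(feats[i, , drop = FALSE])
    posterior(fit, fv,
              age = if (include_age) cohort$age[i] else NULL)$probability_malignant
  })
}

# 12 x 3 repeated-probability fixture with reference ICCs computed by an
# independent ANOVA implementation (Python pingouin 0.6.1):
#   ICC(A,1) = 0.893738389708, 95% CI [0.73, 0.97] (2 dp)
#   ICC(C,1) = 0.916330249712, 95% CI [0.80, 0.97] (2 dp)
icc_fixture <- function() {
  matrix(c(
    0.5662258718, 0.6811227125, 0.5783441633,
    0.2232597817, 0.3515032415, 0.1952925707,
    0.7203662633, 0.6760961663, 0.6153012501,
    0.6336385797, 0.8159162504, 0.6557505847,
    0.0755267365, 0.1116222782, 0.1323776971,
    0.2687996238, 0.3025827076, 0.2540297789,
    0.6968998887, 0.5230548793, 0.4645886623,
    0.3716496633, 0.5160298353, 0.5070692649,
    0.4875239719, 0.4594272503, 0.4106812712,
    0.3814386375, 0.4188515482, 0.3528435559,
    0.6226388184, 0.7244525008, 0.6652144597,
    0.6730534748, 0.7552726893, 0.6534460310
  ), ncol = 3, byrow = TRUE)
}

small_experiment_config <- function(n = 60, master_seed = 11) {
  experiment_config(cohort = cohort_config(n_lesions = n),
                    master_seed = master_seed)
}
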