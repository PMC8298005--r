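# naive-Bayes probability of malignancy from categorical BI-RADS features,
# optionally with a class-conditional normal age term

# resolve the feature source: the cohort's latent columns, or an observation
# joined by lesion_id
resolve_features <- function(cohort, observation, schema) {
  if (is.null(observation)) {
    return(as.data.frame(cohort)[, names(schema), drop = FALSE])
  }
  if (!setequal(observation$lesion_id, cohort$lesion_id)) {
    stop("observation covers a different lesion_id set than the cohort",
         call. = FALSE)
  }
  obs <- observation[match(cohort$lesion_id, observation$lesion_id), ]
  as.data.frame(obs)[, names(schema), drop = FALSE]
}

#' Fit the Bayes probability-of-malignancy model
#'
#' Prior: `P(M) = n_malignant / n`. Class-conditional category
#' probabilities: Laplace-smoothed count ratios
#' `(count + alpha) / (n_class + alpha * K)` for a feature with `K`
#' categories (`alpha = 0` reproduces plain count ratios, which can yield
#' zero probabilities for categories unseen in a class). With
#' `include_age = TRUE` the per-class sample mean and standard deviation of
#' age are stored and age enters prediction as one extra class-conditional
#' normal factor.
#'
#' @param cohort Cohort data frame supplying `label` (and `age`).
#' @param observation Optional observation data frame; if supplied, its
#'   ratings (joined by `lesion_id`) are used as the feature source instead
#'   of the cohort's latent features — this is what "retraining on the
#'   observed features" means.
#' @param schema A [birads_schema()].
#' @param alpha Additive smoothing constant (default 1).
#' @param include_age Add the age term?
#' @return An object of class `bayes_cad`.
#' @export
#' @examples
#' co <- generate_cohort(cohort_config(n_lesions = 60, seed = 3))
#' fit <- fit_bayes(co, alpha = 1)
#' fit$prior_malignant
fit_bayes <- function(cohort, observation = NULL, schema = birads_schema(),
                      alpha = 1, include_age = FALSE) {
  validate_schema(schema)
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha >= 0)
  y <- cohort$label
  if (length(unique(y)) < 2) stop("degenerate training set", call. = FALSE)
  feats <- resolve_features(cohort, observation, schema)
  n <- nrow(cohort)
  n_mal <- sum(y == "malignant")
  tables <- lapply(names(schema), function(f) {
    cats <- schema[[f]]
    K <- length(cats)
    cnt_m <- tabulate(factor(feats[[f]][y == "malignant"], levels = cats), K)
    cnt_b <- tabulate(factor(feats[[f]][y == "benign"], levels = cats), K)
    m <- rbind(malignant = (cnt_m + alpha) / (n_mal + alpha * K),
               benign    = (cnt_b + alpha) / ((n - n_mal) + alpha * K))
    colnames(m) <- cats
    m
  })
  names(tables) <- names(schema)
  if (alpha == 0 && any(vapply(tables, function(m) any(m == 0), logical(1)))) {
    warning("alpha = 0 with categories unseen in a class: some conditional ",
            "probabilities are exactly 0 and posteriors may saturate")
  }
  age_model <- NULL
  if (include_age) {
    age_model <- list(
      malignant = c(mean = mean(cohort$age[y == "malignant"]),
                    sd = stats::sd(cohort$age[y == "malignant"])),
      benign = c(mean = mean(cohort$age[y == "benign"]),
                 sd = stats::sd(cohort$age[y == "benign"]))
    )
  }
  structure(
    list(prior_malignant = n_mal / n, prior_benign = 1 - n_mal / n,
         conditional_tables = tables, age_model = age_model,
         smoothing_alpha = alpha, schema = schema,
         n_train = n, n_malignant = n_mal),
    class = "bayes_cad"
  )
}

#' @export
print.bayes_cad <- function(x, ...) {
  cat(sprintf("Bayes CAD model: n = %d (%d malignant), prior P(M) = %.3f\n",
              x$n_train, x$n_malignant, x$prior_malignant))
  cat(sprintf("  smoothing alpha = %g; age term: %s\n", x$smoothing_alpha,
              if (is.null(x$age_model)) "no" else "yes"))
  invisible(x)
}

# log class scores; features may be a partial named list (no-evidence limit
# returns the priors)
bayes_log_scores <- function(model, features, age = NULL) {
  log_m <- log(model$prior_malignant)
  log_b <- log(model$prior_benign)
  for (f in names(features)) {
    tab <- model$conditional_tables[[f]]
    if (is.null(tab)) {
      stop(sprintf("unknown feature '%s'", f), call. = FALSE)
    }
    v <- as.character(features[[f]])
    if (!(v %in% colnames(tab))) {
      stop(sprintf("unknown category for feature '%s': value '%s'", f, v),
           call. = FALSE)
    }
    log_m <- log_m + log(tab["malignant", v])
    log_b <- log_b + log(tab["benign", v])
  }
  if (!is.null(age) && !is.null(model$age_model)) {
    log_m <- log_m + stats::dnorm(age, model$age_model$malignant[["mean"]],
                                  model$age_model$malignant[["sd"]], log = TRUE)
    log_b <- log_b + stats::dnorm(age, model$age_model$benign[["mean"]],
                                  model$age_model$benign[["sd"]], log = TRUE)
  }
  c(malignant = log_m, benign = log_b)
}

#' Posterior probability of malignancy for one feature presentation
#'
#' Two-class Bayes rule: `score_M = P(M) * prod_i P(F_i = v_i | M)` (times
#' the class-conditional normal age density when an age is supplied and the
#' model carries an age term), `score_B` symmetrically, and
#' `P(M | F) = score_M / (score_M + score_B)`. If both scores vanish (only
#' possible with `alpha = 0`), the prior is returned with a warning.
#'
#' @param model A [fit_bayes()] model.
#' @param features Named list/vector of feature categories (may be a subset
#'   of the schema; empty means no evidence and returns the prior).
#' @param age Optional age in years.
#' @return A list of class `posterior_estimate`: `probability_malignant`,
#'   `used_age`, and the unnormalized log `scores` for debugging.
#' @export
#' @examples
#' co <- generate_cohort(cohort_config(n_lesions = 60, seed = 3))
#' fit <- fit_bayes(co)
#' posterior(fit, list(margin = "spiculated"))$probability_malignant
posterior <- function(model, features = list(), age = NULL) {
  stopifnot(inherits(model, "bayes_cad"))
  ls <- bayes_log_scores(model, features, age)
  if (all(!is.finite(ls))) {
    warning("both class scores are zero; returning the prior")
    p <- model$prior_malignant
  } else {
    # logistic of the log-score difference (stable two-class normalization)
    p <- 1 / (1 + exp(ls[["benign"]] - ls[["malignant"]]))
  }
  structure(
    list(probability_malignant = unname(p),
         used_age = !is.null(age) && !is.null(model$age_model),
         scores = ls),
    class = "posterior_estimate"
  )
}

#' @export
print.posterior_estimate <- function(x, ...) {
  cat(sprintf("P(malignant | evidence) = %.4f%s\n", x$probability_malignant,
              if (x$used_age) " (age included)" else ""))
  invisible(x)
}

#' Leave-one-out cross-validated posterior probabilities
#'
#' Each lesion's probability of malignancy comes from a model fitted on the
#' other n - 1 lesions. Implemented by downdating the full-cohort count
#' statistics (exact: identical to refitting on every fold, up to floating
#' point) so the whole sweep is vectorized.
#'
#' @inheritParams fit_bayes
#' @return Data frame `lesion_id`, `label`, `probability_malignant`,
#'   `used_age`, in the input lesion order.
#' @export
loocv_posteriors <- function(cohort, observation = NULL,
                             schema = birads_schema(), alpha = 1,
                             include_age = FALSE) {
  validate_schema(schema)
  n <- nrow(cohort)
  if (n < 3) stop("need at least 3 lesions for leave-one-out", call. = FALSE)
  y <- cohort$label == "malignant"
  n_mal <- sum(y)
  if (min(n_mal, n - n_mal) < 2) {
    stop("a fold's training set would be single-class: each class needs >= 2 members",
         call. = FALSE)
  }
  feats <- resolve_features(cohort, observation, schema)
  # fold priors and class sizes seen by each held-out lesion
  nm_i <- n_mal - y
  nb_i <- (n - n_mal) - (!y)
  log_m <- log(nm_i / (n - 1))
  log_b <- log(nb_i / (n - 1))
  warned_zero <- FALSE
  for (f in names(schema)) {
    cats <- schema[[f]]
    K <- length(cats)
    xf <- factor(feats[[f]], levels = cats)
    if (anyNA(xf)) {
      i <- which(is.na(xf))[1]
      stop(sprintf("unknown category for feature '%s': value '%s' (lesion '%s')",
                   f, feats[[f]][i], cohort$lesion_id[i]), call. = FALSE)
    }
    xi <- as.integer(xf)
    cnt_m <- tabulate(xf[y], K)
    cnt_b <- tabulate(xf[!y], K)
    num_m <- cnt_m[xi] - (y * 1L) + alpha
    num_b <- cnt_b[xi] - (!y) * 1L + alpha
    p_m <- num_m / (nm_i + alpha * K)
    p_b <- num_b / (nb_i + alpha * K)
    if (alpha == 0 && !warned_zero && any(p_m == 0 | p_b == 0)) {
      warned_zero <- TRUE
      warning("alpha = 0: some held-out categories are unseen in a fold's class; ",
              "posteriors may saturate at 0 or 1")
    }
    log_m <- log_m + log(p_m)
    log_b <- log_b + log(p_b)
  }
  if (include_age) {
    age <- cohort$age
    loo_norm <- function(in_class) {
      s <- sum(age[in_class]); ss <- sum(age[in_class]^2); k <- sum(in_class)
      # leave-one-out mean/sd for members; full-sample values for outsiders
      mu <- ifelse(in_class, (s - age) / (k - 1), s / k)
      ssq <- ifelse(in_class, ss - age^2, ss)
      kk <- ifelse(in_class, k - 1, k)
      var <- pmax((ssq - kk * mu^2) / (kk - 1), 1e-8)
      list(mean = mu, sd = sqrt(var))
    }
    am <- loo_norm(y)
    ab <- loo_norm(!y)
    log_m <- log_m + stats::dnorm(age, am$mean, am$sd, log = TRUE)
    log_b <- log_b + stats::dnorm(age, ab$mean, ab$sd, log = TRUE)
  }
  p <- 1 / (1 + exp(log_b - log_m))
  degen <- !is.finite(log_m) & !is.finite(log_b)
  if (any(degen)) {
    warning("both class scores are zero for some lesions; returning fold priors")
    p[degen] <- (nm_i / (n - 1))[degen]
  }
  data.frame(
    lesion_id = cohort$lesion_id,
    label = cohort$label,
    probability_malignant = unname(p),
    used_age = include_age,
    stringsAsFactors = FALSE
  )
}
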