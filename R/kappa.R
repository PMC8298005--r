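# chance-corrected agreement: Cohen's kappa, pooled-over-features kappa,
# Landis-Koch qualitative labels

new_kappa_result <- function(kappa, p_o, p_e, n_items, categories) {
  structure(
    list(kappa = kappa, p_observed = p_o, p_expected = p_e,
         n_items = n_items, categories = categories,
         label = landis_koch_label(kappa)),
    class = "kappa_result"
  )
}

#' Cohen's kappa for two categorical rating sequences
#'
#' Unweighted multi-category kappa, \eqn{\kappa = (p_o - p_e)/(1 - p_e)},
#' with the chance agreement \eqn{p_e} computed from the product of the two
#' raters' marginal category proportions. If both raters are constant and
#' equal (\eqn{p_e = 1}) the formula is 0/0; complete agreement
#' (\eqn{p_o = 1}) returns \eqn{\kappa = 1}, anything else returns `NaN`
#' with a warning.
#'
#' @param ratings_a,ratings_b Equal-length vectors of category labels.
#' @param categories Optional full category set (defaults to the union of
#'   observed values).
#' @return A `kappa_result`: `kappa`, `p_observed`, `p_expected`, `n_items`,
#'   `categories`, and the Landis-Koch `label`.
#' @export
#' @examples
#' cohen_kappa(c(1, 1, 0, 0), c(1, 0, 0, 0)) # kappa = 0.5
cohen_kappa <- function(ratings_a, ratings_b, categories = NULL) {
  if (length(ratings_a) != length(ratings_b)) {
    stop("rating sequences differ in length", call. = FALSE)
  }
  n <- length(ratings_a)
  if (n == 0) stop("empty rating sequences", call. = FALSE)
  ratings_a <- as.character(ratings_a)
  ratings_b <- as.character(ratings_b)
  if (is.null(categories)) {
    categories <- sort(unique(c(ratings_a, ratings_b)))
  } else {
    categories <- as.character(categories)
    bad <- setdiff(unique(c(ratings_a, ratings_b)), categories)
    if (length(bad)) {
      stop("ratings outside the category set: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  fa <- factor(ratings_a, levels = categories)
  fb <- factor(ratings_b, levels = categories)
  p_o <- mean(ratings_a == ratings_b)
  p_e <- sum((tabulate(fa, length(categories)) / n) *
             (tabulate(fb, length(categories)) / n))
  if (1 - p_e < 1e-15) {
    if (p_o >= 1 - 1e-15) {
      kappa <- 1
    } else {
      warning("degenerate marginals (p_e = 1) without complete agreement; kappa undefined")
      kappa <- NaN
    }
  } else {
    kappa <- (p_o - p_e) / (1 - p_e)
  }
  new_kappa_result(kappa, p_o, p_e, n, categories)
}

#' Pooled kappa over all features of two observations
#'
#' Agreement on all features combined. Default method `"pooled"` treats every
#' (lesion, feature) pair as one item with chance agreement computed within
#' feature (categories of different features can never match), pooling
#' item-weighted:
#' \deqn{\kappa = \sum_f n_f (p_{o,f} - p_{e,f}) / \sum_f n_f (1 - p_{e,f}).}
#' This reduces to ordinary Cohen's kappa when a single feature is used.
#' Method `"mean"` averages the per-feature kappas instead.
#'
#' @param obs_a,obs_b Observation data frames over the same lesions.
#' @param schema A [birads_schema()].
#' @param method `"pooled"` (default) or `"mean"`.
#' @return A `kappa_result` (for `"pooled"`, `p_observed`/`p_expected` are the
#'   item-weighted means over features).
#' @export
overall_kappa <- function(obs_a, obs_b, schema = birads_schema(),
                          method = c("pooled", "mean")) {
  method <- match.arg(method)
  missing_a <- setdiff(names(schema), names(obs_a))
  missing_b <- setdiff(names(schema), names(obs_b))
  if (length(missing_a) || length(missing_b)) {
    stop("observation sets do not match the schema", call. = FALSE)
  }
  if (!setequal(obs_a$lesion_id, obs_b$lesion_id)) {
    stop("observation sets cover different lesion_id sets", call. = FALSE)
  }
  obs_b <- obs_b[match(obs_a$lesion_id, obs_b$lesion_id), ]
  per_feature <- lapply(names(schema), function(f) {
    cohen_kappa(obs_a[[f]], obs_b[[f]], categories = schema[[f]])
  })
  names(per_feature) <- names(schema)
  n_f <- vapply(per_feature, function(k) k$n_items, numeric(1))
  p_o <- vapply(per_feature, function(k) k$p_observed, numeric(1))
  p_e <- vapply(per_feature, function(k) k$p_expected, numeric(1))
  if (method == "pooled") {
    num <- sum(n_f * (p_o - p_e))
    den <- sum(n_f * (1 - p_e))
    kappa <- if (den < 1e-15) {
      if (abs(num) < 1e-15) 1 else NaN
    } else {
      num / den
    }
    res <- new_kappa_result(kappa,
                            p_o = sum(n_f * p_o) / sum(n_f),
                            p_e = sum(n_f * p_e) / sum(n_f),
                            n_items = sum(n_f),
                            categories = unlist(lapply(names(schema), function(f)
                              paste(f, schema[[f]], sep = ":"))))
  } else {
    kappa <- mean(vapply(per_feature, function(k) k$kappa, numeric(1)))
    res <- new_kappa_result(kappa, p_o = mean(p_o), p_e = mean(p_e),
                            n_items = sum(n_f),
                            categories = unlist(lapply(names(schema), function(f)
                              paste(f, schema[[f]], sep = ":"))))
  }
  res$per_feature <- per_feature
  res
}

#' Landis-Koch qualitative label for a kappa value
#'
#' Five-scale system: 0.01--0.20 slight, 0.21--0.40 fair, 0.41--0.60
#' moderate, 0.61--0.80 substantial, 0.81--1.00 almost perfect. Values in
#' (0, 0.01) also map to "slight" (gap closure); kappa of zero or below maps
#' to "poor (chance or worse)".
#'
#' @param kappa Numeric kappa value, at most 1.
#' @return Character label.
#' @export
#' @examples
#' landis_koch_label(0.77) # "substantial"
#' landis_koch_label(0.56) # "moderate"
landis_koch_label <- function(kappa) {
  if (is.na(kappa)) return(NA_character_)
  if (kappa > 1 + 1e-9) stop("kappa cannot exceed 1", call. = FALSE)
  if (kappa <= 0) return("poor (chance or worse)")
  if (kappa <= 0.20) return("slight")
  if (kappa <= 0.40) return("fair")
  if (kappa <= 0.60) return("moderate")
  if (kappa <= 0.80) return("substantial")
  "almost perfect"
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa: %.3f (%s)\n", x$kappa, x$label))
  cat(sprintf("  p_observed = %.3f, p_expected = %.3f, n = %d items\n",
              x$p_observed, x$p_expected, x$n_items))
  invisible(x)
}

#' Per-feature and overall agreement table for pairs of observations
#'
#' One row per feature plus an "overall" row; one kappa (and label) column
#' pair per observation pair — the shape of an intra-observer agreement
#' report.
#'
#' @param observations Named list of observation data frames.
#' @param pairs List of 2-element character vectors of observation names; by
#'   default all unordered pairs in order.
#' @param schema A [birads_schema()].
#' @return Data frame with columns `feature`, then `kappa_<a>_vs_<b>` and
#'   `label_<a>_vs_<b>` per pair.
#' @export
agreement_table <- function(observations, pairs = NULL,
                            schema = birads_schema()) {
  stopifnot(is.list(observations), length(observations) >= 2)
  if (is.null(names(observations))) {
    names(observations) <- paste0("obs", seq_along(observations))
  }
  if (is.null(pairs)) {
    idx <- utils::combn(names(observations), 2, simplify = FALSE)
    pairs <- idx
  }
  out <- data.frame(feature = c(names(schema), "overall"),
                    stringsAsFactors = FALSE)
  for (pr in pairs) {
    ov <- overall_kappa(observations[[pr[1]]], observations[[pr[2]]], schema)
    kap <- c(vapply(ov$per_feature, function(k) k$kappa, numeric(1)), ov$kappa)
    lab <- vapply(kap, landis_koch_label, character(1))
    tag <- paste(pr[1], "vs", pr[2], sep = "_")
    out[[paste0("kappa_", tag)]] <- round(kap, 4)
    out[[paste0("label_", tag)]] <- lab
  }
  out
}
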