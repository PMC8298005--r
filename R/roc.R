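# empirical ROC area, DeLong variance machinery, paired curve comparison

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1", call. = FALSE)
    return(labels == 1)
  }
  lab <- as.character(labels)
  if (!all(lab %in% c("malignant", "benign"))) {
    stop("labels must be logical, 0/1, or 'malignant'/'benign'", call. = FALSE)
  }
  lab == "malignant"
}

# DeLong structural components: V10 (one per positive), V01 (one per
# negative); mean of each is the AUC. Midranks handle ties at 1/2.
delong_components <- function(scores, pos) {
  x <- scores[pos]
  y <- scores[!pos]
  m <- length(x)
  n <- length(y)
  r_all <- rank(c(x, y), ties.method = "average")
  r_x <- rank(x, ties.method = "average")
  r_y <- rank(y, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_x) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_y) / m
  list(v10 = v10, v01 = v01, auc = (sum(r_all[seq_len(m)]) - m * (m + 1) / 2) / (m * n))
}

#' Empirical ROC area with standard error and confidence interval
#'
#' The area under the empirical ROC curve by the Mann-Whitney pairwise rule
#' (ties counted 1/2): the probability that a random malignant case scores
#' above a random benign case. The standard error comes from the DeLong
#' structural-components variance estimator (Hanley-McNeil available as an
#' option) and the confidence interval is a normal approximation on the AUC
#' scale, clipped to \[0, 1\].
#'
#' @param scores Numeric scores (higher = more suspicious).
#' @param labels Case labels (logical, 0/1 or `"malignant"`/`"benign"`).
#' @param level Confidence level (default 0.95).
#' @param se_method `"delong"` (default) or `"hanley"`.
#' @return An object of class `roc_result`: `auc`, `se`, `ci_low`, `ci_high`,
#'   `n_pos`, `n_neg`, `level`, `se_method`.
#' @export
#' @examples
#' roc_auc(c(0.9, 0.7, 0.8, 0.3, 0.1), c(1, 1, 0, 0, 0))
roc_auc <- function(scores, labels, level = 0.95,
                    se_method = c("delong", "hanley")) {
  se_method <- match.arg(se_method)
  if (length(scores) != length(labels)) stop("length mismatch", call. = FALSE)
  pos <- as_binary_labels(labels)
  m <- sum(pos)
  n <- sum(!pos)
  if (m == 0 || n == 0) stop("both classes must be present", call. = FALSE)
  comp <- delong_components(scores, pos)
  auc <- comp$auc
  if (se_method == "delong") {
    s10 <- if (m > 1) stats::var(comp$v10) else 0
    s01 <- if (n > 1) stats::var(comp$v01) else 0
    se <- sqrt(s10 / m + s01 / n)
  } else {
    q1 <- auc / (2 - auc)
    q2 <- 2 * auc^2 / (1 + auc)
    se <- sqrt((auc * (1 - auc) + (m - 1) * (q1 - auc^2) +
                  (n - 1) * (q2 - auc^2)) / (m * n))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(
    list(auc = auc, se = se,
         ci_low = max(0, auc - z * se), ci_high = min(1, auc + z * se),
         n_pos = m, n_neg = n, level = level, se_method = se_method),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("A_z = %.3f +/- %.3f (%d%% CI %.3f - %.3f; %d pos / %d neg; %s)\n",
              x$auc, x$se, round(100 * x$level), x$ci_low, x$ci_high,
              x$n_pos, x$n_neg, x$se_method))
  invisible(x)
}

#' Paired comparison of two correlated ROC areas (DeLong test)
#'
#' Both score vectors are computed on the same cases, so the two empirical
#' AUCs are correlated; the DeLong structural components give the variance of
#' the difference and a two-sided normal test. Identical (or rank-identical)
#' score vectors give a zero difference and p = 1.
#'
#' @param scores_1,scores_2 Two score vectors over the same cases.
#' @param labels Case labels shared by both.
#' @return An object of class `paired_auc`: `auc_1`, `auc_2`, `delta_auc`
#'   (absolute difference), `se_delta`, `z`, `p_value`.
#' @export
compare_paired_auc <- function(scores_1, scores_2, labels) {
  if (length(scores_1) != length(scores_2) ||
      length(scores_1) != length(labels)) {
    stop("length mismatch", call. = FALSE)
  }
  pos <- as_binary_labels(labels)
  m <- sum(pos)
  n <- sum(!pos)
  if (m == 0 || n == 0) stop("both classes must be present", call. = FALSE)
  c1 <- delong_components(scores_1, pos)
  c2 <- delong_components(scores_2, pos)
  s10 <- stats::cov(cbind(c1$v10, c2$v10))
  s01 <- stats::cov(cbind(c1$v01, c2$v01))
  s <- s10 / m + s01 / n
  var_delta <- s[1, 1] + s[2, 2] - 2 * s[1, 2]
  d <- c1$auc - c2$auc
  if (var_delta <= 1e-16) {
    z <- if (abs(d) < 1e-12) 0 else sign(d) * Inf
  } else {
    z <- d / sqrt(var_delta)
  }
  p <- 2 * stats::pnorm(-abs(z))
  structure(
    list(auc_1 = c1$auc, auc_2 = c2$auc, delta_auc = abs(d),
         se_delta = sqrt(max(var_delta, 0)), z = z, p_value = p),
    class = "paired_auc"
  )
}

#' @export
print.paired_auc <- function(x, ...) {
  cat(sprintf("Delta A_z = %.4f (A_z1 = %.3f, A_z2 = %.3f), z = %.3f, p = %.4f\n",
              x$delta_auc, x$auc_1, x$auc_2, x$z, x$p_value))
  invisible(x)
}
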