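# intraclass correlation of repeated probability estimates

#' Intraclass correlation coefficient (two-way, single measure)
#'
#' Consistency of repeated measurements (here, posterior probabilities of
#' malignancy across reading rounds) on the same subjects. Default is the
#' absolute-agreement form ICC(A,1) of McGraw & Wong (Shrout-Fleiss
#' ICC(2,1)), computed from the two-way ANOVA mean squares with rows =
#' subjects and columns = raters/observations:
#' \deqn{ICC = (MS_R - MS_E) / (MS_R + (k-1) MS_E + k (MS_C - MS_E)/n).}
#' Confidence intervals use the F distribution (Satterthwaite degrees of
#' freedom for the agreement form). The consistency form ICC(C,1) is exposed
#' as an option.
#'
#' @param estimates Numeric matrix, `n_subjects x n_raters`, no missing cells.
#' @param level Confidence level (default 0.95).
#' @param type `"agreement"` (default) or `"consistency"`.
#' @return An object of class `icc_result`: `icc`, `ci_low`, `ci_high`,
#'   `n_subjects`, `n_raters`, `type`, `level`, and the ANOVA mean squares.
#' @export
#' @examples
#' icc_agreement(cbind(c(1, 2, 3), c(2, 3, 4))) # icc = 2/3
icc_agreement <- function(estimates, level = 0.95,
                          type = c("agreement", "consistency")) {
  type <- match.arg(type)
  m <- as.matrix(estimates)
  if (anyNA(m)) stop("missing cells are not allowed (no imputation)", call. = FALSE)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 3) stop("need at least 3 subjects", call. = FALSE)
  if (k < 2) stop("need at least 2 raters", call. = FALSE)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  grand <- mean(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  alpha <- 1 - level
  if (type == "agreement") {
    denom <- msr + (k - 1) * mse + k * (msc - mse) / n
    icc <- if (denom <= 0) 0 else (msr - mse) / denom
    # McGraw & Wong ICC(A,1) interval with Satterthwaite df
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    if (!is.finite(a) || !is.finite(b)) { # icc == 1 exactly
      lo <- hi <- 1
    } else {
      v <- (a * msc + b * mse)^2 /
        ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
      fl <- stats::qf(1 - alpha / 2, n - 1, v)
      fu <- stats::qf(1 - alpha / 2, v, n - 1)
      lo <- n * (msr - fl * mse) /
        (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
      hi <- n * (fu * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * fu * msr)
    }
  } else {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
    if (mse <= 0) {
      lo <- hi <- 1
    } else {
      fo <- msr / mse
      fl <- fo / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
      fu <- fo * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
      lo <- (fl - 1) / (fl + k - 1)
      hi <- (fu - 1) / (fu + k - 1)
    }
  }
  structure(
    list(icc = icc, ci_low = min(lo, icc), ci_high = max(hi, icc),
         n_subjects = n, n_raters = k, type = type, level = level,
         msr = msr, msc = msc, mse = mse),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(%s, single) = %.3f (%d%% CI %.3f - %.3f; %d subjects x %d raters)\n",
              if (x$type == "agreement") "A,1" else "C,1", x$icc,
              round(100 * x$level), x$ci_low, x$ci_high,
              x$n_subjects, x$n_raters))
  invisible(x)
}
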