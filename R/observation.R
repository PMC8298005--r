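# repeated noisy observations of a cohort's latent features

#' Observation (reading round) configuration
#'
#' `fidelity` is the per-feature probability that the latent true category is
#' reported unchanged; otherwise the reported category is resampled from that
#' feature's empirical marginal over the whole cohort. Under this
#' keep-or-resample model the expected Cohen's kappa against the latent truth
#' is `f` and between two independent observations is `f_a * f_b` (so `f^2`
#' at equal fidelity): each rating must independently retain the latent value
#' or the pair agrees only at chance level.
#'
#' @param fidelity Either a single value in \[0, 1\] (recycled over all
#'   features) or a named vector with one value per schema feature.
#' @param seed Integer seed for the keep/resample draws.
#' @param observation_id Token identifying the reading round.
#' @param interval_label Free-text metadata (e.g. `"+1 month"`); the
#'   generator does not model time.
#' @param schema A [birads_schema()] used to expand/validate `fidelity`.
#' @return An object of class `observation_config`.
#' @export
observation_config <- function(fidelity = 1, seed = 1L,
                               observation_id = "obs1",
                               interval_label = "",
                               schema = birads_schema()) {
  validate_schema(schema)
  if (length(fidelity) == 1 && is.null(names(fidelity))) {
    fidelity <- stats::setNames(rep(as.numeric(fidelity), length(schema)),
                                names(schema))
  }
  missing_f <- setdiff(names(schema), names(fidelity))
  if (length(missing_f)) {
    stop("fidelity missing for feature(s): ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  }
  fidelity <- fidelity[names(schema)]
  if (!is_prob(fidelity)) stop("fidelity values must lie in [0, 1]", call. = FALSE)
  structure(
    list(fidelity = fidelity, seed = as.integer(seed),
         observation_id = observation_id, interval_label = interval_label),
    class = "observation_config"
  )
}

#' Generate one observation (reading round) of a cohort
#'
#' For each lesion and feature, the latent category is kept with probability
#' `fidelity[feature]`; otherwise a category is drawn from the feature's
#' empirical marginal distribution over the cohort (which may reproduce the
#' true value by chance). Marginal category frequencies are therefore
#' preserved in expectation.
#'
#' @param cohort A cohort from [generate_cohort()] or [read_cohort_csv()].
#' @param config An [observation_config()].
#' @param schema A [birads_schema()].
#' @return Data frame of class `birads_observation` with `lesion_id` plus one
#'   column per feature; attributes `observation_id`, `interval_label`,
#'   `fidelity`, `seed`.
#' @export
#' @examples
#' co <- generate_cohort(cohort_config(n_lesions = 50, seed = 1))
#' ob <- generate_observation(co, observation_config(fidelity = 0.8, seed = 2))
#' mean(ob$margin == co$margin)
generate_observation <- function(cohort, config, schema = birads_schema()) {
  stopifnot(inherits(config, "observation_config"))
  validate_schema(schema)
  if (nrow(cohort) == 0) stop("cohort is empty", call. = FALSE)
  missing_cols <- setdiff(names(schema), names(cohort))
  if (length(missing_cols)) {
    stop("cohort lacks feature column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(cohort)
  out <- data.frame(lesion_id = cohort$lesion_id, stringsAsFactors = FALSE)
  with_seed(config$seed, {
    for (f in names(schema)) {
      truth <- cohort[[f]]
      cats <- schema[[f]]
      marg <- tabulate(factor(truth, levels = cats), nbins = length(cats))
      keep <- stats::runif(n) < config$fidelity[[f]]
      x <- truth
      n_res <- sum(!keep)
      if (n_res > 0) {
        x[!keep] <- sample(cats, n_res, replace = TRUE, prob = marg / n)
      }
      out[[f]] <- x
    }
  })
  class(out) <- c("birads_observation", "data.frame")
  attr(out, "observation_id") <- config$observation_id
  attr(out, "interval_label") <- config$interval_label
  attr(out, "fidelity") <- config$fidelity
  attr(out, "seed") <- config$seed
  out
}
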