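# internal helpers shared across modules

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library code never perturbs the
#' caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage seed from a master seed and string labels
#'
#' Deterministic polynomial rolling hash over the concatenated labels, folded
#' into \[1, 2^31 - 2\]. Adding a new stage or observation id never perturbs
#' the seed of any other stage.
#'
#' @param master_seed Integer master seed.
#' @param ... Character or numeric labels identifying the stage
#'   (e.g. `"observation"`, an observation id).
#' @return A single integer usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(1, "cohort")
#' derive_seed(1, "observation", "obs2")
derive_seed <- function(master_seed, ...) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1)
  key <- paste(c(format(master_seed, scientific = FALSE), ...), collapse = "/")
  codes <- utf8ToInt(key)
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (cc in codes) h <- (h * 31 + cc) %% m
  as.integer(h %% (m - 2) + 1)
}

#' Stable hash of an R object (provenance fingerprint)
#' @noRd
object_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "\n")
  codes <- utf8ToInt(s)
  m <- 2147483647
  h1 <- 0
  h2 <- 0
  for (cc in codes) {
    h1 <- (h1 * 31 + cc) %% m
    h2 <- (h2 * 131 + cc) %% m
  }
  sprintf("%08x%08x", h1, h2)
}

#' @noRd
is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x == round(x) && x >= 0
}

#' @noRd
is_prob <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x <= 1)
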