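# BI-RADS ultrasound feature schema

#' The BI-RADS ultrasound lexicon feature schema
#'
#' The six categorical sonographic descriptors of a solid breast mass in the
#' ACR BI-RADS ultrasound lexicon, with their category sets: shape,
#' orientation, margin, lesion boundary, echo pattern, and posterior acoustic
#' features.
#'
#' @return An object of class `birads_schema`: a named list of character
#'   vectors, one per feature, in canonical column order.
#' @export
#' @examples
#' sch <- birads_schema()
#' names(sch)
#' sch$orientation
birads_schema <- function() {
  schema <- list(
    shape              = c("oval", "round", "irregular"),
    orientation        = c("parallel", "not parallel"),
    margin             = c("circumscribed", "indistinct", "angular",
                           "microlobulated", "spiculated"),
    lesion_boundary    = c("abrupt interface", "echogenic halo"),
    echo_pattern       = c("anechoic", "hyperechoic", "complex",
                           "hypoechoic", "isoechoic"),
    posterior_features = c("none", "enhancement", "shadowing", "combined")
  )
  structure(schema, class = "birads_schema")
}

#' Validate a feature schema
#' @noRd
validate_schema <- function(schema) {
  if (!is.list(schema) || is.null(names(schema)) || any(names(schema) == "")) {
    stop("schema must be a named list of category vectors", call. = FALSE)
  }
  if (anyDuplicated(names(schema))) {
    stop("schema feature names must be unique", call. = FALSE)
  }
  for (f in names(schema)) {
    cats <- schema[[f]]
    if (!is.character(cats) || length(cats) == 0) {
      stop(sprintf("feature '%s' has an empty category list", f), call. = FALSE)
    }
    if (anyDuplicated(cats)) {
      stop(sprintf("feature '%s' has duplicate categories", f), call. = FALSE)
    }
  }
  invisible(schema)
}

#' @export
print.birads_schema <- function(x, ...) {
  cat("BI-RADS ultrasound feature schema (", length(x), " features)\n", sep = "")
  for (f in names(x)) {
    cat("  ", format(f, width = 20), paste(x[[f]], collapse = " | "), "\n", sep = "")
  }
  invisible(x)
}
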