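#' Fluorometry constants
#'
#' Bundles the two constants used to convert PSII quantum efficiency into an
#' electron transport rate: `f`, the fraction of absorbed photons allocated to
#' photosystem II, and `alpha_leaf`, the leaf absorptance. The defaults
#' (f = 0.5, alpha_leaf = 0.88) are the values conventionally assumed for
#' healthy C3 leaves measured with a red/blue LED fluorometer head.
#'
#' @param f Fraction of absorbed light used by PSII, in (0, 1].
#' @param alpha_leaf Leaf absorptance, in (0, 1].
#'
#' @return An object of class `fluoro_constants`: a named list with elements
#'   `f` and `alpha_leaf`.
#' @examples
#' fluoro_constants()
#' fluoro_constants(alpha_leaf = 0.84)
#' @export
fluoro_constants <- function(f = 0.5, alpha_leaf = 0.88) {
  if (!is.numeric(f) || length(f) != 1L || is.na(f) || f <= 0 || f > 1) {
    abort("`f` must be a single number in (0, 1].", class = "leafflow_domain_error")
  }
  if (!is.numeric(alpha_leaf) || length(alpha_leaf) != 1L || is.na(alpha_leaf) ||
      alpha_leaf <= 0 || alpha_leaf > 1) {
    abort("`alpha_leaf` must be a single number in (0, 1].",
          class = "leafflow_domain_error")
  }
  structure(list(f = f, alpha_leaf = alpha_leaf), class = "fluoro_constants")
}

#' @export
print.fluoro_constants <- function(x, ...) {
  cat("Fluorometry constants: f =", x$f, ", alpha_leaf =", x$alpha_leaf, "\n")
  invisible(x)
}

as_fluoro_constants <- function(x) {
  if (inherits(x, "fluoro_constants")) return(x)
  if (is.list(x)) return(fluoro_constants(f = x$f %||% 0.5,
                                          alpha_leaf = x$alpha_leaf %||% 0.88))
  abort("`consts` must be created with `fluoro_constants()`.",
        class = "leafflow_domain_error")
}
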