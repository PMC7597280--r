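# Half the log-volume constant 0.5*log(2*pi*e): differential entropy of N(0,1).
.half_l2pe <- 0.5 * log(2 * pi * exp(1))

# Memoization of h(a): every criterion value in this package is an affine
# combination of h evaluations, so caching h subsumes caching per subset.
.h_cache <- new.env(parent = emptyenv())

#' Quadrature configuration
#'
#' Settings for the adaptive quadrature used to evaluate the mixture entropy
#' function [h_mix()]. The integrand decays like a Gaussian outside the two
#' component centers, so the integral is truncated at `truncation_halfwidth`
#' standard deviations beyond them; at the default of 12 the truncation error
#' is below 1e-30, far under the requested tolerances.
#'
#' @param abs_tol absolute error tolerance passed to the quadrature.
#' @param rel_tol relative error tolerance passed to the quadrature.
#' @param truncation_halfwidth half-width, in standard deviations beyond the
#'   component centers, of the integration interval.
#' @return An object of class `"quad_config"`.
#' @examples
#' quad_config()
#' quad_config(abs_tol = 1e-12)
#' @export
quad_config <- function(abs_tol = 1e-10, rel_tol = 1e-10,
                        truncation_halfwidth = 12) {
  vals <- c(abs_tol = abs_tol, rel_tol = rel_tol,
            truncation_halfwidth = truncation_halfwidth)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("all quadrature settings must be finite and strictly positive")
  }
  structure(list(abs_tol = abs_tol, rel_tol = rel_tol,
                 truncation_halfwidth = truncation_halfwidth),
            class = "quad_config")
}

#' Read a quadrature configuration from a JSON file
#'
#' The file may contain any subset of the keys `abs_tol`, `rel_tol` and
#' `truncation_halfwidth`; missing keys keep their defaults.
#'
#' @param path path to a JSON file.
#' @return An object of class `"quad_config"`.
#' @export
quad_config_from_json <- function(path) {
  cfg <- jsonlite::fromJSON(path)
  keep <- intersect(names(cfg),
                    c("abs_tol", "rel_tol", "truncation_halfwidth"))
  do.call(quad_config, as.list(cfg[keep]))
}

#' Differential entropy of the unit-variance two-component mixture
#'
#' Computes `h(a)`, the differential entropy (in nats) of the equal-weight
#' mixture of `N(0, 1)` and `N(a, 1)`, by adaptive quadrature of
#' `-f log f` with `f(x) = (dnorm(x) + dnorm(x - a)) / 2`. The function is
#' strictly increasing in `a` and bounded between `log(2*pi*e)/2` (at `a = 0`,
#' where the mixture collapses to a standard normal) and
#' `log(2*pi*e)/2 + log(2)` (widely separated components, where the mixing
#' label contributes one full bit).
#'
#' Only `a >= 0` is accepted: the entropy depends on the separation through
#' its magnitude only, so callers pass `abs(a)`.
#'
#' @param a numeric vector of nonnegative separations between the component
#'   means.
#' @param cfg a [quad_config()].
#' @return Numeric vector of entropies in nats.
#' @examples
#' h_mix(0) - 0.5 * log(2 * pi * exp(1)) # 0: standard normal
#' h_mix(1)
#' @export
h_mix <- function(a, cfg = quad_config()) {
  if (!is.numeric(a) || length(a) == 0 || any(!is.finite(a))) {
    stop("'a' must be a finite numeric vector")
  }
  if (any(a < 0)) {
    stop("'a' must be nonnegative; pass abs(a) (the entropy depends on the ",
         "separation magnitude only)")
  }
  vapply(a, .h_one, numeric(1), cfg = cfg)
}

.h_one <- function(a, cfg) {
  key <- sprintf("%.17g|%.8g|%.8g|%.8g", a, cfg$abs_tol, cfg$rel_tol,
                 cfg$truncation_halfwidth)
  hit <- .h_cache[[key]]
  if (!is.null(hit)) return(hit)
  integrand <- function(x) {
    fx <- 0.5 * (stats::dnorm(x) + stats::dnorm(x, mean = a))
    out <- numeric(length(fx))
    ok <- fx >= 1e-300        # f*log(f) -> 0 as f -> 0
    out[ok] <- -fx[ok] * log(fx[ok])
    out
  }
  res <- stats::integrate(integrand,
                          lower = -cfg$truncation_halfwidth,
                          upper = a + cfg$truncation_halfwidth,
                          abs.tol = cfg$abs_tol, rel.tol = cfg$rel_tol,
                          subdivisions = 500L, stop.on.error = FALSE)
  if (!identical(res$message, "OK") || res$abs.error > 100 * cfg$abs_tol) {
    stop(sprintf(
      "quadrature for h(%g) did not converge: %s (estimated error %.3g, requested %.3g)",
      a, res$message, res$abs.error, cfg$abs_tol))
  }
  .h_cache[[key]] <- res$value
  res$value
}

#' Convert nats to bits
#'
#' @param x numeric vector of information values in nats.
#' @return `x / log(2)`.
#' @export
nats_to_bits <- function(x) x / log(2)
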