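#' Two-component Gaussian mixture specification
#'
#' Describes a d-variate random vector distributed as the equal-weight mixture
#' of `N(0, sigma)` and `N(mu, sigma)`: one component sits at the origin, the
#' other at `mu`, and both share the covariance `sigma`. Equivalently, with a
#' Bernoulli(1/2) label `Y`, `X | Y = y ~ N(y * mu, sigma)`. The equal-weight
#' assumption is structural (the entropy and mutual-information formulas below
#' rely on it), so unequal weights are rejected.
#'
#' @param mu numeric vector: difference of the component means.
#' @param sigma shared covariance matrix (symmetric positive definite);
#'   defaults to the identity. A scalar is accepted when `length(mu) == 1`.
#' @param weights mixing weights; must be `c(0.5, 0.5)`.
#' @return An object of class `"mixture_spec"` with fields `d`, `mu`, `sigma`.
#' @examples
#' mixture_spec(mu = 1)                  # N(0,1)/N(1,1) mixture
#' mixture_spec(mu = c(1, 2/3))          # bivariate, identity covariance
#' @export
mixture_spec <- function(mu, sigma = diag(length(mu)), weights = c(0.5, 0.5)) {
  mu <- as.numeric(mu)
  d <- length(mu)
  if (d < 1 || any(!is.finite(mu))) stop("'mu' must be a finite vector, d >= 1")
  if (!identical(as.numeric(weights), c(0.5, 0.5))) {
    stop("only equal weights (1/2, 1/2) are supported")
  }
  sigma <- as.matrix(sigma) * 1.0
  if (!all(dim(sigma) == d)) stop("'sigma' must be a ", d, "x", d, " matrix")
  if (any(!is.finite(sigma)) || max(abs(sigma - t(sigma))) > 1e-10) {
    stop("'sigma' must be finite and symmetric (tolerance 1e-10)")
  }
  ev <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev)) {
    stop("'sigma' is singular or not positive definite ",
         sprintf("(eigenvalue range [%.3g, %.3g])", min(ev), max(ev)))
  }
  structure(list(d = d, mu = mu, sigma = sigma), class = "mixture_spec")
}

#' @export
print.mixture_spec <- function(x, ...) {
  cat(sprintf("Two-component Gaussian mixture, d = %d\n", x$d))
  cat("  mu:   ", paste(signif(x$mu, 6), collapse = ", "), "\n")
  cat("  sigma:", paste(signif(x$sigma[1, ], 6), collapse = ", "),
      if (x$d > 1) "..." else "", "\n")
  invisible(x)
}

# Whitened separation ||sigma^{-1/2} mu||, via symmetric eigendecomposition.
# The entropy depends on sigma^{-1/2} only through this norm, so any
# symmetric square root gives the same answer.
.whitened_sep <- function(spec) {
  e <- eigen((spec$sigma + t(spec$sigma)) / 2, symmetric = TRUE)
  if (min(e$values) <= 1e-12 * max(e$values)) stop("'sigma' is singular")
  z <- drop(crossprod(e$vectors, spec$mu))
  sqrt(sum(z^2 / e$values))
}

.log_det <- function(sigma) {
  determinant(sigma, logarithm = TRUE)$modulus[[1]]
}

#' Differential entropy of a Gaussian mixture
#'
#' Entropy (nats) of the equal-weight mixture of `N(0, sigma)` and
#' `N(mu, sigma)`:
#' `H(X) = h(||sigma^(-1/2) mu||) + (d-1)/2 log(2 pi e) + 1/2 log det(sigma)`,
#' where `h` is [h_mix()]. The multivariate problem reduces to the univariate
#' one because a rotation can align the whitened mean difference with the
#' first coordinate, leaving d-1 independent standard normal coordinates.
#'
#' @param spec a [mixture_spec()].
#' @param cfg a [quad_config()].
#' @return Entropy in nats; always at least the Gaussian entropy
#'   `d/2 log(2 pi e) + 1/2 log det(sigma)`.
#' @examples
#' mixture_entropy(mixture_spec(mu = 0))       # log(2*pi*e)/2
#' mixture_entropy(mixture_spec(mu = c(3, 4))) # h(5) + log(2*pi*e)/2
#' @export
mixture_entropy <- function(spec, cfg = quad_config()) {
  stopifnot(inherits(spec, "mixture_spec"))
  h_mix(.whitened_sep(spec), cfg) + (spec$d - 1) * .half_l2pe +
    0.5 * .log_det(spec$sigma)
}

#' Mutual information between a Gaussian mixture and its mixing label
#'
#' For `Y ~ Bernoulli(1/2)` and `X | Y = y ~ N(y * mu, sigma)`,
#' `I(X, Y) = h(||sigma^(-1/2) mu||) - log(2 pi e)/2` in nats. The value is
#' zero iff `mu = 0` and never exceeds `log(2)`, the entropy of the label.
#'
#' @inheritParams mixture_entropy
#' @return Mutual information in nats.
#' @examples
#' mi_with_label(mixture_spec(mu = 1))            # 0.1114
#' mi_with_label(mixture_spec(mu = 1, sigma = 2)) # 0.0589
#' @export
mi_with_label <- function(spec, cfg = quad_config()) {
  stopifnot(inherits(spec, "mixture_spec"))
  v <- h_mix(.whitened_sep(spec), cfg) - .half_l2pe
  if (v < 0 && v > -1e-12) v <- 0
  v
}

#' Mutual information between two sub-vectors of one mixture
#'
#' Computes `I(A, B) = H(A) + H(B) - H(A, B)` for a partition of one
#' two-component mixture into sub-vectors `A` and `B`, with each entropy
#' evaluated by [mixture_entropy()]. The marginal specifications must be
#' consistent with the joint one: their `mu` and `sigma` must equal the
#' corresponding sub-blocks of `specAB` (A first, then B).
#'
#' @param specA,specB marginal [mixture_spec()] objects for the two blocks.
#' @param specAB joint [mixture_spec()] for `(A, B)`.
#' @param cfg a [quad_config()].
#' @return Mutual information in nats (nonnegative; values within 1e-8 below
#'   zero from quadrature round-off are clamped to 0).
#' @export
subset_entropy_mi <- function(specA, specB, specAB, cfg = quad_config()) {
  stopifnot(inherits(specA, "mixture_spec"), inherits(specB, "mixture_spec"),
            inherits(specAB, "mixture_spec"))
  dA <- specA$d
  dB <- specB$d
  if (specAB$d != dA + dB) stop("joint dimension must be dA + dB")
  ia <- seq_len(dA)
  ib <- dA + seq_len(dB)
  ok <- max(abs(specAB$mu[ia] - specA$mu)) <= 1e-8 &&
    max(abs(specAB$mu[ib] - specB$mu)) <= 1e-8 &&
    max(abs(specAB$sigma[ia, ia, drop = FALSE] - specA$sigma)) <= 1e-8 &&
    max(abs(specAB$sigma[ib, ib, drop = FALSE] - specB$sigma)) <= 1e-8
  if (!ok) stop("marginal specifications are inconsistent with the joint one")
  v <- mixture_entropy(specA, cfg) + mixture_entropy(specB, cfg) -
    mixture_entropy(specAB, cfg)
  if (v < -1e-8) {
    stop(sprintf("negative mutual information %.3g: numerical failure", v))
  }
  max(v, 0)
}

# Canonical name for a subset of indices, used in interaction_information().
.subset_key <- function(idx) paste(sort(unique(idx)), collapse = ",")

#' Interaction information from subset entropies
#'
#' The p-way interaction information is the alternating-sign Moebius sum over
#' subset entropies,
#' `II(X1, ..., Xp) = -sum_T (-1)^(p - |T|) H(X_T)` over nonempty subsets `T`.
#' For `p = 2` it reduces to the mutual information `H(X1)+H(X2)-H(X12)`; for
#' `p = 3` to the familiar three-way synergy/redundancy measure. Negative
#' values indicate redundancy among the variables.
#'
#' The entropies are supplied by the caller (they may mix differential and
#' discrete entropies, e.g. when one variable is a class label), as a named
#' numeric vector whose names are comma-joined sorted index sets: for
#' `p = 3` the required names are `"1", "2", "3", "1,2", "1,3", "2,3",
#' "1,2,3"`.
#'
#' @param entropies named numeric vector with one entry per nonempty subset of
#'   `1..p`; `p` is inferred from the largest index and must be at most 4.
#' @return Interaction information in nats.
#' @examples
#' L <- 0.5 * log(2 * pi * exp(1))
#' # two independent standard normals: II = MI = 0
#' interaction_information(c("1" = L, "2" = L, "1,2" = 2 * L))
#' @export
interaction_information <- function(entropies) {
  if (is.list(entropies)) entropies <- unlist(entropies)
  if (!is.numeric(entropies) || is.null(names(entropies))) {
    stop("'entropies' must be a named numeric vector")
  }
  idx <- lapply(strsplit(names(entropies), ","), function(s) sort(as.integer(s)))
  if (any(vapply(idx, function(i) any(is.na(i)) || length(i) == 0, TRUE))) {
    stop("names must be comma-joined positive integer index sets")
  }
  p <- max(unlist(idx))
  if (p > 4) stop("interaction information supported for p <= 4 only")
  keys <- vapply(idx, paste, character(1), collapse = ",")
  names(entropies) <- keys
  total <- 0
  for (m in seq_len(p)) {
    for (Tset in utils::combn(p, m, simplify = FALSE)) {
      key <- paste(Tset, collapse = ",")
      if (is.na(entropies[key])) {
        stop("missing entropy for subset {", key, "}")
      }
      total <- total - (-1)^(p - m) * entropies[[key]]
    }
  }
  total
}

#' Total correlation of a standardized Gaussian mixture
#'
#' For an equal-weight mixture with identity covariance, the total correlation
#' (sum of marginal entropies minus joint entropy) has the closed form
#' `TC(X) = sum_i h(|mu_i|) - h(||mu||) + (1 - d) log(2 pi e) / 2`.
#' The identity-covariance restriction is structural: for general `sigma` use
#' [subset_entropy_mi()] on the blocks of interest.
#'
#' @inheritParams mixture_entropy
#' @return Total correlation in nats (nonnegative; round-off within 1e-8 below
#'   zero is clamped).
#' @examples
#' total_correlation(mixture_spec(mu = c(1, 1))) # 2 h(1) - h(sqrt(2)) - log(2*pi*e)/2
#' @export
total_correlation <- function(spec, cfg = quad_config()) {
  stopifnot(inherits(spec, "mixture_spec"))
  if (max(abs(spec$sigma - diag(spec$d))) > 1e-10) {
    stop("total_correlation() requires identity covariance; ",
         "use subset_entropy_mi() for general sigma")
  }
  v <- sum(h_mix(abs(spec$mu), cfg)) - h_mix(sqrt(sum(spec$mu^2)), cfg) +
    (1 - spec$d) * .half_l2pe
  if (v < -1e-8) stop(sprintf("negative total correlation %.3g", v))
  max(v, 0)
}
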