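# Independent numerical routes used as oracles; these deliberately avoid the
# package's h_mix()/mixture_entropy() code paths.

L2PE_HALF <- 0.5 * log(2 * pi * exp(1))

# Entropy of the symmetric mixture (N(-a/2,1) + N(a/2,1))/2 by direct
# quadrature; equals h(a) by translation invariance.
h_symmetric_oracle <- function(a) {
  f <- function(x) 0.5 * (dnorm(x, -a / 2) + dnorm(x, a / 2))
  integrand <- function(x) {
    fx <- f(x)
    out <- numeric(length(fx))
    ok <- fx > 1e-300
    out[ok] <- -fx[ok] * log(fx[ok])
    out
  }
  integrate(integrand, -a / 2 - 13, a / 2 + 13,
            abs.tol = 1e-12, rel.tol = 1e-12, subdivisions = 400L)$value
}

# Random symmetric positive-definite matrix with unit-order eigenvalues.
random_spd <- function(d) {
  a <- matrix(rnorm(d * d), d)
  crossprod(a) / d + diag(d) * 0.3
}

# Entropy of a d-variate Gaussian with covariance sigma (exact).
gauss_entropy <- function(sigma) {
  d <- nrow(as.matrix(sigma))
  d * L2PE_HALF + 0.5 * determinant(as.matrix(sigma), TRUE)$modulus[[1]]
}

# Entropies of all nonempty subsets of a mixed system (X_1..X_d, Y) where
# X | Y = y ~ N(y*mu, sigma) and Y ~ Bern(1/2), named for
# interaction_information(): continuous indices 1..d, the label is index d+1.
# H of subsets containing Y uses the grouping identity H(X_T, Y) =
# H(Y) + H(X_T | Y), with H(X_T | Y) Gaussian.
mixed_subset_entropies <- function(mu, sigma) {
  d <- length(mu)
  ents <- c()
  for (m in seq_len(d + 1)) {
    for (Tset in combn(d + 1, m, simplify = FALSE)) {
      key <- paste(Tset, collapse = ",")
      has_y <- (d + 1) %in% Tset
      xs <- setdiff(Tset, d + 1)
      val <- if (length(xs) == 0) {
        log(2)
      } else if (has_y) {
        log(2) + gauss_entropy(sigma[xs, xs, drop = FALSE])
      } else {
        mixture_entropy(mixture_spec(mu[xs], sigma[xs, xs, drop = FALSE]))
      }
      ents[key] <- val
    }
  }
  ents
}

# Absolute-difference expectation (testthat's tolerance is relative).
expect_close <- function(object, expected, tol, label = NULL) {
  if (is.null(label)) label <- deparse(substitute(object))
  testthat::expect_lt(abs(object - expected), tol,
                      label = sprintf("|%s - %g|", label, expected))
}
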