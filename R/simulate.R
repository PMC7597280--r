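# Runs expr under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, globalenv())
    } else {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    }
  })
  set.seed(seed)
  expr
}

#' Sample labeled observations from the generative tree model
#'
#' Draws `Y ~ Bernoulli(1/2)`, then `X_i = gamma^(i-1) * Y + eps_i` for
#' `i = 1..k+1` and `X1(1) = X1 + eps_{k+2}` with i.i.d. standard normal
#' noise. Sampling uses a private RNG stream seeded with `seed`; the caller's
#' RNG state is untouched and identical seeds give bit-identical batches.
#'
#' @param spec a [gtm_spec()].
#' @param n number of observations.
#' @param seed integer seed.
#' @return An object of class `"gtm_sample"`: list with `n`, `labels`
#'   (0/1 vector), `data` (an `n x (k+2)` matrix with columns
#'   `X1..X{k+1}, X1(1)`), `seed` and `spec`.
#' @examples
#' b <- sample_gtm(gtm_spec(2, 2/3), n = 5, seed = 1)
#' b$data
#' @export
sample_gtm <- function(spec, n, seed) {
  stopifnot(inherits(spec, "gtm_spec"))
  if (length(n) != 1 || !is.finite(n) || n < 1 || n != round(n)) {
    stop("'n' must be a positive integer")
  }
  k <- spec$k
  .with_seed(seed, {
    y <- stats::rbinom(n, 1L, 0.5)
    eps <- matrix(stats::rnorm(n * (k + 2)), nrow = n)
    x <- outer(y, spec$gamma^(0:k)) + eps[, seq_len(k + 1), drop = FALSE]
    child <- x[, 1] + eps[, k + 2]
    data <- cbind(x, child)
    colnames(data) <- gtm_variables(spec)
    structure(list(n = as.integer(n), labels = y, data = data,
                   seed = as.integer(seed), spec = spec),
              class = "gtm_sample")
  })
}

#' Write a sample batch as headered CSV
#'
#' Columns `y, x1, ..., x{k+1}, x1_child`.
#'
#' @param batch a `"gtm_sample"` from [sample_gtm()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_sample_csv <- function(batch, path) {
  stopifnot(inherits(batch, "gtm_sample"))
  df <- data.frame(y = batch$labels, batch$data, check.names = FALSE)
  names(df) <- c("y", paste0("x", seq_len(batch$spec$k + 1)), "x1_child")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Log-density of the equal-weight mixture N(0, sigma) / N(mu, sigma) at the
# rows of x, computed through the Cholesky factor for stability.
.log_dgmix <- function(x, spec) {
  R <- chol(spec$sigma)
  log_det <- 2 * sum(log(diag(R)))
  quad0 <- colSums(backsolve(R, t(x), transpose = TRUE)^2)
  quad1 <- colSums(backsolve(R, t(x) - spec$mu, transpose = TRUE)^2)
  const <- -0.5 * (spec$d * log(2 * pi) + log_det)
  m <- pmax(-quad0, -quad1) / 2
  const + m + log(0.5 * (exp(-quad0 / 2 - m) + exp(-quad1 / 2 - m)))
}

#' Monte Carlo estimate of the mixture entropy
#'
#' Draws `n` points from the mixture and averages `-log p(x)` with `p` the
#' exact mixture density; this is the standard validation oracle for the
#' quadrature-based [mixture_entropy()]. The standard error is that of the
#' sample mean of `-log p`.
#'
#' @param spec a [mixture_spec()].
#' @param n number of Monte Carlo draws (at least 1000).
#' @param seed integer seed.
#' @return List with `estimate` and `std_error` (both in nats).
#' @export
mc_entropy <- function(spec, n, seed) {
  stopifnot(inherits(spec, "mixture_spec"))
  if (length(n) != 1 || !is.finite(n) || n < 1000) {
    stop("'n' must be at least 1000")
  }
  n <- as.integer(n)
  .with_seed(seed, {
    R <- chol(spec$sigma)
    z <- matrix(stats::rnorm(n * spec$d), nrow = n) %*% R
    lab <- stats::rbinom(n, 1L, 0.5)
    x <- z + outer(lab, spec$mu)
    nll <- -.log_dgmix(x, spec)
    list(estimate = mean(nll), std_error = stats::sd(nll) / sqrt(n))
  })
}

#' Monte Carlo estimate of the mixture / label mutual information
#'
#' `I(X, Y) = H(X) - H(X | Y)` with `H(X)` estimated by [mc_entropy()] and
#' the conditional entropy exact (both strata are Gaussian with covariance
#' `sigma`): `H(X | Y) = d/2 log(2 pi e) + 1/2 log det(sigma)`. The standard
#' error is that of the entropy estimate.
#'
#' @inheritParams mc_entropy
#' @return List with `estimate` and `std_error` (both in nats).
#' @export
mc_mi_with_label <- function(spec, n, seed) {
  est <- mc_entropy(spec, n, seed)
  cond <- spec$d * .half_l2pe + 0.5 * .log_det(spec$sigma)
  list(estimate = est$estimate - cond, std_error = est$std_error)
}
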