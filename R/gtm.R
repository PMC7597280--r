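#' Generative tree model specification
#'
#' The model `M(k, gamma)` has a binary root `Y ~ Bernoulli(1/2)`, active
#' predictors `X_i | Y ~ N(gamma^(i-1) * Y, 1)` for `i = 1, ..., k+1`
#' (conditionally independent given `Y`), and one inactive descendant
#' `X1(1) | X1 ~ N(X1, 1)`, a child of `X1` rather than of `Y`. The parameter
#' `gamma` in (0, 1] controls how quickly the class separation of the active
#' predictors decays with the index: small `gamma` makes high-index predictors
#' nearly uninformative. `{X1, ..., X_{k+1}}` is the Markov blanket of `Y`;
#' `X1(1)` carries no information about `Y` beyond what `X1` provides.
#'
#' @param k number of active predictors minus one (`k >= 1`).
#' @param gamma geometric decay of the class separation, in (0, 1].
#' @return An object of class `"gtm_spec"`.
#' @examples
#' gtm_spec(k = 2, gamma = 2/3)
#' @export
gtm_spec <- function(k, gamma) {
  if (length(k) != 1 || !is.finite(k) || k < 1 || k != round(k)) {
    stop("'k' must be a positive integer")
  }
  if (length(gamma) != 1 || !is.finite(gamma) || gamma <= 0 || gamma > 1) {
    stop("'gamma' must lie in (0, 1]")
  }
  structure(list(k = as.integer(k), gamma = as.numeric(gamma)),
            class = "gtm_spec")
}

#' @export
print.gtm_spec <- function(x, ...) {
  cat(sprintf(
    "Generative tree model M(k = %d, gamma = %.6g): actives X1..X%d, child X1(1)\n",
    x$k, x$gamma, x$k + 1))
  invisible(x)
}

#' Variable identifiers of a generative tree model
#'
#' Active predictors are labeled `"X1" ... "X{k+1}"`; the inactive child of
#' `X1` is labeled `"X1(1)"` and ordered after all actives (this order is the
#' tie-breaking order of [greedy_select()]).
#'
#' @param spec a [gtm_spec()].
#' @return Character vector of variable labels.
#' @export
gtm_variables <- function(spec) {
  stopifnot(inherits(spec, "gtm_spec"))
  c(paste0("X", seq_len(spec$k + 1)), "X1(1)")
}

.is_child <- function(v) v == "X1(1)"

# Validates labels and returns active indices (NA for the child).
.active_index <- function(spec, vars) {
  all_vars <- gtm_variables(spec)
  bad <- setdiff(vars, all_vars)
  if (length(bad)) {
    stop("unknown variable(s) for this model: ", paste(bad, collapse = ", "))
  }
  idx <- rep(NA_integer_, length(vars))
  act <- !.is_child(vars)
  idx[act] <- as.integer(sub("^X", "", vars[act]))
  idx
}

#' Class-conditional distribution of a variable subset
#'
#' Given `Y = y`, the subset `X_S` is Gaussian `N(y * mu, sigma)` with
#' `mu_i = gamma^(i-1)` for an active `X_i` and `mu = 1` for the child
#' `X1(1)`; `sigma` has unit diagonal for actives, 2 for the child
#' (its noise adds to that of `X1`), covariance 1 between `X1` and `X1(1)`,
#' and 0 elsewhere. Marginally, `X_S` is then the equal-weight mixture
#' `N(0, sigma)` / `N(mu, sigma)`.
#'
#' @param spec a [gtm_spec()].
#' @param vars character vector of variable labels (see [gtm_variables()]),
#'   without duplicates.
#' @return An object of class `"gtm_subset"` with fields `variables`, `mu`,
#'   `sigma`.
#' @examples
#' subset_distribution(gtm_spec(2, 2/3), c("X1", "X1(1)"))
#' @export
subset_distribution <- function(spec, vars) {
  stopifnot(inherits(spec, "gtm_spec"))
  if (length(vars) == 0) stop("'vars' must be nonempty")
  if (anyDuplicated(vars)) stop("duplicate variables in subset")
  idx <- .active_index(spec, vars)
  d <- length(vars)
  mu <- ifelse(is.na(idx), 1, spec$gamma^(idx - 1))
  sigma <- diag(ifelse(is.na(idx), 2, 1), d)
  i1 <- which(!is.na(idx) & idx == 1L)
  ic <- which(is.na(idx))
  if (length(i1) && length(ic)) {
    sigma[i1, ic] <- 1
    sigma[ic, i1] <- 1
  }
  dimnames(sigma) <- list(vars, vars)
  names(mu) <- vars
  structure(list(variables = vars, mu = mu, sigma = sigma),
            class = "gtm_subset")
}

#' Convert a subset distribution to a mixture specification
#'
#' @param x a `"gtm_subset"` from [subset_distribution()].
#' @return A [mixture_spec()] for the marginal law of the subset.
#' @export
as_mixture_spec <- function(x) {
  stopifnot(inherits(x, "gtm_subset"))
  mixture_spec(mu = unname(x$mu), sigma = unname(x$sigma))
}

# I(X_S, Y) for a subset of model variables (0 for the empty set).
.subset_label_mi <- function(spec, vars, cfg) {
  if (length(vars) == 0) return(0)
  mi_with_label(as_mixture_spec(subset_distribution(spec, vars)), cfg)
}

.check_candidate <- function(spec, j, S) {
  if (length(j) != 1) stop("'j' must be a single variable label")
  .active_index(spec, c(j, S))
  if (j %in% S) stop("candidate '", j, "' is already in the conditioning set")
}

#' Conditional mutual information score
#'
#' `I(X_j, Y | X_S) = I(X_{S + j}, Y) - I(X_S, Y)` by the chain rule, with
#' each joint mutual information evaluated exactly from the mixture law of
#' the subset. With an empty conditioning set this is the marginal relevance
#' `I(X_j, Y)`. CMI is nonnegative; quadrature round-off within 1e-9 below
#' zero is clamped to 0.
#'
#' @param spec a [gtm_spec()].
#' @param j candidate variable label, not in `S`.
#' @param S character vector of conditioning variable labels (may be empty).
#' @param cfg a [quad_config()].
#' @return Score in nats.
#' @examples
#' m <- gtm_spec(2, 2/3)
#' gtm_cmi(m, "X1")                 # 0.1114
#' gtm_cmi(m, "X3", c("X1", "X2"))  # 0.0176
#' gtm_cmi(m, "X1(1)", "X1")        # 0: X1 screens off the child
#' @export
gtm_cmi <- function(spec, j, S = character(), cfg = quad_config()) {
  .check_candidate(spec, j, S)
  v <- .subset_label_mi(spec, c(S, j), cfg) - .subset_label_mi(spec, S, cfg)
  if (v < 0) {
    if (v < -1e-9) {
      stop(sprintf("CMI computed as %.3g < 0: numerical failure", v))
    }
    v <- 0
  }
  v
}

#' Unconditional mutual information between two model variables
#'
#' `I(X_i, X_j)` evaluated as `H(X_i) + H(X_j) - H(X_i, X_j)` through
#' [subset_entropy_mi()] on the marginal mixture laws.
#'
#' @param spec a [gtm_spec()].
#' @param i,j distinct variable labels.
#' @param cfg a [quad_config()].
#' @return Mutual information in nats.
#' @export
gtm_pair_mi <- function(spec, i, j, cfg = quad_config()) {
  if (i == j) stop("'i' and 'j' must be distinct")
  sd_ij <- subset_distribution(spec, c(i, j))
  subset_entropy_mi(as_mixture_spec(subset_distribution(spec, i)),
                    as_mixture_spec(subset_distribution(spec, j)),
                    as_mixture_spec(sd_ij), cfg)
}

#' Class-conditional mutual information between two model variables
#'
#' Given `Y`, any subset is jointly Gaussian with the covariance of
#' [subset_distribution()] (the same on both strata), so
#' `I(X_i, X_j | Y) = -log(1 - rho^2) / 2` with `rho` the conditional
#' correlation. This is zero for every pair except `(X1, X1(1))`, whose
#' conditional correlation squared is 1/2, giving `log(2)/2`.
#'
#' @inheritParams gtm_pair_mi
#' @return Mutual information in nats.
#' @export
gtm_pair_mi_conditional <- function(spec, i, j) {
  if (i == j) stop("'i' and 'j' must be distinct")
  s <- subset_distribution(spec, c(i, j))$sigma
  0.5 * log(s[1, 1] * s[2, 2] / (s[1, 1] * s[2, 2] - s[1, 2]^2))
}

#' Joint mutual information score
#'
#' The JMI criterion scores a candidate by the average pairwise conditional
#' mutual information over the selected set:
#' `JMI(X_j | X_S) = mean_{i in S} I(X_j, Y | X_i)` (`form = "pairwise"`).
#' The equivalent interaction-information form
#' `I(X_j, Y) + mean_{i in S} [I(X_i, X_j | Y) - I(X_i, X_j)]`
#' (`form = "interaction"`) is provided as an independent route; the two agree
#' to quadrature accuracy. With an empty `S` the score is the marginal
#' relevance `I(X_j, Y)` (the average is undefined at `|S| = 0` and the first
#' greedy step ranks by marginal relevance).
#'
#' @inheritParams gtm_cmi
#' @param form which algebraic route to evaluate.
#' @return Score in nats.
#' @examples
#' m <- gtm_spec(2, 2/3)
#' gtm_jmi(m, "X1(1)", c("X1", "X2")) # 0.0266: JMI overrates the child
#' @export
gtm_jmi <- function(spec, j, S = character(), cfg = quad_config(),
                    form = c("pairwise", "interaction")) {
  form <- match.arg(form)
  .check_candidate(spec, j, S)
  if (length(S) == 0) return(.subset_label_mi(spec, j, cfg))
  if (form == "pairwise") {
    mean(vapply(S, function(i) gtm_cmi(spec, j, i, cfg), numeric(1)))
  } else {
    .subset_label_mi(spec, j, cfg) +
      mean(vapply(S, function(i) {
        gtm_pair_mi_conditional(spec, i, j) - gtm_pair_mi(spec, i, j, cfg)
      }, numeric(1)))
  }
}

#' Conditional infomax feature extraction score
#'
#' The CIFE criterion is the second-order truncation of the Moebius expansion
#' of CMI: marginal relevance plus the summed three-way interaction
#' informations with each selected variable,
#' `CIFE(X_j | X_S) = I(X_j, Y) + sum_{i in S} [I(X_i, X_j | Y) - I(X_i, X_j)]`.
#' Unlike CMI it can be negative (the redundancy sum is not down-weighted).
#' With empty `S` the score is `I(X_j, Y)`.
#'
#' @inheritParams gtm_cmi
#' @return Score in nats (may be negative).
#' @examples
#' m <- gtm_spec(2, 2/3)
#' gtm_cife(m, "X3", c("X1", "X2"))           # 0.0169
#' gtm_cife(m, "X1(1)", c("X1", "X2", "X3"))  # -0.0083
#' @export
gtm_cife <- function(spec, j, S = character(), cfg = quad_config()) {
  .check_candidate(spec, j, S)
  v <- .subset_label_mi(spec, j, cfg)
  for (i in S) {
    v <- v + gtm_pair_mi_conditional(spec, i, j) - gtm_pair_mi(spec, i, j, cfg)
  }
  v
}

#' Minimum-redundancy maximum-relevance score
#'
#' `mRMR(X_j | X_S) = I(X_j, Y) - mean_{i in S} I(X_i, X_j)`: the JMI
#' interaction form with the class-conditional redundancy terms dropped.
#' With empty `S` the score is `I(X_j, Y)`.
#'
#' @inheritParams gtm_cmi
#' @return Score in nats (may be negative).
#' @export
gtm_mrmr <- function(spec, j, S = character(), cfg = quad_config()) {
  .check_candidate(spec, j, S)
  v <- .subset_label_mi(spec, j, cfg)
  if (length(S) == 0) return(v)
  v - mean(vapply(S, function(i) gtm_pair_mi(spec, i, j, cfg), numeric(1)))
}

#' Gap between the CMI and CIFE scores
#'
#' `CMI - CIFE` for the same candidate and conditioning set: the part of the
#' Moebius expansion that the second-order truncation discards. For the child
#' candidate with `S = {X1, X2}` the gap equals `I(X1(1), X2)` exactly, which
#' is strictly positive — the canonical demonstration that CIFE is not CMI.
#'
#' @inheritParams gtm_cmi
#' @return Gap in nats.
#' @export
cmi_cife_gap <- function(spec, j, S = character(), cfg = quad_config()) {
  gtm_cmi(spec, j, S, cfg) - gtm_cife(spec, j, S, cfg)
}

# ---- Closed forms for S = {X1, ..., Xk} ------------------------------------
# These evaluate the criteria for the two interesting candidates, the last
# active X_{k+1} and the child X1(1), given that the first k actives are
# already selected. They are affine combinations of h evaluations and serve
# both as fast curve generators and as an independent route checked against
# the generic computations in the tests.

#' Closed-form CMI of the last active predictor
#'
#' `I(X_{k+1}, Y | X_1..X_k) = h(sqrt(sum_{i=0..k} gamma^(2i))) -
#' h(sqrt(sum_{i=0..k-1} gamma^(2i)))`, strictly positive for every `k`
#' because `h` is strictly increasing.
#'
#' @param spec a [gtm_spec()].
#' @param cfg a [quad_config()].
#' @return CMI in nats.
#' @export
gtm_cmi_closed <- function(spec, cfg = quad_config()) {
  stopifnot(inherits(spec, "gtm_spec"))
  g2 <- spec$gamma^(2 * (0:spec$k))
  h_mix(sqrt(sum(g2)), cfg) - h_mix(sqrt(sum(g2[-length(g2)])), cfg)
}

#' Closed-form JMI scores given the first k actives
#'
#' For `S = {X1..Xk}`:
#' `k * JMI(X_{k+1} | X_S) = sum_i [h(sqrt(g^(2k) + g^(2(i-1)))) - h(g^(i-1))]`
#' and
#' `k * JMI(X1(1) | X_S) = sum_{i >= 2} [h(sqrt(g^(2(i-1)) + 1/2)) - h(g^(i-1))]`
#' (zero for `k = 1`, since `X1` screens off the child).
#'
#' @param spec a [gtm_spec()].
#' @param candidate `"active"` for `X_{k+1}` or `"child"` for `X1(1)`.
#' @param cfg a [quad_config()].
#' @return Score in nats.
#' @export
gtm_jmi_closed <- function(spec, candidate = c("active", "child"),
                           cfg = quad_config()) {
  stopifnot(inherits(spec, "gtm_spec"))
  candidate <- match.arg(candidate)
  k <- spec$k
  g <- spec$gamma
  sep <- g^(0:(k - 1))               # separations of X1..Xk
  if (candidate == "active") {
    sum(h_mix(sqrt(g^(2 * k) + sep^2), cfg) - h_mix(sep, cfg)) / k
  } else {
    if (k == 1) return(0)
    s <- sep[-1]
    sum(h_mix(sqrt(s^2 + 0.5), cfg) - h_mix(s, cfg)) / k
  }
}

#' Closed-form CIFE scores given the first k actives
#'
#' For `S = {X1..Xk}`:
#' `CIFE(X_{k+1} | X_S) = (1 - k) * (h(g^k) - log(2 pi e)/2) +
#'  sum_i [h(sqrt(g^(2k) + g^(2(i-1)))) - h(g^(i-1))]`
#' and
#' `CIFE(X1(1) | X_S) = (1 - k) * (h(1/sqrt(2)) - log(2 pi e)/2) +
#'  sum_{i >= 2} [h(sqrt(g^(2(i-1)) + 1/2)) - h(g^(i-1))]`
#' (zero for `k = 1`: the X1 interaction term cancels the child's marginal
#' relevance exactly). The child's `(1 - k)` coefficient multiplies
#' `h(1/sqrt(2)) - log(2 pi e)/2 = I(X1(1), Y)` because both the pair
#' redundancy `I(X_i, X1(1))` and the marginal relevance of the child involve
#' its own class separation `1/sqrt(2)` after whitening its variance of 2.
#' At `gamma = 1` both scores are affine in `k` with negative slopes, so both
#' tend to minus infinity.
#'
#' @inheritParams gtm_jmi_closed
#' @return Score in nats.
#' @export
gtm_cife_closed <- function(spec, candidate = c("active", "child"),
                            cfg = quad_config()) {
  stopifnot(inherits(spec, "gtm_spec"))
  candidate <- match.arg(candidate)
  k <- spec$k
  g <- spec$gamma
  sep <- g^(0:(k - 1))
  if (candidate == "active") {
    (1 - k) * (h_mix(g^k, cfg) - .half_l2pe) +
      sum(h_mix(sqrt(g^(2 * k) + sep^2), cfg) - h_mix(sep, cfg))
  } else {
    if (k == 1) return(0)
    s <- sep[-1]
    (1 - k) * (h_mix(1 / sqrt(2), cfg) - .half_l2pe) +
      sum(h_mix(sqrt(s^2 + 0.5), cfg) - h_mix(s, cfg))
  }
}
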