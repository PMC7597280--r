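test_that("h_mix hits its analytic anchors and limits", {
  expect_equal(h_mix(0), L2PE_HALF, tolerance = 1e-10)
  # widely separated components carry one extra bit
  expect_equal(h_mix(50), L2PE_HALF + log(2), tolerance = 1e-9)
  expect_lt(abs(h_mix(1e-6) - L2PE_HALF), 1e-6)
  expect_lt(abs(h_mix(50) - (L2PE_HALF + log(2))), 1e-6)
  # Monte Carlo oracle for an interior point, plus the derived MI value
  mc <- mc_entropy(mixture_spec(1), n = 1e6, seed = 101)
  expect_lt(abs(h_mix(1) - mc$estimate), 3 * mc$std_error)
  expect_close(h_mix(1) - L2PE_HALF, 0.1114, 5e-5)
  expect_error(h_mix(-0.5), "nonnegative")
  expect_error(h_mix(NaN), "finite")
})

test_that("h_mix is strictly increasing and bounded on [0, 10]", {
  grid <- seq(0, 10, length.out = 200)
  hv <- h_mix(grid)
  expect_true(all(diff(hv) > 0))
  expect_true(all(hv >= L2PE_HALF - 1e-12))
  expect_true(all(hv <= L2PE_HALF + log(2) + 1e-12))
})

test_that("h_mix agrees with the symmetric-mixture quadrature route", {
  for (a in c(0.3, 1, 2.5, 6)) {
    expect_equal(h_mix(a), h_symmetric_oracle(a), tolerance = 1e-9)
  }
})

test_that("mixture_spec validates its invariants", {
  expect_error(mixture_spec(1, sigma = matrix(c(1, 0.5, 0.4, 2), 2)),
               "matrix")
  expect_error(mixture_spec(c(1, 1), sigma = matrix(c(1, 0.5, 0.4, 1), 2)),
               "symmetric")
  expect_error(mixture_spec(c(1, 1), sigma = matrix(c(1, 1, 1, 1), 2)),
               "singular|positive definite")
  expect_error(mixture_spec(1, weights = c(0.4, 0.6)), "equal weights")
  expect_error(mixture_spec(Inf), "finite")
})

test_that("mixture_entropy reduces to known cases and scales correctly", {
  expect_equal(mixture_entropy(mixture_spec(0)), L2PE_HALF, tolerance = 1e-10)
  expect_equal(mixture_entropy(mixture_spec(c(0, 0))), 2 * L2PE_HALF,
               tolerance = 1e-10)
  # rotation reduces (3,4) to separation 5 on one axis
  expect_equal(mixture_entropy(mixture_spec(c(3, 4))),
               h_mix(5) + L2PE_HALF, tolerance = 1e-10)
  mc <- mc_entropy(mixture_spec(c(3, 4)), n = 1e6, seed = 7)
  expect_lt(abs(mixture_entropy(mixture_spec(c(3, 4))) - mc$estimate),
            3 * mc$std_error)
  # scaling property: H(mu, sigma) = H(sigma^(-1/2) mu, I) + log det(sigma)/2
  set.seed(11)
  for (d in 1:3) {
    sig <- random_spd(d)
    mu <- rnorm(d)
    e <- eigen(sig, symmetric = TRUE)
    isqrt <- e$vectors %*% diag(1 / sqrt(e$values), d) %*% t(e$vectors)
    expect_equal(
      mixture_entropy(mixture_spec(mu, sig)),
      mixture_entropy(mixture_spec(drop(isqrt %*% mu))) +
        0.5 * determinant(sig, TRUE)$modulus[[1]],
      tolerance = 1e-9)
  }
})

test_that("mi_with_label matches its anchors and the entropy-difference route", {
  expect_equal(mi_with_label(mixture_spec(c(0, 0), random_spd(2))), 0,
               tolerance = 1e-10)
  expect_close(mi_with_label(mixture_spec(1)), 0.1114, 5e-5)
  expect_close(mi_with_label(mixture_spec(1, sigma = 2)), 0.0589, 5e-5)
  set.seed(22)
  for (d in 1:3) {
    sig <- random_spd(d)
    mu <- rnorm(d)
    spec <- mixture_spec(mu, sig)
    cond <- d * L2PE_HALF + 0.5 * determinant(sig, TRUE)$modulus[[1]]
    expect_equal(mi_with_label(spec), mixture_entropy(spec) - cond,
                 tolerance = 1e-9)
    expect_gte(mi_with_label(spec), 0)
    expect_lte(mi_with_label(spec), log(2))
  }
})

test_that("subset_entropy_mi handles independence, tree pairs and consistency", {
  # independent blocks: block-diagonal sigma, mu = 0
  sA <- mixture_spec(0)
  sB <- mixture_spec(c(0, 0), diag(c(2, 3)))
  sAB <- mixture_spec(c(0, 0, 0), diag(c(1, 2, 3)))
  expect_equal(subset_entropy_mi(sA, sB, sAB), 0, tolerance = 1e-8)
  # the (X1, X1(1)) pair of the tree model is strictly dependent
  pAB <- mixture_spec(c(1, 1), matrix(c(1, 1, 1, 2), 2))
  v <- subset_entropy_mi(mixture_spec(1), mixture_spec(1, 2), pAB)
  expect_gt(v, 0)
  # (X1, X2) pair at gamma = 2/3: explicit h combination
  g <- 2 / 3
  v12 <- subset_entropy_mi(mixture_spec(1), mixture_spec(g),
                           mixture_spec(c(1, g)))
  expect_equal(v12, h_mix(1) + h_mix(g) - h_mix(sqrt(1 + g^2)) - L2PE_HALF,
               tolerance = 1e-8)
  expect_error(
    subset_entropy_mi(mixture_spec(2), mixture_spec(g), mixture_spec(c(1, g))),
    "inconsistent")
})

test_that("interaction_information implements the alternating Moebius sum", {
  # p = 2 with independent standard normals: reduces to MI = 0
  expect_equal(
    interaction_information(c("1" = L2PE_HALF, "2" = L2PE_HALF,
                              "1,2" = 2 * L2PE_HALF)),
    0, tolerance = 1e-12)
  # tree-model triple (X1, X1(1), Y): II = -I(X1(1), Y)
  sig <- matrix(c(1, 1, 1, 2), 2)
  ents <- mixed_subset_entropies(c(1, 1), sig)
  expect_equal(interaction_information(ents),
               -mi_with_label(mixture_spec(1, 2)), tolerance = 1e-9)
  # random 3-way instance: Moebius route vs the defining MI decomposition
  set.seed(33)
  mu <- rnorm(2)
  sig2 <- random_spd(2)
  ents2 <- mixed_subset_entropies(mu, sig2)
  joint <- mi_with_label(mixture_spec(mu, sig2))
  m1 <- mi_with_label(mixture_spec(mu[1], sig2[1, 1]))
  m2 <- mi_with_label(mixture_spec(mu[2], sig2[2, 2]))
  expect_equal(interaction_information(ents2), joint - m1 - m2,
               tolerance = 1e-9)
  expect_error(interaction_information(ents2[-2]), "missing entropy")
  expect_error(interaction_information(c("1,2,3,4,5" = 1)), "p <= 4")
})

test_that("total_correlation follows its closed form", {
  expect_equal(total_correlation(mixture_spec(1.3)), 0, tolerance = 1e-8)
  expect_equal(total_correlation(mixture_spec(c(2, 0, 0))), 0,
               tolerance = 1e-8)
  tc <- total_correlation(mixture_spec(c(1, 1)))
  expect_equal(tc, 2 * h_mix(1) - h_mix(sqrt(2)) - L2PE_HALF,
               tolerance = 1e-10)
  # cross-check against the subset MI on the same mixture
  v <- subset_entropy_mi(mixture_spec(1), mixture_spec(1),
                         mixture_spec(c(1, 1)))
  expect_equal(tc, v, tolerance = 1e-8)
  expect_error(total_correlation(mixture_spec(c(1, 1), random_spd(2))),
               "identity covariance")
})

test_that("quad_config validates and round-trips through JSON", {
  expect_error(quad_config(abs_tol = 0), "positive")
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  jsonlite::write_json(list(abs_tol = 1e-11, truncation_halfwidth = 10), path,
                       auto_unbox = TRUE)
  cfg <- quad_config_from_json(path)
  expect_equal(cfg$abs_tol, 1e-11)
  expect_equal(cfg$truncation_halfwidth, 10)
  expect_equal(cfg$rel_tol, 1e-10)
  expect_equal(h_mix(1, cfg), h_mix(1), tolerance = 1e-9)
})
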