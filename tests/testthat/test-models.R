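test_that("DINA success probability follows the conjunctive rule", {
  expect_equal(p_correct_dina(c(1, 1), c(1, 1), s = 0.2, g = 0.1), 0.8)
  expect_equal(p_correct_dina(c(0, 1), c(1, 1), s = 0.2, g = 0.1), 0.1)
  # unrequired attributes are ignored
  expect_equal(p_correct_dina(c(1, 0), c(1, 0), s = 0.1, g = 0.2), 0.9)
  expect_error(p_correct_dina(c(1, 1), c(1, 1), s = 0.6, g = 0.5),
               "monotonicity")
  expect_error(dina_params(s = c(0.2, 0.7), g = c(0.1, 0.4)), "monotonicity")
})

test_that("G-DINA success probability sums active coefficients", {
  it13 <- gdina_item(c(0.20, 0.10, 0.15, 0.40), kstar = 2)
  expect_equal(p_correct_gdina(c(1, 1), it13), 0.85)
  expect_equal(p_correct_gdina(c(0, 0), it13), 0.20)
  expect_equal(p_correct_gdina(c(1, 0), it13), 0.30)
  expect_equal(p_correct_gdina(c(0, 1), it13), 0.35)
  # full profile reduced through q_row
  expect_equal(p_correct_gdina(c(1, 0, 1), it13, q_row = c(1, 1, 0)), 0.30)
  # invariant breach is rejected at construction
  expect_error(gdina_item(c(0.3, -0.2, 0.1, 0.2), kstar = 2), "monotonicity")
  expect_error(gdina_item(c(0.5, 0.4, 0.4, 0.2), kstar = 2), "monotonicity")
})

test_that("coefficient sweep order is intercept, mains, then interactions", {
  it <- gdina_item(rep(0.1, 8), kstar = 3, check = FALSE)
  expect_equal(it$labels, c("0", "1", "2", "3", "12", "13", "23", "123"))
})

test_that("a DINA item embeds exactly into G-DINA coefficients", {
  e <- dina_as_gdina(s = 0.2, g = 0.1, q_row = c(1, 1))
  expect_equal(e$delta, c(0.1, 0, 0, 0.7))
  e1 <- dina_as_gdina(s = 0.1, g = 0.1, q_row = c(1))
  expect_equal(e1$delta, c(0.1, 0.8))
  # round trip over all profiles for random valid (s, g), K up to 4
  set.seed(31)
  for (rep in 1:25) {
    K <- sample(1:4, 1)
    q_row <- rep(1L, K)
    g <- runif(1, 0.01, 0.6)
    s <- runif(1, 0.01, 0.99 - g)
    item <- dina_as_gdina(s, g, q_row)
    prof <- attribute_profiles(K)
    for (c in seq_len(nrow(prof))) {
      expect_equal(p_correct_gdina(prof[c, ], item),
                   p_correct_dina(prof[c, ], q_row, s, g))
    }
  }
})

test_that("marginal log-likelihood matches hand and brute-force values", {
  Q1 <- q_matrix(matrix(1, 1, 1))
  expect_equal(
    marginal_log_likelihood(matrix(1L, 1, 1), Q1, dina_params(0.2, 0.1),
                            pi = c(0.5, 0.5)),
    log(0.45))
  # noiseless limit: mass on the true class, (s, g) -> 0, matching response
  expect_equal(
    marginal_log_likelihood(matrix(1L, 1, 1), Q1, dina_params(1e-9, 1e-9),
                            pi = c(0, 1)),
    0, tolerance = 1e-6)
  # 3 x 2 toy equals the product over examinees of per-examinee mixtures
  set.seed(41)
  Q <- q_matrix(rbind(c(1, 0), c(0, 1)))
  Y <- matrix(rbinom(6, 1, 0.5), 3, 2)
  par <- dina_params(s = c(0.2, 0.15), g = c(0.1, 0.25))
  pi <- c(0.1, 0.2, 0.3, 0.4)
  prof <- attribute_profiles(2)
  brute <- 0
  for (i in 1:3) {
    mix <- 0
    for (c in 1:4) {
      lik <- 1
      for (j in 1:2) {
        f <- p_correct_dina(prof[c, ], Q[j, ], par$s[j], par$g[j])
        lik <- lik * ifelse(Y[i, j] == 1, f, 1 - f)
      }
      mix <- mix + pi[c] * lik
    }
    brute <- brute + log(mix)
  }
  expect_equal(marginal_log_likelihood(Y, Q, par, pi), brute)
})

test_that("likelihood is invariant under attribute relabelling", {
  set.seed(42)
  Q <- default_q(3)[c(1, 2, 3, 13, 25), ]
  sim <- simulate_cdm(I = 20, Q = Q, model = "dina", s = 0.2, g = 0.2)
  pi <- rep(1 / 8, 8)
  ll <- marginal_log_likelihood(sim$Y, sim$Q, sim$params, pi)
  perm <- c(3, 1, 2) # relabel attributes; uniform pi is permutation-symmetric
  ll_perm <- marginal_log_likelihood(sim$Y, q_matrix(unclass(sim$Q)[, perm]),
                                     sim$params, pi)
  expect_equal(ll, ll_perm)
})

test_that("valid G-DINA items are monotone over the whole lattice", {
  truth <- gdina_params(default_q(3), gdina_true_params())
  for (item in truth) {
    P <- slicecdm:::gdina_cell_probs(item)
    cov <- slicecdm:::lattice_covers(item$kstar)
    expect_true(all(P >= -1e-12 & P <= 1 + 1e-12))
    expect_true(all(P[cov[, 1] + 1] <= P[cov[, 2] + 1] + 1e-12))
  }
})

test_that("intercept truncation interval matches the K*=3 bound rule", {
  # P(100)=0.3, P(010)=0.4, P(001)=0.35 with delta0 = 0.1
  it <- gdina_item(c(0.1, 0.2, 0.3, 0.25, -0.2, -0.15, -0.2, 0.3), kstar = 3,
                   check = FALSE)
  expect_equal(slicecdm:::gdina_cell_probs(it)[c(2, 3, 5)], c(0.3, 0.4, 0.35))
  iv <- gdina_truncation_interval(it, "0")
  expect_equal(unname(iv), c(0, 0.3))
})

test_that("two-way truncation interval matches the cumulative bound rule", {
  it <- gdina_item(c(0.1, 0.2, 0.3, 0.25, -0.2, -0.15, -0.2, 0.3), kstar = 3,
                   check = FALSE)
  P <- slicecdm:::gdina_cell_probs(it)
  iv <- gdina_truncation_interval(it, "12")
  resid <- P[3 + 1] - it$delta[5] # cell (110), other active coefficients
  # cumulative-scale bounds: [max{P(100), P(010)}, P(111)]
  expect_equal(unname(iv["lower"]) + resid, max(P[2], P[3]))
  expect_equal(unname(iv["upper"]) + resid, P[8])
})

test_that("truncation interval equals the exhaustive-grid feasible set", {
  it <- gdina_item(c(0.2, 0.1, 0.15, 0), kstar = 2)
  iv <- gdina_truncation_interval(it, "12")
  expect_equal(unname(iv), c(-0.10, 0.55))
  # grid oracle: scan candidate values, accept iff the full partial order
  # (with all other cells held fixed) is satisfied
  feasible <- function(item, target, x) {
    P <- slicecdm:::gdina_cell_probs(item)
    r <- item$subsets[target]
    P[r + 1] <- P[r + 1] - item$delta[target] + x
    cov <- slicecdm:::lattice_covers(item$kstar)
    all(P >= -1e-12, P <= 1 + 1e-12,
        P[cov[, 1] + 1] <= P[cov[, 2] + 1] + 1e-12)
  }
  grid <- seq(-0.5, 1, by = 0.01)
  ok <- vapply(grid, function(x) feasible(it, 4L, x), logical(1))
  expect_equal(range(grid[ok]), c(-0.10, 0.55))
  # endpoint sharpness at +-1e-9
  set.seed(7)
  for (target in 1:4) {
    iv <- gdina_truncation_interval(it, target)
    inside <- runif(5, iv["lower"], iv["upper"])
    for (x in inside) expect_true(feasible(it, target, x))
    expect_false(feasible(it, target, iv["lower"] - 1e-9))
    expect_false(feasible(it, target, iv["upper"] + 1e-9))
  }
})

test_that("lattice probabilities round trip through the coefficient map", {
  set.seed(11)
  for (kstar in 1:3) {
    P <- slicecdm:::init_monotone_cells(kstar)
    subsets <- slicecdm:::item_subsets(kstar)
    delta <- slicecdm:::cells_to_delta(P, subsets)
    it <- gdina_item(delta, kstar)
    expect_equal(slicecdm:::gdina_cell_probs(it), P)
  }
})
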