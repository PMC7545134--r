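test_that("auxiliary draws live strictly inside their slices", {
  set.seed(21)
  Y <- rbind(c(1L, 0L), c(0L, 1L))
  f <- rbind(c(0.5, 0.3), c(0.3, 0.5))
  for (r in 1:20) {
    aux <- sample_auxiliary(Y, f)
    expect_true(all(aux$U[Y == 1] > 0 & aux$U[Y == 1] < f[Y == 1]))
    expect_true(all(aux$V[Y == 0] > 0 & aux$V[Y == 0] < (1 - f)[Y == 0]))
    expect_true(all(is.na(aux$U[Y == 0])) && all(is.na(aux$V[Y == 1])))
  }
  # empirical mean of U at f = 0.8 is f/2
  Y1 <- matrix(1L, 1e5, 1)
  aux <- sample_auxiliary(Y1, matrix(0.8, 1e5, 1))
  expect_lt(abs(mean(aux$U) - 0.4), 3 * (0.8 / sqrt(12)) / sqrt(1e5))
})

test_that("DINA slip bounds reproduce the truncated-conditional formula", {
  # two mastery examinees: one non-responder with V = 0.10, one responder
  # with U = 0.60; g = 0.30
  Y <- matrix(c(0L, 1L), 2, 1)
  aux <- list(U = matrix(c(NA, 0.60), 2, 1), V = matrix(c(0.10, NA), 2, 1))
  b <- dina_item_bounds(1, "slip", Y, aux, eta = c(1L, 1L), s = 0.2, g = 0.30)
  expect_equal(unname(b), c(0.10, 0.40))
  # no mastery examinees: trivial bounds (0, 1 - g)
  b0 <- dina_item_bounds(1, "slip", Y, aux, eta = c(0L, 0L), s = 0.2, g = 0.30)
  expect_equal(unname(b0), c(0, 0.70))
  # guessing mirror over non-mastery examinees
  bg <- dina_item_bounds(1, "guess", Y, aux, eta = c(0L, 0L), s = 0.2, g = 0.1)
  expect_equal(unname(bg), c(0.60, min(1 - 0.2, 1 - 0.10)))
})

test_that("values drawn inside the DINA bounds preserve every slice", {
  set.seed(33)
  Q <- q_matrix(rbind(c(1, 0), c(0, 1), c(1, 1)))
  for (r in 1:20) {
    sim <- simulate_cdm(I = 15, Q = Q, model = "dina", s = 0.2, g = 0.2)
    par <- sim$params
    eta_cls <- slicecdm:::eta_matrix(Q)
    f <- slicecdm:::dina_class_probs(Q, par$s, par$g)[sim$alpha, ]
    aux <- sample_auxiliary(sim$Y, f)
    for (j in 1:3) {
      eta_j <- eta_cls[sim$alpha, j]
      bs <- dina_item_bounds(j, "slip", sim$Y, aux, eta_j, par$s[j], par$g[j])
      s_new <- runif(1, bs["L"], bs["R"])
      bg <- dina_item_bounds(j, "guess", sim$Y, aux, eta_j, s_new, par$g[j])
      g_new <- runif(1, bg["L"], bg["R"])
      expect_lt(s_new + g_new, 1)
      f_new <- ifelse(eta_j == 1, 1 - s_new, g_new)
      yj <- sim$Y[, j]
      expect_true(all(aux$U[yj == 1, j] < f_new[yj == 1]))
      expect_true(all(aux$V[yj == 0, j] < 1 - f_new[yj == 0]))
    }
  }
})

test_that("G-DINA bounds intersect data and monotonicity constraints", {
  # single examinee at the cell of coefficient "1": Y = 1, U = 0.25,
  # f = 0.30 with target coefficient 0.10 -> data lower bound 0.05
  Q <- q_matrix(rbind(c(1, 0), c(0, 1), c(1, 1)))
  params <- gdina_params(Q, list(c(0.2, 0.6), c(0.2, 0.6),
                                 c(0.20, 0.10, 0.15, 0.40)))
  # examinee masters attribute 1 only: class 2; item 3 reduced cell = (1,0)
  Y <- matrix(c(1L, 1L, 1L), 1, 3)
  aux <- list(U = matrix(c(0.5, 0.5, 0.25), 1, 3),
              V = matrix(NA_real_, 1, 3))
  b <- gdina_item_bounds(3, "1", Y, aux, alpha = 2L, Q, params)
  mono <- gdina_truncation_interval(params[[3]], "1")
  expect_equal(unname(b["L"]), max(0.25 - 0.20, mono["lower"], 0.05))
  expect_equal(unname(b["R"]), unname(mono["upper"]))
  # nobody at the target cell: bounds equal the monotonicity interval
  b12 <- gdina_item_bounds(3, "12", Y, aux, alpha = 2L, Q, params)
  expect_equal(unname(b12), unname(gdina_truncation_interval(params[[3]], "12")))
})

test_that("draws inside the G-DINA bounds keep all constraints satisfied", {
  set.seed(55)
  Q <- default_q(3)[c(1, 2, 3, 13, 25), ]
  for (r in 1:10) {
    sim <- simulate_cdm(I = 20, Q = Q, model = "gdina",
                        params = gdina_params(Q, list(
                          c(0.1, 0.7), c(0.1, 0.7), c(0.1, 0.7),
                          c(0.2, 0.1, 0.15, 0.4),
                          c(0.2, 0.1, 0.1, 0.1, 0.05, -0.05, 0.05, 0.15))))
    params <- sim$params
    f <- slicecdm:::gdina_class_probs(Q, params)[sim$alpha, ]
    aux <- sample_auxiliary(sim$Y, f)
    cellmat <- slicecdm:::reduced_cell_matrix(Q)
    for (j in seq_len(nrow(Q))) {
      item <- params[[j]]
      for (target in seq_along(item$subsets)) {
        b <- gdina_item_bounds(j, target, sim$Y, aux, sim$alpha, Q, params)
        expect_lt(b["L"], b["R"] + 1e-12)
        x <- runif(1, b["L"], b["R"])
        item2 <- gdina_set_coefficient(item, target, x)
        # monotonicity intact
        expect_true(slicecdm:::check_monotone_item(item2, tol = 1e-9)$ok)
        # auxiliary constraints intact for examinees at the moved cell
        at <- cellmat[sim$alpha, j] == item$subsets[target]
        f_new <- slicecdm:::gdina_cell_probs(item2)[cellmat[sim$alpha, j] + 1]
        yj <- sim$Y[, j]
        expect_true(all(aux$U[at & yj == 1, j] < f_new[at & yj == 1]))
        expect_true(all(aux$V[at & yj == 0, j] < 1 - f_new[at & yj == 0]))
      }
    }
  }
})

test_that("pi update is the conjugate Dirichlet with closed-form mean", {
  set.seed(61)
  # phi0 = 1, counts (3, 1): posterior mean (4/6, 2/6)
  alpha <- c(1L, 1L, 1L, 2L)
  draws <- t(replicate(1e5, update_pi(alpha, phi0 = 1, C = 2)))
  se <- sqrt(4 / 6 * 2 / 6 / 7) / sqrt(1e5)
  expect_lt(max(abs(colMeans(draws) - c(4 / 6, 2 / 6))), 4 * se)
  # no data: prior Dirichlet
  prior_draws <- t(replicate(2e4, update_pi(integer(0), phi0 = 1, C = 3)))
  expect_lt(max(abs(colMeans(prior_draws) - 1 / 3)), 0.006)
})

test_that("class membership update draws from the stated posterior", {
  Q1 <- q_matrix(matrix(1, 1, 1))
  par <- dina_params(0.2, 0.1)
  p <- update_alpha(1L, Q1, par, pi = c(0.5, 0.5), probs = TRUE)
  expect_equal(p[2], 8 / 9) # mastery class posterior
  # degenerate pi always returns its class
  set.seed(71)
  draws <- replicate(50, update_alpha(1L, Q1, par, pi = c(1, 0)))
  expect_true(all(draws == 1L))
  # empirical frequencies match brute-force enumeration on a J=3, K=2 toy
  Q <- q_matrix(rbind(c(1, 0), c(0, 1), c(1, 1)))
  par3 <- dina_params(s = c(0.2, 0.1, 0.15), g = c(0.1, 0.2, 0.25))
  pi4 <- c(0.4, 0.3, 0.2, 0.1)
  y <- c(1L, 0L, 1L)
  prof <- attribute_profiles(2)
  brute <- vapply(1:4, function(c) {
    lik <- 1
    for (j in 1:3) {
      f <- p_correct_dina(prof[c, ], Q[j, ], par3$s[j], par3$g[j])
      lik <- lik * ifelse(y[j] == 1, f, 1 - f)
    }
    pi4[c] * lik
  }, numeric(1))
  brute <- brute / sum(brute)
  freq <- tabulate(replicate(2e4, update_alpha(y, Q, par3, pi4)), nbins = 4) / 2e4
  expect_lt(max(abs(freq - brute)), 3 * sqrt(max(brute) / 2e4) + 0.005)
})
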