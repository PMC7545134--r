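test_that("class memberships follow the categorical law", {
  set.seed(51)
  # degenerate pi puts everyone in one class
  expect_true(all(gen_attributes(50, c(0, 1, 0, 0)) == 2L))
  # uniform pi over K = 5: each class frequency near 1/32 = 0.03125
  pi32 <- rep(1 / 32, 32)
  a <- gen_attributes(1e5, pi32)
  freq <- tabulate(a, 32) / 1e5
  expect_lt(max(abs(freq - 0.03125)), 4 * sqrt(0.03125 * (1 - 0.03125) / 1e5))
  # chi-square goodness of fit at alpha = 0.01 for a non-uniform pi
  pi4 <- c(0.1, 0.2, 0.3, 0.4)
  a4 <- gen_attributes(1e5, pi4)
  expect_gt(chisq.test(tabulate(a4, 4), p = pi4)$p.value, 0.01)
})

test_that("fixed and correlated item-parameter generators match their laws", {
  p <- gen_item_params(30, "fixed", s = 0.1, g = 0.1)
  expect_equal(p$s, rep(0.1, 30))
  expect_equal(p$g, rep(0.1, 30))
  set.seed(52)
  big <- gen_item_params(1e5, "correlated")
  # logit-scale moments of the generating law (rejection of s + g >= 1 is
  # too rare to shift them at this tolerance)
  lg <- log(big$g / (1 - big$g)); ls <- log(big$s / (1 - big$s))
  expect_lt(abs(mean(lg) - (-2.564)), 0.02)
  expect_lt(abs(mean(ls) - (-1.995)), 0.02)
  expect_lt(abs(var(lg) - 1.233), 0.03)
  expect_lt(abs(var(ls) - 0.571), 0.015)
  expect_lt(abs(cor(lg, ls) - (-0.415 / sqrt(1.233 * 0.571))), 0.02)
  # implied probability-scale means (negatively correlated, low noise)
  expect_lt(abs(mean(big$g) - 0.104), 0.01)
  expect_lt(abs(mean(big$s) - 0.141), 0.01)
  expect_true(all(big$s + big$g < 1))
})

test_that("responses are Bernoulli draws from the class success matrix", {
  set.seed(53)
  Q <- default_q(3)[c(1, 2, 3, 13, 25), ]
  # deterministic at (near) zero noise
  eta <- slicecdm:::eta_matrix(Q)
  alpha <- sample.int(8, 50, replace = TRUE)
  par0 <- dina_params(rep(1e-12, 5), rep(1e-12, 5))
  expect_equal(unname(gen_responses(alpha, Q, par0)), unname(eta[alpha, ]))
  # cell-wise empirical means match f
  par <- dina_params(rep(0.2, 5), rep(0.15, 5))
  alpha1 <- rep(8L, 4000) # full mastery
  Y <- gen_responses(alpha1, Q, par)
  expect_lt(max(abs(colMeans(Y) - 0.8)), 4 * sqrt(0.16 / 4000))
  # G-DINA: full-mastery success on an item with a negative interaction
  gpar <- gdina_params(Q, list(c(0.1, 0.7), c(0.1, 0.7), c(0.1, 0.7),
                               c(0.2, 0.3, 0.3, -0.05),
                               c(0.2, 0.1, 0.1, 0.1, 0.05, -0.05, 0.05, 0.15)))
  Yg <- gen_responses(rep(8L, 4000), Q, gpar)
  expect_lt(abs(mean(Yg[, 4]) - 0.75), 4 * sqrt(0.1875 / 4000))
})

test_that("recovery study scores an oracle estimator as exact", {
  cond <- list(I = 40, Q = default_q(3)[c(1:6, 13, 25), ], model = "dina",
               s = 0.1, g = 0.1, label = "oracle")
  rep <- run_study(list(cond), replications = 3, seed = 5,
                   fit_fun = function(sim, seed) {
                     slicecdm:::truth_vector(sim$params, sim$pi, sim$Q)
                   })
  expect_true(all(rep$bias == 0))
  expect_true(all(rep$rmse == 0))
})

test_that("recovery aggregates satisfy the error-decomposition identity", {
  set.seed(56)
  cond <- list(I = 40, Q = default_q(3)[c(1:6, 13, 25), ], model = "dina",
               s = 0.15, g = 0.15, label = "noisy")
  # noisy pseudo-estimator keeps the runtime negligible while exercising
  # the aggregation path
  rep <- run_study(list(cond), replications = 4, seed = 6,
                   fit_fun = function(sim, seed) {
                     tv <- slicecdm:::truth_vector(sim$params, sim$pi, sim$Q)
                     tv + rnorm(length(tv), sd = 0.03)
                   })
  expect_true(all(rep$rmse >= abs(rep$bias)))
  expect_equal(rep$rmse^2, rep$bias^2 + rep$var, tolerance = 1e-12)
})

test_that("the study driver is reproducible and improves with sample size", {
  Q <- default_q(3)[c(1:6, 13, 25), ]
  conds <- list(
    list(I = 60, Q = Q, model = "dina", s = 0.1, g = 0.1, label = "small"),
    list(I = 600, Q = Q, model = "dina", s = 0.1, g = 0.1, label = "large"))
  r1 <- run_study(conds, replications = 3, n_iter = 1500, burn_in = 750, seed = 77)
  r2 <- run_study(conds, replications = 3, n_iter = 1500, burn_in = 750, seed = 77)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  rm_s <- function(r, lab) r$rmse[r$condition == lab & r$group == "s"]
  expect_lt(rm_s(r1, "large"), rm_s(r1, "small"))
  p <- autoplot(r1)
  expect_s3_class(p, "ggplot")
})
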