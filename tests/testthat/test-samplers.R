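test_that("identical seeds give bit-identical chains", {
  set.seed(1)
  sim <- simulate_cdm(I = 40, Q = default_q(3)[c(1:6, 13, 25), ], model = "dina")
  f1 <- fit_cdm(sim$Y, sim$Q, n_iter = 400, burn_in = 200, seed = 123)
  f2 <- fit_cdm(sim$Y, sim$Q, n_iter = 400, burn_in = 200, seed = 123)
  expect_identical(cdm_draws(f1), cdm_draws(f2))
  expect_identical(f1$chains[[1]]$alpha_draws, f2$chains[[1]]$alpha_draws)
  g1 <- fit_cdm(sim$Y, sim$Q, model = "gdina", n_iter = 300, burn_in = 100,
                seed = 9, prior = prior_spec("flat"))
  g2 <- fit_cdm(sim$Y, sim$Q, model = "gdina", n_iter = 300, burn_in = 100,
                seed = 9, prior = prior_spec("flat"))
  expect_identical(cdm_draws(g1), cdm_draws(g2))
})

test_that("near-noiseless data concentrate the posterior at the truth", {
  set.seed(2)
  Q <- default_q(3)[c(1:6, 13:15), ]
  C <- 8L
  alpha <- sample.int(C, 150, replace = TRUE)
  eta <- slicecdm:::eta_matrix(Q)
  Y <- eta[alpha, ] # s = g = 0 deterministic responses
  fit <- fit_cdm(Y, Q, n_iter = 800, burn_in = 400, seed = 4)
  e <- eap_se(fit)$parameters
  expect_lt(max(e$eap[grepl("^s\\[|^g\\[", e$term)]), 0.06)
  # identified patterns recover the generating class
  post <- eap_se(fit)$class_membership
  expect_gt(mean(max.col(post) == alpha), 0.95)
})

test_that("all samplers keep every retained draw in the monotone region", {
  set.seed(3)
  sim <- simulate_cdm(I = 120, Q = default_q(3)[c(1:6, 13, 16, 25), ],
                      model = "dina", s = 0.2, g = 0.2)
  for (smp in c("slice", "mh", "gibbs")) {
    fit <- fit_cdm(sim$Y, sim$Q, sampler = smp, n_iter = 600, burn_in = 200,
                   seed = 5, proposal_sd = 1, check_aux = (smp == "slice"))
    counters <- slicecdm:::warning_counters(fit)
    expect_equal(unname(counters["monotonicity_violations"]), 0L)
    expect_equal(unname(counters["aux_violations"]), 0L)
    d <- cdm_draws(fit)
    J <- nrow(sim$Q)
    s_cols <- d[, paste0("s[", 1:J, "]")]
    g_cols <- d[, paste0("g[", 1:J, "]")]
    expect_true(all(s_cols + g_cols < 1))
    expect_true(all(d > 0))
  }
})

test_that("the G-DINA chain satisfies the partial order at every draw", {
  set.seed(6)
  Q <- default_q(3)[c(1:6, 13, 25), ]
  params <- gdina_params(Q, c(rep(list(c(0.1, 0.7)), 6),
                              list(c(0.2, 0.1, 0.15, 0.4)),
                              list(c(0.2, 0.1, 0.1, 0.1, 0.05, -0.05, 0.05, 0.15))))
  sim <- simulate_cdm(I = 150, Q = Q, model = "gdina", params = params)
  fit <- fit_cdm(sim$Y, sim$Q, model = "gdina", n_iter = 500, burn_in = 200,
                 seed = 8, prior = prior_spec("flat"), check_aux = TRUE)
  counters <- slicecdm:::warning_counters(fit)
  expect_equal(unname(counters["monotonicity_violations"]), 0L)
  expect_equal(unname(counters["aux_violations"]), 0L)
  # re-verify a sample of retained draws in R
  d <- cdm_draws(fit)
  kstar <- rowSums(Q)
  for (r in seq(1, nrow(d), by = 37)) {
    params_r <- slicecdm:::draw_to_params(fit, d[r, ])
    for (item in params_r) {
      expect_true(slicecdm:::check_monotone_item(item, tol = 1e-9)$ok)
    }
  }
})

test_that("MH and Gibbs baselines require the DINA model and beta prior", {
  set.seed(10)
  sim <- simulate_cdm(I = 20, Q = default_q(3)[c(1:6, 25), ], model = "dina")
  expect_error(fit_cdm(sim$Y, sim$Q, model = "gdina", sampler = "mh"),
               "DINA model only")
  expect_error(fit_cdm(sim$Y, sim$Q, sampler = "gibbs",
                       prior = prior_spec("normal")), "beta prior")
  # non-identifiable Q warns but still runs
  Qbad <- q_matrix(rbind(c(1, 0), c(1, 1), c(1, 1), c(0, 1)))
  simb <- simulate_cdm(I = 20, Q = Qbad, model = "dina")
  expect_warning(fit_cdm(simb$Y, Qbad, n_iter = 50, burn_in = 10, seed = 2),
                 "C1")
})

test_that("dimension and type errors are caught before sampling", {
  sim <- simulate_cdm(I = 10, Q = default_q(3)[c(1:6, 25), ], model = "dina")
  expect_error(fit_cdm(sim$Y[, 1:3], sim$Q), "ncol")
  Ybad <- sim$Y; Ybad[1, 1] <- 3L
  expect_error(fit_cdm(Ybad, sim$Q), "binary")
})
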