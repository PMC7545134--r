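# Exact DINA posterior on a small data set, by exhaustive enumeration over
# all C^I latent class assignments combined with closed-form/quadrature
# integrals. Independent of the samplers: the only shared ingredient is the
# model definition itself.
#
# Prior structure matched to the samplers' defaults: s_j, g_j iid
# Uniform(0,1) restricted to s_j + g_j < 1; pi ~ Dirichlet(phi0, ..., phi0).
#
# Per-item integrals over the triangle {s + g < 1}: the inner g-integral is
# an incomplete Beta function (exact); the outer s-integral uses a midpoint
# rule on a fine grid, so the only numerical error is O(h^2) on a smooth
# integrand.
exact_dina_posterior <- function(Y, Q, phi0 = 1, ngrid = 2000) {
  I <- nrow(Y); J <- ncol(Y)
  K <- ncol(Q); C <- 2L^K
  eta <- slicecdm:::eta_matrix(slicecdm::q_matrix(Q))
  stopifnot(C^I <= 3e5) # keep the enumeration honest and feasible
  assign_mat <- as.matrix(expand.grid(rep(list(seq_len(C)), I)))
  A <- nrow(assign_mat)

  sg <- (seq_len(ngrid) - 0.5) / ngrid # midpoints on (0,1)
  h <- 1 / ngrid
  keys_of <- function(n1, k1, k0) (n1 * (I + 1) + k1) * (I + 1) + k0
  logm <- matrix(0, A, J)
  Es <- matrix(0, A, J)
  Eg <- matrix(0, A, J)
  for (j in seq_len(J)) {
    etaj <- eta[, j]
    M <- matrix(etaj[assign_mat], A, I)
    n1 <- rowSums(M)
    k1 <- as.vector(M %*% Y[, j])
    k0 <- as.vector((1 - M) %*% Y[, j])
    key <- keys_of(n1, k1, k0)
    uk <- unique(key)
    tab <- matrix(0, length(uk), 3,
                  dimnames = list(NULL, c("logm", "Es", "Eg")))
    for (u in seq_along(uk)) {
      kk <- uk[u]
      k0u <- kk %% (I + 1); rest <- kk %/% (I + 1)
      k1u <- rest %% (I + 1); n1u <- rest %/% (I + 1)
      n0u <- I - n1u
      a <- (1 - sg)^k1u * sg^(n1u - k1u) # slip factor over the s grid
      # inner integral over g in (0, 1 - s): incomplete Beta, exact
      G0 <- beta(k0u + 1, n0u - k0u + 1) * stats::pbeta(1 - sg, k0u + 1, n0u - k0u + 1)
      G1 <- beta(k0u + 2, n0u - k0u + 1) * stats::pbeta(1 - sg, k0u + 2, n0u - k0u + 1)
      m <- sum(a * G0) * h
      tab[u, "logm"] <- log(m)
      tab[u, "Es"] <- sum(a * sg * G0) * h / m
      tab[u, "Eg"] <- sum(a * G1) * h / m
    }
    idx <- match(key, uk)
    logm[, j] <- tab[idx, "logm"]
    Es[, j] <- tab[idx, "Es"]
    Eg[, j] <- tab[idx, "Eg"]
  }
  n_c <- vapply(seq_len(C), function(c) rowSums(assign_mat == c), numeric(A))
  logw <- rowSums(logm) + rowSums(lgamma(phi0 + n_c)) # Dirichlet-multinomial kernel
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  list(
    s = colSums(w * Es),
    g = colSums(w * Eg),
    pi = colSums(w * (phi0 + n_c)) / (C * phi0 + I))
}

# Batch-means Monte Carlo standard error (autocorrelation-robust for the
# chain lengths used here).
mcse_batch <- function(x, n_batch = 50) {
  n <- length(x)
  bs <- floor(n / n_batch)
  bm <- vapply(seq_len(n_batch), function(b) mean(x[((b - 1) * bs + 1):(b * bs)]),
               numeric(1))
  stats::sd(bm) / sqrt(n_batch)
}

# Fixed small DINA toy shared by the oracle-equivalence checks.
oracle_toy <- function(seed = 202) {
  set.seed(seed)
  Q <- slicecdm::q_matrix(rbind(c(1, 0), c(0, 1), c(1, 0), c(0, 1), c(1, 1)))
  sim <- slicecdm::simulate_cdm(I = 8, Q = Q, model = "dina", s = 0.15, g = 0.15)
  sim
}

# RMSE of EAP estimates per parameter group for one fit against the truth.
rmse_groups <- function(fit, sim) {
  e <- slicecdm::eap_se(fit)$parameters
  truth <- slicecdm:::truth_vector(sim$params, sim$pi, sim$Q)
  err <- e$eap - truth[e$term]
  tapply(err, slicecdm:::term_groups(e$term), function(x) sqrt(mean(x^2)))
}

# The uniform-prior slice study on the sampler-comparison condition is used
# by several acceptance checks; run it once and cache the report.
.acceptance_cache <- new.env(parent = emptyenv())
slice_uniform_study <- function() {
  if (is.null(.acceptance_cache$slice_uniform)) {
    cond <- list(I = 500, Q = slicecdm::default_q(5), model = "dina",
                 s = 0.1, g = 0.1, label = "low-noise")
    .acceptance_cache$slice_uniform <- slicecdm::run_study(
      list(cond), sampler = "slice", replications = 10,
      n_iter = 5000, burn_in = 2500, seed = 2024)
  }
  .acceptance_cache$slice_uniform
}
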