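#' Fit a cognitive diagnosis model by MCMC
#'
#' The workhorse estimator. The default sampler is the slice-within-Gibbs
#' scheme: (1) uniform auxiliary variables are drawn under each response's
#' current success probability; (2) each item parameter is drawn exactly
#' from its full conditional, which the augmentation reduces to the prior
#' truncated to an explicit interval that also encodes the monotonicity
#' (identifiability) constraints; (3) latent classes and class
#' probabilities are refreshed by their multinomial/Dirichlet conditionals.
#' Two DINA baselines are included: a random-walk Metropolis-Hastings
#' sampler with truncated-normal proposals (`sampler = "mh"`) and the
#' conjugate Beta Gibbs sampler (`sampler = "gibbs"`); both share Step 3
#' with the slice sampler.
#'
#' @param Y Binary `I x J` response matrix.
#' @param Q A [q_matrix()] (`J x K`).
#' @param model `"dina"` or `"gdina"`. The MH and Gibbs baselines support
#'   the DINA model only; the G-DINA model uses the slice sampler with a
#'   flat coefficient prior by default.
#' @param sampler `"slice"`, `"mh"`, or `"gibbs"`.
#' @param prior A [prior_spec()] for the item parameters (slip and, unless
#'   `prior_g` is given, guessing). Default Beta(1, 1), i.e. uniform.
#'   For `"gibbs"` this must be a `"beta"` prior (conjugacy).
#' @param prior_g Optional separate [prior_spec()] for guessing parameters.
#' @param proposal_sd Standard deviation of the MH truncated-normal
#'   proposal. `1` is the large-step comparison case; `0.001` is the
#'   small step whose slow convergence the comparison study documents
#'   (`sqrt(0.001)` — the same quantity read as a variance — is instead
#'   close to optimally tuned for these posteriors; see the vignette).
#' @param n_iter,burn_in,thin Chain length, burn-in, thinning. Defaults
#'   20,000 / 10,000 / 1.
#' @param n_chains Number of chains; each chain is initialized
#'   independently from the prior restricted to the monotone region
#'   (overdispersed starts).
#' @param seed Optional integer seed; the run is exactly reproducible
#'   given (`seed`, configuration).
#' @param store_alpha Retain per-iteration latent class draws (default
#'   `TRUE`); class-membership tallies are always kept.
#' @param check_aux Re-verify the auxiliary constraints after every item
#'   update (costly audit; counts violations, which must be zero).
#' @return An object of class `cdm_fit`; see [tidy.cdm_fit()],
#'   [glance.cdm_fit()], [eap_se()], [psrf()], [dic()].
#' @examples
#' set.seed(7)
#' sim <- simulate_cdm(I = 60, Q = default_q(3)[1:6, ], model = "dina",
#'                     s = rep(0.1, 6), g = rep(0.1, 6))
#' fit <- fit_cdm(sim$Y, sim$Q, n_iter = 300, burn_in = 150, seed = 1)
#' tidy(fit)
#' @export
fit_cdm <- function(Y, Q, model = c("dina", "gdina"),
                    sampler = c("slice", "mh", "gibbs"),
                    prior = prior_spec("beta", shape1 = 1, shape2 = 1),
                    prior_g = NULL, proposal_sd = 1,
                    n_iter = 20000, burn_in = floor(n_iter / 2), thin = 1,
                    n_chains = 1, seed = NULL, store_alpha = TRUE,
                    check_aux = FALSE) {
  model <- match.arg(model)
  sampler <- match.arg(sampler)
  Y <- check_binary_matrix(Y, "Y")
  Q <- q_matrix(Q)
  if (ncol(Y) != nrow(Q)) stop("ncol(Y) must equal nrow(Q)", call. = FALSE)
  if (model == "gdina" && sampler != "slice") {
    stop("the MH and Gibbs baselines are implemented for the DINA model only",
         call. = FALSE)
  }
  if (sampler == "gibbs" && prior$family != "beta") {
    stop("the conjugate Gibbs baseline requires a beta prior", call. = FALSE)
  }
  id <- check_identifiability(Q)
  if (!id$pass) {
    warning("Q-matrix fails completeness condition C1; parameters may not be identified")
  }
  stopifnot(n_iter >= 1, burn_in >= 0, burn_in < n_iter, thin >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(prior_g)) prior_g <- prior
  if (model == "gdina" && missing(prior)) prior <- prior_spec("flat")

  I <- nrow(Y); J <- ncol(Y); K <- ncol(Q); C <- 2L^K
  chains <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    init <- init_chain(model, Q, I, prior, prior_g)
    chains[[ch]] <- run_engine(Y, Q, model, sampler, prior, prior_g,
                               proposal_sd, n_iter, burn_in, thin, init,
                               store_alpha, check_aux)
  }
  structure(
    list(chains = chains, model = model, sampler = sampler, Q = Q,
         dims = c(I = I, J = J, K = K, C = C),
         prior = prior, prior_g = prior_g, proposal_sd = proposal_sd,
         config = list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                       n_chains = n_chains, seed = seed),
         identifiability = id),
    class = "cdm_fit")
}

# Overdispersed initial state drawn from the prior restricted to the
# monotone region.
init_chain <- function(model, Q, I, prior, prior_g) {
  J <- nrow(Q); K <- ncol(Q); C <- 2L^K
  if (model == "dina") {
    draw01 <- function(pr) {
      if (pr$family == "flat") stats::runif(J) else sample_truncated_prior(pr, 1e-9, 1 - 1e-9, J)
    }
    s <- draw01(prior); g <- draw01(prior_g)
    bad <- which(s + g >= 1)
    while (length(bad)) { # rejection onto the monotone region
      s[bad] <- draw01(prior)[bad]; g[bad] <- draw01(prior_g)[bad]
      bad <- which(s + g >= 1)
    }
    params <- list(s = s, g = g)
  } else {
    params <- list(P = lapply(seq_len(J), function(j) {
      init_monotone_cells(sum(Q[j, ]))
    }))
  }
  list(params = params,
       alpha = sample.int(C, I, replace = TRUE),
       pi = rep(1 / C, C))
}

# Random monotone cell probabilities: running maxima of iid uniforms over
# the subset lattice are monotone by construction.
init_monotone_cells <- function(kstar) {
  ncell <- 2L^kstar
  x <- stats::runif(ncell, 0.02, 0.98)
  P <- numeric(ncell)
  for (r in 0:(ncell - 1L)) {
    sub <- which(bitwAnd(0:(ncell - 1L), r) == 0:(ncell - 1L)) - 1L
    P[r + 1L] <- max(x[sub + 1L])
  }
  P
}

run_engine <- function(Y, Q, model, sampler, prior, prior_g, proposal_sd,
                       n_iter, burn_in, thin, init, store_alpha, check_aux) {
  J <- nrow(Q); K <- ncol(Q); C <- 2L^K
  phi0 <- prior$dirichlet_phi0
  if (model == "dina") {
    eta <- eta_matrix(Q)
    ps <- prior_code(prior); pg <- prior_code(prior_g)
    out <- switch(
      sampler,
      slice = slice_dina_engine(Y, eta, n_iter, burn_in, thin,
                                ps$fam, ps$par, pg$fam, pg$par, phi0,
                                init$params$s, init$params$g, init$alpha,
                                init$pi, store_alpha, check_aux),
      mh = mh_dina_engine(Y, eta, n_iter, burn_in, thin, proposal_sd,
                          ps$fam, ps$par, pg$fam, pg$par, phi0,
                          init$params$s, init$params$g, init$alpha,
                          init$pi, store_alpha),
      gibbs = gibbs_dina_engine(Y, eta, n_iter, burn_in, thin,
                                prior$params[["shape1"]], prior$params[["shape2"]],
                                phi0, init$params$s, init$params$g,
                                init$alpha, init$pi, store_alpha))
    cn <- c(paste0("s[", seq_len(J), "]"), paste0("g[", seq_len(J), "]"),
            paste0("pi[", seq_len(C), "]"))
  } else {
    kstar <- as.integer(rowSums(Q))
    sweep <- lapply(kstar, item_subsets)
    # rows of solve(A) already follow the coefficient (subset) order of A's
    # columns; cells index the columns by raw bitmask
    Ainv <- lapply(kstar, function(k) solve(activation_matrix(item_subsets(k))))
    pc <- prior_code(prior)
    out <- slice_gdina_engine(Y, reduced_cell_matrix(Q), kstar, sweep, Ainv,
                              n_iter, burn_in, thin, pc$fam, pc$par, phi0,
                              init$params$P, init$alpha, init$pi,
                              store_alpha, check_aux)
    cn <- c(unlist(lapply(seq_len(J), function(j) {
      paste0("d[", j, ",", subset_labels(item_subsets(kstar[j])), "]")
    })), paste0("pi[", seq_len(C), "]"))
  }
  colnames(out$draws) <- cn
  out
}

# Stack retained draws across chains (draw-major within chain).
#' Extract retained draws from a fit
#'
#' @param fit A `cdm_fit`.
#' @param chain Optional chain index; default stacks all chains.
#' @return A numeric matrix with one named column per parameter.
#' @export
cdm_draws <- function(fit, chain = NULL) {
  stopifnot(inherits(fit, "cdm_fit"))
  if (!is.null(chain)) return(fit$chains[[chain]]$draws)
  do.call(rbind, lapply(fit$chains, `[[`, "draws"))
}

#' @export
print.cdm_fit <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("cdm_fit: %s model, %s sampler\n", toupper(x$model), x$sampler))
  cat(sprintf("  I = %d examinees, J = %d items, K = %d attributes (%d classes)\n",
              x$dims["I"], x$dims["J"], x$dims["K"], x$dims["C"]))
  cat(sprintf("  %d chain(s) x %d iterations (%d burn-in, thin %d): %d retained draws/chain\n",
              cfg$n_chains, cfg$n_iter, cfg$burn_in, cfg$thin,
              nrow(x$chains[[1]]$draws)))
  counters <- warning_counters(x)
  if (any(counters > 0)) {
    cat("  counters:", paste(sprintf("%s=%d", names(counters), counters),
                             collapse = ", "), "\n")
  }
  invisible(x)
}

# Aggregate warning counters across chains.
warning_counters <- function(fit) {
  n <- function(f) sum(vapply(fit$chains, function(ch) as.integer(ch[[f]]), integer(1)))
  c(empty_interval = n("n_empty_interval"),
    aux_violations = n("n_aux_violations"),
    monotonicity_violations = n("n_monotonicity_violations"))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior summaries of a fitted model
#'
#' One row per parameter with the EAP point estimate (posterior mean),
#' posterior standard deviation, and central 95% credible bounds, pooled
#' across chains.
#'
#' @param x A `cdm_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `group` (`"s"`, `"g"`, `"delta"`,
#'   `"pi"`), `item` (`NA` for `pi`), `order` (coefficient interaction
#'   order, G-DINA only), `estimate`, `std.error`, `conf.low`,
#'   `conf.high`.
#' @export
tidy.cdm_fit <- function(x, ...) {
  d <- cdm_draws(x)
  q <- t(apply(d, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE))
  term <- colnames(d)
  grp <- sub("\\[.*", "", term)
  grp[grp == "d"] <- "delta"
  item <- ifelse(grp == "pi", NA_integer_,
                 as.integer(sub("^[a-z]+\\[(\\d+).*", "\\1", term)))
  ord <- rep(NA_integer_, length(term))
  is_d <- grp == "delta"
  ord[is_d] <- nchar(sub("^d\\[\\d+,(\\w+)\\]$", "\\1", term[is_d]))
  ord[is_d][sub("^d\\[\\d+,(\\w+)\\]$", "\\1", term[is_d]) == "0"] <- 0L
  tibble::tibble(
    term = term, group = grp, item = item, order = ord,
    estimate = colMeans(d), std.error = apply(d, 2, stats::sd),
    conf.low = q[, 1], conf.high = q[, 2])
}

#' One-row summary of a fitted model
#'
#' @param x A `cdm_fit`.
#' @param ... Unused.
#' @return A tibble with the model, sampler, chain geometry, retained draw
#'   count, MH acceptance rate (`NA` otherwise), and the warning counters
#'   (empty truncation intervals, auxiliary-constraint violations,
#'   monotonicity violations among retained draws).
#' @export
glance.cdm_fit <- function(x, ...) {
  counters <- warning_counters(x)
  acc <- vapply(x$chains, function(ch) {
    if (is.null(ch$acceptance_rate)) NA_real_ else ch$acceptance_rate
  }, numeric(1))
  tibble::tibble(
    model = x$model, sampler = x$sampler,
    n_chains = x$config$n_chains, n_iter = x$config$n_iter,
    burn_in = x$config$burn_in, thin = x$config$thin,
    n_draws = nrow(cdm_draws(x)),
    acceptance_rate = mean(acc),
    empty_interval = counters["empty_interval"],
    aux_violations = counters["aux_violations"],
    monotonicity_violations = counters["monotonicity_violations"])
}
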