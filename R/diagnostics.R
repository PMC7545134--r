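#' Potential scale reduction factor (Brooks-Gelman)
#'
#' The corrected univariate scale-reduction statistic for one parameter
#' monitored across `M >= 2` chains of `N` draws: with within-chain
#' variance `W` and between-chain variance `B` (N times the variance of
#' the chain means), the pooled posterior-variance estimate is
#' `V = (N-1)/N W + (1 + 1/M) B/N`, inflated by the sampling-variability
#' degrees-of-freedom correction `(d+3)/(d+1)` with `d = 2 V^2 / var(V)`.
#' Values below 1.1 are conventionally taken as converged.
#'
#' @param chains A numeric matrix (`N` draws x `M` chains) or list of
#'   equal-length numeric vectors, one per chain.
#' @return The scale reduction factor (scalar, `>= 0`).
#' @export
psrf <- function(chains) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  chains <- as.matrix(chains)
  M <- ncol(chains); N <- nrow(chains)
  stopifnot(M >= 2, N >= 10)
  xbar <- colMeans(chains)
  S2 <- apply(chains, 2, stats::var)
  W <- mean(S2)
  if (W < 1e-300) stop("zero within-chain variance: stuck chain(s)", call. = FALSE)
  B <- N * stats::var(xbar)
  V <- (N - 1) / N * W + (1 + 1 / M) * B / N
  # sampling variability of V (Brooks & Gelman 1998, as in standard toolkits)
  var_w <- stats::var(S2) / M
  var_b <- 2 * B^2 / (M - 1)
  cov_wb <- (N / M) * (stats::cov(S2, xbar^2) - 2 * mean(xbar) * stats::cov(S2, xbar))
  var_V <- ((N - 1)^2 * var_w + (1 + 1 / M)^2 * var_b +
              2 * (N - 1) * (1 + 1 / M) * cov_wb) / N^2
  df_V <- 2 * V^2 / var_V
  sqrt((V / W) * (df_V + 3) / (df_V + 1))
}

#' Cumulative PSRF trace over a grid of iteration counts
#'
#' Recomputes the scale reduction factor for every monitored parameter at
#' a grid of chain prefixes, using the second half of each prefix (the
#' first half plays the role of a growing burn-in, mirroring how
#' convergence is monitored in practice). All item parameters and all
#' class probabilities are monitored.
#'
#' @param fit A multi-chain `cdm_fit` (`n_chains >= 2`).
#' @param every Grid spacing in retained iterations (default 250).
#' @param threshold Convergence threshold (default 1.1).
#' @return An object of class `psrf_trace`: a tibble with columns
#'   `iteration`, `parameter`, `rhat`, plus attributes `threshold` and
#'   `convergence_iteration` (first grid point at which every monitored
#'   parameter has `rhat < threshold`; `NA` if never).
#' @export
psrf_trace <- function(fit, every = 250, threshold = 1.1) {
  stopifnot(inherits(fit, "cdm_fit"), fit$config$n_chains >= 2)
  mats <- lapply(fit$chains, `[[`, "draws")
  N <- nrow(mats[[1]])
  pars <- colnames(mats[[1]])
  grid <- seq(every, N, by = every)
  if (length(grid) == 0 || grid[length(grid)] != N) grid <- c(grid, N)
  rows <- purrr::map_dfr(grid, function(n) {
    lo <- floor(n / 2) + 1
    rh <- vapply(pars, function(p) {
      x <- vapply(mats, function(m) m[lo:n, p], numeric(n - lo + 1))
      if (mean(apply(x, 2, stats::var)) < 1e-300) return(Inf)
      psrf(x)
    }, numeric(1))
    tibble::tibble(iteration = n, parameter = pars, rhat = rh)
  })
  conv <- rows |>
    dplyr::group_by(.data$iteration) |>
    dplyr::summarise(ok = all(.data$rhat < threshold)) |>
    dplyr::filter(.data$ok)
  structure(rows,
            threshold = threshold,
            convergence_iteration = if (nrow(conv)) min(conv$iteration) else NA_integer_,
            class = c("psrf_trace", class(rows)))
}

#' First retained iteration at which all monitored parameters converge
#'
#' @param trace A [psrf_trace()].
#' @return Integer iteration (in retained-draw units), or `NA`.
#' @export
convergence_iteration <- function(trace) {
  attr(trace, "convergence_iteration")
}

#' @export
autoplot.psrf_trace <- function(object, ...) {
  thr <- attr(object, "threshold")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$iteration, y = .data$rhat,
                                       group = .data$parameter)) +
    ggplot2::geom_line(alpha = 0.35) +
    ggplot2::geom_hline(yintercept = thr, linetype = 2, colour = "red") +
    ggplot2::coord_cartesian(ylim = c(1, max(1.5, stats::quantile(object$rhat, 0.99)))) +
    ggplot2::labs(x = "iteration", y = expression(hat(R)),
                  title = "Brooks-Gelman scale reduction, cumulative second halves")
}

#' EAP point estimates and posterior standard errors
#'
#' Expected a posteriori estimates (posterior means) with posterior
#' standard deviations for every item parameter and class probability,
#' pooled across chains; per-examinee posterior class frequencies come
#' from the retained class-membership tallies.
#'
#' @param fit A `cdm_fit`.
#' @return A list with `parameters` (tibble: `term`, `eap`, `se`) and
#'   `class_membership` (`I x C` matrix of posterior frequencies, rows
#'   summing to 1).
#' @export
eap_se <- function(fit) {
  d <- cdm_draws(fit)
  tal <- Reduce(`+`, lapply(fit$chains, `[[`, "tally"))
  list(parameters = tibble::tibble(term = colnames(d),
                                   eap = colMeans(d),
                                   se = apply(d, 2, stats::sd)),
       class_membership = tal / rowSums(tal))
}

#' Deviance information criterion
#'
#' Uses the class-marginalized deviance
#' `D(theta) = -2 log p(Y | item parameters, pi)` (the latent classes are
#' summed out), so models with different class structures are comparable:
#' `DIC = Dbar + pD` with `pD = Dbar - D(posterior means)`. If the
#' posterior-mean G-DINA coefficients violate monotonicity (possible for
#' means of constrained draws), they are projected onto the monotone
#' region by an isotonic pass over the mastery lattice before evaluating
#' the plug-in deviance, and a note is attached.
#'
#' @param fit A `cdm_fit`.
#' @param Y,Q The data the model was fitted to.
#' @param thin_deviance Evaluate the deviance on every `thin_deviance`-th
#'   retained draw (default 1 = all draws).
#' @return A list with `dic`, `p_d`, `mean_deviance`, `deviance_at_mean`,
#'   and `projected` (was the plug-in repaired).
#' @export
dic <- function(fit, Y, Q, thin_deviance = 1) {
  stopifnot(inherits(fit, "cdm_fit"))
  Y <- check_binary_matrix(Y, "Y")
  Q <- q_matrix(Q)
  d <- cdm_draws(fit)
  idx <- seq(1, nrow(d), by = thin_deviance)
  dev <- vapply(idx, function(r) {
    -2 * marginal_log_likelihood(Y, Q, draw_to_params(fit, d[r, ]),
                                 draw_to_pi(fit, d[r, ]))
  }, numeric(1))
  mean_dev <- mean(dev)
  eap <- colMeans(d)
  params_bar <- draw_to_params(fit, eap)
  projected <- FALSE
  if (fit$model == "gdina") {
    proj <- project_monotone(params_bar)
    projected <- proj$changed
    params_bar <- proj$params
  }
  dev_at_mean <- -2 * marginal_log_likelihood(Y, Q, params_bar, draw_to_pi(fit, eap))
  p_d <- mean_dev - dev_at_mean
  list(dic = mean_dev + p_d, p_d = p_d, mean_deviance = mean_dev,
       deviance_at_mean = dev_at_mean, projected = projected)
}

# Rebuild parameter objects from one draw row (named as in cdm_draws).
draw_to_params <- function(fit, row) {
  J <- fit$dims[["J"]]
  if (fit$model == "dina") {
    dina_params(row[paste0("s[", seq_len(J), "]")],
                row[paste0("g[", seq_len(J), "]")])
  } else {
    kstar <- rowSums(fit$Q)
    deltas <- lapply(seq_len(J), function(j) {
      labs <- subset_labels(item_subsets(kstar[j]))
      unname(row[paste0("d[", j, ",", labs, "]")])
    })
    gdina_params(fit$Q, deltas, check = FALSE)
  }
}

draw_to_pi <- function(fit, row) {
  pi <- row[grep("^pi\\[", names(row))]
  unname(pi / sum(pi))
}

# Project G-DINA cell probabilities onto the monotone region: sweep the
# lattice upward taking running maxima with predecessors, then clamp to
# [0,1]. Idempotent on already-monotone items.
project_monotone <- function(params) {
  changed <- FALSE
  out <- lapply(params, function(item) {
    P <- gdina_cell_probs(item)
    ncell <- length(P)
    newP <- pmin(pmax(P, 0), 1)
    for (r in 0:(ncell - 1L)) {
      for (k in seq_len(item$kstar)) {
        bit <- bitwShiftL(1L, k - 1L)
        if (bitwAnd(r, bit) == bit) {
          newP[r + 1L] <- max(newP[r + 1L], newP[bitwXor(r, bit) + 1L])
        }
      }
    }
    if (any(abs(newP - P) > 1e-12)) changed <<- TRUE
    gdina_item(cells_to_delta(newP, item$subsets), item$kstar, check = FALSE)
  })
  list(params = structure(out, class = "gdina_params"), changed = changed)
}
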