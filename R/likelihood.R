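# Class-by-item success probability matrix for either model.
# params: dina_params or gdina_params.
class_success_probs <- function(Q, params) {
  if (inherits(params, "dina_params")) {
    dina_class_probs(Q, params$s, params$g)
  } else if (inherits(params, "gdina_params")) {
    gdina_class_probs(Q, params)
  } else {
    stop("params must be dina_params or gdina_params", call. = FALSE)
  }
}

#' Marginal log-likelihood of a cognitive diagnosis model
#'
#' The likelihood marginalized over the latent classes:
#' `sum_i log sum_c pi_c prod_j P(Y_ij | alpha_c)`, with per-examinee
#' products accumulated in log space. Success probabilities within
#' `1e-12` of 0 or 1 are clamped before taking logs.
#'
#' @param Y Binary `I x J` response matrix.
#' @param Q A [q_matrix()].
#' @param params A [dina_params()] or [gdina_params()].
#' @param pi Length-`2^K` vector of latent class probabilities.
#' @return The marginal log-likelihood (scalar).
#' @examples
#' Q <- q_matrix(matrix(1, 1, 1))
#' marginal_log_likelihood(matrix(1L, 1, 1), Q, dina_params(0.2, 0.1),
#'                         pi = c(0.5, 0.5)) # log(0.45)
#' @export
marginal_log_likelihood <- function(Y, Q, params, pi) {
  Y <- check_binary_matrix(Y, "Y")
  Q <- q_matrix(Q)
  C <- 2L^ncol(Q)
  stopifnot(length(pi) == C, ncol(Y) == nrow(Q))
  if (any(pi < -1e-12) || abs(sum(pi) - 1) > 1e-8) {
    stop("pi must be a probability vector over the latent classes", call. = FALSE)
  }
  P <- class_success_probs(Q, params)
  P <- pmin(pmax(P, 1e-12), 1 - 1e-12)
  # I x C log-likelihood by two matrix products over items
  ll_ic <- Y %*% t(log(P)) + (1 - Y) %*% t(log1p(-P))
  lw <- sweep(ll_ic, 2, log(pmax(pi, 1e-300)), "+")
  m <- apply(lw, 1, max)
  if (any(!is.finite(m))) {
    stop("data have zero probability under every latent class", call. = FALSE)
  }
  sum(m + log(rowSums(exp(lw - m))))
}

# I x C posterior class weights (rows sum to 1) -- used by update_alpha and
# by EAP class summaries.
class_posteriors <- function(Y, Q, params, pi) {
  P <- class_success_probs(Q, params)
  P <- pmin(pmax(P, 1e-12), 1 - 1e-12)
  lw <- Y %*% t(log(P)) + (1 - Y) %*% t(log1p(-P))
  lw <- sweep(lw, 2, log(pmax(pi, 1e-300)), "+")
  m <- apply(lw, 1, max)
  w <- exp(lw - m)
  w / rowSums(w)
}
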