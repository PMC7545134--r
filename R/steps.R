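#' Sample the uniform auxiliary variables of the slice augmentation
#'
#' The Bernoulli likelihood term of each response is replaced by a uniform
#' slice: where `Y_ij = 1` draw `U_ij ~ Uniform(0, f_ij)`, where
#' `Y_ij = 0` draw `V_ij ~ Uniform(0, 1 - f_ij)`. Conditioning on these
#' auxiliary variables turns every item-parameter full conditional into
#' the prior truncated to an explicit interval.
#'
#' @param Y Binary `I x J` response matrix.
#' @param f `I x J` matrix of current success probabilities, interior to
#'   `(0, 1)` (values are clamped to `[1e-12, 1 - 1e-12]`).
#' @return List with matrices `U` and `V`; `U` is `NA` where `Y = 0`, `V`
#'   is `NA` where `Y = 1`.
#' @export
sample_auxiliary <- function(Y, f) {
  Y <- check_binary_matrix(Y, "Y")
  stopifnot(all(dim(Y) == dim(f)))
  f <- pmin(pmax(f, 1e-12), 1 - 1e-12)
  U <- matrix(NA_real_, nrow(Y), ncol(Y))
  V <- matrix(NA_real_, nrow(Y), ncol(Y))
  i1 <- Y == 1L
  U[i1] <- stats::runif(sum(i1)) * f[i1]
  V[!i1] <- stats::runif(sum(!i1)) * (1 - f[!i1])
  list(U = U, V = V)
}

#' Truncation interval for a DINA slip or guessing parameter
#'
#' Given the auxiliary variables, the full conditional of `s_j` is the
#' prior truncated to `(max V over mastery non-responders, min (1 - U)
#' over mastery responders)`, further capped by the monotonicity
#' constraint `s_j < 1 - g_j`; the guessing parameter is the mirror
#' construction over examinees lacking full mastery, capped at
#' `g_j < 1 - s_j`. Empty index sets contribute the trivial bounds.
#'
#' @param j Item index.
#' @param which `"slip"` or `"guess"`.
#' @param Y Binary response matrix.
#' @param aux List with `U`, `V` as returned by [sample_auxiliary()].
#' @param eta Length-`I` binary vector: does each examinee master all
#'   attributes item `j` requires?
#' @param s,g Current parameter values for item `j` (the one not being
#'   updated caps the interval).
#' @return Named vector `c(L, R)`.
#' @examples
#' # one mastery non-responder with V = 0.10, one mastery responder with
#' # U = 0.60, g = 0.30: slip interval (0.10, 0.40)
#' @export
dina_item_bounds <- function(j, which = c("slip", "guess"), Y, aux, eta, s, g) {
  which <- match.arg(which)
  Yj <- Y[, j]
  Uj <- aux$U[, j]
  Vj <- aux$V[, j]
  if (which == "slip") {
    lo <- c(0, Vj[eta == 1L & Yj == 0L])
    hi <- c(1 - g, 1 - Uj[eta == 1L & Yj == 1L])
  } else {
    lo <- c(0, Uj[eta == 0L & Yj == 1L])
    hi <- c(1 - s, 1 - Vj[eta == 0L & Yj == 0L])
  }
  c(L = max(lo, na.rm = TRUE), R = min(hi, na.rm = TRUE))
}

#' Truncation interval for one G-DINA coefficient given the auxiliaries
#'
#' Intersects (a) the data interval contributed by the examinees whose
#' reduced profile sits at the target coefficient's cell (their auxiliary
#' draws bound that cell's success probability from below via `U` and
#' from above via `1 - V`) with (b) the monotonicity interval of
#' [gdina_truncation_interval()]. Returned on the coefficient scale. When
#' no examinee occupies the cell the data interval is vacuous and the
#' result is the monotonicity interval alone.
#'
#' @param j Item index.
#' @param target Coefficient index in subset order (or label).
#' @param Y Binary response matrix.
#' @param aux List with `U`, `V`.
#' @param alpha Length-`I` class indices.
#' @param Q A [q_matrix()].
#' @param params A [gdina_params()].
#' @return Named vector `c(L, R)` for the target coefficient.
#' @export
gdina_item_bounds <- function(j, target, Y, aux, alpha, Q, params) {
  item <- params[[j]]
  if (is.character(target)) target <- match(target, item$labels)
  mono <- gdina_truncation_interval(item, target)
  cellmat <- reduced_cell_matrix(Q)
  cell_i <- cellmat[alpha, j]
  at_cell <- cell_i == item$subsets[target]
  P <- gdina_cell_probs(item)
  resid <- P[item$subsets[target] + 1L] - item$delta[target]
  Yj <- Y[, j]
  lo <- c(mono["lower"], aux$U[at_cell & Yj == 1L, j] - resid)
  hi <- c(mono["upper"], 1 - aux$V[at_cell & Yj == 0L, j] - resid)
  c(L = max(lo, na.rm = TRUE), R = min(hi, na.rm = TRUE))
}

#' Conjugate Dirichlet update of the latent class probabilities
#'
#' With a symmetric Dirichlet(`phi0`) prior and the current class
#' memberships, `pi` is drawn from Dirichlet(`phi0 + n_1, ...,
#' phi0 + n_C`), where `n_c` counts examinees in class `c`.
#'
#' @param alpha Length-`I` integer class indices (may be length 0).
#' @param phi0 Positive Dirichlet hyperparameter.
#' @param C Number of latent classes.
#' @return Length-`C` probability vector.
#' @export
update_pi <- function(alpha, phi0, C) {
  stopifnot(phi0 > 0, C >= 1)
  n_c <- tabulate(alpha, nbins = C)
  gam <- stats::rgamma(C, shape = phi0 + n_c, rate = 1)
  gam / sum(gam)
}

#' Posterior draw of one examinee's latent class
#'
#' Class `c` is drawn with probability proportional to
#' `pi_c prod_j P(Y_ij | alpha_c)`, accumulated in log space.
#'
#' @param Y_i Length-`J` binary response vector.
#' @param Q A [q_matrix()].
#' @param params Item parameters ([dina_params()] or [gdina_params()]).
#' @param pi Class probability vector.
#' @param probs If `TRUE` return the posterior class probabilities
#'   instead of a draw.
#' @return An integer class index (or a length-`C` probability vector).
#' @export
update_alpha <- function(Y_i, Q, params, pi, probs = FALSE) {
  w <- class_posteriors(matrix(as.integer(Y_i), nrow = 1), Q, params, pi)[1, ]
  if (any(!is.finite(w))) stop("all class posteriors are degenerate", call. = FALSE)
  if (probs) return(w)
  sample.int(length(w), 1L, prob = w)
}
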