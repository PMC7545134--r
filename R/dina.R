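#' DINA item success probability
#'
#' Under the DINA (deterministic-input, noisy-and) model an examinee answers
#' item `j` correctly with probability `1 - s_j` when they master every
#' attribute the item requires, and with the guessing probability `g_j`
#' otherwise. Monotonicity (identifiability) requires `s_j + g_j < 1`.
#'
#' @param profile Binary length-K mastery profile.
#' @param q_row Binary length-K requirement vector for the item.
#' @param s,g Slip and guessing probabilities, `s + g < 1`.
#' @return The success probability (`1 - s` or `g`).
#' @examples
#' p_correct_dina(c(1, 1), c(1, 1), s = 0.2, g = 0.1) # 0.8
#' p_correct_dina(c(0, 1), c(1, 1), s = 0.2, g = 0.1) # 0.1
#' @export
p_correct_dina <- function(profile, q_row, s, g) {
  check_sg(s, g)
  profile <- check_binary_vector(profile, "profile")
  q_row <- check_binary_vector(q_row, "q_row")
  stopifnot(length(profile) == length(q_row))
  if (all(profile[q_row == 1L] == 1L)) 1 - s else g
}

check_sg <- function(s, g) {
  if (any(s <= 0) || any(g <= 0) || any(s + g >= 1)) {
    stop("invalid DINA parameters: need 0 < g, 0 < s and s + g < 1 (monotonicity)",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct DINA item parameters
#'
#' @param s,g Length-J vectors of slip and guessing probabilities satisfying
#'   `0 < s_j`, `0 < g_j`, `s_j + g_j < 1`.
#' @return A list of class `dina_params` with elements `s` and `g`.
#' @export
dina_params <- function(s, g) {
  stopifnot(length(s) == length(g))
  check_sg(s, g)
  structure(list(s = as.numeric(s), g = as.numeric(g)), class = "dina_params")
}

#' Express a DINA item in G-DINA coefficient form
#'
#' The DINA model is the special case of the G-DINA model in which only the
#' intercept and the highest-order interaction are nonzero: the intercept is
#' `g_j` and the top interaction is `1 - s_j - g_j`, so success probability
#' is `g_j` for any profile short of full required mastery and `1 - s_j`
#' at full mastery.
#'
#' @inheritParams p_correct_dina
#' @return A `gdina_item` (see [gdina_item()]) over the item's required
#'   attributes.
#' @examples
#' dina_as_gdina(s = 0.2, g = 0.1, q_row = c(1, 1))
#' @export
dina_as_gdina <- function(s, g, q_row) {
  check_sg(s, g)
  q_row <- check_binary_vector(q_row, "q_row")
  kstar <- sum(q_row)
  subsets <- item_subsets(kstar)
  delta <- numeric(length(subsets))
  delta[1] <- g
  delta[length(delta)] <- 1 - s - g
  gdina_item(delta, kstar)
}

# C x J matrix of class success probabilities under DINA.
dina_class_probs <- function(Q, s, g) {
  prof <- attribute_profiles(ncol(Q))
  eta <- eta_matrix(Q, prof)
  P <- t(t(eta) * (1 - s - g)) # eta * (1-s) + (1-eta)*g = g + eta*(1-s-g)
  P <- sweep(P, 2, g, "+")
  P
}

# C x J mastery indicator: does class c master all attributes of item j?
eta_matrix <- function(Q, prof = attribute_profiles(ncol(Q))) {
  need <- rowSums(Q)
  have <- prof %*% t(Q) # attributes mastered among required
  eta <- matrix(0L, nrow(prof), nrow(Q))
  eta[have == rep(need, each = nrow(prof))] <- 1L
  eta
}
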