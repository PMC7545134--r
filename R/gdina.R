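#' @title G-DINA item parameters
#'
#' @description
#' Under the (identity-link) G-DINA model the success probability of item
#' `j` for the reduced profile `alpha*` (the mastery bits of the item's
#' `K*_j` required attributes) is a saturated linear function:
#' an intercept `delta_0`, main effects `delta_k`, and interactions
#' `delta_{kk'} ... delta_{12...K*}` summed over every subset of mastered
#' required attributes. Equivalently, each of the `2^{K*_j}` reduced
#' profiles ("cells") has its own success probability
#' `P(alpha*) = sum of active coefficients`; the two parametrizations are
#' related by a triangular inclusion-exclusion transform.
#'
#' `gdina_item()` builds one item from its coefficient vector in the fixed
#' subset order (intercept, main effects ascending, interactions by subset
#' size then lexicographic order); `gdina_params()` assembles a per-item
#' list aligned with a Q-matrix.
#'
#' @param delta Numeric vector of `2^kstar` coefficients in subset order.
#' @param kstar Number of required attributes of the item.
#' @param check Validate the monotonicity invariants (default `TRUE`).
#' @return `gdina_item()`: a list of class `gdina_item` with fields
#'   `delta`, `kstar`, `subsets` (bitmask per coefficient), and `labels`.
#' @examples
#' it <- gdina_item(c(0.2, 0.1, 0.15, 0.4), kstar = 2)
#' p_correct_gdina(c(1, 1), it)
#' @export
gdina_item <- function(delta, kstar, check = TRUE) {
  subsets <- item_subsets(kstar)
  stopifnot(length(delta) == length(subsets))
  item <- structure(
    list(delta = as.numeric(delta), kstar = as.integer(kstar),
         subsets = subsets, labels = subset_labels(subsets)),
    class = "gdina_item")
  if (check) {
    chk <- check_monotone_item(item)
    if (!chk$ok) {
      stop("gdina_item violates monotonicity/probability bounds: ",
           chk$why, call. = FALSE)
    }
  }
  item
}

#' @rdname gdina_item
#' @param Q A [q_matrix()].
#' @param deltas A list of coefficient vectors (one per item, subset order),
#'   or a data frame with columns `item`, `subset` (label such as `"0"`,
#'   `"1"`, `"12"`), and `delta`.
#' @return `gdina_params()`: a list of class `gdina_params` of `gdina_item`
#'   objects, one per row of `Q`.
#' @export
gdina_params <- function(Q, deltas, check = TRUE) {
  Q <- q_matrix(Q)
  if (is.data.frame(deltas)) {
    deltas <- lapply(seq_len(nrow(Q)), function(j) {
      d <- deltas[deltas$item == j, , drop = FALSE]
      kstar <- sum(Q[j, ])
      labs <- subset_labels(item_subsets(kstar))
      if (!setequal(as.character(d$subset), labs)) {
        stop(sprintf("item %d: subsets in data frame do not match Q row", j),
             call. = FALSE)
      }
      d$delta[match(labs, as.character(d$subset))]
    })
  }
  stopifnot(length(deltas) == nrow(Q))
  items <- lapply(seq_len(nrow(Q)), function(j) {
    gdina_item(deltas[[j]], kstar = sum(Q[j, ]), check = check)
  })
  structure(items, class = "gdina_params")
}

# Subset bitmasks over kstar reduced attributes, in sweep order:
# size ascending, lexicographic (by lowest attribute) within size.
item_subsets <- function(kstar) {
  masks <- 0:(2L^kstar - 1L)
  sizes <- vapply(masks, function(m) sum(bitwAnd(bitwShiftR(m, 0:(max(kstar, 1) - 1L)), 1L)), numeric(1))
  # lexicographic within size: attribute 1 sorts first, so weight low
  # attributes most heavily and sort that key descending within size
  lexkey <- vapply(masks, function(m) {
    bits <- bitwAnd(bitwShiftR(m, seq_len(kstar) - 1L), 1L)
    sum(bits * 2^(kstar - seq_len(kstar)))
  }, numeric(1))
  masks[order(sizes, -lexkey)]
}

subset_labels <- function(subsets) {
  vapply(subsets, function(m) {
    if (m == 0L) return("0")
    k <- which(bitwAnd(bitwShiftR(m, 0:30), 1L) == 1L)
    paste(k, collapse = "")
  }, character(1))
}

# Activation matrix: cell r (bitmask row index r+1) activates coefficient m
# iff  m is a subset of r. Cells indexed by raw bitmask 0..2^kstar-1.
activation_matrix <- function(subsets) {
  ncell <- length(subsets)
  cells <- 0:(ncell - 1L)
  A <- matrix(0L, ncell, ncell)
  for (mi in seq_along(subsets)) {
    A[bitwAnd(cells, subsets[mi]) == subsets[mi], mi] <- 1L
  }
  A
}

# Cell success probabilities of one item: length 2^kstar vector indexed by
# cell bitmask + 1.
gdina_cell_probs <- function(item) {
  as.numeric(activation_matrix(item$subsets) %*% item$delta)
}

# Inverse transform: cell probabilities -> coefficients (subset order).
cells_to_delta <- function(P, subsets) {
  A <- activation_matrix(subsets)
  as.numeric(solve(A, P))
}

#' G-DINA success probability for one profile
#'
#' Sums the intercept, main effects, and interactions over every subset of
#' required attributes that the profile fully masters.
#'
#' @param profile Binary mastery vector. Either the reduced profile of
#'   length `kstar`, or a full length-K profile together with `q_row`.
#' @param item A [gdina_item()].
#' @param q_row Optional binary requirement vector used to reduce a full
#'   profile.
#' @return The success probability.
#' @examples
#' it <- gdina_item(c(0.2, 0.1, 0.15, 0.4), kstar = 2)
#' p_correct_gdina(c(1, 1), it) # 0.85
#' p_correct_gdina(c(0, 0), it) # 0.20
#' @export
p_correct_gdina <- function(profile, item, q_row = NULL) {
  profile <- check_binary_vector(profile, "profile")
  if (!is.null(q_row)) {
    q_row <- check_binary_vector(q_row, "q_row")
    profile <- profile[q_row == 1L]
  }
  stopifnot(length(profile) == item$kstar)
  cell <- sum(profile * 2L^(seq_along(profile) - 1L))
  p <- sum(item$delta[bitwAnd(cell, item$subsets) == item$subsets])
  if (p < -1e-12 || p > 1 + 1e-12) {
    stop(sprintf("success probability %.6f outside [0,1]: invalid G-DINA item", p),
         call. = FALSE)
  }
  min(max(p, 0), 1)
}

# Cover pairs (lower cell, upper cell) of the Boolean lattice on kstar
# attributes, as a 2-column matrix of cell bitmasks.
lattice_covers <- function(kstar) {
  cells <- 0:(2L^kstar - 1L)
  out <- matrix(0L, 0L, 2L)
  for (r in cells) {
    for (k in seq_len(kstar)) {
      bit <- bitwShiftL(1L, k - 1L)
      if (bitwAnd(r, bit) == 0L) out <- rbind(out, c(r, bitwOr(r, bit)))
    }
  }
  out
}

# Validate one item's monotonicity: all cells in [0,1] and non-decreasing
# along every cover relation of the mastery partial order.
check_monotone_item <- function(item, tol = 1e-12) {
  P <- gdina_cell_probs(item)
  if (any(P < -tol) || any(P > 1 + tol)) {
    return(list(ok = FALSE, why = "a cell probability lies outside [0,1]"))
  }
  cov <- lattice_covers(item$kstar)
  bad <- P[cov[, 1] + 1L] > P[cov[, 2] + 1L] + tol
  if (any(bad)) {
    i <- which(bad)[1]
    return(list(ok = FALSE,
                why = sprintf("P(cell %d) > P(cell %d): order violated",
                              cov[i, 1], cov[i, 2])))
  }
  list(ok = TRUE, why = "")
}

#' Admissible interval for one G-DINA coefficient under monotonicity
#'
#' Holding every other reduced-profile success probability fixed, the
#' monotonicity partial order (each cell's probability at least that of
#' every immediate predecessor and at most that of every immediate
#' successor, all within `[0, 1]`) confines the cell probability tied to
#' the target subset to an explicit interval. For `K* = 3` this reproduces
#' the textbook bound rules (intercept bounded above by the smallest
#' single-attribute cell; a two-way cumulative effect bounded below by its
#' two one-attribute predecessors and above by the full-mastery cell). The
#' interval is returned on the coefficient scale: cell bounds minus the sum
#' of the other coefficients active at the target cell.
#'
#' @param item A [gdina_item()] holding the current coefficient values.
#' @param target Index of the target coefficient in subset order (1 =
#'   intercept), or a subset label such as `"12"`.
#' @return Named numeric vector `c(lower, upper)` for the target
#'   coefficient. `lower >= upper` signals that the current state itself
#'   violates monotonicity.
#' @examples
#' it <- gdina_item(c(0.2, 0.1, 0.15, 0), kstar = 2)
#' gdina_truncation_interval(it, "12")
#' @export
gdina_truncation_interval <- function(item, target) {
  if (is.character(target)) target <- match(target, item$labels)
  stopifnot(!is.na(target), target >= 1, target <= length(item$subsets))
  P <- gdina_cell_probs(item)
  r <- item$subsets[target] # the cell whose probability this coefficient tops off
  kstar <- item$kstar
  lower <- 0
  upper <- 1
  for (k in seq_len(kstar)) {
    bit <- bitwShiftL(1L, k - 1L)
    if (bitwAnd(r, bit) == bit) {
      lower <- max(lower, P[bitwXor(r, bit) + 1L]) # predecessor r \ {k}
    } else {
      upper <- min(upper, P[bitwOr(r, bit) + 1L]) # successor r + {k}
    }
  }
  resid <- P[r + 1L] - item$delta[target] # other coefficients active at the cell
  c(lower = lower - resid, upper = upper - resid)
}

#' Apply a Step-2 coefficient draw to a G-DINA item
#'
#' The sampler's item update moves one reduced-profile cell probability at
#' a time: assigning `value` to the target coefficient sets its cell to
#' `residual + value` while every other cell stays fixed, which means the
#' higher-order coefficients absorb the move. This is the transformation
#' under which [gdina_truncation_interval()] bounds are exact: any `value`
#' inside the interval yields a monotone item; values outside do not.
#'
#' @param item A [gdina_item()].
#' @param target Coefficient index in subset order (or label).
#' @param value New coefficient value.
#' @return A new `gdina_item` (unchecked; validate with the interval).
#' @export
gdina_set_coefficient <- function(item, target, value) {
  if (is.character(target)) target <- match(target, item$labels)
  P <- gdina_cell_probs(item)
  r <- item$subsets[target]
  P[r + 1L] <- P[r + 1L] - item$delta[target] + value
  gdina_item(cells_to_delta(P, item$subsets), item$kstar, check = FALSE)
}

#' Built-in true G-DINA coefficients for the K = 3 recovery design
#'
#' The fixed generating coefficients paired with [default_q()] `(K = 3)`:
#' single-attribute items have intercept 0.10 and main effect 0.70;
#' two-attribute items use one of three coefficient patterns (including a
#' small negative interaction); three-attribute items mix positive and
#' negative interactions summing to a 0.75 full-mastery probability.
#'
#' @return A tibble with columns `item`, `subset`, `delta`.
#' @export
gdina_true_params <- function() {
  path <- system.file("extdata", "gdina_true_params.csv",
                      package = "slicecdm", mustWork = TRUE)
  df <- utils::read.csv(path, colClasses = c("integer", "character", "numeric"))
  tibble::as_tibble(df)
}

# C x J success probability matrix for gdina_params under the package's
# class enumeration; also used to build the likelihood.
gdina_class_probs <- function(Q, params) {
  prof <- attribute_profiles(ncol(Q))
  C <- nrow(prof)
  P <- matrix(0, C, nrow(Q))
  for (j in seq_len(nrow(Q))) {
    req <- which(Q[j, ] == 1L)
    red <- prof[, req, drop = FALSE]
    cell <- as.integer(red %*% 2L^(seq_along(req) - 1L))
    P[, j] <- gdina_cell_probs(params[[j]])[cell + 1L]
  }
  P
}

# C x J matrix of each class's reduced-profile cell index (bitmask) per item.
reduced_cell_matrix <- function(Q) {
  prof <- attribute_profiles(ncol(Q))
  out <- matrix(0L, nrow(prof), nrow(Q))
  for (j in seq_len(nrow(Q))) {
    req <- which(Q[j, ] == 1L)
    out[, j] <- as.integer(prof[, req, drop = FALSE] %*% 2L^(seq_along(req) - 1L))
  }
  out
}
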