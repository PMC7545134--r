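#' Enumerate all attribute profiles for K attributes
#'
#' Latent classes in a cognitive diagnosis model are the `2^K` binary mastery
#' profiles. The enumeration order is fixed package-wide: attribute `k`
#' contributes bit `k - 1`, so class `c` (1-based) has profile
#' `alpha_k = bit (k-1) of (c - 1)` and conversely
#' `c = 1 + sum_k alpha_k * 2^(k-1)`. Attribute 1 is the least-significant
#' bit; class 1 is the zero profile, class `2^K` is full mastery.
#'
#' @param K Number of attributes (positive integer).
#' @return A `2^K x K` binary matrix; row `c` is the profile of class `c`.
#'   Column names are `A1..AK`.
#' @examples
#' attribute_profiles(2)
#' @export
attribute_profiles <- function(K) {
  stopifnot(is.numeric(K), length(K) == 1L, K >= 1, K == as.integer(K))
  K <- as.integer(K)
  C <- 2L^K
  prof <- matrix(0L, nrow = C, ncol = K,
                 dimnames = list(NULL, paste0("A", seq_len(K))))
  for (k in seq_len(K)) {
    prof[, k] <- bitwAnd(bitwShiftR(0:(C - 1L), k - 1L), 1L)
  }
  prof
}

#' Convert a binary attribute profile to its class index
#'
#' @param bits Binary vector of length K (mastery indicators).
#' @return Integer class index in `1..2^K` under the package's enumeration
#'   (attribute 1 = least-significant bit).
#' @examples
#' profile_to_class(c(1, 0, 1)) # 1 + 1 + 4 = 6
#' @export
profile_to_class <- function(bits) {
  bits <- check_binary_vector(bits, "bits")
  1L + as.integer(sum(bits * 2L^(seq_along(bits) - 1L)))
}

#' Convert a class index to its binary attribute profile
#'
#' @param class_index Integer in `1..2^K`.
#' @param K Number of attributes.
#' @return Binary integer vector of length `K`.
#' @export
class_to_profile <- function(class_index, K) {
  stopifnot(class_index >= 1, class_index <= 2^K)
  bitwAnd(bitwShiftR(as.integer(class_index) - 1L, seq_len(K) - 1L), 1L)
}

# Validate a strictly binary vector; returns it as integer.
check_binary_vector <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || !all(x %in% c(0, 1))) {
    stop(sprintf("'%s' must be a binary (0/1) vector", name), call. = FALSE)
  }
  as.integer(x)
}

# Validate a strictly binary matrix; returns it as integer matrix.
check_binary_matrix <- function(x, name) {
  x <- as.matrix(x)
  bad <- which(!(x %in% c(0, 1)) | is.na(x))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(x)) + 1
    j <- ((bad[1] - 1) %/% nrow(x)) + 1
    stop(sprintf("'%s' must be binary: offending value %s at row %d, column %d",
                 name, deparse(x[bad[1]]), i, j), call. = FALSE)
  }
  storage.mode(x) <- "integer"
  x
}
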