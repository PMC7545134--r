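#' Read a response matrix or Q-matrix from delimited text
#'
#' Both formats are headered CSV with one row per examinee (columns
#' `item_1..item_J`) or per item (columns `A1..AK`), values strictly 0/1.
#' Validation errors name the offending row and column.
#'
#' @param path File path.
#' @param kind `"responses"` or `"qmatrix"`.
#' @return An integer binary matrix; a [q_matrix()] for `kind =
#'   "qmatrix"`.
#' @export
read_matrix <- function(path, kind = c("responses", "qmatrix")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(m, 2, as.numeric))), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at row %d, column %d of %s",
                 bad[1], bad[2], path), call. = FALSE)
  }
  m <- check_binary_matrix(m, basename(path))
  if (kind == "qmatrix") q_matrix(m) else {
    colnames(m) <- paste0("item_", seq_len(ncol(m)))
    m
  }
}

#' Write a binary matrix as headered CSV
#'
#' @param m Matrix (responses or Q-matrix).
#' @param path Output path.
#' @param kind Column naming convention.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, kind = c("responses", "qmatrix")) {
  kind <- match.arg(kind)
  m <- as.matrix(unclass(m))
  colnames(m) <- if (kind == "qmatrix") paste0("A", seq_len(ncol(m)))
                 else paste0("item_", seq_len(ncol(m)))
  utils::write.csv(m, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Persist retained chains as delimited text with a JSON sidecar
#'
#' One CSV per chain (one column per parameter, one row per retained
#' draw) plus `<stem>_manifest.json` carrying the configuration echo,
#' package version, seed, warning counters, and timestamps — every number
#' in downstream reports is re-derivable from these files.
#'
#' @param fit A `cdm_fit`.
#' @param stem Output path stem (directory must exist).
#' @param input_files Optional named character vector of input file paths
#'   whose MD5 digests are recorded in the manifest.
#' @return Character vector of files written, invisibly.
#' @export
write_chains <- function(fit, stem, input_files = NULL) {
  files <- character(0)
  for (ch in seq_along(fit$chains)) {
    f <- sprintf("%s_chain%d.csv", stem, ch)
    utils::write.csv(as.data.frame(fit$chains[[ch]]$draws), f,
                     row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  man <- sprintf("%s_manifest.json", stem)
  jsonlite::write_json(run_manifest(fit, files, input_files), man,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(files, man))
}

#' Read chains written by [write_chains()]
#'
#' @param stem The path stem used when writing.
#' @return A list with `chains` (list of draw matrices) and `manifest`.
#' @export
read_chains <- function(stem) {
  man <- jsonlite::read_json(sprintf("%s_manifest.json", stem),
                             simplifyVector = TRUE)
  chains <- lapply(man$files, function(f) {
    as.matrix(utils::read.csv(f, check.names = FALSE))
  })
  list(chains = chains, manifest = man)
}

# Run manifest: configuration echo plus audit counters.
run_manifest <- function(fit, files, input_files = NULL) {
  counters <- warning_counters(fit)
  digests <- if (length(input_files)) {
    as.list(tools::md5sum(input_files))
  }
  list(
    package = "slicecdm",
    version = as.character(utils::packageVersion("slicecdm")),
    model = fit$model, sampler = fit$sampler,
    dims = as.list(fit$dims), config = fit$config,
    prior = list(family = fit$prior$family, params = as.list(fit$prior$params),
                 dirichlet_phi0 = fit$prior$dirichlet_phi0),
    proposal_sd = if (fit$sampler == "mh") fit$proposal_sd else NULL,
    counters = as.list(counters),
    input_digests = digests,
    files = files,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}
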