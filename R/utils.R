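#' Derive a reproducible child seed from a master seed
#'
#' Deterministically maps a master seed plus a stream of integer tags
#' (e.g. iteration, dimension, k) to a new seed in `[1, 2^31 - 2]`, so that
#' every randomised unit of work in the pipeline is independently
#' reproducible from one master seed.
#'
#' @param master integer master seed.
#' @param ... further integer tags identifying the unit of work.
#' @return a single integer seed.
#' @export
derive_seed <- function(master, ...) {
  tags <- c(master, unlist(list(...)))
  stopifnot(all(is.finite(tags)))
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  s <- 0
  for (t in as.numeric(tags)) {
    # mixed congruential step; doubles hold these products exactly (< 2^53)
    s <- (s * 48271 + (t %% m) * 16807 + 12345) %% m
  }
  as.integer(s %% (m - 1) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

#' Write a matrix as TSV with an id column
#'
#' First column holds row ids (default column name `probe_id`), remaining
#' columns the matrix columns with their names as header.
#' @param x numeric matrix with rownames and colnames.
#' @param path output file.
#' @param id_name header for the id column.
#' @export
write_matrix_tsv <- function(x, path, id_name = "probe_id") {
  df <- data.frame(id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_matrix_tsv()]
#' @param path input file.
#' @return numeric matrix with rownames from the first column.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
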