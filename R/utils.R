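#' Derive a reproducible child seed
#'
#' Hashes a master seed together with one or more integer indices into a new
#' seed in `[1, 2^31 - 2]`. Every stage and every sample of the pipeline draws
#' its own seed through this function, so no stage consumes global random
#' state and any sample can be regenerated in isolation.
#'
#' @param master integer master seed.
#' @param ... further integers (e.g. a sample index, a stage number).
#' @return a single integer seed.
#' @export
derive_seed <- function(master, ...) {
  ix <- c(master, ...)
  stopifnot(length(ix) >= 1, all(is.finite(ix)))
  # 64-bit-safe multiplicative hash done in doubles below 2^53
  h <- 0
  for (v in as.numeric(ix)) {
    h <- (h * 48271 + (v %% 2147483647) + 1) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Write a data frame as TSV
#'
#' Plain tab-separated output with no quoting and no row names; the format all
#' pipeline artifacts (frequency tables, F-measure reports, cluster profiles)
#' are exported in.
#'
#' @param x data frame.
#' @param path output path.
#' @export
write_tsv_out <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
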