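# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
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
  }
  force(code)
}

# Fixed stream indices: adding a stream never perturbs existing ones.
.sim_streams <- c(
  compounds = 1L, genes = 2L, graph = 3L, expression = 4L,
  embedding = 5L, annotation = 6L
)

#' Derive a per-stream child seed from one global seed
#' @noRd
child_seed <- function(seed, stream) {
  idx <- .sim_streams[[stream]]
  with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L,
                                         length(.sim_streams)))[idx]
}

#' Deterministic polynomial hash of an integer vector, in [0, 2^31 - 2]
#'
#' All intermediates stay below 2^53, so the arithmetic is exact in doubles.
#' @noRd
poly_hash <- function(ints) {
  m <- 2147483647
  h <- 17
  for (x in as.numeric(ints)) {
    h <- (h * 31 + (x %% m)) %% m
  }
  h
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Write a data.frame as a UTF-8 TSV with a single header row
#' @noRd
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
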