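#' Validate a feature map
#'
#' Feature maps are 4-D numeric arrays laid out `(row, col, channel, sample)`,
#' the column-major convention also used by EBImage.  All values must be
#' finite and every dimension at least 1.
#'
#' @param x object to check.
#' @param what name used in error messages.
#' @return `x`, invisibly, if valid.
#' @export
check_feature_map <- function(x, what = "feature map") {
  if (!is.array(x) || length(dim(x)) != 4L || !is.numeric(x))
    stop(what, " must be a 4-D numeric array (row, col, channel, sample)",
         call. = FALSE)
  if (any(dim(x) < 1L))
    stop(what, " has a zero-length dimension", call. = FALSE)
  if (!all(is.finite(x)))
    stop(what, " contains non-finite values", call. = FALSE)
  invisible(x)
}

#' Construct a feature map from a vector or array
#'
#' @param values numeric data.
#' @param dim length-4 integer vector `(rows, cols, channels, samples)`.
#' @return a 4-D array.
#' @export
feature_map <- function(values, dim) {
  x <- array(as.double(values), dim = as.integer(dim))
  check_feature_map(x)
  x
}

# Evaluate expr under a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Reshape (H,W,C,N) -> matrix with one column per channel (rows run over
# H, W, N), and back.  Used by every per-channel operation.
to_cmat <- function(x) {
  d <- dim(x)
  m <- aperm(x, c(1L, 2L, 4L, 3L))
  dim(m) <- c(d[1L] * d[2L] * d[4L], d[3L])
  m
}

from_cmat <- function(m, d) {
  a <- array(m, c(d[1L], d[2L], d[4L], d[3L]))
  aperm(a, c(1L, 2L, 4L, 3L))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Derive stream-specific child seeds from one master seed (kept < 2^31).
derive_seed <- function(seed, k) {
  ((as.integer(seed) %% 1000003L) * 1009L + 97L * as.integer(k)) %% 2147483647L
}
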