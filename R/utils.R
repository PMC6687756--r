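#' Derive a reproducible child seed from a master seed
#'
#' Runs that need several independent random streams (one per training seed,
#' one per population, ...) derive child seeds deterministically from a single
#' master seed and a text tag, so a whole experiment is reproducible from one
#' integer.
#'
#' @param master integer master seed.
#' @param tag character label of the stream (e.g. "run3", "actor-noise").
#' @return An integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(master, tag = "") {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  h <- as.double(master) %% 2147483647
  for (ch in utf8ToInt(as.character(tag))) {
    # 31-bit multiplicative hash, kept in double-safe range
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer(h %% 2147483645) + 1L
}

#' Forward moving average of a series
#'
#' \code{moving_average(x, w)[k]} is the mean of \code{x[k:(k + w - 1)]}: the
#' average of the *next* \code{w} values starting at position \code{k}.  Used
#' to express reward per step over a forward-looking window when judging
#' whether a policy has become optimal.
#'
#' @param x numeric vector.
#' @param w window length (positive integer, \code{w <= length(x)}).
#' @return Numeric vector of length \code{length(x) - w + 1}.
#' @export
moving_average <- function(x, w) {
  stopifnot(is.numeric(x), w >= 1, w <= length(x))
  cs <- cumsum(c(0, x))
  n <- length(x) - w + 1
  (cs[(w + 1):(w + n)] - cs[1:n]) / w
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
assert_finite <- function(x, name = deparse(substitute(x))) {
  if (!all(is.finite(x))) stop("non-finite values in ", name, call. = FALSE)
  invisible(x)
}
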