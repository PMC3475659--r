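# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Display rounding used for linkerity values: ties at .5 round away from
#' zero (so 9.185 -> 9.19), unlike [base::round()]'s round-half-to-even.
#' Internal analysis always keeps full precision; this is presentation only.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits (default 2).
#' @return Rounded numeric vector.
#' @export
round_display <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# run `expr` under `seed` when non-NULL, otherwise in the ambient RNG state
with_seed_opt <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# decode pair index in 1..choose(n,2) into (i, j), i < j, lexicographic order;
# lets us sample edges uniformly without enumerating all node pairs.
# pairs with first index < i number S(i-1) = (i-1)n - i(i-1)/2
decode_pair <- function(idx, n) {
  i <- ceiling(((2 * n - 1) - sqrt((2 * n - 1)^2 - 8 * idx)) / 2)
  offset <- (i - 1) * n - i * (i - 1) / 2
  j <- i + (idx - offset)
  cbind(i, j)
}

# unordered-pair key for character endpoints
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

abort_if <- function(cond, msg) {
  if (cond) rlang::abort(msg)
}
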