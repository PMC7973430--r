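clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Stable integer hash of a character tuple
#'
#' Deterministic 31-adic rolling hash over the UTF-8 code points of the
#' `|`-joined arguments, reduced modulo 2^31 - 1. Used to derive scene seeds
#' from factor tuples so runs are reproducible across sessions and platforms.
#'
#' @param ... atomic values, coerced to character.
#' @param init integer offset folded into the hash (typically a master seed).
#' @return a non-negative integer below 2^31 - 1.
#' @export
stable_hash <- function(..., init = 0L) {
  s <- paste(vapply(list(...), function(x) paste(as.character(x), collapse = ","),
                    character(1)), collapse = "|")
  h <- as.numeric(init) %% 2147483647
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}

gaussian_kernel2d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(2.5 * sigma)))
  xs <- -r:r
  g <- exp(-xs^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}
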