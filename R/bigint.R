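## Exact non-negative integer arithmetic --------------------------------------
##
## Coding bounds involve quantities like 4^90 that overflow doubles, and the
## comparisons they feed must be exact, so bounds arithmetic is done on
## arbitrary-precision non-negative integers stored as little-endian limb
## vectors in base 1e7.  Only the handful of operations the bounds need are
## provided: add, multiply, exact small division, compare and power.

.BIG_BASE <- 1e7

big_from_num <- function(x) {
  x <- as.numeric(x)
  stopifnot(length(x) == 1L, !is.na(x), x >= 0, x == floor(x), x < 2^53)
  limbs <- numeric(0)
  repeat {
    limbs <- c(limbs, x %% .BIG_BASE)
    x <- floor(x / .BIG_BASE)
    if (x == 0) break
  }
  structure(limbs, class = "bigint")
}

.big_norm <- function(limbs) {
  carry <- 0
  out <- numeric(0)
  i <- 1L
  while (i <= length(limbs) || carry > 0) {
    v <- carry + if (i <= length(limbs)) limbs[i] else 0
    out[i] <- v %% .BIG_BASE
    carry <- floor(v / .BIG_BASE)
    i <- i + 1L
  }
  while (length(out) > 1L && out[length(out)] == 0) out <- out[-length(out)]
  structure(out, class = "bigint")
}

big_add <- function(a, b) {
  la <- length(a); lb <- length(b); l <- max(la, lb)
  .big_norm(c(unclass(a), numeric(l - la)) + c(unclass(b), numeric(l - lb)))
}

# multiply by a plain number below 2^26 (limb products stay exact)
big_mul_small <- function(a, s) {
  stopifnot(s >= 0, s == floor(s), s < 2^26)
  if (s == 0) return(big_from_num(0))
  .big_norm(unclass(a) * s)
}

big_mul <- function(a, b) {
  A <- unclass(a); B <- unclass(b)
  acc <- big_from_num(0)
  for (i in seq_along(B)) {
    if (B[i] == 0) next
    # limb products stay below 1e14, well inside exact double range
    acc <- big_add(acc, .big_norm(c(numeric(i - 1L), A * B[i])))
  }
  acc
}

# exact division by a plain positive number (errors if not exact)
big_div_small <- function(a, s) {
  stopifnot(s > 0, s == floor(s), s < 2^26)
  limbs <- rev(unclass(a))
  out <- numeric(length(limbs))
  rem <- 0
  for (i in seq_along(limbs)) {
    cur <- rem * .BIG_BASE + limbs[i]
    out[i] <- floor(cur / s)
    rem <- cur - out[i] * s
  }
  if (rem != 0) stop("big_div_small: division is not exact", call. = FALSE)
  .big_norm(rev(out))
}

# -1, 0, 1 as a < b, a == b, a > b
big_cmp <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  la <- length(a); lb <- length(b)
  if (la != lb) return(if (la < lb) -1L else 1L)
  for (i in rev(seq_len(la))) {
    if (a[i] != b[i]) return(if (a[i] < b[i]) -1L else 1L)
  }
  0L
}

big_pow_small <- function(base, exp) {
  stopifnot(exp >= 0, exp == floor(exp))
  out <- big_from_num(1)
  for (i in seq_len(exp)) out <- big_mul_small(out, base)
  out
}

#' @export
format.bigint <- function(x, ...) {
  limbs <- rev(unclass(x))
  paste0(sprintf("%.0f", limbs[1L]),
         paste(sprintf("%07.0f", limbs[-1L]), collapse = ""))
}

#' @export
print.bigint <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
as.character.bigint <- function(x, ...) format(x)

#' @export
as.double.bigint <- function(x, ...) {
  v <- sum(unclass(x) * .BIG_BASE^(seq_along(x) - 1L))
  if (v >= 2^53) warning("bigint exceeds exact double range", call. = FALSE)
  v
}
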