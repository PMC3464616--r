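## q-ary coding bounds --------------------------------------------------------

.check_nkq <- function(n, k = NULL, q = NULL) {
  stopifnot(n >= 1, n == floor(n))
  if (!is.null(k)) stopifnot(k >= 1, k <= n, k == floor(k))
  if (!is.null(q)) stopifnot(q >= 2, q == floor(q))
}

#' Volume of a Hamming ball
#'
#' The number of q-ary words within Hamming distance `r` of a fixed word of
#' length `n`: `sum_(i=0..r) choose(n, i) (q-1)^i`, computed in exact
#' integer arithmetic.
#'
#' @param n word length.
#' @param r ball radius, `0 <= r <= n`.
#' @param q alphabet size.
#' @return A `bigint`; coerce with `as.numeric()` when small enough.
#' @examples
#' as.numeric(sphere_volume(60, 1, 4))  # 181
#' @export
sphere_volume <- function(n, r, q) {
  .check_nkq(n, q = q)
  stopifnot(r >= 0, r <= n, r == floor(r))
  total <- big_from_num(1)
  term <- big_from_num(1)
  for (i in seq_len(r)) {
    # term_i = term_(i-1) * (n - i + 1) * (q - 1) / i, always exact
    term <- big_div_small(big_mul_small(big_mul_small(term, n - i + 1), q - 1), i)
    total <- big_add(total, term)
  }
  total
}

#' Hamming (sphere-packing) limit on guaranteed correction
#'
#' The largest `t` such that disjoint radius-`t` balls around `q^k`
#' codewords can fit in the space of `q^n` words, i.e. the largest `t` with
#' `sphere_volume(n, t, q) <= q^(n-k)`.  No length-`n`, dimension-`k` code
#' can guarantee to correct more than this many errors.
#'
#' @param n code length.
#' @param k source length.
#' @param q alphabet size.
#' @return An integer.
#' @examples
#' hamming_max_correctable(60, 50, 4)  # 3
#' @export
hamming_max_correctable <- function(n, k, q) {
  .check_nkq(n, k, q)
  budget <- big_pow_small(q, n - k)
  t <- 0L
  total <- big_from_num(1)
  term <- big_from_num(1)
  while (t < n) {
    i <- t + 1L
    term <- big_div_small(big_mul_small(big_mul_small(term, n - i + 1), q - 1), i)
    total <- big_add(total, term)
    if (big_cmp(total, budget) > 0L) break
    t <- i
  }
  t
}

#' Gilbert and Varshamov existence bounds on minimum distance
#'
#' `gilbert_guaranteed_distance()` returns the largest `d` for which the
#' Gilbert argument guarantees a (not necessarily linear) code of size
#' `q^k`: a code of size `M` exists whenever
#' `M * sphere_volume(n, d-1, q) <= q^n`.
#' `varshamov_guaranteed_distance()` is the strictly stronger linear-code
#' form (largest `d` with `sphere_volume(n-1, d-2, q) < q^(n-k)`), provided
#' for comparison and clearly labelled: the two forms differ for the
#' parameter sets of interest here.
#'
#' @param n code length.
#' @param k source length.
#' @param q alphabet size.
#' @return An integer minimum distance.
#' @examples
#' gilbert_guaranteed_distance(60, 50, 4)  # 4
#' @export
gilbert_guaranteed_distance <- function(n, k, q) {
  .check_nkq(n, k, q)
  budget <- big_pow_small(q, n - k)
  r <- 0L
  total <- big_from_num(1)
  term <- big_from_num(1)
  while (r < n) {
    i <- r + 1L
    term <- big_div_small(big_mul_small(big_mul_small(term, n - i + 1), q - 1), i)
    total <- big_add(total, term)
    if (big_cmp(total, budget) > 0L) break
    r <- i
  }
  r + 1L
}

#' @rdname gilbert_guaranteed_distance
#' @export
varshamov_guaranteed_distance <- function(n, k, q) {
  .check_nkq(n, k, q)
  budget <- big_pow_small(q, n - k)
  d <- 1L
  while (d < n) {
    vol <- sphere_volume(n - 1, d - 1, q)   # radius (d+1)-2 for candidate d+1
    if (big_cmp(vol, budget) >= 0L) break
    d <- d + 1L
  }
  d
}

#' Singleton limit on minimum distance
#'
#' @param n code length.
#' @param k source length.
#' @return `n - k + 1`, the largest minimum distance any code of these
#'   dimensions can have.
#' @export
singleton_max_distance <- function(n, k) {
  .check_nkq(n, k)
  as.integer(n - k + 1L)
}

#' Johnson-type upper bound on code size
#'
#' Upper bound on `A_q(n, d)`, the largest q-ary code of length `n` and
#' minimum distance `d`.  Variant implemented (documented here because the
#' bound family has several forms): the anticode/Plotkin recursion
#' `A_q(n, d) <= q * A_q(n-1, d)`, applied until `q d > (q-1) n0`, at which
#' point `A_q(n0, d) <= floor(q d / (q d - (q-1) n0))`; i.e.
#' `A_q(n, d) <= q^(n - n0) * floor(q d / (q d - (q-1) n0))` with
#' `n0 = floor((q d - 1) / (q - 1))`.  For `d = 1` the space itself is a
#' code, so the bound is `q^n`.
#'
#' @param n code length.
#' @param d minimum distance, `1 <= d <= n`.
#' @param q alphabet size.
#' @return A `bigint` upper bound on the number of codewords.
#' @examples
#' as.numeric(johnson_max_codewords(4, 4, 2))  # 2: the repetition code
#' @export
johnson_max_codewords <- function(n, d, q) {
  .check_nkq(n, q = q)
  stopifnot(d >= 1, d <= n, d == floor(d))
  if (d == 1) return(big_pow_small(q, n))
  n0 <- min(n, floor((q * d - 1) / (q - 1)))
  head_bound <- floor(q * d / (q * d - (q - 1) * n0))
  big_mul_small(big_pow_small(q, n - n0), head_bound)
}

#' Error-handling capabilities implied by a minimum distance
#'
#' @param d minimum distance, `d >= 1`.
#' @return A list with `correct` (`floor((d-1)/2)`), `detect` (`d - 1`) and
#'   `simultaneous`, a data frame of the `(correct, detect)` pairs
#'   `c <= e`, `c + e <= d - 1` achievable at once.
#' @examples
#' distance_capabilities(4)  # correct 1 while detecting 2
#' @export
distance_capabilities <- function(d) {
  stopifnot(d >= 1, d == floor(d))
  pairs <- expand.grid(correct = 0:max(0L, d - 1L), detect = 0:max(0L, d - 1L))
  pairs <- pairs[pairs$correct <= pairs$detect &
                   pairs$correct + pairs$detect <= d - 1L, , drop = FALSE]
  pairs <- pairs[order(pairs$correct, pairs$detect), ]
  rownames(pairs) <- NULL
  list(correct = as.integer((d - 1L) %/% 2L),
       detect = as.integer(d - 1L),
       simultaneous = pairs)
}

# Largest t for which an upper bound still admits q^k codewords at d = 2t+1.
.johnson_max_correctable <- function(n, k, q) {
  size_needed <- big_pow_small(q, k)
  t <- 0L
  while (2L * (t + 1L) + 1L <= n) {
    if (big_cmp(johnson_max_codewords(n, 2L * (t + 1L) + 1L, q),
                size_needed) < 0L) break
    t <- t + 1L
  }
  t
}

#' Summary table of coding bounds for given parameters
#'
#' Collects, for an `(n, k)` code over a `q`-letter alphabet: the minimum
#' distance whose existence the Gilbert bound guarantees (with the
#' correction/detection capabilities it implies), the stronger Varshamov
#' linear-code distance, and the maximum guaranteed-correctable error count
#' permitted by each implemented upper bound (Hamming, Singleton, Johnson).
#'
#' @param n code length.
#' @param k source length.
#' @param q alphabet size.
#' @return An object of class `bounds_table`: a list with `guaranteed`
#'   (Gilbert/Varshamov existence results) and `upper` (a data frame, one
#'   row per upper bound).
#' @examples
#' bounds_table(60, 50, 4)
#' @export
bounds_table <- function(n, k, q) {
  .check_nkq(n, k, q)
  d_gilbert <- gilbert_guaranteed_distance(n, k, q)
  caps <- distance_capabilities(d_gilbert)
  upper <- data.frame(
    bound = c("hamming", "johnson", "singleton"),
    max_correctable = c(
      hamming_max_correctable(n, k, q),
      .johnson_max_correctable(n, k, q),
      (singleton_max_distance(n, k) - 1L) %/% 2L))
  structure(list(n = n, k = k, q = q,
                 guaranteed = list(
                   gilbert_distance = d_gilbert,
                   correct = caps$correct,
                   detect = caps$detect,
                   simultaneous = caps$simultaneous,
                   varshamov_distance = varshamov_guaranteed_distance(n, k, q)),
                 upper = upper),
            class = "bounds_table")
}

#' @export
print.bounds_table <- function(x, ...) {
  cat(sprintf("Coding bounds for n = %d, k = %d, q = %d\n", x$n, x$k, x$q))
  g <- x$guaranteed
  cat(sprintf("  Gilbert existence: a code with minimum distance %d exists\n",
              g$gilbert_distance))
  cat(sprintf("    -> can correct %d while detecting %d errors\n",
              g$correct, g$detect))
  cat(sprintf("  Varshamov (linear-code form, stronger): distance %d\n",
              g$varshamov_distance))
  cat("  Upper limits on guaranteed-correctable errors:\n")
  for (i in seq_len(nrow(x$upper))) {
    cat(sprintf("    %-9s t <= %d\n", x$upper$bound[i],
                x$upper$max_correctable[i]))
  }
  invisible(x)
}
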