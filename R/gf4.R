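## GF(4) arithmetic ----------------------------------------------------------
##
## The four-element field is the common algebra behind nucleotides, SOLiD
## colors and error types.  Elements are represented throughout the package as
## plain integers 0..3 standing for the abstract symbols {0, 1, alpha, beta}.
## With this labelling (alpha = 2, beta = 3) addition is bitwise XOR
## (characteristic 2) and multiplication is a 4x4 lookup table.

# Multiplication table, MUL[a + 1, b + 1] = a (x) b.
.GF4_MUL <- matrix(as.integer(c(
  0L, 0L, 0L, 0L,
  0L, 1L, 2L, 3L,
  0L, 2L, 3L, 1L,
  0L, 3L, 1L, 2L
)), nrow = 4L, byrow = TRUE)

# Multiplicative inverses of the nonzero elements: 1 -> 1, alpha -> beta,
# beta -> alpha.
.GF4_INV <- c(NA_integer_, 1L, 3L, 2L)

# flat copy for vectorised lookups (a matrix-shaped index into a matrix
# would otherwise be read as coordinate pairs)
.GF4_MULV <- as.integer(.GF4_MUL)

.GF4_SYMBOL <- c("0", "1", "a", "b")
.GF4_BASE   <- c("A", "C", "G", "T")
.GF4_COLOR  <- c("0", "1", "2", "3")

# Additive-offset interpretation in base space (metadata only; arithmetic
# never consults these labels).
.GF4_ERROR_LABEL <- c("identity", "transcomplement", "transition", "complement")

.check_gf4 <- function(x, what = "value") {
  if (length(x) == 0L) return(invisible(x))
  if (anyNA(x) || any(x < 0L | x > 3L) || any(x != as.integer(x))) {
    stop(sprintf("%s must consist of GF(4) elements coded as integers 0-3", what),
         call. = FALSE)
  }
  invisible(x)
}

#' GF(4) arithmetic on integer-coded elements
#'
#' Elements of the four-element finite field are coded as integers
#' `0, 1, 2, 3` standing for `0, 1, alpha, beta`.  Under this coding
#' addition is bitwise XOR and every element is its own additive inverse
#' (the field has characteristic 2).  Nucleotides `A, C, G, T` and SOLiD
#' colors `0, 1, 2, 3` are alternative labellings of the same four
#' elements; see [gf4_convert()].
#'
#' @param a,b integer vectors of GF(4) elements (values 0-3); recycled to a
#'   common length.
#' @return An integer vector of GF(4) elements.
#' @examples
#' gf4_add(1L, 3L)  # 1 + beta = alpha (2)
#' gf4_mul(3L, 3L)  # beta * beta = alpha (2)
#' gf4_inv(2L)      # alpha^-1 = beta (3)
#' @export
gf4_add <- function(a, b) {
  .check_gf4(a); .check_gf4(b)
  bitwXor(as.integer(a), as.integer(b))
}

#' @rdname gf4_add
#' @export
gf4_mul <- function(a, b) {
  .check_gf4(a); .check_gf4(b)
  n <- max(length(a), length(b))
  a <- rep_len(as.integer(a), n)
  b <- rep_len(as.integer(b), n)
  .GF4_MUL[a * 4L + b + 1L]
}

#' @rdname gf4_add
#' @export
gf4_inv <- function(a) {
  .check_gf4(a)
  if (any(a == 0L)) {
    stop("0 has no multiplicative inverse in GF(4)", call. = FALSE)
  }
  .GF4_INV[as.integer(a) + 1L]
}

#' Sum of a GF(4) vector (XOR reduction)
#' @param x integer vector of GF(4) elements.
#' @return A single GF(4) element.
#' @export
gf4_sum <- function(x) {
  .check_gf4(x)
  Reduce(bitwXor, as.integer(x), accumulate = FALSE, right = FALSE) %||% 0L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# bitwXor strips dim attributes; this keeps the shape of `a`
.xor_dim <- function(a, b) {
  r <- bitwXor(a, b)
  dim(r) <- dim(a)
  r
}

#' Matrix product over GF(4)
#'
#' Row-vector times matrix and matrix times matrix products with addition and
#' multiplication carried out in GF(4).  All operands are integer matrices (or
#' vectors, treated as single rows) with entries 0-3.
#'
#' @param A,B integer matrices over GF(4); `ncol(A)` must equal `nrow(B)`.
#' @return The integer matrix product over GF(4).
#' @export
gf4_matmul <- function(A, B) {
  if (is.null(dim(A))) A <- matrix(as.integer(A), nrow = 1L)
  if (is.null(dim(B))) B <- matrix(as.integer(B), ncol = 1L)
  .check_gf4(A, "matrix"); .check_gf4(B, "matrix")
  if (ncol(A) != nrow(B)) stop("non-conformable GF(4) matrices", call. = FALSE)
  out <- matrix(0L, nrow(A), ncol(B))
  for (i in seq_len(nrow(B))) {
    # accumulate outer contribution of A[, i] and B[i, ]
    contrib <- .GF4_MULV[outer(A[, i], B[i, ], function(a, b) a * 4L + b + 1L)]
    out <- .xor_dim(out, matrix(contrib, nrow(A), ncol(B)))
  }
  out
}

#' Identity matrix over GF(4)
#' @param n dimension.
#' @return An `n` by `n` integer identity matrix.
#' @export
gf4_identity <- function(n) diag(1L, n, n)

#' Invert a square matrix over GF(4) by Gaussian elimination
#'
#' @param A a square integer matrix over GF(4).
#' @return The inverse matrix, or an error if `A` is singular.
#' @export
gf4_solve <- function(A) {
  .check_gf4(A, "matrix")
  n <- nrow(A)
  if (is.null(n) || n != ncol(A)) stop("matrix must be square", call. = FALSE)
  aug <- cbind(A, gf4_identity(n))
  for (col in seq_len(n)) {
    piv <- which(aug[col:n, col] != 0L)[1L]
    if (is.na(piv)) stop("matrix is singular over GF(4)", call. = FALSE)
    piv <- piv + col - 1L
    if (piv != col) aug[c(col, piv), ] <- aug[c(piv, col), ]
    aug[col, ] <- gf4_mul(gf4_inv(aug[col, col]), aug[col, ])
    for (row in seq_len(n)[-col]) {
      if (aug[row, col] != 0L) {
        aug[row, ] <- bitwXor(aug[row, ], gf4_mul(aug[row, col], aug[col, ]))
      }
    }
  }
  aug[, n + seq_len(n), drop = FALSE]
}

## Alphabet conversions ------------------------------------------------------

#' Convert between GF(4) elements, nucleotides, colors and field symbols
#'
#' The fixed bijections are `A,C,G,T <-> 0,1,alpha,beta` for nucleotides and
#' `0,1,2,3 <-> 0,1,alpha,beta` for colors.  The `"gf4"` alphabet uses the
#' symbols `0,1,a,b`.
#'
#' @param x for `to-field`, a character vector of single symbols or a single
#'   string (split into characters); for `from-field`, an integer vector of
#'   GF(4) elements.
#' @param alphabet one of `"base"`, `"color"`, `"gf4"`.
#' @param direction `"to-field"` or `"from-field"`.
#' @return An integer vector of GF(4) elements (`to-field`) or a character
#'   vector of symbols (`from-field`).
#' @examples
#' gf4_convert("G", "base")                 # 2 (alpha)
#' gf4_convert(c(0L, 1L, 2L), "base", "from-field")  # "A" "C" "G"
#' @export
gf4_convert <- function(x, alphabet = c("base", "color", "gf4"),
                        direction = c("to-field", "from-field")) {
  alphabet <- match.arg(alphabet)
  direction <- match.arg(direction)
  symbols <- switch(alphabet, base = .GF4_BASE, color = .GF4_COLOR,
                    gf4 = .GF4_SYMBOL)
  if (direction == "from-field") {
    .check_gf4(x)
    return(symbols[as.integer(x) + 1L])
  }
  if (is.character(x) && length(x) == 1L && nchar(x) > 1L) {
    x <- strsplit(x, "", fixed = TRUE)[[1L]]
  }
  if (alphabet == "base") x <- toupper(x)
  idx <- match(x, symbols)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop(sprintf("unknown %s symbol '%s' at position %d", alphabet,
                 x[bad], bad), call. = FALSE)
  }
  idx - 1L
}

#' Shorthand alphabet conversions
#'
#' Thin wrappers around [gf4_convert()]: `bases_to_gf4()`/`gf4_to_bases()` map
#' nucleotide characters to field elements and back; the color variants do the
#' same for color digits.  String inputs of length one are split into
#' characters; the `gf4_to_*` functions return a single collapsed string.
#'
#' @param x a character vector/string (`*_to_gf4`) or integer vector of GF(4)
#'   elements (`gf4_to_*`).
#' @return An integer vector, or a single string for the `gf4_to_*` direction.
#' @export
bases_to_gf4 <- function(x) gf4_convert(x, "base", "to-field")

#' @rdname bases_to_gf4
#' @export
gf4_to_bases <- function(x) paste(gf4_convert(x, "base", "from-field"),
                                  collapse = "")

#' @rdname bases_to_gf4
#' @export
colors_to_gf4 <- function(x) gf4_convert(x, "color", "to-field")

#' @rdname bases_to_gf4
#' @export
gf4_to_colors <- function(x) paste(gf4_convert(x, "color", "from-field"),
                                   collapse = "")

#' Name the base-space interpretation of an additive error offset
#'
#' Adding a nonzero field element to a base has a concrete biological
#' reading: `+1` preserves amino/keto class ("transcomplement"), `+alpha` is a
#' transition and `+beta` complements the base; `+0` is the identity.  The
#' label is metadata only and never enters any arithmetic.
#'
#' @param offset integer vector of GF(4) elements.
#' @return A character vector of labels.
#' @examples
#' error_type_label(0:3)
#' @export
error_type_label <- function(offset) {
  .check_gf4(offset, "offset")
  .GF4_ERROR_LABEL[as.integer(offset) + 1L]
}
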