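## Probe generators and the code family --------------------------------------
##
## A probe generator is the vector of 5 GF(4) coefficients (p1..p5) that
## defines the color a ligated probe reports for the 5-base window it
## interrogates: color = sum_i p_i * b_i.  The two-base chemistry uses
## rho1 = 11000; the ECC round uses rho2 = 1b0b0 (interrogating window
## positions 1, 2 and 4).

#' Construct a probe generator
#'
#' @param x the 5 coefficients, either as an integer vector of GF(4)
#'   elements or as a 5-character string over `0 1 a b` (field symbols) or
#'   `0 1 2 3` (colors); the two notations agree on `0` and `1`.
#' @return An object of class `probe_generator` (an integer vector of length
#'   5 with a class attribute).
#' @examples
#' probe_generator("1b0b0")   # the ECC probe set
#' probe_generator("11000")   # the two-base-encoding probe set
#' @export
probe_generator <- function(x) {
  if (inherits(x, "probe_generator")) return(x)
  if (is.character(x)) {
    if (length(x) == 1L) x <- strsplit(x, "", fixed = TRUE)[[1L]]
    map <- c("0" = 0L, "1" = 1L, "2" = 2L, "3" = 3L,
             "a" = 2L, "b" = 3L, "A" = 2L, "B" = 3L)
    coef <- unname(map[x])
    if (anyNA(coef)) {
      stop(sprintf("unknown probe coefficient '%s'; use characters 0,1,a,b or 0-3",
                   x[which(is.na(coef))[1L]]), call. = FALSE)
    }
  } else {
    coef <- as.integer(x)
    .check_gf4(coef, "probe coefficient")
  }
  if (length(coef) != 5L) {
    stop("a probe generator has exactly 5 coefficients", call. = FALSE)
  }
  structure(coef, class = "probe_generator")
}

#' @rdname probe_generator
#' @export
ecc_probe <- function() probe_generator(c(1L, 3L, 0L, 3L, 0L))

#' @rdname probe_generator
#' @export
two_base_probe <- function() probe_generator(c(1L, 1L, 0L, 0L, 0L))

#' @export
format.probe_generator <- function(x, ...) {
  paste(.GF4_SYMBOL[unclass(x) + 1L], collapse = "")
}

#' @export
print.probe_generator <- function(x, ...) {
  cat("<probe generator ", format(x), ">\n", sep = "")
  invisible(x)
}

#' Build the invertible 5x5 block generator for a probe set
#'
#' Ignoring the junction parity colors, each 5-base block `b` of a read maps
#' to its 5 data colors as `c = b %*% G`, where columns 1-4 of `G` form the
#' within-block adjacent-pair sums `c_j = b_j + b_(j+1)` and column 5 holds
#' the second-round probe coefficients.  The inverse is computed in closed
#' form: with `L` the lower-triangular all-ones matrix, `x = L p` and
#' `y = x_5`, the inverse is `[I | x y^-1 ; 0 | y^-1] L`.  It exists exactly
#' when `y`, the GF(4) sum of the probe coefficients, is nonzero.
#'
#' @param probe a [probe_generator()] (or anything it accepts).
#' @return An object of class `block_generator` with components `forward`,
#'   `inverse` (5x5 integer matrices over GF(4)), `probe`, `L`, `x` and `y`.
#' @examples
#' gen <- block_generator(ecc_probe())
#' encode_block("ACGAT", gen)   # colors 13233
#' @export
block_generator <- function(probe) {
  probe <- probe_generator(probe)
  p <- as.integer(probe)
  L <- matrix(0L, 5L, 5L)
  L[lower.tri(L, diag = TRUE)] <- 1L
  x <- as.integer(gf4_matmul(L, p))      # x_i = p_1 + ... + p_i
  y <- x[5L]
  if (y == 0L) {
    stop(sprintf(paste0("probe generator %s does not yield an invertible block",
                        " generator: the GF(4) sum of its coefficients is zero"),
                 format(probe)), call. = FALSE)
  }
  forward <- matrix(0L, 5L, 5L)
  for (j in 1:4) forward[c(j, j + 1L), j] <- 1L
  forward[, 5L] <- p
  yinv <- gf4_inv(y)
  A <- gf4_identity(5L)
  A[1:4, 5L] <- gf4_mul(x[1:4], yinv)
  A[5L, 5L] <- yinv
  inverse <- gf4_matmul(A, L)
  stopifnot(identical(gf4_matmul(forward, inverse), gf4_identity(5L)))
  structure(list(forward = forward, inverse = inverse, probe = probe,
                 L = L, x = x, y = y),
            class = "block_generator")
}

#' @export
print.block_generator <- function(x, ...) {
  cat("<block generator for probe ", format(x$probe), ", y = ",
      .GF4_SYMBOL[x$y + 1L], ">\n", sep = "")
  invisible(x)
}

#' Encode or decode a single 5-base block
#'
#' `encode_block()` maps 5 bases to their 5 data colors (`b %*% forward`);
#' `decode_block()` inverts (`c %*% inverse`).  The two are mutually inverse
#' on all 1024 blocks for any invertible probe generator.
#'
#' @param bases 5 bases as a string (`"ACGAT"`) or integer GF(4) vector.
#' @param colors 5 data colors as a string (`"13233"`) or integer GF(4)
#'   vector.
#' @param gen a [block_generator()].
#' @return An integer GF(4) vector of length 5 (colors for `encode_block`,
#'   bases for `decode_block`); render with [gf4_to_colors()] or
#'   [gf4_to_bases()].
#' @export
encode_block <- function(bases, gen) {
  b <- if (is.character(bases)) bases_to_gf4(bases) else as.integer(bases)
  if (length(b) != 5L) stop("a block has exactly 5 bases", call. = FALSE)
  as.integer(gf4_matmul(b, gen$forward))
}

#' @rdname encode_block
#' @export
decode_block <- function(colors, gen) {
  cc <- if (is.character(colors)) colors_to_gf4(colors) else as.integer(colors)
  if (length(cc) != 5L) stop("a block has exactly 5 data colors", call. = FALSE)
  as.integer(gf4_matmul(cc, gen$inverse))
}

## Code specification and read encoding --------------------------------------

#' Specify an ECC-style punctured code
#'
#' A read of `k` bases (`k` a multiple of 5) is encoded into `n = 6k/5`
#' colors: `k` two-base colors (the first formed against the known adapter
#' base) plus one punctured second-stream color per 5-base block.
#'
#' @param read_length read length `k` in bases; must be a positive multiple
#'   of 5.
#' @param probe the second-round probe generator (default the ECC probe
#'   `1b0b0`).
#' @param adapter the known adapter base adjacent to the template, as a
#'   nucleotide character (default `"T"`, the CSFASTA convention).
#' @return An object of class `code_spec` with components `k`, `m` (number
#'   of blocks), `n`, `probe`, `gen` (the [block_generator()]) and `adapter`
#'   (GF(4) element).
#' @examples
#' code <- ecc_code(50)
#' code$n   # 60 colors
#' @export
ecc_code <- function(read_length, probe = ecc_probe(), adapter = "T") {
  k <- as.integer(read_length)
  if (is.na(k) || k <= 0L || k %% 5L != 0L) {
    stop("read length must be a positive multiple of 5 bases", call. = FALSE)
  }
  probe <- probe_generator(probe)
  adapter <- if (is.character(adapter)) bases_to_gf4(adapter) else {
    .check_gf4(adapter, "adapter"); as.integer(adapter)
  }
  if (length(adapter) != 1L) stop("adapter is a single base", call. = FALSE)
  structure(list(k = k, m = k %/% 5L, n = k + k %/% 5L,
                 probe = probe, gen = block_generator(probe),
                 adapter = adapter),
            class = "code_spec")
}

#' @export
print.code_spec <- function(x, ...) {
  cat(sprintf("<code spec: k = %d bases, n = %d colors (%d blocks), probe %s, adapter %s>\n",
              x$k, x$n, x$m, format(x$probe), .GF4_BASE[x$adapter + 1L]))
  invisible(x)
}

# Batch encoder: B is an N x k integer matrix of bases, one read per row.
# Returns list(stream = N x k two-base colors, ecc = N x m second-stream
# colors).  encode_read() is the single-read wrapper.
.encode_batch <- function(B, code) {
  k <- code$k
  stopifnot(ncol(B) == k)
  prev <- cbind(matrix(code$adapter, nrow(B), 1L), B[, -k, drop = FALSE])
  stream <- .xor_dim(prev, B)
  p <- as.integer(code$probe)
  ecc <- matrix(0L, nrow(B), code$m)
  for (j in 1:5) {
    if (p[j] == 0L) next
    cols <- seq(j, k, by = 5L)
    ecc <- .xor_dim(ecc, matrix(.GF4_MULV[p[j] * 4L + B[, cols, drop = FALSE] + 1L],
                               nrow(B), code$m))
  }
  list(stream = stream, ecc = ecc)
}

#' Encode a read under a punctured two-stream code
#'
#' Produces the two-base color stream (first color formed against the
#' adapter base) and the punctured second stream, one color per 5-base
#' block.
#'
#' @param bases the read, as a nucleotide string or integer GF(4) vector of
#'   length `k`.
#' @param code a [ecc_code()] specification whose `k` matches.
#' @return An object of class `encoded_read`: a list with integer GF(4)
#'   components `color_stream` (length `k`) and `ecc_stream` (length
#'   `k/5`), plus the `code`.
#' @export
encode_read <- function(bases, code) {
  b <- if (is.character(bases)) bases_to_gf4(bases) else as.integer(bases)
  .check_gf4(b, "base")
  if (length(b) != code$k) {
    stop(sprintf("read has %d bases but the code expects k = %d (a multiple of 5)",
                 length(b), code$k), call. = FALSE)
  }
  enc <- .encode_batch(matrix(b, nrow = 1L), code)
  structure(list(color_stream = as.integer(enc$stream),
                 ecc_stream = as.integer(enc$ecc),
                 code = code),
            class = "encoded_read")
}

#' @export
print.encoded_read <- function(x, ...) {
  cat("<encoded read>\n  colors: ", gf4_to_colors(x$color_stream),
      "\n  ecc:    ", gf4_to_colors(x$ecc_stream), "\n", sep = "")
  invisible(x)
}

#' An observed (possibly corrupted) color-space read
#'
#' @param color_stream integer GF(4) vector of length `k`; `NA` marks a
#'   missing call (`.` in CSFASTA).
#' @param ecc_stream integer GF(4) vector of length `k/5`; `NA` allowed.
#' @param qualities optional integer Phred qualities, one per color, in
#'   stream order followed by ECC order (length `n = k + k/5`).
#' @return An object of class `observed_read`.
#' @export
observed_read <- function(color_stream, ecc_stream, qualities = NULL) {
  color_stream <- as.integer(color_stream)
  ecc_stream <- as.integer(ecc_stream)
  if (length(color_stream) %% 5L != 0L ||
      length(ecc_stream) * 5L != length(color_stream)) {
    stop("color stream length must be 5x the ECC stream length", call. = FALSE)
  }
  n <- length(color_stream) + length(ecc_stream)
  if (!is.null(qualities)) {
    qualities <- as.integer(qualities)
    if (length(qualities) != n) {
      stop(sprintf("expected %d qualities (one per color), got %d",
                   n, length(qualities)), call. = FALSE)
    }
  }
  structure(list(color_stream = color_stream, ecc_stream = ecc_stream,
                 qualities = qualities),
            class = "observed_read")
}

#' @export
print.observed_read <- function(x, ...) {
  render <- function(v) paste(ifelse(is.na(v), ".", .GF4_COLOR[v + 1L]),
                              collapse = "")
  cat("<observed read>\n  colors: ", render(x$color_stream),
      "\n  ecc:    ", render(x$ecc_stream), "\n", sep = "")
  invisible(x)
}

#' View an encoded or observed read as its per-block structure
#'
#' Block `i` consists of data colors `c1..c4` (within-block adjacent-pair
#' colors), `c5` (the second-stream color) and the junction parities: the
#' upstream parity `p-` (shared with the previous block, or formed against
#' the adapter for block 1) and the downstream parity `p+` (absent for the
#' final block).
#'
#' @param read an `encoded_read` or `observed_read`.
#' @return A list with one element per block, each a list with `p_minus`,
#'   `data` (length-5 integer vector) and `p_plus` (`NA` for the final
#'   block).
#' @export
read_blocks <- function(read) {
  k <- length(read$color_stream)
  m <- k %/% 5L
  lapply(seq_len(m), function(i) {
    off <- 5L * (i - 1L)
    list(p_minus = read$color_stream[off + 1L],
         data = c(read$color_stream[off + 2:5], read$ecc_stream[i]),
         p_plus = if (i < m) read$color_stream[off + 6L] else NA_integer_)
  })
}

## Full generator and parity check -------------------------------------------

# Codeword coordinate convention: positions 1..5m are the data colors in
# block-major order (c1..c5 of block 1, then block 2, ...); positions
# 5m+1..6m are the junction parities j_1..j_m, where j_1 is the adapter
# junction (upstream of block 1) and j_i (i > 1) straddles blocks i-1 and i.

# Streams -> codeword vector.  The known adapter offset is subtracted from
# the first junction so the codeword is a pure function of the source.
.to_codeword <- function(read, code) {
  k <- code$k; m <- code$m
  cw <- integer(code$n)
  for (i in seq_len(m)) {
    off <- 5L * (i - 1L)
    cw[off + 1:4] <- read$color_stream[off + 2:5]
    cw[off + 5L] <- read$ecc_stream[i]
  }
  junc <- read$color_stream[seq(1L, k, by = 5L)]
  junc[1L] <- bitwXor(junc[1L], code$adapter)
  cw[5L * m + seq_len(m)] <- junc
  cw
}

.from_codeword <- function(cw, code) {
  k <- code$k; m <- code$m
  stream <- integer(k)
  ecc <- integer(m)
  junc <- cw[5L * m + seq_len(m)]
  junc[1L] <- bitwXor(junc[1L], code$adapter)
  for (i in seq_len(m)) {
    off <- 5L * (i - 1L)
    stream[off + 1L] <- junc[i]
    stream[off + 2:5] <- cw[off + 1:4]
    ecc[i] <- cw[off + 5L]
  }
  list(color_stream = stream, ecc_stream = ecc)
}

#' Build the full code generator G = [G* | P]
#'
#' `G*` is block-diagonal in the 5x5 block generator; `P` holds one parity
#' column per junction.  The adapter-junction column is the unit vector
#' `u1` of block 1 (the known adapter contributes a constant offset that is
#' handled outside the matrix); each interior junction column has exactly
#' two ones, at position 5 of block `i-1` and position 1 of block `i`.
#'
#' @param code a [ecc_code()].
#' @return A list with integer matrices `G` (`k` x `n`), `Gstar`
#'   (`k` x `5m`) and `P` (`k` x `m`).
#' @export
build_full_generator <- function(code) {
  k <- code$k; m <- code$m
  Gstar <- matrix(0L, k, 5L * m)
  for (i in seq_len(m)) {
    idx <- 5L * (i - 1L) + 1:5
    Gstar[idx, idx] <- code$gen$forward
  }
  P <- matrix(0L, k, m)
  P[1L, 1L] <- 1L
  for (i in seq_len(m)[-1L]) {
    P[5L * (i - 1L), i] <- 1L       # b5 of block i-1
    P[5L * (i - 1L) + 1L, i] <- 1L  # b1 of block i
  }
  list(G = cbind(Gstar, P), Gstar = Gstar, P = P)
}

#' Build the parity-check matrix H
#'
#' Factorised construction: the data rows of `H` are `G*^-1 P` (invert the
#' observation block by block to a putative decoding, then recompute the
#' junction parities it implies) and the parity rows are the identity (add
#' the observed parities).  By construction `G %*% H = 0` over GF(4), so
#' the syndrome of any valid codeword is all-zero.
#'
#' @param code a [ecc_code()].
#' @return An `n` x `(n - k)` integer matrix over GF(4).
#' @export
build_parity_check <- function(code) {
  m <- code$m
  fg <- build_full_generator(code)
  Gstar_inv <- matrix(0L, 5L * m, 5L * m)
  for (i in seq_len(m)) {
    idx <- 5L * (i - 1L) + 1:5
    Gstar_inv[idx, idx] <- code$gen$inverse
  }
  rbind(gf4_matmul(Gstar_inv, fg$P), gf4_identity(m))
}

#' Check whether an observed read is a valid codeword
#'
#' @param read an `encoded_read` or `observed_read` with no missing calls.
#' @param code the matching [ecc_code()].
#' @return A list with `valid` (logical) and `syndrome` (integer GF(4)
#'   vector of length `n - k`, one component per junction parity).
#' @export
is_valid_codeword <- function(read, code) {
  syn <- compute_syndrome(read, code)
  list(valid = all(syn == 0L), syndrome = syn)
}

## Alternative chemistries ----------------------------------------------------

#' Enumerate candidate second-round probe generators
#'
#' Walks all length-5 coefficient vectors over GF(4) in lexicographic order
#' and applies the platform-motivated restrictions: a leading coefficient of
#' 1 (any code starting with alpha or beta is a relabelling of one starting
#' with 1, and leading zeros merely shift the block boundary), a trailing
#' zero (probes are ligated less accurately at their final base), and
#' invertibility of the block generator (nonzero coefficient sum).  With all
#' three restrictions there are exactly 48 generators.
#'
#' @param require_first_one keep only generators with `p1 = 1`.
#' @param require_last_zero keep only generators with `p5 = 0`.
#' @param require_invertible keep only generators with nonzero GF(4)
#'   coefficient sum.
#' @return A list of [probe_generator()] objects in lexicographic order.
#' @examples
#' length(enumerate_probe_generators())  # 48
#' @export
enumerate_probe_generators <- function(require_first_one = TRUE,
                                       require_last_zero = TRUE,
                                       require_invertible = TRUE) {
  grid <- as.matrix(expand.grid(p5 = 0:3, p4 = 0:3, p3 = 0:3, p2 = 0:3,
                                p1 = 0:3))[, 5:1, drop = FALSE]
  # expand.grid varies the first factor fastest; columns reordered so rows
  # run in lexicographic order over (p1, ..., p5).
  grid <- grid[order(grid[, 1L], grid[, 2L], grid[, 3L], grid[, 4L],
                     grid[, 5L]), , drop = FALSE]
  keep <- rep(TRUE, nrow(grid))
  if (require_first_one) keep <- keep & grid[, 1L] == 1L
  if (require_last_zero) keep <- keep & grid[, 5L] == 0L
  if (require_invertible) {
    sums <- Reduce(bitwXor, lapply(1:5, function(j) grid[, j]))
    keep <- keep & sums != 0L
  }
  lapply(seq_len(nrow(grid))[keep],
         function(i) probe_generator(as.integer(grid[i, ])))
}
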