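# Independent oracles and shared fixtures, kept deliberately naive.

# The published GF(4) addition and multiplication tables, frozen verbatim
# (elements coded 0, 1, alpha = 2, beta = 3).
REF_ADD <- matrix(c(
  0L, 1L, 2L, 3L,
  1L, 0L, 3L, 2L,
  2L, 3L, 0L, 1L,
  3L, 2L, 1L, 0L), 4L, 4L, byrow = TRUE)
REF_MUL <- matrix(c(
  0L, 0L, 0L, 0L,
  0L, 1L, 2L, 3L,
  0L, 2L, 3L, 1L,
  0L, 3L, 1L, 2L), 4L, 4L, byrow = TRUE)

# All 4^k base sequences, one per row, in lexicographic order.
all_sequences <- function(k) {
  seqs <- as.matrix(expand.grid(rep(list(0:3), k)))[, k:1, drop = FALSE]
  dimnames(seqs) <- NULL
  seqs
}

# Joint log-likelihood of every candidate source sequence given an observed
# read, by direct enumeration (used against the trellis decoders).
# all_enc may be precomputed with enumerate_encodings() to amortise the cost.
enumerate_encodings <- function(code) {
  seqs <- all_sequences(code$k)
  enc <- solidecc:::.encode_batch(seqs, code)
  list(seqs = seqs, colors = cbind(enc$stream, enc$ecc))
}

brute_force_loglik <- function(obs, eps, code, all_enc) {
  obsv <- c(obs$color_stream, obs$ecc_stream)
  ll <- numeric(nrow(all_enc$seqs))
  for (j in seq_len(code$n)) {
    if (is.na(obsv[j])) {
      ll <- ll + log(0.25)
    } else {
      ll <- ll + ifelse(all_enc$colors[, j] == obsv[j],
                        log1p(-eps[j]), log(eps[j] / 3))
    }
  }
  ll
}

# Lexicographically smallest maximiser, with a tolerance because float sums
# accumulated in different orders tie only approximately.
brute_force_viterbi <- function(obs, eps, code, all_enc, tol = 1e-9) {
  ll <- brute_force_loglik(obs, eps, code, all_enc)
  best <- which(ll >= max(ll) - tol)[1L]
  list(bases = as.integer(all_enc$seqs[best, ]), loglik = max(ll))
}

brute_force_marginals <- function(obs, eps, code, all_enc) {
  ll <- brute_force_loglik(obs, eps, code, all_enc)
  w <- exp(ll - max(ll))
  w <- w / sum(w)
  marg <- matrix(0, code$k, 4L)
  for (j in seq_len(code$k)) {
    for (b in 0:3) marg[j, b + 1L] <- sum(w[all_enc$seqs[, j] == b])
  }
  marg
}

# Gaussian-elimination rank over GF(4), independent of the package's solver.
gf4_rank <- function(A) {
  A <- A
  r <- 0L
  for (col in seq_len(ncol(A))) {
    piv <- which(A[(r + 1L):nrow(A), col] != 0L)[1L]
    if (is.na(piv)) next
    piv <- piv + r
    r <- r + 1L
    if (piv != r) A[c(r, piv), ] <- A[c(piv, r), ]
    A[r, ] <- gf4_mul(gf4_inv(A[r, col]), A[r, ])
    for (row in seq_len(nrow(A))[-r]) {
      if (A[row, col] != 0L) {
        A[row, ] <- bitwXor(A[row, ], gf4_mul(A[row, col], A[r, ]))
      }
    }
    if (r == nrow(A)) break
  }
  r
}

# Apply additive offsets at codeword positions and return the observed read.
corrupt_codeword <- function(encoded, code, positions, offsets,
                             qualities = NULL) {
  cw <- solidecc:::.to_codeword(encoded, code)
  cw[positions] <- bitwXor(cw[positions], as.integer(offsets))
  st <- solidecc:::.from_codeword(cw, code)
  observed_read(st$color_stream, st$ecc_stream, qualities)
}

# Quality-vector index (stream first, then ECC) of a codeword position.
pos_to_quality_index <- function(pos, code) {
  solidecc:::.codeword_quality_index(code)[pos]
}

# Block index a codeword position belongs to (junction i -> earlier block).
block_of_position <- function(pos, code) {
  ifelse(pos <= 5L * code$m, (pos - 1L) %/% 5L + 1L,
         pmax(pos - 5L * code$m - 1L, 1L))
}
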