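# The printed block generator and inverse for the ECC probe set, frozen.
ECC_FORWARD <- matrix(c(
  1L, 0L, 0L, 0L, 1L,
  1L, 1L, 0L, 0L, 3L,
  0L, 1L, 1L, 0L, 0L,
  0L, 0L, 1L, 1L, 3L,
  0L, 0L, 0L, 1L, 0L), 5L, 5L, byrow = TRUE)
ECC_INVERSE <- matrix(c(
  0L, 1L, 1L, 1L, 1L,
  3L, 3L, 2L, 2L, 2L,
  3L, 3L, 3L, 2L, 2L,
  0L, 0L, 0L, 0L, 1L,
  1L, 1L, 1L, 1L, 1L), 5L, 5L, byrow = TRUE)

test_that("the ECC block generator matches its printed form and inverse", {
  gen <- block_generator(ecc_probe())
  expect_identical(gen$forward, ECC_FORWARD)
  expect_identical(gen$inverse, ECC_INVERSE)
  expect_identical(gen$y, 1L)
})

test_that("block generators follow the adjacent-pair + probe-column layout", {
  gen <- block_generator("10b00")
  expect_identical(gen$forward[, 5L], c(1L, 0L, 3L, 0L, 0L))
  expect_identical(gen$y, 2L)   # alpha: 1 + beta + beta... = 1+0+b+0+0
  for (j in 1:4) {
    col <- integer(5L); col[c(j, j + 1L)] <- 1L
    expect_identical(gen$forward[, j], col)
  }
  expect_error(block_generator("1ba00"), "sum of its coefficients is zero")
  expect_error(probe_generator("1b0b"), "exactly 5 coefficients")
})

test_that("the worked block example encodes and decodes both ways", {
  gen <- block_generator(ecc_probe())
  expect_identical(gf4_to_colors(encode_block("ACGAT", gen)), "13233")
  expect_identical(gf4_to_bases(decode_block("13233", gen)), "ACGAT")
  expect_identical(encode_block("AAAAA", gen), rep(0L, 5L))
  expect_identical(gf4_to_bases(decode_block("00000", gen)), "AAAAA")
})

test_that("encode_block agrees with a direct matrix-product oracle", {
  gen <- block_generator(ecc_probe())
  b <- bases_to_gf4("ATGCG")
  oracle <- integer(5L)
  for (j in 1:5) {
    acc <- 0L
    for (i in 1:5) acc <- gf4_add(acc, gf4_mul(b[i], gen$forward[i, j]))
    oracle[j] <- acc
  }
  expect_identical(encode_block("ATGCG", gen), oracle)
})

test_that("closed-form inverses equal Gaussian elimination for all 48 codes", {
  gens <- enumerate_probe_generators()
  expect_length(gens, 48L)
  for (p in gens) {
    g <- block_generator(p)
    expect_identical(g$inverse, gf4_solve(g$forward))
  }
})

test_that("encode/decode is the identity on all 1024 blocks for all 48 codes", {
  blocks <- all_sequences(5L)
  for (p in enumerate_probe_generators()) {
    g <- block_generator(p)
    enc <- gf4_matmul(blocks, g$forward)
    dec <- gf4_matmul(enc, g$inverse)
    expect_identical(dec, blocks)
  }
})

test_that("probe generator enumeration honours each restriction flag", {
  expect_length(enumerate_probe_generators(), 48L)
  expect_length(enumerate_probe_generators(require_invertible = FALSE), 64L)
  expect_length(enumerate_probe_generators(require_last_zero = FALSE), 192L)
  gens <- enumerate_probe_generators()
  strs <- vapply(gens, format, character(1))
  expect_identical(strs, sort(strs))       # deterministic lexicographic order
  expect_true(all(substr(strs, 1, 1) == "1"))
  expect_true(all(substr(strs, 5, 5) == "0"))
  expect_true("1b0b0" %in% strs)
})

test_that("encode_read produces the expected stream and block structure", {
  code <- ecc_code(10, adapter = "A")
  er <- encode_read("ACGATACGAT", code)
  expect_length(er$color_stream, 10L)
  expect_length(er$ecc_stream, 2L)
  blocks <- read_blocks(er)
  expect_identical(gf4_to_colors(blocks[[1L]]$data), "13233")
  expect_identical(gf4_to_colors(blocks[[2L]]$data), "13233")
  expect_identical(blocks[[1L]]$p_minus, 0L)   # adapter A against b1 = A
  expect_identical(blocks[[1L]]$p_plus, 3L)    # b5 (T) + b1 of block 2 (A)
  expect_true(is.na(blocks[[2L]]$p_plus))      # final block has no p+
  # all-A read encodes to all zeros
  code50 <- ecc_code(50, adapter = "A")
  er0 <- encode_read(strrep("A", 50), code50)
  expect_true(all(er0$color_stream == 0L) && all(er0$ecc_stream == 0L))
  expect_error(encode_read("ACGATA", ecc_code(10)), "k = 10")
  expect_error(ecc_code(12), "multiple of 5")
})

test_that("the adapter base changes exactly one color of the encoding", {
  s <- "ACGATTGCAT"
  ea <- encode_read(s, ecc_code(10, adapter = "A"))
  et <- encode_read(s, ecc_code(10, adapter = "T"))
  expect_identical(ea$ecc_stream, et$ecc_stream)
  expect_identical(sum(ea$color_stream != et$color_stream), 1L)
  expect_identical(which(ea$color_stream != et$color_stream), 1L)
})

test_that("the full generator has the documented shape and full rank", {
  code <- ecc_code(10)
  fg <- build_full_generator(code)
  expect_identical(dim(fg$G), c(10L, 12L))
  expect_identical(dim(fg$P), c(10L, 2L))
  # adapter-junction column is u1; the interior junction column has two 1s
  expect_identical(fg$P[, 1L], c(1L, rep(0L, 9L)))
  expect_identical(which(fg$P[, 2L] != 0L), c(5L, 6L))
  expect_true(all(fg$P[fg$P != 0L] == 1L))
  expect_identical(gf4_rank(fg$G), 10L)
  # s G equals the stream encoder (after adapter handling)
  set.seed(21)
  for (rep in 1:20) {
    s <- sample(0:3, 10, TRUE)
    cw <- as.integer(gf4_matmul(s, fg$G))
    er <- encode_read(s, code)
    expect_identical(solidecc:::.to_codeword(er, code), cw)
  }
})

test_that("the parity check annihilates the generator and flags single errors", {
  code <- ecc_code(10)
  fg <- build_full_generator(code)
  H <- build_parity_check(code)
  expect_identical(dim(H), c(12L, 2L))
  expect_true(all(gf4_matmul(fg$G, H) == 0L))
  set.seed(5)
  for (rep in 1:100) {
    s <- sample(0:3, 10, TRUE)
    expect_true(all(gf4_matmul(gf4_matmul(s, fg$G), H) == 0L))
  }
  # every single corrupted position, every offset -> nonzero syndrome,
  # except c1/c4 of the final block: their single-error syndromes have zero
  # upstream component and the final block has no downstream junction
  er <- encode_read(sample(0:3, 10, TRUE), code)
  blind <- c(6L, 9L)
  for (pos in setdiff(seq_len(code$n), blind)) {
    for (off in 1:3) {
      obs <- corrupt_codeword(er, code, pos, off)
      chk <- is_valid_codeword(obs, code)
      expect_false(chk$valid)
      expect_true(any(chk$syndrome != 0L))
    }
  }
})

test_that("valid codewords are linear: combinations of codewords are codewords", {
  code <- ecc_code(15)
  fg <- build_full_generator(code)
  H <- build_parity_check(code)
  set.seed(31)
  for (rep in 1:25) {
    c1 <- gf4_matmul(sample(0:3, 15, TRUE), fg$G)
    c2 <- gf4_matmul(sample(0:3, 15, TRUE), fg$G)
    w1 <- sample(0:3, 1)
    w2 <- sample(0:3, 1)
    comb <- bitwXor(gf4_mul(w1, as.integer(c1)), gf4_mul(w2, as.integer(c2)))
    expect_true(all(gf4_matmul(comb, H) == 0L))
  }
})

test_that("applying the same error twice restores validity (characteristic 2)", {
  code <- ecc_code(10)
  er <- encode_read(sample(0:3, 10, TRUE), code)
  once <- corrupt_codeword(er, code, c(3L, 8L), c(2L, 1L))
  expect_false(is_valid_codeword(once, code)$valid)
  twice <- corrupt_codeword(once, code, c(3L, 8L), c(2L, 1L))
  expect_true(is_valid_codeword(twice, code)$valid)
})
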