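test_that("single-error syndromes reproduce the published tables cell-for-cell", {
  for (probe in names(REF_SYNDROMES)) {
    gen <- block_generator(probe)
    for (tname in names(REF_SYNDROMES[[probe]])) {
      type <- match(sub("\\+", "", tname), c("1", "a", "b"))
      for (pi in seq_along(positions7)) {
        pair <- single_error_syndrome(positions7[pi], type, gen)
        rendered <- paste(c("0", "1", "a", "b")[pair + 1L], collapse = "")
        expect_identical(rendered, REF_SYNDROMES[[probe]][[tname]][pi],
                         label = sprintf("%s %s %s", probe, tname, positions7[pi]))
      }
    }
  }
  expect_identical(single_error_syndrome("c3", 0L, block_generator("1b0b0")),
                   c(0L, 0L))
})

test_that("equivalence classes match the published partitions for every type", {
  for (probe in names(REF_CLASSES)) {
    cls <- equivalence_classes(block_generator(probe))
    for (tname in names(cls)) {
      got <- lapply(cls[[tname]], sort)
      want <- lapply(REF_CLASSES[[probe]], sort)
      expect_setequal(vapply(got, paste, character(1), collapse = ","),
                      vapply(want, paste, character(1), collapse = ","))
    }
  }
})

test_that("unused syndromes are exactly the published sets", {
  expect_setequal(unused_syndromes(block_generator("1b0b0")),
                  c("ab", "b1", "1a"))
  expect_setequal(unused_syndromes(block_generator("10b00")),
                  c("1b", "a1", "ba"))
  expect_identical(unused_syndromes(block_generator("1b010")), character(0))
})

test_that("miscorrection patterns reproduce the published tables", {
  for (probe in names(REF_PATTERNS)) {
    gen <- block_generator(probe)
    for (row in REF_PATTERNS[[probe]]) {
      for (type in 1:3) {
        mp <- miscorrection_pattern(row[[1L]], row[[2L]], type, gen)
        unit <- colors_to_gf4(chartr("ab", "23", row[[3L]]))
        expect_identical(mp$pattern, gf4_mul(type, unit))
        expect_identical(mp$label, row[[4L]])
      }
    }
  }
  # the worked miscorrection: +a at c2 corrected at c3 induces 00a00
  mp <- miscorrection_pattern("c2", "c3", 2L, block_generator("1b0b0"))
  expect_identical(mp$rendered, "00a00")
  expect_error(miscorrection_pattern("c1", "c2", 1L, block_generator("1b0b0")),
               "not confusable")
})

test_that("ECC miscorrections never touch the first base of a block and share one offset", {
  gen <- block_generator("1b0b0")
  cls <- equivalence_classes(gen)
  for (tname in names(cls)) {
    type <- match(sub("\\+", "", tname), c("1", "a", "b"))
    for (members in cls[[tname]]) {
      if (length(members) < 2L) next
      pairs <- utils::combn(members, 2L)
      for (ci in seq_len(ncol(pairs))) {
        mp <- miscorrection_pattern(pairs[1L, ci], pairs[2L, ci], type, gen)
        expect_identical(mp$pattern[1L], 0L)
        expect_true(all(mp$pattern %in% c(0L, type)))
      }
    }
  }
})

test_that("syndromes depend on the error only, not the source", {
  code <- ecc_code(15)
  set.seed(77)
  for (rep in 1:25) {
    s1 <- sample(0:3, 15, TRUE)
    s2 <- sample(0:3, 15, TRUE)
    npos <- sample(1:3, 1)
    pos <- sample(code$n, npos)
    off <- sample(1:3, npos, TRUE)
    syn1 <- compute_syndrome(corrupt_codeword(encode_read(s1, code), code, pos, off), code)
    syn2 <- compute_syndrome(corrupt_codeword(encode_read(s2, code), code, pos, off), code)
    expect_identical(syn1, syn2)
  }
})

test_that("block-local syndromes appear at the expected junction components", {
  code <- ecc_code(15)
  er <- encode_read(sample(0:3, 15, TRUE), code)
  # +b at c5 of block 2 (interior): upstream and downstream both beta
  obs <- corrupt_codeword(er, code, 10L, 3L)
  expect_identical(compute_syndrome(obs, code), c(0L, 3L, 3L))
  # +a on the interior junction parity alone: a single alpha component
  obs <- corrupt_codeword(er, code, 5L * 3L + 2L, 2L)
  expect_identical(compute_syndrome(obs, code), c(0L, 2L, 0L))
  # clean read: all-zero
  expect_identical(compute_syndrome(er, code), c(0L, 0L, 0L))
})

test_that("weight-1 table entries mirror the per-block equivalence classes", {
  code <- ecc_code(15)
  tab <- build_syndrome_table(code)
  # +a at c1 of block 1 -> syndrome (0, a, 0); candidates are c1, c4 of
  # block 1, the shared junction, and the final-block positions whose
  # downstream component is out of range
  syn_key <- "020"
  entry <- tab$entries[[syn_key]]
  expect_identical(entry$weight, 1L)
  expect_true(length(entry$candidates) > 1L)
  cand <- do.call(rbind, entry$candidates)
  expect_true(all(cand[, "offset"] == 2L | cand[, "position"] > 5L * code$m |
                    block_of_position(cand[, "position"], code) >= code$m))
  core <- cand[cand[, "position"] %in% c(1L, 4L, 17L), , drop = FALSE]
  expect_identical(core[, "position"], c(1L, 4L, 17L))
  expect_true(all(core[, "offset"] == 2L))
  # the all-zero syndrome is not an entry: nothing to correct
  expect_null(tab$entries[[paste(rep("0", 3L), collapse = "")]])
})

test_that("singleton-class single errors are corrected exactly", {
  code <- ecc_code(15)
  tab <- build_syndrome_table(code)
  set.seed(13)
  s <- sample(0:3, 15, TRUE)
  er <- encode_read(s, code)
  ue <- unambiguous_single_errors(tab)
  expect_true(nrow(ue) > 0L)
  for (r in seq_len(nrow(ue))) {
    obs <- corrupt_codeword(er, code, ue[r, "position"], ue[r, "offset"])
    sd <- syndrome_decode(obs, code, tab)
    expect_identical(sd$bases, s)
    expect_true("corrected" %in% sd$status)
    expect_true(is_valid_codeword(sd$corrected, code)$valid)
  }
})

test_that("ambiguous errors report their candidate set and qualities resolve them", {
  code <- ecc_code(15)
  tab <- build_syndrome_table(code)
  set.seed(14)
  s <- sample(0:3, 15, TRUE)
  er <- encode_read(s, code)
  # +1 at c1 of block 1: class {c1, c4, p+} plus final-block aliases
  obs <- corrupt_codeword(er, code, 1L, 1L)
  sd <- syndrome_decode(obs, code, tab)
  expect_true("ambiguous" %in% sd$status)
  expect_true(length(sd$candidates) > 1L)
  expect_true(is_valid_codeword(sd$corrected, code)$valid)
  # every candidate correction yields a valid codeword
  for (cand in sd$candidates) {
    fixed <- corrupt_codeword(obs, code, cand[, "position"], cand[, "offset"])
    expect_true(is_valid_codeword(fixed, code)$valid)
  }
  # qualities flagging position 1 as unreliable pick the right correction
  q <- rep(30L, code$n)
  q[2L] <- 5L   # stream position of c1, block 1
  obs_q <- corrupt_codeword(er, code, 1L, 1L, qualities = q)
  sd_q <- syndrome_decode(obs_q, code, tab)
  expect_identical(sd_q$bases, s)
  expect_identical(sd_q$status[1L], "corrected")
})

test_that("clean reads pass through untouched", {
  code <- ecc_code(15)
  tab <- build_syndrome_table(code)
  s <- bases_to_gf4("ACGTTGCATAACGTA")
  er <- encode_read(s, code)
  sd <- syndrome_decode(er, code, tab)
  expect_identical(sd$bases, s)
  expect_identical(sd$status, rep("clean", 3L))
  expect_identical(sd$corrected$color_stream, er$color_stream)
})

test_that("single errors in non-adjacent blocks are corrected independently", {
  code <- ecc_code(25)
  tab <- build_syndrome_table(code)
  set.seed(15)
  s <- sample(0:3, 25, TRUE)
  er <- encode_read(s, code)
  ue <- unambiguous_single_errors(tab)
  blk <- block_of_position(ue[, "position"], code)
  checked <- 0L
  for (i in seq_len(nrow(ue) - 1L)) {
    for (j in (i + 1L):nrow(ue)) {
      if (abs(blk[i] - blk[j]) < 2L) next
      obs <- corrupt_codeword(er, code, ue[c(i, j), "position"],
                              ue[c(i, j), "offset"])
      sd <- syndrome_decode(obs, code, tab)
      expect_identical(sd$bases, s)
      checked <- checked + 1L
    }
  }
  expect_true(checked >= 40L)
})

test_that("final-block c1/c4 errors are invisible to the parity check", {
  # the last block has no downstream junction, and c1/c4 single errors have
  # zero upstream component, so the syndrome cannot see them
  code <- ecc_code(10)
  er <- encode_read(sample(0:3, 10, TRUE), code)
  for (pos in c(6L, 9L)) {   # c1, c4 of block 2 (the final block)
    obs <- corrupt_codeword(er, code, pos, 1L)
    expect_true(is_valid_codeword(obs, code)$valid)
  }
  # whereas c5 of the final block is still detected (upstream component)
  obs <- corrupt_codeword(er, code, 10L, 1L)
  expect_false(is_valid_codeword(obs, code)$valid)
})

test_that("syndromes beyond the table depth are flagged uncorrectable", {
  code <- ecc_code(25)
  tab <- build_syndrome_table(code)
  set.seed(16)
  s <- sample(0:3, 25, TRUE)
  er <- encode_read(s, code)
  # three c5 errors in blocks 1, 3 and 5 light up five junction components;
  # a weight-2 error can touch at most four, so no table entry can match
  obs <- corrupt_codeword(er, code, c(5L, 15L, 25L), c(3L, 3L, 3L))
  syn <- compute_syndrome(obs, code)
  expect_identical(sum(syn != 0L), 5L)
  sd <- syndrome_decode(obs, code, tab)
  expect_true("uncorrectable" %in% sd$status)
  expect_identical(sd$corrected$color_stream, obs$color_stream)
})
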