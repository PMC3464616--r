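test_that("synthetic references are reproducible and follow their composition", {
  expect_identical(synth_reference(1000, 1), synth_reference(1000, 1))
  expect_false(identical(synth_reference(1000, 1), synth_reference(1000, 2)))
  expect_true(all(synth_reference(200, 3, c(1, 0, 0, 0)) == 0L))
  # uniform composition: each base frequency within 3 binomial sd of 1/4
  ref <- synth_reference(100000, 4)
  sd3 <- 3 * sqrt(0.25 * 0.75 / 100000)
  for (b in 0:3) expect_lt(abs(mean(ref == b) - 0.25), sd3)
})

test_that("simulation is deterministic and error-free settings stay clean", {
  cfg <- sim_config(n_fragments = 50, seed = 9)
  ref <- synth_reference(2000, 8)
  expect_identical(simulate_reads(ref, cfg), simulate_reads(ref, cfg))
  # generalised error off and Q93 per-read quality vectors: miscall
  # probability 5e-10 per color, so the whole run stays clean
  cfg0 <- sim_config(n_fragments = 40, seed = 9, generalized_error = 0,
                     quality = list(rep(93L, 60L)))
  sim0 <- simulate_reads(ref, cfg0)
  expect_identical(sim0$true, sim0$mutated)
  expect_identical(sim0$stream_obs, sim0$stream_clean)
  expect_identical(sim0$ecc_obs, sim0$ecc_clean)
  expect_error(sim_config(n_fragments = 10), "seed")
})

test_that("miscall counts follow the binomial the qualities imply", {
  # flat Q20 profile: eps = 0.01 per color
  cfg <- sim_config(n_fragments = 2000, seed = 10, generalized_error = 0,
                    quality = quality_profile(20, 20))
  sim <- simulate_reads(synth_reference(5000, 11), cfg)
  mism <- sum(cbind(sim$stream_obs, sim$ecc_obs) !=
                cbind(sim$stream_clean, sim$ecc_clean))
  total <- 2000 * 60
  expected <- total * 0.01
  expect_lt(abs(mism - expected), 3 * sqrt(total * 0.01 * 0.99))
})

test_that("per-color qualities follow the declining per-cycle profile", {
  q <- solidecc:::.profile_qualities(quality_profile(30, 15), 50L)
  expect_length(q, 60L)
  expect_identical(q[1L], 30L)            # first cycle of round 1
  expect_identical(q[50L], 15L)           # last cycle of round 5
  expect_identical(q[51L], 30L)           # first ECC cycle
  expect_identical(q[60L], 15L)           # last ECC cycle
  expect_true(all(diff(q[seq(1, 50, by = 5)]) < 0))   # declines over cycles
})

test_that("a single early color error propagates under naive decoding but stays local with ECC", {
  code <- ecc_code(50)
  tab <- build_syndrome_table(code)
  set.seed(12)
  s <- sample(0:3, 50, TRUE)
  er <- encode_read(s, code)
  # corrupt stream position 3 (c2 of block 1)
  cs <- er$color_stream
  cs[3L] <- gf4_add(cs[3L], 2L)
  obs <- observed_read(cs, er$ecc_stream)
  naive <- as.integer(solidecc:::.naive_decode_batch(matrix(cs, 1L), code))
  color_errors <- sum(cs != er$color_stream)
  base_errors_naive <- sum(naive != s)
  expect_gte(base_errors_naive, color_errors)
  expect_gte(base_errors_naive, 40L)      # everything downstream corrupted
  sd <- syndrome_decode(obs, code, tab)
  expect_lte(sum(sd$bases != s), 5L)      # at worst one block's pattern
})

test_that("run_experiment tallies are sane and error-free runs are perfect", {
  cfg0 <- sim_config(n_fragments = 30, seed = 21, generalized_error = 0,
                     quality = quality_profile(41, 41))
  res <- run_experiment(cfg0, "none")
  expect_identical(unname(res[["0"]]), c(1, 1))
  cfg <- sim_config(n_fragments = 150, seed = 22)
  res <- run_experiment(cfg, "syndrome")
  expect_setequal(res$decoder, c("none", "syndrome"))
  bins <- as.matrix(res[, as.character(0:5)])
  expect_true(all(bins >= 0 & bins <= 1))
  expect_true(all(rowSums(cbind(bins, res[[">5"]])) - 1 < 1e-9))
})

test_that("syndrome decoding increases the perfect-read fraction across seeds", {
  wins <- 0L
  for (seed in 1:10) {
    cfg <- sim_config(n_fragments = 150, seed = seed)
    res <- run_experiment(cfg, "syndrome")
    perfect <- function(space, dec) {
      res[res$space == space & res$decoder == dec, "0"]
    }
    if (perfect("color", "syndrome") > perfect("color", "none")) {
      wins <- wins + 1L
    }
  }
  expect_gte(wins, 8L)
})

test_that("trellis decoders can drive run_experiment at small scale", {
  cfg <- sim_config(n_fragments = 25, seed = 30, fragment_length = 10L,
                    reference_length = 500L)
  res_map <- run_experiment(cfg, "map")
  res_vit <- run_experiment(cfg, "viterbi")
  expect_true("map" %in% res_map$decoder)
  expect_true("viterbi" %in% res_vit$decoder)
  bins <- as.matrix(res_map[, as.character(0:5)])
  expect_true(all(rowSums(cbind(bins, res_map[[">5"]])) - 1 < 1e-9))
})

test_that("MAP decoding repairs forced singleton-class color errors", {
  # one +1 error at an interior second-stream color per read: undecoded,
  # no read is color-perfect; MAP decoding recovers essentially all of them
  set.seed(31)
  code <- ecc_code(20)
  n_reads <- 30L
  perfect_raw <- perfect_map <- 0L
  for (i in seq_len(n_reads)) {
    s <- sample(0:3, 20, TRUE)
    er <- encode_read(s, code)
    pos <- 5L * sample(code$m - 1L, 1L)   # c5 of an interior block
    obs <- corrupt_codeword(er, code, pos, 1L, qualities = rep(25L, code$n))
    if (identical(obs$ecc_stream, er$ecc_stream) &&
        identical(obs$color_stream, er$color_stream)) {
      perfect_raw <- perfect_raw + 1L
    }
    if (identical(posterior_decode(obs, code)$bases, s)) {
      perfect_map <- perfect_map + 1L
    }
  }
  expect_identical(perfect_raw, 0L)
  expect_gt(perfect_map / n_reads, perfect_raw / n_reads)
  expect_gte(perfect_map, n_reads - 1L)
})

test_that("matched seeds give paired comparisons between probe generators", {
  cfg_ecc <- sim_config(n_fragments = 100, seed = 41, probe = "1b0b0")
  cfg_alt <- sim_config(n_fragments = 100, seed = 41, probe = "1b010")
  res_ecc <- run_experiment(cfg_ecc, "syndrome")
  res_alt <- run_experiment(cfg_alt, "syndrome")
  # identical fragments and identical raw two-base color stream
  expect_identical(attr(res_ecc, "sim")$true, attr(res_alt, "sim")$true)
  expect_identical(attr(res_ecc, "sim")$stream_clean,
                   attr(res_alt, "sim")$stream_clean)
  # both report a perfect-read fraction for their own code
  expect_true(is.finite(res_ecc[res_ecc$space == "color" &
                                  res_ecc$decoder == "syndrome", "0"]))
  expect_true(is.finite(res_alt[res_alt$space == "color" &
                                  res_alt$decoder == "syndrome", "0"]))
})
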