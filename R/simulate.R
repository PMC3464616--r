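## Read simulation and truth-based evaluation ---------------------------------
##
## The simulation follows the five-step scheme: sample a fragment from a
## reference (base-space); mutate its bases independently ('generalised
## error' -- pre-encoding damage no code can correct); encode the mutated
## fragment; attach per-color qualities; and miscall each color with the
## probability its quality implies, the wrong color drawn uniformly from the
## three alternatives.  Evaluation compares decodings directly against the
## known truth (Hamming distance in color- and base-space) instead of
## mapping to a genome.

#' Synthetic quality profile
#'
#' Per-cycle Phred qualities for simulated runs: quality declines linearly
#' from `q_start` on the first ligation cycle to `q_end` on the last
#' (sequencing errors concentrate in late cycles), with an additive offset
#' per round (five two-base rounds plus the second-stream round).
#'
#' @param q_start,q_end Phred quality at the first and last cycle.
#' @param round_offsets numeric length-6 additive offsets, rounds 1-5 then
#'   the second-stream round.
#' @return An object of class `quality_profile`.
#' @export
quality_profile <- function(q_start = 30, q_end = 15,
                            round_offsets = rep(0, 6)) {
  stopifnot(length(round_offsets) == 6L)
  structure(list(q_start = q_start, q_end = q_end,
                 round_offsets = round_offsets),
            class = "quality_profile")
}

# Expand a profile to the per-color quality vector (stream order then ECC
# order) for a k-base read.  Color j of the stream comes from round
# ((j-1) mod 5) + 1, cycle (j-1) %/% 5 + 1; ECC color i from round 6,
# cycle i.
.profile_qualities <- function(profile, k) {
  m <- k %/% 5L
  cyc <- function(cycle) {
    if (m == 1L) profile$q_start
    else profile$q_start +
      (profile$q_end - profile$q_start) * (cycle - 1) / (m - 1)
  }
  j <- seq_len(k)
  stream_q <- cyc((j - 1L) %/% 5L + 1L) + profile$round_offsets[(j - 1L) %% 5L + 1L]
  ecc_q <- cyc(seq_len(m)) + profile$round_offsets[6L]
  pmax(pmin(as.integer(round(c(stream_q, ecc_q))), 41L), 2L)
}

#' Simulation configuration
#'
#' @param n_fragments number of reads to simulate.
#' @param seed integer random seed; mandatory, and the single source of all
#'   randomness in a run.
#' @param fragment_length read length in bases (multiple of 5, default 50).
#' @param reference_length synthetic reference length in bases (used when no
#'   reference is supplied to [run_experiment()]).
#' @param generalized_error per-base probability of a pre-encoding mutation
#'   (default `10^-3.4`, the Q34 equivalent typical of prepared samples).
#' @param probe second-round probe generator.
#' @param adapter adapter base.
#' @param quality either a [quality_profile()], or a list of integer
#'   per-color quality vectors (e.g. from a real QUAL file via
#'   [read_csfasta()]) from which one vector is sampled per read.
#' @param base_composition length-4 base sampling probabilities (A, C, G,
#'   T) for the synthetic reference.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_fragments, seed, fragment_length = 50L,
                       reference_length = 10000L,
                       generalized_error = 10^-3.4,
                       probe = ecc_probe(), adapter = "T",
                       quality = quality_profile(),
                       base_composition = rep(0.25, 4)) {
  stopifnot(n_fragments >= 1, fragment_length %% 5 == 0,
            fragment_length <= reference_length,
            generalized_error >= 0, generalized_error <= 1,
            length(base_composition) == 4L,
            abs(sum(base_composition) - 1) < 1e-8)
  if (missing(seed) || is.null(seed)) {
    stop("a seed is mandatory for reproducible simulation", call. = FALSE)
  }
  structure(list(n_fragments = as.integer(n_fragments),
                 seed = as.integer(seed),
                 fragment_length = as.integer(fragment_length),
                 reference_length = as.integer(reference_length),
                 generalized_error = generalized_error,
                 probe = probe_generator(probe), adapter = adapter,
                 quality = quality,
                 base_composition = base_composition),
            class = "sim_config")
}

#' Generate a synthetic reference sequence
#'
#' Bases drawn i.i.d. from the given composition; a stand-in for a real
#' genome when only the error process, not genomic structure, matters.
#'
#' @param length reference length in bases.
#' @param seed integer random seed.
#' @param base_composition length-4 sampling probabilities (A, C, G, T).
#' @return An integer GF(4) vector of bases.
#' @export
synth_reference <- function(length, seed, base_composition = rep(0.25, 4)) {
  stopifnot(length >= 1, length(base_composition) == 4L,
            abs(sum(base_composition) - 1) < 1e-8)
  set.seed(as.integer(seed))
  sample(0:3, length, replace = TRUE, prob = base_composition)
}

# quality matrix (reads x n colors) for a batch
.sim_qualities <- function(config, N, code) {
  q <- config$quality
  if (inherits(q, "quality_profile")) {
    qvec <- .profile_qualities(q, code$k)
    matrix(qvec, N, code$n, byrow = TRUE)
  } else if (is.list(q)) {
    pick <- sample.int(length(q), N, replace = TRUE)
    qm <- do.call(rbind, q[pick])
    if (ncol(qm) != code$n) {
      stop(sprintf("sampled quality vectors have %d values but the code needs %d",
                   ncol(qm), code$n), call. = FALSE)
    }
    qm
  } else {
    stop("config$quality must be a quality_profile or a list of quality vectors",
         call. = FALSE)
  }
}

#' Simulate a batch of color-space reads
#'
#' Runs the five-step scheme against `ref` under `config`; all randomness
#' flows from `config$seed`, so equal configurations give byte-identical
#' results.  Fragments are sampled uniformly from the positive strand.
#'
#' @param ref reference as an integer GF(4) vector (see
#'   [synth_reference()]) or nucleotide string.
#' @param config a [sim_config()].
#' @return An object of class `sim_reads`: matrices (one read per row)
#'   `true` and `mutated` (bases), `stream_clean`/`ecc_clean` (encoding of
#'   the mutated fragment), `stream_obs`/`ecc_obs` (after miscalls),
#'   `qualities` (per-color Phred, stream then ECC order), plus `starts`,
#'   the `code` and the `config`.
#' @export
simulate_reads <- function(ref, config) {
  if (is.character(ref)) ref <- bases_to_gf4(ref)
  .check_gf4(ref, "reference base")
  k <- config$fragment_length
  if (length(ref) < k) stop("reference shorter than the fragment length",
                            call. = FALSE)
  code <- ecc_code(k, probe = config$probe, adapter = config$adapter)
  N <- config$n_fragments
  set.seed(config$seed)
  starts <- sample.int(length(ref) - k + 1L, N, replace = TRUE)
  true <- matrix(ref[outer(starts - 1L, seq_len(k), `+`)], N, k)
  gen_mask <- matrix(runif(N * k) < config$generalized_error, N, k)
  mutated <- true
  if (any(gen_mask)) {
    mutated[gen_mask] <- bitwXor(mutated[gen_mask],
                                 sample(1:3, sum(gen_mask), replace = TRUE))
  }
  enc <- .encode_batch(mutated, code)
  qualities <- .sim_qualities(config, N, code)
  eps <- 10^(-qualities / 10)
  clean <- cbind(enc$stream, enc$ecc)
  err_mask <- matrix(runif(N * code$n) < eps, N, code$n)
  obs <- clean
  if (any(err_mask)) {
    obs[err_mask] <- bitwXor(obs[err_mask],
                             sample(1:3, sum(err_mask), replace = TRUE))
  }
  structure(list(true = true, mutated = mutated,
                 stream_clean = enc$stream, ecc_clean = enc$ecc,
                 stream_obs = obs[, seq_len(k), drop = FALSE],
                 ecc_obs = obs[, k + seq_len(code$m), drop = FALSE],
                 qualities = qualities, starts = starts,
                 code = code, config = config),
            class = "sim_reads")
}

#' @export
print.sim_reads <- function(x, ...) {
  cat(sprintf("<%d simulated %d-base reads (probe %s, seed %d)>\n",
              nrow(x$true), ncol(x$true), format(x$code$probe),
              x$config$seed))
  invisible(x)
}

#' Extract one simulated read as an `observed_read`
#'
#' @param sim a [simulate_reads()] result.
#' @param i read index.
#' @param clean return the error-free encoding instead of the observation.
#' @return An `observed_read` carrying the read's qualities.
#' @export
sim_record <- function(sim, i, clean = FALSE) {
  if (clean) {
    observed_read(sim$stream_clean[i, ], sim$ecc_clean[i, ], sim$qualities[i, ])
  } else {
    observed_read(sim$stream_obs[i, ], sim$ecc_obs[i, ], sim$qualities[i, ])
  }
}

# Hamming error counts per read between two equal-shaped matrices
.row_errors <- function(a, b) rowSums(a != b)

.tally_errors <- function(err) {
  bins <- c(as.character(0:5), ">5")
  counts <- c(vapply(0:5, function(e) sum(err == e), numeric(1)),
              sum(err > 5))
  setNames(counts / length(err), bins)
}

#' Simulate, decode and tally errors against the truth
#'
#' Simulates reads under `config`, decodes them with the chosen engine and
#' counts per-read errors against the known truth -- the original fragment
#' in base-space and its clean encoding in color-space (so generalised
#' errors count as errors, as they would against a reference).  Rows for
#' the undecoded observation are always included as the baseline.
#'
#' @param config a [sim_config()].
#' @param decoder `"syndrome"`, `"viterbi"`, `"map"` or `"none"`.
#' @param ref optional reference (integer GF(4) vector); when omitted a
#'   synthetic reference of `config$reference_length` bases is generated
#'   from `config$seed + 1`.
#' @param table optional prebuilt [build_syndrome_table()] for the syndrome
#'   decoder.
#' @return An object of class `sim_summary`: a data frame with one row per
#'   (space, decoder), the fraction of reads with 0-5 errors and with more
#'   than 5, and the mean error count; the `sim_reads` object is attached
#'   as attribute `"sim"`.
#' @export
run_experiment <- function(config, decoder = c("syndrome", "viterbi", "map", "none"),
                           ref = NULL, table = NULL) {
  decoder <- match.arg(decoder)
  if (is.null(ref)) {
    ref <- synth_reference(config$reference_length, config$seed + 1L,
                           config$base_composition)
  }
  sim <- simulate_reads(ref, config)
  code <- sim$code
  N <- nrow(sim$true)
  truth_enc <- .encode_batch(sim$true, code)
  truth_colors <- cbind(truth_enc$stream, truth_enc$ecc)

  obs_colors <- cbind(sim$stream_obs, sim$ecc_obs)
  rows <- list()
  add_row <- function(space, dec, err) {
    rows[[length(rows) + 1L]] <<- cbind(
      data.frame(space = space, decoder = dec),
      as.data.frame(as.list(.tally_errors(err)), check.names = FALSE),
      data.frame(mean_errors = mean(err)))
  }
  # undecoded baseline: raw colors; naive base-space integration of the
  # two-base stream (a single early color error propagates to the read end)
  add_row("color", "none", .row_errors(obs_colors, truth_colors))
  add_row("base", "none",
          .row_errors(.naive_decode_batch(sim$stream_obs, code), sim$true))

  if (decoder == "syndrome") {
    if (is.null(table)) table <- build_syndrome_table(code)
    dec_stream <- sim$stream_obs
    dec_ecc <- sim$ecc_obs
    bases <- matrix(0L, N, code$k)
    syn <- .syndrome_batch(sim$stream_obs, sim$ecc_obs, code)
    needs <- rowSums(syn != 0L) > 0L
    clean_idx <- which(!needs)
    if (length(clean_idx)) {
      bases[clean_idx, ] <- .decode_blocks_batch(
        sim$stream_obs[clean_idx, , drop = FALSE],
        sim$ecc_obs[clean_idx, , drop = FALSE], code)
    }
    for (i in which(needs)) {
      sd <- syndrome_decode(sim_record(sim, i), code, table)
      dec_stream[i, ] <- sd$corrected$color_stream
      dec_ecc[i, ] <- sd$corrected$ecc_stream
      bases[i, ] <- sd$bases
    }
    add_row("color", "syndrome",
            .row_errors(cbind(dec_stream, dec_ecc), truth_colors))
    add_row("base", "syndrome", .row_errors(bases, sim$true))
  } else if (decoder %in% c("viterbi", "map")) {
    bases <- matrix(0L, N, code$k)
    for (i in seq_len(N)) {
      rec <- sim_record(sim, i)
      bases[i, ] <- if (decoder == "viterbi") {
        viterbi_decode(rec, code)$bases
      } else {
        posterior_decode(rec, code)$bases
      }
    }
    called_enc <- .encode_batch(bases, code)
    add_row("color", decoder,
            .row_errors(cbind(called_enc$stream, called_enc$ecc), truth_colors))
    add_row("base", decoder, .row_errors(bases, sim$true))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sim_summary", class(out))
  attr(out, "sim") <- sim
  out
}

#' @export
print.sim_summary <- function(x, ...) {
  cat(sprintf("Per-read error tallies for %d simulated reads (fractions):\n",
              nrow(attr(x, "sim")$true)))
  y <- x
  attr(y, "sim") <- NULL
  print.data.frame(y, row.names = FALSE, digits = 4)
  invisible(x)
}
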