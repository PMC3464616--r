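## Syndrome analysis ----------------------------------------------------------
##
## The syndrome has one GF(4) component per junction parity.  Each component
## is the sum of the observed junction color and the junction color implied
## by the block-by-block putative decoding; a valid codeword has an all-zero
## syndrome and, because the code is linear, the syndrome depends on the
## error pattern only, not on the source sequence.

# Batch syndrome computation.  stream: N x k observed two-base colors,
# ecc: N x m observed second-stream colors.  Returns N x m syndromes
# (component i = junction i, with junction 1 the adapter junction).
.syndrome_batch <- function(stream, ecc, code) {
  m <- code$m
  inv <- code$gen$inverse
  N <- nrow(stream)
  b1 <- matrix(0L, N, m)  # putative first base of each block
  b5 <- matrix(0L, N, m)  # putative last base of each block
  for (i in seq_len(m)) {
    off <- 5L * (i - 1L)
    D <- cbind(stream[, off + 2:5, drop = FALSE], ecc[, i])
    for (j in 1:5) {
      if (inv[j, 1L] != 0L) {
        b1[, i] <- bitwXor(b1[, i], .GF4_MUL[inv[j, 1L] * 4L + D[, j] + 1L])
      }
      if (inv[j, 5L] != 0L) {
        b5[, i] <- bitwXor(b5[, i], .GF4_MUL[inv[j, 5L] * 4L + D[, j] + 1L])
      }
    }
  }
  junc <- stream[, seq(1L, code$k, by = 5L), drop = FALSE]
  junc[, 1L] <- bitwXor(junc[, 1L], code$adapter)
  expected <- cbind(b1[, 1L, drop = FALSE],
                    if (m > 1L) .xor_dim(b5[, -m, drop = FALSE],
                                         b1[, -1L, drop = FALSE]))
  .xor_dim(junc, expected)
}

#' Compute the syndrome of an observed read
#'
#' Inverts the observation block by block to a putative base decoding,
#' recomputes the junction parity colors that decoding implies, and adds
#' them to the observed junction colors (the known adapter offset is
#' removed from the first junction).  The result is all-zero exactly when
#' the observation is a valid codeword.
#'
#' @param read an `encoded_read` or `observed_read` without missing calls.
#' @param code the matching [ecc_code()].
#' @return An integer GF(4) vector of length `n - k` (one component per
#'   junction parity; component 1 is the adapter junction).
#' @export
compute_syndrome <- function(read, code) {
  if (length(read$color_stream) != code$k) {
    stop(sprintf("read has %d colors but code expects k = %d",
                 length(read$color_stream), code$k), call. = FALSE)
  }
  if (anyNA(read$color_stream) || anyNA(read$ecc_stream)) {
    stop("read contains missing color calls; use the trellis decoders",
         call. = FALSE)
  }
  as.integer(.syndrome_batch(matrix(read$color_stream, nrow = 1L),
                             matrix(read$ecc_stream, nrow = 1L), code))
}

.BLOCK_POSITIONS <- c("p-", "c1", "c2", "c3", "c4", "c5", "p+")

#' Syndrome pair produced by a single color error in a block
#'
#' For an error of additive type `type` at one of the seven per-block
#' positions, returns the (upstream, downstream) syndrome components it
#' induces.  A data-color error at `cj` changes the putative decoding by
#' `type` times row `j` of the inverse block generator, so the upstream
#' component is the induced change in the block's first base and the
#' downstream component the change in its last base; a parity-color error
#' contributes its own offset to the corresponding component directly.
#'
#' @param position one of `"p-"`, `"c1"` ... `"c5"`, `"p+"`.
#' @param type the error offset, a nonzero GF(4) element (or 0, giving the
#'   zero pair).
#' @param gen a [block_generator()].
#' @return An integer GF(4) vector `c(upstream, downstream)`.
#' @examples
#' gen <- block_generator(ecc_probe())
#' single_error_syndrome("c2", 1L, gen)  # c(3, 2): beta alpha
#' @export
single_error_syndrome <- function(position, type, gen) {
  position <- match.arg(position, .BLOCK_POSITIONS)
  .check_gf4(type, "error type")
  type <- as.integer(type)
  if (position == "p-") return(c(type, 0L))
  if (position == "p+") return(c(0L, type))
  j <- match(position, c("c1", "c2", "c3", "c4", "c5"))
  gf4_mul(type, c(gen$inverse[j, 1L], gen$inverse[j, 5L]))
}

.render_pair <- function(pair) paste(.GF4_SYMBOL[pair + 1L], collapse = "")

#' Single-error syndrome equivalence classes of a block generator
#'
#' Groups the in-block positions `c1..c5` and the downstream parity `p+`
#' by the syndrome pair a single error of each type produces.  Positions in
#' the same class cannot be distinguished by the syndrome alone; singleton
#' classes are the unambiguously correctable positions.  (`p-` is excluded:
#' it is the `p+` of the previous block.)
#'
#' @param gen a [block_generator()].
#' @return A list with one element per error type (`"+1"`, `"+a"`,
#'   `"+b"`), each a named list of character vectors of positions, named by
#'   the rendered syndrome pair.
#' @examples
#' equivalence_classes(block_generator(ecc_probe()))[["+1"]]
#' @export
equivalence_classes <- function(gen) {
  positions <- c("c1", "c2", "c3", "c4", "c5", "p+")
  out <- list()
  for (type in 1:3) {
    pairs <- vapply(positions, function(p) {
      .render_pair(single_error_syndrome(p, type, gen))
    }, character(1))
    cls <- split(positions, pairs)
    # preserve first-appearance order of the classes
    cls <- cls[unique(pairs)]
    out[[paste0("+", .GF4_SYMBOL[type + 1L])]] <- cls
  }
  out
}

#' Nonzero syndrome pairs unreachable by any single-color error
#'
#' Of the 15 nonzero (upstream, downstream) pairs, returns those that no
#' single error at `p-`, `c1..c5` or `p+` produces.  Codes that leave
#' syndromes unused squander resolution that could separate ambiguous
#' errors; the ECC generator leaves three unused, while e.g. generator
#' `1b010` uses all fifteen.
#'
#' @param gen a [block_generator()].
#' @return A character vector of rendered pairs (e.g. `"ab"`), in
#'   lexicographic order of the underlying elements; possibly empty.
#' @export
unused_syndromes <- function(gen) {
  all_pairs <- expand.grid(up = 0:3, down = 0:3)
  all_pairs <- all_pairs[order(all_pairs$up, all_pairs$down), ]
  all_pairs <- all_pairs[!(all_pairs$up == 0L & all_pairs$down == 0L), ]
  seen <- character(0)
  for (p in .BLOCK_POSITIONS) {
    for (type in 1:3) {
      seen <- c(seen, .render_pair(single_error_syndrome(p, type, gen)))
    }
  }
  keys <- paste0(.GF4_SYMBOL[all_pairs$up + 1L], .GF4_SYMBOL[all_pairs$down + 1L])
  keys[!keys %in% seen]
}

#' Base-space pattern induced by correcting an error at the wrong position
#'
#' When a single error of type `t` at `true_pos` is 'corrected' by applying
#' `t` at another position of the same equivalence class, the data colors
#' end up differing from the truth by `d`, and the decoded bases differ by
#' the pattern `d %*% inverse`.  The pattern depends only on the two
#' positions and the type, never on the underlying sequence; parity
#' positions contribute nothing to `d` (they are not used in block
#' inversion).
#'
#' @param true_pos,corrected_pos positions among `"c1".."c5"`, `"p+"`;
#'   they must lie in the same equivalence class for this type.
#' @param type a nonzero GF(4) error offset.
#' @param gen a [block_generator()].
#' @return A list with `pattern` (integer GF(4) vector of length 5),
#'   `label` (`"single"`, `"double"`, `"triple"` or `"quadruple"`) and
#'   `rendered` (the pattern in field symbols).
#' @examples
#' gen <- block_generator(ecc_probe())
#' miscorrection_pattern("c2", "c3", 2L, gen)$rendered  # "00a00"
#' @export
miscorrection_pattern <- function(true_pos, corrected_pos, type, gen) {
  true_pos <- match.arg(true_pos, .BLOCK_POSITIONS)
  corrected_pos <- match.arg(corrected_pos, .BLOCK_POSITIONS)
  .check_gf4(type, "error type")
  type <- as.integer(type)
  if (type == 0L) stop("error type must be nonzero", call. = FALSE)
  s1 <- single_error_syndrome(true_pos, type, gen)
  s2 <- single_error_syndrome(corrected_pos, type, gen)
  if (!identical(s1, s2)) {
    stop(sprintf("positions %s and %s are not confusable for type +%s (syndromes %s vs %s)",
                 true_pos, corrected_pos, .GF4_SYMBOL[type + 1L],
                 .render_pair(s1), .render_pair(s2)), call. = FALSE)
  }
  d <- integer(5L)
  for (p in c(true_pos, corrected_pos)) {
    j <- match(p, c("c1", "c2", "c3", "c4", "c5"))
    if (!is.na(j)) d[j] <- bitwXor(d[j], type)
  }
  pattern <- as.integer(gf4_matmul(d, gen$inverse))
  w <- sum(pattern != 0L)
  label <- c("none", "single", "double", "triple", "quadruple", "quintuple")[w + 1L]
  list(pattern = pattern, label = label,
       rendered = paste(.GF4_SYMBOL[pattern + 1L], collapse = ""))
}

## Code analysis report -------------------------------------------------------

#' Analyse the single-error behaviour of a probe generator
#'
#' Produces the full per-block picture for one code: the syndrome of every
#' single-color error by position and type, the equivalence classes, the
#' unused syndromes and the base-space miscorrection patterns for every
#' confusable position pair.
#'
#' @param probe a [probe_generator()] (or string such as `"1b0b0"`).
#' @return An object of class `code_analysis` with data frames `syndromes`
#'   (type x position grid of rendered pairs), `patterns` (one row per
#'   unordered confusable pair), the `classes` list and the `unused`
#'   character vector.
#' @examples
#' analyze_code("1b0b0")
#' @export
analyze_code <- function(probe) {
  probe <- probe_generator(probe)
  gen <- block_generator(probe)
  types <- 1:3
  syn <- do.call(rbind, lapply(types, function(t) {
    vals <- vapply(.BLOCK_POSITIONS, function(p) {
      .render_pair(single_error_syndrome(p, t, gen))
    }, character(1))
    df <- as.data.frame(as.list(vals), check.names = FALSE)
    cbind(data.frame(type = paste0("+", .GF4_SYMBOL[t + 1L]),
                     interpretation = error_type_label(t)), df)
  }))
  cls <- equivalence_classes(gen)
  # miscorrection patterns: every unordered pair within a multi-member class
  pat_rows <- list()
  for (tname in names(cls)) {
    t <- match(sub("^\\+", "", tname), .GF4_SYMBOL) - 1L
    for (members in cls[[tname]]) {
      if (length(members) < 2L) next
      combs <- utils::combn(members, 2L)
      for (ci in seq_len(ncol(combs))) {
        mp <- miscorrection_pattern(combs[1L, ci], combs[2L, ci], t, gen)
        pat_rows[[length(pat_rows) + 1L]] <- data.frame(
          type = tname, pos1 = combs[1L, ci], pos2 = combs[2L, ci],
          change = mp$label, pattern = mp$rendered)
      }
    }
  }
  patterns <- if (length(pat_rows)) do.call(rbind, pat_rows) else
    data.frame(type = character(0), pos1 = character(0), pos2 = character(0),
               change = character(0), pattern = character(0))
  structure(list(probe = probe, gen = gen, syndromes = syn, classes = cls,
                 patterns = patterns, unused = unused_syndromes(gen)),
            class = "code_analysis")
}

#' @export
print.code_analysis <- function(x, ...) {
  cat("Code analysis for probe generator ", format(x$probe), "\n\n", sep = "")
  cat("Single-error syndromes (upstream, downstream):\n")
  print(x$syndromes, row.names = FALSE)
  cat("\nEquivalence classes over {c1..c5, p+}:\n")
  for (tname in names(x$classes)) {
    rendered <- vapply(x$classes[[tname]], function(m) {
      paste0("{", paste(m, collapse = ","), "}")
    }, character(1))
    cat(" ", tname, ": ", paste(rendered, collapse = " "), "\n", sep = "")
  }
  cat("\nUnused syndromes: ",
      if (length(x$unused)) paste(x$unused, collapse = ", ") else "(none)",
      "\n\nMiscorrection patterns (base-space):\n", sep = "")
  print(x$patterns, row.names = FALSE)
  invisible(x)
}

#' Write a code analysis as tab-separated tables
#'
#' @param x a [analyze_code()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_code_analysis <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# probe generator\t", format(x$probe)), con)
  writeLines("# single-error syndromes", con)
  write.table(x$syndromes, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(paste0("# unused syndromes\t",
                    paste(x$unused, collapse = ",")), con)
  writeLines("# miscorrection patterns", con)
  write.table(x$patterns, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
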