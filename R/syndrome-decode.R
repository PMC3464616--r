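## Syndrome-table decoding ----------------------------------------------------

# Putative base decoding: invert each block's data colors, ignoring parities.
# stream: N x k, ecc: N x m; returns N x k bases.
.decode_blocks_batch <- function(stream, ecc, code) {
  inv <- code$gen$inverse
  out <- matrix(0L, nrow(stream), code$k)
  for (i in seq_len(code$m)) {
    off <- 5L * (i - 1L)
    D <- cbind(stream[, off + 2:5, drop = FALSE], ecc[, i])
    for (col in 1:5) {
      acc <- 0L
      for (j in 1:5) {
        if (inv[j, col] != 0L) {
          acc <- bitwXor(acc, .GF4_MUL[inv[j, col] * 4L + D[, j] + 1L])
        }
      }
      out[, off + col] <- acc
    }
  }
  out
}

# Naive two-base decoding: cumulative GF(4) sum of the color stream from the
# adapter base.  A single color error corrupts every downstream base.
.naive_decode_batch <- function(stream, code) {
  out <- matrix(0L, nrow(stream), code$k)
  acc <- rep.int(code$adapter, nrow(stream))
  for (j in seq_len(code$k)) {
    acc <- bitwXor(acc, stream[, j])
    out[, j] <- acc
  }
  out
}

# Codeword position -> index into the quality vector (stream qualities first,
# then ECC qualities).
.codeword_quality_index <- function(code) {
  m <- code$m
  idx <- integer(code$n)
  for (i in seq_len(m)) {
    off <- 5L * (i - 1L)
    idx[off + 1:4] <- off + 2:5        # c1..c4 <- stream colors
    idx[off + 5L] <- code$k + i        # c5    <- ECC color
    idx[5L * m + i] <- off + 1L        # junction <- stream color
  }
  idx
}

#' Build the syndrome table for a code
#'
#' Enumerates all error vectors of weight 1, then weight 2 (and so on up to
#' `max_weight`) over the `n` color positions, records the syndrome of
#' each, and maps every syndrome reached to its minimal-weight candidate
#' errors.  Entries reached by several equally simple errors are flagged
#' ambiguous.  The table depends only on the code, so it is built once and
#' reused across reads.
#'
#' @param code a [ecc_code()].
#' @param max_weight largest error weight enumerated (default 2: single
#'   errors are the per-block analysis unit and weight-2 entries expose the
#'   ambiguity structure without combinatorial blow-up).
#' @return An object of class `syndrome_table`.
#' @export
build_syndrome_table <- function(code, max_weight = 2L) {
  max_weight <- as.integer(max_weight)
  if (max_weight < 1L) stop("max_weight must be at least 1", call. = FALSE)
  H <- build_parity_check(code)
  n <- code$n
  m <- code$m
  # single-error syndromes, rows indexed by (position - 1) * 3 + offset
  S1 <- matrix(0L, 3L * n, m)
  for (pos in seq_len(n)) {
    for (off in 1:3) {
      S1[(pos - 1L) * 3L + off, ] <- gf4_mul(off, H[pos, ])
    }
  }
  key_of <- function(sig_rows) {
    if (is.null(dim(sig_rows))) sig_rows <- matrix(sig_rows, nrow = 1L)
    do.call(paste0, as.data.frame(sig_rows))
  }
  entries <- new.env(parent = emptyenv(), size = 4096L)
  zero_key <- paste(rep("0", m), collapse = "")
  add <- function(key, weight, err) {
    # the all-zero syndrome is a valid codeword, never a correction target
    # (final-block c1/c4 single errors reach it but are undetectable)
    if (key == zero_key) return(invisible())
    cur <- entries[[key]]
    if (is.null(cur)) {
      entries[[key]] <- list(weight = weight, candidates = list(err))
    } else if (cur$weight == weight) {
      cur$candidates[[length(cur$candidates) + 1L]] <- err
      entries[[key]] <- cur
    } # simpler (lighter-weight) entries always win
  }
  for (pos in seq_len(n)) {
    for (off in 1:3) {
      add(key_of(S1[(pos - 1L) * 3L + off, ]), 1L,
          cbind(position = pos, offset = off))
    }
  }
  if (max_weight >= 2L) {
    for (p1 in seq_len(n - 1L)) {
      for (o1 in 1:3) {
        s1 <- S1[(p1 - 1L) * 3L + o1, ]
        for (p2 in (p1 + 1L):n) {
          rows <- .xor_dim(matrix(s1, 3L, m, byrow = TRUE),
                          S1[(p2 - 1L) * 3L + 1:3, , drop = FALSE])
          keys <- key_of(rows)
          for (o2 in 1:3) {
            add(keys[o2], 2L,
                cbind(position = c(p1, p2), offset = c(o1, o2)))
          }
        }
      }
    }
  }
  if (max_weight >= 3L) {
    warning("syndrome tables beyond weight 2 are not enumerated; ",
            "weight capped at 2", call. = FALSE)
  }
  structure(list(entries = entries, max_weight = min(max_weight, 2L),
                 n = n, k = code$k, H = H,
                 probe = format(code$probe), adapter = code$adapter),
            class = "syndrome_table")
}

#' @export
print.syndrome_table <- function(x, ...) {
  keys <- ls(x$entries)
  amb <- sum(vapply(keys, function(k) length(x$entries[[k]]$candidates) > 1L,
                    logical(1)))
  cat(sprintf("<syndrome table: probe %s, n = %d, max weight %d; %d syndromes reachable, %d ambiguous>\n",
              x$probe, x$n, x$max_weight, length(keys), amb))
  invisible(x)
}

#' Single errors the code corrects unambiguously
#'
#' Returns the weight-1 errors whose syndrome identifies them uniquely at
#' the table's enumeration depth: apply one of these to a valid codeword
#' and [syndrome_decode()] recovers the truth exactly.  Positions use the
#' codeword coordinate convention (data colors block-major, then junction
#' parities).
#'
#' @param table a [build_syndrome_table()] result.
#' @return An integer matrix with columns `position` and `offset`.
#' @export
unambiguous_single_errors <- function(table) {
  out <- list()
  for (key in ls(table$entries)) {
    entry <- table$entries[[key]]
    if (entry$weight == 1L && length(entry$candidates) == 1L) {
      out[[length(out) + 1L]] <- entry$candidates[[1L]]
    }
  }
  res <- do.call(rbind, out)
  res[order(res[, "position"], res[, "offset"]), , drop = FALSE]
}

#' Hard-decision syndrome decoding of an observed read
#'
#' Computes the read's syndrome and looks it up in the table.  A unique
#' minimal-weight candidate is applied directly; when several candidates
#' tie and per-color qualities are available the candidate whose error
#' positions are the least reliable (highest error probability) is chosen,
#' otherwise the first candidate in deterministic (position, offset) order
#' is applied and the affected blocks are flagged ambiguous.  A syndrome
#' absent from the table (more errors than the table enumerates) is flagged
#' uncorrectable and the uncorrected putative decoding is returned.
#'
#' @param read an `observed_read` (or `encoded_read`) without missing
#'   calls.
#' @param code the matching [ecc_code()].
#' @param table a [build_syndrome_table()] result for this code; built on
#'   the fly when omitted.
#' @param qualities optional per-color Phred qualities (stream order then
#'   ECC order); defaults to `read$qualities`.
#' @return An object of class `syndrome_decoded`: a list with `bases`
#'   (integer GF(4) vector, the decoded sequence), `corrected` (an
#'   `observed_read` holding the corrected color streams), `status`
#'   (per-block: `"clean"`, `"corrected"`, `"ambiguous"` or
#'   `"uncorrectable"`), `syndrome`, `candidates` (list of candidate error
#'   matrices) and `applied` (the error matrix applied, or `NULL`).
#' @export
syndrome_decode <- function(read, code, table = NULL, qualities = NULL) {
  if (is.null(table)) table <- build_syndrome_table(code)
  if (table$k != code$k || table$probe != format(code$probe) ||
      table$adapter != code$adapter) {
    stop("syndrome table was built for a different code", call. = FALSE)
  }
  if (is.null(qualities)) qualities <- read$qualities
  syn <- compute_syndrome(read, code)
  m <- code$m
  status <- rep("clean", m)
  stream <- read$color_stream
  ecc <- read$ecc_stream
  candidates <- list()
  applied <- NULL
  if (any(syn != 0L)) {
    key <- paste(syn, collapse = "")
    entry <- table$entries[[key]]
    if (is.null(entry)) {
      touched <- unique(c(pmax(which(syn != 0L) - 1L, 1L),
                          pmin(which(syn != 0L), m)))
      status[touched] <- "uncorrectable"
    } else {
      candidates <- entry$candidates
      choice <- 1L
      resolved <- length(candidates) == 1L
      if (!resolved && !is.null(qualities)) {
        qidx <- .codeword_quality_index(code)
        eps <- 10^(-pmax(qualities, 1L) / 10)
        score <- vapply(candidates, function(err) {
          e <- eps[qidx[err[, "position"]]]
          sum(log(e / 3) - log1p(-e))
        }, numeric(1))
        choice <- which.max(score)  # ties resolve to the first candidate
        resolved <- TRUE
      }
      applied <- candidates[[choice]]
      cw <- .to_codeword(read, code)
      cw[applied[, "position"]] <- bitwXor(cw[applied[, "position"]],
                                           applied[, "offset"])
      streams <- .from_codeword(cw, code)
      stream <- streams$color_stream
      ecc <- streams$ecc_stream
      # attribute junction corrections to the earlier block's p+
      pos <- applied[, "position"]
      blk <- ifelse(pos <= 5L * m, (pos - 1L) %/% 5L + 1L,
                    pmax(pos - 5L * m - 1L, 1L))
      status[unique(blk)] <- if (resolved) "corrected" else "ambiguous"
    }
  }
  bases <- as.integer(.decode_blocks_batch(matrix(stream, nrow = 1L),
                                           matrix(ecc, nrow = 1L), code))
  structure(list(bases = bases,
                 corrected = observed_read(stream, ecc, read$qualities),
                 status = status, syndrome = syn,
                 candidates = candidates, applied = applied),
            class = "syndrome_decoded")
}

#' @export
print.syndrome_decoded <- function(x, ...) {
  cat("<syndrome-decoded read>\n  bases:  ", gf4_to_bases(x$bases),
      "\n  status: ", paste(x$status, collapse = " "), "\n", sep = "")
  invisible(x)
}
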