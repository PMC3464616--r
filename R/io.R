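## File formats ---------------------------------------------------------------
##
## CSFASTA carries one color-space read per record: a '>' header, then a
## line whose first character is the primer (adapter) base followed by the
## color digits, '.' marking a missing call.  Qualities live in a paired
## QUAL file with the same headers.  The punctured second stream has no
## standard container, so it travels in a CSFASTA-like companion file with
## the same headers, k/5 color characters and no primer base.  Nucleotide
## sequence uses FASTA/FASTQ through Biostrings and a plain Sanger
## (Phred+33) FASTQ writer.

#' A color-space read record
#'
#' @param id read identifier (no leading `>`).
#' @param primer the primer/adapter base, a nucleotide character.
#' @param colors integer GF(4) vector of color calls, `NA` for missing.
#' @param qualities optional integer qualities, one per color.
#' @param ecc optional integer GF(4) vector of second-stream colors.
#' @param ecc_qualities optional integer qualities, one per ECC color.
#' @return An object of class `color_read`.
#' @export
color_read <- function(id, primer, colors, qualities = NULL, ecc = NULL,
                       ecc_qualities = NULL) {
  stopifnot(is.character(id), length(id) == 1L)
  primer <- toupper(primer)
  if (!primer %in% .GF4_BASE) {
    stop(sprintf("record '%s': primer base '%s' is not a nucleotide", id, primer),
         call. = FALSE)
  }
  colors <- as.integer(colors)
  if (!is.null(qualities) && length(qualities) != length(colors)) {
    stop(sprintf("record '%s': %d qualities for %d colors", id,
                 length(qualities), length(colors)), call. = FALSE)
  }
  if (!is.null(ecc_qualities) && length(ecc_qualities) != length(ecc)) {
    stop(sprintf("record '%s': %d ECC qualities for %d ECC colors", id,
                 length(ecc_qualities), length(ecc)), call. = FALSE)
  }
  structure(list(id = id, primer = primer, colors = colors,
                 qualities = if (is.null(qualities)) NULL else as.integer(qualities),
                 ecc = if (is.null(ecc)) NULL else as.integer(ecc),
                 ecc_qualities = if (is.null(ecc_qualities)) NULL else
                   as.integer(ecc_qualities)),
            class = "color_read")
}

.parse_color_chars <- function(chars, path, line_no) {
  map <- c("0" = 0L, "1" = 1L, "2" = 2L, "3" = 3L, "." = NA_integer_)
  vals <- map[chars]
  bad <- which(!chars %in% names(map))
  if (length(bad)) {
    stop(sprintf("%s line %d: invalid color character '%s' at position %d",
                 path, line_no, chars[bad[1L]], bad[1L]), call. = FALSE)
  }
  unname(vals)
}

.read_headed_records <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  is_header <- startsWith(lines, ">")
  if (length(lines) && !is_header[1L]) {
    stop(sprintf("%s line %d: expected a '>' header", path, line_no[1L]),
         call. = FALSE)
  }
  rec_idx <- cumsum(is_header)
  list(lines = lines, line_no = line_no, is_header = is_header,
       rec_idx = rec_idx)
}

#' Read CSFASTA color-space reads (with optional QUAL and ECC companions)
#'
#' `#` comment lines are skipped; each record is a `>` header followed by
#' one sequence line whose first character is the primer base.  When
#' `qual_path`/`ecc_path` are given, identifiers and counts must agree with
#' the main file.
#'
#' @param path CSFASTA file.
#' @param qual_path optional paired QUAL file (whitespace-separated
#'   integers under matching headers).
#' @param ecc_path optional companion file of second-stream colors
#'   (matching headers, no primer base).
#' @param ecc_qual_path optional QUAL file for the ECC companion.
#' @return A list of [color_read()] records.
#' @export
read_csfasta <- function(path, qual_path = NULL, ecc_path = NULL,
                         ecc_qual_path = NULL) {
  parsed <- .read_headed_records(path)
  ids <- character(0)
  records <- list()
  i <- 1L
  while (i <= length(parsed$lines)) {
    header <- parsed$lines[i]
    if (i + 1L > length(parsed$lines) || parsed$is_header[i + 1L]) {
      stop(sprintf("%s line %d: header without a sequence line", path,
                   parsed$line_no[i]), call. = FALSE)
    }
    id <- sub("^>\\s*", "", header)
    seqline <- parsed$lines[i + 1L]
    chars <- strsplit(seqline, "", fixed = TRUE)[[1L]]
    primer <- toupper(chars[1L])
    if (!primer %in% .GF4_BASE) {
      stop(sprintf("%s line %d: first sequence character '%s' is not a primer base",
                   path, parsed$line_no[i + 1L], chars[1L]), call. = FALSE)
    }
    colors <- .parse_color_chars(chars[-1L], path, parsed$line_no[i + 1L])
    records[[length(records) + 1L]] <- color_read(id, primer, colors)
    ids <- c(ids, id)
    i <- i + 2L
  }
  attach_quals <- function(records, qpath, field, lengths) {
    qp <- .read_headed_records(qpath)
    hdr <- which(qp$is_header)
    qids <- sub("^>\\s*", "", qp$lines[hdr])
    if (!identical(qids, ids)) {
      stop(sprintf("%s: read identifiers do not match %s", qpath, path),
           call. = FALSE)
    }
    for (r in seq_along(hdr)) {
      body_lines <- qp$lines[setdiff(
        seq(hdr[r], if (r < length(hdr)) hdr[r + 1L] - 1L else length(qp$lines)),
        hdr[r])]
      vals <- as.integer(strsplit(trimws(paste(body_lines, collapse = " ")),
                                  "\\s+")[[1L]])
      if (length(vals) != lengths[r]) {
        stop(sprintf("%s record '%s': %d qualities for %d colors", qpath,
                     ids[r], length(vals), lengths[r]), call. = FALSE)
      }
      records[[r]][[field]] <- vals
    }
    records
  }
  if (!is.null(ecc_path)) {
    ep <- .read_headed_records(ecc_path)
    hdr <- which(ep$is_header)
    eids <- sub("^>\\s*", "", ep$lines[hdr])
    if (!identical(eids, ids)) {
      stop(sprintf("%s: read identifiers do not match %s", ecc_path, path),
           call. = FALSE)
    }
    for (r in seq_along(hdr)) {
      chars <- strsplit(ep$lines[hdr[r] + 1L], "", fixed = TRUE)[[1L]]
      records[[r]]$ecc <- .parse_color_chars(chars, ecc_path,
                                             ep$line_no[hdr[r] + 1L])
    }
  }
  if (!is.null(qual_path)) {
    records <- attach_quals(records, qual_path, "qualities",
                            vapply(records, function(r) length(r$colors),
                                   integer(1)))
  }
  if (!is.null(ecc_qual_path)) {
    records <- attach_quals(records, ecc_qual_path, "ecc_qualities",
                            vapply(records, function(r) length(r$ecc),
                                   integer(1)))
  }
  records
}

.render_colors <- function(colors) {
  paste(ifelse(is.na(colors), ".", .GF4_COLOR[colors + 1L]), collapse = "")
}

#' Write color-space reads as CSFASTA (plus QUAL / ECC companions)
#'
#' @param records a list of [color_read()] records.
#' @param path output CSFASTA path.
#' @param qual_path optional QUAL output (records must carry qualities).
#' @param ecc_path optional second-stream companion output (records must
#'   carry `ecc` colors).
#' @param ecc_qual_path optional QUAL output for the ECC companion.
#' @return `path`, invisibly.
#' @export
write_csfasta <- function(records, path, qual_path = NULL, ecc_path = NULL,
                          ecc_qual_path = NULL) {
  emit <- function(out, field, render) {
    lines <- character(0)
    for (r in records) {
      val <- r[[field]]
      if (is.null(val)) {
        stop(sprintf("record '%s' has no %s", r$id, field), call. = FALSE)
      }
      lines <- c(lines, paste0(">", r$id), render(r, val))
    }
    writeLines(lines, out)
  }
  emit(path, "colors", function(r, v) paste0(r$primer, .render_colors(v)))
  if (!is.null(qual_path)) {
    emit(qual_path, "qualities", function(r, v) paste(v, collapse = " "))
  }
  if (!is.null(ecc_path)) {
    emit(ecc_path, "ecc", function(r, v) .render_colors(v))
  }
  if (!is.null(ecc_qual_path)) {
    emit(ecc_qual_path, "ecc_qualities", function(r, v) paste(v, collapse = " "))
  }
  invisible(path)
}

#' Convert a color read record to an `observed_read`
#'
#' Qualities are attached only when the record carries them for both
#' streams.
#'
#' @param record a [color_read()] with `ecc` colors.
#' @param code the matching [ecc_code()]; its adapter must equal the
#'   record's primer base.
#' @return An [observed_read()].
#' @export
as_observed_read <- function(record, code) {
  if (is.null(record$ecc)) {
    stop(sprintf("record '%s' has no second-stream colors", record$id),
         call. = FALSE)
  }
  if (bases_to_gf4(record$primer) != code$adapter) {
    stop(sprintf("record '%s': primer base %s does not match the code adapter %s",
                 record$id, record$primer, .GF4_BASE[code$adapter + 1L]),
         call. = FALSE)
  }
  quals <- if (!is.null(record$qualities) && !is.null(record$ecc_qualities)) {
    c(record$qualities, record$ecc_qualities)
  } else NULL
  observed_read(record$colors, record$ecc, quals)
}

## Nucleotide formats ---------------------------------------------------------

#' Read a FASTA file of unambiguous nucleotide sequences
#'
#' Case-insensitive; any IUPAC ambiguity code is rejected with an error
#' naming the record, since the code algebra is defined on A, C, G, T only.
#'
#' @param path FASTA file.
#' @return A named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(seqs))
  for (i in seq_along(out)) {
    chars <- strsplit(out[i], "", fixed = TRUE)[[1L]]
    bad <- which(!chars %in% .GF4_BASE)
    if (length(bad)) {
      stop(sprintf("%s record '%s': ambiguous or invalid base '%s' at position %d",
                   path, names(out)[i], chars[bad[1L]], bad[1L]), call. = FALSE)
    }
  }
  out
}

#' Write named nucleotide sequences as FASTA
#'
#' @param seqs a named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write called bases and qualities as Sanger FASTQ
#'
#' @param ids record identifiers.
#' @param bases a character vector of base strings, or a list of integer
#'   GF(4) vectors.
#' @param qualities a list (or matrix rows) of integer Phred qualities, one
#'   per base; encoded as Phred+33.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(ids, bases, qualities, path) {
  if (is.list(bases)) bases <- vapply(bases, gf4_to_bases, character(1))
  if (is.matrix(qualities)) {
    qualities <- lapply(seq_len(nrow(qualities)), function(i) qualities[i, ])
  }
  stopifnot(length(ids) == length(bases), length(ids) == length(qualities))
  lines <- character(4L * length(ids))
  for (i in seq_along(ids)) {
    q <- qualities[[i]]
    if (length(q) != nchar(bases[i])) {
      stop(sprintf("record '%s': %d qualities for %d bases", ids[i],
                   length(q), nchar(bases[i])), call. = FALSE)
    }
    lines[4L * i - 3L] <- paste0("@", ids[i])
    lines[4L * i - 2L] <- bases[i]
    lines[4L * i - 1L] <- "+"
    lines[4L * i] <- rawToChar(as.raw(pmin(pmax(q, 0L), 93L) + 33L))
  }
  writeLines(lines, path)
  invisible(path)
}
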