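# Generic segment-table format: a TSV with header
#   accession  sequence  tmh_spans  orientations
# tmh_spans:     semicolon-separated "start-end" spans, 1-based inclusive
# orientations:  semicolon-separated per-TMH flags in
#                {in_before, in_after, unknown}
# The flags are converted into synthetic flanking topological domains that
# carry (or omit) the "cytoplasmic" keyword, so downstream orientation uses
# exactly the same rule as for flat-file input.

#' Parse a plain segment table into protein records
#'
#' @param text A single string or character vector of lines holding a
#'   tab-separated table with columns `accession`, `sequence`, `tmh_spans`
#'   and `orientations` (see Details).
#' @param strict Reject records containing nonstandard residue letters.
#'
#' @details Each TMH span is written `start-end`; each orientation flag is
#' one of `in_before` (the loop preceding the helix is cytoplasmic),
#' `in_after` (the following loop is cytoplasmic) or `unknown`. Flags become
#' synthetic topological domains labelled `"Cytoplasmic"` or
#' `"Extracellular"` over the sequence gaps adjacent to the helix;
#' `unknown` contributes no domain, so such helices are later omitted for
#' lack of the keyword. Rows whose spans fall outside the sequence or whose
#' flags conflict on a shared loop are reported as row-level problems.
#'
#' @return A record tibble (see [protein_records()]).
#' @export
parse_segment_table <- function(text, strict = FALSE) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1) return(protein_records(character(), character()))
  tab <- utils::read.delim(
    text = paste(lines, collapse = "\n"),
    stringsAsFactors = FALSE, colClasses = "character"
  )
  required <- c("accession", "sequence", "tmh_spans", "orientations")
  if (!all(required %in% names(tab))) {
    stop("segment table must have columns: ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  problems <- list()
  acc <- character()
  seqs <- character()
  feats <- list()
  doms <- list()
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    sq <- toupper(row$sequence)
    spans_txt <- strsplit(row$tmh_spans, ";", fixed = TRUE)[[1]]
    flags <- strsplit(row$orientations, ";", fixed = TRUE)[[1]]
    spans_txt <- trimws(spans_txt)
    flags <- trimws(flags)
    err <- NULL
    m <- regmatches(spans_txt, regexec("^(\\d+)-(\\d+)$", spans_txt))
    if (any(lengths(m) != 3)) {
      err <- "malformed TMH span"
    } else {
      starts <- as.integer(vapply(m, `[`, character(1), 2))
      ends <- as.integer(vapply(m, `[`, character(1), 3))
      if (any(starts < 1) || any(ends > nchar(sq)) || any(starts > ends)) {
        err <- "TMH span outside sequence"
      } else if (length(flags) != length(starts)) {
        err <- "orientation flag count does not match span count"
      } else if (!all(flags %in% c("in_before", "in_after", "unknown"))) {
        err <- "unknown orientation flag"
      }
    }
    if (is.null(err)) {
      o <- order(starts)
      starts <- starts[o]; ends <- ends[o]; flags <- flags[o]
      dm <- flags_to_domains(starts, ends, flags, nchar(sq))
      if (is.character(dm)) {
        err <- dm
      } else {
        acc <- c(acc, row$accession)
        seqs <- c(seqs, sq)
        feats[[length(feats) + 1L]] <- tibble(
          kind = rep("TRANSMEM", length(starts)), start = starts, end = ends
        )
        doms[[length(doms) + 1L]] <- dm
      }
    }
    if (!is.null(err)) {
      problems[[length(problems) + 1L]] <-
        tibble(accession = row$accession, problem = err)
    }
  }
  out <- protein_records(acc, seqs, feats, doms, strict = strict)
  if (length(problems) > 0) {
    prob <- bind_rows(c(list(record_problems(out)), problems))
    warning(sprintf("%d row(s) failed validation", nrow(prob)), call. = FALSE)
    attr(out, "problems") <- prob
  }
  out
}

# Turn per-TMH orientation flags into domain annotations over the sequence
# gaps. Each flag labels the gap on its cytoplasmic side "Cytoplasmic" and
# the gap on the other side "Extracellular"; conflicting claims on a shared
# gap are a row-level error (returned as a string).
flags_to_domains <- function(starts, ends, flags, seqlen) {
  k <- length(starts)
  # gap g in 0..k: gap 0 precedes TMH 1, gap k follows TMH k
  gap_start <- c(1L, ends + 1L)
  gap_end <- c(starts - 1L, seqlen)
  claims <- vector("list", k + 1L)
  for (j in seq_len(k)) {
    if (flags[j] == "in_before") {
      claims[[j]] <- c(claims[[j]], "cyto")
      claims[[j + 1L]] <- c(claims[[j + 1L]], "noncyto")
    } else if (flags[j] == "in_after") {
      claims[[j]] <- c(claims[[j]], "noncyto")
      claims[[j + 1L]] <- c(claims[[j + 1L]], "cyto")
    }
  }
  dm <- empty_domains()
  for (g in seq_len(k + 1L)) {
    cl <- unique(claims[[g]])
    if (length(cl) > 1) return("conflicting orientation flags on a shared loop")
    if (length(cl) == 0) next
    if (gap_end[g] < gap_start[g]) {
      # zero-length loop claimed cytoplasmic: nothing to annotate; the
      # neighbouring flag still carries the information on its other side.
      next
    }
    dm <- bind_rows(dm, tibble(
      start = gap_start[g], end = gap_end[g],
      label = if (cl == "cyto") "Cytoplasmic" else "Extracellular"
    ))
  }
  arrange(dm, .data$start)
}

#' Read a segment table from a path
#'
#' @param path File path to a TSV in the format of [parse_segment_table()].
#' @inheritParams parse_segment_table
#' @return A record tibble.
#' @export
read_segment_table <- function(path, strict = FALSE) {
  parse_segment_table(readLines(path, warn = FALSE), strict = strict)
}

#' Write records as a segment table
#'
#' The inverse of [parse_segment_table()] up to orientation information:
#' per-TMH flags are derived from the domain annotation with the same
#' keyword rule used by [orient_tmh()], so a cohort expressed in either
#' format yields the same oriented helix set downstream. INTRAMEM features
#' cannot be represented and trigger a warning.
#'
#' @inheritParams record_problems
#' @param path Optional output path.
#' @return The table text as a single string (invisibly when `path` given).
#' @export
write_segment_table <- function(records, path = NULL) {
  header <- "accession\tsequence\ttmh_spans\torientations"
  rows <- character(nrow(records))
  dropped <- character()
  for (i in seq_len(nrow(records))) {
    ft <- records$features[[i]]
    if (any(ft$kind == "INTRAMEM")) {
      dropped <- c(dropped, records$accession[[i]])
    }
    tm <- arrange(filter(ft, .data$kind == "TRANSMEM"), .data$start)
    flags <- vapply(seq_len(nrow(tm)), function(j) {
      o <- orient_tmh(records[i, ], j)
      switch(o, keep = "in_before", reverse = "in_after", "unknown")
    }, character(1))
    rows[i] <- paste(
      records$accession[[i]], records$sequence[[i]],
      paste(sprintf("%d-%d", tm$start, tm$end), collapse = ";"),
      paste(flags, collapse = ";"),
      sep = "\t"
    )
  }
  if (length(dropped) > 0) {
    warning("INTRAMEM features are not representable in the segment table; ",
            "affected: ", paste(unique(dropped), collapse = ", "),
            call. = FALSE)
  }
  txt <- paste0(paste(c(header, rows), collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}
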