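#' Build a table of annotated protein records
#'
#' The central input container of the package is a tibble with one row per
#' protein and list-columns holding the membrane features and topological
#' domains. All coordinates are 1-based inclusive residue indices into
#' `sequence`.
#'
#' @param accession Character vector of accessions.
#' @param sequence Character vector of residue strings (20-letter alphabet;
#'   nonstandard letters B/Z/X/U/O/J are tolerated unless `strict`).
#' @param features List of tibbles with columns `kind` (`"TRANSMEM"` or
#'   `"INTRAMEM"`), `start`, `end`.
#' @param domains List of tibbles with columns `start`, `end`, `label`
#'   (free text; orientation matches the keyword "cytoplasmic"
#'   case-insensitively).
#' @param strict If `TRUE`, records containing nonstandard residue letters
#'   are rejected.
#'
#' @return A tibble with columns `accession`, `sequence`, `features`,
#'   `domains`.
#' @export
protein_records <- function(accession, sequence, features = NULL,
                            domains = NULL, strict = FALSE) {
  n <- length(accession)
  if (is.null(features)) features <- rep(list(empty_features()), n)
  if (is.null(domains)) domains <- rep(list(empty_domains()), n)
  out <- tibble(
    accession = as.character(accession),
    sequence = toupper(as.character(sequence)),
    features = features,
    domains = domains
  )
  validate_records(out, strict = strict)
}

empty_features <- function() {
  tibble(kind = character(), start = integer(), end = integer())
}

empty_domains <- function() {
  tibble(start = integer(), end = integer(), label = character())
}

# Validates coordinates and overlap invariants. Invalid records are reported
# via a warning and an attached `problems` attribute, never silently dropped.
validate_records <- function(records, strict = FALSE) {
  problems <- list()
  keep <- rep(TRUE, nrow(records))
  for (i in seq_len(nrow(records))) {
    acc <- records$accession[[i]]
    seqlen <- nchar(records$sequence[[i]])
    errs <- character()
    if (seqlen == 0L) errs <- c(errs, "empty sequence")
    letters_seen <- unique(seq_chars(records$sequence[[i]]))
    bad <- setdiff(letters_seen, c(AA_ALPHABET, AA_NONSTANDARD))
    if (length(bad) > 0) {
      errs <- c(errs, paste0("unknown residue letters: ",
                             paste(bad, collapse = "")))
    }
    if (strict && any(letters_seen %in% AA_NONSTANDARD)) {
      errs <- c(errs, "nonstandard residue letters in strict mode")
    }
    ft <- records$features[[i]]
    dm <- records$domains[[i]]
    spans <- rbind(
      data.frame(start = ft$start, end = ft$end),
      data.frame(start = dm$start, end = dm$end)
    )
    if (nrow(spans) > 0) {
      if (any(is.na(spans$start)) || any(is.na(spans$end)) ||
          any(spans$start < 1) || any(spans$end > seqlen) ||
          any(spans$start > spans$end)) {
        errs <- c(errs, "malformed coordinates (need 1 <= start <= end <= length)")
      }
    }
    if (nrow(ft) > 1 && !anyNA(ft$start) && !anyNA(ft$end)) {
      o <- order(ft$start)
      if (any(ft$start[o][-1] <= ft$end[o][-nrow(ft)])) {
        errs <- c(errs, "overlapping membrane features")
      }
    }
    if (nrow(ft) > 0 && nrow(dm) > 0 && !anyNA(c(ft$start, ft$end, dm$start, dm$end))) {
      for (j in seq_len(nrow(dm))) {
        if (any(dm$start[j] <= ft$end & dm$end[j] >= ft$start)) {
          errs <- c(errs, "topological domain overlaps a membrane feature")
          break
        }
      }
    }
    if (length(errs) > 0) {
      keep[i] <- FALSE
      problems[[length(problems) + 1L]] <-
        tibble(accession = acc, problem = paste(errs, collapse = "; "))
    }
  }
  out <- records[keep, , drop = FALSE]
  if (length(problems) > 0) {
    prob <- bind_rows(problems)
    warning(
      sprintf(
        "%d record(s) failed validation and were set aside: %s",
        nrow(prob), paste(prob$accession, collapse = ", ")
      ),
      call. = FALSE
    )
    attr(out, "problems") <- prob
  }
  out
}

#' Problems reported while reading or validating records
#'
#' @param records A record tibble returned by [protein_records()],
#'   [parse_flatfile()] or [parse_segment_table()].
#' @return A tibble of accession/problem pairs, or `NULL` when everything
#'   validated.
#' @export
record_problems <- function(records) attr(records, "problems")

#' Number of membrane-spanning features per record
#'
#' Single-pass means exactly one TRANSMEM feature; INTRAMEM features never
#' count as membrane-spanning helices.
#'
#' @inheritParams record_problems
#' @return `records` with added columns `n_tmh` and `pass_class`
#'   (`"single"`/`"multi"`; `NA` for records without TRANSMEM features).
#' @export
annotate_pass_class <- function(records) {
  n_tmh <- vapply(
    records$features,
    function(ft) sum(ft$kind == "TRANSMEM"),
    integer(1)
  )
  records$n_tmh <- n_tmh
  records$pass_class <- dplyr::case_when(
    n_tmh == 1L ~ "single",
    n_tmh > 1L ~ "multi",
    TRUE ~ NA_character_
  )
  records
}

# ---------------------------------------------------------------------------
# Flat-file dialect
#
# A documented minimal subset of the UniProt text format:
#   ID   <accession>
#   AC   <accession>;
#   FT   TRANSMEM        20..41
#   FT   TOPO_DOM        1..19
#   FT                   /note="Cytoplasmic"
#   SQ   SEQUENCE   60 AA
#        MKTAYIAKQR QISFVKSHFS ...
#   //
# Qualifier text may also trail the coordinates on the FT line itself.
# Unknown line types and unknown FT feature kinds are ignored (the latter
# with a warning).
# ---------------------------------------------------------------------------

#' Parse UniProt-style flat-file topology annotation
#'
#' @param text A single string (or character vector of lines) holding one or
#'   more concatenated records in the minimal flat-file dialect.
#' @param strict Reject records containing nonstandard residue letters.
#'
#' @return A record tibble (see [protein_records()]); records that fail
#'   coordinate validation are reported through [record_problems()].
#' @export
parse_flatfile <- function(text, strict = FALSE) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- sub("\r$", "", lines)
  recs <- list()
  cur <- NULL
  unknown_kinds <- character()
  flush_seq <- FALSE
  for (ln in lines) {
    if (grepl("^//", ln)) {
      if (!is.null(cur)) recs[[length(recs) + 1L]] <- cur
      cur <- NULL
      flush_seq <- FALSE
      next
    }
    if (is.null(cur)) {
      cur <- list(
        id = NA_character_, ac = NA_character_, seq = character(),
        ft = list()
      )
    }
    if (grepl("^ID\\s", ln)) {
      cur$id <- strsplit(trimws(sub("^ID\\s+", "", ln)), "\\s+")[[1]][1]
    } else if (grepl("^AC\\s", ln)) {
      cur$ac <- sub(";.*$", "", trimws(sub("^AC\\s+", "", ln)))
    } else if (grepl("^FT\\s", ln)) {
      body <- sub("^FT\\s*", "", ln)
      if (grepl("^/note=", trimws(body))) {
        # qualifier continuation for the previous feature
        if (length(cur$ft) > 0) {
          note <- sub("^/note=\"?", "", trimws(body))
          note <- sub("\"$", "", note)
          cur$ft[[length(cur$ft)]]$note <- note
        }
      } else {
        m <- regmatches(
          body,
          regexec("^(\\S+)\\s+(\\d+)\\.\\.(\\d+)\\s*(.*)$", body)
        )[[1]]
        if (length(m) == 5) {
          cur$ft[[length(cur$ft) + 1L]] <- list(
            kind = m[2], start = as.integer(m[3]), end = as.integer(m[4]),
            note = if (nzchar(trimws(m[5]))) trimws(m[5]) else NA_character_
          )
        }
      }
    } else if (grepl("^SQ\\s", ln)) {
      flush_seq <- TRUE
    } else if (flush_seq && grepl("^\\s", ln)) {
      cur$seq <- c(cur$seq, gsub("[^A-Za-z]", "", ln))
    }
  }
  if (!is.null(cur)) recs[[length(recs) + 1L]] <- cur

  if (length(recs) == 0) {
    return(protein_records(character(), character()))
  }

  acc <- character(length(recs))
  seqs <- character(length(recs))
  feats <- vector("list", length(recs))
  doms <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    acc[i] <- if (!is.na(r$ac)) r$ac else r$id
    seqs[i] <- toupper(paste(r$seq, collapse = ""))
    ft_rows <- empty_features()
    dm_rows <- empty_domains()
    for (f in r$ft) {
      if (f$kind %in% c("TRANSMEM", "INTRAMEM")) {
        ft_rows <- bind_rows(ft_rows, tibble(
          kind = f$kind, start = f$start, end = f$end
        ))
      } else if (f$kind == "TOPO_DOM") {
        dm_rows <- bind_rows(dm_rows, tibble(
          start = f$start, end = f$end,
          label = if (is.na(f$note)) "" else f$note
        ))
      } else {
        unknown_kinds <- c(unknown_kinds, f$kind)
      }
    }
    feats[[i]] <- arrange(ft_rows, .data$start)
    doms[[i]] <- arrange(dm_rows, .data$start)
  }
  if (length(unknown_kinds) > 0) {
    warning(
      "ignoring unknown feature kind(s): ",
      paste(unique(unknown_kinds), collapse = ", "),
      call. = FALSE
    )
  }
  protein_records(acc, seqs, feats, doms, strict = strict)
}

#' Read flat-file annotation from a path or connection
#'
#' @param path File path (or connection) to a flat file in the dialect
#'   described in [parse_flatfile()].
#' @inheritParams parse_flatfile
#' @return A record tibble.
#' @export
read_flatfile <- function(path, strict = FALSE) {
  parse_flatfile(readLines(path, warn = FALSE), strict = strict)
}

#' Serialize records to the flat-file dialect
#'
#' `parse_flatfile(write_flatfile(x))` reproduces `x` field by field:
#' features and domains are emitted sorted by start coordinate, which is also
#' the canonical order the parser returns.
#'
#' @inheritParams record_problems
#' @param path Optional path; when given the text is written there.
#' @return The flat-file content as a single string (invisibly when `path`
#'   is given).
#' @export
write_flatfile <- function(records, path = NULL) {
  out <- character()
  for (i in seq_len(nrow(records))) {
    acc <- records$accession[[i]]
    sq <- records$sequence[[i]]
    ft <- records$features[[i]]
    dm <- records$domains[[i]]
    lines <- c(
      sprintf("ID   %s", acc),
      sprintf("AC   %s;", acc)
    )
    spans <- bind_rows(
      if (nrow(ft) > 0) tibble(kind = ft$kind, start = ft$start,
                               end = ft$end, note = NA_character_),
      if (nrow(dm) > 0) tibble(kind = "TOPO_DOM", start = dm$start,
                               end = dm$end, note = dm$label)
    )
    if (!is.null(spans) && nrow(spans) > 0) {
      spans <- arrange(spans, .data$start)
      for (j in seq_len(nrow(spans))) {
        lines <- c(lines, sprintf("FT   %-15s %d..%d",
                                  spans$kind[j], spans$start[j], spans$end[j]))
        if (!is.na(spans$note[j]) && nzchar(spans$note[j])) {
          lines <- c(lines, sprintf("FT   %-15s /note=\"%s\"", "", spans$note[j]))
        }
      }
    }
    lines <- c(lines, sprintf("SQ   SEQUENCE   %d AA", nchar(sq)))
    starts <- seq(1, max(nchar(sq), 1), by = 60)
    for (s in starts) {
      chunk <- substr(sq, s, min(s + 59, nchar(sq)))
      if (!nzchar(chunk)) next
      tens <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      lines <- c(lines, paste0("     ", paste(tens, collapse = " ")))
    }
    out <- c(out, lines, "//")
  }
  txt <- paste0(paste(out, collapse = "\n"), if (length(out)) "\n" else "")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}

#' Export oriented segments as FASTA for inspection
#'
#' Writes each oriented helix (inside flank + core + outside flank, read
#' inside to outside) as one FASTA entry named `accession|tmh<k>|<regime>`.
#'
#' @param segments A segment tibble from [extract_segments()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_segment_fasta <- function(segments, path) {
  hdr <- sprintf(">%s|tmh%d|%s", segments$accession, segments$tmh_index,
                 segments$regime)
  seqs <- paste0(segments$inside_flank, segments$core, segments$outside_flank)
  writeLines(as.vector(rbind(hdr, seqs)), path)
  invisible(path)
}
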