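# Orientation and flank extraction.
#
# Every helix is placed on a cytoplasmic -> non-cytoplasmic axis ("inside"
# -> "outside"). All stored strings (core, flanks, central alignment) read
# in that inside->outside direction; when the cytoplasmic domain follows
# the helix in the source sequence, the segment is reversed.

#' Resolve the membrane orientation of one helix
#'
#' The nearest topological domain on each side of the TRANSMEM feature is
#' inspected for the case-insensitive keyword "cytoplasmic": a preceding
#' cytoplasmic domain keeps the source direction, a following one reverses
#' it, and a helix with the keyword on neither side is omitted. The keyword
#' on both sides is a record-level inconsistency.
#'
#' @param record A one-row record tibble.
#' @param tmh_index Ordinal of the TRANSMEM feature within the record
#'   (in start order).
#' @return One of `"keep"`, `"reverse"`, `"omit"`, `"conflict"`.
#' @export
orient_tmh <- function(record, tmh_index) {
  ft <- record$features[[1]]
  tm_idx <- which(ft$kind == "TRANSMEM")
  tm_idx <- tm_idx[order(ft$start[tm_idx])]
  if (tmh_index < 1 || tmh_index > length(tm_idx)) {
    stop("tmh_index does not address a TRANSMEM feature", call. = FALSE)
  }
  dm <- record$domains[[1]]
  orient_from_domains(dm$start, dm$end, dm$label,
                      ft$start[tm_idx[tmh_index]], ft$end[tm_idx[tmh_index]])
}

orient_from_domains <- function(dm_start, dm_end, dm_label, s, e) {
  before <- which(dm_end < s)
  after <- which(dm_start > e)
  pre_c <- length(before) > 0 &&
    grepl("cytoplasmic", dm_label[before[which.max(dm_end[before])]],
          ignore.case = TRUE)
  post_c <- length(after) > 0 &&
    grepl("cytoplasmic", dm_label[after[which.min(dm_start[after])]],
          ignore.case = TRUE)
  if (pre_c && post_c) return("conflict")
  if (pre_c) return("keep")
  if (post_c) return("reverse")
  "omit"
}

#' Resolve orientation for every helix of a cohort
#'
#' Orientation is resolved independently for each helix of a multi-pass
#' protein; a warning is issued when the resulting orientations do not
#' alternate along the protein, which indicates inconsistent annotation.
#'
#' @inheritParams record_problems
#' @return A tibble with `accession`, `tmh_index`, `start`, `end`,
#'   `orientation`.
#' @export
orient_tmhs <- function(records) {
  rows <- purrr::map(seq_len(nrow(records)), function(i) {
    tm <- arrange(filter(records$features[[i]], .data$kind == "TRANSMEM"),
                  .data$start)
    if (nrow(tm) == 0) return(NULL)
    tibble(
      accession = records$accession[[i]],
      tmh_index = seq_len(nrow(tm)),
      start = tm$start,
      end = tm$end,
      orientation = vapply(seq_len(nrow(tm)),
                           function(j) orient_tmh(records[i, ], j),
                           character(1))
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) > 0) {
    bad <- out %>%
      filter(.data$orientation %in% c("keep", "reverse")) %>%
      group_by(.data$accession) %>%
      summarise(
        alternates = all(rle(.data$orientation)$lengths == 1L) || n() == 1L,
        .groups = "drop"
      ) %>%
      filter(!.data$alternates)
    if (nrow(bad) > 0) {
      warning("orientation does not alternate along: ",
              paste(bad$accession, collapse = ", "), call. = FALSE)
    }
  }
  out
}

#' Helix core length filter
#'
#' @param core_len Integer vector of helix lengths.
#' @param min_len,max_len Inclusive bounds (defaults 16 and 38, the cut-offs
#'   that remove atypically short or long annotated helices).
#' @return Logical vector.
#' @export
filter_tmh_length <- function(core_len, min_len = 16, max_len = 38) {
  core_len >= min_len & core_len <= max_len
}

#' Flank extraction configuration
#'
#' @param regime One of `"db_no_overlap"` (database boundaries, shared loops
#'   split evenly with the odd middle residue unassigned),
#'   `"db_overlap"` (flanks run to `max_flank` regardless of neighbouring
#'   helices, but never into a membrane core), `"db_viable"` (as
#'   `db_no_overlap`, keeping only helices with at least
#'   `ceiling(viable_fraction * max_flank)` residues on both flanks) or
#'   `"central"` (gapless alignment on the helix central residue).
#' @param max_flank Maximum flank length in residues (5, 10 or 20 are the
#'   usual analysis depths). Under `central` this is the database-defined
#'   flank limit beyond which positions are absent.
#' @param viable_fraction Fraction of `max_flank` required on both sides for
#'   `db_viable` (default 0.5, i.e. viable length 5 for a 10-residue flank).
#' @param central_half_width Half-width of the central-alignment window in
#'   positions (default 20: window -20..+20).
#' @param central_core_halfwidth Positions treated as helix under central
#'   alignment (default 10: flank windows are -20..-10 and +10..+20).
#' @param even_center For even-length cores, which of the two middle
#'   residues anchors position 0: `"lower"` (the cytoplasmic-side one,
#'   default) or `"upper"`.
#' @param min_len,max_len Helix length filter bounds (see
#'   [filter_tmh_length()]).
#' @return A `flank_config` list.
#' @export
flank_config <- function(regime = c("db_no_overlap", "db_overlap",
                                    "db_viable", "central"),
                         max_flank = 10, viable_fraction = 0.5,
                         central_half_width = 20,
                         central_core_halfwidth = 10,
                         even_center = c("lower", "upper"),
                         min_len = 16, max_len = 38) {
  regime <- match.arg(regime)
  even_center <- match.arg(even_center)
  stopifnot(max_flank > 0, viable_fraction > 0, viable_fraction <= 1,
            central_half_width >= 1, min_len >= 1, max_len >= min_len)
  structure(
    list(
      regime = regime, max_flank = as.integer(max_flank),
      viable_fraction = viable_fraction,
      central_half_width = as.integer(central_half_width),
      central_core_halfwidth = as.integer(central_core_halfwidth),
      even_center = even_center,
      min_len = as.integer(min_len), max_len = as.integer(max_len)
    ),
    class = "flank_config"
  )
}

# Index (1-based, within the core read inside->outside) of the residue that
# anchors central position 0.
central_index <- function(n, even_center = "lower") {
  if (n %% 2L == 1L || even_center == "lower") {
    (n - 1L) %/% 2L + 1L
  } else {
    n %/% 2L + 1L
  }
}

# Flank lengths available on the left/right of TMH j in source coordinates.
# Internal loops under the no-overlap rule contribute floor(L/2) to each
# adjoining flank (odd middle residue unassigned); terminal tails are
# clipped only by the sequence end. The overlap regime ignores loop sharing
# but never crosses into a membrane core.
flank_extents <- function(mem, j, seqlen, cfg) {
  s <- mem$start[j]
  e <- mem$end[j]
  before <- mem$end[mem$end < s]
  after <- mem$start[mem$start > e]
  prev_end <- if (length(before) > 0) max(before) else 0L
  next_start <- if (length(after) > 0) min(after) else seqlen + 1L
  l_loop <- s - prev_end - 1L
  r_loop <- next_start - e - 1L
  overlap <- cfg$regime == "db_overlap"
  l_avail <- if (overlap || prev_end == 0L) l_loop else l_loop %/% 2L
  r_avail <- if (overlap || next_start > seqlen) r_loop else r_loop %/% 2L
  list(
    left = min(cfg$max_flank, l_avail),
    right = min(cfg$max_flank, r_avail),
    left_note = flank_note(min(cfg$max_flank, l_avail), cfg$max_flank),
    right_note = flank_note(min(cfg$max_flank, r_avail), cfg$max_flank)
  )
}

flank_note <- function(len, max_flank) {
  if (len == 0L) "empty"
  else if (len < max_flank) sprintf("truncated(%d)", len)
  else "full"
}

# Extract one oriented helix under a db regime; a plain list of fields.
extract_one_db <- function(sq, mem, tm_row, orientation, cfg) {
  s <- mem$start[tm_row]
  e <- mem$end[tm_row]
  ext <- flank_extents(mem, tm_row, nchar(sq), cfg)
  core_src <- substr(sq, s, e)
  left <- substr_safe(sq, s - ext$left, s - 1L)
  right <- substr_safe(sq, e + 1L, e + ext$right)
  if (orientation == "keep") {
    list(core = core_src, inside = left, outside = right,
         in_note = ext$left_note, out_note = ext$right_note)
  } else {
    list(core = str_rev(core_src),
         inside = str_rev(right), outside = str_rev(left),
         in_note = ext$right_note, out_note = ext$left_note)
  }
}

#' Extract database-boundary flanks for one helix
#'
#' Low-level single-helix interface; [extract_segments()] is the cohort
#' driver. The helix must orient (`keep`/`reverse`); skipped or
#' length-filtered helices return `NULL`.
#'
#' @inheritParams orient_tmh
#' @param cfg A [flank_config()] with a `db_*` regime.
#' @return A one-row segment tibble, or `NULL` when the helix is omitted,
#'   outside the length limits, or fails the viability requirement.
#' @export
extract_db_flanks <- function(record, tmh_index, cfg = flank_config()) {
  stopifnot(cfg$regime %in% c("db_no_overlap", "db_overlap", "db_viable"))
  res <- extract_segments(record, cfg)
  res <- filter(res, .data$tmh_index == !!tmh_index)
  if (nrow(res) == 0) NULL else res
}

#' Extract the central-alignment window for one helix
#'
#' @inheritParams extract_db_flanks
#' @param cfg A [flank_config()] with `regime = "central"`.
#' @return A one-row segment tibble with an `aligned` string (window
#'   positions `-central_half_width..+central_half_width`, `-` marking
#'   absent positions), or `NULL` when the helix is omitted or filtered.
#' @export
extract_central_flanks <- function(record, tmh_index,
                                   cfg = flank_config(regime = "central",
                                                      max_flank = 20)) {
  stopifnot(cfg$regime == "central")
  res <- extract_segments(record, cfg)
  res <- filter(res, .data$tmh_index == !!tmh_index)
  if (nrow(res) == 0) NULL else res
}

#' Orient, filter and extract every helix of a cohort
#'
#' Applies the length filter, resolves orientation, and extracts flanks
#' under the configured regime. Central alignment builds on the
#' no-overlap database flanks (limited to `cfg$max_flank`) and anchors a
#' window of `2 * central_half_width + 1` positions on the helix central
#' residue.
#'
#' @inheritParams record_problems
#' @param cfg A [flank_config()].
#' @return A segment tibble (one row per kept helix) with columns
#'   `accession`, `tmh_index`, `start`, `end`, `pass_class`, `orientation`,
#'   `regime`, `core`, `inside_flank`, `outside_flank`, truncation notes and
#'   (under `central`) `aligned`. The per-helix audit trail is attached as
#'   attribute `"ledger"` (see [extraction_ledger()]).
#' @export
extract_segments <- function(records, cfg = flank_config()) {
  records <- annotate_pass_class(records)
  db_cfg <- cfg
  if (cfg$regime == "central") db_cfg$regime <- "db_no_overlap"
  viable_len <- as.integer(ceiling(cfg$viable_fraction * cfg$max_flank))

  # flat accumulators; one tibble built at the end
  acc <- new_accumulator()
  led <- new_accumulator()

  for (i in seq_len(nrow(records))) {
    ft <- records$features[[i]]
    sq <- records$sequence[[i]]
    dm <- records$domains[[i]]
    pass_class <- records$pass_class[[i]]
    accession <- records$accession[[i]]
    mem_idx <- order(ft$start)
    mem <- list(kind = ft$kind[mem_idx], start = ft$start[mem_idx],
                end = ft$end[mem_idx])
    tm_rows <- which(mem$kind == "TRANSMEM")
    for (j in seq_along(tm_rows)) {
      r <- tm_rows[j]
      core_len <- mem$end[r] - mem$start[r] + 1L
      if (!filter_tmh_length(core_len, cfg$min_len, cfg$max_len)) {
        led$add(list(
          accession = accession, tmh_index = j, regime = cfg$regime,
          decision = "skipped",
          reason = sprintf("length %d outside [%d, %d]", core_len,
                           cfg$min_len, cfg$max_len),
          core_length = core_len, flank_in = NA_integer_,
          flank_out = NA_integer_
        ))
        next
      }
      orientation <- orient_from_domains(dm$start, dm$end, dm$label,
                                         mem$start[r], mem$end[r])
      if (orientation %in% c("omit", "conflict")) {
        led$add(list(
          accession = accession, tmh_index = j, regime = cfg$regime,
          decision = "omitted",
          reason = if (orientation == "conflict") {
            "cytoplasmic keyword on both sides"
          } else "no cytoplasmic keyword on either side",
          core_length = core_len, flank_in = NA_integer_,
          flank_out = NA_integer_
        ))
        next
      }
      seg <- extract_one_db(sq, mem, r, orientation, db_cfg)
      fin <- nchar(seg$inside)
      fout <- nchar(seg$outside)
      if (cfg$regime == "db_viable" &&
          (fin < viable_len || fout < viable_len)) {
        led$add(list(
          accession = accession, tmh_index = j, regime = cfg$regime,
          decision = "skipped",
          reason = sprintf("flank below viable length %d (in %d, out %d)",
                           viable_len, fin, fout),
          core_length = core_len, flank_in = fin, flank_out = fout
        ))
        next
      }
      acc$add(list(
        accession = accession, tmh_index = j, start = mem$start[r],
        end = mem$end[r], pass_class = pass_class,
        orientation = orientation, regime = cfg$regime,
        core = seg$core, inside_flank = seg$inside,
        outside_flank = seg$outside,
        inside_truncation = seg$in_note, outside_truncation = seg$out_note,
        aligned = if (cfg$regime == "central") {
          central_align(seg$inside, seg$core, seg$outside, cfg)
        } else NA_character_
      ))
      led$add(list(
        accession = accession, tmh_index = j, regime = cfg$regime,
        decision = "kept", reason = NA_character_,
        core_length = core_len, flank_in = fin, flank_out = fout
      ))
    }
  }
  out <- acc$collect(c(
    accession = "character", tmh_index = "integer", start = "integer",
    end = "integer", pass_class = "character", orientation = "character",
    regime = "character", core = "character", inside_flank = "character",
    outside_flank = "character", inside_truncation = "character",
    outside_truncation = "character", aligned = "character"
  ))
  if (cfg$regime != "central") out$aligned <- NULL
  attr(out, "ledger") <- led$collect(c(
    accession = "character", tmh_index = "integer", regime = "character",
    decision = "character", reason = "character",
    core_length = "integer", flank_in = "integer", flank_out = "integer"
  ))
  attr(out, "config") <- cfg
  out
}

# Grow-by-list row accumulator: add() stores a named list, collect() binds
# the rows into a tibble with the given column prototypes.
new_accumulator <- function() {
  rows <- vector("list", 256L)
  n <- 0L
  add <- function(row) {
    n <<- n + 1L
    if (n > length(rows)) length(rows) <<- 2L * length(rows)
    rows[[n]] <<- row
  }
  collect <- function(proto) {
    cols <- lapply(names(proto), function(nm) {
      vals <- vapply(rows[seq_len(n)], function(r) r[[nm]],
                     vector(proto[[nm]], 1))
      vals
    })
    names(cols) <- names(proto)
    as_tibble(cols)
  }
  list(add = add, collect = collect)
}

# Place the oriented segment into the -hw..+hw window anchored at the core
# central residue; absent positions (beyond flanks/termini) become "-".
central_align <- function(inside, core, outside, cfg) {
  hw <- cfg$central_half_width
  full <- paste0(inside, core, outside)
  ci <- nchar(inside) + central_index(nchar(core), cfg$even_center)
  idx <- ci + (-hw:hw)
  ch <- rep("-", 2L * hw + 1L)
  ok <- idx >= 1L & idx <= nchar(full)
  ch[ok] <- seq_chars(full)[idx[ok]]
  paste(ch, collapse = "")
}

#' Per-helix extraction audit trail
#'
#' @param segments A segment tibble from [extract_segments()].
#' @return A tibble with one row per helix considered: `accession`,
#'   `tmh_index`, `regime`, `decision` (`kept`/`skipped`/`omitted`),
#'   `reason`, `core_length` and flank lengths.
#' @export
extraction_ledger <- function(segments) attr(segments, "ledger")

#' Split a helix core into membrane leaflet halves
#'
#' The core (read inside to outside) is divided into an inner
#' (cytoplasmic-side) and an outer half of `floor(n/2)` residues each; for
#' odd lengths the central residue belongs to neither half by default.
#'
#' @param core Character vector of oriented core strings.
#' @param center `"exclude"` (default) leaves the odd central residue out of
#'   both halves; `"inner"` assigns it to the inner half.
#' @return A tibble with columns `inner`, `center`, `outer`.
#' @export
split_leaflets <- function(core, center = c("exclude", "inner")) {
  center <- match.arg(center)
  n <- nchar(core)
  h <- n %/% 2L
  inner_end <- ifelse(center == "inner" & n %% 2L == 1L, h + 1L, h)
  tibble(
    inner = substr(core, 1L, inner_end),
    center = ifelse(n %% 2L == 1L & center == "exclude",
                    substr(core, h + 1L, h + 1L), ""),
    outer = substr(core, n - h + 1L, n)
  )
}

#' Count residues of given types in each flank
#'
#' The per-helix inside/outside counts behind the skew tables: residues of
#' `residues` are tallied in the inside and outside flank of each segment.
#'
#' @param segments A segment tibble (db regime).
#' @param residues Character vector of single-letter residue types, e.g.
#'   `c("D", "E")`.
#' @return `segments` reduced to `accession`, `tmh_index`, `pass_class`
#'   plus integer columns `inside` and `outside`.
#' @export
flank_residue_counts <- function(segments, residues = c("D", "E")) {
  count_in <- count_residues(segments$inside_flank, residues)
  count_out <- count_residues(segments$outside_flank, residues)
  tibble(
    accession = segments$accession, tmh_index = segments$tmh_index,
    pass_class = segments$pass_class,
    inside = count_in, outside = count_out
  )
}

#' Count residues of given types in central-alignment windows
#'
#' @param segments A segment tibble with `regime == "central"`.
#' @param residues Character vector of residue types.
#' @param inside_window,outside_window Inclusive position windows on the
#'   central axis (defaults `c(-20, -10)` and `c(10, 20)`).
#' @return A tibble with `accession`, `tmh_index`, `pass_class`, `inside`,
#'   `outside`.
#' @export
central_flank_counts <- function(segments, residues = c("D", "E"),
                                 inside_window = c(-20, -10),
                                 outside_window = c(10, 20)) {
  stopifnot(all(segments$regime == "central"))
  cfg <- attr(segments, "config")
  hw <- if (!is.null(cfg)) cfg$central_half_width else
    (nchar(segments$aligned[1]) - 1L) %/% 2L
  window_str <- function(aligned, win) {
    substr(aligned, win[1] + hw + 1L, win[2] + hw + 1L)
  }
  tibble(
    accession = segments$accession, tmh_index = segments$tmh_index,
    pass_class = segments$pass_class,
    inside = count_residues(window_str(segments$aligned, inside_window),
                            residues),
    outside = count_residues(window_str(segments$aligned, outside_window),
                             residues)
  )
}

count_residues <- function(strings, residues) {
  pat <- paste0("[", paste(residues, collapse = ""), "]")
  vapply(strings, function(s) {
    lengths(regmatches(s, gregexpr(pat, s)))
  }, integer(1), USE.NAMES = FALSE)
}
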