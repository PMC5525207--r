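# Sliding-window hydrophobicity.
#
# Scale values are data, not code: they live in
# inst/extdata/hydrophobicity_scales.tsv with their literature sources
# (Kyte & Doolittle water-vapour transfer; White & Wimley water-octanol
# whole-residue; Hessa translocon biological scale; Eisenberg consensus).
# Note the scales differ in sign convention: Kyte-Doolittle and Eisenberg
# increase with hydrophobicity, the two transfer-energy scales decrease.

scale_cache <- new.env(parent = emptyenv())

#' Hydrophobicity scale tables
#'
#' @return `hydrophobicity_scales()`: a tibble of all shipped scales, one
#'   row per residue.
#' @export
hydrophobicity_scales <- function() {
  if (is.null(scale_cache$tbl)) {
    path <- system.file("extdata", "hydrophobicity_scales.tsv",
                        package = "tmhflanks", mustWork = TRUE)
    scale_cache$tbl <- readr::read_tsv(path, show_col_types = FALSE)
  }
  scale_cache$tbl
}

#' @rdname hydrophobicity_scales
#' @param name Scale name: `"kyte_doolittle"`, `"white_wimley_octanol"`,
#'   `"hessa_biological"` or `"eisenberg_consensus"`.
#' @return `hydro_scale()`: a named numeric vector over the 20 residues.
#' @export
hydro_scale <- function(name = c("kyte_doolittle", "white_wimley_octanol",
                                 "hessa_biological", "eisenberg_consensus")) {
  name <- match.arg(name)
  tbl <- hydrophobicity_scales()
  setNames(tbl[[name]], tbl$residue)
}

#' Windowed hydrophobicity of one sequence
#'
#' Un-weighted sliding-window mean of per-residue scale values. Windows are
#' clipped at the segment ends (partial windows are averaged over the
#' residues available). Unknown residues are excluded from the window mean
#' in lenient mode and are an error in strict mode.
#'
#' @param sequence A residue string.
#' @param scale A scale name (see [hydro_scale()]) or a named numeric
#'   vector.
#' @param window Odd window length in residues (default 3).
#' @param strict Error on nonstandard residue letters.
#' @return Numeric vector of windowed values, one per residue.
#' @export
windowed_hydrophobicity <- function(sequence, scale = "kyte_doolittle",
                                    window = 3, strict = FALSE) {
  stopifnot(window >= 1, window %% 2 == 1)
  if (is.character(scale)) scale <- hydro_scale(scale)
  ch <- seq_chars(sequence)
  vals <- unname(scale[ch])
  if (anyNA(vals) && strict) {
    stop("nonstandard residue in strict mode: ",
         paste(unique(ch[is.na(vals)]), collapse = ""), call. = FALSE)
  }
  n <- length(vals)
  if (n == 0) return(numeric())
  h <- (window - 1L) %/% 2L
  known <- !is.na(vals)
  cs <- cumsum(c(0, ifelse(known, vals, 0)))
  ck <- cumsum(c(0, as.numeric(known)))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  sums <- cs[hi + 1L] - cs[lo]
  cnts <- ck[hi + 1L] - ck[lo]
  out <- sums / cnts
  out[cnts == 0] <- NA_real_
  out
}

#' Per-segment windowed hydrophobicity on the central axis
#'
#' Each segment's observed residues (inside flank + core + outside flank)
#' are window-averaged end to end, then mapped back onto their
#' central-alignment positions.
#'
#' @param segments A segment tibble with `regime == "central"`.
#' @inheritParams windowed_hydrophobicity
#' @return A long tibble: `accession`, `tmh_index`, `pass_class`,
#'   `position`, `value`.
#' @export
hydrophobicity_values <- function(segments, scale = "kyte_doolittle",
                                  window = 3, strict = FALSE) {
  stopifnot(all(segments$regime == "central"))
  if (is.character(scale)) scale <- hydro_scale(scale)
  width <- nchar(segments$aligned[1])
  hw <- (width - 1L) %/% 2L
  rows <- purrr::map(seq_len(nrow(segments)), function(i) {
    ch <- seq_chars(segments$aligned[i])
    present <- which(ch != "-")
    if (length(present) == 0) return(NULL)
    vals <- windowed_hydrophobicity(
      paste(ch[present], collapse = ""), scale, window, strict
    )
    tibble(
      accession = segments$accession[i],
      tmh_index = segments$tmh_index[i],
      pass_class = segments$pass_class[i],
      position = present - hw - 1L,
      value = vals
    )
  })
  bind_rows(rows)
}

#' Mean hydrophobicity profile over a segment set
#'
#' Per-position mean of the per-segment windowed values, optionally
#' stratified by the number of helices in the parent protein (classes 1,
#' 2, ..., `max_class - 1`, `"max_class+"`).
#'
#' @inheritParams hydrophobicity_values
#' @param stratify_by_count Add a `tmh_class` stratification column from
#'   the per-accession count of helices present in `segments` (i.e.
#'   helices that survived extraction; proteins whose helices were partly
#'   omitted stratify by the surviving count).
#' @param max_class Counts at or above this are pooled (default 15,
#'   labelled `"15+"`).
#' @return A tibble with `position`, `value` (mean), `n` (segments
#'   contributing) and, when stratified, `tmh_class`.
#' @export
hydrophobicity_profile <- function(segments, scale = "kyte_doolittle",
                                   window = 3, stratify_by_count = FALSE,
                                   max_class = 15) {
  vals <- hydrophobicity_values(segments, scale, window)
  if (stratify_by_count) {
    counts <- segments %>%
      group_by(.data$accession) %>%
      summarise(n_tmh = dplyr::n_distinct(.data$tmh_index),
                .groups = "drop") %>%
      mutate(tmh_class = ifelse(.data$n_tmh >= max_class,
                                paste0(max_class, "+"),
                                as.character(.data$n_tmh)))
    vals <- left_join(vals, counts, by = "accession")
    vals %>%
      group_by(.data$tmh_class, .data$position) %>%
      summarise(value = mean(.data$value, na.rm = TRUE), n = n(),
                .groups = "drop")
  } else {
    vals %>%
      group_by(.data$position) %>%
      summarise(value = mean(.data$value, na.rm = TRUE), n = n(),
                .groups = "drop")
  }
}
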