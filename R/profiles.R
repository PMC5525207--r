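# Positional profiles derived from aligned segment sets.
#
# Two bespoke normalisations:
#  * absolute relative occurrence  p_{i,r} = a_{i,r} / max_r(coverage(r))
#    - dominated by the abundant residue types; reveals what sits where.
#  * relative percentage           q_{i,r} = 100 * a_{i,r} / a_i
#    - conditioned on the residue type itself; reveals where a rare type
#      sits if it occurs at all. Sums to 100 over positions for each type.

# Expand single letters / composite classes ("D+E") into residue vectors.
resolve_classes <- function(classes) {
  if (is.null(classes)) {
    classes <- as.list(AA_ALPHABET)
    names(classes) <- AA_ALPHABET
  }
  if (is.character(classes)) {
    classes <- setNames(as.list(classes), classes)
  }
  lapply(classes, function(cl) {
    res <- unlist(strsplit(cl, "+", fixed = TRUE))
    if (!all(res %in% AA_ALPHABET)) {
      stop("unknown residue type in class: ", paste(cl, collapse = "+"),
           call. = FALSE)
    }
    res
  })
}

class_counts <- function(set, classes) {
  t(vapply(classes, function(res) {
    colSums(set$counts[res, , drop = FALSE])
  }, numeric(length(set$positions))))
}

#' Absolute relative occurrence profile
#'
#' p_{i,r} = a_{i,r} / max_r(a_r), where the denominator is the maximal
#' number of residues in any alignment column (the number of sequences at
#' full coverage). Values lie in `[0, 1]` and are largest for the dominant
#' residue types.
#'
#' @param set An [aligned_set()].
#' @param classes Residue types to profile: a character vector of letters
#'   or composite classes like `"D+E"` (default: all 20 types).
#' @return A tibble with columns `residue`, `position`, `value` and a
#'   `kind` column equal to `"p_abs"`.
#' @export
absolute_relative_occurrence <- function(set, classes = NULL) {
  denom <- max(set$coverage)
  if (denom <= 0) stop("zero coverage everywhere", call. = FALSE)
  cls <- resolve_classes(classes)
  cc <- class_counts(set, cls)
  tibble(
    kind = "p_abs",
    residue = rep(names(cls), each = length(set$positions)),
    position = rep(set$positions, times = length(cls)),
    value = as.vector(t(cc)) / denom
  )
}

#' Relative percentage profile
#'
#' q_{i,r} = 100 * a_{i,r} / a_i, where a_i is the total abundance of
#' residues of type i over the whole analysed region (helix plus both
#' adjoining flanks for central sets). Each residue type's curve sums to
#' 100 over positions. Types absent from the region are flagged and carry
#' `NA` values, never a zero-filled curve.
#'
#' @inheritParams absolute_relative_occurrence
#' @param per_side Normalise the negative-position and positive-position
#'   halves separately (the natural reading for boundary-anchored flank
#'   distributions, where each side is its own region).
#' @return A tibble with columns `residue`, `position`, `value`, `kind`
#'   (`"q_rel"`); undefined residue types are listed in the
#'   `"undefined_classes"` attribute.
#' @export
relative_percentage <- function(set, classes = NULL, per_side = FALSE) {
  cls <- resolve_classes(classes)
  cc <- class_counts(set, cls)
  if (!per_side) {
    a_i <- rowSums(cc)
    q <- sweep(cc, 1, a_i, "/") * 100
    q[a_i == 0, ] <- NA_real_
    undefined <- names(cls)[a_i == 0]
  } else {
    neg <- set$positions < 0
    pos <- set$positions > 0
    q <- cc
    a_neg <- rowSums(cc[, neg, drop = FALSE])
    a_pos <- rowSums(cc[, pos, drop = FALSE])
    q[, neg] <- sweep(cc[, neg, drop = FALSE], 1, a_neg, "/") * 100
    q[, pos] <- sweep(cc[, pos, drop = FALSE], 1, a_pos, "/") * 100
    if (any(set$positions == 0)) q[, set$positions == 0] <- NA_real_
    q[a_neg == 0, neg] <- NA_real_
    q[a_pos == 0, pos] <- NA_real_
    undefined <- names(cls)[a_neg == 0 & a_pos == 0]
  }
  out <- tibble(
    kind = "q_rel",
    residue = rep(names(cls), each = length(set$positions)),
    position = rep(set$positions, times = length(cls)),
    value = as.vector(t(q))
  )
  attr(out, "undefined_classes") <- undefined
  out
}

#' Background level of a positional profile
#'
#' The unweighted mean of the profile over positions -30..-25 and 25..30
#' (inclusive; 12 positions), the windows far enough from the membrane to
#' approximate the unconstrained level of each residue type.
#'
#' @param profile A long profile tibble (`residue`, `position`, `value`).
#' @param windows A list of two inclusive position windows.
#' @return A tibble with `residue` and `background`.
#' @export
background_level <- function(profile,
                             windows = list(c(-30, -25), c(25, 30))) {
  want <- sort(unique(unlist(lapply(windows, function(w) w[1]:w[2]))))
  have <- unique(profile$position)
  if (!all(want %in% have)) {
    stop("profile does not span the background windows (need positions ",
         min(want), "..", max(want), ")", call. = FALSE)
  }
  profile %>%
    filter(.data$position %in% want) %>%
    group_by(.data$residue) %>%
    summarise(background = mean(.data$value), .groups = "drop")
}

#' Flank averages of a positional profile
#'
#' Unweighted means over the inner flank window (positions -20..-10) and
#' the outer flank window (+10..+20), both inclusive (11 positions each).
#'
#' @inheritParams background_level
#' @param inside_window,outside_window Inclusive position windows.
#' @return A tibble with `residue`, `inside_avg`, `outside_avg`.
#' @export
flank_average <- function(profile, inside_window = c(-20, -10),
                          outside_window = c(10, 20)) {
  win_in <- inside_window[1]:inside_window[2]
  win_out <- outside_window[1]:outside_window[2]
  have <- unique(profile$position)
  if (!all(c(win_in, win_out) %in% have)) {
    stop("profile does not span the flank windows", call. = FALSE)
  }
  profile %>%
    group_by(.data$residue) %>%
    summarise(
      inside_avg = mean(.data$value[.data$position %in% win_in]),
      outside_avg = mean(.data$value[.data$position %in% win_out]),
      .groups = "drop"
    )
}

#' Per-position mean net charge
#'
#' c_r = ((a_{K,r} + a_{R,r}) - (a_{D,r} + a_{E,r})) / N with N the number
#' of segments: +1 per lysine/arginine, -1 per aspartate/glutamate,
#' histidine and every other residue contributing zero. Values lie in
#' `[-1, 1]`.
#'
#' @param set An [aligned_set()].
#' @return A tibble with `kind = "net_charge"`, `position`, `value`.
#' @export
net_charge_profile <- function(set) {
  stopifnot(set$n_segments > 0)
  pos_counts <- colSums(set$counts[c("K", "R"), , drop = FALSE])
  neg_counts <- colSums(set$counts[c("D", "E"), , drop = FALSE])
  tibble(
    kind = "net_charge",
    position = set$positions,
    value = unname(pos_counts - neg_counts) / set$n_segments
  )
}

#' Residue-type composition of a segment set
#'
#' Overall abundance of each amino-acid type across the helices and their
#' flanks (the bar-chart view of which residues a membrane neighbourhood
#' tolerates). Nonstandard letters enter the total but no type's count.
#'
#' @param segments A segment tibble from [extract_segments()], or a
#'   character vector of residue strings.
#' @return A tibble with `residue`, `count`, `total` and `percent`
#'   (= 100 * count / total), sorted by descending count.
#' @export
residue_composition <- function(segments) {
  strings <- if (is.character(segments)) {
    segments
  } else {
    paste0(segments$inside_flank, segments$core, segments$outside_flank)
  }
  ch <- unlist(strsplit(strings, "", fixed = TRUE))
  total <- length(ch)
  tb <- table(factor(ch[is_standard_residue(ch)], levels = AA_ALPHABET))
  tibble(
    residue = names(tb),
    count = as.integer(tb),
    total = total,
    percent = 100 * as.integer(tb) / total
  ) %>%
    arrange(dplyr::desc(.data$count))
}
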