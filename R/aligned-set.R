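# Aligned segment sets: the per-position residue count matrix a_{i,r}
# over a set of oriented helices, the common substrate of all profiles.

#' Construct an aligned segment set from a count matrix
#'
#' @param counts Numeric matrix of per-position residue counts with one row
#'   per amino-acid type (rownames from the 20-letter alphabet) and one
#'   column per position; column names are the integer positions on the
#'   inside(-) to outside(+) axis.
#' @param coverage Optional integer vector of per-position coverage (number
#'   of segments contributing a residue there); defaults to the column sums
#'   of `counts`. Must be at least the column sum at every position (the
#'   excess being nonstandard residues that count towards coverage only).
#' @param n_segments Total number of segments behind the counts.
#' @param anchor One of `"central"`, `"boundary"`.
#' @return An `aligned_set` object.
#' @export
aligned_set <- function(counts, coverage = NULL, n_segments,
                        anchor = c("central", "boundary")) {
  anchor <- match.arg(anchor)
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  if (!all(rownames(counts) %in% AA_ALPHABET)) {
    stop("count matrix rows must be standard amino-acid letters",
         call. = FALSE)
  }
  counts <- counts[, order(as.integer(colnames(counts))), drop = FALSE]
  full <- matrix(0, nrow = length(AA_ALPHABET), ncol = ncol(counts),
                 dimnames = list(AA_ALPHABET, colnames(counts)))
  full[rownames(counts), ] <- counts
  if (is.null(coverage)) coverage <- colSums(full)
  stopifnot(length(coverage) == ncol(full))
  if (any(full < 0) || any(coverage < colSums(full) - 1e-9)) {
    stop("counts must be nonnegative and no larger than coverage",
         call. = FALSE)
  }
  if (n_segments < max(coverage)) {
    stop("coverage cannot exceed the number of segments", call. = FALSE)
  }
  structure(
    list(
      counts = full,
      positions = as.integer(colnames(full)),
      coverage = as.numeric(coverage),
      n_segments = as.integer(n_segments),
      anchor = anchor
    ),
    class = "aligned_set"
  )
}

#' @export
print.aligned_set <- function(x, ...) {
  cat(sprintf(
    "<aligned_set> %d segments, positions %d..%d, anchor '%s'\n",
    x$n_segments, min(x$positions), max(x$positions), x$anchor
  ))
  invisible(x)
}

#' @rdname aligned_set
#' @param x An `aligned_set`.
#' @param ... Unused.
#' @export
tidy.aligned_set <- function(x, ...) {
  as_tibble(as.table(x$counts), .name_repair = "minimal") %>%
    setNames(c("residue", "position", "count")) %>%
    mutate(position = as.integer(as.character(.data$position)))
}

#' Tally residue occurrences over aligned segments
#'
#' Builds the count matrix a_{i,r}: the occurrence of amino-acid type i at
#' aligned position r. With `anchor = "central"` the segments must carry
#' central-alignment windows and the axis is the distance from the helix
#' central residue. With `anchor = "boundary"` the flanks are aligned on
#' the membrane boundary: the inside flank occupies positions -1 (adjacent
#' to the helix) down to -max_flank, the outside flank +1..+max_flank, and
#' core residues are not assigned positions.
#'
#' Positions a segment does not reach (truncated flanks, clipped windows)
#' contribute nothing; nonstandard residue letters count towards coverage
#' but towards no amino-acid type.
#'
#' @param segments A segment tibble from [extract_segments()].
#' @param anchor `"central"` or `"boundary"`.
#' @return An [aligned_set()].
#' @export
count_occurrences <- function(segments, anchor = c("central", "boundary")) {
  anchor <- match.arg(anchor)
  if (nrow(segments) == 0) stop("empty segment list", call. = FALSE)
  if (anchor == "central") {
    stopifnot("aligned" %in% names(segments))
    width <- nchar(segments$aligned[1])
    hw <- (width - 1L) %/% 2L
    mat <- matrix(unlist(strsplit(segments$aligned, "", fixed = TRUE)),
                  ncol = width, byrow = TRUE)
    positions <- -hw:hw
    counts <- matrix(0, nrow = length(AA_ALPHABET), ncol = width,
                     dimnames = list(AA_ALPHABET, positions))
    coverage <- numeric(width)
    for (p in seq_len(width)) {
      col <- mat[, p]
      col <- col[col != "-"]
      coverage[p] <- length(col)
      tb <- table(factor(col[is_standard_residue(col)],
                         levels = AA_ALPHABET))
      counts[, p] <- as.numeric(tb)
    }
    return(aligned_set(counts, coverage, nrow(segments), "central"))
  }
  max_in <- max(nchar(segments$inside_flank))
  max_out <- max(nchar(segments$outside_flank))
  if (max_in == 0 && max_out == 0) stop("no flank residues", call. = FALSE)
  positions <- c(if (max_in > 0) seq(-max_in, -1L), if (max_out > 0) seq(1L, max_out))
  counts <- matrix(0, nrow = length(AA_ALPHABET), ncol = length(positions),
                   dimnames = list(AA_ALPHABET, positions))
  coverage <- setNames(numeric(length(positions)), positions)
  add <- function(res_chr, pos) {
    pos <- as.character(pos)
    for (k in seq_along(res_chr)) {
      p <- pos[k]
      coverage[p] <<- coverage[p] + 1
      if (is_standard_residue(res_chr[k])) {
        counts[res_chr[k], p] <<- counts[res_chr[k], p] + 1
      }
    }
  }
  for (i in seq_len(nrow(segments))) {
    fi <- segments$inside_flank[i]
    fo <- segments$outside_flank[i]
    if (nchar(fi) > 0) {
      # inside flank reads inside->outside: last character sits at -1
      add(seq_chars(fi), seq(-nchar(fi), -1L))
    }
    if (nchar(fo) > 0) {
      add(seq_chars(fo), seq(1L, nchar(fo)))
    }
  }
  aligned_set(counts, coverage, nrow(segments), "boundary")
}
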