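# Simple / twilight / complex helix classification.
#
# Anchor-only helices cluster as hydrophobic, low-entropy sequences;
# helices with roles beyond anchorage are more polar and more complex.
# The external classifier used in the literature does not publish its
# decision parameters, so this module ships a configurable linear boundary
# in the (mean hydrophobicity, sequence entropy) plane, clearly documented
# as an approximation, and accepts externally produced three-way calls via
# TSV instead (see [read_complexity_calls()]).

#' Shannon sequence entropy
#'
#' Entropy (log base 2) of the residue-type frequency distribution of each
#' string; nonstandard letters are ignored. A homopolymer has 0 bits, the
#' maximum over 20 types is log2(20) = 4.32 bits.
#'
#' @param x Character vector of residue strings.
#' @return Numeric vector of entropies in bits.
#' @export
sequence_entropy <- function(x) {
  vapply(x, function(s) {
    ch <- seq_chars(s)
    ch <- ch[is_standard_residue(ch)]
    if (length(ch) == 0) return(NA_real_)
    f <- table(ch) / length(ch)
    -sum(f * log2(f))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Decision boundary for helix complexity calls
#'
#' A linear rule in the (mean hydrophobicity, entropy) plane with a
#' twilight band: the decision score is
#' `mean_hydrophobicity - (intercept + slope * entropy)`; scores above
#' `+margin` are simple, below `-margin` complex, in between twilight.
#' The defaults place typical poly-leucine-like anchors (Kyte-Doolittle
#' mean around 3, entropy below 2 bits) deep on the simple side and polar
#' high-entropy cores on the complex side; they approximate, not
#' reproduce, the published classifier.
#'
#' @param intercept,slope,margin Boundary parameters (Kyte-Doolittle scale
#'   units; `slope` is units per bit).
#' @return A `complexity_boundary` list.
#' @export
complexity_boundary <- function(intercept = 2.0, slope = -0.25,
                                margin = 0.5) {
  stopifnot(margin >= 0)
  structure(list(intercept = intercept, slope = slope, margin = margin),
            class = "complexity_boundary")
}

#' @rdname complexity_boundary
#' @param mean_hydrophobicity,entropy Feature values.
#' @param boundary A [complexity_boundary()].
#' @return `complexity_score()`: the signed distance-like decision score
#'   (positive towards simple).
#' @export
complexity_score <- function(mean_hydrophobicity, entropy,
                             boundary = complexity_boundary()) {
  mean_hydrophobicity - (boundary$intercept + boundary$slope * entropy)
}

#' Classify helix cores as simple, twilight or complex
#'
#' @param cores Character vector of core residue strings.
#' @param scale Hydrophobicity scale name or named vector (mean per-residue
#'   value, no windowing); must increase with hydrophobicity for the
#'   default boundary to make sense (Kyte-Doolittle, Eisenberg).
#' @param boundary A [complexity_boundary()].
#' @return A tibble with `core`, `mean_hydrophobicity`, `shannon_entropy`,
#'   `score` and `call` (`"simple"`, `"twilight"`, `"complex"`). Calls are
#'   deterministic given the boundary and invariant to core reversal.
#' @export
classify_complexity <- function(cores, scale = "kyte_doolittle",
                                boundary = complexity_boundary()) {
  if (is.character(scale)) scale <- hydro_scale(scale)
  mh <- vapply(cores, function(s) {
    v <- unname(scale[seq_chars(s)])
    mean(v, na.rm = TRUE)
  }, numeric(1), USE.NAMES = FALSE)
  ent <- sequence_entropy(cores)
  sc <- complexity_score(mh, ent, boundary)
  tibble(
    core = cores,
    mean_hydrophobicity = mh,
    shannon_entropy = ent,
    score = sc,
    call = dplyr::case_when(
      sc >= boundary$margin ~ "simple",
      sc <= -boundary$margin ~ "complex",
      TRUE ~ "twilight"
    )
  )
}

#' Import / export per-helix complexity calls
#'
#' TSV with columns `accession`, `tmh_index`, `call`; externally produced
#' calls imported this way take the place of [classify_complexity()] in
#' downstream stratification.
#'
#' @param path File path.
#' @return A tibble of calls.
#' @export
read_complexity_calls <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           accession = readr::col_character(),
                           tmh_index = readr::col_integer(),
                           call = readr::col_character()
                         ))
  bad <- setdiff(unique(out$call), c("simple", "twilight", "complex"))
  if (length(bad) > 0) {
    stop("unknown complexity call(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out
}

#' @rdname read_complexity_calls
#' @param calls A tibble with columns `accession`, `tmh_index`, `call`.
#' @export
write_complexity_calls <- function(calls, path) {
  readr::write_tsv(calls[, c("accession", "tmh_index", "call")], path)
  invisible(path)
}
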