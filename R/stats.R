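# Skew statistics: rank tests on inside/outside counts, leaflet asymmetry,
# distribution comparisons, and the Bahadur slope.

# Two-group Kruskal-Wallis with the standard tie correction. Below
# `exact_max` observations per group the p value comes from exhaustive
# permutation of group labels (the rank multiset is fixed, so H depends
# only on the group-1 rank sum).
kw_two_sample <- function(x, y, exact_max = 8) {
  n1 <- length(x)
  n2 <- length(y)
  N <- n1 + n2
  stopifnot(n1 >= 1, n2 >= 1)
  all_v <- c(x, y)
  r <- rank(all_v)
  ties <- table(all_v)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (C == 0) {
    return(list(H = 0, p = NA_real_, method = "degenerate"))
  }
  h_of_s1 <- function(s1) {
    s2 <- sum(r) - s1
    (12 / (N * (N + 1))) *
      ((s1 - n1 * (N + 1) / 2)^2 / n1 + (s2 - n2 * (N + 1) / 2)^2 / n2) / C
  }
  H <- h_of_s1(sum(r[seq_len(n1)]))
  if (n1 <= exact_max && n2 <= exact_max) {
    sel <- combn(N, n1)
    s1_all <- colSums(matrix(r[sel], nrow = n1))
    H_all <- vapply(s1_all, h_of_s1, numeric(1))
    p <- mean(H_all >= H - 1e-10)
    method <- "exact_permutation"
  } else {
    p <- pchisq(H, df = 1, lower.tail = FALSE)
    method <- "chi_square_approximation"
  }
  list(H = H, p = p, method = method)
}

new_skew_test <- function(test, statistic, signed_statistic, p_value, N,
                          group_sizes, direction, groups, extra = list(),
                          method = NA_character_) {
  b <- if (is.na(p_value)) NA_real_ else bahadur_slope(p_value, N)
  structure(
    c(list(
      test = test, statistic = statistic,
      signed_statistic = signed_statistic, p_value = p_value, N = N,
      bahadur_slope = b, group_sizes = group_sizes, direction = direction,
      groups = groups, method = method
    ), extra),
    class = "skew_test"
  )
}

#' @export
print.skew_test <- function(x, ...) {
  cat(sprintf("<skew_test: %s>\n", x$test))
  cat(sprintf("  groups: %s (n = %s)\n",
              paste(x$groups, collapse = " vs "),
              paste(x$group_sizes, collapse = ", ")))
  cat(sprintf("  statistic = %.4g (signed %.4g), p = %.4g\n",
              x$statistic, x$signed_statistic, x$p_value))
  cat(sprintf("  N = %d, Bahadur slope = %.4g, direction = %s\n",
              x$N, x$bahadur_slope, x$direction))
  invisible(x)
}

#' @rdname inside_outside_skew
#' @param x A `skew_test` object.
#' @param ... Unused.
#' @export
tidy.skew_test <- function(x, ...) {
  tibble(
    test = x$test,
    statistic = x$statistic,
    signed_statistic = x$signed_statistic,
    p_value = x$p_value,
    N = x$N,
    bahadur_slope = x$bahadur_slope,
    n_group1 = x$group_sizes[1],
    n_group2 = x$group_sizes[2],
    direction = x$direction
  )
}

#' @rdname inside_outside_skew
#' @export
glance.skew_test <- function(x, ...) tidy(x)

#' Inside-versus-outside residue count skew
#'
#' Tests whether residues of a class are distributed unevenly between the
#' cytoplasmic (inside) and non-cytoplasmic (outside) flanks: a two-group
#' rank (Kruskal-Wallis) test on the per-helix inside-count sample against
#' the per-helix outside-count sample. The reported statistic carries a
#' sign from the direction of the group means (positive = outside excess),
#' matching the interpretive use of signed H values; the underlying H is
#' always nonnegative.
#'
#' @param pairs A tibble with integer columns `inside` and `outside`, one
#'   row per helix (see [flank_residue_counts()] /
#'   [central_flank_counts()]).
#' @param exact_max Use the exhaustive permutation null when both groups
#'   have at most this many observations (default 8).
#' @return A `skew_test` object; identical inside and outside samples give
#'   `direction = "none"`, signed statistic 0 and an undefined p value.
#' @export
inside_outside_skew <- function(pairs, exact_max = 8) {
  stopifnot(all(c("inside", "outside") %in% names(pairs)))
  if (nrow(pairs) < 2) stop("need at least 2 helices", call. = FALSE)
  x <- pairs$inside
  y <- pairs$outside
  kw <- kw_two_sample(x, y, exact_max)
  d_mean <- mean(y) - mean(x)
  direction <- if (d_mean > 0) "outside_excess"
  else if (d_mean < 0) "inside_excess" else "none"
  new_skew_test(
    test = "kruskal_wallis",
    statistic = kw$H,
    signed_statistic = kw$H * sign(d_mean),
    p_value = kw$p, N = length(x) + length(y),
    group_sizes = c(length(x), length(y)),
    direction = direction, groups = c("inside", "outside"),
    extra = list(totals = c(inside = sum(x), outside = sum(y)),
                 means = c(inside = mean(x), outside = mean(y))),
    method = kw$method
  )
}

#' Leucine (or other residue) asymmetry between membrane leaflets
#'
#' Splits each helix core into inner and outer leaflet halves (see
#' [split_leaflets()]), counts the residue of interest in each half per
#' helix (or per protein), and tests the inner-count sample against the
#' outer-count sample with the two-group rank test. The headline number is
#' the inside/outside percentage 100 * total_inner / total_outer.
#'
#' @param cores Character vector of oriented core strings, or a tibble with
#'   columns `accession` and `core` (required for `unit = "per_protein"`).
#' @param residue Single-letter residue type (default `"L"`).
#' @param unit `"per_helix"` (default) or `"per_protein"` aggregation.
#' @param center Odd-core central residue handling (see [split_leaflets()]).
#' @param exact_max Passed to the rank test.
#' @return A `skew_test` with an extra `percentage` element (`NA` when the
#'   outer total is zero).
#' @export
leaflet_asymmetry <- function(cores, residue = "L",
                              unit = c("per_helix", "per_protein"),
                              center = "exclude", exact_max = 8) {
  unit <- match.arg(unit)
  if (is.data.frame(cores)) {
    acc <- cores$accession
    core_str <- cores$core
  } else {
    acc <- as.character(seq_along(cores))
    core_str <- cores
  }
  halves <- split_leaflets(core_str, center = center)
  counts <- tibble(
    accession = acc,
    inner = count_residues(halves$inner, residue),
    outer = count_residues(halves$outer, residue)
  )
  if (unit == "per_protein") {
    counts <- counts %>%
      group_by(.data$accession) %>%
      summarise(inner = sum(.data$inner), outer = sum(.data$outer),
                .groups = "drop")
  }
  kw <- kw_two_sample(counts$inner, counts$outer, exact_max)
  d_mean <- mean(counts$outer) - mean(counts$inner)
  total_inner <- sum(counts$inner)
  total_outer <- sum(counts$outer)
  direction <- if (d_mean > 0) "outside_excess"
  else if (d_mean < 0) "inside_excess" else "none"
  new_skew_test(
    test = "kruskal_wallis", statistic = kw$H,
    signed_statistic = kw$H * sign(d_mean), p_value = kw$p,
    N = 2L * nrow(counts), group_sizes = rep(nrow(counts), 2),
    direction = direction, groups = c("inner_leaflet", "outer_leaflet"),
    extra = list(
      percentage = if (total_outer > 0) 100 * total_inner / total_outer
      else NA_real_,
      totals = c(inner = total_inner, outer = total_outer)
    ),
    method = kw$method
  )
}

#' Acidic content of single-pass versus multi-pass helix cores
#'
#' Compares the per-helix count of a residue class inside the helix cores
#' (database-defined limits, flanks excluded) between the single-pass and
#' multi-pass groups with the two-group rank test, reporting the group
#' means per helix.
#'
#' @param sp_counts,mp_counts Integer vectors of per-helix residue counts
#'   for the single-pass and multi-pass groups.
#' @param exact_max Passed to the rank test.
#' @return A `skew_test` with extra `mu_sp` and `mu_mp` elements.
#' @export
acidic_content_test <- function(sp_counts, mp_counts, exact_max = 8) {
  if (length(sp_counts) == 0 || length(mp_counts) == 0) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  kw <- kw_two_sample(sp_counts, mp_counts, exact_max)
  d_mean <- mean(mp_counts) - mean(sp_counts)
  direction <- if (d_mean > 0) "multi_excess"
  else if (d_mean < 0) "single_excess" else "none"
  new_skew_test(
    test = "kruskal_wallis", statistic = kw$H,
    signed_statistic = kw$H * sign(d_mean), p_value = kw$p,
    N = length(sp_counts) + length(mp_counts),
    group_sizes = c(length(sp_counts), length(mp_counts)),
    direction = direction, groups = c("single_pass", "multi_pass"),
    extra = list(mu_sp = mean(sp_counts), mu_mp = mean(mp_counts)),
    method = kw$method
  )
}

# Pool adjacent position columns of a 2 x R count table until every
# expected count is >= 1. Greedy: the offending column is merged with its
# smaller neighbour. Errors when pooling cannot produce two valid columns.
pool_chisq_table <- function(tab) {
  groups <- as.list(seq_len(ncol(tab)))
  repeat {
    pooled <- vapply(groups, function(g) rowSums(tab[, g, drop = FALSE]),
                     numeric(2))
    if (is.null(dim(pooled))) pooled <- matrix(pooled, nrow = 2)
    expected <- outer(rowSums(pooled), colSums(pooled)) / sum(pooled)
    if (all(expected >= 1)) {
      return(list(table = pooled, groups = groups))
    }
    if (length(groups) <= 2) {
      stop("chi-square expected counts below 1 even after pooling; ",
           "use coarser position bins", call. = FALSE)
    }
    j <- which(apply(expected, 2, min) < 1)[1]
    nb <- if (j == 1) 2
    else if (j == length(groups)) j - 1
    else if (sum(pooled[, j - 1]) <= sum(pooled[, j + 1])) j - 1
    else j + 1
    lo <- min(j, nb)
    groups[[lo]] <- c(groups[[lo]], groups[[max(j, nb)]])
    groups[[max(j, nb)]] <- NULL
  }
}

#' Compare positional distributions of a residue class between two groups
#'
#' Each residue occurrence contributes one observation valued by its
#' aligned position, so the sample size N is the residue-type count - the
#' scale on which the Bahadur slope is computed. Kolmogorov-Smirnov probes
#' the maximal distribution-curve difference, the rank (Kruskal-Wallis)
#' test probes location skew, and the chi-square test probes the average
#' difference via a 2 x R homogeneity table of per-position counts with
#' adjacent low-count positions pooled until all expected counts reach 1.
#'
#' @param group_a,group_b Integer vectors of aligned positions, one entry
#'   per residue occurrence. With `observation_unit = "per_position"` the
#'   groups are instead reduced to one per-position count value per
#'   position before testing (the alternative reading of per-position
#'   abundance; not available for `chi_square`, which is already
#'   position-tabulated).
#' @param test `"kolmogorov_smirnov"`, `"kruskal_wallis"` or
#'   `"chi_square"`.
#' @param observation_unit `"per_occurrence"` (default) or
#'   `"per_position"`.
#' @param exact_max Passed to the rank test.
#' @return A `skew_test`; for the chi-square test the pooling map is
#'   attached as element `pooling`.
#' @export
position_distribution_test <- function(group_a, group_b,
                                       test = c("kolmogorov_smirnov",
                                                "kruskal_wallis",
                                                "chi_square"),
                                       observation_unit = c("per_occurrence",
                                                            "per_position"),
                                       exact_max = 8) {
  test <- match.arg(test)
  observation_unit <- match.arg(observation_unit)
  N <- length(group_a) + length(group_b)
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  a <- group_a
  b <- group_b
  if (observation_unit == "per_position" && test != "chi_square") {
    all_pos <- sort(unique(c(a, b)))
    a <- as.numeric(table(factor(group_a, levels = all_pos)))
    b <- as.numeric(table(factor(group_b, levels = all_pos)))
  }
  d_mean <- mean(b) - mean(a)
  direction_of <- function() {
    if (d_mean > 0) "outside_excess"
    else if (d_mean < 0) "inside_excess" else "none"
  }
  if (test == "kolmogorov_smirnov") {
    ks <- suppressWarnings(ks.test(a, b))
    return(new_skew_test(
      "kolmogorov_smirnov", unname(ks$statistic),
      unname(ks$statistic) * sign(d_mean), ks$p.value, N,
      c(length(a), length(b)), direction_of(), c("group_a", "group_b")
    ))
  }
  if (test == "kruskal_wallis") {
    kw <- kw_two_sample(a, b, exact_max)
    return(new_skew_test(
      "kruskal_wallis", kw$H, kw$H * sign(d_mean), kw$p, N,
      c(length(a), length(b)), direction_of(), c("group_a", "group_b"),
      method = kw$method
    ))
  }
  all_pos <- sort(unique(c(group_a, group_b)))
  tab <- rbind(
    as.numeric(table(factor(group_a, levels = all_pos))),
    as.numeric(table(factor(group_b, levels = all_pos)))
  )
  pooled <- pool_chisq_table(tab)
  O <- pooled$table
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  stat <- sum((O - E)^2 / E)
  df <- (nrow(O) - 1) * (ncol(O) - 1)
  p <- pchisq(stat, df = df, lower.tail = FALSE)
  new_skew_test(
    "chi_square", stat, stat * sign(d_mean), p, N,
    c(length(group_a), length(group_b)), direction_of(),
    c("group_a", "group_b"),
    extra = list(pooling = lapply(pooled$groups, function(g) all_pos[g]),
                 df = df)
  )
}

#' Bahadur slope
#'
#' B = |ln(p)| / N: a measure of distance between two distributions that,
#' unlike the p value itself, does not grow with the amount of data. At
#' fixed p it halves when N doubles; p = 1 gives 0.
#'
#' @param p_value P value(s) in (0, 1].
#' @param N Total number of observations used in the test.
#' @return Numeric vector of slopes.
#' @export
bahadur_slope <- function(p_value, N) {
  if (any(!is.na(p_value) & p_value <= 0)) {
    stop("p value of 0: the slope is unbounded, report a lower bound ",
         "from the smallest representable p instead", call. = FALSE)
  }
  if (any(!is.na(p_value) & p_value > 1)) {
    stop("p values must lie in (0, 1]", call. = FALSE)
  }
  stopifnot(all(N >= 1))
  abs(log(p_value)) / N
}

#' Per-position tests of windowed hydrophobicity between two groups
#'
#' At every central-alignment position the per-segment windowed values of
#' the two groups are compared; positions with fewer than two values in
#' either group are skipped. Both the rank test and the Welch two-sample
#' t test are available, mirroring the two analysis traditions for this
#' comparison.
#'
#' @param values A tibble with columns `position`, `group` (two levels)
#'   and `value` (e.g. from [hydrophobicity_values()] plus a grouping
#'   column).
#' @param test `"kruskal_wallis"` or `"t"` (Welch).
#' @return A tibble with `position`, `statistic`, `p_value`, `n_a`, `n_b`.
#' @export
positionwise_hydro_test <- function(values, test = c("kruskal_wallis", "t")) {
  test <- match.arg(test)
  groups <- unique(values$group)
  if (length(groups) != 2) stop("need exactly two groups", call. = FALSE)
  values %>%
    group_by(.data$position) %>%
    summarise(
      n_a = sum(.data$group == groups[1] & !is.na(.data$value)),
      n_b = sum(.data$group == groups[2] & !is.na(.data$value)),
      res = list({
        va <- .data$value[.data$group == groups[1]]
        vb <- .data$value[.data$group == groups[2]]
        va <- va[!is.na(va)]
        vb <- vb[!is.na(vb)]
        if (length(va) < 2 || length(vb) < 2) {
          c(NA_real_, NA_real_)
        } else if (test == "t") {
          tt <- t.test(va, vb)
          c(unname(tt$statistic), tt$p.value)
        } else {
          kw <- kw_two_sample(va, vb, exact_max = 0)
          c(kw$H, kw$p)
        }
      }),
      .groups = "drop"
    ) %>%
    mutate(
      statistic = vapply(.data$res, `[`, numeric(1), 1),
      p_value = vapply(.data$res, `[`, numeric(1), 2)
    ) %>%
    select("position", "statistic", "p_value", "n_a", "n_b") %>%
    filter(!is.na(.data$statistic))
}
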