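# Fixture builders and independent oracles shared across test files.

# One hand-built record: 60 residues, a single TMH at 20..41 with a
# cytoplasmic N-terminal domain.
fixture_single_pass <- function() {
  protein_records(
    accession = "FIX00001",
    sequence = paste0(
      "MKKLLDDAAE", "SSTTGGHHPP",  # 1..20  N-tail (cytoplasmic)
      "LLLLIIIVVV", "AALLLIIVVF",  # 21..40 (TMH is 20..41)
      "AQQNNDDEEK", "RRSSTTGGYW"   # 41..60 C-tail
    ),
    features = list(tibble::tibble(kind = "TRANSMEM",
                                   start = 20L, end = 41L)),
    domains = list(tibble::tibble(start = 1L, end = 19L,
                                  label = "Cytoplasmic"))
  )
}

# A multi-pass record with a configurable loop between two 21-residue
# TMHs (16..36 and beyond); topology alternates so both helices orient.
fixture_two_pass <- function(loop_len = 7L, label_first = "Cytoplasmic",
                             label_last = "Cytoplasmic") {
  t1 <- 21L
  tail1 <- 15L
  tail2 <- 15L
  s1 <- tail1 + 1L
  e1 <- s1 + t1 - 1L
  s2 <- e1 + loop_len + 1L
  e2 <- s2 + t1 - 1L
  total <- e2 + tail2
  set.seed(99)
  sq <- paste(sample(c("A", "L", "I", "V", "S", "T", "D", "E", "K", "R"),
                     total, replace = TRUE), collapse = "")
  mid_label <- if (grepl("cyto", label_first, ignore.case = TRUE)) {
    "Extracellular"
  } else "Cytoplasmic"
  doms <- tibble::tibble(
    start = c(1L, e1 + 1L, e2 + 1L),
    end = c(s1 - 1L, s2 - 1L, total),
    label = c(label_first, mid_label, label_last)
  )
  if (loop_len == 0L) doms <- doms[-2L, ]
  protein_records(
    accession = "FIX00002", sequence = sq,
    features = list(tibble::tibble(kind = c("TRANSMEM", "TRANSMEM"),
                                   start = c(s1, s2), end = c(e1, e2))),
    domains = list(doms)
  )
}

# Small random multi-pass cohort for property tests.
random_cohort <- function(n = 20, seed = 123, ...) {
  generate_cohort(cohort_config(
    n_proteins = n,
    tmh_count_distribution = c("1" = 0.4, "2" = 0.2, "3" = 0.2, "5" = 0.2),
    seed = seed, ...
  ))
}

# Source-coordinate spans of both flanks of every extracted helix:
# the bookkeeping oracle works in the original sequence frame.
flank_spans_source <- function(segments) {
  purrr::map_dfr(seq_len(nrow(segments)), function(i) {
    fin <- nchar(segments$inside_flank[i])
    fout <- nchar(segments$outside_flank[i])
    s <- segments$start[i]
    e <- segments$end[i]
    if (segments$orientation[i] == "keep") {
      left_len <- fin; right_len <- fout
    } else {
      left_len <- fout; right_len <- fin
    }
    out <- tibble::tibble(
      accession = segments$accession[i], tmh_index = segments$tmh_index[i],
      side = c("left", "right"),
      span_start = c(s - left_len, e + 1L),
      span_end = c(s - 1L, e + right_len)
    )
    out[out$span_end >= out$span_start, ]
  })
}

# Brute-force expected flank length on each side of each loop under the
# no-overlap rule, enumerated directly from the annotation.
oracle_no_overlap_extents <- function(record, max_flank) {
  ft <- dplyr::arrange(record$features[[1]], start)
  seqlen <- nchar(record$sequence[[1]])
  n <- nrow(ft)
  res <- list()
  for (j in seq_len(n)) {
    prev_end <- if (j > 1) ft$end[j - 1] else 0L
    next_start <- if (j < n) ft$start[j + 1] else seqlen + 1L
    l_loop <- ft$start[j] - prev_end - 1L
    r_loop <- next_start - ft$end[j] - 1L
    left <- min(max_flank, if (j > 1) l_loop %/% 2L else l_loop)
    right <- min(max_flank, if (j < n) r_loop %/% 2L else r_loop)
    res[[j]] <- c(left = left, right = right)
  }
  res
}

# Exhaustive-permutation Kruskal-Wallis p value via stats::kruskal.test on
# every reassignment of the pooled observations (independent of the
# package's own rank-sum shortcut).
oracle_permutation_kw_p <- function(x, y) {
  vals <- c(x, y)
  n1 <- length(x)
  obs <- suppressWarnings(kruskal.test(list(x, y))$statistic)
  sel <- utils::combn(length(vals), n1)
  hs <- apply(sel, 2, function(ix) {
    suppressWarnings(kruskal.test(list(vals[ix], vals[-ix]))$statistic)
  })
  mean(hs >= obs - 1e-10)
}
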