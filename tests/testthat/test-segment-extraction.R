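test_that("orientation follows the cytoplasmic keyword rule", {
  rec <- fixture_single_pass()
  expect_equal(orient_tmh(rec, 1), "keep")

  # cytoplasmic domain after the helix -> reversed
  rec_after <- protein_records(
    "REV1", rec$sequence,
    features = rec$features,
    domains = list(tibble::tibble(start = 42L, end = 60L,
                                  label = "Cytoplasmic"))
  )
  expect_equal(orient_tmh(rec_after, 1), "reverse")

  # no cytoplasmic keyword anywhere -> omitted
  rec_none <- protein_records(
    "OMIT1", rec$sequence, features = rec$features,
    domains = list(tibble::tibble(start = 1L, end = 19L,
                                  label = "Lumenal"))
  )
  expect_equal(orient_tmh(rec_none, 1), "omit")

  # keyword on both sides -> inconsistency
  rec_both <- protein_records(
    "CONF1", rec$sequence, features = rec$features,
    domains = list(tibble::tibble(start = c(1L, 42L), end = c(19L, 60L),
                                  label = c("Cytoplasmic", "Cytoplasmic")))
  )
  expect_equal(orient_tmh(rec_both, 1), "conflict")

  # matching is case-insensitive on the keyword
  rec_case <- protein_records(
    "CASE1", rec$sequence, features = rec$features,
    domains = list(tibble::tibble(start = 1L, end = 19L,
                                  label = "CYTOPLASMIC side"))
  )
  expect_equal(orient_tmh(rec_case, 1), "keep")
})

test_that("orientation flips under sequence reversal (involution)", {
  mirror_record <- function(rec) {
    len <- nchar(rec$sequence[[1]])
    ft <- rec$features[[1]]
    dm <- rec$domains[[1]]
    protein_records(
      rec$accession, paste(rev(strsplit(rec$sequence[[1]], "")[[1]]),
                           collapse = ""),
      features = list(dplyr::arrange(tibble::tibble(
        kind = ft$kind, start = len - ft$end + 1L, end = len - ft$start + 1L
      ), start)),
      domains = list(dplyr::arrange(tibble::tibble(
        start = len - dm$end + 1L, end = len - dm$start + 1L,
        label = dm$label
      ), start))
    )
  }
  flip <- c(keep = "reverse", reverse = "keep", omit = "omit",
            conflict = "conflict")
  cohort <- random_cohort(15, seed = 5, orientation_noise = 0.3)
  for (i in seq_len(nrow(cohort))) {
    rec <- cohort[i, ]
    k <- sum(rec$features[[1]]$kind == "TRANSMEM")
    mir <- mirror_record(rec)
    for (j in seq_len(k)) {
      expect_equal(orient_tmh(mir, k - j + 1L),
                   unname(flip[orient_tmh(rec, j)]))
    }
  }
})

test_that("length filter bounds are inclusive", {
  expect_false(filter_tmh_length(15))
  expect_true(filter_tmh_length(16))
  expect_true(filter_tmh_length(38))
  expect_false(filter_tmh_length(39))
  expect_equal(filter_tmh_length(19:23, min_len = 21, max_len = 21),
               c(FALSE, FALSE, TRUE, FALSE, FALSE))
})

test_that("an odd loop splits evenly with the middle residue unassigned", {
  rec <- fixture_two_pass(loop_len = 7L)
  seg <- extract_segments(rec, flank_config("db_no_overlap", max_flank = 10))
  expect_equal(nrow(seg), 2L)
  # 7-residue loop: 3 to each adjoining flank, 1 unassigned; the loop is
  # the outside flank of both helices (TMH2 is reversed)
  expect_equal(seg$orientation, c("keep", "reverse"))
  expect_equal(nchar(seg$outside_flank[seg$tmh_index == 1]), 3L)
  expect_equal(nchar(seg$outside_flank[seg$tmh_index == 2]), 3L)
  spans <- flank_spans_source(seg)
  loop_spans <- spans[spans$span_start >= 37 & spans$span_end <= 43, ]
  claimed <- unlist(purrr::map2(loop_spans$span_start, loop_spans$span_end,
                                seq))
  expect_equal(length(claimed), 6L)
  expect_equal(anyDuplicated(claimed), 0L)

  # a zero-length loop leaves both adjoining flanks empty
  rec0 <- fixture_two_pass(loop_len = 0L, label_first = "Extracellular",
                           label_last = "Cytoplasmic")
  seg0 <- extract_segments(rec0, flank_config("db_no_overlap", max_flank = 10))
  expect_equal(seg0$orientation, c("reverse", "reverse"))
  expect_equal(nchar(seg0$inside_flank[seg0$tmh_index == 1]), 0L)
  expect_equal(nchar(seg0$outside_flank[seg0$tmh_index == 2]), 0L)
  expect_equal(seg0$inside_truncation[seg0$tmh_index == 1], "empty")
})

test_that("flank bookkeeping matches the brute-force oracle on random cohorts", {
  cohort <- random_cohort(25, seed = 31,
                          loop_length_distribution =
                            stats::setNames(rep(1, 26), 0:25))
  cfg <- flank_config("db_no_overlap", max_flank = 10)
  seg <- extract_segments(cohort, cfg)
  for (i in seq_len(nrow(cohort))) {
    rec <- cohort[i, ]
    expected <- oracle_no_overlap_extents(rec, cfg$max_flank)
    sub <- seg[seg$accession == rec$accession[[1]], ]
    for (r in seq_len(nrow(sub))) {
      j <- sub$tmh_index[r]
      if (sub$orientation[r] == "keep") {
        expect_equal(nchar(sub$inside_flank[r]), unname(expected[[j]]["left"]))
        expect_equal(nchar(sub$outside_flank[r]), unname(expected[[j]]["right"]))
      } else {
        expect_equal(nchar(sub$inside_flank[r]), unname(expected[[j]]["right"]))
        expect_equal(nchar(sub$outside_flank[r]), unname(expected[[j]]["left"]))
      }
    }
  }
  # no flank residue overlaps any membrane core, and none is claimed twice
  spans <- flank_spans_source(seg)
  spans <- spans[spans$span_end >= spans$span_start, ]
  for (acci in unique(spans$accession)) {
    rec <- cohort[cohort$accession == acci, ]
    ft <- rec$features[[1]]
    sp <- spans[spans$accession == acci, ]
    claimed <- unlist(purrr::map2(sp$span_start, sp$span_end, seq))
    expect_equal(anyDuplicated(claimed), 0L)
    in_core <- unlist(purrr::map2(ft$start, ft$end, seq))
    expect_length(intersect(claimed, in_core), 0L)
  }
})

test_that("overlapping flanks ignore neighbours but never enter a core", {
  rec <- fixture_two_pass(loop_len = 7L)
  seg <- extract_segments(rec, flank_config("db_overlap", max_flank = 10))
  # both loop-side flanks take the whole 7-residue loop
  expect_equal(nchar(seg$outside_flank[seg$tmh_index == 1]), 7L)
  expect_equal(nchar(seg$outside_flank[seg$tmh_index == 2]), 7L)
  spans <- flank_spans_source(seg)
  ft <- rec$features[[1]]
  claimed <- unlist(purrr::map2(spans$span_start, spans$span_end, seq))
  expect_length(intersect(claimed, unlist(purrr::map2(ft$start, ft$end, seq))),
                0L)
})

test_that("viable regime keeps exactly the helices with both flanks >= half max", {
  cohort <- random_cohort(30, seed = 47)
  base <- extract_segments(cohort, flank_config("db_no_overlap", max_flank = 10))
  viable <- extract_segments(cohort, flank_config("db_viable", max_flank = 10))
  key <- function(x) paste(x$accession, x$tmh_index)
  expect_true(all(key(viable) %in% key(base)))
  ok <- nchar(base$inside_flank) >= 5 & nchar(base$outside_flank) >= 5
  expect_setequal(key(viable), key(base)[ok])
  # the kept rows are bona fide no-overlap extractions
  merged <- merge(as.data.frame(viable), as.data.frame(base),
                  by = c("accession", "tmh_index"))
  expect_equal(merged$core.x, merged$core.y)
  expect_equal(merged$inside_flank.x, merged$inside_flank.y)
})

test_that("INTRAMEM neighbours truncate flanks like TRANSMEM ones", {
  # TMH at 21..41, INTRAMEM at 49..58: loop of 7 -> 3 residues to the TMH
  set.seed(7)
  sq <- paste(sample(c("A", "L", "S", "D", "K"), 80, TRUE), collapse = "")
  rec <- protein_records(
    "INTRA1", sq,
    features = list(tibble::tibble(kind = c("TRANSMEM", "INTRAMEM"),
                                   start = c(21L, 49L), end = c(41L, 58L))),
    domains = list(tibble::tibble(start = 1L, end = 20L,
                                  label = "Cytoplasmic"))
  )
  seg <- extract_segments(rec, flank_config("db_no_overlap", max_flank = 10))
  expect_equal(nrow(seg), 1L)  # the INTRAMEM itself is never a helix
  expect_equal(nchar(seg$outside_flank), 3L)
  expect_equal(seg$outside_truncation, "truncated(3)")
})

test_that("central alignment agrees with boundary flanks on isolated helices", {
  rec <- fixture_single_pass()  # core 20..41 is 22 long; build a 21-long one
  rec21 <- protein_records(
    "C21", rec$sequence[[1]],
    features = list(tibble::tibble(kind = "TRANSMEM", start = 20L, end = 40L)),
    domains = rec$domains
  )
  cfg <- flank_config("central", max_flank = 20, central_half_width = 20)
  seg <- extract_segments(rec21, cfg)
  db <- extract_segments(rec21, flank_config("db_no_overlap", max_flank = 20))
  aligned <- strsplit(seg$aligned, "")[[1]]
  # core length 21: central residue is the 11th core residue
  expect_equal(aligned[21], substr(db$core, 11, 11))
  # positions -10..+10 are exactly the standardized core
  expect_equal(paste(aligned[11:31], collapse = ""), db$core)
  # positions -20..-11 are the last 10 inside-flank residues
  fin <- nchar(db$inside_flank)
  expect_equal(paste(aligned[1:10], collapse = ""),
               substr(db$inside_flank, fin - 9, fin))
  # clipping at termini yields '-' fill, never an error
  wide <- flank_config("central", max_flank = 20, central_half_width = 40)
  segw <- extract_segments(rec21, wide)
  expect_equal(nchar(segw$aligned), 81L)
  expect_true(grepl("^-+", segw$aligned))
})

test_that("central window occupancy is complete for generous loops", {
  # 21-residue core mid-sequence, >= 20 residues on both sides, no neighbours
  sq <- strrep("A", 80)
  rec <- protein_records(
    "FULL1", sq,
    features = list(tibble::tibble(kind = "TRANSMEM", start = 30L, end = 50L)),
    domains = list(tibble::tibble(start = 1L, end = 29L,
                                  label = "Cytoplasmic"))
  )
  seg <- extract_segments(
    rec, flank_config("central", max_flank = 20, central_half_width = 20)
  )
  expect_false(grepl("-", seg$aligned, fixed = TRUE))
  expect_equal(nchar(seg$aligned), 41L)
})

test_that("leaflet split conserves residues and excludes odd centres", {
  expect_equal(
    as.list(split_leaflets("AAAAABBBBBCCCCCDDDDD")[1, ]),
    list(inner = "AAAAABBBBB", center = "", outer = "CCCCCDDDDD")
  )
  sp <- split_leaflets(strrep("L", 21))
  expect_equal(nchar(sp$inner), 10L)
  expect_equal(nchar(sp$outer), 10L)
  expect_equal(nchar(sp$center), 1L)
  sp_in <- split_leaflets(strrep("L", 21), center = "inner")
  expect_equal(nchar(sp_in$inner), 11L)

  # conservation oracle: inner + centre + outer leucines = total leucines
  set.seed(11)
  cores <- vapply(1:50, function(i) {
    paste(sample(c("L", "A", "V", "I"), sample(16:38, 1), TRUE),
          collapse = "")
  }, character(1))
  halves <- split_leaflets(cores)
  count_l <- function(x) lengths(regmatches(x, gregexpr("L", x)))
  expect_equal(count_l(halves$inner) + count_l(halves$center) +
                 count_l(halves$outer), count_l(cores))
})

test_that("the extraction ledger conserves helix counts", {
  cohort <- random_cohort(30, seed = 59, orientation_noise = 0.2)
  total_tmh <- sum(vapply(cohort$features,
                          function(ft) sum(ft$kind == "TRANSMEM"),
                          integer(1)))
  for (regime in c("db_no_overlap", "db_overlap", "db_viable", "central")) {
    seg <- extract_segments(cohort, flank_config(regime, max_flank = 10))
    led <- extraction_ledger(seg)
    expect_equal(nrow(led), total_tmh)
    expect_equal(sum(led$decision == "kept"), nrow(seg))
    expect_true(all(led$decision %in% c("kept", "skipped", "omitted")))
  }
})
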