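# A convenient hand-made aligned set: counts given explicitly.
toy_set <- function(counts, coverage = NULL, n_segments = NULL) {
  if (is.null(n_segments)) {
    n_segments <- max(colSums(counts), coverage, 1)
  }
  aligned_set(counts, coverage, n_segments, anchor = "central")
}

test_that("count matrices tally exactly what the segments contain", {
  seg <- tibble::tibble(
    accession = c("A", "B"), tmh_index = c(1L, 1L),
    pass_class = "single", regime = "central",
    aligned = c("KLD", "KLD")
  )
  set <- count_occurrences(seg, anchor = "central")
  expect_equal(set$positions, -1:1)
  expect_equal(unname(set$counts["K", "-1"]), 2)
  expect_equal(unname(set$counts["L", "0"]), 2)
  expect_equal(unname(set$counts["D", "1"]), 2)
  expect_equal(sum(set$counts), 6)
  expect_equal(set$coverage, c(2, 2, 2))

  # column sums equal coverage on a random cohort (brute-force recount)
  cen <- extract_segments(
    random_cohort(15, seed = 3),
    flank_config("central", max_flank = 10, central_half_width = 20)
  )
  set2 <- count_occurrences(cen, anchor = "central")
  chars <- strsplit(cen$aligned, "")
  recount <- vapply(seq_along(set2$positions), function(p) {
    col <- vapply(chars, `[`, character(1), p)
    sum(col != "-")
  }, numeric(1))
  expect_equal(unname(set2$coverage), recount)
  expect_true(all(colSums(set2$counts) <= set2$coverage))
  expect_error(count_occurrences(cen[0, ], "central"), "empty")
})

test_that("boundary anchoring puts flank residues at signed offsets", {
  seg <- tibble::tibble(
    accession = "A", tmh_index = 1L, pass_class = "single",
    regime = "db_no_overlap",
    core = "LLLLLLLLLLLLLLLLLLLL",
    inside_flank = "KRD", outside_flank = "EQ"
  )
  set <- count_occurrences(seg, anchor = "boundary")
  # inside flank reads inside->outside, so D is adjacent to the core at -1
  expect_equal(unname(set$counts["D", "-1"]), 1)
  expect_equal(unname(set$counts["R", "-2"]), 1)
  expect_equal(unname(set$counts["K", "-3"]), 1)
  expect_equal(unname(set$counts["E", "1"]), 1)
  expect_equal(unname(set$counts["Q", "2"]), 1)
  expect_equal(sum(set$counts), 5)
})

test_that("absolute relative occurrence reproduces the worked example", {
  pos <- -20:20
  counts <- matrix(0, 2, length(pos), dimnames = list(c("E", "L"), pos))
  counts["E", "12"] <- 91
  counts["E", "-12"] <- 22
  counts["E", "0"] <- 615 - 91 - 22
  counts["L", ] <- 1705 - counts["E", ]
  set <- toy_set(counts, n_segments = 1705)
  p <- absolute_relative_occurrence(set, "E")
  expect_equal(round(p$value[p$position == 12], 3), 0.053)
  expect_equal(round(p$value[p$position == -12], 3), 0.013)
  q <- relative_percentage(set, "E")
  expect_equal(round(q$value[q$position == 12] / 100, 3), 0.148)
  expect_equal(round(q$value[q$position == -12] / 100, 3), 0.036)

  # a single segment yields an indicator profile
  one <- matrix(0, 1, 3, dimnames = list("K", -1:1))
  one["K", "0"] <- 1
  p1 <- absolute_relative_occurrence(toy_set(one, coverage = c(1, 1, 1)))
  expect_equal(p1$value[p1$residue == "K"], c(0, 1, 0))
  expect_true(all(p1$value[p1$residue != "K"] == 0))
})

test_that("relative percentage curves sum to 100 and composites work", {
  cen <- extract_segments(
    random_cohort(20, seed = 9),
    flank_config("central", max_flank = 10, central_half_width = 20)
  )
  set <- count_occurrences(cen, "central")
  q <- relative_percentage(set, c("D", "E", "D+E", "K+R", "L"))
  sums <- tapply(q$value, q$residue, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  # composite class equals the sum of its parts, renormalised
  qd <- relative_percentage(set, "D")
  qe <- relative_percentage(set, "E")
  cd <- (qd$value * sum(set$counts["D", ]) +
           qe$value * sum(set$counts["E", ])) /
    sum(set$counts[c("D", "E"), ])
  expect_equal(q$value[q$residue == "D+E"], cd)
  # a type with zero abundance is flagged, not zero-filled
  no_w <- set
  no_w$counts["W", ] <- 0
  no_w <- aligned_set(no_w$counts, no_w$coverage, no_w$n_segments, "central")
  qw <- relative_percentage(no_w, "W")
  expect_true(all(is.na(qw$value)))
  expect_equal(attr(qw, "undefined_classes"), "W")
})

test_that("p_abs respects its bounds with equality at full coverage", {
  cen <- extract_segments(
    random_cohort(20, seed = 15),
    flank_config("central", max_flank = 10, central_half_width = 20)
  )
  set <- count_occurrences(cen, "central")
  p <- absolute_relative_occurrence(set)
  expect_true(all(p$value >= 0 & p$value <= 1))
  colsum <- tapply(p$value, p$position, sum)
  expect_true(all(colsum <= 1 + 1e-12))
  full <- set$coverage == max(set$coverage)
  expect_equal(as.numeric(colsum[as.character(set$positions[full])]),
               rep(1, sum(full)))
})

test_that("background and flank averages are plain inclusive means", {
  pos <- -35:35
  val <- sin(pos / 5) + 2
  prof <- tibble::tibble(residue = "D", position = pos, value = val)
  bg <- background_level(prof)
  expect_equal(bg$background,
               mean(val[pos %in% c(-30:-25, 25:30)]))
  fa <- flank_average(prof)
  expect_equal(fa$inside_avg, mean(val[pos %in% -20:-10]))
  expect_equal(fa$outside_avg, mean(val[pos %in% 10:20]))

  # constant profile: background equals the constant
  prof2 <- tibble::tibble(residue = "E", position = pos, value = 2.5)
  expect_equal(background_level(prof2)$background, 2.5)
  # profile supported on a single inside position
  prof3 <- tibble::tibble(residue = "K", position = pos,
                          value = ifelse(pos == -15, 11, 0))
  fa3 <- flank_average(prof3)
  expect_equal(fa3$inside_avg, 1)
  expect_equal(fa3$outside_avg, 0)
  # symmetric profile has equal flank averages
  prof4 <- tibble::tibble(residue = "R", position = pos, value = abs(pos))
  fa4 <- flank_average(prof4)
  expect_equal(fa4$inside_avg, fa4$outside_avg)
  # too-narrow profile errors
  expect_error(background_level(prof[abs(prof$position) <= 20, ]), "span")
})

test_that("net charge matches brute-force per-segment averaging", {
  seg <- tibble::tibble(
    accession = letters[1:4], tmh_index = 1L, pass_class = "single",
    regime = "central",
    aligned = c("KAD", "KAD", "RAE", "DAK")
  )
  set <- count_occurrences(seg, "central")
  nc <- net_charge_profile(set)
  expect_equal(nc$value, c((3 - 1) / 4, 0, (1 - 3) / 4))

  cen <- extract_segments(
    random_cohort(15, seed = 21),
    flank_config("central", max_flank = 10, central_half_width = 20)
  )
  set2 <- count_occurrences(cen, "central")
  nc2 <- net_charge_profile(set2)
  chars <- strsplit(cen$aligned, "")
  brute <- vapply(seq_along(set2$positions), function(p) {
    col <- vapply(chars, `[`, character(1), p)
    sum(col %in% c("K", "R")) - sum(col %in% c("D", "E"))
  }, numeric(1)) / nrow(cen)
  expect_equal(nc2$value, brute)
  expect_true(all(abs(nc2$value) <= 1))
  # sign flips under charge conjugation
  conj <- cen
  conj$aligned <- chartr("KRDE", "DEKR", conj$aligned)
  nc3 <- net_charge_profile(count_occurrences(conj, "central"))
  expect_equal(nc3$value, -nc2$value)
})

test_that("composition percentages follow directly from counts", {
  comp <- residue_composition(c(strrep("E", 3), strrep("L", 7)))
  expect_equal(comp$total[1], 10L)
  expect_equal(comp$percent[comp$residue == "E"], 30)
  expect_equal(comp$percent[comp$residue == "L"], 70)
  expect_equal(sum(comp$count), 10L)
})
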