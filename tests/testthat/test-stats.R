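test_that("identical flank samples give no skew and a defined zero", {
  pairs <- tibble::tibble(inside = c(1, 2, 0, 3), outside = c(1, 2, 0, 3))
  st <- inside_outside_skew(pairs)
  expect_equal(st$direction, "none")
  expect_equal(st$signed_statistic, 0)
  # all counts identical: degenerate, reported as no-skew with NA p
  same <- tibble::tibble(inside = rep(2, 5), outside = rep(2, 5))
  st2 <- inside_outside_skew(same)
  expect_true(is.na(st2$p_value))
  expect_equal(st2$direction, "none")
})

test_that("forced one-sided pairs yield the outside direction", {
  pairs <- tibble::tibble(inside = rep(0, 12), outside = rep(1, 12))
  st <- inside_outside_skew(pairs)
  expect_equal(st$direction, "outside_excess")
  expect_gt(st$signed_statistic, 0)
  expect_lt(st$p_value, 0.01)
  expect_equal(st$N, 24L)
})

test_that("small samples use the exhaustive permutation null", {
  set.seed(4)
  for (i in 1:5) {
    x <- rpois(sample(3:8, 1), 1)
    y <- rpois(sample(3:8, 1), 2)
    len <- min(length(x), length(y))
    x <- x[seq_len(len)]
    y <- y[seq_len(len)]
    st <- inside_outside_skew(tibble::tibble(inside = x, outside = y))
    expect_equal(st$method, "exact_permutation")
    expect_equal(st$p_value, oracle_permutation_kw_p(x, y))
  }
  # and the statistic always matches stats::kruskal.test
  x <- rpois(30, 1); y <- rpois(30, 1.5)
  st <- inside_outside_skew(tibble::tibble(inside = x, outside = y))
  kt <- suppressWarnings(kruskal.test(list(x, y)))
  expect_equal(st$statistic, unname(kt$statistic))
  expect_equal(st$p_value, kt$p.value)
})

test_that("two-group rank test agrees with Mann-Whitney on tie-free data", {
  set.seed(10)
  x <- rnorm(25)
  y <- rnorm(30, 0.5)
  st <- position_distribution_test(x, y, test = "kruskal_wallis")
  mw <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(st$p_value, mw$p.value, tolerance = 1e-10)
})

test_that("leaflet asymmetry reproduces printed-ratio arithmetic", {
  # counts spread over helices: ratio depends only on the totals
  inner_heavy <- c(rep(paste0(strrep("L", 5), strrep("A", 5)), 3),
                   rep(paste0(strrep("A", 5), strrep("L", 5)), 2))
  st <- leaflet_asymmetry(inner_heavy)
  expect_equal(st$percentage, 100 * 15 / 10)
  expect_equal(st$direction, "inside_excess")
  # symmetric cores: 100% and signed H = 0
  sym <- rep(paste0(strrep("L", 5), strrep("L", 5)), 4)
  st2 <- leaflet_asymmetry(sym)
  expect_equal(st2$percentage, 100)
  expect_equal(st2$signed_statistic, 0)
  # outer total of zero: percentage undefined
  st3 <- leaflet_asymmetry(rep(paste0(strrep("L", 5), strrep("A", 5)), 3))
  expect_true(is.na(st3$percentage))
})

test_that("per-protein aggregation changes the test unit, not the totals", {
  tbl <- tibble::tibble(
    accession = c("P1", "P1", "P2", "P2"),
    core = c(paste0(strrep("L", 5), strrep("A", 5)),
             paste0(strrep("L", 3), strrep("A", 3), strrep("L", 4)),
             strrep("A", 10),
             paste0(strrep("A", 5), strrep("L", 5)))
  )
  per_h <- leaflet_asymmetry(tbl, unit = "per_helix")
  per_p <- leaflet_asymmetry(tbl, unit = "per_protein")
  expect_equal(per_h$totals, per_p$totals)
  expect_equal(per_h$group_sizes[1], 4)
  expect_equal(per_p$group_sizes[1], 2)
})

test_that("acidic content comparison reports group means and direction", {
  st <- acidic_content_test(rep(0, 10), rep(1, 10))
  expect_equal(st$mu_sp, 0)
  expect_equal(st$mu_mp, 1)
  expect_equal(st$direction, "multi_excess")
  expect_lt(st$p_value, 0.01)
  # identical groups: p near 1
  st2 <- acidic_content_test(c(0, 1, 2, 0, 1, 2, 1, 0, 2),
                             c(0, 1, 2, 0, 1, 2, 1, 0, 2))
  expect_equal(st2$mu_sp, st2$mu_mp)
  expect_gt(st2$p_value, 0.9)
  expect_error(acidic_content_test(numeric(), 1:3), "nonempty")
})

test_that("distribution tests hit their closed-form corners", {
  a <- c(-15, -15, -15, -14, -15, -14, -15, -15, -14, -15)
  # identical groups: KS p = 1, Bahadur slope 0
  st <- position_distribution_test(a, a, test = "kolmogorov_smirnov")
  expect_equal(st$p_value, 1)
  expect_equal(st$bahadur_slope, 0)
  # disjoint supports: KS statistic 1
  b <- a + 30
  st2 <- position_distribution_test(a, b, test = "kolmogorov_smirnov")
  expect_equal(st2$statistic, 1)
})

test_that("chi-square equals the direct formula and pools sparse columns", {
  a <- c(rep(-2, 12), rep(0, 20), rep(2, 8))
  b <- c(rep(-2, 6), rep(0, 18), rep(2, 16))
  st <- position_distribution_test(a, b, test = "chi_square")
  O <- rbind(c(12, 20, 8), c(6, 18, 16))
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(st$statistic, sum((O - E)^2 / E))
  expect_equal(st$p_value,
               pchisq(sum((O - E)^2 / E), df = 2, lower.tail = FALSE))
  expect_equal(st$N, length(a) + length(b))

  # a sparse far position gets pooled into its neighbour
  a2 <- c(a, 30)
  b2 <- b
  st2 <- position_distribution_test(a2, b2, test = "chi_square")
  expect_true(any(vapply(st2$pooling, length, integer(1)) > 1))
  # pooling impossible on tiny disjoint tables -> informative error
  expect_error(
    position_distribution_test(c(1, 1), c(50), test = "chi_square"),
    "pooling"
  )
})

test_that("Bahadur slope follows its closed form and halves with N", {
  expect_equal(bahadur_slope(1, 100), 0)
  expect_equal(bahadur_slope(exp(-10), 100), 0.1)
  expect_equal(bahadur_slope(0.05, 1000), abs(log(0.05)) / 1000)
  p <- c(0.2, 0.01, 1e-8)
  expect_equal(bahadur_slope(p, 200), bahadur_slope(p, 100) / 2)
  expect_error(bahadur_slope(0, 10), "lower bound")
  expect_error(bahadur_slope(1.2, 10), "in \\(0, 1\\]")
})

test_that("per-position hydrophobicity tests match the Welch formula", {
  set.seed(20)
  vals <- tibble::tibble(
    position = rep(rep(-1:1, each = 8), 2),
    group = rep(c("single", "multi"), each = 24),
    value = c(rnorm(24, 0), rnorm(24, 1))
  )
  res <- positionwise_hydro_test(vals, test = "t")
  expect_equal(nrow(res), 3L)
  for (p in -1:1) {
    va <- vals$value[vals$group == "single" & vals$position == p]
    vb <- vals$value[vals$group == "multi" & vals$position == p]
    tt <- t.test(va, vb)
    expect_equal(res$p_value[res$position == p], tt$p.value)
    expect_equal(res$statistic[res$position == p], unname(tt$statistic))
  }
  # identical groups: p near 1 everywhere; shifted groups: p tiny
  same <- vals
  same$value <- rep(rnorm(24), 2)
  res_same <- positionwise_hydro_test(same, test = "t")
  expect_true(all(res_same$p_value > 0.999))
  shift <- vals
  shift$value <- ifelse(shift$group == "multi", shift$value + 100,
                        shift$value)
  res_shift <- positionwise_hydro_test(shift, test = "kruskal_wallis")
  expect_true(all(res_shift$p_value < 1e-3))
  # under-filled positions are skipped
  thin <- vals[-(which(vals$position == 0 & vals$group == "single")[1:7]), ]
  res_thin <- positionwise_hydro_test(thin, test = "t")
  expect_false(0 %in% res_thin$position)
})

test_that("tidy and glance return one-row summaries", {
  st <- inside_outside_skew(tibble::tibble(inside = rpois(20, 1),
                                           outside = rpois(20, 2)))
  td <- tidy(st)
  expect_equal(nrow(td), 1L)
  expect_true(all(c("statistic", "p_value", "N", "bahadur_slope",
                    "direction") %in% names(td)))
  expect_equal(glance(st), td)
  expect_equal(td$bahadur_slope, abs(log(td$p_value)) / td$N)
})
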