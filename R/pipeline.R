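# End-to-end orchestration: parse -> orient/filter -> extract (per regime)
# -> profiles -> statistics -> report bundle.

#' Analysis run configuration
#'
#' @param dataset Dataset label stamped on every output table.
#' @param regimes Named or unnamed list of [flank_config()]s to run; the
#'   default runs database-defined no-overlap flanks at depth 10 and a
#'   central alignment with database flank limit 20 and a window wide
#'   enough (+-30) for background estimation.
#' @param residue_classes Residue classes of interest (letters or
#'   composites like `"D+E"`).
#' @param scale Hydrophobicity scale name.
#' @param window Hydrophobicity window length.
#' @param hydro_test `"t"` (Welch) or `"kruskal_wallis"` for the
#'   per-position single- vs multi-pass hydrophobicity comparison.
#' @param out_dir Optional directory; when given, all tables are written
#'   there as TSV (one subdirectory per regime).
#' @param seed Seed recorded with the run (the analysis itself is
#'   deterministic; the seed feeds any future resampling extensions).
#' @param strict Strict residue-alphabet handling.
#' @return A `run_config` list.
#' @export
run_config <- function(dataset = "cohort",
                       regimes = list(
                         db_no_overlap = flank_config("db_no_overlap",
                                                      max_flank = 10),
                         central = flank_config("central", max_flank = 20,
                                                central_half_width = 30)
                       ),
                       residue_classes = c("D", "E", "D+E", "K", "R",
                                           "K+R", "L", "W", "Y", "C", "P"),
                       scale = "kyte_doolittle", window = 3,
                       hydro_test = "t",
                       out_dir = NULL, seed = 1, strict = FALSE) {
  stopifnot(length(regimes) >= 1, nzchar(dataset))
  if (is.null(names(regimes)) || any(!nzchar(names(regimes)))) {
    names(regimes) <- vapply(regimes, function(r) r$regime, character(1))
  }
  structure(
    list(
      dataset = dataset, regimes = regimes,
      residue_classes = residue_classes, scale = scale, window = window,
      hydro_test = hydro_test, out_dir = out_dir, seed = as.integer(seed),
      strict = strict
    ),
    class = "run_config"
  )
}

skew_row <- function(st, residue_class, pass_class, regime) {
  tidy(st) %>%
    mutate(
      residue_class = residue_class, pass_class = pass_class,
      regime = regime,
      inside_total = st$totals[["inside"]],
      outside_total = st$totals[["outside"]]
    )
}

#' Run the full positional-composition analysis
#'
#' Orchestrates extraction under every configured regime and emits the
#' report bundle: the per-helix extraction ledger, the single- vs
#' multi-pass acidic content comparison, inside/outside skew tables per
#' regime, leaflet asymmetry, relative-percentage and absolute-occurrence
#' profiles with background and flank averages, the net charge profile,
#' hydrophobicity curves stratified by helix count with a per-position
#' p curve, and (when complexity calls are supplied) complexity-stratified
#' profiles. Every table carries the dataset label, regime and config
#' hash; statistical comparisons that cannot run on the data at hand are
#' listed in `$skipped` with their reasons rather than failing the run.
#'
#' @param records A record tibble.
#' @param config A [run_config()].
#' @param complexity_calls Optional tibble of per-helix complexity calls
#'   (`accession`, `tmh_index`, `call`).
#' @return A `tmh_report` list of tibbles.
#' @export
run_analysis <- function(records, config = run_config(),
                         complexity_calls = NULL) {
  if (nrow(records) == 0) stop("no records to analyse", call. = FALSE)
  hash <- config_hash(config[setdiff(names(config), "out_dir")])
  stamp <- function(tbl, regime = NA_character_) {
    if (is.null(tbl) || nrow(tbl) == 0) return(tbl)
    mutate(tbl, dataset = config$dataset,
           regime = if ("regime" %in% names(tbl)) .data$regime else regime,
           config_hash = hash)
  }
  skipped <- list()
  skip <- function(what, reason) {
    skipped[[length(skipped) + 1L]] <<- tibble(analysis = what,
                                               reason = reason)
  }

  segments <- lapply(config$regimes, function(cfg) {
    extract_segments(records, cfg)
  })
  ledger <- bind_rows(lapply(segments, extraction_ledger))
  for (nm in names(segments)) {
    if (nrow(segments[[nm]]) == 0) {
      led <- extraction_ledger(segments[[nm]])
      dominant <- if (nrow(led) > 0) {
        names(sort(table(led$reason), decreasing = TRUE))[1]
      } else "no TRANSMEM features in the input"
      stop(sprintf(
        "regime '%s': every helix was removed (most common reason: %s)",
        nm, dominant
      ), call. = FALSE)
    }
  }

  is_central <- vapply(config$regimes, function(r) r$regime == "central",
                       logical(1))
  db_idx <- which(!is_central)[1]
  central_idx <- which(is_central)[1]
  db_first <- segments[[if (is.na(db_idx)) 1L else db_idx]]
  central <- if (is.na(central_idx)) NULL else segments[[central_idx]]

  # --- acidic content of helix cores, single- vs multi-pass -------------
  acidic <- NULL
  sp_cores <- db_first$core[db_first$pass_class == "single"]
  mp_cores <- db_first$core[db_first$pass_class == "multi"]
  if (length(sp_cores) >= 2 && length(mp_cores) >= 2) {
    acidic <- bind_rows(lapply(c("D+E", "D", "E"), function(cl) {
      res <- unlist(strsplit(cl, "+", fixed = TRUE))
      st <- acidic_content_test(count_residues(sp_cores, res),
                                count_residues(mp_cores, res))
      tidy(st) %>%
        mutate(residue_class = cl, mu_sp = st$mu_sp, mu_mp = st$mu_mp)
    }))
  } else {
    skip("acidic_content", "need >= 2 helices in both pass classes")
  }

  # --- inside/outside skew per regime and pass class --------------------
  skew <- list()
  for (nm in names(segments)) {
    seg <- segments[[nm]]
    cfg <- config$regimes[[nm]]
    for (pc in unique(seg$pass_class)) {
      sub <- seg[seg$pass_class == pc, ]
      if (nrow(sub) < 2) {
        skip(paste0("skew/", nm, "/", pc), "fewer than 2 helices")
        next
      }
      for (cl in config$residue_classes) {
        res <- unlist(strsplit(cl, "+", fixed = TRUE))
        pairs <- if (cfg$regime == "central") {
          central_flank_counts(
            sub, res,
            inside_window = c(-cfg$central_half_width,
                              -cfg$central_core_halfwidth),
            outside_window = c(cfg$central_core_halfwidth,
                               cfg$central_half_width)
          )
        } else {
          flank_residue_counts(sub, res)
        }
        skew[[length(skew) + 1L]] <-
          skew_row(inside_outside_skew(pairs), cl, pc, nm)
      }
    }
  }
  skew <- bind_rows(skew)

  # --- leaflet asymmetry -------------------------------------------------
  leaflet <- bind_rows(lapply(unique(db_first$pass_class), function(pc) {
    sub <- db_first[db_first$pass_class == pc, ]
    if (nrow(sub) < 2) return(NULL)
    st <- leaflet_asymmetry(sub$core, residue = "L")
    tidy(st) %>%
      mutate(pass_class = pc, residue_class = "L",
             inner_total = st$totals[["inner"]],
             outer_total = st$totals[["outer"]],
             percentage = st$percentage)
  }))

  # --- profiles on the central alignment --------------------------------
  profiles <- NULL
  flank_avgs <- NULL
  backgrounds <- NULL
  net_charge <- NULL
  hydro <- NULL
  hydro_p <- NULL
  complexity_profiles <- NULL
  if (!is.null(central)) {
    ccfg <- config$regimes[[central_idx]]
    prof_rows <- list()
    for (pc in unique(central$pass_class)) {
      sub <- central[central$pass_class == pc, ]
      set <- count_occurrences(sub, anchor = "central")
      q <- relative_percentage(set, config$residue_classes)
      p <- absolute_relative_occurrence(set, config$residue_classes)
      prof_rows[[length(prof_rows) + 1L]] <-
        bind_rows(q, p) %>% mutate(pass_class = pc, n_segments = nrow(sub))
      fa <- tryCatch(
        flank_average(q) %>% mutate(pass_class = pc),
        error = function(e) NULL
      )
      if (is.null(fa)) {
        skip(paste0("flank_average/", pc),
             "central window narrower than the +-20 flank windows")
      } else {
        flank_avgs <- bind_rows(flank_avgs, fa)
      }
      bg <- tryCatch(
        background_level(q) %>% mutate(pass_class = pc),
        error = function(e) NULL
      )
      if (is.null(bg)) {
        skip(paste0("background/", pc),
             "central window narrower than the +-25..30 background windows")
      } else {
        backgrounds <- bind_rows(backgrounds, bg)
      }
      net_charge <- bind_rows(
        net_charge,
        net_charge_profile(set) %>%
          mutate(pass_class = pc, n_segments = nrow(sub))
      )
    }
    profiles <- bind_rows(prof_rows)

    hydro <- hydrophobicity_profile(central, config$scale, config$window,
                                    stratify_by_count = TRUE)
    vals <- hydrophobicity_values(central, config$scale, config$window)
    if (all(c("single", "multi") %in% vals$pass_class)) {
      hydro_p <- positionwise_hydro_test(
        vals %>% rename(group = "pass_class"),
        test = if (config$hydro_test == "t") "t" else "kruskal_wallis"
      )
    } else {
      skip("hydrophobicity_test", "need both pass classes")
    }

    if (!is.null(complexity_calls)) {
      sp <- central[central$pass_class == "single", ] %>%
        left_join(complexity_calls, by = c("accession", "tmh_index"))
      complexity_profiles <- bind_rows(lapply(
        intersect(c("simple", "complex"), unique(sp$call)),
        function(cl) {
          sub <- sp[!is.na(sp$call) & sp$call == cl, ]
          if (nrow(sub) == 0) return(NULL)
          set <- count_occurrences(sub, anchor = "central")
          relative_percentage(set, config$residue_classes) %>%
            mutate(complexity = cl, n_segments = nrow(sub))
        }
      ))
    }
  } else {
    skip("profiles", "no central regime configured")
  }

  out <- list(
    ledger = stamp(ledger),
    acidic_content = stamp(acidic),
    skew = stamp(skew),
    leaflet = stamp(leaflet, regime = names(segments)[1]),
    profiles = stamp(profiles, regime = "central"),
    flank_averages = stamp(flank_avgs, regime = "central"),
    backgrounds = stamp(backgrounds, regime = "central"),
    net_charge = stamp(net_charge, regime = "central"),
    hydrophobicity = stamp(hydro, regime = "central"),
    hydrophobicity_tests = stamp(hydro_p, regime = "central"),
    complexity_profiles = stamp(complexity_profiles, regime = "central"),
    skipped = bind_rows(skipped),
    config = config,
    config_hash = hash
  )
  class(out) <- "tmh_report"
  if (!is.null(config$out_dir)) write_report(out, config$out_dir)
  out
}

#' @export
print.tmh_report <- function(x, ...) {
  cat(sprintf("<tmh_report> dataset '%s', config %s\n",
              x$config$dataset, substr(x$config_hash, 1, 8)))
  for (nm in setdiff(names(x), c("config", "config_hash"))) {
    tbl <- x[[nm]]
    if (is.data.frame(tbl)) {
      cat(sprintf("  $%s: %d rows\n", nm, nrow(tbl)))
    }
  }
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in setdiff(names(report), c("config", "config_hash"))) {
    tbl <- report[[nm]]
    if (is.data.frame(tbl) && nrow(tbl) > 0) {
      drop <- names(tbl)[vapply(tbl, is.list, logical(1))]
      readr::write_tsv(tbl[, setdiff(names(tbl), drop)],
                       file.path(out_dir, paste0(nm, ".tsv")))
    }
  }
  invisible(out_dir)
}

#' Compare residue position distributions across helix groups
#'
#' The group-comparison matrix: for each residue class and each of the
#' Kolmogorov-Smirnov, rank (Kruskal-Wallis) and chi-square tests, every
#' pairwise comparison between the groups is run on the positional
#' observations (one per residue occurrence) taken from a central
#' alignment with flanks limited to 10 residues, and reported with its
#' p value, sample size and Bahadur slope.
#'
#' @param records A record tibble.
#' @param grouping `"single_vs_multi"` or
#'   `"simple_vs_complex_vs_multi"` (the latter needs `complexity_calls`
#'   or uses [classify_complexity()] on the single-pass cores).
#' @param complexity_calls Optional per-helix calls tibble.
#' @param residue_classes Residue classes to compare.
#' @param cfg Central-alignment [flank_config()] (default: flank limit 10,
#'   window +-20).
#' @param min_group Minimum residue occurrences per group; smaller groups
#'   are skipped with a reason.
#' @return A tibble: `residue_class`, `test`, `comparison`, `statistic`,
#'   `p_value`, `N`, `bahadur_slope` (attribute `"skipped"` lists skipped
#'   comparisons).
#' @export
compare_groups <- function(records,
                           grouping = c("single_vs_multi",
                                        "simple_vs_complex_vs_multi"),
                           complexity_calls = NULL,
                           residue_classes = c("R", "K", "D", "E", "Y",
                                               "W", "L", "C", "K+R",
                                               "D+E"),
                           cfg = flank_config("central", max_flank = 10,
                                              central_half_width = 20),
                           min_group = 2) {
  grouping <- match.arg(grouping)
  segments <- extract_segments(records, cfg)
  if (nrow(segments) == 0) stop("no helices survive extraction", call. = FALSE)
  if (grouping == "single_vs_multi") {
    segments$group <- segments$pass_class
  } else {
    if (is.null(complexity_calls)) {
      sp <- segments$pass_class == "single"
      calls <- classify_complexity(segments$core[sp])$call
      segments$group <- segments$pass_class
      segments$group[sp] <- calls
    } else {
      segments <- left_join(segments, complexity_calls,
                            by = c("accession", "tmh_index"))
      segments$group <- ifelse(segments$pass_class == "multi", "multi",
                               segments$call)
    }
    segments <- segments[!is.na(segments$group) &
                           segments$group != "twilight", ]
  }
  hw <- cfg$central_half_width
  obs_positions <- function(sub, residues) {
    ch <- matrix(unlist(strsplit(sub$aligned, "", fixed = TRUE)),
                 ncol = 2L * hw + 1L, byrow = TRUE)
    hits <- which(matrix(ch %in% residues, nrow = nrow(ch)), arr.ind = TRUE)
    hits[, "col"] - hw - 1L
  }
  groups <- sort(unique(segments$group))
  pairs <- combn(groups, 2, simplify = FALSE)
  skipped <- list()
  rows <- list()
  for (cl in residue_classes) {
    res <- unlist(strsplit(cl, "+", fixed = TRUE))
    obs <- lapply(groups, function(g) {
      obs_positions(segments[segments$group == g, ], res)
    })
    names(obs) <- groups
    for (pr in pairs) {
      cmp <- paste(pr, collapse = "_vs_")
      if (length(obs[[pr[1]]]) < min_group ||
          length(obs[[pr[2]]]) < min_group) {
        skipped[[length(skipped) + 1L]] <- tibble(
          residue_class = cl, comparison = cmp,
          reason = "group below minimum size"
        )
        next
      }
      for (ts in c("kolmogorov_smirnov", "kruskal_wallis", "chi_square")) {
        st <- tryCatch(
          position_distribution_test(obs[[pr[1]]], obs[[pr[2]]], test = ts),
          error = function(e) e
        )
        if (inherits(st, "error")) {
          skipped[[length(skipped) + 1L]] <- tibble(
            residue_class = cl, comparison = cmp,
            reason = conditionMessage(st)
          )
          next
        }
        rows[[length(rows) + 1L]] <- tibble(
          residue_class = cl, test = ts, comparison = cmp,
          statistic = st$statistic, p_value = st$p_value, N = st$N,
          bahadur_slope = st$bahadur_slope
        )
      }
    }
  }
  out <- bind_rows(rows)
  attr(out, "skipped") <- bind_rows(skipped)
  out
}
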