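sim_screen_cohort <- function(seed, n_mirnas = 50, beta = log(2.5)) {
  cfg <- synthetic_config(
    seed = seed, n_mirnas = n_mirnas,
    main_effects = stats::setNames(beta, "miR-sim-001"),
    interaction_effects = stats::setNames(numeric(0), character(0)))
  suppressMessages(simulate_cohort(cfg))
}

test_that("the oncomiR screen finds a strongly planted miRNA and filters low expression", {
  co <- sim_screen_cohort(seed = 1)
  hits <- vapply(1:20, function(s) {
    co <- sim_screen_cohort(seed = s)
    sc <- screen_oncomirs(co$expr, co$clinical)
    "miR-sim-001" %in% sc$mirna_id[sc$passes]
  }, TRUE)
  expect_gte(mean(hits), 0.95)

  # a low-RPM miRNA is rejected before any survival computation
  expr <- co$expr
  expr["miR-sim-002", ] <- expr["miR-sim-001", ] / max(expr["miR-sim-001", ]) * 0.4
  sc <- screen_oncomirs(expr, co$clinical)
  r <- sc[sc$mirna_id == "miR-sim-002", ]
  expect_false(r$passes)
  expect_equal(r$reason, "low expression")
  expect_true(is.na(r$hr))

  # passing rows come first, sorted by p
  pp <- sc$logrank_p[sc$passes]
  expect_equal(pp, sort(pp))
  expect_equal(which(sc$passes), seq_len(sum(sc$passes)))
})

test_that("published synergistic-pair summaries all pass the 1.5-fold rule", {
  tab <- published_pairs()
  ok <- synergy_passes(tab$pair_hr, tab$hr_a, tab$hr_b, tab$pair_p)
  expect_true(all(ok))
  # the pass margin is thin: the weakest ratio is just above 1.5
  ratios <- pmin(tab$pair_hr / tab$hr_a, tab$pair_hr / tab$hr_b)
  expect_gt(min(ratios), 1.5)
  expect_lt(min(ratios), 1.52)
  # a pair whose HR only equals the larger single HR fails
  expect_false(synergy_passes(1.84, 1.75, 1.84, 1e-5))
  # and the union of miRNAs over the passing pairs has size six
  expect_equal(length(unique(c(tab$mirna_a, tab$mirna_b))), 6L)
})

test_that("the synergy screen recovers a planted interacting pair", {
  cfg <- synthetic_config(
    seed = 31, n_mirnas = 10,
    main_effects = stats::setNames(rep(log(1.3), 2), c("miR-sim-001", "miR-sim-002")),
    interaction_effects = stats::setNames(log(2), "miR-sim-001+miR-sim-002"))
  co <- suppressMessages(simulate_cohort(cfg))
  sy <- synergy_screen(c("miR-sim-001", "miR-sim-002", "miR-sim-003"),
                       co$expr, co$clinical)
  expect_equal(nrow(sy), 3L)
  planted <- sy[sy$mirna_a == "miR-sim-001" & sy$mirna_b == "miR-sim-002", ]
  expect_true(planted$pair_hr > planted$hr_a & planted$pair_hr > planted$hr_b)
})

test_that("the additive search enumerates subsets and matches the single-miRNA screen at k = 1", {
  co <- sim_screen_cohort(seed = 8, n_mirnas = 6)
  ids <- rownames(co$expr)
  combos <- additive_search(ids, co$expr, co$clinical)
  expect_equal(nrow(combos), 2^6 - 1)
  expect_equal(sum(combos$k == 3), choose(6, 3))

  cfg3 <- screen_config(max_combo_size = 3)
  combos3 <- additive_search(ids, co$expr, co$clinical, cfg3)
  expect_equal(nrow(combos3), choose(6, 1) + choose(6, 2) + choose(6, 3))

  # k = 1 rows agree with screen_oncomirs (same stratification machinery)
  sc <- screen_oncomirs(co$expr, co$clinical)
  k1 <- combos[combos$k == 1, ]
  for (m in ids) {
    expect_equal(k1$hr[k1$combo_id == m], sc$hr[sc$mirna_id == m],
                 tolerance = 1e-12)
  }

  # group sizes shrink monotonically as combinations grow
  for (k in 2:6) {
    sub <- combos[combos$k == k, ]
    sup <- combos[combos$k == k - 1, ]
    for (i in seq_len(nrow(sub))) {
      members <- strsplit(sub$combo_id[i], "+", fixed = TRUE)[[1]]
      parents <- sup[vapply(strsplit(sup$combo_id, "+", fixed = TRUE),
                            function(p) all(p %in% members), TRUE), ]
      expect_true(all(sub$n_high[i] <= parents$n_high))
    }
  }

  expect_error(additive_search(paste0("m", 1:26), co$expr, co$clinical),
               "26 candidate miRNAs")
})

test_that("select_best applies thresholds and deterministic tie-breaking", {
  base <- data.frame(combo_id = c("a", "a+b", "a+c"), k = c(1, 2, 2),
                     beta = log(c(2, 3, 3)), hr = c(2, 3, 3),
                     log2_hr = log2(c(2, 3, 3)),
                     logrank_chi2 = c(5, 9, 9), logrank_p = c(0.01, 0.001, 0.001),
                     n_high = c(50, 20, 20), n_low = c(50, 20, 20),
                     degenerate = FALSE, stringsAsFactors = FALSE)
  expect_equal(select_best(base)$combo_id, "a+b")  # tie on HR/p: lexicographic at equal k

  base$k <- c(1, 3, 2)
  expect_equal(select_best(base)$combo_id, "a+c")  # smaller k wins the tie

  base$hr <- c(3.5, 3, 3)
  expect_equal(select_best(base)$combo_id, "a")    # plain maximum HR

  # undersized groups and non-significant combos are excluded
  cfg <- screen_config(min_group_size = 30)
  expect_equal(select_best(base, cfg)$combo_id, "a")
  base$n_high <- c(5, 20, 20)
  base$logrank_p <- c(0.01, 0.2, 0.2)
  out <- select_best(base, cfg)
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "report"), "no significant combination")

  # single qualifying combo is returned as-is
  solo <- data.frame(combo_id = "x+y", k = 2, beta = log(2.2), hr = 2.2,
                     log2_hr = log2(2.2), logrank_chi2 = 6,
                     logrank_p = 0.01, n_high = 40, n_low = 45,
                     degenerate = FALSE, stringsAsFactors = FALSE)
  expect_equal(select_best(solo)$combo_id, "x+y")
})

test_that("the screening cascade is deterministic given config and seed", {
  run1 <- suppressMessages(run_pipeline(simulate = synthetic_config(seed = 5)))
  run2 <- suppressMessages(run_pipeline(simulate = synthetic_config(seed = 5)))
  expect_identical(run1$oncomirs, run2$oncomirs)
  expect_identical(run1$synergy, run2$synergy)
  expect_identical(run1$combos, run2$combos)
  expect_identical(run1$best, run2$best)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  mircombo:::write_run(run1, d1)
  mircombo:::write_run(run2, d2)
  for (f in c("oncomirs.tsv", "synergy_pairs.tsv", "combinations.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})
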