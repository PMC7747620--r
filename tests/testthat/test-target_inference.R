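test_that("triple correlation matches closed forms and the Kendall enumeration oracle", {
  x <- 1:10
  expect_equal(unname(triple_correlation(x, -2 * x + 1)), c(-1, -1, -1))

  # tau-b by exhaustive pair enumeration: 4 concordant, 2 discordant of 6
  tc <- triple_correlation(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  x4 <- c(1, 2, 3, 4); y4 <- c(2, 1, 4, 3)
  expect_equal(stats::cor(x4, y4, method = "kendall"), 1 / 3)
  expect_equal(oracle_kendall(x4, y4), 1 / 3)

  # Kendall tau-b equals the enumeration oracle, including ties
  set.seed(17)
  for (i in 1:10) {
    n <- sample(5:12, 1)
    a <- sample(1:6, n, replace = TRUE)
    b <- sample(1:6, n, replace = TRUE)
    if (sd(a) == 0 || sd(b) == 0) next
    expect_equal(unname(triple_correlation(a, b)["kendall"]),
                 oracle_kendall(a, b), tolerance = 1e-12)
    # Spearman equals Pearson on average ranks
    expect_equal(unname(triple_correlation(a, b)["spearman"]),
                 stats::cor(rank(a), rank(b)), tolerance = 1e-12)
  }

  # independent vectors: all three near zero
  set.seed(23)
  a <- rnorm(1000); b <- rnorm(1000)
  expect_true(all(abs(triple_correlation(a, b)) < 0.1))

  expect_error(triple_correlation(rep(1, 6), 1:6), "undefined correlation")
  expect_error(triple_correlation(1:4, 4:1), "n >= 5")
})

make_target_fixture <- function(seed = 1) {
  cfg <- synthetic_config(
    seed = seed, n_mirnas = 5, n_genes = 60, targets_per_mirna = 10,
    main_effects = stats::setNames(log(1.8), "miR-sim-001"),
    interaction_effects = stats::setNames(numeric(0), character(0)),
    missing_evidence_rate = 0, decoy_evidence_rate = 0)
  co <- suppressMessages(simulate_cohort(cfg))
  mrna <- simulate_targets(cfg, co$expr)
  ev <- make_evidence(cfg, co$truth)
  list(cfg = cfg, co = co, mrna = mrna, ev = ev)
}

test_that("planted anti-correlated targets pass and decoy-free passing sets are true targets", {
  hits <- vapply(1:15, function(s) {
    fx <- make_target_fixture(seed = s)
    tg <- infer_targets("miR-sim-001", fx$co$expr, fx$mrna, fx$co$clinical,
                        fx$ev, target_config())
    # with no decoys, every passing gene must be a true planted target
    expect_true(all(tg$gene_id[tg$passes] %in% fx$co$truth$true_targets))
    mean(tg$passes)
  }, 0)
  # planted targets: slope -0.8, noise 0.3, regulator HR ~1.8.  The gene
  # inherits a slightly attenuated hazard contrast, so the binding
  # criterion is its own log-rank significance (power ~0.7 at ~90 events);
  # assert 3 SEs below that
  expect_gt(mean(hits), 0.55)
})

test_that("the three target criteria produce the documented failure reasons", {
  fx <- make_target_fixture(seed = 4)
  # strong evidence but positive correlation: build an upregulated decoy
  mrna <- fx$mrna
  mrna["gene-sim-0060", ] <- fx$co$expr["miR-sim-001", ] * 2 + 1
  ev <- rbind(fx$ev, data.frame(mirna_id = "miR-sim-001",
                                gene_id = "gene-sim-0060",
                                validated = 1, tool_count = 12))
  tg <- infer_targets("miR-sim-001", fx$co$expr, mrna, fx$co$clinical, ev)
  r <- tg[tg$gene_id == "gene-sim-0060", ]
  expect_false(r$passes)
  expect_match(r$failure_reasons, "correlation")

  # tool_count = 4, not validated: "more than four" is strict, so it fails
  ev2 <- fx$ev
  ev2$validated <- 0
  ev2$tool_count <- 4
  tg2 <- infer_targets("miR-sim-001", fx$co$expr, fx$mrna, fx$co$clinical, ev2)
  expect_false(any(tg2$passes))
  expect_true(all(grepl("insufficient evidence", tg2$failure_reasons)))
  # while tool_count = 5 restores the evidence criterion
  ev2$tool_count <- 5
  tg3 <- infer_targets("miR-sim-001", fx$co$expr, fx$mrna, fx$co$clinical, ev2)
  expect_gt(sum(tg3$passes), 0)
})

test_that("the passes flag is reproducible from the stored audit fields", {
  fx <- make_target_fixture(seed = 6)
  cfg <- target_config()
  tg <- infer_targets("miR-sim-001", fx$co$expr, fx$mrna, fx$co$clinical,
                      fx$ev, cfg)
  recomputed <- pmin(tg$pearson, tg$spearman, tg$kendall) <
    cfg$correlation_threshold &
    tg$target_logrank_p < cfg$target_p_threshold &
    (tg$validated == 1 | tg$tool_count >= cfg$min_tools)
  expect_equal(tg$passes, recomputed)

  # relaxing the correlation threshold can only grow the passing set
  tg0 <- infer_targets("miR-sim-001", fx$co$expr, fx$mrna, fx$co$clinical,
                       fx$ev, target_config(correlation_threshold = -1e-6))
  expect_true(all(tg$gene_id[tg$passes] %in% tg0$gene_id[tg0$passes]))
})

test_that("network export counts edges and cross-miRNA overlaps", {
  aud <- data.frame(
    mirna_id = c("m1", "m1", "m2", "m2", "m3", "m3"),
    gene_id = c("g1", "g2", "g3", "g4", "g5", "g6"),
    pearson = -0.5, spearman = -0.6, kendall = -0.4,
    target_logrank_p = 0.01, validated = c(1, 0, 1, 0, 1, 0),
    tool_count = c(2, 7, 12, 6, 1, 9), passes = TRUE,
    failure_reasons = "", stringsAsFactors = FALSE)
  net <- export_network(aud)
  expect_equal(nrow(net$edges), 6L)
  expect_equal(net$overlap, 0L)
  expect_equal(unname(net$counts), c(2L, 2L, 2L))
  expect_equal(unique(net$edges$min_correlation), -0.6)

  # one shared gene between two miRNAs
  aud$gene_id[3] <- "g1"
  expect_equal(export_network(aud)$overlap, 1L)

  # empty passing set: empty edge list, not an error
  aud$passes <- FALSE
  net0 <- export_network(aud)
  expect_equal(nrow(net0$edges), 0L)
  expect_equal(net0$overlap, 0L)
})
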