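make_counts <- function(mat, mirna_ids = NULL, sample_ids = NULL) {
  mirna_ids <- mirna_ids %||% sprintf("mir%02d", seq_len(nrow(mat)))
  sample_ids <- sample_ids %||% sprintf("s%02d", seq_len(ncol(mat)))
  colnames(mat) <- sample_ids
  dplyr::bind_cols(tibble::tibble(mirna_id = mirna_ids), tibble::as_tibble(mat))
}

test_that("total-count normalization produces fractions and log2 CPM", {
  counts <- make_counts(matrix(c(10, 30, 60, 1, 1, 1), ncol = 2))
  norm <- normalize_counts(counts)

  s1 <- norm[norm$sample_id == "s01", ]
  expect_equal(s1$fraction, c(0.1, 0.3, 0.6))
  s2 <- norm[norm$sample_id == "s02", ]
  expect_equal(s2$fraction, rep(1 / 3, 3))

  # fractions sum to 1 per sample; log2 scale is monotone in fractions
  sums <- tapply(norm$fraction, norm$sample_id, sum)
  expect_equal(as.numeric(sums), c(1, 1), tolerance = 1e-9)
  expect_true(all(diff(order(s1$fraction)) == diff(order(s1$log2_expr))))
  expect_equal(s1$log2_expr, log2((c(10, 30, 60) + 1) / 100 * 1e6))

  # ratio preservation on random matrices
  withr::with_seed(21, {
    m <- matrix(rpois(60, 50) + 1, nrow = 10)
  })
  n2 <- normalize_counts(make_counts(m))
  frac <- tidyr::pivot_wider(n2[c("mirna_id", "sample_id", "fraction")],
    names_from = "sample_id", values_from = "fraction"
  )
  fm <- as.matrix(frac[-1])
  expect_equal(colSums(fm), rep(1, 6), ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(fm[1, ] / fm[2, ], m[1, ] / m[2, ], ignore_attr = TRUE)

  zero <- make_counts(matrix(c(1, 2, 0, 0), ncol = 2))
  expect_error(normalize_counts(zero), "zero total.*s02")
})

test_that("abundance percentages behave and sum to 100 within a sample", {
  counts <- make_counts(matrix(c(1000, 99000, 500, 99500), ncol = 2),
    mirna_ids = c("target", "rest")
  )
  norm <- normalize_counts(counts)
  expect_equal(abundance_percent(norm, "target", samples = "s01"), 1.0)
  expect_equal(abundance_percent(norm, "target"), mean(c(1, 0.5)))
  expect_error(abundance_percent(norm, "nope"), "unknown miRNA")

  per_mirna <- vapply(
    c("target", "rest"),
    function(m) abundance_percent(norm, m, samples = "s01"),
    numeric(1)
  )
  expect_equal(sum(per_mirna), 100)

  zero_row <- normalize_counts(make_counts(matrix(c(0, 5, 0, 7), ncol = 2),
    mirna_ids = c("silent", "rest")
  ))
  expect_equal(abundance_percent(zero_row, "silent"), 0)
})

test_that("score screen finds planted correlations and flags constant rows", {
  cfg <- sim_config(n_samples = 32, seed = 1)
  clin <- simulate_clinical(cfg)
  sim <- simulate_counts(clin, cfg)
  norm <- normalize_counts(sim$counts)
  scores <- setNames(clin$dx_score, clin$patient_id)

  scr <- screen_vs_score(norm, scores)
  expect_s3_class(scr, "mir_screen")

  # constant log2 expression (equal column totals) is flagged untestable
  flat <- make_counts(matrix(c(5, 5, 5, 5, 1, 2, 3, 4, 4, 3, 2, 1),
    nrow = 3, byrow = TRUE
  ))
  flat_scr <- screen_vs_score(
    normalize_counts(flat),
    setNames(c(10, 20, 30, 40), sprintf("s%02d", 1:4))
  )
  expect_false(flat_scr$testable[1])
  expect_true(all(flat_scr$testable[2:3]))

  rec <- evaluate_screen_recovery(scr, sim$truth, type = "score")
  expect_equal(rec$sensitivity, 1)
  expect_equal(rec$sign_accuracy, 1)

  # direction encodes the sign of the estimate
  ok <- scr$testable
  expect_equal(
    scr$direction[ok],
    ifelse(scr$estimate[ok] < 0, "down", "up")
  )
  # BH inside the screen matches bh_adjust exactly
  expect_equal(scr$adj_p, bh_adjust(scr$p_value))
})

test_that("screen estimates are invariant to library-depth rescaling", {
  cfg <- sim_config(n_samples = 20, n_mirnas = 60, seed = 4)
  clin <- simulate_clinical(cfg)
  sim <- simulate_counts(clin, cfg)
  scores <- setNames(clin$dx_score, clin$patient_id)

  base <- screen_vs_score(normalize_counts(sim$counts, pseudocount = 0), scores)
  rescaled <- sim$counts
  depth <- rep(c(3L, 7L), length.out = nrow(clin))
  rescaled[-1] <- sweep(as.matrix(rescaled[-1]), 2, depth, "*")
  got <- screen_vs_score(normalize_counts(rescaled, pseudocount = 0), scores)
  expect_equal(got$estimate, base$estimate, tolerance = 1e-9)
})

test_that("age screen is a spearman screen with the same machinery", {
  cfg <- sim_config(n_samples = 32, seed = 7)
  clin <- simulate_clinical(cfg)
  sim <- simulate_counts(clin, cfg)
  norm <- normalize_counts(sim$counts)
  ages <- setNames(clin$age, clin$patient_id)

  scr <- screen_vs_age(norm, ages)
  rec <- evaluate_screen_recovery(scr, sim$truth, type = "age")
  expect_gte(rec$sensitivity, 8 / 9)
  expect_equal(rec$sign_accuracy, 1)

  # planted decreasing miRNAs are reported down, increasing up
  truth <- sim$truth$mirnas
  down_ids <- truth$mirna_id[truth$is_age_assoc & truth$gamma < 0]
  hit <- scr[scr$mirna_id %in% down_ids & scr$adj_p < 0.05, ]
  expect_true(all(hit$estimate < 0))

  # constant covariate makes every row untestable
  flat <- screen_vs_age(norm, setNames(rep(60, nrow(clin)), clin$patient_id))
  expect_false(any(flat$testable))

  # per-miRNA agreement with the single-pair implementation
  mat <- as.matrix(sim$counts[-1])
  log2e <- log2(sweep(mat + 1, 2, colSums(mat), "/") * 1e6)
  for (i in c(16, 20, 150)) {
    expect_equal(
      scr$estimate[i],
      cor_test_spearman(log2e[i, ], ages[colnames(mat)])$estimate,
      tolerance = 1e-9
    )
    expect_equal(
      scr$p_value[i],
      cor_test_spearman(log2e[i, ], ages[colnames(mat)])$p_value,
      tolerance = 1e-9
    )
  }
})

test_that("batch-partial screen tracks the naive screen when batch is null", {
  cfg0 <- sim_config(n_samples = 40, n_mirnas = 80, batch_sd = 0, seed = 9)
  clin <- simulate_clinical(cfg0)
  sim <- simulate_counts(clin, cfg0)
  norm <- normalize_counts(sim$counts)
  scores <- setNames(clin$dx_score, clin$patient_id)
  batch <- setNames(sim$samples$batch, sim$samples$sample_id)

  naive <- screen_vs_score(norm, scores)
  adj <- screen_vs_score(norm, scores, adjust_batch = TRUE, batch = batch)
  ok <- naive$testable
  # with no batch effect, partialling out batch only perturbs the
  # estimates at the finite-sample level expected from spending
  # (batch levels - 1) degrees of freedom
  expect_gt(cor(adj$estimate[ok], naive$estimate[ok]), 0.97)
  expect_lt(mean(abs(adj$estimate[ok] - naive$estimate[ok])), 0.08)

  expect_error(
    screen_vs_score(norm, scores, adjust_batch = TRUE),
    "batch labels"
  )
})

test_that("batch-partial screen outperforms the naive screen under strong batch noise", {
  cfg <- sim_config(n_samples = 32, batch_sd = 2, seed = 19)
  clin <- simulate_clinical(cfg)
  sim <- simulate_counts(clin, cfg)
  norm <- normalize_counts(sim$counts)
  scores <- setNames(clin$dx_score, clin$patient_id)
  batch <- setNames(sim$samples$batch, sim$samples$sample_id)

  naive <- evaluate_screen_recovery(
    screen_vs_score(norm, scores),
    sim$truth,
    type = "score"
  )
  adj <- evaluate_screen_recovery(
    screen_vs_score(norm, scores, adjust_batch = TRUE, batch = batch),
    sim$truth,
    type = "score"
  )
  expect_gte(adj$sensitivity, naive$sensitivity)
  expect_gt(adj$sensitivity, 0.8)
})

test_that("ages bin into <=55 / 56-70 / >70", {
  expect_equal(bin_age(c(25, 55, 56, 70, 71, 90)), c(1L, 1L, 2L, 2L, 3L, 3L))
  expect_error(bin_age(0), "positive")
})

test_that("panel selection unions the top hits with provenance", {
  screen_stub <- function(ids, adj_p, estimate) {
    out <- tibble::tibble(
      mirna_id = ids, estimate = estimate, p_value = adj_p / 2,
      adj_p = adj_p, direction = ifelse(estimate < 0, "down", "up"),
      testable = TRUE, mean_abundance_pct = 1, n = 30
    )
    class(out) <- c("mir_screen", class(out))
    out
  }
  ids <- sprintf("m%02d", 1:20)
  adj_score <- c(rep(0.001, 3), rep(0.5, 17))
  adj_age <- c(rep(0.5, 17), rep(0.01, 3))
  s1 <- screen_stub(ids, adj_score, rep(c(-0.5, 0.5), 10))
  s2 <- screen_stub(ids, adj_age, rep(0.4, 20))

  panel <- select_panel(s1, s2, alpha = 0.05)
  expect_setequal(panel$mirna_id, c(ids[1:3], ids[18:20]))
  expect_equal(sort(unique(panel$provenance)), c("age", "score"))
  expect_equal(panel$direction[panel$mirna_id == "m01"], "down")

  # identical screens: everything is provenance "both"
  both <- select_panel(s1, s1, alpha = 0.05)
  expect_true(all(both$provenance == "both"))

  # nothing passing alpha: empty panel, not an error
  none <- select_panel(s1, s2, alpha = 1e-6)
  expect_equal(nrow(none), 0)

  expect_error(select_panel(s1, s2, alpha = 2), "alpha")
})

test_that("panel CSV fixtures load with valid directions", {
  p5 <- read_panel(dcismir_example("mirna_panel_qpcr5.csv"))
  expect_equal(nrow(p5), 5)
  expect_true(all(p5$direction == "down"))

  p17 <- read_panel(dcismir_example("mirna_panel_ngs17.csv"))
  expect_equal(nrow(p17), 17)
  expect_equal(sum(p17$direction == "up"), 10)
  expect_equal(sum(p17$direction == "down"), 7)
})
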