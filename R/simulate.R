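#' Simulation configuration for synthetic DCIS cohorts
#'
#' Bundles every parameter of the synthetic-cohort generators. The
#' defaults emulate the study design the package analyses: 41
#' patients weighted 26/10/5 across the low/intermediate/high Oncotype
#' DX DCIS groups with their score ranges, group age structure matching
#' the cohort's boundary-coded means, four barcoded sequencing
#' libraries of up to 18 samples each, negative-binomial counts
#' (variance mu + mu^2/theta, theta = 10), and 15 + 9 planted miRNAs
#' whose log2 expression varies linearly with the risk score
#' respectively monotonically with age at 0.8 log2 units per realized
#' SD of the covariate — effect sizes that land the planted Pearson
#' correlations in the 0.3-0.65 band the screens are meant to detect.
#'
#' @param n_samples Number of patients (default 41).
#' @param group_weights Probabilities over low/intermediate/high
#'   (default 26/41, 10/41, 5/41).
#' @param score_ranges Per-group integer score intervals (defaults:
#'   low 0-38, intermediate 39-54, high 55-80).
#' @param age_mean,age_sd Per-group age model in years; ages are
#'   rounded and clamped to 25-90.
#' @param n_mirnas Number of miRNAs (default 300).
#' @param n_score_assoc,n_age_assoc Planted score- and age-associated
#'   miRNAs (defaults 15 and 9, disjoint sets).
#' @param beta,gamma Absolute planted effect sizes, log2 units per
#'   realized SD of score respectively age (defaults 0.8).
#' @param frac_up_score,frac_up_age Fraction of planted miRNAs with a
#'   positive sign (defaults 10/17 and 2/9, the sign mix the screens
#'   are expected to report).
#' @param batch_count Number of sequencing libraries (default 4).
#' @param batch_max Maximum samples per library (default 18).
#' @param batch_sd SD of per-(library, miRNA) log2 batch effects
#'   (default 0.25).
#' @param dispersion Negative-binomial size parameter theta
#'   (default 10).
#' @param libsize_range Log-uniform bounds for per-sample library
#'   size (default 2e5-2e6 reads).
#' @param baseline_mean,baseline_sd Log2 relative-abundance baseline
#'   for background miRNAs.
#' @param planted_mean,planted_sd Log2 relative-abundance baseline
#'   for planted miRNAs; defaults center the planted fractions on the
#'   0.1-1 percent abundance band.
#' @param ct_intercept Ct model intercept in cycles:
#'   Ct = intercept - log2(relative expression) + noise (default 18).
#' @param ct_control Endogenous-control Ct level (default 20 cycles).
#' @param ct_sigma Replicate Ct noise SD in cycles (default 0.3).
#' @param seed Integer seed; all three generators derive their RNG
#'   state from it (clinical uses `seed`, counts `seed + 1`, Ct
#'   `seed + 2`), so a config is fully reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 41,
                       group_weights = c(low = 26, intermediate = 10, high = 5) / 41,
                       score_ranges = list(
                         low = c(0, 38),
                         intermediate = c(39, 54),
                         high = c(55, 80)
                       ),
                       age_mean = c(low = 64.8, intermediate = 63.7, high = 56.4),
                       age_sd = c(low = 12, intermediate = 13, high = 10),
                       n_mirnas = 300,
                       n_score_assoc = 15,
                       n_age_assoc = 9,
                       beta = 0.8,
                       gamma = 0.8,
                       frac_up_score = 10 / 17,
                       frac_up_age = 2 / 9,
                       batch_count = 4,
                       batch_max = 18,
                       batch_sd = 0.25,
                       dispersion = 10,
                       libsize_range = c(2e5, 2e6),
                       baseline_mean = -10,
                       baseline_sd = 1.5,
                       planted_mean = log2(0.003),
                       planted_sd = 0.8,
                       ct_intercept = 18,
                       ct_control = 20,
                       ct_sigma = 0.3,
                       seed = 1L) {
  cfg <- list(
    n_samples = n_samples, group_weights = group_weights,
    score_ranges = score_ranges, age_mean = age_mean, age_sd = age_sd,
    n_mirnas = n_mirnas, n_score_assoc = n_score_assoc,
    n_age_assoc = n_age_assoc, beta = beta, gamma = gamma,
    frac_up_score = frac_up_score, frac_up_age = frac_up_age,
    batch_count = batch_count, batch_max = batch_max, batch_sd = batch_sd,
    dispersion = dispersion, libsize_range = libsize_range,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    planted_mean = planted_mean, planted_sd = planted_sd,
    ct_intercept = ct_intercept, ct_control = ct_control,
    ct_sigma = ct_sigma, seed = as.integer(seed)
  )
  if (abs(sum(cfg$group_weights) - 1) > 1e-8) {
    abort("group_weights must sum to 1")
  }
  if (any(cfg$group_weights < 0)) abort("group_weights must be non-negative")
  if (cfg$n_score_assoc + cfg$n_age_assoc > cfg$n_mirnas) {
    abort("n_score_assoc + n_age_assoc must not exceed n_mirnas")
  }
  if (any(c(cfg$age_sd, cfg$batch_sd, cfg$ct_sigma) < 0)) {
    abort("all SDs must be non-negative")
  }
  if (cfg$batch_count * cfg$batch_max < cfg$n_samples) {
    abort("batch_count * batch_max must cover n_samples")
  }
  if (cfg$dispersion <= 0) abort("dispersion must be positive")
  structure(cfg, class = "sim_config")
}

local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Simulate a clinical cohort table
#'
#' Draws, per sample in order: risk group (by `group_weights`), an
#' integer Oncotype DX DCIS score uniform on the group's range, an
#' age from the group's normal model (rounded, clamped to 25-90) and
#' a nuclear grade from group-conditional frequencies matching the
#' packaged cohort. Deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A clinical tibble with the same columns as
#'   [read_clinical()] output.
#' @export
#' @examples
#' clin <- simulate_clinical(sim_config(seed = 7))
#' risk_group_counts(clin)
simulate_clinical <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  grade_probs <- list(
    low = c(0.24, 0.56, 0.20),
    intermediate = c(0, 0.4, 0.6),
    high = c(0, 0.4, 0.6)
  )
  local_seed(cfg$seed, {
    n <- cfg$n_samples
    group <- sample(risk_group_levels, n, replace = TRUE, prob = cfg$group_weights)
    dx <- vapply(group, function(g) {
      rng <- cfg$score_ranges[[g]]
      sample(seq(rng[1], rng[2]), 1)
    }, integer(1))
    age <- vapply(seq_len(n), function(i) {
      g <- group[i]
      a <- round(rnorm(1, cfg$age_mean[[g]], cfg$age_sd[[g]]))
      as.integer(min(max(a, 25), 90))
    }, integer(1))
    grade <- vapply(group, function(g) {
      sample(1:3, 1, prob = grade_probs[[g]])
    }, integer(1))
    tibble::tibble(
      patient_id = sprintf("SIM-%03d", seq_len(n)),
      dx_score = as.integer(dx),
      age = age,
      age_censor = "none",
      nuclear_grade = grade,
      risk_group = assign_risk_group(dx),
      follow_up_years = NA_real_,
      treatment = NA_character_,
      recurrence = NA_character_
    )
  })
}

#' Simulate a miRNA count matrix with planted effects
#'
#' Per-miRNA log2 relative abundance is baseline + beta x standardized
#' score + gamma x standardized age + a per-(library, miRNA) batch
#' effect; abundances are normalized within each sample and counts
#' drawn negative-binomially with mean library-size x fraction and
#' size `dispersion`. Standardization uses the realized cohort mean
#' and SD, so planted effects are interpretable as log2 change per
#' realized SD regardless of n. Samples are assigned round-robin to
#' `batch_count` libraries. Deterministic given `cfg$seed`.
#'
#' @param clinical A clinical tibble (real or from
#'   [simulate_clinical()]).
#' @param cfg A [sim_config()].
#' @return A list of class `sim_counts`: `counts` (wide tibble,
#'   `mirna_id` + one column per sample), `samples` (tibble
#'   `sample_id`, `batch`, `libsize`), and `truth` — a list with
#'   `mirnas` (per-miRNA tibble: `mirna_id`, `is_score_assoc`,
#'   `is_age_assoc`, `beta`, `gamma`, `baseline`) and `log2_rel`
#'   (batch-free log2 relative-expression matrix used by
#'   [simulate_ct()]).
#' @export
simulate_counts <- function(clinical, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (nrow(clinical) == 0) abort("clinical table is empty")
  n <- nrow(clinical)
  m <- cfg$n_mirnas
  mirna_ids <- sprintf("mir-sim-%03d", seq_len(m))
  score_idx <- seq_len(cfg$n_score_assoc)
  age_idx <- seq_len(cfg$n_age_assoc) + cfg$n_score_assoc
  signed <- function(idx, frac_up, size) {
    s <- numeric(m)
    n_up <- round(frac_up * length(idx))
    s[idx] <- size * c(rep(1, n_up), rep(-1, length(idx) - n_up))
    s
  }
  beta <- signed(score_idx, cfg$frac_up_score, cfg$beta)
  gamma <- signed(age_idx, cfg$frac_up_age, cfg$gamma)
  std <- function(x) {
    if (sd(x) == 0) {
      rep(0, length(x))
    } else {
      (x - mean(x)) / sd(x)
    }
  }
  score_std <- std(clinical$dx_score)
  age_std <- std(clinical$age)
  batch <- ((seq_len(n) - 1L) %% cfg$batch_count) + 1L
  local_seed(cfg$seed + 1L, {
    baseline <- rnorm(m, cfg$baseline_mean, cfg$baseline_sd)
    baseline[c(score_idx, age_idx)] <-
      rnorm(length(score_idx) + length(age_idx), cfg$planted_mean, cfg$planted_sd)
    libsize <- round(exp(runif(n, log(cfg$libsize_range[1]), log(cfg$libsize_range[2]))))
    batch_eff <- matrix(rnorm(cfg$batch_count * m, 0, cfg$batch_sd),
      nrow = cfg$batch_count
    )
    # batch-free log2 relative expression (drives the Ct model)
    l0 <- outer(baseline, rep(1, n)) +
      outer(beta, score_std) + outer(gamma, age_std)
    log2_rel <- log2(sweep(2^l0, 2, colSums(2^l0), "/"))
    l <- l0 + t(batch_eff[batch, , drop = FALSE])
    p <- sweep(2^l, 2, colSums(2^l), "/")
    mu <- sweep(p, 2, libsize, "*")
    counts <- matrix(
      rnbinom(m * n, mu = as.vector(mu), size = cfg$dispersion),
      nrow = m
    )
    dimnames(counts) <- list(mirna_ids, clinical$patient_id)
    dimnames(log2_rel) <- dimnames(counts)
    structure(
      list(
        counts = dplyr::bind_cols(
          tibble::tibble(mirna_id = mirna_ids),
          tibble::as_tibble(counts)
        ),
        samples = tibble::tibble(
          sample_id = clinical$patient_id,
          batch = batch,
          libsize = libsize
        ),
        truth = list(
          mirnas = tibble::tibble(
            mirna_id = mirna_ids,
            is_score_assoc = seq_len(m) %in% score_idx,
            is_age_assoc = seq_len(m) %in% age_idx,
            beta = beta,
            gamma = gamma,
            baseline = baseline
          ),
          log2_rel = log2_rel
        )
      ),
      class = "sim_counts"
    )
  })
}

#' Simulate a matched qPCR Ct table
#'
#' For each panel miRNA and sample, draws three replicate Ct values
#' from Ct = `ct_intercept` - log2(relative expression) + N(0,
#' `ct_sigma`^2), where the relative expression is the batch-free
#' truth from [simulate_counts()] — Ct is inversely linear in log2
#' abundance, with triplicate noise. The endogenous control (RNU6B)
#' is drawn around the constant `ct_control` level with the same
#' noise. Deterministic given `cfg$seed`.
#'
#' @param sim A `sim_counts` object from [simulate_counts()].
#' @param panel Panel tibble (`mirna_id`, ...); members must exist in
#'   the simulated truth.
#' @param cfg A [sim_config()].
#' @param control_gene Name of the endogenous control row (default
#'   `"RNU6B"`).
#' @return A long Ct tibble as from [read_ct()].
#' @export
simulate_ct <- function(sim, panel, cfg, control_gene = "RNU6B") {
  stopifnot(inherits(cfg, "sim_config"), inherits(sim, "sim_counts"))
  log2_rel <- sim$truth$log2_rel
  missing_m <- setdiff(panel$mirna_id, rownames(log2_rel))
  if (length(missing_m) > 0) {
    abort(paste0(
      "panel member(s) absent from the simulated truth: ",
      paste(missing_m, collapse = ", ")
    ))
  }
  samples <- colnames(log2_rel)
  mirnas <- panel$mirna_id
  local_seed(cfg$seed + 2L, {
    grid <- tidyr::expand_grid(
      mirna_id = mirnas,
      sample_id = samples,
      replicate = 1:3
    )
    true_ct <- cfg$ct_intercept -
      log2_rel[cbind(grid$mirna_id, grid$sample_id)]
    grid$ct <- true_ct + rnorm(nrow(grid), 0, cfg$ct_sigma)
    ctrl <- tidyr::expand_grid(
      mirna_id = control_gene,
      sample_id = samples,
      replicate = 1:3
    )
    ctrl$ct <- cfg$ct_control + rnorm(nrow(ctrl), 0, cfg$ct_sigma)
    out <- dplyr::bind_rows(grid, ctrl)[
      ,
      c("sample_id", "mirna_id", "replicate", "ct")
    ]
    out$detected <- TRUE
    out
  })
}

#' Evaluate screen recovery against simulated truth
#'
#' Compares a screen's discoveries (`adj_p < alpha` among testable
#' rows) with the planted associations: sensitivity = recovered /
#' planted, empirical FDR = false discoveries / max(discoveries, 1),
#' and sign accuracy among the true positives (a planted positive
#' effect should be reported `"up"`).
#'
#' @param screen A `mir_screen` tibble.
#' @param truth The `truth` element of a [simulate_counts()] result.
#' @param alpha Adjusted-p discovery cutoff (default 0.05).
#' @param type Which planted set to score against: `"score"` or
#'   `"age"`.
#' @return A one-row tibble: `n_planted`, `n_discovered`,
#'   `n_true_pos`, `sensitivity`, `fdr`, `sign_accuracy`.
#' @export
evaluate_screen_recovery <- function(screen, truth, alpha = 0.05,
                                     type = c("score", "age")) {
  type <- match.arg(type)
  mirnas <- truth$mirnas
  if (!setequal(screen$mirna_id, mirnas$mirna_id)) {
    abort("screen and truth cover different miRNA universes")
  }
  mirnas <- mirnas[match(screen$mirna_id, mirnas$mirna_id), ]
  planted <- if (type == "score") mirnas$is_score_assoc else mirnas$is_age_assoc
  effect <- if (type == "score") mirnas$beta else mirnas$gamma
  discovered <- !is.na(screen$adj_p) & screen$adj_p < alpha & screen$testable
  tp <- discovered & planted
  sign_ok <- screen$direction[tp] == ifelse(effect[tp] > 0, "up", "down")
  tibble::tibble(
    n_planted = sum(planted),
    n_discovered = sum(discovered),
    n_true_pos = sum(tp),
    sensitivity = sum(tp) / max(sum(planted), 1),
    fdr = sum(discovered & !planted) / max(sum(discovered), 1),
    sign_accuracy = if (sum(tp) > 0) mean(sign_ok) else NA_real_
  )
}
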