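# Shared fixtures and brute-force oracles used across the suite.

cohort_path <- dcismir_example("dcis_cohort41.csv")

cohort41 <- read_clinical(cohort_path)

# Minimal synthetic clinical table built in code (not the packaged fixture)
tiny_clinical <- function(scores, ages = NULL, ids = NULL) {
  n <- length(scores)
  tibble::tibble(
    patient_id = ids %||% sprintf("P%02d", seq_len(n)),
    dx_score = as.integer(scores),
    age = as.integer(ages %||% rep(60, n)),
    age_censor = "none",
    nuclear_grade = NA_integer_,
    risk_group = assign_risk_group(scores),
    follow_up_years = NA_real_,
    treatment = NA_character_,
    recurrence = NA_character_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# O(m^2) definition-level Benjamini-Hochberg step-up oracle
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[ord[i]] <- min(vapply(
      i:m,
      function(j) m / j * p[ord[j]],
      numeric(1)
    ), 1)
  }
  adj
}

# Exact two-sided Mann-Whitney p by full enumeration of group labelings
mw_enum_oracle <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  u_stat <- function(x, y) {
    sum(rank(c(x, y))[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  }
  obs <- u_stat(a, b)
  mid <- n_a * length(b) / 2
  splits <- utils::combn(length(pooled), n_a)
  us <- apply(splits, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  # two-sided: as or more extreme in distance from the null mean
  mean(abs(us - mid) >= abs(obs - mid) - 1e-12)
}

# Textbook chi-square statistic, sum (O - E)^2 / E
chisq_stat_oracle <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# Closed-form Welch test oracle
welch_oracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t_stat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(statistic = t_stat, df = df, p = 2 * pt(-abs(t_stat), df))
}
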