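#' Z-standardize expression per miRNA across samples
#'
#' Centers and scales each miRNA's values to mean 0 and sample
#' standard deviation 1 (n - 1 denominator) across samples. Constant
#' rows cannot be standardized; they are flagged (`z = NA`) with a
#' warning rather than erroring, and are excluded from composite
#' scoring.
#'
#' @param expr Long tibble with columns `mirna_id`, `sample_id` and a
#'   value column.
#' @param value Name of the value column (default `"log2_expr"`).
#' @return The input with additional columns `z` and `z_ok`.
#' @export
z_standardize <- function(expr, value = "log2_expr") {
  if (!value %in% names(expr)) {
    abort(paste0("no column called '", value, "' in expr"))
  }
  out <- expr |>
    dplyr::group_by(.data$mirna_id) |>
    dplyr::mutate(
      .sd = sd(.data[[value]]),
      z_ok = .data$.sd > 0 & dplyr::n() >= 2,
      z = dplyr::if_else(
        .data$z_ok,
        (.data[[value]] - mean(.data[[value]])) / .data$.sd,
        NA_real_
      )
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-".sd")
  bad <- unique(out$mirna_id[!out$z_ok])
  if (length(bad) > 0) {
    warn(paste0(
      "constant or single-sample miRNA row(s) could not be standardized: ",
      paste(bad, collapse = ", ")
    ))
  }
  out
}

#' Composite miRNA score
#'
#' The per-sample composite "miRNA score": the sum over a miRNA panel
#' of signed z-standardized values, score_i = sum_m s_m z_mi. On the
#' expression scale, a downregulated panel member contributes its
#' negated z (s = -1), so the score increases as panel expression
#' falls, i.e. rises with recurrence risk; upregulated members
#' contribute +z. On the delta-delta-Ct scale the signs are flipped
#' internally, because a higher delta-delta Ct already means lower
#' expression — scoring delta-delta-Ct values or their negation on
#' the expression scale gives identical scores.
#'
#' @param expr Long tibble with `mirna_id`, `sample_id` and a value
#'   column covering every panel member in every sample.
#' @param panel Panel tibble with `mirna_id` and `direction`
#'   (`up`/`down`), e.g. from [read_panel()] or [select_panel()].
#' @param value Name of the value column (default `"log2_expr"`; use
#'   `"delta_delta_ct"` with `scale = "delta_delta_ct"`).
#' @param scale `"expression"` (default) or `"delta_delta_ct"`.
#' @return An object of class `mirna_score`: list with `scores` (a
#'   tibble `sample_id`, `score`, `n_mirnas`), `panel`, `scale` and
#'   `excluded` (panel members dropped as constant). `tidy()`,
#'   `glance()` and `autoplot()` methods are provided.
#' @export
mirna_score <- function(expr, panel, value = "log2_expr",
                        scale = c("expression", "delta_delta_ct")) {
  scale <- match.arg(scale)
  if (nrow(panel) == 0) abort("panel is empty")
  missing_m <- setdiff(panel$mirna_id, unique(expr$mirna_id))
  if (length(missing_m) > 0) {
    abort(paste0(
      "panel member(s) absent from the expression data: ",
      paste(missing_m, collapse = ", ")
    ))
  }
  z <- z_standardize(expr[expr$mirna_id %in% panel$mirna_id, ], value = value)
  excluded <- unique(z$mirna_id[!z$z_ok])
  z <- z[z$z_ok, ]
  if (nrow(z) == 0) abort("no usable (non-constant) panel members")
  sign_tab <- tibble::tibble(
    mirna_id = panel$mirna_id,
    s = ifelse(panel$direction == "down", -1, 1) *
      (if (scale == "delta_delta_ct") -1 else 1)
  )
  scores <- z |>
    dplyr::left_join(sign_tab, by = "mirna_id") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      score = sum(.data$s * .data$z),
      n_mirnas = dplyr::n(),
      .groups = "drop"
    )
  structure(
    list(
      scores = scores, panel = panel, scale = scale, excluded = excluded
    ),
    class = "mirna_score"
  )
}

#' @export
print.mirna_score <- function(x, ...) {
  cat(sprintf(
    "Composite miRNA score: %d samples, %d-miRNA panel (%s scale)\n",
    nrow(x$scores), nrow(x$panel), x$scale
  ))
  if (length(x$excluded) > 0) {
    cat("excluded constant members:", paste(x$excluded, collapse = ", "), "\n")
  }
  print(x$scores, n = 5)
  invisible(x)
}

#' @method tidy mirna_score
#' @export
tidy.mirna_score <- function(x, ...) {
  x$scores
}

#' @method glance mirna_score
#' @export
glance.mirna_score <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$scores),
    n_panel = nrow(x$panel),
    n_excluded = length(x$excluded),
    score_sd = sd(x$scores$score),
    scale = x$scale
  )
}

score_with_groups <- function(score, clinical) {
  grp <- setNames(as.character(clinical$risk_group), clinical$patient_id)
  out <- score$scores
  out$risk_group <- factor(unname(grp[out$sample_id]), levels = risk_group_levels)
  if (anyNA(out$risk_group)) {
    abort(paste0(
      "scored sample(s) missing from the clinical table: ",
      paste(out$sample_id[is.na(out$risk_group)], collapse = ", ")
    ))
  }
  out
}

#' Correlate the composite miRNA score with the Oncotype DX score
#'
#' @param score A `mirna_score` object.
#' @param clinical Clinical tibble with `patient_id` and `dx_score`.
#' @return A one-row tibble: Pearson `estimate`, `p_value`, `n`,
#'   `method`, `testable`.
#' @export
score_vs_dx <- function(score, clinical) {
  dx <- setNames(clinical$dx_score, clinical$patient_id)
  s <- score$scores
  if (anyNA(dx[s$sample_id])) {
    abort("scored sample(s) missing from the clinical table")
  }
  cor_test_pearson(s$score, as.numeric(dx[s$sample_id]))
}

#' Risk-group discrimination of the composite miRNA score
#'
#' Compares composite scores between Oncotype DX DCIS risk groups:
#' either low vs pooled intermediate/high (default, the comparison
#' with the largest expression differences in this cohort) or all
#' three pairwise comparisons. Both a Welch t and a Mann-Whitney U
#' p-value are reported per comparison.
#'
#' @param score A `mirna_score` object.
#' @param clinical Clinical tibble with `patient_id` and `risk_group`.
#' @param grouping `"low_vs_int_high"` (default) or `"three_way"`.
#' @return A tibble with one row per comparison: `comparison`, group
#'   sizes, mean difference, `welch_p`, `mann_whitney_p`.
#' @export
score_group_discrimination <- function(score, clinical,
                                       grouping = c("low_vs_int_high", "three_way")) {
  grouping <- match.arg(grouping)
  dat <- score_with_groups(score, clinical)
  compare <- function(label, a, b) {
    if (length(a) < 2 || length(b) < 2) {
      abort(paste0("group with < 2 samples in comparison ", label))
    }
    tibble::tibble(
      comparison = label,
      n_1 = length(a), n_2 = length(b),
      mean_diff = mean(b) - mean(a),
      welch_p = welch_t(a, b)$p_value,
      mann_whitney_p = mann_whitney(a, b)$p_value
    )
  }
  s <- split(dat$score, dat$risk_group)
  if (grouping == "low_vs_int_high") {
    compare("low vs int+high", s$low, c(s$intermediate, s$high))
  } else {
    dplyr::bind_rows(
      compare("low vs intermediate", s$low, s$intermediate),
      compare("intermediate vs high", s$intermediate, s$high),
      compare("low vs high", s$low, s$high)
    )
  }
}

#' Rank of a sample's score within its risk group
#'
#' Descending-score rank (1 = most extreme toward high risk) of one
#' sample among the samples of its own group. Ties are broken by
#' sample-id order.
#'
#' @param score A `mirna_score` object.
#' @param clinical Clinical tibble with `patient_id` and `risk_group`.
#' @param sample_id The sample to rank.
#' @param grouping `"low_vs_int_high"` (default, ranks within low or
#'   pooled intermediate/high) or `"three_way"`.
#' @return A one-row tibble: `sample_id`, `group`, `rank`,
#'   `group_size`.
#' @export
rank_extremity <- function(score, clinical, sample_id,
                           grouping = c("low_vs_int_high", "three_way")) {
  grouping <- match.arg(grouping)
  dat <- score_with_groups(score, clinical)
  dat$group <- if (grouping == "low_vs_int_high") {
    ifelse(dat$risk_group == "low", "low", "int_high")
  } else {
    as.character(dat$risk_group)
  }
  if (!sample_id %in% dat$sample_id) {
    abort(paste0("unknown sample: ", sample_id))
  }
  g <- dat$group[dat$sample_id == sample_id]
  members <- dat[dat$group == g, ]
  members <- members[order(-members$score, members$sample_id), ]
  tibble::tibble(
    sample_id = sample_id,
    group = g,
    rank = which(members$sample_id == sample_id),
    group_size = nrow(members)
  )
}
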