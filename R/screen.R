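#' Read a miRNA count matrix from TSV
#'
#' Expects a tab-separated file whose first column is `mirna_id` and
#' whose remaining columns are one per sample, containing non-negative
#' integer read counts.
#'
#' @param path Path to the counts TSV.
#' @return A wide tibble: `mirna_id` plus one integer column per sample.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  counts <- readr::read_tsv(path, col_types = readr::cols(
    mirna_id = readr::col_character(),
    .default = readr::col_double()
  ))
  if (!"mirna_id" %in% names(counts)) {
    abort("counts file must have a 'mirna_id' first column")
  }
  mat <- as.matrix(counts[-1])
  if (any(mat < 0) || any(mat != round(mat))) {
    abort("counts must be non-negative integers")
  }
  counts
}

counts_to_matrix <- function(counts) {
  mat <- as.matrix(counts[setdiff(names(counts), "mirna_id")])
  rownames(mat) <- counts$mirna_id
  mat
}

#' Total-count normalization of a miRNA count matrix
#'
#' Converts raw read counts to within-sample fractions (each sample's
#' fractions sum to 1) and to log2 counts-per-`scale` with a
#' pseudocount added to the raw counts before scaling (default: log2
#' CPM with pseudocount 1). Total-count fractions remove library-size
#' differences; the log2 scale is what the screens correlate.
#'
#' @param counts Wide counts tibble (`mirna_id` + one column per
#'   sample), as returned by [read_counts()] or [simulate_counts()].
#' @param scale Scale factor for the log2 expression (default 1e6,
#'   i.e. counts per million).
#' @param pseudocount Added to raw counts before the log2-CPM
#'   transform (default 1). Fractions are computed without it.
#' @return A long tibble of class `mir_norm` with columns `mirna_id`,
#'   `sample_id`, `count`, `fraction`, `log2_expr`.
#' @export
#' @examples
#' counts <- tibble::tibble(
#'   mirna_id = c("a", "b", "c"),
#'   s1 = c(10, 30, 60), s2 = c(5, 5, 90)
#' )
#' normalize_counts(counts)
normalize_counts <- function(counts, scale = 1e6, pseudocount = 1) {
  mat <- counts_to_matrix(counts)
  totals <- colSums(mat)
  if (any(totals == 0)) {
    abort(paste0(
      "sample(s) with zero total counts: ",
      paste(colnames(mat)[totals == 0], collapse = ", ")
    ))
  }
  frac <- sweep(mat, 2, totals, "/")
  log2_expr <- log2(sweep(mat + pseudocount, 2, totals, "/") * scale)
  out <- tibble::tibble(
    mirna_id = rep(rownames(mat), times = ncol(mat)),
    sample_id = rep(colnames(mat), each = nrow(mat)),
    count = as.vector(mat),
    fraction = as.vector(frac),
    log2_expr = as.vector(log2_expr)
  )
  class(out) <- c("mir_norm", class(out))
  attr(out, "scale") <- scale
  attr(out, "pseudocount") <- pseudocount
  out
}

norm_to_matrix <- function(norm, value = "log2_expr") {
  wide <- tidyr::pivot_wider(
    norm[c("mirna_id", "sample_id", value)],
    names_from = "sample_id", values_from = dplyr::all_of(value)
  )
  counts_to_matrix(wide)
}

#' Mean abundance of a miRNA as a percentage of all reads
#'
#' @param norm A normalized long tibble from [normalize_counts()].
#' @param mirna A single miRNA identifier.
#' @param samples Optional character vector restricting the averaging
#'   to a sample subset (default: all samples).
#' @return 100 times the mean within-sample fraction of that miRNA.
#' @export
abundance_percent <- function(norm, mirna, samples = NULL) {
  if (!mirna %in% norm$mirna_id) {
    abort(paste0("unknown miRNA: ", mirna))
  }
  rows <- norm[norm$mirna_id == mirna, ]
  if (!is.null(samples)) {
    missing_s <- setdiff(samples, rows$sample_id)
    if (length(missing_s) > 0) {
      abort(paste0("unknown sample(s): ", paste(missing_s, collapse = ", ")))
    }
    rows <- rows[rows$sample_id %in% samples, ]
  }
  100 * mean(rows$fraction)
}

# Vectorised per-row correlation of an expression matrix against a
# numeric covariate: Pearson r (optionally on mid-ranks for Spearman)
# with two-sided p from the t distribution on n - 2 df. Constant rows
# come back untestable rather than erroring.
row_correlations <- function(mat, y, method = c("pearson", "spearman"),
                             df_loss = 0) {
  method <- match.arg(method)
  if (ncol(mat) != length(y)) {
    abort("covariate length must match the number of samples")
  }
  if (method == "spearman") {
    mat <- t(apply(mat, 1, rank))
    y <- rank(y)
  }
  n <- length(y)
  df <- n - 2 - df_loss
  row_sd <- apply(mat, 1, sd)
  testable <- row_sd > 0 & sd(y) > 0 & df >= 1
  r <- rep(NA_real_, nrow(mat))
  if (any(testable) && sd(y) > 0) {
    r[testable] <- as.vector(cor(t(mat[testable, , drop = FALSE]), y))
  }
  tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = df)
  p <- pmin(p, 1)
  p[!testable] <- NA_real_
  r[!testable] <- NA_real_
  tibble::tibble(estimate = r, p_value = p, testable = testable)
}

screen_impl <- function(norm, covariate, method, adjust_batch, batch) {
  mat <- norm_to_matrix(norm, "log2_expr")
  frac <- norm_to_matrix(norm, "fraction")
  samples <- colnames(mat)
  if (is.null(names(covariate))) {
    if (length(covariate) != length(samples)) {
      abort("covariate must be named by sample or match the sample count")
    }
    names(covariate) <- samples
  }
  missing_cov <- setdiff(samples, names(covariate))
  if (length(missing_cov) > 0) {
    abort(paste0(
      "no covariate value for sample(s): ",
      paste(missing_cov, collapse = ", ")
    ))
  }
  y <- as.numeric(covariate[samples])
  df_loss <- 0
  if (adjust_batch) {
    if (is.null(batch)) abort("adjust_batch = TRUE requires batch labels")
    if (is.null(names(batch))) names(batch) <- samples
    b <- factor(batch[samples])
    if (nlevels(b) > 1) {
      # partial correlation given batch: residualize both sides and
      # spend the corresponding degrees of freedom
      mat <- t(apply(mat, 1, function(row) resid(lm(row ~ b))))
      colnames(mat) <- samples
      y <- resid(lm(y ~ b))
      df_loss <- nlevels(b) - 1
    }
  }
  res <- row_correlations(mat, y, method, df_loss = df_loss)
  out <- tibble::tibble(
    mirna_id = rownames(mat),
    estimate = res$estimate,
    p_value = res$p_value,
    adj_p = bh_adjust(res$p_value),
    direction = dplyr::if_else(res$estimate < 0, "down", "up",
      missing = NA_character_
    ),
    testable = res$testable,
    mean_abundance_pct = 100 * rowMeans(frac),
    n = length(y)
  )
  class(out) <- c("mir_screen", class(out))
  attr(out, "method") <- method
  attr(out, "adjust_batch") <- adjust_batch
  out
}

#' Screen miRNA expression against the Oncotype DX DCIS score
#'
#' Per-miRNA Pearson correlation of log2 normalized expression with
#' the continuous Oncotype DX DCIS score across samples, with
#' Benjamini-Hochberg adjustment over all testable miRNAs. Direction
#' `"down"` means expression decreases as the risk score increases.
#' Optionally a batch-partial correlation is computed (expression and
#' covariate both residualized on sequencing batch before
#' correlating), since barcoded multi-sample libraries can carry
#' batch effects.
#'
#' @param norm Normalized long tibble from [normalize_counts()].
#' @param scores Numeric Oncotype DX DCIS scores, named by sample id
#'   (or in sample-column order).
#' @param adjust_batch Residualize log2 expression on `batch` first.
#' @param batch Per-sample batch labels, named by sample id; only used
#'   when `adjust_batch = TRUE`.
#' @return A tibble of class `mir_screen`, one row per miRNA:
#'   `mirna_id`, `estimate` (r), `p_value`, `adj_p`, `direction`,
#'   `testable`, `mean_abundance_pct`, `n`.
#' @export
screen_vs_score <- function(norm, scores, adjust_batch = FALSE, batch = NULL) {
  screen_impl(norm, scores, "pearson", adjust_batch, batch)
}

#' Screen miRNA expression against patient age
#'
#' As [screen_vs_score()], but uses Spearman rank correlation of log2
#' normalized expression with age, the appropriate choice for a
#' monotone-but-not-necessarily-linear age trend.
#'
#' @inheritParams screen_vs_score
#' @param ages Numeric patient ages, named by sample id.
#' @return A tibble of class `mir_screen` (see [screen_vs_score()]).
#' @export
screen_vs_age <- function(norm, ages, adjust_batch = FALSE, batch = NULL) {
  screen_impl(norm, ages, "spearman", adjust_batch, batch)
}

#' Bin patient age into the three analysis age groups
#'
#' Groups: 1 for ages <= 55, 2 for 56-70, 3 for > 70.
#'
#' @param age Positive integer vector of ages in years.
#' @return Integer vector of group labels (1, 2 or 3).
#' @export
#' @examples
#' bin_age(c(55, 56, 70, 71))
bin_age <- function(age) {
  if (any(is.na(age)) || any(age <= 0)) {
    abort("ages must be positive")
  }
  ifelse(age <= 55, 1L, ifelse(age <= 70, 2L, 3L))
}

#' Select a validation panel from the two screens
#'
#' Takes the top `k_score` miRNAs associated with the risk score and
#' the top `k_age` associated with age (ranked by adjusted p among
#' those passing `adj_p < alpha`), and returns their union annotated
#' with provenance (`score`, `age` or `both`) and direction. The
#' direction of a `both` member is taken from the score screen.
#'
#' @param score_screen,age_screen `mir_screen` tibbles over the same
#'   miRNA universe, from [screen_vs_score()] and [screen_vs_age()].
#' @param alpha Adjusted-p cutoff in (0, 1), default 0.05.
#' @param k_score,k_age Panel sizes per screen (defaults 10 and 9).
#' @return A tibble with columns `mirna_id`, `direction`,
#'   `provenance`; empty (zero rows) if nothing passes `alpha`.
#' @export
select_panel <- function(score_screen, age_screen, alpha = 0.05,
                         k_score = 10, k_age = 9) {
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  if (!setequal(score_screen$mirna_id, age_screen$mirna_id)) {
    abort("the two screens must cover the same miRNA universe")
  }
  top <- function(screen, k) {
    hits <- dplyr::filter(screen, .data$testable, .data$adj_p < alpha)
    hits <- dplyr::arrange(hits, .data$adj_p, .data$p_value)
    utils::head(hits[c("mirna_id", "direction")], k)
  }
  top_score <- top(score_screen, k_score)
  top_age <- top(age_screen, k_age)
  members <- union(top_score$mirna_id, top_age$mirna_id)
  tibble::tibble(
    mirna_id = members,
    direction = dplyr::coalesce(
      top_score$direction[match(members, top_score$mirna_id)],
      top_age$direction[match(members, top_age$mirna_id)]
    ),
    provenance = dplyr::case_when(
      members %in% top_score$mirna_id & members %in% top_age$mirna_id ~ "both",
      members %in% top_score$mirna_id ~ "score",
      TRUE ~ "age"
    )
  )
}

#' Read a miRNA panel CSV
#'
#' Schema: `mirna_id,direction,provenance` with direction in
#' `up`/`down`. The two packaged panels are
#' `mirna_panel_qpcr5.csv` (the five RT-qPCR-validated downregulated
#' miRNAs) and `mirna_panel_ngs17.csv` (the 17-miRNA sequencing panel
#' with its mixed signs).
#'
#' @param path Path to the panel CSV.
#' @return A tibble with columns `mirna_id`, `direction`, `provenance`.
#' @export
#' @examples
#' read_panel(dcismir_example("mirna_panel_qpcr5.csv"))
read_panel <- function(path) {
  panel <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  required <- c("mirna_id", "direction")
  missing_cols <- setdiff(required, names(panel))
  if (length(missing_cols) > 0) {
    abort(paste0("panel is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!all(panel$direction %in% c("up", "down"))) {
    abort("panel direction must be 'up' or 'down'")
  }
  if (anyDuplicated(panel$mirna_id)) abort("panel mirna_id values must be unique")
  if (!"provenance" %in% names(panel)) panel$provenance <- NA_character_
  panel[c("mirna_id", "direction", "provenance")]
}
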