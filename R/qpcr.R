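#' Read a long-format qPCR Ct table
#'
#' Schema: `sample_id,mirna_id,replicate,ct` with one row per
#' technical replicate (up to three per sample x miRNA) and an empty
#' `ct` cell for undetected reactions.
#'
#' @param path Path to the Ct CSV.
#' @return A tibble with columns `sample_id`, `mirna_id`, `replicate`,
#'   `ct` and a derived logical `detected`.
#' @export
read_ct <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  ct <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    mirna_id = readr::col_character(),
    replicate = readr::col_integer(),
    ct = readr::col_double()
  ))
  required <- c("sample_id", "mirna_id", "replicate", "ct")
  missing_cols <- setdiff(required, names(ct))
  if (length(missing_cols) > 0) {
    abort(paste0("Ct table is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (any(ct$ct <= 0, na.rm = TRUE)) abort("detected Ct values must be positive")
  ct$detected <- !is.na(ct$ct)
  ct
}

#' Aggregate technical qPCR replicates
#'
#' Collapses up to three technical replicates per (sample, miRNA)
#' into a mean Ct with a quality flag: `pass` when all three
#' replicates are detected and their SD is within `sd_threshold`
#' cycles, `partial` when fewer than three are detected, `discordant`
#' when the replicate SD exceeds the threshold, and `undetected` when
#' no replicate amplified (such rows carry `NA` mean Ct and are
#' dropped, with a warning, by [delta_ct()]).
#'
#' @param ct A Ct tibble as from [read_ct()].
#' @param sd_threshold Replicate-SD tolerance in cycles (default 0.5).
#' @return A tibble with one row per (sample, miRNA): `sample_id`,
#'   `mirna_id`, `mean_ct`, `ct_sd`, `n_detected`, `qc_flag`.
#' @export
aggregate_triplicates <- function(ct, sd_threshold = 0.5) {
  if (!"detected" %in% names(ct)) ct$detected <- !is.na(ct$ct)
  n_rep <- dplyr::count(ct, .data$sample_id, .data$mirna_id)
  if (any(n_rep$n > 3)) {
    abort("more than 3 replicates for some (sample, miRNA)")
  }
  out <- ct |>
    dplyr::group_by(.data$sample_id, .data$mirna_id) |>
    dplyr::summarise(
      mean_ct = mean(.data$ct[.data$detected]),
      ct_sd = sd(.data$ct[.data$detected]),
      n_detected = sum(.data$detected),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      mean_ct = dplyr::if_else(.data$n_detected == 0, NA_real_, .data$mean_ct),
      qc_flag = dplyr::case_when(
        n_detected == 0 ~ "undetected",
        n_detected < 3 ~ "partial",
        ct_sd > sd_threshold ~ "discordant",
        TRUE ~ "pass"
      )
    )
  out
}

#' Normalize Ct values to the endogenous control
#'
#' Subtracts each sample's endogenous-control mean Ct (default
#' RNU6B) from that sample's target-miRNA mean Ct values:
#' delta Ct = mean Ct(miRNA) - mean Ct(control). Undetected rows are
#' dropped with a warning.
#'
#' @param agg Aggregated Ct tibble from [aggregate_triplicates()].
#' @param control_gene Identifier of the endogenous control (default
#'   `"RNU6B"`).
#' @return A tibble with one row per (sample, target miRNA):
#'   `sample_id`, `mirna_id`, `mean_ct`, `control_ct`, `delta_ct`,
#'   `qc_flag`.
#' @export
delta_ct <- function(agg, control_gene = "RNU6B") {
  undet <- agg$qc_flag == "undetected"
  if (any(undet)) {
    warn(paste0(
      sum(undet), " undetected (sample, miRNA) pair(s) dropped: ",
      paste(utils::head(paste0(agg$sample_id[undet], "/", agg$mirna_id[undet]), 5),
        collapse = ", "
      )
    ))
    agg <- agg[!undet, ]
  }
  ctrl <- agg[agg$mirna_id == control_gene, c("sample_id", "mean_ct")]
  names(ctrl)[2] <- "control_ct"
  targets <- agg[agg$mirna_id != control_gene, ]
  no_ctrl <- setdiff(unique(targets$sample_id), ctrl$sample_id)
  if (length(no_ctrl) > 0) {
    abort(paste0(
      "no ", control_gene, " control Ct for sample(s): ",
      paste(no_ctrl, collapse = ", ")
    ))
  }
  dplyr::left_join(targets, ctrl, by = "sample_id") |>
    dplyr::mutate(delta_ct = .data$mean_ct - .data$control_ct) |>
    dplyr::select(
      "sample_id", "mirna_id", "mean_ct", "control_ct",
      "delta_ct", "qc_flag"
    )
}

#' Delta-delta-Ct relative quantification
#'
#' References each sample's delta Ct to the mean delta Ct of a
#' reference sample group (here the Oncotype DX low-risk group), per
#' miRNA: delta-delta Ct = delta Ct - mean(delta Ct over reference),
#' and fold change = 2^(-delta-delta Ct), assuming perfect (2-fold
#' per cycle) amplification efficiency. By construction the reference
#' group's mean delta-delta Ct is 0 and its fold changes have
#' geometric mean 1 for every miRNA.
#'
#' @param dct Delta-Ct tibble from [delta_ct()].
#' @param reference Character vector of reference sample ids (e.g.
#'   the low-risk patients).
#' @return The input tibble plus `delta_delta_ct` and `fold_change`
#'   columns.
#' @export
delta_delta_ct <- function(dct, reference) {
  reference <- intersect(reference, unique(dct$sample_id))
  if (length(reference) == 0) {
    abort("reference sample set is empty (no overlap with the Ct data)")
  }
  ref_means <- dct |>
    dplyr::filter(.data$sample_id %in% reference) |>
    dplyr::group_by(.data$mirna_id) |>
    dplyr::summarise(ref_mean_dct = mean(.data$delta_ct), .groups = "drop")
  missing_ref <- setdiff(unique(dct$mirna_id), ref_means$mirna_id)
  if (length(missing_ref) > 0) {
    abort(paste0(
      "no reference samples measured for miRNA(s): ",
      paste(missing_ref, collapse = ", ")
    ))
  }
  dplyr::left_join(dct, ref_means, by = "mirna_id") |>
    dplyr::mutate(
      delta_delta_ct = .data$delta_ct - .data$ref_mean_dct,
      fold_change = 2^(-.data$delta_delta_ct)
    ) |>
    dplyr::select(-"ref_mean_dct")
}

#' Per-miRNA group comparison of delta-delta-Ct values
#'
#' Compares delta-delta-Ct values between the low-risk group and the
#' pooled intermediate/high group, per miRNA, with both a Welch t
#' test and a Mann-Whitney U test. Direction is reported on the
#' expression scale: `"down"` means lower expression (higher
#' delta-delta Ct) in the intermediate/high group than in the
#' low-risk group. Benjamini-Hochberg adjustment is applied across
#' the panel to the primary p-value.
#'
#' @param ddct Tibble from [delta_delta_ct()].
#' @param clinical Clinical tibble giving each sample's `risk_group`
#'   (matched on `patient_id` = `sample_id`).
#' @param primary Which test feeds `adj_p`: `"mann_whitney"`
#'   (default) or `"welch"`.
#' @return A tibble with one row per miRNA: group sizes, mean
#'   delta-delta Ct per group, `welch_p`, `mann_whitney_p`, `p_value`
#'   (the primary), `adj_p`, `direction`.
#' @export
compare_groups_ddct <- function(ddct, clinical,
                                primary = c("mann_whitney", "welch")) {
  primary <- match.arg(primary)
  grp_map <- setNames(
    ifelse(clinical$risk_group == "low", "low", "int_high"),
    clinical$patient_id
  )
  ddct$group <- unname(grp_map[ddct$sample_id])
  if (anyNA(ddct$group)) {
    abort(paste0(
      "sample(s) missing from the clinical table: ",
      paste(unique(ddct$sample_id[is.na(ddct$group)]), collapse = ", ")
    ))
  }
  out <- ddct |>
    dplyr::group_by(.data$mirna_id) |>
    dplyr::group_modify(function(d, key) {
      a <- d$delta_delta_ct[d$group == "low"]
      b <- d$delta_delta_ct[d$group == "int_high"]
      if (length(a) < 2 || length(b) < 2) {
        abort(paste0("group with < 2 samples for miRNA ", key$mirna_id))
      }
      tibble::tibble(
        n_low = length(a),
        n_int_high = length(b),
        mean_ddct_low = mean(a),
        mean_ddct_int_high = mean(b),
        welch_p = welch_t(a, b)$p_value,
        mann_whitney_p = mann_whitney(a, b)$p_value,
        direction = dplyr::if_else(mean(b) > mean(a), "down", "up")
      )
    }) |>
    dplyr::ungroup()
  out$p_value <- if (primary == "welch") out$welch_p else out$mann_whitney_p
  out$adj_p <- bh_adjust(out$p_value)
  out
}

#' Concordance between sequencing and qPCR measurements
#'
#' Pearson correlation between log2-transformed sequencing expression
#' and qPCR abundance over paired (sample, miRNA) observations. Since
#' Ct is inversely proportional to log2 template abundance, the
#' default orientation correlates against the negated delta Ct, so a
#' concordant pair of assays yields a positive r; the raw delta-Ct
#' orientation (expected negative r) is available as an option.
#'
#' @param norm Normalized long tibble from [normalize_counts()] (uses
#'   its `log2_expr` column), or any tibble with `sample_id`,
#'   `mirna_id`, `log2_expr`.
#' @param dct Delta-Ct tibble from [delta_ct()].
#' @param orientation `"neg_delta_ct"` (default) or `"delta_ct"`.
#' @return A one-row tibble: `estimate`, `p_value`, `n`, `method`,
#'   `testable`, `orientation`.
#' @export
ngs_qpcr_concordance <- function(norm, dct,
                                 orientation = c("neg_delta_ct", "delta_ct")) {
  orientation <- match.arg(orientation)
  pairs <- dplyr::inner_join(
    norm[c("sample_id", "mirna_id", "log2_expr")],
    dct[c("sample_id", "mirna_id", "delta_ct")],
    by = c("sample_id", "mirna_id")
  )
  if (nrow(pairs) < 3) {
    abort("need at least 3 paired (sample, miRNA) observations")
  }
  y <- if (orientation == "neg_delta_ct") -pairs$delta_ct else pairs$delta_ct
  res <- cor_test_pearson(pairs$log2_expr, y)
  res$orientation <- orientation
  res
}
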