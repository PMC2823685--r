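#' Per-spot m/a values from two-channel intensities
#'
#' `m = log2(test/ref)` and `a = 0.5 * log2(test * ref)` per spot. The spot
#' table labels channels by sample (test vs reference), so `m > 0` always
#' means higher expression in the test condition regardless of which dye
#' carried it; the `dye_orientation` column merely records the labelling
#' and is what dye-bias corrections condition on. Spots with non-positive
#' intensity are excluded with a message.
#'
#' @param spots Tibble with columns `gene_id`, `array_id`,
#'   `intensity_test`, `intensity_ref` (and optionally `dye_orientation`).
#' @return The spot tibble with `m` and `a` columns added.
#' @export
#' @examples
#' compute_ma(tibble::tibble(gene_id = "g", array_id = 1,
#'                           intensity_test = 800, intensity_ref = 200))
compute_ma <- function(spots) {
  bad <- spots$intensity_test <= 0 | spots$intensity_ref <= 0
  if (any(bad)) {
    message(sum(bad), " spot(s) with non-positive intensity excluded")
    spots <- spots[!bad, ]
  }
  dplyr::mutate(spots,
                m = log2(.data$intensity_test / .data$intensity_ref),
                a = 0.5 * log2(.data$intensity_test * .data$intensity_ref))
}

#' LOWESS normalization of m against a, per array
#'
#' Fits a locally weighted regression of `m` on `a` within each array and
#' subtracts the fit, removing intensity-dependent dye bias; `a` is left
#' unchanged. Arrays with fewer than `min_spots` spots are skipped with a
#' warning. Span 0.3 follows common two-colour practice.
#'
#' @param spots Tibble with `array_id`, `m`, `a` (from [compute_ma()]).
#' @param span LOWESS span (fraction of spots in each local fit).
#' @param min_spots Minimum spots per array for the fit.
#' @return The tibble with `m` replaced by the normalized value and the raw
#'   value kept in `m_raw`.
#' @export
lowess_normalize <- function(spots, span = 0.3, min_spots = 20) {
  spots |>
    dplyr::group_by(.data$array_id) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < min_spots) {
        warning(sprintf("array '%s': only %d spots; normalization skipped",
                        as.character(key$array_id), nrow(df)), call. = FALSE)
        return(dplyr::mutate(df, m_raw = .data$m))
      }
      fit <- stats::lowess(df$a, df$m, f = span)
      trend <- stats::approx(fit$x, fit$y, xout = df$a, rule = 2, ties = mean)$y
      dplyr::mutate(df, m_raw = .data$m, m = .data$m - trend)
    }) |>
    dplyr::ungroup()
}

#' Differential-expression calls with replicate-significance filtering
#'
#' Mirrors the stringent replicate filter used for corynebacterial
#' two-colour arrays: each gene is measured on `n_expected` technical
#' replicate spots (4 spots x 2 dye-swapped arrays); a gene is only
#' considered if at least `min_sig` of its spots are individually
#' significant at `alpha`, and is then called `up` when its mean m is at or
#' above `cutoff` (two-fold for cutoff 1), `down` at or below `-cutoff`,
#' else `unchanged`. Cut-offs are inclusive. Spot-level significance tests
#' each normalized m against the array-wide null spread (MAD about zero),
#' two-sided; the gene-level p is a one-sample t-test of the replicate m
#' values against zero. No multiple-testing correction is applied by
#' default (`adjust = "none"`), matching the per-test 5% rule; set
#' `adjust = "BH"` for Benjamini-Hochberg on the gene-level p.
#'
#' @param spots Tibble with `gene_id`, `array_id`, `m` (normalized) and
#'   optionally `a`.
#' @param alpha Per-spot (and gene-level) significance level.
#' @param min_sig Minimum significant spots per gene.
#' @param n_expected Expected replicate spots per gene (informational).
#' @param cutoff Absolute mean-m call threshold (inclusive).
#' @param sigma0 Null spread of m; default per-array MAD about 0.
#' @param adjust Multiple-testing adjustment for the gene-level p.
#' @return Tibble: `gene_id`, `m_mean`, `a_mean`, `n_spots`,
#'   `n_significant`, `p_value`, `call` in
#'   `{up, down, unchanged, filtered}`.
#' @export
call_differential <- function(spots, alpha = 0.05, min_sig = 6, n_expected = 8,
                              cutoff = 1.0, sigma0 = NULL, adjust = "none") {
  spots <- spots |>
    dplyr::group_by(.data$array_id) |>
    dplyr::mutate(.sigma0 = sigma0 %||% stats::mad(.data$m, center = 0)) |>
    dplyr::ungroup() |>
    dplyr::mutate(.p_spot = 2 * stats::pnorm(-abs(.data$m) / .data$.sigma0))
  calls <- spots |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      m_mean = mean(.data$m),
      a_mean = if ("a" %in% names(spots)) mean(.data$a) else NA_real_,
      n_spots = dplyr::n(),
      n_significant = sum(.data$.p_spot < alpha),
      p_value = tryCatch(stats::t.test(.data$m, mu = 0)$p.value,
                         error = function(e) NA_real_),
      .groups = "drop")
  calls$p_value <- stats::p.adjust(calls$p_value, method = adjust)
  dplyr::mutate(calls,
                call = dplyr::case_when(
                  .data$n_spots < min_sig | .data$n_significant < min_sig ~ "filtered",
                  .data$m_mean >= cutoff ~ "up",
                  .data$m_mean <= -cutoff ~ "down",
                  TRUE ~ "unchanged"))
}

#' Classify per-gene mean m values by the fold-change cut-off alone
#'
#' For published per-gene m values whose replicate filter has already been
#' applied upstream: `up` iff `m >= cutoff`, `down` iff `m <= -cutoff`
#' (inclusive), else `unchanged`.
#'
#' @param m Numeric vector of per-gene mean log2 ratios.
#' @param cutoff Inclusive threshold (default 1.0, i.e. two-fold).
#' @return Character vector of calls.
#' @export
#' @examples
#' de_call(c(1, 0.99, -1.35))
de_call <- function(m, cutoff = 1.0) {
  dplyr::case_when(m >= cutoff ~ "up", m <= -cutoff ~ "down", TRUE ~ "unchanged")
}

#' qPCR fold change from crossing points
#'
#' The relative expression change is `2^-dCP` with
#' `dCP = mean(CP_test) - mean(CP_control)` per gene: an earlier crossing
#' point in the test condition (negative dCP) means more transcript.
#'
#' @param cp Tibble with columns `gene_id`, `condition`
#'   (`"test"`/`"control"`), `cp` (replicated crossing points).
#' @return Tibble: `gene_id`, `delta_cp`, `fold_change`.
#' @export
#' @examples
#' rtpcr_fold_change(tibble::tibble(gene_id = "g",
#'   condition = c("test", "test", "control", "control"),
#'   cp = c(17, 17, 20, 20)))
rtpcr_fold_change <- function(cp) {
  stopifnot(all(cp$condition %in% c("test", "control")))
  cp |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      delta_cp = mean(.data$cp[.data$condition == "test"]) -
                 mean(.data$cp[.data$condition == "control"]),
      .groups = "drop") |>
    dplyr::mutate(fold_change = 2^-.data$delta_cp)
}

#' Integrate expression calls, qPCR and regulon membership
#'
#' Labels each gene: `direct` (up-regulated and member of a site-bearing
#' transcription unit), `indirect` (up-regulated without a site), `down`,
#' `site_without_expression_support` (site-bearing but not up-regulated,
#' the adhA pattern), else `unchanged`. When a qPCR table is supplied,
#' `rtpcr_confirmed` marks genes whose measured fold change is present and
#' at least `rtpcr_min_fold`.
#'
#' @param calls Tibble with `gene_id` and `call` (from
#'   [call_differential()] or [de_call()]).
#' @param regulon_members Tibble with a `gene_id` column (e.g.
#'   `tidy(regulon)`), or `NULL`.
#' @param rtpcr Optional tibble with `gene_id`, `fold_change` (`NA` = not
#'   significant).
#' @param rtpcr_min_fold Minimum qPCR fold for confirmation.
#' @return The calls tibble with `in_regulon`, `status`, and (if qPCR
#'   given) `rtpcr_fold`, `rtpcr_confirmed` columns.
#' @export
integrate_targets <- function(calls, regulon_members = NULL, rtpcr = NULL,
                              rtpcr_min_fold = 2) {
  site_genes <- if (is.null(regulon_members)) character() else
    unique(regulon_members$gene_id)
  out <- calls |>
    dplyr::mutate(in_regulon = .data$gene_id %in% site_genes,
                  status = dplyr::case_when(
                    .data$call == "up" & .data$in_regulon ~ "direct",
                    .data$call == "up" ~ "indirect",
                    .data$call == "down" ~ "down",
                    .data$in_regulon ~ "site_without_expression_support",
                    TRUE ~ "unchanged"))
  if (!is.null(rtpcr)) {
    out <- out |>
      dplyr::left_join(dplyr::select(rtpcr, "gene_id", rtpcr_fold = "fold_change"),
                       by = "gene_id") |>
      dplyr::mutate(rtpcr_confirmed = !is.na(.data$rtpcr_fold) &
                      .data$rtpcr_fold >= rtpcr_min_fold)
  }
  out
}

#' MA plot of expression calls
#'
#' @param calls Output of [call_differential()] (needs `a_mean`).
#' @param cutoff Horizontal guide lines at `+-cutoff`.
#' @return A ggplot.
#' @export
plot_ma <- function(calls, cutoff = 1.0) {
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$a_mean, y = .data$m_mean,
                                      colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.2) +
    ggplot2::geom_hline(yintercept = c(-cutoff, cutoff), linetype = 2,
                        colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(up = "black", down = "#D62839",
                                            unchanged = "grey70",
                                            filtered = "grey85")) +
    ggplot2::labs(x = "a (mean log2 intensity)", y = "m (log2 ratio)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
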