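#' Percentile placement of an ensemble result among single-conformer runs
#'
#' Places one ensemble-protocol metric value inside the frequency
#' distribution of the single-conformer results for the same target. With
#' `c` the number of single-run values the ensemble value strictly
#' outperforms and `k` the number of runs, the percentile is
#' `floor(100 * (c + 1) / (k + 1))`: outperforming all runs gives the 100th
#' percentile; outperforming none of `k` runs gives `floor(100 / (k + 1))`.
#' Ties never count as outperformed.
#'
#' @param mrc_value the ensemble protocol's metric value.
#' @param src_values numeric vector of the single-conformer values (length
#'   >= 1).
#' @param higher_is_better direction of the metric (`TRUE` for all five
#'   figures of merit in this package).
#' @param metric,target_id optional labels carried into the summary.
#' @return A `percentile_summary` list: `target_id`, `metric`, `src_values`,
#'   `mrc_value`, `n_outperformed`, `percentile`.
#' @examples
#' percentile_placement(0.71, c(0.72, 0.70, 0.65, 0.62, 0.61, 0.61))
#' @export
percentile_placement <- function(mrc_value, src_values,
                                 higher_is_better = TRUE,
                                 metric = NA_character_,
                                 target_id = NA_character_) {
  if (length(src_values) < 1)
    stop("src_values must hold at least one single-conformer result",
         call. = FALSE)
  c_out <- if (higher_is_better) sum(src_values < mrc_value)
           else sum(src_values > mrc_value)
  k <- length(src_values)
  structure(
    list(target_id = target_id, metric = metric,
         src_values = src_values, mrc_value = mrc_value,
         n_outperformed = c_out,
         percentile = as.integer(floor(100 * (c_out + 1) / (k + 1)))),
    class = "percentile_summary"
  )
}

#' @export
print.percentile_summary <- function(x, ...) {
  cat(sprintf("<percentile_summary> %s %s: value %.4g beats %d/%d runs -> %dth percentile\n",
              x$target_id, x$metric, x$mrc_value, x$n_outperformed,
              length(x$src_values), x$percentile))
  invisible(x)
}

#' Paired one-tailed t-test for protocol superiority
#'
#' Tests whether the ensemble protocol outperforms a per-target reference
#' (typically the mean single-conformer value): a paired t-test on the
#' differences `mrc - reference` with the one-tailed alternative "mean
#' difference > 0". Degenerate inputs are resolved before delegating to
#' [stats::t.test()]: all-zero differences give p = 0.5; zero-variance
#' differences with nonzero mean give p = 0 (positive mean) or 1 (negative).
#'
#' @param mrc_values ensemble metric value per target.
#' @param src_reference paired reference value per target (same length >= 2).
#' @return List with `t`, `df`, `p`, and `mean_difference`.
#' @export
paired_one_tailed_ttest <- function(mrc_values, src_reference) {
  if (length(mrc_values) != length(src_reference))
    stop("paired samples must have equal length", call. = FALSE)
  if (length(mrc_values) < 2)
    stop("need at least two pairs", call. = FALSE)
  d <- mrc_values - src_reference
  if (stats::sd(d) == 0) {
    m <- mean(d)
    p <- if (m == 0) 0.5 else if (m > 0) 0 else 1
    return(list(t = if (m == 0) 0 else sign(m) * Inf,
                df = length(d) - 1L, p = p, mean_difference = m))
  }
  ht <- stats::t.test(mrc_values, src_reference, paired = TRUE,
                      alternative = "greater")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_difference = mean(d))
}

#' Ideal (maximum achievable) value of a figure of merit
#'
#' @param metric one of `"auac"`, `"roc_auc"`, `"ef"`, `"rie"`, `"bedroc"`.
#' @param n number of binders.
#' @param N library size.
#' @param chi fraction (enrichment factor only).
#' @param alpha exponential parameter (RIE only).
#' @export
ideal_metric <- function(metric = c("auac", "roc_auc", "ef", "rie", "bedroc"),
                         n, N, chi = 0.01, alpha = 20) {
  metric <- match.arg(metric)
  switch(metric,
         auac = 1 - (n - 1) / (2 * N),
         roc_auc = 1,
         ef = enrichment_factor_max(n, N, chi),
         rie = rie(seq_len(n), N, alpha),
         bedroc = 1)
}

#' Benchmark ensemble protocols against single-conformer runs
#'
#' For every target, computes each figure of merit for every single-conformer
#' run and for each requested combination protocol, then summarizes the
#' single-run distribution (min / max / mean), the ideal value, and the
#' percentile placement of each protocol.
#'
#' @param screens a named list of [ensemble_screen] (or a single screen).
#' @param methods combination protocols to evaluate (any method accepted by
#'   [combine_screen()]).
#' @param metrics subset of `c("auac", "roc_auc", "ef", "rie", "bedroc")`;
#'   `"ef"` expands to one row per `chi`.
#' @param chi_values enrichment-factor fractions.
#' @param alpha RIE/BEDROC parameter.
#' @param relabel_chemotypes if `TRUE`, metrics are computed after
#'   [chemotype_representative_relabel()] on each ranked list (requires every
#'   binder chemotyped).
#' @return A data frame with one row per target x metric x method and columns
#'   `target`, `metric`, `n_conformers`, `src_min`, `src_max`, `src_mean`,
#'   `method`, `value`, `percentile`, `n_outperformed`, `ideal`.
#' @export
benchmark_report <- function(screens, methods = c("mrc_score", "mrc_rank"),
                             metrics = c("auac", "ef", "bedroc"),
                             chi_values = 0.01, alpha = 20,
                             relabel_chemotypes = FALSE) {
  if (inherits(screens, "ensemble_screen"))
    screens <- stats::setNames(list(screens), screens$target_id)
  rows <- lapply(screens, function(screen) {
    benchmark_one_target(screen, methods, metrics, chi_values, alpha,
                         relabel_chemotypes)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

metric_value <- function(ranked, library, metric, chi, alpha) {
  switch(metric,
         auac = auac(ranked, library),
         roc_auc = roc_auc(ranked, library),
         ef = enrichment_factor(ranked, chi, library),
         rie = rie(binder_ranks(ranked, library), nrow(ranked), alpha),
         bedroc = bedroc(binder_ranks(ranked, library), nrow(ranked), alpha),
         stop("unknown metric ", metric, call. = FALSE))
}

benchmark_one_target <- function(screen, methods, metrics, chi_values,
                                 alpha, relabel_chemotypes) {
  lib <- screen$library
  k <- nrow(screen$scores)
  src <- lapply(rownames(screen$scores),
                function(cf) rank_single_run(screen, conformer = cf))
  mrc <- lapply(methods, function(m) combine_screen(screen, method = m))
  names(mrc) <- methods
  eval_lib <- function(ranked) {
    if (relabel_chemotypes) chemotype_representative_relabel(ranked, lib)
    else lib
  }
  spec <- expand_metric_spec(metrics, chi_values)
  do.call(rbind, lapply(seq_len(nrow(spec)), function(i) {
    metric <- spec$metric[i]; chi <- spec$chi[i]
    src_vals <- vapply(src, function(r)
      metric_value(r, eval_lib(r), metric, chi, alpha), numeric(1))
    do.call(rbind, lapply(methods, function(m) {
      l <- eval_lib(mrc[[m]])
      v <- metric_value(mrc[[m]], l, metric, chi, alpha)
      pp <- percentile_placement(v, src_vals, metric = spec$label[i],
                                 target_id = screen$target_id)
      data.frame(target = screen$target_id, metric = spec$label[i],
                 n_conformers = k,
                 src_min = min(src_vals), src_max = max(src_vals),
                 src_mean = mean(src_vals),
                 method = m, value = v,
                 percentile = pp$percentile,
                 n_outperformed = pp$n_outperformed,
                 ideal = ideal_metric(metric, sum(l$is_binder), nrow(l),
                                      chi, alpha),
                 stringsAsFactors = FALSE)
    }))
  }))
}

expand_metric_spec <- function(metrics, chi_values) {
  rows <- lapply(metrics, function(m) {
    if (m == "ef")
      data.frame(metric = "ef", chi = chi_values,
                 label = paste0("ef_", format_chi(chi_values)),
                 stringsAsFactors = FALSE)
    else data.frame(metric = m, chi = NA_real_, label = m,
                    stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Histogram table of metric values across targets
#'
#' Fixed-width binning of a \[0, 1\] figure of merit across targets, the
#' tabular backing of cross-target frequency-distribution figures.
#'
#' @param values numeric metric values.
#' @param width bin width (default 0.05).
#' @param limits histogram range.
#' @return Data frame with `bin_low`, `bin_high`, `count`.
#' @export
metric_histogram <- function(values, width = 0.05, limits = c(0, 1)) {
  breaks <- seq(limits[1], limits[2], by = width)
  if (breaks[length(breaks)] < limits[2])
    breaks <- c(breaks, limits[2])
  h <- graphics::hist(pmin(pmax(values, limits[1]), limits[2]),
                      breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = TRUE)
  data.frame(bin_low = utils::head(breaks, -1),
             bin_high = breaks[-1],
             count = h$counts)
}
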