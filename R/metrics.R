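#' Accumulation curve of a ranked screen
#'
#' The accumulation curve F_a(k) counts how many true binders obtained a rank
#' better than or equal to k. It carries all the information the five figures
#' of merit need.
#'
#' @param ranked a `ranked_list` from [rank_single_run()] or a combination
#'   protocol.
#' @param library the [ligand_library] with binder annotations.
#' @return An `accumulation_curve`: integer vector F_a(1..N) with attributes
#'   `n` (number of binders) and `N` (library size).
#' @examples
#' lib <- ligand_library(paste0("L", 1:4), 300, c(TRUE, FALSE, TRUE, FALSE))
#' r <- rank_single_run(c(L1 = -9, L2 = -8, L3 = -7, L4 = -6), lib)
#' accumulation_curve(r, lib) # 1 1 2 2
#' @export
accumulation_curve <- function(ranked, library) {
  br <- binder_ranks(ranked, library)
  N <- nrow(ranked)
  fa <- cumsum(tabulate(br, nbins = N))
  structure(fa, n = length(br), N = N, class = "accumulation_curve")
}

#' Ranks of the binders in a ranked list
#'
#' @inheritParams accumulation_curve
#' @return Sorted integer vector of binder rank positions; errors when the
#'   library holds no binder (every metric is undefined without actives).
#' @export
binder_ranks <- function(ranked, library) {
  if (!setequal(ranked$ligand_id, library$ligand_id))
    stop("ranked list does not cover the library", call. = FALSE)
  binders <- library$ligand_id[library$is_binder]
  if (length(binders) == 0)
    stop("metrics undefined without actives: library has no binder",
         call. = FALSE)
  sort(ranked$rank[ranked$ligand_id %in% binders])
}

#' Area under the accumulation curve
#'
#' AUAC = (1/(nN)) * sum_k F_a(k). An ideal ranking gives 1 - (n-1)/(2N); the
#' worst possible ranking gives (n+1)/(2N); higher is better.
#'
#' @param curve an [accumulation_curve], or a `ranked_list` (then `library`
#'   is required).
#' @param library ligand library, only when `curve` is a ranked list.
#' @return AUAC in (0, 1).
#' @export
auac <- function(curve, library = NULL) {
  curve <- as_accumulation_curve(curve, library)
  n <- attr(curve, "n"); N <- attr(curve, "N")
  sum(as.numeric(curve)) / (n * N)
}

as_accumulation_curve <- function(curve, library) {
  if (inherits(curve, "accumulation_curve")) return(curve)
  accumulation_curve(curve, library)
}

#' Area under the ROC curve
#'
#' The probability that a randomly chosen binder is ranked better than a
#' randomly chosen decoy (Mann-Whitney form); pairs tied on the primary sort
#' key receive half credit. For a tie-free ranking this equals the linear
#' transform of the AUAC, (N * AUAC - (n+1)/2) / (N - n).
#'
#' @inheritParams accumulation_curve
#' @return ROC AUC in \[0, 1\].
#' @export
roc_auc <- function(ranked, library) {
  if (!setequal(ranked$ligand_id, library$ligand_id))
    stop("ranked list does not cover the library", call. = FALSE)
  is_b <- library$is_binder[match(ranked$ligand_id, library$ligand_id)]
  n <- sum(is_b); m <- sum(!is_b)
  if (n == 0) stop("metrics undefined without actives", call. = FALSE)
  if (m == 0) stop("ROC undefined without decoys", call. = FALSE)
  # average ranks of the primary key (lower key = better); the Mann-Whitney
  # identity turns the binder rank-sum into wins + half the ties
  r <- rank(ranked$primary_key, ties.method = "average")
  wins <- sum(r[!is_b]) - m * (m + 1) / 2
  wins / (n * m)
}

#' Enrichment factor at an early-recognition fraction
#'
#' EF_chi = F_a(floor(chi * N)) / (n * chi): how many more binders sit in the
#' top fraction chi of the list than a uniformly random ordering would put
#' there. Its maximum is min(n, floor(chi * N)) / (n * chi).
#'
#' @param curve an [accumulation_curve] (or `ranked_list` plus `library`).
#' @param chi early-recognition fraction in (0, 1\]; `floor(chi * N)` must be
#'   at least 1.
#' @param library ligand library, only when `curve` is a ranked list.
#' @return Non-negative enrichment factor.
#' @export
enrichment_factor <- function(curve, chi, library = NULL) {
  curve <- as_accumulation_curve(curve, library)
  n <- attr(curve, "n"); N <- attr(curve, "N")
  k <- floor(chi * N)
  if (k < 1)
    stop("fraction too small for library size: floor(chi * N) = 0",
         call. = FALSE)
  curve[[k]] / (n * chi)
}

#' Maximum achievable enrichment factor
#'
#' @param n number of binders.
#' @param N library size.
#' @param chi early-recognition fraction.
#' @export
enrichment_factor_max <- function(n, N, chi) {
  k <- floor(chi * N)
  if (k < 1)
    stop("fraction too small for library size: floor(chi * N) = 0",
         call. = FALSE)
  min(n, k) / (n * chi)
}

#' Robust initial enhancement
#'
#' Exponentially rank-weighted enrichment: RIE =
#' sum_i exp(-alpha r_i / N) / \[(n/N) (1 - e^-alpha) / (e^(alpha/N) - 1)\],
#' where r_i are the binder ranks. The denominator is the expectation of the
#' numerator under a uniformly random ordering, so a random ranking has RIE
#' close to 1 and the smoothing parameter alpha plays the role the fraction
#' chi plays for the enrichment factor.
#'
#' @param ranks integer vector of binder ranks (1-based).
#' @param N library size.
#' @param alpha exponential weight parameter (> 0); 20 is the conventional
#'   early-recognition choice.
#' @return RIE value.
#' @export
rie <- function(ranks, N, alpha = 20) {
  stopifnot(alpha > 0, N >= 1, all(ranks >= 1), all(ranks <= N))
  n <- length(ranks)
  num <- sum(exp(-alpha * ranks / N))
  denom <- (n / N) * (1 - exp(-alpha)) / (exp(alpha / N) - 1)
  num / denom
}

#' Boltzmann-enhanced discrimination of ROC
#'
#' BEDROC standardizes the RIE to \[0, 1\]:
#' (RIE - RIE_min) / (RIE_max - RIE_min), where RIE_max and RIE_min are the
#' RIE of the ideal ordering (binders at ranks 1..n) and of the worst
#' ordering (binders at ranks N-n+1..N). The standardization is evaluated
#' numerically from the same formula, so BEDROC is exactly 1 and 0 at the two
#' endpoints for every (n, N, alpha).
#'
#' @inheritParams rie
#' @return BEDROC in \[0, 1\].
#' @export
bedroc <- function(ranks, N, alpha = 20) {
  n <- length(ranks)
  stopifnot(n < N)
  r <- rie(ranks, N, alpha)
  r_max <- rie(seq_len(n), N, alpha)
  r_min <- rie(seq.int(N - n + 1L, N), N, alpha)
  (r - r_min) / (r_max - r_min)
}

#' Full metric report for a ranked list
#'
#' Bundles the five figures of merit for one ranked screen: AUAC, ROC AUC,
#' enrichment factors at the requested fractions, RIE and BEDROC.
#'
#' @inheritParams accumulation_curve
#' @param chi_values early-recognition fractions for the enrichment factor;
#'   defaults to 1% and 10%.
#' @param alpha RIE/BEDROC exponential parameter.
#' @return A `metric_report` list with elements `auac`, `roc_auc`, `ef`
#'   (named by fraction), `rie`, `bedroc`, `n_binders`, `n_total`, `alpha`,
#'   `chi_values`, `method`, `target_id`.
#' @export
metric_report <- function(ranked, library, chi_values = c(0.01, 0.10),
                          alpha = 20) {
  curve <- accumulation_curve(ranked, library)
  n <- attr(curve, "n"); N <- attr(curve, "N")
  br <- binder_ranks(ranked, library)
  ef <- vapply(chi_values, function(chi) enrichment_factor(curve, chi),
               numeric(1))
  names(ef) <- format_chi(chi_values)
  structure(
    list(auac = auac(curve),
         roc_auc = roc_auc(ranked, library),
         ef = ef,
         rie = rie(br, N, alpha),
         bedroc = bedroc(br, N, alpha),
         n_binders = n, n_total = N,
         alpha = alpha, chi_values = chi_values,
         method = attr(ranked, "method"),
         target_id = attr(ranked, "target_id")),
    class = "metric_report"
  )
}

format_chi <- function(chi) paste0(formatC(100 * chi, format = "fg"), "%")

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> target %s, method %s (n = %d, N = %d)\n",
              x$target_id, x$method, x$n_binders, x$n_total))
  cat(sprintf("  AUAC %.4f | ROC AUC %.4f | RIE %.3f | BEDROC %.4f (alpha = %g)\n",
              x$auac, x$roc_auc, x$rie, x$bedroc, x$alpha))
  cat("  EF:", paste(sprintf("%s = %.2f", names(x$ef), x$ef),
                     collapse = ", "), "\n")
  invisible(x)
}

#' Truncate to a fixed number of decimals
#'
#' Published per-target tables in this field typically truncate (not round)
#' to one decimal; this helper reproduces that convention when comparing
#' against printed values. The metric functions themselves always return full
#' precision.
#'
#' @param x numeric.
#' @param digits decimals kept.
#' @export
truncate_decimals <- function(x, digits = 1) {
  trunc(x * 10^digits) / 10^digits
}
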