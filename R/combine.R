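#' Combine an ensemble screen by best score
#'
#' The best-score ensemble protocol: every ligand keeps the single most
#' favorable (minimum) score it achieved across the conformer runs; the
#' merged list is sorted ascending on that score. Ligands tied on the best
#' score are ordered by lower molecular weight, then ligand id, and each
#' ligand appears exactly once (duplicate removal is implicit in the
#' per-ligand minimum).
#'
#' @param screen an [ensemble_screen] with at least one run.
#' @return A `ranked_list` with `method = "mrc_score"`; `primary_key` is the
#'   best score, `secondary_key` the molecular weight used for tie-breaks.
#' @export
combine_mrc_score <- function(screen) {
  lib <- screen$library
  best <- apply(screen$scores, 2, min)
  ord <- order_ligands(list(best), lib$mw, lib$ligand_id)
  new_ranked_list(lib$ligand_id[ord], unname(best[ord]), lib$mw[ord],
                  method = "mrc_score", target_id = screen$target_id)
}

#' Combine an ensemble screen by best rank
#'
#' The best-rank ensemble protocol: each run is ranked on its own, then every
#' ligand keeps the best (minimum) rank it obtained across runs. Because up
#' to one ligand per run can hold rank 1, best ranks are heavily tied; ties
#' are resolved by the ligand's best score across runs, then molecular
#' weight, then ligand id.
#'
#' @inheritParams combine_mrc_score
#' @return A `ranked_list` with `method = "mrc_rank"`; `primary_key` is the
#'   best per-run rank, `secondary_key` the best score.
#' @export
combine_mrc_rank <- function(screen) {
  lib <- screen$library
  rk <- rank_matrix(screen)
  best_rank <- apply(rk, 2, min)
  best_score <- apply(screen$scores, 2, min)
  ord <- order_ligands(list(best_rank, best_score), lib$mw, lib$ligand_id)
  new_ranked_list(lib$ligand_id[ord], unname(best_rank[ord]),
                  unname(best_score[ord]),
                  method = "mrc_rank", target_id = screen$target_id)
}

#' Alternative ensemble combination schemes
#'
#' Documented alternatives to the two main protocols, provided for
#' completeness; none is expected to outperform [combine_mrc_score()] or
#' [combine_mrc_rank()].
#'
#' * `mrc_rank_deep`: best rank, with ties broken by the second-best then
#'   third-best per-run rank.
#' * `boltzmann_score`: soft-minimum key `-T * log(sum_j exp(-s_j / T))`
#'   over the per-run scores; converges to the best-score protocol as the
#'   temperature `T` approaches 0. The functional form is this package's own
#'   reconstruction, not a published formula.
#' * `boltzmann_score_mw`: the same key plus an additive molecular-weight
#'   penalty `lambda * mw` (`lambda = 0` disables the penalty, leaving only
#'   the usual weight tie-break).
#' * `rank_consensus`: key = the sum of the ligand's ranks over every run.
#'
#' @inheritParams combine_mrc_score
#' @param method one of `"mrc_rank_deep"`, `"boltzmann_score"`,
#'   `"boltzmann_score_mw"`, `"rank_consensus"` (the two main protocols are
#'   accepted too and dispatched to their dedicated functions).
#' @param temperature Boltzmann temperature `T` in score units (> 0).
#' @param lambda molecular-weight penalty weight for `boltzmann_score_mw`,
#'   in key units per Dalton.
#' @return A `ranked_list` whose `method` attribute names the scheme.
#' @export
combine_alternative <- function(screen,
                                method = c("mrc_rank_deep", "boltzmann_score",
                                           "boltzmann_score_mw",
                                           "rank_consensus", "mrc_score",
                                           "mrc_rank"),
                                temperature = 1, lambda = 0) {
  method <- match.arg(method)
  lib <- screen$library
  switch(
    method,
    mrc_score = combine_mrc_score(screen),
    mrc_rank = combine_mrc_rank(screen),
    mrc_rank_deep = {
      rk <- rank_matrix(screen)
      # best, 2nd-best, 3rd-best rank per ligand (absent depths fall back to
      # the worst possible rank so single-run ensembles still sort)
      depth <- function(d) apply(rk, 2, function(r)
        if (length(r) >= d) sort(r, partial = d)[d] else ncol(rk) + 1L)
      k1 <- depth(1); k2 <- depth(2); k3 <- depth(3)
      ord <- order_ligands(list(k1, k2, k3), lib$mw, lib$ligand_id)
      new_ranked_list(lib$ligand_id[ord], unname(k1[ord]), unname(k2[ord]),
                      method = "mrc_rank_deep", target_id = screen$target_id)
    },
    boltzmann_score = {
      key <- boltzmann_key(screen$scores, temperature)
      ord <- order_ligands(list(key), lib$mw, lib$ligand_id)
      new_ranked_list(lib$ligand_id[ord], unname(key[ord]), lib$mw[ord],
                      method = "boltzmann_score", target_id = screen$target_id)
    },
    boltzmann_score_mw = {
      key <- boltzmann_key(screen$scores, temperature) + lambda * lib$mw
      ord <- order_ligands(list(key), lib$mw, lib$ligand_id)
      new_ranked_list(lib$ligand_id[ord], unname(key[ord]), lib$mw[ord],
                      method = "boltzmann_score_mw",
                      target_id = screen$target_id)
    },
    rank_consensus = {
      rk <- rank_matrix(screen)
      key <- colSums(rk)
      ord <- order_ligands(list(key), lib$mw, lib$ligand_id)
      new_ranked_list(lib$ligand_id[ord], unname(key[ord]), lib$mw[ord],
                      method = "rank_consensus", target_id = screen$target_id)
    }
  )
}

# numerically stable soft minimum: -T log sum_j exp(-s_j / T)
boltzmann_key <- function(scores, temperature) {
  stopifnot(temperature > 0)
  apply(scores, 2, function(s) {
    m <- min(s)
    m - temperature * log(sum(exp(-(s - m) / temperature)))
  })
}

#' Combine a screen with any supported method
#'
#' Thin dispatcher used by the pipeline and the command-line interface.
#'
#' @inheritParams combine_alternative
#' @export
combine_screen <- function(screen, method = "mrc_rank", temperature = 1,
                           lambda = 0) {
  combine_alternative(screen, method = method, temperature = temperature,
                      lambda = lambda)
}

#' Write a ranked list to a delimited file
#'
#' @param ranked a `ranked_list`.
#' @param path output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @export
write_ranked_list <- function(ranked, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  out <- data.frame(
    target = attr(ranked, "target_id"),
    rank = ranked$rank,
    ligand = ranked$ligand_id,
    primary_key = signif(ranked$primary_key, 6),
    secondary_key = signif(ranked$secondary_key, 6),
    method = attr(ranked, "method"),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
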