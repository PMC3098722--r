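#' Drop degenerate all-positive-score runs
#'
#' A conformer run in which every ligand receives a strictly positive score
#' found no favorable pose for anything; such runs track enrichment factors
#' below 1 (worse than random picking) and only inject noise into ensemble
#' combinations. This filter removes every run whose minimum score is
#' strictly greater than zero. A run containing even one score <= 0 is always
#' kept, and the filter is idempotent.
#'
#' @param screen an [ensemble_screen].
#' @return A list with elements `screen` (the reduced ensemble; flagged
#'   `excluded = TRUE` when no run survives), `removed` (character vector of
#'   dropped conformer ids) and `excluded` (logical).
#' @export
drop_all_positive_runs <- function(screen) {
  run_min <- apply(screen$scores, 1, min)
  bad <- run_min > 0
  removed <- rownames(screen$scores)[bad]
  out <- screen
  out$scores <- screen$scores[!bad, , drop = FALSE]
  out$excluded <- nrow(out$scores) == 0L
  list(screen = out, removed = removed, excluded = out$excluded)
}

#' Drop runs whose early enrichment falls below a threshold
#'
#' Retrospective companion to [drop_all_positive_runs()]: removes every
#' conformer run whose 1% enrichment factor is below `threshold` (default 1,
#' i.e. worse than random picking). In retrospective screens the all-positive
#' and the EF-below-1 criteria tend to select the same runs, but the score
#' criterion needs no activity annotations, so the two filters are kept
#' separate rather than assumed equivalent; this one requires binder labels.
#'
#' @param screen an [ensemble_screen] whose library has binder annotations.
#' @param chi enrichment fraction (default 1%).
#' @param threshold minimum EF to keep a run.
#' @return Same shape as [drop_all_positive_runs()]: `screen`, `removed`,
#'   `excluded`.
#' @export
drop_low_ef_runs <- function(screen, chi = 0.01, threshold = 1) {
  ef <- vapply(rownames(screen$scores), function(cf)
    enrichment_factor(rank_single_run(screen, conformer = cf), chi,
                      screen$library),
    numeric(1))
  bad <- ef < threshold
  out <- screen
  out$scores <- screen$scores[!bad, , drop = FALSE]
  out$excluded <- nrow(out$scores) == 0L
  list(screen = out, removed = rownames(screen$scores)[bad],
       excluded = out$excluded)
}

#' Exclude co-crystallized binders and their chemotype analogs
#'
#' Receptor conformers extracted from co-crystals retain a memory of their
#' cognate ligand, so self-docking can inflate ensemble results. This filter
#' deletes from the library (i) every binder co-crystallized with a conformer
#' present in the screen and (ii) every binder sharing a chemotype with such
#' a co-crystallized binder. Decoys are never touched. Binders are deleted,
#' not relabeled, so the binder count n is recomputed on the filtered set.
#'
#' @param screen the [ensemble_screen] whose conformers define "present".
#' @param library the [ligand_library]; defaults to the screen's own library.
#' @return A list with `library` (the filtered library), `removed_binders`,
#'   `removed_chemotypes` (character vectors) and `excluded` (`TRUE` when no
#'   binder survives, in which case the target cannot be analyzed this way).
#'   A `cocrystal_of` naming a conformer absent from the screen triggers a
#'   warning and no removal.
#' @export
cognate_ligand_filter <- function(screen, library = NULL) {
  if (is.null(library)) library <- screen$library
  library <- validate_ligand_library(library)
  confs <- conformer_ids(screen)
  has_coc <- !is.na(library$cocrystal_of)
  unknown <- has_coc & !(library$cocrystal_of %in% confs)
  if (any(unknown))
    warning("cocrystal_of names conformer(s) absent from the screen (no ",
            "removal): ",
            paste(unique(library$cocrystal_of[unknown]), collapse = ", "),
            call. = FALSE)
  cocrystallized <- has_coc & library$cocrystal_of %in% confs
  tainted_chem <- unique(stats::na.omit(library$chemotype[cocrystallized]))
  drop <- cocrystallized |
    (library$is_binder & !is.na(library$chemotype) &
       library$chemotype %in% tainted_chem)
  removed_binders <- library$ligand_id[drop]
  out <- library[!drop, , drop = FALSE]
  class(out) <- c("ligand_library", "data.frame")
  list(library = out,
       removed_binders = removed_binders,
       removed_chemotypes = tainted_chem,
       excluded = sum(out$is_binder) == 0L)
}
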