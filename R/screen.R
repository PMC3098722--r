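#' Construct an ensemble screen
#'
#' An ensemble screen holds the complete result of docking one ligand library
#' against every member of a target's receptor-conformer ensemble: a score
#' matrix with one row per conformer run and one column per ligand. Scores
#' follow the empirical docking convention that lower (more negative) is more
#' favorable. Every run must score every ligand; missing scores are a hard
#' error, never imputed.
#'
#' @param target_id target identifier.
#' @param scores numeric matrix, conformers x ligands, with rownames the
#'   conformer ids and colnames the ligand ids.
#' @param library the [ligand_library] screened; its ligand set must equal the
#'   matrix columns.
#' @return An `ensemble_screen` object.
#' @export
ensemble_screen <- function(target_id, scores, library) {
  if (!is.matrix(scores) || !is.numeric(scores))
    stop("scores must be a numeric matrix (conformers x ligands)", call. = FALSE)
  if (is.null(rownames(scores)) || is.null(colnames(scores)))
    stop("scores matrix needs conformer rownames and ligand colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(scores)))
    stop("conformer ids must be unique within a target", call. = FALSE)
  library <- validate_ligand_library(library)
  if (!setequal(colnames(scores), library$ligand_id) ||
      ncol(scores) != nrow(library))
    stop("score matrix columns must match the ligand library exactly",
         call. = FALSE)
  if (anyNA(scores))
    stop("missing scores in target ", target_id,
         ": every conformer must score every ligand", call. = FALSE)
  scores <- scores[, library$ligand_id, drop = FALSE]
  structure(
    list(target_id = as.character(target_id), scores = scores,
         library = library, excluded = FALSE),
    class = "ensemble_screen"
  )
}

#' @export
print.ensemble_screen <- function(x, ...) {
  cat(sprintf("<ensemble_screen> target %s: %d conformer run(s) x %d ligands%s\n",
              x$target_id, nrow(x$scores), ncol(x$scores),
              if (isTRUE(x$excluded)) " [excluded]" else ""))
  invisible(x)
}

#' @export
#' @rdname ensemble_screen
#' @param x an `ensemble_screen`.
conformer_ids <- function(x) rownames(x$scores)

#' Read a long-form docking score table
#'
#' The table has header columns `target`, `conformer`, `ligand`, `score`
#' (tab-separated by default), one row per docked ligand-conformer pair.
#' Each distinct target becomes one [ensemble_screen] built against the
#' supplied annotation library (or a minimal stand-in library when
#' `annotations` is `NULL`, usable for ranking but not for binder metrics).
#'
#' @param path file path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param annotations optional [ligand_library] shared by all targets, or a
#'   named list of libraries keyed by target id.
#' @param invert_scores if `TRUE`, scores are negated on load, for engines
#'   that emit higher-is-better scores.
#' @return Named list of [ensemble_screen], one per target; empty list (with
#'   a warning) for a header-only file.
#' @export
read_score_table <- function(path, dialect = c("tsv", "csv"),
                             annotations = NULL, invert_scores = FALSE) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", strip.white = TRUE,
                           quote = "\"", comment.char = "")
  needed <- c("target", "conformer", "ligand", "score")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0)
    stop("score table ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(raw) == 0) {
    warning("score table ", path, " has a header but no rows", call. = FALSE)
    return(structure(list(), names = character(0)))
  }
  score <- suppressWarnings(as.numeric(raw$score))
  bad <- which(is.na(score))
  if (length(bad) > 0)
    stop("non-numeric score at line ", bad[1] + 1L, " of ", path,
         call. = FALSE)
  if (invert_scores) score <- -score
  screens <- lapply(split(seq_len(nrow(raw)), raw$target), function(idx) {
    tgt <- raw$target[idx[1]]
    confs <- unique(raw$conformer[idx])
    ligs <- unique(raw$ligand[idx])
    m <- matrix(NA_real_, nrow = length(confs), ncol = length(ligs),
                dimnames = list(confs, ligs))
    key <- cbind(match(raw$conformer[idx], confs), match(raw$ligand[idx], ligs))
    if (anyDuplicated(key) > 0)
      stop("duplicate (conformer, ligand) row for target ", tgt, call. = FALSE)
    m[key] <- score[idx]
    if (anyNA(m)) {
      holes <- which(is.na(m), arr.ind = TRUE)
      stop("incomplete coverage for target ", tgt, ": ",
           paste(sprintf("(%s, %s, %s)", tgt, confs[holes[, 1]],
                         ligs[holes[, 2]]), collapse = ", "),
           call. = FALSE)
    }
    lib <- resolve_annotations(annotations, tgt, ligs)
    ensemble_screen(tgt, m, lib)
  })
  screens[order(names(screens))]
}

resolve_annotations <- function(annotations, target, ligand_ids) {
  if (is.null(annotations)) {
    # stand-in library: unit weights, everything a decoy; enough to rank,
    # not enough to compute binder metrics
    return(ligand_library(ligand_ids, mw = 1, is_binder = FALSE))
  }
  lib <- if (inherits(annotations, "ligand_library")) annotations
         else annotations[[target]]
  if (is.null(lib))
    stop("no annotations provided for target ", target, call. = FALSE)
  missing_ligs <- setdiff(ligand_ids, lib$ligand_id)
  if (length(missing_ligs) > 0)
    stop("ligand(s) absent from annotations for target ", target, ": ",
         paste(utils::head(missing_ligs, 5), collapse = ", "), call. = FALSE)
  validate_ligand_library(lib[match(ligand_ids, lib$ligand_id), ,
                               drop = FALSE])
}

#' Write ensemble screens back to a long-form score table
#'
#' @param screens a single [ensemble_screen] or a list of them.
#' @param path output file path.
#' @param dialect `"tsv"` or `"csv"`.
#' @export
write_score_table <- function(screens, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  if (inherits(screens, "ensemble_screen")) screens <- list(screens)
  rows <- do.call(rbind, lapply(screens, function(s) {
    data.frame(
      target = s$target_id,
      conformer = rep(rownames(s$scores), times = ncol(s$scores)),
      ligand = rep(colnames(s$scores), each = nrow(s$scores)),
      score = signif(as.vector(s$scores), 6),
      stringsAsFactors = FALSE
    )
  }))
  utils::write.table(rows, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Deterministic multi-key ordering shared by every ranking routine: earlier
# keys dominate, the trailing keys are always molecular weight then ligand id
# so that any ranking is a total order.
order_ligands <- function(keys, mw, ligand_id) {
  do.call(order, c(unname(keys), list(mw, ligand_id)))
}

new_ranked_list <- function(ligand_id, primary_key, secondary_key,
                            method, target_id) {
  out <- data.frame(
    rank = seq_along(ligand_id),
    ligand_id = ligand_id,
    primary_key = primary_key,
    secondary_key = secondary_key,
    stringsAsFactors = FALSE
  )
  attr(out, "method") <- method
  attr(out, "target_id") <- target_id
  class(out) <- c("ranked_list", "data.frame")
  out
}

#' @export
print.ranked_list <- function(x, ...) {
  cat(sprintf("<ranked_list> target %s, method %s, %d ligands\n",
              attr(x, "target_id"), attr(x, "method"), nrow(x)))
  NextMethod()
}

#' Rank one single-conformer run
#'
#' Orders the library by ascending docking score (lower = better). Score ties
#' are broken in favor of the lower molecular weight, then lexicographic
#' ligand id, so the resulting ranks are dense, 1-based and deterministic.
#'
#' @param scores named numeric vector of scores covering the whole library,
#'   or an [ensemble_screen] together with `conformer`.
#' @param library the [ligand_library].
#' @param conformer when `scores` is an `ensemble_screen`, which run to rank.
#' @return A `ranked_list` data frame (columns `rank`, `ligand_id`,
#'   `primary_key` = score, `secondary_key` = molecular weight) with
#'   attributes `method = "SRC"` and `target_id`.
#' @examples
#' lib <- ligand_library(c("A", "B", "C"), c(300, 250, 280), c(TRUE, FALSE, FALSE))
#' rank_single_run(c(A = -30, B = -20, C = -25), lib)
#' @export
rank_single_run <- function(scores, library, conformer = NULL) {
  target_id <- NA_character_
  if (inherits(scores, "ensemble_screen")) {
    screen <- scores
    if (is.null(conformer)) {
      if (nrow(screen$scores) != 1L)
        stop("specify `conformer` for a multi-run ensemble", call. = FALSE)
      conformer <- rownames(screen$scores)[1]
    }
    if (!conformer %in% rownames(screen$scores))
      stop("unknown conformer ", conformer, call. = FALSE)
    if (missing(library) || is.null(library)) library <- screen$library
    target_id <- screen$target_id
    scores <- screen$scores[conformer, ]
  }
  library <- validate_ligand_library(library)
  if (!setequal(names(scores), library$ligand_id) ||
      length(scores) != nrow(library))
    stop("run must score exactly the library's ligand set", call. = FALSE)
  s <- scores[library$ligand_id]
  ord <- order_ligands(list(s), library$mw, library$ligand_id)
  new_ranked_list(library$ligand_id[ord], unname(s[ord]), library$mw[ord],
                  method = "SRC", target_id = target_id)
}

# rank position of every ligand (named vector, library order) in one run
run_rank_vector <- function(scores, library) {
  s <- scores[library$ligand_id]
  ord <- order_ligands(list(s), library$mw, library$ligand_id)
  r <- integer(length(ord))
  r[ord] <- seq_along(ord)
  names(r) <- library$ligand_id
  r
}

#' Per-run rank matrix of an ensemble screen
#'
#' @param screen an [ensemble_screen].
#' @return Integer matrix, conformers x ligands, of dense 1-based ranks using
#'   the [rank_single_run()] tie-break rules.
#' @export
rank_matrix <- function(screen) {
  t(vapply(seq_len(nrow(screen$scores)),
           function(i) run_rank_vector(screen$scores[i, ], screen$library),
           integer(ncol(screen$scores)))) |>
    `rownames<-`(rownames(screen$scores))
}
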