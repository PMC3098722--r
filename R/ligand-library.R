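#' Construct and validate a ligand library
#'
#' A ligand library is the annotation table for one screened compound
#' collection: one row per molecule with its molecular weight, its activity
#' label (known binder vs *bona fide* decoy), an optional chemotype (scaffold
#' cluster) label for binders, and an optional co-crystal provenance pointing
#' at the receptor conformer the binder was crystallized with.
#'
#' Invariants enforced: ligand ids unique; molecular weights strictly
#' positive; decoys carry neither a chemotype nor a co-crystal annotation.
#'
#' @param ligand_id character vector of unique ligand identifiers.
#' @param mw positive molecular weights in Dalton.
#' @param is_binder logical, `TRUE` for annotated binders.
#' @param chemotype optional chemotype labels (binders only); `NA` elsewhere.
#' @param cocrystal_of optional conformer id the binder was co-crystallized
#'   with; `NA` elsewhere.
#' @return A `ligand_library`, a data frame with the five columns above.
#' @examples
#' ligand_library(c("L1", "D1"), c(250.3, 310), c(TRUE, FALSE),
#'                chemotype = c("C1", NA))
#' @export
ligand_library <- function(ligand_id, mw, is_binder,
                           chemotype = NA_character_,
                           cocrystal_of = NA_character_) {
  lib <- data.frame(
    ligand_id = as.character(ligand_id),
    mw = as.numeric(mw),
    is_binder = as.logical(is_binder),
    chemotype = rep_len(as.character(chemotype), length(ligand_id)),
    cocrystal_of = rep_len(as.character(cocrystal_of), length(ligand_id)),
    stringsAsFactors = FALSE
  )
  validate_ligand_library(lib)
}

#' @rdname ligand_library
#' @param lib a data frame with columns `ligand_id`, `mw`, `is_binder`,
#'   `chemotype`, `cocrystal_of`.
#' @export
validate_ligand_library <- function(lib) {
  needed <- c("ligand_id", "mw", "is_binder", "chemotype", "cocrystal_of")
  missing_cols <- setdiff(needed, names(lib))
  if (length(missing_cols) > 0)
    stop("ligand library is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  dup <- unique(lib$ligand_id[duplicated(lib$ligand_id)])
  if (length(dup) > 0)
    stop("duplicate ligand_id: ", paste(dup, collapse = ", "), call. = FALSE)
  if (anyNA(lib$mw) || any(lib$mw <= 0))
    stop("molecular weight must be a positive number for every ligand",
         call. = FALSE)
  if (anyNA(lib$is_binder))
    stop("is_binder must be TRUE or FALSE for every ligand", call. = FALSE)
  bad_chem <- !lib$is_binder & !is.na(lib$chemotype)
  if (any(bad_chem))
    stop("decoys must not carry a chemotype label: ",
         paste(lib$ligand_id[bad_chem], collapse = ", "), call. = FALSE)
  bad_coc <- !lib$is_binder & !is.na(lib$cocrystal_of)
  if (any(bad_coc))
    stop("decoys must not carry a cocrystal_of annotation: ",
         paste(lib$ligand_id[bad_coc], collapse = ", "), call. = FALSE)
  class(lib) <- c("ligand_library", "data.frame")
  lib
}

#' Read a ligand annotation table
#'
#' Expects a delimited text file with header columns `ligand`, `mw`, `label`,
#' `chemotype`, `cocrystal_of`; `label` must be `binder` or `decoy`; the last
#' two columns may be empty. Empty cells become `NA`.
#'
#' @param path file path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return A validated [ligand_library].
#' @export
read_ligand_annotations <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", strip.white = TRUE,
                           na.strings = c("", "NA"), quote = "\"",
                           comment.char = "")
  needed <- c("ligand", "mw", "label", "chemotype", "cocrystal_of")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0)
    stop("annotation file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  mw <- suppressWarnings(as.numeric(raw$mw))
  bad <- which(is.na(mw) & !is.na(raw$mw))
  if (length(bad) > 0)
    stop("non-numeric mw at line ", bad[1] + 1L, " of ", path, call. = FALSE)
  lab <- tolower(raw$label)
  if (!all(lab %in% c("binder", "decoy")))
    stop("label column must be 'binder' or 'decoy'", call. = FALSE)
  ligand_library(raw$ligand, mw, lab == "binder",
                 chemotype = raw$chemotype, cocrystal_of = raw$cocrystal_of)
}

#' Write a ligand annotation table
#'
#' Inverse of [read_ligand_annotations()]; `NA` chemotype / co-crystal cells
#' are written empty.
#'
#' @param lib a [ligand_library].
#' @param path output file path.
#' @param dialect `"tsv"` or `"csv"`.
#' @export
write_ligand_annotations <- function(lib, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  out <- data.frame(
    ligand = lib$ligand_id,
    mw = signif(lib$mw, 6),
    label = ifelse(lib$is_binder, "binder", "decoy"),
    chemotype = ifelse(is.na(lib$chemotype), "", lib$chemotype),
    cocrystal_of = ifelse(is.na(lib$cocrystal_of), "", lib$cocrystal_of),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.ligand_library <- function(x, ...) {
  cat(sprintf("<ligand_library> %d ligands: %d binders, %d decoys, %d chemotypes\n",
              nrow(x), sum(x$is_binder), sum(!x$is_binder),
              length(unique(stats::na.omit(x$chemotype)))))
  NextMethod()
}
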