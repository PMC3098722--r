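#' Keep only the best-ranked binder of each chemotype
#'
#' Scaffold-aware evaluation: for every chemotype cluster, the binder with
#' the best rank in the supplied ranking stays a binder; all other members of
#' the cluster are relabeled as non-binders (and lose their chemotype label,
#' since decoys are never chemotyped). The library size N is unchanged; the
#' binder count drops to the number of chemotypes, which suppresses the noise
#' of over-represented scaffolds. The representative depends on the ranking
#' being scored, so the relabeling is evaluated per ranked list.
#'
#' @param ranked the `ranked_list` being evaluated.
#' @param library a [ligand_library] in which every binder is chemotyped.
#' @return The relabeled `ligand_library` (same ligands, same order).
#' @export
chemotype_representative_relabel <- function(ranked, library) {
  library <- validate_ligand_library(library)
  if (any(library$is_binder & is.na(library$chemotype)))
    stop("every binder needs a chemotype for representative relabeling",
         call. = FALSE)
  rk <- ranked$rank[match(library$ligand_id, ranked$ligand_id)]
  if (anyNA(rk[library$is_binder]))
    stop("ranked list does not cover every binder", call. = FALSE)
  keep <- rep(FALSE, nrow(library))
  for (ct in unique(stats::na.omit(library$chemotype))) {
    members <- which(library$is_binder & !is.na(library$chemotype) &
                       library$chemotype == ct)
    keep[members[which.min(rk[members])]] <- TRUE
  }
  out <- library
  demote <- out$is_binder & !keep
  out$is_binder[demote] <- FALSE
  out$chemotype[demote] <- NA_character_
  out$cocrystal_of[demote] <- NA_character_
  class(out) <- c("ligand_library", "data.frame")
  out
}

#' Binder and chemotype content of the top-ranked fraction
#'
#' Counts the binders and the distinct chemotypes among the first
#' `floor(chi * N)` positions of a ranked list, and reports the sorted
#' chemotype label set both as a vector and as a dash-joined summary string
#' (e.g. `"1-3-4-9"`).
#'
#' @param ranked a `ranked_list`.
#' @param library the [ligand_library].
#' @param chi top fraction (default 1%); `floor(chi * N)` must be >= 1.
#' @return List with `n_binders_top`, `n_chemotypes_top`, `chemotype_ids`
#'   (sorted character vector), `label` (summary string) and `top_size`.
#' @export
top_fraction_chemotypes <- function(ranked, library, chi = 0.01) {
  N <- nrow(ranked)
  k <- floor(chi * N)
  if (k < 1)
    stop("fraction too small for library size: floor(chi * N) = 0",
         call. = FALSE)
  top <- ranked$ligand_id[ranked$rank <= k]
  idx <- match(top, library$ligand_id)
  binder <- library$is_binder[idx]
  chems <- sort(unique(stats::na.omit(library$chemotype[idx][binder])))
  list(n_binders_top = sum(binder),
       n_chemotypes_top = length(chems),
       chemotype_ids = chems,
       label = paste(chems, collapse = "-"),
       top_size = k)
}
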