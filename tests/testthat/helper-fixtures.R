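# In-code fixtures shared across the suite.

# Library of N ligands with binders at the given positions (by id order);
# constant weights unless given, so score order alone decides ranks.
make_library <- function(N, binder_pos, mw = rep(300, N),
                         chemotype = NULL) {
  ids <- sprintf("L%03d", seq_len(N))
  is_b <- seq_len(N) %in% binder_pos
  chem <- rep(NA_character_, N)
  if (!is.null(chemotype)) chem[binder_pos] <- chemotype
  ligand_library(ids, mw, is_b, chemotype = chem)
}

# Ranked list realizing an exact placement: binders occupy `binder_ranks`
# of 1..N. Returns list(ranked, library). Scores are -N..-1 so rank i gets
# score -(N - i + 1); tie-free by construction.
make_placement <- function(N, binder_ranks, chemotype = NULL) {
  lib <- make_library(N, seq_along(binder_ranks), chemotype = chemotype)
  decoy_ranks <- setdiff(seq_len(N), binder_ranks)
  rank_of <- integer(N)
  rank_of[seq_along(binder_ranks)] <- binder_ranks
  if (length(decoy_ranks) > 0)
    rank_of[seq.int(length(binder_ranks) + 1, N)] <- decoy_ranks
  scores <- stats::setNames(as.numeric(rank_of) - N - 1, lib$ligand_id)
  list(ranked = rank_single_run(scores, lib), library = lib)
}

# Two-conformer toy ensemble used across combination / filter tests.
make_toy_screen <- function() {
  lib <- ligand_library(
    c("B1", "B2", "D1", "D2", "D3", "D4"),
    mw = c(250, 320, 280, 300, 310, 330),
    is_binder = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    chemotype = c("C1", "C2", NA, NA, NA, NA),
    cocrystal_of = c("conf1", NA, NA, NA, NA, NA)
  )
  scores <- rbind(
    conf1 = c(B1 = -40, B2 = -10, D1 = -20, D2 = -15, D3 = -12, D4 = -18),
    conf2 = c(B1 = -11, B2 = -38, D1 = -19, D2 = -16, D3 = -14, D4 = -17)
  )
  ensemble_screen("TOY", scores, lib)
}
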