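two_run_screen <- function(s1, s2, mw = NULL, binders = 1) {
  ids <- names(s1)
  N <- length(ids)
  if (is.null(mw)) mw <- rep(300, N)
  lib <- ligand_library(ids, mw, seq_len(N) %in% binders)
  ensemble_screen("T", rbind(c1 = s1, c2 = s2[ids]), lib)
}

test_that("best-score combination takes the per-ligand minimum", {
  sc <- two_run_screen(c(A = -32, B = -25), c(A = -20, B = -31))
  r <- combine_mrc_score(sc)
  expect_equal(r$ligand_id, c("A", "B"))
  expect_equal(r$primary_key, c(-32, -31))
  expect_equal(attr(r, "method"), "mrc_score")

  # equal best scores: lower molecular weight first
  sc2 <- two_run_screen(c(A = -30, B = -30), c(A = -10, B = -10),
                        mw = c(300, 250))
  expect_equal(combine_mrc_score(sc2)$ligand_id, c("B", "A"))

  # single-run ensemble is identical to ranking that run
  screen <- make_toy_screen()
  single <- ensemble_screen("TOY", screen$scores[1, , drop = FALSE],
                            screen$library)
  expect_equal(combine_mrc_score(single)$ligand_id,
               rank_single_run(screen, conformer = "conf1")$ligand_id)
})

test_that("best-rank combination uses best rank then best score", {
  # A: ranks (1, 3); B: ranks (3, 1); C: (2, 2); D: (4, 4)
  sc <- two_run_screen(c(A = -40, B = -10, C = -30, D = -5),
                       c(A = -10, B = -40, C = -30, D = -5))
  r <- combine_mrc_rank(sc)
  expect_equal(r$primary_key[match(c("A", "B", "C", "D"), r$ligand_id)],
               c(1, 1, 2, 4))
  # A and B tie on best rank 1 and on best score -40; C never ranked 1st
  # even though its scores match A's and B's second-best
  expect_equal(r$ligand_id[3], "C")

  # best-rank ties sorted by the better (lower) best score
  sc2 <- two_run_screen(c(A = -28, B = -5, C = -1), c(A = -2, B = -31, C = -1))
  r2 <- combine_mrc_rank(sc2)
  expect_equal(r2$ligand_id[1:2], c("B", "A"))

  # an ensemble of identical runs reproduces the single-run ordering
  sc3 <- two_run_screen(c(A = -9, B = -4, C = -7), c(A = -9, B = -4, C = -7))
  expect_equal(combine_mrc_rank(sc3)$ligand_id,
               rank_single_run(sc3, conformer = "c1")$ligand_id)
})

test_that("every combination method outputs a dense permutation of the library", {
  screen <- generate_screen(synthetic_config(
    n_targets = 1, conformers_range = c(4, 4), n_binders = 5, n_decoys = 45,
    seed = 3))$screens[[1]]
  for (m in c("mrc_score", "mrc_rank", "mrc_rank_deep", "boltzmann_score",
              "boltzmann_score_mw", "rank_consensus")) {
    r <- combine_screen(screen, method = m)
    expect_setequal(r$ligand_id, screen$library$ligand_id)
    expect_equal(r$rank, seq_len(nrow(screen$library)))
    expect_equal(attr(r, "method"), m)
  }
})

test_that("alternative schemes match their hand-computed keys", {
  # rank consensus: A ranks (1, 3) -> 4; B ranks (2, 1) -> 3; C (3, 2) -> 5
  sc <- two_run_screen(c(A = -30, B = -20, C = -10),
                       c(A = -10, B = -30, C = -20))
  r <- combine_alternative(sc, "rank_consensus")
  expect_equal(r$ligand_id, c("B", "A", "C"))
  expect_equal(r$primary_key, c(3, 4, 5))

  # deep ranks: A (2, 5, 9) vs B (2, 4, 9) -> B first on the 2nd-best rank
  lib <- make_library(10, 1:2)
  ids <- lib$ligand_id
  mk_run <- function(ranks) stats::setNames(ranks - 11, ids)
  scores <- rbind(c1 = mk_run(c(2, 5, setdiff(1:10, c(2, 5))[1:8])),
                  c2 = mk_run(c(5, 2, setdiff(1:10, c(5, 2))[1:8])),
                  c3 = mk_run(c(9, 4, setdiff(1:10, c(9, 4))[1:8])),
                  c4 = mk_run(c(2, 9, setdiff(1:10, c(2, 9))[1:8])))
  # L001 ranks: 2,5,9,2 -> best three (2,2,5); L002: 5,2,4,9 -> (2,4,5)
  screen <- ensemble_screen("T", scores, lib)
  rd <- combine_alternative(screen, "mrc_rank_deep")
  expect_lt(which(rd$ligand_id == "L001"), which(rd$ligand_id == "L002"))

  # Boltzmann soft-min converges to the best-score ordering as T -> 0
  screen2 <- generate_screen(synthetic_config(
    n_targets = 1, conformers_range = c(3, 3), n_binders = 4, n_decoys = 36,
    seed = 9))$screens[[1]]
  cold <- combine_alternative(screen2, "boltzmann_score", temperature = 1e-4)
  expect_equal(cold$ligand_id, combine_mrc_score(screen2)$ligand_id)

  # molecular-weight penalty reorders near-ties when lambda is active
  sc3 <- two_run_screen(c(A = -30.00, B = -29.95), c(A = -1, B = -1),
                        mw = c(500, 200))
  plain <- combine_alternative(sc3, "boltzmann_score_mw", temperature = 0.01,
                               lambda = 0)
  penal <- combine_alternative(sc3, "boltzmann_score_mw", temperature = 0.01,
                               lambda = 0.01)
  expect_equal(plain$ligand_id[1], "A")
  expect_equal(penal$ligand_id[1], "B")

  expect_error(combine_screen(make_toy_screen(), method = "nonsense"))
})

test_that("run order never changes a combined ordering", {
  screen <- generate_screen(synthetic_config(
    n_targets = 1, conformers_range = c(5, 5), n_binders = 5, n_decoys = 45,
    seed = 21))$screens[[1]]
  flipped <- screen
  flipped$scores <- screen$scores[rev(seq_len(nrow(screen$scores))), ]
  for (m in c("mrc_score", "mrc_rank", "mrc_rank_deep", "rank_consensus",
              "boltzmann_score"))
    expect_equal(combine_screen(screen, m)$ligand_id,
                 combine_screen(flipped, m)$ligand_id)
})

test_that("adding a run can only improve a ligand's best-score key", {
  set.seed(13)
  for (i in 1:20) {
    screen <- generate_screen(synthetic_config(
      n_targets = 1, conformers_range = c(3, 3), n_binders = 4,
      n_decoys = 30, seed = i))$screens[[1]]
    sub <- screen
    sub$scores <- screen$scores[-1, , drop = FALSE]
    k_sub <- combine_mrc_score(sub)
    k_all <- combine_mrc_score(screen)
    key_sub <- k_sub$primary_key[match(screen$library$ligand_id, k_sub$ligand_id)]
    key_all <- k_all$primary_key[match(screen$library$ligand_id, k_all$ligand_id)]
    expect_true(all(key_all <= key_sub))
  }
})

test_that("chemotype-specialized conformers boost early recognition synergistically", {
  # conformers covering disjoint chemotype subsets: the combined list should
  # beat the best single run's EF_1% in nearly every replicate
  disjoint_screen <- function() {
    n_chem <- 4; per_chem <- 3; nd <- 288
    nb <- n_chem * per_chem
    chem <- rep(as.character(seq_len(n_chem)), each = per_chem)
    lib <- ligand_library(
      c(sprintf("B%02d", seq_len(nb)), sprintf("D%03d", seq_len(nd))),
      mw = round(stats::runif(nb + nd, 150, 550), 1),
      is_binder = c(rep(TRUE, nb), rep(FALSE, nd)),
      chemotype = c(chem, rep(NA, nd)))
    scores <- t(vapply(seq_len(n_chem), function(cf) {
      mu_b <- ifelse(chem == as.character(cf), -35, -12)
      c(stats::rnorm(nb, mu_b, 5), stats::rnorm(nd, -15, 5))
    }, numeric(nb + nd)))
    dimnames(scores) <- list(paste0("conf", seq_len(n_chem)), lib$ligand_id)
    ensemble_screen("DIS", scores, lib)
  }
  wins <- 0L
  n_rep <- 30L
  set.seed(1000)
  for (i in seq_len(n_rep)) {
    screen <- disjoint_screen()
    lib <- screen$library
    src_ef <- vapply(rownames(screen$scores), function(cf)
      enrichment_factor(rank_single_run(screen, conformer = cf), 0.01, lib),
      numeric(1))
    mrc_ef <- enrichment_factor(combine_mrc_rank(screen), 0.01, lib)
    if (mrc_ef >= max(src_ef)) wins <- wins + 1L
  }
  expect_gte(wins / n_rep, 0.9)
})
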