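#' Configuration for the synthetic screen generator
#'
#' The generator emulates the statistical structure of a retrospective
#' ensemble docking benchmark with an explicit induced-fit mechanism: every
#' binder belongs to a chemotype, every conformer recognizes a random subset
#' of chemotypes, and a binder only scores like an active when docked against
#' a compatible conformer. Incompatible binders score slightly *worse* than
#' an average decoy, which is what produces the two peaks of the pooled
#' binder rank distribution seen in single-conformer screens. A configurable
#' fraction of runs is degenerate ("bad"): shifted so that every ligand gets
#' a strictly positive score.
#'
#' Score means are dimensionless empirical docking scores, lower = better,
#' and must satisfy `mu_active < mu_decoy <= mu_incompatible`.
#'
#' @param n_targets number of targets to simulate.
#' @param conformers_range inclusive range the per-target conformer count is
#'   drawn from (crystallographic ensembles typically hold 2-30 members).
#' @param n_binders,n_decoys library composition per target; the default
#'   10:430 keeps the benchmark's ~1:43 binder:decoy ratio at desk scale.
#' @param n_chemotypes number of binder scaffold clusters (<= n_binders).
#' @param compat_fraction probability a conformer recognizes a given
#'   chemotype.
#' @param mu_active,mu_incompatible,mu_decoy Gaussian score means for
#'   compatible binders, incompatible binders, and decoys.
#' @param sigma common score standard deviation.
#' @param frac_bad_runs probability a run is degenerate (all-positive).
#' @param bad_run_shift additive score shift applied to degenerate runs.
#' @param mw_range molecular-weight range in Dalton (uniform draw).
#' @param cocrystal_fraction fraction of binders annotated as co-crystallized
#'   with a compatible conformer of their target.
#' @param seed master seed; each target derives its own reproducible stream
#'   from it, so per-target data is stable when `n_targets` changes.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_targets = 1,
                             conformers_range = c(2, 30),
                             n_binders = 10,
                             n_decoys = 430,
                             n_chemotypes = 4,
                             compat_fraction = 0.5,
                             mu_active = -35,
                             mu_incompatible = -12,
                             mu_decoy = -15,
                             sigma = 5,
                             frac_bad_runs = 0.1,
                             bad_run_shift = 30,
                             mw_range = c(150, 550),
                             cocrystal_fraction = 0.25,
                             seed = 0) {
  cfg <- list(n_targets = n_targets, conformers_range = conformers_range,
              n_binders = n_binders, n_decoys = n_decoys,
              n_chemotypes = n_chemotypes, compat_fraction = compat_fraction,
              mu_active = mu_active, mu_incompatible = mu_incompatible,
              mu_decoy = mu_decoy, sigma = sigma,
              frac_bad_runs = frac_bad_runs, bad_run_shift = bad_run_shift,
              mw_range = mw_range, cocrystal_fraction = cocrystal_fraction,
              seed = seed)
  if (cfg$n_chemotypes > cfg$n_binders)
    stop("infeasible config: n_chemotypes > n_binders", call. = FALSE)
  if (!(cfg$mu_active < cfg$mu_decoy && cfg$mu_decoy <= cfg$mu_incompatible))
    stop("score means must satisfy mu_active < mu_decoy <= mu_incompatible",
         call. = FALSE)
  probs <- c(cfg$compat_fraction, cfg$frac_bad_runs, cfg$cocrystal_fraction)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (cfg$sigma <= 0) stop("sigma must be positive", call. = FALSE)
  class(cfg) <- "synthetic_config"
  cfg
}

# per-target reproducible seed below 2^31
derive_seed <- function(master, index) {
  (as.numeric(master) * 48271 + index * 1000003) %% 2147483647
}

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate synthetic ensemble screens
#'
#' Deterministic given the config seed. For each target: a conformer count is
#' drawn from `conformers_range`; every binder is assigned a chemotype (each
#' chemotype gets at least one member); every conformer draws the chemotype
#' subset it recognizes with probability `compat_fraction` per chemotype;
#' binder scores come from `Normal(mu_active, sigma)` in compatible runs and
#' `Normal(mu_incompatible, sigma)` otherwise, decoys from
#' `Normal(mu_decoy, sigma)`. Degenerate runs recognize no chemotype and are
#' shifted by `bad_run_shift` (plus whatever extra is needed so that their
#' minimum score is strictly positive). A `cocrystal_fraction` of binders is
#' annotated as co-crystallized with a compatible conformer when one exists.
#'
#' @param config a [synthetic_config].
#' @return A `synthetic_screens` list with elements `screens` (named list of
#'   [ensemble_screen]) and `config`.
#' @examples
#' sim <- generate_screen(synthetic_config(n_targets = 1, seed = 1))
#' sim$screens[[1]]
#' @export
generate_screen <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  screens <- lapply(seq_len(config$n_targets), function(t)
    with_local_seed(derive_seed(config$seed, t),
                    generate_target(config, t)))
  names(screens) <- vapply(screens, function(s) s$target_id, character(1))
  structure(list(screens = screens, config = config),
            class = "synthetic_screens")
}

generate_target <- function(cfg, t) {
  target_id <- sprintf("T%03d", t)
  nb <- cfg$n_binders; nd <- cfg$n_decoys; N <- nb + nd
  k <- if (cfg$conformers_range[1] == cfg$conformers_range[2])
    cfg$conformers_range[1]
  else sample(cfg$conformers_range[1]:cfg$conformers_range[2], 1)
  conf_ids <- sprintf("%s_C%02d", target_id, seq_len(k))
  lig_ids <- c(sprintf("%s_B%03d", target_id, seq_len(nb)),
               sprintf("%s_D%04d", target_id, seq_len(nd)))
  is_binder <- c(rep(TRUE, nb), rep(FALSE, nd))
  # every chemotype populated, remaining binders spread at random
  chem <- rep(NA_character_, N)
  assign <- c(seq_len(cfg$n_chemotypes),
              sample(cfg$n_chemotypes, nb - cfg$n_chemotypes, replace = TRUE))
  chem[seq_len(nb)] <- as.character(sample(assign))
  mw <- round(stats::runif(N, cfg$mw_range[1], cfg$mw_range[2]), 1)

  bad <- stats::runif(k) < cfg$frac_bad_runs
  compat <- matrix(stats::runif(k * cfg$n_chemotypes) < cfg$compat_fraction,
                   nrow = k)
  compat[bad, ] <- FALSE # a degenerate pocket recognizes nothing

  scores <- matrix(NA_real_, nrow = k, ncol = N,
                   dimnames = list(conf_ids, lig_ids))
  chem_idx <- as.integer(chem[seq_len(nb)])
  for (i in seq_len(k)) {
    mu_b <- ifelse(compat[i, chem_idx], cfg$mu_active, cfg$mu_incompatible)
    row <- c(stats::rnorm(nb, mu_b, cfg$sigma),
             stats::rnorm(nd, cfg$mu_decoy, cfg$sigma))
    if (bad[i]) {
      row <- row + cfg$bad_run_shift
      if (min(row) <= 0) row <- row + (0.5 - min(row))
    }
    scores[i, ] <- row
  }

  cocrystal <- rep(NA_character_, N)
  n_coc <- round(cfg$cocrystal_fraction * nb)
  if (n_coc > 0) {
    for (b in sample(seq_len(nb), n_coc)) {
      hosts <- which(compat[, chem_idx[b]])
      if (length(hosts) > 0)
        cocrystal[b] <- conf_ids[hosts[sample.int(length(hosts), 1)]]
    }
  }

  lib <- ligand_library(lig_ids, mw, is_binder, chemotype = chem,
                        cocrystal_of = cocrystal)
  ensemble_screen(target_id, scores, lib)
}

#' @export
print.synthetic_screens <- function(x, ...) {
  cat(sprintf("<synthetic_screens> %d target(s), seed %s\n",
              length(x$screens), format(x$config$seed)))
  invisible(x)
}

#' Annotation table pooled over the targets of a synthetic batch
#'
#' @param sim a `synthetic_screens` object.
#' @return One [ligand_library] covering all targets (ligand ids are
#'   target-prefixed, hence unique).
#' @export
synthetic_annotations <- function(sim) {
  libs <- lapply(sim$screens, function(s) as.data.frame(s$library))
  validate_ligand_library(do.call(rbind, c(libs, make.row.names = FALSE)))
}

#' Pooled binder relative-rank histogram across single-conformer runs
#'
#' Generates screens from `config`, ranks every conformer run on its own,
#' pools the binders' relative ranks (rank / N) and bins them. With an
#' intermediate `compat_fraction` the histogram is bimodal: a left peak of
#' binders that met a compatible conformer and a late peak of binders scored
#' worse than an average decoy by incompatible pockets. The `bimodal`
#' predicate checks that the leftmost bin and the mean rightmost-quartile bin
#' each exceed the mean bin count of the middle half of the distribution.
#'
#' @param config a [synthetic_config].
#' @param bins number of histogram bins on (0, 1\].
#' @return List with `counts`, `breaks`, `relative_ranks`, `bimodal`.
#' @export
generate_bimodality_check <- function(config = synthetic_config(),
                                      bins = 20) {
  sim <- generate_screen(config)
  rel <- unlist(lapply(sim$screens, function(screen) {
    rk <- rank_matrix(screen)
    b <- screen$library$is_binder
    as.vector(rk[, b, drop = FALSE]) / ncol(rk)
  }), use.names = FALSE)
  breaks <- seq(0, 1, length.out = bins + 1)
  counts <- graphics::hist(rel, breaks = breaks, plot = FALSE,
                           include.lowest = TRUE, right = TRUE)$counts
  mid <- counts[breaks[-1] > 0.25 & breaks[-1] <= 0.75]
  right <- counts[breaks[-1] > 0.75]
  bimodal <- counts[1] > mean(mid) && mean(right) > mean(mid)
  list(counts = counts, breaks = breaks, relative_ranks = rel,
       bimodal = bimodal)
}
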