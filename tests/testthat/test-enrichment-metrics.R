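test_that("accumulation curve counts binders at or above each rank", {
  p <- make_placement(4, c(1, 3))
  expect_equal(as.integer(accumulation_curve(p$ranked, p$library)),
               c(1, 1, 2, 2))

  p2 <- make_placement(10, c(1, 4, 7))
  expect_equal(as.integer(accumulation_curve(p2$ranked, p2$library)),
               c(1, 1, 1, 2, 2, 2, 3, 3, 3, 3))

  # ideal placement: F_a(k) = min(k, n)
  p3 <- make_placement(9, 1:4)
  expect_equal(as.integer(accumulation_curve(p3$ranked, p3$library)),
               pmin(1:9, 4))

  # no binders -> metrics undefined
  lib0 <- make_library(3, integer(0))
  r0 <- rank_single_run(stats::setNames(c(-1, -2, -3), lib0$ligand_id), lib0)
  expect_error(accumulation_curve(r0, lib0), "without actives")
})

test_that("AUAC matches the hand-computed sums and range endpoints", {
  p <- make_placement(10, c(1, 4, 7))
  expect_equal(auac(p$ranked, p$library), 21 / 30)

  # N = 2, n = 1: ideal is 1, worst is (n+1)/(2N) = 0.5
  expect_equal(auac(make_placement(2, 1)$ranked,
                    make_placement(2, 1)$library), 1.0)
  expect_equal(auac(make_placement(2, 2)$ranked,
                    make_placement(2, 2)$library), 0.5)

  # closed-form endpoints at larger sizes
  ideal <- make_placement(50, 1:7)
  expect_equal(auac(ideal$ranked, ideal$library), 1 - (7 - 1) / (2 * 50))
  worst <- make_placement(50, 44:50)
  expect_equal(auac(worst$ranked, worst$library), (7 + 1) / (2 * 50))
})

test_that("ROC AUC agrees with pair enumeration and the AUAC transform", {
  p <- make_placement(10, c(1, 4, 7))
  expect_equal(roc_auc(p$ranked, p$library), 15 / 21)
  a <- auac(p$ranked, p$library)
  expect_equal(roc_auc(p$ranked, p$library), (10 * a - 2) / 7)

  # all scores tied across the binder/decoy boundary -> half credit = 0.5
  lib <- make_library(6, c(2, 5))
  r <- rank_single_run(stats::setNames(rep(-7, 6), lib$ligand_id), lib)
  expect_equal(roc_auc(r, lib), 0.5)

  expect_error(roc_auc(make_placement(3, 1:3)$ranked,
                       make_placement(3, 1:3)$library), "without decoys")
})

test_that("AUAC-ROC linear transform identity holds for random tie-free rankings", {
  set.seed(42)
  for (i in 1:250) {
    N <- sample(5:60, 1)
    n <- sample(seq_len(N - 1), 1)
    p <- make_placement(N, sort(sample(N, n)))
    lhs <- roc_auc(p$ranked, p$library)
    rhs <- (N * auac(p$ranked, p$library) - (n + 1) / 2) / (N - n)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("enrichment factor follows its truncation formula and bounds", {
  p <- make_placement(10, c(1, 4, 7))
  expect_equal(enrichment_factor(p$ranked, 0.2, p$library), 1 / 0.6)

  # whole-list fraction: EF = 1 exactly
  expect_equal(enrichment_factor(p$ranked, 1, p$library), 1)

  # ideal placements reproduce the published maxima (truncated to 1 dp)
  ideal <- function(n, N) {
    q <- make_placement(N, 1:n)
    enrichment_factor(q$ranked, 0.01, q$library)
  }
  expect_equal(ideal(8, 163), 12.5)
  expect_equal(truncate_decimals(ideal(32, 2617)), 81.2)
  expect_equal(truncate_decimals(ideal(9, 727)), 77.7)
  expect_equal(truncate_decimals(ideal(13, 649)), 46.1)
  expect_equal(enrichment_factor_max(8, 163, 0.01), 12.5)

  # fraction too small for the library
  expect_error(enrichment_factor(p$ranked, 0.05, p$library), "too small")
})

test_that("RIE is normalized to 1 under random ranking and at n = N", {
  # all actives: numerator equals its random expectation exactly
  N <- 40
  expect_equal(rie(1:N, N, alpha = 20), 1, tolerance = 1e-12)

  # ideal ordering equals direct evaluation at ranks 1..n
  expect_equal(rie(1:5, 100, 20), oracle_rie(1:5, 100, 20))

  # Monte-Carlo mean over random permutations ~ 1 (3 standard errors)
  set.seed(7)
  vals <- replicate(4000, rie(sample(100, 10), 100, 20))
  se <- stats::sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 1), 3 * se)
})

test_that("BEDROC is the min-max standardized RIE with exact endpoints", {
  expect_equal(bedroc(1:8, 163, 20), 1)
  expect_equal(bedroc(156:163, 163, 20), 0)

  # random-ranking mean matches the closed-form (1 - RIEmin)/(RIEmax - RIEmin)
  set.seed(11)
  N <- 200; n <- 10; alpha <- 20
  vals <- replicate(4000, bedroc(sample(N, n), N, alpha))
  expected <- (1 - rie((N - n + 1):N, N, alpha)) /
    (rie(1:n, N, alpha) - rie((N - n + 1):N, N, alpha))
  se <- stats::sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - expected), 3 * se)
})

test_that("production metrics equal the enumeration oracle for all small placements", {
  for (N in 3:8) {
    for (n in seq_len(N - 1)) {
      for (ranks in utils::combn(N, n, simplify = FALSE)) {
        p <- make_placement(N, ranks)
        curve <- accumulation_curve(p$ranked, p$library)
        expect_identical(as.integer(curve), oracle_accumulation(ranks, N))
        expect_equal(auac(curve), oracle_auac(ranks, N))
        expect_equal(roc_auc(p$ranked, p$library), oracle_roc_auc(ranks, N))
        expect_equal(enrichment_factor(curve, 0.5),
                     oracle_ef(ranks, N, 0.5))
        expect_equal(rie(ranks, N, 20), oracle_rie(ranks, N, 20))
        expect_equal(bedroc(ranks, N, 20), oracle_bedroc(ranks, N, 20))
      }
    }
  }
})

test_that("metrics are monotone when a binder moves to a better rank", {
  set.seed(3)
  for (i in 1:40) {
    N <- sample(10:40, 1)
    n <- sample(2:5, 1)
    ranks <- sort(sample(N, n))
    movable <- ranks[ranks > 1]
    r_old <- movable[length(movable)]
    gaps <- setdiff(seq_len(r_old - 1), ranks)
    if (length(gaps) == 0) next
    new_ranks <- sort(c(setdiff(ranks, r_old), sample(gaps, 1)))
    p0 <- make_placement(N, ranks); p1 <- make_placement(N, new_ranks)
    m0 <- metric_report(p0$ranked, p0$library, chi_values = 0.5)
    m1 <- metric_report(p1$ranked, p1$library, chi_values = 0.5)
    expect_gte(m1$auac, m0$auac)
    expect_gte(m1$roc_auc, m0$roc_auc)
    expect_gte(m1$ef[[1]], m0$ef[[1]])
    expect_gte(m1$rie, m0$rie)
    expect_gte(m1$bedroc, m0$bedroc)
  }
})

test_that("metric_report bundles consistent endpoint values", {
  ideal <- make_placement(30, 1:3)
  m <- metric_report(ideal$ranked, ideal$library, chi_values = c(0.1, 0.5))
  expect_equal(m$auac, 1 - (3 - 1) / (2 * 30))
  expect_equal(m$roc_auc, 1)
  expect_equal(m$bedroc, 1)
  expect_equal(m$ef[["10%"]], enrichment_factor_max(3, 30, 0.1))

  worst <- make_placement(30, 28:30)
  mw <- metric_report(worst$ranked, worst$library, chi_values = 0.1)
  expect_equal(mw$roc_auc, 0)
  expect_equal(mw$bedroc, 0)
  expect_equal(mw$ef[["10%"]], 0)
  expect_equal(mw$n_binders, 3)
  expect_equal(mw$n_total, 30)
})

test_that("metrics ignore how decoys are permuted among themselves", {
  set.seed(5)
  N <- 20; ranks <- c(2, 9, 15)
  p <- make_placement(N, ranks)
  base <- metric_report(p$ranked, p$library, chi_values = 0.25)
  # rebuild with decoy ids shuffled: same binder placement, different decoys
  lib2 <- p$library
  decoys <- which(!lib2$is_binder)
  lib2$ligand_id[decoys] <- sample(lib2$ligand_id[decoys])
  scores <- stats::setNames(p$ranked$primary_key[match(lib2$ligand_id,
                                                       p$ranked$ligand_id)],
                            lib2$ligand_id)
  r2 <- rank_single_run(scores, lib2)
  m2 <- metric_report(r2, lib2, chi_values = 0.25)
  for (f in c("auac", "roc_auc", "rie", "bedroc"))
    expect_equal(m2[[f]], base[[f]])
  expect_equal(m2$ef, base$ef)
})
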