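# Naive reference implementations of the five figures of merit, written as
# literal loops over the definitions. They stay independent of the package's
# production code paths and serve as the enumeration oracle.

oracle_accumulation <- function(binder_ranks, N) {
  fa <- integer(N)
  for (k in seq_len(N)) fa[k] <- sum(binder_ranks <= k)
  fa
}

oracle_auac <- function(binder_ranks, N) {
  n <- length(binder_ranks)
  sum(oracle_accumulation(binder_ranks, N)) / (n * N)
}

# explicit binder-decoy pair enumeration (tie-free rankings)
oracle_roc_auc <- function(binder_ranks, N) {
  decoy_ranks <- setdiff(seq_len(N), binder_ranks)
  wins <- 0
  for (b in binder_ranks) for (d in decoy_ranks) if (b < d) wins <- wins + 1
  wins / (length(binder_ranks) * length(decoy_ranks))
}

oracle_ef <- function(binder_ranks, N, chi) {
  n <- length(binder_ranks)
  k <- floor(chi * N)
  stopifnot(k >= 1)
  sum(binder_ranks <= k) / (n * chi)
}

oracle_rie <- function(binder_ranks, N, alpha) {
  n <- length(binder_ranks)
  num <- 0
  for (r in binder_ranks) num <- num + exp(-alpha * r / N)
  num / ((n / N) * (1 - exp(-alpha)) / (exp(alpha / N) - 1))
}

oracle_bedroc <- function(binder_ranks, N, alpha) {
  n <- length(binder_ranks)
  r <- oracle_rie(binder_ranks, N, alpha)
  rmax <- oracle_rie(1:n, N, alpha)
  rmin <- oracle_rie((N - n + 1):N, N, alpha)
  (r - rmin) / (rmax - rmin)
}
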