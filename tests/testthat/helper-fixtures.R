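# Shared builders for small test systems.

cat2 <- factor_catalog(c("F1", "F2"), c("alpha", "beta"))
cat3 <- factor_catalog(c("F1", "F2", "F3"))

mk_expert <- function(values, catalog = cat2, id = "E1", scale_max = 3L) {
  expert_scores(matrix(values, nrow(catalog), nrow(catalog), byrow = TRUE),
                catalog, expert_id = id, scale_max = scale_max)
}

# Random direct-relation matrix with spectral radius of X well below 1.
random_direct <- function(n, seed, scale_max = 3) {
  set.seed(seed)
  v <- matrix(runif(n * n, 0, scale_max), n, n)
  diag(v) <- 0
  direct_relation(v, factor_catalog(paste0("F", seq_len(n))),
                  scale_max = scale_max)
}

# Independent series oracle for the total-relation matrix: truncated
# geometric accumulation of X^k, no solve() involved.
series_total <- function(X, K) {
  Xu <- unclass(X)
  acc <- matrix(0, nrow(Xu), ncol(Xu))
  term <- diag(nrow(Xu))
  for (k in seq_len(K)) {
    term <- term %*% Xu
    acc <- acc + term
  }
  acc
}
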