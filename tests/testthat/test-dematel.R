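test_that("normalization divides by the maximum row sum", {
  A <- direct_relation(matrix(c(0, 2, 1, 0), 2, 2, byrow = TRUE), cat2)
  X <- normalize_direct(A)
  expect_equal(attr(X, "normalizing_constant"), 2)
  expect_equal(unclass(X), matrix(c(0, 1, 0.5, 0), 2, 2, byrow = TRUE),
               ignore_attr = TRUE)

  # single non-zero entry normalizes to exactly 1 at that cell
  v <- matrix(0, 3, 3); v[1, 3] <- 0.7
  X1 <- normalize_direct(direct_relation(v, cat3))
  expect_equal(unclass(X1)[1, 3], 1)
  expect_equal(sum(X1), 1)

  expect_error(normalize_direct(direct_relation(matrix(0, 2, 2), cat2)),
               "degenerate")

  # the row attaining the max row sum sums to exactly 1
  A15 <- fpt_direct_relation()
  X15 <- normalize_direct(A15)
  rs <- rowSums(X15)
  expect_equal(max(rs), 1, tolerance = 1e-12)
  expect_true(all(X15 >= 0 & X15 <= 1))
  expect_equal(names(which.max(rowSums(A15))), "F10")
})

test_that("total relation matches the 2x2 closed form and the fixed point", {
  X <- structure(matrix(c(0, 0.5, 0.25, 0), 2, 2, byrow = TRUE,
                        dimnames = list(cat2$factor_id, cat2$factor_id)),
                 catalog = cat2, normalizing_constant = 1,
                 class = c("normalized_direct", "matrix", "array"))
  Tm <- total_relation(X)
  expect_equal(unclass(Tm),
               matrix(c(1/7, 4/7, 2/7, 1/7), 2, 2, byrow = TRUE),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_lt(max(abs(Tm - (unclass(X) + unclass(X) %*% unclass(Tm)))), 1e-9)
})

test_that("total relation agrees with the truncated-series oracle", {
  for (seed in 1:6) {
    n <- 2 + seed %% 5  # n in 2..6
    A <- random_direct(n, seed = 100 + seed)
    X <- normalize_direct(A)
    expect_lt(max(abs(Re(eigen(unclass(X), only.values = TRUE)$values))),
              1)
    Tm <- total_relation(X)
    expect_lt(max(abs(unclass(Tm) - series_total(X, 200))), 1e-8)
    # convergence is geometric: K = 60 already much closer than K = 15
    e15 <- max(abs(unclass(Tm) - series_total(X, 15)))
    e60 <- max(abs(unclass(Tm) - series_total(X, 60)))
    expect_lt(e60, e15)
  }
})

test_that("a row-stochastic normalized matrix is rejected, not regularized", {
  # all row sums equal -> X row-stochastic -> I - X singular
  v <- matrix(1, 3, 3); diag(v) <- 0
  X <- normalize_direct(direct_relation(v, cat3))
  expect_error(total_relation(X), "non-convergent")
})

test_that("profiles carry row/column sums and the strict cause rule", {
  Tm <- structure(matrix(c(0.1, 0.6, 0.2, 0.1), 2, 2, byrow = TRUE,
                         dimnames = list(c("F1", "F2"), c("F1", "F2"))),
                  catalog = cat2,
                  class = c("total_relation", "matrix", "array"))
  prof <- prominence_relation(Tm)
  expect_equal(prof$R, c(0.7, 0.3))
  expect_equal(prof$C, c(0.3, 0.7))
  expect_equal(prof$relation, c(0.4, -0.4))
  expect_equal(prof$prominence, prof$R + prof$C)
  expect_equal(prof$group, c("Cause", "Effect"))
  expect_equal(compute_threshold(Tm), 0.25)

  expect_equal(classify_group(c(0.31, -0.07)), c("Cause", "Effect"))
  expect_warning(g0 <- classify_group(0), "Effect")
  expect_equal(g0, "Effect")
  expect_error(classify_group(NaN), "finite")

  # symmetric A (unequal row sums) => symmetric T => all relations zero
  v <- matrix(c(0, 1, 2, 1, 0, 0.5, 2, 0.5, 0), 3, 3)
  Xs <- normalize_direct(direct_relation(v, cat3))
  Ts <- total_relation(Xs)
  ps <- suppressWarnings(prominence_relation(Ts))
  expect_equal(ps$relation, rep(0, 3), tolerance = 1e-12)
})

test_that("influence is conserved: sum(R) = sum(C) = sum(T)", {
  for (seed in c(3, 17)) {
    A <- random_direct(5, seed)
    res <- dematel(A)
    prof <- res$profiles
    expect_lt(abs(sum(prof$R) - sum(res$T)), 1e-9)
    expect_lt(abs(sum(prof$C) - sum(res$T)), 1e-9)
    expect_lt(abs(sum(prof$relation)), 1e-9)
  }
})

test_that("the pipeline is invariant to positive rescaling of A", {
  A <- random_direct(4, seed = 5)
  r1 <- dematel(A)
  r2 <- dematel(direct_relation(unclass(A) * 7.3, attr(A, "catalog")))
  expect_equal(unclass(r2$X), unclass(r1$X), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unclass(r2$T), unclass(r1$T), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(r2$profiles, r1$profiles, tolerance = 1e-12)
  expect_equal(r2$threshold, r1$threshold, tolerance = 1e-12)
})

test_that("relabeling factors permutes all outputs consistently", {
  A <- random_direct(5, seed = 9)
  res <- dematel(A)
  perm <- c(3, 1, 5, 2, 4)
  ids <- attr(A, "catalog")$factor_id
  Ap <- direct_relation(unclass(A)[perm, perm],
                        factor_catalog(ids[perm]))
  resp <- dematel(Ap)
  m <- match(res$profiles$factor_id, resp$profiles$factor_id)
  expect_equal(resp$profiles$prominence[m], res$profiles$prominence,
               tolerance = 1e-12)
  expect_equal(resp$profiles$relation[m], res$profiles$relation,
               tolerance = 1e-12)
  expect_equal(resp$profiles$group[m], res$profiles$group)
  expect_equal(resp$threshold, res$threshold, tolerance = 1e-12)
})

test_that("raising one direct influence never lowers its total influence", {
  A <- random_direct(5, seed = 21)
  v <- unclass(A)
  # bump a cell outside the max row without changing which row is max
  stopifnot(which.max(rowSums(v)) != 2)
  T0 <- dematel(direct_relation(v, attr(A, "catalog")))$T
  v2 <- v; v2[2, 4] <- v2[2, 4] + 0.1
  stopifnot(max(rowSums(v2)) == max(rowSums(v)))
  T1 <- dematel(direct_relation(v2, attr(A, "catalog")))$T
  expect_gte(unclass(T1)[2, 4], unclass(T0)[2, 4])
})

test_that("a single influence edge yields one Cause and one influenced factor", {
  v <- matrix(0, 3, 3); v[1, 2] <- 2
  res <- suppressWarnings(dematel(direct_relation(v, cat3)))
  prof <- res$profiles
  expect_equal(prof$group[prof$factor_id == "F1"], "Cause")
  expect_equal(sum(prof$group == "Cause"), 1)
  expect_equal(prof$C[prof$factor_id == "F2"], 1)
  expect_equal(prof$C[prof$factor_id == "F3"], 0)
})
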