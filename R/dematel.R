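#' Normalize a direct-relation matrix
#'
#' Divides the direct-relation matrix A by its largest row sum, the
#' classical DEMATEL normalization. Every entry of the result X lies in
#' \[0, 1\] and the row attaining the maximum row sum of A sums to exactly 1;
#' all other rows sum to less than 1, which is what makes the influence
#' series converge.
#'
#' @param A A [direct_relation()] matrix with at least one positive entry.
#' @return A `normalized_direct` matrix with attribute
#'   `normalizing_constant` (the max row sum of A).
#' @examples
#' cat2 <- factor_catalog(c("F1", "F2"))
#' A <- direct_relation(matrix(c(0, 1, 2, 0), 2, 2), cat2)
#' normalize_direct(A)  # constant 2, X = [[0, 1], [0.5, 0]]
#' @export
normalize_direct <- function(A) {
  stopifnot(inherits(A, "direct_relation"))
  s <- max(rowSums(A))
  if (s <= 0)
    stop("degenerate matrix (no influence): all entries are zero",
         call. = FALSE)
  structure(unclass(A) / s,
            catalog = attr(A, "catalog"),
            normalizing_constant = s,
            class = c("normalized_direct", "matrix", "array"))
}

#' Total-relation matrix
#'
#' Solves T = X (I - X)^-1, the closed form of the geometric series
#' X + X^2 + X^3 + ... that accumulates direct influence plus all indirect
#' influence transmitted through chains of intermediary factors. Computed
#' by a linear solve of (I - X)' Z' = X' rather than an explicit inverse.
#'
#' The series converges iff the spectral radius of X is below 1. With
#' max-row-sum normalization that holds unless every row of A attains the
#' maximum row sum (X row-stochastic), a degenerate system reported as an
#' error rather than silently regularized.
#'
#' @param X A `normalized_direct` matrix from [normalize_direct()].
#' @param max_condition Reciprocal-condition guard for I - X; a condition
#'   estimate above this raises an error. Default `1e12`.
#' @return A `total_relation` matrix (all entries non-negative).
#' @examples
#' cat2 <- factor_catalog(c("F1", "F2"))
#' A <- direct_relation(matrix(c(0, 0.5, 1, 0), 2, 2) * 2, cat2)
#' total_relation(normalize_direct(A))
#' @export
total_relation <- function(X, max_condition = 1e12) {
  stopifnot(inherits(X, "normalized_direct"))
  n <- nrow(X)
  ImX <- diag(n) - unclass(X)
  rc <- rcond(ImX)
  if (!is.finite(rc) || rc < 1 / max_condition)
    stop(sprintf(
      "non-convergent influence system: I - X has condition estimate %.3g",
      1 / rc), call. = FALSE)
  Tm <- unclass(X) %*% solve(ImX)
  # tiny negative round-off is numerically possible; anything material is a bug
  if (any(Tm < -1e-8))
    stop("total-relation matrix has negative entries; input is not a valid normalized matrix",
         call. = FALSE)
  Tm[Tm < 0] <- 0
  dimnames(Tm) <- dimnames(X)
  structure(Tm, catalog = attr(X, "catalog"),
            class = c("total_relation", "matrix", "array"))
}

#' Classify a factor by its net influence
#'
#' A factor with positive relation R - C dispatches more influence than it
#' receives and belongs to the cause group; a negative relation places it in
#' the effect group. An exact zero is classified Effect with a warning,
#' since cause membership is defined strictly by positivity.
#'
#' @param relation Numeric vector of R - C values (finite).
#' @return Character vector, `"Cause"` or `"Effect"`.
#' @examples
#' classify_group(c(0.31, -0.07))
#' @export
classify_group <- function(relation) {
  if (any(!is.finite(relation)))
    stop("relation values must be finite", call. = FALSE)
  if (any(relation == 0))
    warning("relation exactly 0 classified as Effect (cause group requires R - C > 0)",
            call. = FALSE)
  ifelse(relation > 0, "Cause", "Effect")
}

#' Prominence and relation profiles
#'
#' From the total-relation matrix T, R_i is the i-th row sum (influence the
#' factor dispatches to the system) and C_j the j-th column sum (influence
#' it receives). Their sum R + C ("prominence") measures how engaged a
#' factor is overall; their difference R - C ("relation") measures its net
#' role, splitting factors into the cause group (R - C > 0) and the effect
#' group.
#'
#' @param T_ A `total_relation` matrix from [total_relation()].
#' @return A data frame with one row per factor in catalog order and
#'   columns `factor_id`, `label`, `R`, `C`, `prominence`, `relation`,
#'   `group`.
#' @export
prominence_relation <- function(T_) {
  stopifnot(inherits(T_, "total_relation"))
  cat0 <- catalog_of(T_)
  R <- rowSums(T_)
  C <- colSums(T_)
  data.frame(factor_id = cat0$factor_id,
             label = cat0$label,
             R = unname(R), C = unname(C),
             prominence = unname(R + C),
             relation = unname(R - C),
             group = classify_group(unname(R - C)),
             stringsAsFactors = FALSE)
}

#' Mean-of-T edge threshold
#'
#' The conventional cut for drawing the causal network: the arithmetic mean
#' over all n^2 entries of the total-relation matrix, diagonal included.
#' Influences at or below it are treated as negligible.
#'
#' @param T_ A `total_relation` matrix.
#' @return A single number, the mean of all entries of T.
#' @export
compute_threshold <- function(T_) {
  stopifnot(inherits(T_, "total_relation"))
  mean(unclass(T_))
}

#' Run the full DEMATEL analysis
#'
#' Orchestrates the pipeline on a direct-relation matrix A: normalization
#' (X = A / max row sum), total-relation solve (T = X (I - X)^-1),
#' prominence/relation profiles with cause/effect grouping, the mean-of-T
#' threshold, and the thresholded causal network.
#'
#' @param A A [direct_relation()] matrix (or plain square matrix, which is
#'   validated against `catalog`).
#' @param catalog Optional [factor_catalog()] when `A` is a plain matrix;
#'   ignored if `A` is already typed.
#' @param threshold Optional override for the network edge threshold;
#'   default is the mean of all entries of T.
#' @param edge_rule `"strict"` keeps edges with t_ij > threshold (default);
#'   `"inclusive"` keeps t_ij >= threshold.
#' @return A `dematel_result` list with elements `A`, `X`, `T`, `profiles`,
#'   `threshold`, `network`, `normalizing_constant` and `provenance`.
#' @examples
#' A <- fpt_direct_relation()
#' res <- dematel(A)
#' res$threshold
#' subset(res$profiles, group == "Cause")$factor_id
#' @export
dematel <- function(A, catalog = NULL, threshold = NULL,
                    edge_rule = c("strict", "inclusive")) {
  edge_rule <- match.arg(edge_rule)
  if (!inherits(A, "direct_relation")) {
    if (is.null(catalog))
      catalog <- factor_catalog(rownames(as.matrix(A)))
    A <- direct_relation(A, catalog)
  }
  X <- normalize_direct(A)
  T_ <- total_relation(X)
  profiles <- prominence_relation(T_)
  thr <- if (is.null(threshold)) compute_threshold(T_) else threshold
  net <- build_network(T_, profiles, thr, edge_rule = edge_rule)
  structure(list(
    A = A, X = X, T = T_,
    profiles = profiles,
    threshold = thr,
    network = net,
    normalizing_constant = attr(X, "normalizing_constant"),
    provenance = list(
      package = "dematelr",
      version = as.character(utils::packageVersion("dematelr")),
      threshold_rule = if (is.null(threshold)) "mean_of_T" else "override",
      edge_rule = edge_rule)),
    class = "dematel_result")
}

#' @export
print.dematel_result <- function(x, digits = 2, ...) {
  cat(sprintf("DEMATEL analysis of %d factors\n", nrow(x$profiles)))
  cat(sprintf("  normalizing constant (max row sum of A): %.4f\n",
              x$normalizing_constant))
  cat(sprintf("  edge threshold: %.3f (%s)\n", x$threshold,
              x$provenance$threshold_rule))
  cat(sprintf("  cause group: %s\n",
              paste(x$profiles$factor_id[x$profiles$group == "Cause"],
                    collapse = ", ")))
  cat(sprintf("  effect group: %s\n",
              paste(x$profiles$factor_id[x$profiles$group == "Effect"],
                    collapse = ", ")))
  prof <- x$profiles
  for (col in c("R", "C", "prominence", "relation"))
    prof[[col]] <- round_half_away(prof[[col]], digits)
  print(prof[, c("factor_id", "R", "C", "prominence", "relation", "group")],
        row.names = FALSE)
  invisible(x)
}
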