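#' Construct one expert's score matrix
#'
#' Each expert rates the direct influence of every factor on every other
#' factor with an integer score from 0 (no influence) to `scale_max`
#' (very strong influence). The diagonal is zero by convention: a factor
#' is not rated as influencing itself.
#'
#' @param scores Square integer matrix of ratings; rows are the influencing
#'   factor, columns the influenced factor.
#' @param catalog A [factor_catalog()] fixing the factor order.
#' @param expert_id Token identifying the expert (used in error messages and
#'   file names).
#' @param scale_max Upper end of the integer rating scale. Default 3.
#' @return An `expert_scores` matrix with the catalog attached.
#' @examples
#' cat2 <- factor_catalog(c("F1", "F2"))
#' expert_scores(matrix(c(0, 2, 1, 0), 2, 2), cat2, "E1")
#' @export
expert_scores <- function(scores, catalog, expert_id = "expert",
                          scale_max = 3L) {
  stopifnot(inherits(catalog, "factor_catalog"))
  scores <- as.matrix(scores)
  scores <- check_catalog_dimnames(scores, catalog,
                                   sprintf("scores of expert '%s'", expert_id))
  bad <- which(!is.finite(scores) | scores != floor(scores) |
                 scores < 0 | scores > scale_max, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf(
      "expert '%s': score at (%s, %s) is outside the integer scale 0..%d",
      expert_id, rownames(scores)[bad[1, 1]], colnames(scores)[bad[1, 2]],
      scale_max), call. = FALSE)
  nz <- which(diag(scores) != 0)
  if (length(nz) > 0)
    stop(sprintf("expert '%s': non-zero diagonal at %s",
                 expert_id,
                 paste(catalog$factor_id[nz], collapse = ", ")),
         call. = FALSE)
  structure(scores, catalog = catalog, expert_id = expert_id,
            scale_max = as.integer(scale_max),
            class = c("expert_scores", class(scores)))
}

#' Aggregate an expert panel into a direct-relation matrix
#'
#' The direct-relation matrix A is the unweighted elementwise arithmetic
#' mean of the panel's score matrices: a_ij = (1/m) sum_k a_ij^k. No
#' per-expert weighting is offered; all experts count equally.
#'
#' @param panel Non-empty list of [expert_scores()] matrices sharing one
#'   catalog and rating scale.
#' @return A `direct_relation` matrix with attributes `catalog`,
#'   `m_experts` and `scale_max`.
#' @examples
#' cat2 <- factor_catalog(c("F1", "F2"))
#' e1 <- expert_scores(matrix(c(0, 2, 1, 0), 2, 2), cat2, "E1")
#' e2 <- expert_scores(matrix(c(0, 3, 2, 0), 2, 2), cat2, "E2")
#' aggregate_panel(list(e1, e2))
#' @export
aggregate_panel <- function(panel) {
  if (!is.list(panel) || length(panel) == 0L)
    stop("empty panel", call. = FALSE)
  if (!all(vapply(panel, inherits, logical(1), "expert_scores")))
    stop("panel members must be expert_scores objects", call. = FALSE)
  cat0 <- attr(panel[[1]], "catalog")
  smax <- attr(panel[[1]], "scale_max")
  for (e in panel) {
    if (!identical(attr(e, "catalog")$factor_id, cat0$factor_id) ||
        !identical(attr(e, "scale_max"), smax))
      stop("incompatible panel: members differ in catalog or scale",
           call. = FALSE)
  }
  acc <- Reduce(`+`, lapply(panel, unclass))
  values <- acc / length(panel)
  diag(values) <- 0
  direct_relation(values, cat0, m_experts = length(panel),
                  scale_max = smax)
}

#' Validate (or construct) a direct-relation matrix
#'
#' Wraps a pre-aggregated matrix of mean influence scores — such as a
#' published direct-relation table — as a typed `direct_relation` object
#' after checking shape, non-negativity and the zero diagonal.
#'
#' @param values Square numeric matrix of non-negative mean scores.
#' @param catalog A [factor_catalog()]; its order must match the matrix.
#' @param m_experts Number of experts averaged, if known (`NA` otherwise).
#' @param scale_max Rating scale ceiling the means were formed on.
#' @param diagonal `"error"` (default) rejects a non-zero diagonal;
#'   `"coerce"` zeroes it with a warning.
#' @return A `direct_relation` matrix.
#' @examples
#' cat2 <- factor_catalog(c("F1", "F2"))
#' direct_relation(matrix(c(0, 1.5, 2.5, 0), 2, 2), cat2)
#' @export
direct_relation <- function(values, catalog, m_experts = NA_integer_,
                            scale_max = 3L,
                            diagonal = c("error", "coerce")) {
  diagonal <- match.arg(diagonal)
  stopifnot(inherits(catalog, "factor_catalog"))
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop(sprintf("direct-relation matrix must be square (got %dx%d)",
                 nrow(values), ncol(values)), call. = FALSE)
  values <- check_catalog_dimnames(values, catalog, "direct-relation matrix")
  if (any(!is.finite(values)))
    stop("direct-relation matrix has non-finite entries", call. = FALSE)
  if (any(values < 0))
    stop("direct-relation matrix has negative entries", call. = FALSE)
  nz <- which(diag(values) != 0)
  if (length(nz) > 0) {
    if (diagonal == "coerce") {
      warning("coercing non-zero diagonal to zero at ",
              paste(catalog$factor_id[nz], collapse = ", "), call. = FALSE)
      diag(values) <- 0
    } else {
      stop("non-zero diagonal at ",
           paste(catalog$factor_id[nz], collapse = ", "),
           "; use diagonal = \"coerce\" to zero it", call. = FALSE)
    }
  }
  structure(values, catalog = catalog,
            m_experts = as.integer(m_experts),
            scale_max = as.integer(scale_max),
            class = c("direct_relation", "matrix", "array"))
}

#' @export
print.direct_relation <- function(x, digits = 2, ...) {
  m <- attr(x, "m_experts")
  cat(sprintf("Direct-relation matrix (%d factors%s)\n", nrow(x),
              if (is.na(m)) "" else sprintf(", mean of %d experts", m)))
  print(round(unclass(x), digits), ...)
  invisible(x)
}
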