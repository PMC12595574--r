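#' Create a factor catalog
#'
#' A factor catalog fixes the identity and order of the factors in an
#' influence system. Every matrix in a DEMATEL analysis (expert scores,
#' direct-relation, normalized, total-relation) is indexed by one catalog:
#' row i is the influencing factor, column j the influenced factor, and the
#' order given here is significant and shared by all of them.
#'
#' @param factor_id Character vector of unique, non-empty factor identifiers
#'   (short tokens such as `"F1"`).
#' @param label Character vector of human-readable labels, parallel to
#'   `factor_id`. Defaults to the ids themselves.
#' @return A `factor_catalog`: a data frame with columns `factor_id` and
#'   `label`, one row per factor, in fixed order.
#' @examples
#' factor_catalog(c("F1", "F2", "F3"), c("needs", "trust", "teamwork"))
#' @export
factor_catalog <- function(factor_id, label = factor_id) {
  factor_id <- as.character(factor_id)
  label <- as.character(label)
  if (length(factor_id) < 2L)
    stop("a factor catalog needs at least 2 factors", call. = FALSE)
  if (length(label) != length(factor_id))
    stop("'label' must be parallel to 'factor_id'", call. = FALSE)
  if (anyDuplicated(factor_id))
    stop("duplicate factor_id: ",
         paste(unique(factor_id[duplicated(factor_id)]), collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(factor_id)) || anyNA(factor_id))
    stop("factor_id entries must be non-empty", call. = FALSE)
  structure(data.frame(factor_id = factor_id, label = label,
                       stringsAsFactors = FALSE),
            class = c("factor_catalog", "data.frame"))
}

#' @export
print.factor_catalog <- function(x, ...) {
  cat("Factor catalog with", nrow(x), "factors\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Number of factors in a catalog
#' @param catalog A [factor_catalog()].
#' @return Integer count of factors.
#' @export
n_factors <- function(catalog) {
  stopifnot(inherits(catalog, "factor_catalog"))
  nrow(catalog)
}

# Internal: check that a matrix's dimnames agree with the catalog order.
check_catalog_dimnames <- function(values, catalog, what = "matrix") {
  ids <- catalog$factor_id
  if (nrow(values) != length(ids) || ncol(values) != length(ids))
    stop(sprintf("%s must be %dx%d to match the catalog (got %dx%d)",
                 what, length(ids), length(ids), nrow(values), ncol(values)),
         call. = FALSE)
  dn <- dimnames(values)
  if (is.null(dn)) {
    dimnames(values) <- list(ids, ids)
  } else {
    if (!identical(dn[[1]], ids) || !identical(dn[[2]], ids))
      stop(sprintf("%s dimnames do not match the catalog order", what),
           call. = FALSE)
  }
  values
}

# Internal: catalog attached to a matrix object, with fallback from dimnames.
catalog_of <- function(x) {
  cat <- attr(x, "catalog")
  if (is.null(cat)) cat <- factor_catalog(rownames(x))
  cat
}
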