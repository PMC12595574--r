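#' Read a labeled square matrix from CSV
#'
#' Parses the labeled-matrix CSV dialect used throughout the package: the
#' first row is a blank corner cell followed by the factor ids; each
#' subsequent row is a factor id followed by n numeric cells (UTF-8, "."
#' decimal separator). If a catalog is supplied, row/column labels are
#' verified against it; a permuted but complete label set is reordered to
#' catalog order, a set-wise mismatch is an error.
#'
#' @param path Path to the CSV file.
#' @param catalog Optional [factor_catalog()] to verify and order against.
#' @return Numeric matrix with dimnames, in catalog order when a catalog
#'   is given.
#' @examples
#' p <- system.file("extdata", "fpt_direct_relation.csv",
#'                  package = "dematelr")
#' A <- read_matrix_csv(p)
#' A["F1", "F2"]  # 2.26
#' @export
read_matrix_csv <- function(path, catalog = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("not a labeled-matrix CSV: ", path,
                              call. = FALSE)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  col_ids <- trimws(header[-1])
  n <- length(col_ids)
  row_ids <- character(length(lines) - 1)
  values <- matrix(NA_real_, length(lines) - 1, n)
  for (i in seq_along(row_ids)) {
    cells <- trimws(strsplit(lines[i + 1], ",", fixed = TRUE)[[1]])
    if (length(cells) != n + 1)
      stop(sprintf("line %d of %s: expected %d cells, found %d",
                   i + 1, path, n + 1, length(cells)), call. = FALSE)
    row_ids[i] <- cells[1]
    num <- suppressWarnings(as.numeric(cells[-1]))
    if (anyNA(num))
      stop(sprintf("line %d of %s: non-numeric cell '%s'",
                   i + 1, path, cells[-1][which(is.na(num))[1]]),
           call. = FALSE)
    values[i, ] <- num
  }
  dimnames(values) <- list(row_ids, col_ids)
  if (!setequal(row_ids, col_ids)) {
    mr <- setdiff(col_ids, row_ids)
    mc <- setdiff(row_ids, col_ids)
    stop("row/column label mismatch in ", path,
         if (length(mr)) paste0("; missing rows: ",
                                paste(mr, collapse = ", ")),
         if (length(mc)) paste0("; missing columns: ",
                                paste(mc, collapse = ", ")),
         call. = FALSE)
  }
  if (nrow(values) != ncol(values))
    stop(sprintf("matrix in %s is not square (%dx%d): duplicated labels",
                 path, nrow(values), ncol(values)), call. = FALSE)
  if (!is.null(catalog)) {
    ids <- catalog$factor_id
    missing_ids <- setdiff(ids, row_ids)
    extra <- setdiff(row_ids, ids)
    if (length(missing_ids) > 0 || length(extra) > 0)
      stop("label set mismatch in ", path,
           if (length(missing_ids)) paste0("; missing: ",
                                           paste(missing_ids, collapse = ", ")),
           if (length(extra)) paste0("; unexpected: ",
                                     paste(extra, collapse = ", ")),
           call. = FALSE)
    values <- values[ids, ids, drop = FALSE]
  } else {
    values <- values[, row_ids, drop = FALSE]  # align columns to row order
  }
  values
}

#' Write a labeled square matrix to CSV
#'
#' Inverse of [read_matrix_csv()]. By default values are written with
#' enough digits to round-trip exactly; pass `digits` for fixed-decimal
#' display output.
#'
#' @param values Matrix with dimnames (any of the package's matrix types).
#' @param path Output path.
#' @param digits Decimal places for display output; `NULL` (default)
#'   writes full precision.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(values, path, digits = NULL) {
  values <- as.matrix(unclass(values))
  fmt <- if (is.null(digits)) format_full else function(x) format_fixed(x, digits)
  lines <- c(paste(c("", colnames(values)), collapse = ","),
             vapply(seq_len(nrow(values)), function(i)
               paste(c(rownames(values)[i], fmt(values[i, ])),
                     collapse = ","), character(1)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a factor catalog from CSV or JSON
#'
#' CSV files need columns `factor_id` and `label`; JSON files hold an
#' array of objects with those fields (or a `factors` wrapper object).
#'
#' @param path Path ending in `.csv` or `.json`.
#' @return A [factor_catalog()].
#' @examples
#' p <- system.file("extdata", "fpt_factors.csv", package = "dematelr")
#' read_factor_catalog(p)
#' @export
read_factor_catalog <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (is.list(obj) && !is.data.frame(obj) && !is.null(obj$factors))
      obj <- obj$factors
    df <- as.data.frame(obj, stringsAsFactors = FALSE)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (!all(c("factor_id", "label") %in% names(df)))
    stop("catalog file must provide factor_id and label: ", path,
         call. = FALSE)
  factor_catalog(df$factor_id, df$label)
}

#' Write a full analysis to a directory
#'
#' Emits the complete artifact set for a [dematel()] result: the three
#' matrices (`A.csv`, `X.csv`, `T.csv`), the profiles table
#' (`profiles.csv`), the cause-effect diagram coordinates (`coords.csv`),
#' the thresholded network (`network.dot`, `network.graphml`, `edges.csv`)
#' and a `result.json` carrying full-precision values plus a
#' display-rounded block. Content is deterministic for a fixed input:
#' rerunning writes byte-identical files.
#'
#' @param result A `dematel_result` from [dematel()].
#' @param dir Output directory (created if missing).
#' @param precision Decimal places for the display CSVs; `NULL` (default)
#'   writes matrices at full precision. `result.json` always keeps full
#'   precision.
#' @return Character vector of the files written, invisibly.
#' @export
write_analysis <- function(result, dir, precision = NULL) {
  stopifnot(inherits(result, "dematel_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("A.csv", "X.csv", "T.csv", "profiles.csv",
                            "coords.csv", "network.dot", "network.graphml",
                            "edges.csv", "result.json"))
  names(paths) <- basename(paths)
  write_matrix_csv(result$A, paths["A.csv"], digits = precision)
  write_matrix_csv(result$X, paths["X.csv"], digits = precision)
  write_matrix_csv(result$T, paths["T.csv"], digits = precision)

  prof <- result$profiles
  disp <- prof
  if (!is.null(precision))
    for (col in c("R", "C", "prominence", "relation"))
      disp[[col]] <- format_fixed(disp[[col]], precision)
  else
    for (col in c("R", "C", "prominence", "relation"))
      disp[[col]] <- format_full(disp[[col]])
  utils::write.csv(disp, paths["profiles.csv"], row.names = FALSE,
                   quote = TRUE)

  coords <- cause_effect_coords(result)
  cdisp <- coords
  fmt <- if (is.null(precision)) format_full else function(x) format_fixed(x, precision)
  cdisp$prominence <- fmt(coords$prominence)
  cdisp$relation <- fmt(coords$relation)
  utils::write.csv(cdisp, paths["coords.csv"], row.names = FALSE,
                   quote = TRUE)

  writeLines(export_network(result$network, "dot", digits = precision),
             paths["network.dot"], sep = "", useBytes = TRUE)
  writeLines(export_network(result$network, "graphml", digits = precision),
             paths["network.graphml"], sep = "", useBytes = TRUE)
  writeLines(export_network(result$network, "edgelist", digits = precision),
             paths["edges.csv"], sep = "", useBytes = TRUE)

  display <- result$profiles
  for (col in c("R", "C", "prominence", "relation"))
    display[[col]] <- round_half_away(display[[col]],
                                      if (is.null(precision)) 2 else precision)
  payload <- list(
    catalog = attr(result$A, "catalog"),
    m_experts = attr(result$A, "m_experts"),
    normalizing_constant = result$normalizing_constant,
    threshold = result$threshold,
    profiles = result$profiles,
    profiles_display = display,
    A = unclass(result$A), X = unclass(result$X), T = unclass(result$T),
    edges = result$network$edges,
    edge_rule = result$network$edge_rule,
    provenance = result$provenance)
  jsonlite::write_json(payload, paths["result.json"], auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(unname(paths))
}
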