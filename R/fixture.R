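#' The family-physician-team motivator study matrices
#'
#' Accessors for the packaged 15-motivator study of integrated-care
#' delivery by family physician teams: 15 factors (F1-F15) spanning
#' resident, team, institution and government levels, rated by a panel of
#' 20 experts on a 0-3 influence scale and averaged into the
#' direct-relation matrix shipped here at its published 2-decimal
#' precision.
#'
#' `fpt_catalog()` returns the factor catalog. Labels for F2, F8, F9 and
#' F14 were not available in transcribed form and are shipped as marked
#' placeholders; pass your own catalog file to override them.
#' `fpt_direct_relation()` returns the aggregated direct-relation matrix.
#' `fpt_total_relation_reported()` and `fpt_profiles_reported()` return
#' the study's published total-relation matrix and prominence/relation
#' table, as reference values for comparison against recomputation (they
#' are not inputs to any analysis).
#'
#' @return A [factor_catalog()], a `direct_relation` matrix, a plain
#'   numeric matrix, or a data frame, respectively.
#' @examples
#' A <- fpt_direct_relation()
#' res <- dematel(A)
#' round(res$threshold, 3)
#' @name fpt_fixture
NULL

#' @rdname fpt_fixture
#' @export
fpt_catalog <- function() {
  read_factor_catalog(system.file("extdata", "fpt_factors.csv",
                                  package = "dematelr", mustWork = TRUE))
}

#' @rdname fpt_fixture
#' @export
fpt_direct_relation <- function() {
  cat0 <- fpt_catalog()
  values <- read_matrix_csv(system.file("extdata",
                                        "fpt_direct_relation.csv",
                                        package = "dematelr",
                                        mustWork = TRUE), cat0)
  direct_relation(values, cat0, m_experts = 20L, scale_max = 3L)
}

#' @rdname fpt_fixture
#' @export
fpt_total_relation_reported <- function() {
  read_matrix_csv(system.file("extdata", "fpt_total_relation_reported.csv",
                              package = "dematelr", mustWork = TRUE),
                  fpt_catalog())
}

#' @rdname fpt_fixture
#' @export
fpt_profiles_reported <- function() {
  utils::read.csv(system.file("extdata", "fpt_profiles_reported.csv",
                              package = "dematelr", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
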