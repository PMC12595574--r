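#' Build the thresholded causal influence digraph
#'
#' Keeps the directed edge i -> j when the total influence t_ij exceeds the
#' threshold (strictly by default), dropping everything else as negligible.
#' Self-loops are never drawn: the diagram shows inter-factor influence
#' only, even though diagonal entries of T count toward the mean-of-T
#' threshold. Every catalog factor appears as a node, isolated or not, and
#' nodes carry their (prominence, relation) coordinates — the axes of the
#' cause-effect diagram — plus the group label.
#'
#' @param T_ A `total_relation` matrix.
#' @param profiles Profiles data frame from [prominence_relation()];
#'   computed from `T_` if omitted.
#' @param threshold Finite edge cut-off; default [compute_threshold()] of
#'   `T_`. A negative threshold is allowed but warned about (the network
#'   will be near-complete).
#' @param edge_rule `"strict"` keeps t_ij > threshold (default);
#'   `"inclusive"` keeps t_ij >= threshold.
#' @return A `causal_network` list with `nodes` (factor_id, label,
#'   prominence, relation, group), `edges` (source, target, weight, in
#'   catalog order by source then target), `threshold` and `edge_rule`.
#' @examples
#' res <- dematel(fpt_direct_relation())
#' net <- res$network
#' nrow(net$edges)
#' @export
build_network <- function(T_, profiles = NULL, threshold = NULL,
                          edge_rule = c("strict", "inclusive")) {
  edge_rule <- match.arg(edge_rule)
  stopifnot(inherits(T_, "total_relation"))
  cat0 <- catalog_of(T_)
  if (is.null(profiles)) profiles <- prominence_relation(T_)
  if (!identical(profiles$factor_id, cat0$factor_id))
    stop("profiles do not match the catalog of T", call. = FALSE)
  if (is.null(threshold)) threshold <- compute_threshold(T_)
  if (!is.finite(threshold))
    stop("threshold must be finite", call. = FALSE)
  if (threshold < 0)
    warning("negative threshold: network will be near-complete",
            call. = FALSE)
  n <- nrow(T_)
  keep <- if (edge_rule == "strict") unclass(T_) > threshold
          else unclass(T_) >= threshold
  diag(keep) <- FALSE
  idx <- which(t(keep), arr.ind = TRUE)  # transpose => source-major order
  edges <- data.frame(
    source = cat0$factor_id[idx[, 2]],
    target = cat0$factor_id[idx[, 1]],
    weight = unclass(T_)[cbind(idx[, 2], idx[, 1])],
    stringsAsFactors = FALSE)
  nodes <- profiles[, c("factor_id", "label", "prominence", "relation",
                        "group")]
  structure(list(nodes = nodes, edges = edges, threshold = threshold,
                 edge_rule = edge_rule, catalog = cat0),
            class = "causal_network")
}

#' @export
print.causal_network <- function(x, ...) {
  cat(sprintf(
    "Causal network: %d nodes, %d edges (threshold %.3f, rule %s)\n",
    nrow(x$nodes), nrow(x$edges), x$threshold, x$edge_rule))
  invisible(x)
}

#' Serialize a causal network
#'
#' Renders the network as Graphviz DOT, GraphML, or an edge-list CSV.
#' Nodes carry label, prominence, relation and group attributes; edges
#' carry their total-influence weight. Output ordering is deterministic:
#' nodes in catalog order, edges by source then target.
#'
#' @param net A `causal_network` from [build_network()].
#' @param format One of `"dot"`, `"graphml"`, `"edgelist"`.
#' @param digits Decimal places for weights/coordinates in the output;
#'   `NULL` (default) writes full precision.
#' @return A single character string, the serialized document.
#' @examples
#' net <- dematel(fpt_direct_relation())$network
#' cat(substr(export_network(net, "dot"), 1, 200))
#' @export
export_network <- function(net, format = c("dot", "graphml", "edgelist"),
                           digits = NULL) {
  stopifnot(inherits(net, "causal_network"))
  if (!is.character(format) || !format[1] %in% c("dot", "graphml", "edgelist"))
    stop("unknown format '", format[1],
         "'; supported: dot, graphml, edgelist", call. = FALSE)
  format <- match.arg(format)
  num <- if (is.null(digits)) format_full else function(x) format_fixed(x, digits)
  switch(format,
         dot = export_dot(net, num),
         graphml = export_graphml(net, num),
         edgelist = export_edgelist(net, num))
}

export_dot <- function(net, num) {
  esc <- function(x) gsub('"', '\\\\"', x)
  lines <- c("digraph causal_network {")
  for (i in seq_len(nrow(net$nodes))) {
    nd <- net$nodes[i, ]
    lines <- c(lines, sprintf(
      '  "%s" [label="%s", prominence=%s, relation=%s, group="%s"];',
      esc(nd$factor_id), esc(nd$label), num(nd$prominence),
      num(nd$relation), nd$group))
  }
  for (i in seq_len(nrow(net$edges))) {
    ed <- net$edges[i, ]
    lines <- c(lines, sprintf('  "%s" -> "%s" [weight=%s];',
                              esc(ed$source), esc(ed$target),
                              num(ed$weight)))
  }
  paste0(paste(c(lines, "}"), collapse = "\n"), "\n")
}

export_graphml <- function(net, num) {
  xml_esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  head <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="label" for="node" attr.name="label" attr.type="string"/>',
    '  <key id="prominence" for="node" attr.name="prominence" attr.type="double"/>',
    '  <key id="relation" for="node" attr.name="relation" attr.type="double"/>',
    '  <key id="group" for="node" attr.name="group" attr.type="string"/>',
    '  <key id="weight" for="edge" attr.name="weight" attr.type="double"/>',
    '  <graph id="causal_network" edgedefault="directed">')
  nodes <- vapply(seq_len(nrow(net$nodes)), function(i) {
    nd <- net$nodes[i, ]
    paste0(
      sprintf('    <node id="%s">\n', xml_esc(nd$factor_id)),
      sprintf('      <data key="label">%s</data>\n', xml_esc(nd$label)),
      sprintf('      <data key="prominence">%s</data>\n', num(nd$prominence)),
      sprintf('      <data key="relation">%s</data>\n', num(nd$relation)),
      sprintf('      <data key="group">%s</data>\n', nd$group),
      "    </node>")
  }, character(1))
  edges <- vapply(seq_len(nrow(net$edges)), function(i) {
    ed <- net$edges[i, ]
    paste0(
      sprintf('    <edge source="%s" target="%s">\n',
              xml_esc(ed$source), xml_esc(ed$target)),
      sprintf('      <data key="weight">%s</data>\n', num(ed$weight)),
      "    </edge>")
  }, character(1))
  paste0(paste(c(head, nodes, edges, "  </graph>", "</graphml>"),
               collapse = "\n"), "\n")
}

export_edgelist <- function(net, num) {
  lines <- c("source,target,weight",
             if (nrow(net$edges) > 0)
               sprintf("%s,%s,%s", net$edges$source, net$edges$target,
                       num(net$edges$weight)))
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Read an edge-list CSV back into edge form
#'
#' Inverse of `export_network(net, "edgelist")`: parses the three-column
#' CSV into a data frame of directed weighted edges.
#'
#' @param path Path to an edge-list CSV with header `source,target,weight`.
#' @return Data frame with columns `source`, `target`, `weight`.
#' @export
read_edgelist <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), c("source", "target", "weight")))
    stop("edge-list CSV must have columns source,target,weight",
         call. = FALSE)
  df
}

#' Cause-effect diagram coordinates
#'
#' The scatter coordinates of the cause-effect diagram: each factor plotted
#' at (prominence, relation), with the cause group in the upper half-plane.
#'
#' @param x A `dematel_result`, `causal_network`, or profiles data frame.
#' @return Data frame with columns `factor_id`, `prominence`, `relation`,
#'   `group`.
#' @export
cause_effect_coords <- function(x) {
  prof <- if (inherits(x, "dematel_result")) x$profiles
          else if (inherits(x, "causal_network")) x$nodes
          else x
  prof[, c("factor_id", "prominence", "relation", "group")]
}
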