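fixture_result <- dematel(fpt_direct_relation())

test_that("edges are exactly the supra-threshold off-diagonal cells", {
  res <- fixture_result
  net <- res$network
  Tm <- unclass(res$T)
  # brute-force cell count over T
  expected <- sum(Tm > res$threshold) -
    sum(diag(Tm) > res$threshold)
  expect_equal(nrow(net$edges), expected)
  expect_true(all(net$edges$weight > net$threshold))
  expect_false(any(net$edges$source == net$edges$target))
  expect_equal(net$nodes$factor_id, fpt_catalog()$factor_id)

  # spot checks against the published total-relation table
  expect_true(any(net$edges$source == "F10" & net$edges$target == "F5"))
  expect_false(any(net$edges$source == "F2" & net$edges$target == "F15"))
})

test_that("edge rule boundaries behave: strict vs inclusive, extremes", {
  res <- fixture_result
  Tm <- res$T
  prof <- res$profiles
  w <- unclass(Tm)[1, 2]
  strict <- build_network(Tm, prof, threshold = w, edge_rule = "strict")
  incl <- build_network(Tm, prof, threshold = w, edge_rule = "inclusive")
  expect_false(any(strict$edges$source == "F1" & strict$edges$target == "F2"))
  expect_true(any(incl$edges$source == "F1" & incl$edges$target == "F2"))
  expect_true(nrow(incl$edges) >= nrow(strict$edges))

  # above the max entry: empty graph, nodes retained
  empty <- build_network(Tm, prof, threshold = max(Tm) + 1)
  expect_equal(nrow(empty$edges), 0)
  expect_equal(nrow(empty$nodes), 15)

  # below the min off-diagonal entry: complete digraph n(n-1)
  offdiag <- unclass(Tm)[row(Tm) != col(Tm)]
  full <- build_network(Tm, prof, threshold = min(offdiag) - 1e-9)
  expect_equal(nrow(full$edges), 15 * 14)

  expect_warning(build_network(Tm, prof, threshold = -1), "near-complete")
  expect_error(build_network(Tm, prof, threshold = Inf), "finite")

  # edge count is non-increasing in the threshold
  thr <- seq(0.4, 0.7, by = 0.05)
  counts <- vapply(thr, function(th)
    nrow(build_network(Tm, prof, threshold = th)$edges), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("DOT export carries nodes, edges, and attributes deterministically", {
  res <- fixture_result
  dot <- export_network(res$network, "dot", digits = 3)
  expect_equal(length(gregexpr("\\[label=", dot)[[1]]), 15)
  expect_equal(length(gregexpr("->", dot, fixed = TRUE)[[1]]),
               nrow(res$network$edges))
  expect_match(dot, 'group="Cause"')

  empty <- build_network(res$T, res$profiles, threshold = max(res$T) + 1)
  dot0 <- export_network(empty, "dot")
  expect_equal(length(gregexpr("\\[label=", dot0)[[1]]), 15)
  expect_false(grepl("->", dot0, fixed = TRUE))

  single <- build_network(res$T, res$profiles,
                          threshold = max(unclass(res$T) *
                                            (row(res$T) != col(res$T))) -
                            1e-9)
  dots <- export_network(single, "dot")
  expect_equal(length(gregexpr("->", dots, fixed = TRUE)[[1]]), 1)
  expect_match(dots, "\\[weight=")

  expect_identical(export_network(res$network, "dot"),
                   export_network(res$network, "dot"))
  expect_error(export_network(res$network, "gexf"), "supported")
})

test_that("edge-list CSV round-trips the edge set and weights", {
  net <- fixture_result$network
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(export_network(net, "edgelist"), path, sep = "")
  back <- read_edgelist(path)
  expect_equal(back$source, net$edges$source)
  expect_equal(back$target, net$edges$target)
  expect_equal(back$weight, net$edges$weight)  # full stored precision
})

test_that("GraphML export is readable by an independent graph library", {
  skip_if_not_installed("igraph")
  net <- fixture_result$network
  path <- withr::local_tempfile(fileext = ".graphml")
  writeLines(export_network(net, "graphml"), path, sep = "")
  g <- igraph::read_graph(path, format = "graphml")
  expect_true(igraph::is_directed(g))
  expect_equal(igraph::vcount(g), 15)
  expect_equal(igraph::ecount(g), nrow(net$edges))
  ids <- igraph::V(g)$id
  el <- igraph::as_edgelist(g, names = FALSE)
  expect_setequal(paste(ids[el[, 1]], ids[el[, 2]]),
                  paste(net$edges$source, net$edges$target))
  expect_equal(sort(igraph::E(g)$weight), sort(net$edges$weight),
               tolerance = 1e-12)
  expect_setequal(unique(igraph::V(g)$group), c("Cause", "Effect"))
})

test_that("cause-effect coordinates expose (prominence, relation) per factor", {
  coords <- cause_effect_coords(fixture_result)
  expect_equal(names(coords),
               c("factor_id", "prominence", "relation", "group"))
  expect_equal(nrow(coords), 15)
  expect_true(all(coords$relation[coords$group == "Cause"] > 0))
})
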