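tiny_table <- function() {
  data.frame(hub = c("H1", "H1", "H1"),
             partner = c("P1", "P2", "P3"),
             class = c("redox", "signaling", "unknown"),
             known = c(TRUE, FALSE, FALSE),
             stringsAsFactors = FALSE)
}

test_that("network construction attaches attributes deterministically", {
  g <- build_network(tiny_table(), "H1")
  expect_equal(igraph::vcount(g), 4L)
  expect_equal(igraph::ecount(g), 3L)
  expect_equal(igraph::V(g)$name[1], "H1")
  expect_true(igraph::V(g)$is_hub[1])
  expect_equal(igraph::V(g)$class[igraph::V(g)$name == "P2"], "signaling")
  expect_true(igraph::V(g)$known[igraph::V(g)$name == "P1"])
  # duplicate rows collapse with multiplicity
  tab2 <- rbind(tiny_table(), tiny_table()[2, ])
  g2 <- build_network(tab2, "H1")
  expect_equal(igraph::ecount(g2), 3L)
  ends2 <- igraph::ends(g2, igraph::E(g2))
  dup <- which(ends2[, 2] == "P2" | ends2[, 1] == "P2")
  expect_equal(igraph::E(g2)$multiplicity[dup], 2L)
  # self edges dropped with a warning; unknown class labels rejected
  tab3 <- rbind(tiny_table(), data.frame(hub = "H1", partner = "H1",
                                         class = "redox", known = FALSE))
  expect_warning(g3 <- build_network(tab3, "H1"), "self-edge")
  expect_equal(igraph::ecount(g3), 3L)
  tab4 <- tiny_table(); tab4$class[2] <- "mystery"
  expect_error(build_network(tab4, "H1"), "valid vocabulary")
})

test_that("co-expression overlay flags strict threshold exceedance only", {
  g <- build_network(tiny_table(), "H1")
  prof <- c(1, 5, 2, 8, 3, 9)
  v <- rbind(H1 = prof, P1 = prof + rnorm(6, sd = 0.01), P2 = rev(prof))
  colnames(v) <- paste0("s", 1:6)
  x <- expression_set(v, setNames(rep(c("a", "b"), 3), colnames(v)))
  g <- overlay_coexpression(g, x, threshold = 0.5)
  ends_g <- igraph::ends(g, igraph::E(g))
  other <- ifelse(ends_g[, 1] == "H1", ends_g[, 2], ends_g[, 1])
  pcc <- setNames(igraph::E(g)$pcc, other)
  flag <- setNames(igraph::E(g)$coexpressed, other)
  expect_gt(pcc[["P1"]], 0.99)
  expect_true(flag[["P1"]])
  expect_false(flag[["P2"]])
  # absent endpoint -> NA PCC and NA flag, never FALSE-as-data
  expect_true(is.na(pcc[["P3"]]))
  expect_true(is.na(flag[["P3"]]))
  # strictness: PCC exactly at the threshold is not flagged
  g_eq <- overlay_coexpression(build_network(tiny_table(), "H1"), x,
                               threshold = unname(pcc[["P1"]]))
  flag_eq <- setNames(igraph::E(g_eq)$coexpressed,
                      ifelse(ends_g[, 1] == "H1", ends_g[, 2], ends_g[, 1]))
  expect_false(flag_eq[["P1"]])
})

test_that("hub summary counts distinct partners and their union", {
  it <- gen_interaction_table(synth_config(seed = 44))
  g <- build_network(it$table, it$hubs)
  hs <- hub_summary(g)
  expect_equal(unname(hs$degrees), c(60L, 16L, 3L, 3L))
  expect_equal(hs$union_partners, 82L)
  expect_equal(hs$n_interactions, 82L)
  # union <= sum of degrees, equality iff disjoint
  expect_equal(hs$union_partners, sum(hs$degrees))
  shared_tab <- data.frame(hub = c("h1", "h1", "h2", "h2"),
                           partner = c("x", "y", "x", "y"))
  hs2 <- hub_summary(build_network(shared_tab, c("h1", "h2")))
  expect_equal(hs2$union_partners, 2L)
  expect_lt(hs2$union_partners, sum(hs2$degrees))
  # single hub: union equals its degree
  hs3 <- hub_summary(build_network(tiny_table(), "H1"))
  expect_equal(hs3$union_partners, unname(hs3$degrees["H1"]))
})

test_that("exports serialize faithfully in SIF, GraphML and TSV", {
  g <- build_network(tiny_table(), "H1")
  prof <- c(1, 5, 2, 8, 3, 9)
  v <- rbind(H1 = prof, P1 = prof + 0.01 * seq(6))
  colnames(v) <- paste0("s", 1:6)
  g <- overlay_coexpression(
    g, expression_set(v, setNames(rep(c("a", "b"), 3), colnames(v))))
  sif <- tempfile(fileext = ".sif")
  export_network(g, sif, "sif")
  lines <- readLines(sif)
  expect_length(lines, 3L)
  expect_true(all(grepl(" pp ", lines)))
  # GraphML round trip preserves node/edge/attribute multisets
  gml <- tempfile(fileext = ".graphml")
  export_network(g, gml, "graphml")
  g2 <- read_network_graphml(gml)
  expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
  expect_equal(sort(igraph::V(g2)$class), sort(igraph::V(g)$class))
  ep1 <- apply(igraph::ends(g, igraph::E(g)), 1, function(r) paste(sort(r), collapse = "-"))
  ep2 <- apply(igraph::ends(g2, igraph::E(g2)), 1, function(r) paste(sort(r), collapse = "-"))
  expect_setequal(ep2, ep1)
  expect_equal(sort(igraph::E(g2)$pcc, na.last = TRUE),
               sort(igraph::E(g)$pcc, na.last = TRUE))
  expect_equal(igraph::E(g2)$coexpressed[order(ep2)],
               igraph::E(g)$coexpressed[order(ep1)])
  # TSV: missing PCC serialized as NA token, not 0
  tsv <- tempfile(fileext = ".tsv")
  export_network(g, tsv, "tsv")
  edges <- read.delim(sub("\\.tsv$", "_edges.tsv", tsv))
  expect_true(any(is.na(edges$pcc)))
  expect_false(any(edges$pcc == 0, na.rm = TRUE))
  expect_error(export_network(g, tsv, "xgmml"), "arg")
})

test_that("engineered network expression yields the configured flagged edges", {
  cfg <- synth_config(seed = 52)
  it <- gen_interaction_table(cfg)
  ne <- gen_network_expression(cfg, it)
  g <- overlay_coexpression(build_network(it$table, it$hubs), ne$expr)
  ends_g <- igraph::ends(g, igraph::E(g))
  for (i in seq_along(it$hubs)) {
    h <- it$hubs[i]
    on_hub <- ends_g[, 1] == h | ends_g[, 2] == h
    expect_equal(sum(igraph::E(g)$coexpressed[on_hub], na.rm = TRUE),
                 cfg$coexpressed_per_hub[i])
  }
  # flags match generator truth edge-by-edge
  truth <- ne$truth
  for (r in seq_len(nrow(truth))) {
    e <- igraph::get_edge_ids(g, c(truth$hub[r], truth$partner[r]))
    expect_equal(igraph::E(g)$coexpressed[e], truth$coexpressed[r])
  }
})
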