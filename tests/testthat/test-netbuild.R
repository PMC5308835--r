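test_that("fisher_exact_right boundary, frozen value and tail property", {
  expect_equal(fisher_exact_right(0, 5, 10, 20), 1.0)
  # (3,1,1,3): enumeration gives (C(4,3)C(4,1) + C(4,4)C(4,0)) / C(8,4) = 17/70
  expect_equal(fisher_exact_right(3, 1, 1, 3), 17 / 70, tolerance = 1e-15)
  expect_equal(fisher_exact_right(3, 1, 1, 3), oracle_fisher_right(3, 1, 1, 3),
               tolerance = 1e-15)
  # monotone non-increasing in a at fixed margins
  margins <- list(c(2, 8, 8, 12), c(5, 5, 5, 15))
  for (m in margins) {
    K <- m[1] + m[3]; n <- m[1] + m[2]; N <- sum(m)
    ps <- vapply(0:min(K, n), function(a) {
      fisher_exact_right(a, n - a, K - a, N - n - K + a)
    }, 0)
    expect_true(all(diff(ps) <= 1e-15))
  }
  expect_error(fisher_exact_right(-1, 1, 1, 1),
               class = "screenet_validation_error")
})

test_that("fisher_exact_right agrees with stats::fisher.test right tail", {
  set.seed(55)
  for (i in 1:25) {
    cells <- rpois(4, 6)
    ours <- fisher_exact_right(cells[1], cells[2], cells[3], cells[4])
    ref <- stats::fisher.test(matrix(cells, 2, byrow = TRUE),
                              alternative = "greater")$p.value
    expect_equal(ours, ref, tolerance = 1e-9)
  }
})

test_that("star evidence produces one network with the hub at degree n-1", {
  ev <- evidence_from_pairs(rep("H", 5), paste0("L", 1:5))
  ns <- build_networks(c("H", paste0("L", 1:5)), ev, network_config())
  expect_length(ns$networks, 1L)
  net <- ns$networks[[1]]
  expect_identical(nrow(net$nodes), 6L)
  expect_identical(net$n_internal_edges, 5L)
  hubs <- hub_rank(net)
  expect_identical(hubs$gene[1], "H")
  expect_identical(hubs$degree[1], 5L)
})

test_that("disconnected focus cliques become separate networks", {
  ev <- interaction_evidence(rbind(
    as.data.frame(complete_graph_evidence(c("A1", "A2", "A3"))),
    as.data.frame(complete_graph_evidence(c("B1", "B2", "B3")))
  ))
  ns <- build_networks(c("A1", "A2", "A3", "B1", "B2", "B3"), ev)
  expect_length(ns$networks, 2L)
  sizes <- sort(vapply(ns$networks, function(n) nrow(n$nodes), 0L))
  expect_identical(sizes, c(3L, 3L))
})

test_that("a 40-gene focus clique is capped at 35 nodes per network", {
  genes <- sprintf("F%02d", 1:40)
  ev <- complete_graph_evidence(genes)
  ns <- build_networks(genes, ev, network_config(max_nodes = 35))
  expect_identical(nrow(ns$networks[[1]]$nodes), 35L)
  expect_true(all(vapply(ns$networks, function(n) nrow(n$nodes), 0L) <= 35L))
  # every focus gene with evidence appears in exactly one network
  members <- unlist(lapply(ns$networks, function(n) n$nodes$gene))
  expect_identical(sort(members), sort(genes))
})

test_that("networks are induced subgraphs and focus genes are not shared", {
  set.seed(77)
  genes <- sprintf("G%02d", 1:30)
  idx <- which(upper.tri(matrix(0, 30, 30)), arr.ind = TRUE)
  pick <- idx[runif(nrow(idx)) < 0.12, , drop = FALSE]
  ev <- evidence_from_pairs(genes[pick[, 1]], genes[pick[, 2]])
  focus <- genes[1:12]
  ns <- build_networks(focus, ev, network_config(max_nodes = 10))
  for (net in ns$networks) {
    expect_lte(nrow(net$nodes), 10L)
    in_net <- ev$gene_a %in% net$nodes$gene & ev$gene_b %in% net$nodes$gene
    expect_identical(net$n_internal_edges, sum(in_net))
    expect_identical(sum(vapply(net$nodes$gene, function(g)
      sum(c(net$edges$gene_a, net$edges$gene_b) == g), 0L)),
      2L * net$n_internal_edges)
  }
  focus_member <- unlist(lapply(ns$networks, function(n)
    intersect(n$nodes$gene, focus)))
  expect_false(any(duplicated(focus_member)))
  networked_or_single <- c(focus_member, ns$singletons)
  has_edge <- focus %in% c(ev$gene_a, ev$gene_b)
  expect_setequal(networked_or_single[networked_or_single %in% focus[has_edge]],
                  focus[has_edge])
})

test_that("focus genes absent from evidence are reported as singletons", {
  ev <- evidence_from_pairs("A", "B")
  ns <- build_networks(c("A", "B", "LONER"), ev)
  expect_identical(ns$singletons, "LONER")
})

test_that("connectors join networks only when they add edges", {
  # C links F1 and F2 which are otherwise unconnected
  ev <- evidence_from_pairs(c("F1", "F2"), c("C", "C"))
  ns <- build_networks(c("F1", "F2"), ev)
  expect_length(ns$networks, 1L)
  expect_setequal(ns$networks[[1]]$nodes$gene, c("C", "F1", "F2"))
  expect_false(ns$networks[[1]]$nodes$focus[ns$networks[[1]]$nodes$gene == "C"])
  # with connectors disallowed, F1 and F2 stay apart
  ns2 <- build_networks(c("F1", "F2"), ev,
                        network_config(allow_connectors = FALSE))
  expect_true(all(vapply(ns2$networks, function(n) nrow(n$nodes), 0L) == 1L))
})

test_that("network scoring matches the enumeration oracle on a toy instance", {
  genes <- sprintf("N%02d", 1:10)
  ev <- complete_graph_evidence(genes)
  ns <- build_networks(genes[1:8], ev, network_config(max_nodes = 10))
  net <- ns$networks[[1]]
  scored <- score_network(net, n_focus_total = 50, background_size = 1000)
  a <- sum(scored$nodes$focus); b <- nrow(scored$nodes) - a
  expect_equal(scored$fisher_p,
               oracle_fisher_right(a, b, 50 - a, 1000 - a - b - (50 - a)),
               tolerance = 1e-12)
  expect_equal(scored$score, -log10(scored$fisher_p))
  expect_error(score_network(net, n_focus_total = 3, background_size = 1000),
               class = "screenet_validation_error")
})

test_that("all-focus networks score better than half-focus ones; zero focus = 1", {
  genes <- sprintf("X%02d", 1:10)
  ev <- complete_graph_evidence(genes)
  all_focus <- score_network(
    build_networks(genes, ev, network_config(max_nodes = 10))$networks[[1]],
    n_focus_total = 20, background_size = 500)
  half <- score_network(
    build_networks(genes[1:5], ev, network_config(max_nodes = 10))$networks[[1]],
    n_focus_total = 20, background_size = 500)
  expect_lt(all_focus$fisher_p, half$fisher_p)
  none <- gene_network_for_test(genes, ev, focus = character())
  scored <- score_network(none, n_focus_total = 20, background_size = 500)
  expect_equal(scored$fisher_p, 1.0)
  expect_equal(scored$score, 0)
})

test_that("scores are invariant under node relabeling", {
  genes <- sprintf("A%02d", 1:8)
  ev <- complete_graph_evidence(genes)
  s1 <- score_network(
    build_networks(genes[1:6], ev)$networks[[1]],
    n_focus_total = 10, background_size = 200)
  relabel <- sprintf("Z%02d", 1:8)
  ev2 <- complete_graph_evidence(relabel)
  s2 <- score_network(
    build_networks(relabel[1:6], ev2)$networks[[1]],
    n_focus_total = 10, background_size = 200)
  expect_identical(s1$fisher_p, s2$fisher_p)
})

test_that("adding a connected focus node never increases the fisher p", {
  genes <- sprintf("B%02d", 1:12)
  ev <- complete_graph_evidence(genes)
  ps <- vapply(3:12, function(k) {
    net <- build_networks(genes[1:k], ev,
                          network_config(max_nodes = 12,
                                         allow_connectors = FALSE))$networks[[1]]
    score_network(net, n_focus_total = 15, background_size = 500)$fisher_p
  }, 0)
  expect_true(all(diff(ps) <= 1e-15))
})

test_that("hub ranking uses degree, then betweenness, then name", {
  # path A - B - C - D: degrees 1,2,2,1; B and C tie, equal betweenness -> B
  ev <- evidence_from_pairs(c("A", "B", "C"), c("B", "C", "D"))
  net <- gene_network_for_test(c("A", "B", "C", "D"), ev, focus = "A")
  hr <- hub_rank(net)
  expect_identical(hr$gene[1:2], c("B", "C"))
  # cycle: all degrees equal, lexicographic order
  evc <- evidence_from_pairs(c("P", "Q", "R", "S"), c("Q", "R", "S", "P"))
  hrc <- hub_rank(gene_network_for_test(c("P", "Q", "R", "S"), evc, "P"))
  expect_identical(hrc$gene, c("P", "Q", "R", "S"))
  expect_identical(sum(hrc$degree), 2L * 4L)
})

test_that("network export: graphml is deterministic, sif round-trips, tsv pairs", {
  ev <- evidence_from_pairs(c("A", "B"), c("B", "C"),
                            relation = c("direct", "indirect"))
  net <- gene_network_for_test(c("A", "B", "C"), ev, focus = c("A", "C"))
  f1 <- tempfile(fileext = ".graphml"); f2 <- tempfile(fileext = ".graphml")
  write_network(net, f1, "graphml")
  write_network(net, f2, "graphml")
  expect_identical(readLines(f1), readLines(f2))
  expect_match(paste(readLines(f1), collapse = ""), "relation")

  fs <- tempfile(fileext = ".sif")
  write_network(net, fs, "sif")
  back <- read_edge_list(fs, dialect = "sif")
  expect_identical(as.data.frame(back), as.data.frame(net$edges))

  ft <- tempfile(fileext = ".tsv")
  write_network(net, ft, "tsv")
  expect_true(file.exists(sub("\\.tsv$", "_nodes.tsv", ft)))
  nodes <- utils::read.delim(sub("\\.tsv$", "_nodes.tsv", ft))
  expect_identical(nodes$gene, c("A", "B", "C"))
  expect_identical(nodes$focus, c(TRUE, FALSE, TRUE))

  expect_error(write_network(net, tempfile(), "dot"),
               class = "screenet_usage_error")
})

test_that("an empty network still writes a valid file", {
  ev <- evidence_from_pairs("A", "B")
  net <- gene_network_for_test(character(), ev, focus = character())
  f <- tempfile(fileext = ".sif")
  write_network(net, f, "sif")
  expect_identical(readLines(f), character())
})
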