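# Size-capped, interconnectivity-maximizing network construction over an
# interaction-evidence graph, scored by right-tailed Fisher's exact tests.
#
# "Focus" genes are the screen candidates used to nucleate networks;
# "connector" genes are non-candidates admitted because they link
# candidates. The growth rule is a documented greedy interpretation of the
# commercial pathway tools' one-sentence description of their algorithm;
# exact reproduction of any proprietary tool is not claimed.

#' Network construction configuration
#'
#' @param max_nodes Hard cap on nodes per network (default 35).
#' @param background_size Number of genes in the evidence universe eligible
#'   for membership. Defaults (at scoring time) to the number of distinct
#'   genes in the evidence file; override for genome-scale backgrounds.
#' @param allow_connectors Admit non-focus genes that link focus genes.
#' @return A `network_config` list.
#' @export
network_config <- function(max_nodes = 35L, background_size = NULL,
                           allow_connectors = TRUE) {
  if (max_nodes < 2L) abort_validation("`max_nodes` must be >= 2")
  if (!is.null(background_size) && background_size < 2L) {
    abort_validation("`background_size` must be >= 2")
  }
  structure(
    list(max_nodes = as.integer(max_nodes),
         background_size = if (is.null(background_size)) NULL else
           as.integer(background_size),
         allow_connectors = isTRUE(allow_connectors)),
    class = "network_config"
  )
}

#' Right-tailed Fisher's exact test on a 2x2 table
#'
#' The probability, under the hypergeometric null with fixed margins, of
#' observing at least `a` focus genes in the network: the chance the seen
#' degree of focus-gene clustering arises from a random draw. Computed as a
#' log-space hypergeometric tail sum for numerical stability.
#'
#' Table layout: `a` focus genes in the network, `b` non-focus genes in the
#' network, `c` focus genes outside, `d` non-focus genes outside.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return The right-tail p-value in (0, 1\].
#' @export
fisher_exact_right <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0) || any(c(a, b, c, d) != round(c(a, b, c, d)))) {
    abort_validation("contingency cells must be non-negative integers")
  }
  k_focus <- a + c        # focus genes in the universe
  k_other <- b + d        # non-focus genes
  n_draw <- a + b         # network size
  if (a == 0) return(1)
  ks <- a:min(k_focus, n_draw)
  lp <- stats::dhyper(ks, k_focus, k_other, n_draw, log = TRUE)
  m <- max(lp)
  min(exp(m + log(sum(exp(lp - m)))), 1)
}

#' Grow size-capped networks from focus genes over interaction evidence
#'
#' Greedy construction: (1) seed a network with the unassigned focus gene
#' having the most evidence edges to other unassigned focus genes (ties:
#' lexicographic); (2) repeatedly add the gene contributing the most edges
#' to the current node set — unassigned focus genes preferred over
#' connectors, then by edges added, then lexicographic — requiring at least
#' one added edge; (3) stop at `max_nodes` or when no addition qualifies;
#' (4) mark the network's focus genes assigned and repeat while unassigned
#' focus genes with evidence remain. Each network's edge set is the evidence
#' subgraph induced on its nodes. A focus gene appears in at most one
#' network; connectors may recur across networks. Focus genes with no
#' evidence edge at all are reported as singletons, not networked.
#'
#' @param focus Character vector of focus (candidate) gene symbols.
#' @param evidence An [interaction_evidence()] edge set.
#' @param config A [network_config()].
#' @param corr_sign Optional named vector (+1/-1) of correlation signs used
#'   to annotate nodes for display.
#' @return A `network_set`: list of `gene_network` objects plus `singletons`.
#' @export
build_networks <- function(focus, evidence, config = network_config(),
                           corr_sign = NULL) {
  stopifnot(inherits(evidence, "interaction_evidence"),
            inherits(config, "network_config"))
  focus <- unique(toupper(focus))
  if (!length(focus)) abort_validation("focus gene set is empty")
  if (!nrow(evidence)) abort_validation("interaction evidence is empty")

  nbrs <- adjacency_list(evidence)
  in_evidence <- names(nbrs)
  singletons <- sort(setdiff(focus, in_evidence))
  unassigned <- sort(intersect(focus, in_evidence))
  networks <- list()

  while (length(unassigned)) {
    # seed: most edges to other unassigned focus genes, tie lexicographic
    nfocus_deg <- vapply(unassigned, function(g) {
      length(intersect(nbrs[[g]], setdiff(unassigned, g)))
    }, 0L)
    seed <- unassigned[order(-nfocus_deg, unassigned)][[1L]]
    nodes <- seed
    repeat {
      if (length(nodes) >= config$max_nodes) break
      cand <- setdiff(unique(unlist(nbrs[nodes], use.names = FALSE)), nodes)
      cand <- setdiff(cand, setdiff(focus, unassigned))  # assigned focus barred
      if (!config$allow_connectors) cand <- intersect(cand, unassigned)
      if (!length(cand)) break
      gain <- vapply(cand, function(g) length(intersect(nbrs[[g]], nodes)), 0L)
      cand <- cand[gain >= 1L]
      gain <- gain[gain >= 1L]
      if (!length(cand)) break
      is_focus <- cand %in% unassigned
      pick <- cand[order(-is_focus, -gain, cand)][[1L]]
      nodes <- c(nodes, pick)
    }
    net_focus <- intersect(nodes, focus)
    networks[[length(networks) + 1L]] <-
      gene_network(nodes, evidence, focus = focus, corr_sign = corr_sign)
    unassigned <- setdiff(unassigned, net_focus)
  }
  structure(list(networks = networks, singletons = singletons),
            class = "network_set")
}

adjacency_list <- function(evidence) {
  genes <- sort(unique(c(evidence$gene_a, evidence$gene_b)))
  nb <- c(split(evidence$gene_b, evidence$gene_a),
          split(evidence$gene_a, evidence$gene_b))
  nb <- lapply(split(unname(nb), names(nb)), function(x) unique(unlist(x)))
  nb[genes]
}

# induced evidence subgraph on `nodes`, with focus flags and display signs
gene_network <- function(nodes, evidence, focus, corr_sign = NULL) {
  keep <- evidence$gene_a %in% nodes & evidence$gene_b %in% nodes
  edges <- evidence[keep, , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(nodes)
  sgn <- rep(NA_integer_, length(nodes))
  if (!is.null(corr_sign)) {
    idx <- match(nodes, toupper(names(corr_sign)))
    sgn <- as.integer(sign(corr_sign[idx]))
  }
  structure(
    list(
      nodes = data.frame(gene = nodes, focus = nodes %in% focus,
                         corr_sign = sgn, stringsAsFactors = FALSE),
      edges = edges,
      n_internal_edges = nrow(edges),
      fisher_p = NA_real_,
      score = NA_real_
    ),
    class = "gene_network"
  )
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf(
    "<gene_network> %d nodes (%d focus), %d edges%s\n",
    nrow(x$nodes), sum(x$nodes$focus), x$n_internal_edges,
    if (is.na(x$fisher_p)) "" else
      sprintf(", fisher p = %.3g (score %.1f)", x$fisher_p, x$score)
  ))
  invisible(x)
}

#' @export
print.network_set <- function(x, ...) {
  cat(sprintf("<network_set> %d network(s), %d singleton focus gene(s)\n",
              length(x$networks), length(x$singletons)))
  for (n in x$networks) print(n)
  invisible(x)
}

#' Score a network by a right-tailed Fisher's exact test
#'
#' Contingency: `a` = focus nodes in the network, `b` = non-focus nodes in
#' the network, `c` = remaining focus genes, `d` = remainder of the
#' background universe. The score is `-log10(p)`.
#'
#' @param net A `gene_network`.
#' @param n_focus_total Total number of focus genes in the universe.
#' @param config A [network_config()]; its `background_size` (or
#'   `background_size` argument) defines the universe.
#' @param background_size Overrides `config$background_size`.
#' @return The network with `fisher_p` and `score` filled in.
#' @export
score_network <- function(net, n_focus_total, config = network_config(),
                          background_size = NULL) {
  stopifnot(inherits(net, "gene_network"))
  bg <- background_size %||% config$background_size
  if (is.null(bg)) abort_validation("background_size is required for scoring")
  a <- sum(net$nodes$focus)
  b <- nrow(net$nodes) - a
  cc <- n_focus_total - a
  d <- bg - a - b - cc
  if (cc < 0 || d < 0) {
    abort_validation(sprintf(
      "inconsistent counts: focus total %d, background %d, network %d/%d",
      n_focus_total, bg, a, b
    ))
  }
  net$fisher_p <- fisher_exact_right(a, b, cc, d)
  net$score <- -log10(net$fisher_p)
  net
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Score every network in a set
#'
#' @param ns A `network_set` from [build_networks()].
#' @param n_focus_total Total focus genes in the universe.
#' @param background_size Size of the gene universe; defaults to the number
#'   of distinct genes in `evidence` when that is supplied.
#' @param evidence Optional [interaction_evidence()] used for the default
#'   background size.
#' @return The `network_set` with networks scored and sorted by descending
#'   score (ties: more nodes first, then first node id).
#' @export
score_networks <- function(ns, n_focus_total, background_size = NULL,
                           evidence = NULL) {
  stopifnot(inherits(ns, "network_set"))
  if (is.null(background_size)) {
    if (is.null(evidence)) abort_validation("need background_size or evidence")
    background_size <- length(unique(c(evidence$gene_a, evidence$gene_b)))
  }
  ns$networks <- lapply(ns$networks, score_network, n_focus_total = n_focus_total,
                        background_size = background_size)
  if (length(ns$networks)) {
    scores <- vapply(ns$networks, `[[`, 0, "score")
    sizes <- vapply(ns$networks, function(n) nrow(n$nodes), 0L)
    first <- vapply(ns$networks, function(n) n$nodes$gene[[1L]], "")
    ns$networks <- ns$networks[order(-scores, -sizes, first)]
  }
  ns
}

#' Rank the hubs of a network
#'
#' Degree within the network, descending; ties broken by betweenness
#' centrality (descending), then lexicographically. The top-ranked node is
#' the network's hub.
#'
#' @param net A non-empty `gene_network`.
#' @return A `data.frame` with `gene`, `degree`, `betweenness`, `rank`.
#' @export
hub_rank <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  if (!nrow(net$nodes)) abort_validation("network is empty")
  g <- network_igraph(net)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE)
  genes <- igraph::V(g)$name
  o <- order(-deg, -btw, genes)
  out <- data.frame(gene = genes[o], degree = as.integer(deg[o]),
                    betweenness = unname(btw[o]), rank = seq_along(o),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

network_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges[, c("gene_a", "gene_b"), drop = FALSE],
    directed = FALSE,
    vertices = net$nodes$gene
  )
}

#' Write a network to GraphML, SIF or TSV
#'
#' Nodes carry `focus` and `corr_sign` attributes (positive/negative seed
#' correlation, for display in the style of signed co-expression network
#' figures); edges carry the `relation` attribute (`direct`/`indirect`).
#' Element order is deterministic. The TSV format writes the edge table to
#' `path` and node attributes alongside it (`*_nodes.tsv`).
#'
#' @param net A `gene_network`.
#' @param path Output path.
#' @param format `"graphml"`, `"sif"` or `"tsv"`.
#' @export
write_network <- function(net, path, format = c("graphml", "sif", "tsv")) {
  stopifnot(inherits(net, "gene_network"))
  if (length(format) != 1L || !format %in% c("graphml", "sif", "tsv")) {
    abort_usage("unknown network format; use graphml, sif or tsv")
  }
  if (format == "graphml") {
    g <- network_igraph(net)
    igraph::V(g)$focus <- as.integer(net$nodes$focus)
    igraph::V(g)$corr_sign <- ifelse(is.na(net$nodes$corr_sign), 0L,
                                     net$nodes$corr_sign)
    if (nrow(net$edges)) igraph::E(g)$relation <- net$edges$relation
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "sif") {
    con <- try_open(path)
    on.exit(close(con))
    if (nrow(net$edges)) {
      writeLines(paste(net$edges$gene_a, net$edges$relation, net$edges$gene_b,
                       sep = "\t"), con)
    }
    solo <- setdiff(net$nodes$gene, c(net$edges$gene_a, net$edges$gene_b))
    if (length(solo)) writeLines(sort(solo), con)
  } else {
    write_tsv_deterministic(net$edges, path)
    node_path <- sub("(\\.[^.]*)?$", "_nodes.tsv", path)
    write_tsv_deterministic(net$nodes, node_path)
  }
  invisible(path)
}
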