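# Programmatic fixtures: everything is generated at test time, nothing is
# stored on disk.

# compact generator settings for fast unit tests: 5-member module (2 of
# them negatively loaded) over a small background
small_spec <- function(rng_seed = 42L, n_background_genes = 50L,
                       loading = 2, background_edge_prob = 0,
                       n_samples_1 = 60L, n_samples_2 = 40L) {
  synth_spec(
    n_background_genes = n_background_genes,
    module = default_module(n_members = 5L, loading = loading, n_negative = 2L),
    n_samples_1 = n_samples_1, n_samples_2 = n_samples_2,
    background_edge_prob = background_edge_prob,
    rng_seed = rng_seed
  )
}

# a GEO-style Series Matrix file around a values matrix
write_series_matrix_fixture <- function(path, values,
                                        drop_end_marker = FALSE,
                                        na_token = "null") {
  lines <- c(
    "!Series_title\t\"synthetic fixture\"",
    "!Series_platform_id\t\"GPL0000\"",
    "!series_matrix_table_begin",
    paste(c("\"ID_REF\"", sprintf('"%s"', colnames(values))), collapse = "\t")
  )
  for (i in seq_len(nrow(values))) {
    v <- values[i, ]
    cells <- ifelse(is.na(v), na_token, format(v, trim = TRUE))
    lines <- c(lines, paste(c(sprintf('"%s"', rownames(values)[i]), cells),
                            collapse = "\t"))
  }
  if (!drop_end_marker) lines <- c(lines, "!series_matrix_table_end")
  writeLines(lines, path)
  path
}

write_tsv_fixture <- function(path, lines) {
  writeLines(lines, path)
  path
}

random_expression <- function(n_features, n_samples, rng_seed = 1L,
                              na_fraction = 0) {
  set.seed(rng_seed)
  v <- matrix(rnorm(n_features * n_samples), n_features,
              dimnames = list(sprintf("f%03d", seq_len(n_features)),
                              sprintf("s%03d", seq_len(n_samples))))
  if (na_fraction > 0) {
    idx <- sample(length(v), round(na_fraction * length(v)))
    v[idx] <- NA_real_
  }
  expression_matrix(v, dataset_id = "random")
}

# evidence data frame -> interaction_evidence without touching disk
evidence_from_pairs <- function(a, b, relation = "direct") {
  interaction_evidence(data.frame(gene_a = a, gene_b = b, relation = relation,
                                  stringsAsFactors = FALSE))
}

# assemble a gene_network directly (bypassing the greedy growth) so export
# and scoring can be exercised on exactly chosen node sets
gene_network_for_test <- function(nodes, evidence, focus) {
  screenet:::gene_network(nodes, evidence, focus = focus)
}

complete_graph_evidence <- function(genes) {
  idx <- utils::combn(length(genes), 2)
  evidence_from_pairs(genes[idx[1, ]], genes[idx[2, ]])
}
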