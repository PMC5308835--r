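# Planted-module synthetic data generator.
#
# A single latent factor drives a module of genes (the seed gene, a hub
# regulator, and further members) in two independently sampled datasets,
# giving known ground-truth co-expression with full sign concordance across
# datasets — the minimal structure behind a two-dataset seed-correlation
# screen. Matching interaction evidence places the regulator at the centre
# of a star, plus Erdos-Renyi background edges.

#' Specification of the planted-module generator
#'
#' Module gene `g` in sample `s` takes the value
#' `sign_g * beta_g * z_s + e`, with `z_s ~ N(0, 1)` a shared latent factor
#' and `e ~ N(0, noise_sd^2)` independent noise; background genes are iid
#' `N(0, 1)`. The expected correlation between module genes follows in
#' closed form ([expected_correlation()]), so screen operating points can be
#' dialled in exactly via the loadings.
#'
#' Defaults mirror a paired lung-cancer cell-line study design: 166 and 76
#' samples, a 22-gene module (seed + hub regulator + 20 members, loadings
#' giving expected within-module |r| = 0.8 at `noise_sd = 1`, a quarter of
#' the members negatively loaded), and 5000 background genes.
#'
#' @param n_background_genes Number of independent background genes.
#' @param module Data frame with columns `gene`, `loading` (beta, > 0) and
#'   `sign` (+1/-1); must contain the seed gene and the hub and at least one
#'   more member.
#' @param seed_gene,hub_gene Names of the seed and hub genes in `module`.
#' @param noise_sd Within-module noise standard deviation (> 0).
#' @param n_samples_1,n_samples_2 Sample sizes of the two datasets.
#' @param background_edge_prob Erdos-Renyi edge probability among all genes
#'   in the simulated interaction evidence, in \[0, 1).
#' @param rng_seed Integer master seed; all draws derive from it.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(n_background_genes = 5000L,
                       module = default_module(),
                       seed_gene = "SEED", hub_gene = "HUB",
                       noise_sd = 1, n_samples_1 = 166L, n_samples_2 = 76L,
                       background_edge_prob = 0, rng_seed = 1L) {
  stopifnot(is.data.frame(module),
            all(c("gene", "loading", "sign") %in% names(module)))
  module$gene <- toupper(module$gene)
  if (nrow(module) < 3L) {
    abort_validation("module needs >= 3 genes (seed + hub + at least one member)")
  }
  if (!all(c(seed_gene, hub_gene) %in% module$gene) || seed_gene == hub_gene) {
    abort_validation("module must contain distinct seed and hub genes")
  }
  if (anyDuplicated(module$gene)) abort_validation("duplicate module gene names")
  if (any(!is.finite(module$loading)) || noise_sd <= 0) {
    abort_validation("loadings must be finite and noise_sd > 0")
  }
  if (!all(module$sign %in% c(-1, 1))) abort_validation("signs must be +1 or -1")
  if (background_edge_prob < 0 || background_edge_prob >= 1) {
    abort_validation("background_edge_prob must lie in [0, 1)")
  }
  structure(
    list(n_background_genes = as.integer(n_background_genes), module = module,
         seed_gene = seed_gene, hub_gene = hub_gene, noise_sd = noise_sd,
         n_samples_1 = as.integer(n_samples_1),
         n_samples_2 = as.integer(n_samples_2),
         background_edge_prob = background_edge_prob,
         rng_seed = as.integer(rng_seed)),
    class = "synth_spec"
  )
}

#' Default planted module: seed + hub + 20 members at expected |r| = 0.8
#'
#' With `loading = 2` and `noise_sd = 1`, every within-module expected
#' correlation has magnitude `2 * 2 / (2^2 + 1) = 0.8`. Five members are
#' negatively loaded to exercise sign-concordance logic and signed display
#' annotation.
#'
#' @param n_members Number of module members besides seed and hub.
#' @param loading Common loading magnitude.
#' @param n_negative How many members load negatively.
#' @return Data frame with columns `gene`, `loading`, `sign`.
#' @export
default_module <- function(n_members = 20L, loading = 2, n_negative = 5L) {
  stopifnot(n_negative <= n_members)
  members <- sprintf("MOD%02d", seq_len(n_members))
  data.frame(
    gene = c("SEED", "HUB", members),
    loading = loading,
    sign = c(1, 1, rep(c(-1, 1), c(n_negative, n_members - n_negative))),
    stringsAsFactors = FALSE
  )
}

#' Expected correlation between two module genes
#'
#' Closed form under the single-factor model:
#' `r = s_g * s_h * b_g * b_h / sqrt((b_g^2 + sd^2) * (b_h^2 + sd^2))`.
#'
#' @param beta_g,beta_h Loadings of the two genes.
#' @param sign_g,sign_h Their signs (+1/-1).
#' @param noise_sd Noise standard deviation (> 0).
#' @return The population Pearson correlation.
#' @export
expected_correlation <- function(beta_g, beta_h, sign_g = 1, sign_h = 1,
                                 noise_sd = 1) {
  if (any(noise_sd <= 0)) abort_validation("noise_sd must be > 0")
  sign_g * sign_h * beta_g * beta_h /
    sqrt((beta_g^2 + noise_sd^2) * (beta_h^2 + noise_sd^2))
}

synth_gene_universe <- function(spec) {
  c(spec$module$gene, sprintf("BG%05d", seq_len(spec$n_background_genes)))
}

#' Ground-truth labels for a generated universe
#'
#' @param spec A [synth_spec()].
#' @return A `truth_table` data frame: `gene`, `label` in
#'   `{seed, module, background}`, `loading`, `sign`; the hub gene id in
#'   `attr(., "hub")`. Labels partition the gene universe.
#' @export
truth_table <- function(spec) {
  genes <- synth_gene_universe(spec)
  idx <- match(genes, spec$module$gene)
  out <- data.frame(
    gene = genes,
    label = ifelse(genes == spec$seed_gene, "seed",
                   ifelse(!is.na(idx), "module", "background")),
    loading = ifelse(is.na(idx), 0, spec$module$loading[idx]),
    sign = ifelse(is.na(idx), 0, spec$module$sign[idx]),
    stringsAsFactors = FALSE
  )
  structure(out, hub = spec$hub_gene, class = c("truth_table", "data.frame"))
}

#' Simulate one expression dataset with the planted module
#'
#' Fully reproducible given `(spec$rng_seed, stream_label)`; the two
#' datasets of a pair use distinct stream labels and are therefore
#' independent draws over the same gene universe and loadings.
#'
#' @param spec A [synth_spec()].
#' @param n_samples Number of samples to draw.
#' @param stream_label Label naming the RNG sub-stream (and the dataset).
#' @return List with `expr` (an [expression_matrix()]) and `truth`
#'   (a [truth_table()]).
#' @export
simulate_dataset <- function(spec, n_samples, stream_label = "ds1") {
  stopifnot(inherits(spec, "synth_spec"), n_samples >= 3L)
  genes <- synth_gene_universe(spec)
  n_mod <- nrow(spec$module)
  values <- with_stream_seed(stream_seed(spec$rng_seed, stream_label), {
    z <- stats::rnorm(n_samples)
    module_vals <- outer(spec$module$sign * spec$module$loading, z) +
      matrix(stats::rnorm(n_mod * n_samples, sd = spec$noise_sd), n_mod)
    bg_vals <- matrix(stats::rnorm(spec$n_background_genes * n_samples),
                      spec$n_background_genes)
    rbind(module_vals, bg_vals)
  })
  dimnames(values) <- list(genes, sprintf("%s_S%04d", stream_label,
                                          seq_len(n_samples)))
  list(
    expr = expression_matrix(values, dataset_id = stream_label, log_scale = TRUE),
    truth = truth_table(spec)
  )
}

#' Simulate a pair of independent datasets sharing the planted module
#'
#' Mirrors a two-dataset screening design: same gene universe and loadings,
#' independent sample draws (distinct RNG streams).
#'
#' @param spec A [synth_spec()].
#' @return List with `expr_1`, `expr_2` and the shared `truth`.
#' @export
simulate_pair <- function(spec) {
  d1 <- simulate_dataset(spec, spec$n_samples_1, "ds1")
  d2 <- simulate_dataset(spec, spec$n_samples_2, "ds2")
  list(expr_1 = d1$expr, expr_2 = d2$expr, truth = d1$truth)
}

#' Simulate interaction evidence with the hub at the centre
#'
#' A star of `direct` edges from the hub regulator to every other module
#' gene, plus Erdos-Renyi `indirect` background edges among all genes with
#' probability `background_edge_prob`. Seeded and deterministic.
#'
#' @param spec A [synth_spec()].
#' @return An [interaction_evidence()] edge set.
#' @export
simulate_evidence <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  genes <- synth_gene_universe(spec)
  star <- data.frame(
    gene_a = spec$hub_gene,
    gene_b = setdiff(spec$module$gene, spec$hub_gene),
    relation = "direct",
    stringsAsFactors = FALSE
  )
  bg <- if (spec$background_edge_prob > 0) {
    n <- length(genes)
    n_pairs <- n * (n - 1) / 2
    with_stream_seed(stream_seed(spec$rng_seed, "evidence"), {
      m <- stats::rbinom(1L, n_pairs, spec$background_edge_prob)
      k <- sort(sample(n_pairs, m))
      ij <- pair_index_to_ij(k, n)
      data.frame(gene_a = genes[ij$i], gene_b = genes[ij$j],
                 relation = "indirect", stringsAsFactors = FALSE)
    })
  } else {
    NULL
  }
  interaction_evidence(rbind(star, bg))
}

# invert the linear index over unordered pairs (i < j) of 1..n
pair_index_to_ij <- function(k, n) {
  offsets <- cumsum(c(0, (n - 1):1))  # pairs with first element <= i
  i <- findInterval(k - 0.5, offsets)
  j <- i + (k - offsets[i])
  list(i = i, j = j)
}

#' Write a synthetic bundle to disk
#'
#' Emits everything the pipeline consumes: expression TSVs for both
#' datasets, an identity annotation table (symbol -> symbol), the evidence
#' edge list, the truth table, and a YAML echo of the generator settings.
#'
#' @param spec A [synth_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisible named list of the written paths.
#' @export
write_synth_bundle <- function(spec, dir) {
  stopifnot(inherits(spec, "synth_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pair <- simulate_pair(spec)
  ev <- simulate_evidence(spec)
  genes <- synth_gene_universe(spec)
  paths <- list(
    expression_1 = file.path(dir, "expression_ds1.tsv"),
    expression_2 = file.path(dir, "expression_ds2.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    evidence = file.path(dir, "evidence.tsv"),
    truth = file.path(dir, "truth.tsv"),
    spec = file.path(dir, "synth_spec.yaml")
  )
  write_expression_tsv(pair$expr_1, paths$expression_1)
  write_expression_tsv(pair$expr_2, paths$expression_2)
  write_tsv_deterministic(
    data.frame(feature_id = genes, gene_symbol = genes,
               description = "", stringsAsFactors = FALSE),
    paths$annotation
  )
  write_tsv_deterministic(as.data.frame(ev), paths$evidence)
  write_tsv_deterministic(as.data.frame(pair$truth), paths$truth)
  echo <- list(
    n_background_genes = spec$n_background_genes,
    seed_gene = spec$seed_gene, hub_gene = spec$hub_gene,
    noise_sd = spec$noise_sd,
    n_samples_1 = spec$n_samples_1, n_samples_2 = spec$n_samples_2,
    background_edge_prob = spec$background_edge_prob,
    rng_seed = spec$rng_seed,
    module = list(gene = spec$module$gene, loading = spec$module$loading,
                  sign = spec$module$sign)
  )
  yaml::write_yaml(echo, paths$spec)
  invisible(paths)
}

#' Rebuild a generator spec from a written YAML echo
#'
#' @param path Path to a `synth_spec.yaml` written by [write_synth_bundle()].
#' @return A [synth_spec()].
#' @export
read_synth_spec <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  y <- yaml::read_yaml(path)
  module <- if (!is.null(y$module)) {
    data.frame(gene = unlist(y$module$gene),
               loading = unlist(y$module$loading),
               sign = unlist(y$module$sign), stringsAsFactors = FALSE)
  } else {
    default_module()
  }
  synth_spec(
    n_background_genes = y$n_background_genes %||% 5000L,
    module = module,
    seed_gene = y$seed_gene %||% "SEED",
    hub_gene = y$hub_gene %||% "HUB",
    noise_sd = y$noise_sd %||% 1,
    n_samples_1 = y$n_samples_1 %||% 166L,
    n_samples_2 = y$n_samples_2 %||% 76L,
    background_edge_prob = y$background_edge_prob %||% 0,
    rng_seed = y$rng_seed %||% 1L
  )
}
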