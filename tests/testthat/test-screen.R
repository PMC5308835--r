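test_that("seed resolution: explicit id wins, else highest-variance probe", {
  v <- rbind(p1 = c(1, 2, 3, 4), p2 = c(1, 3, 5, 7), p3 = c(0, 0, 0, 1))
  colnames(v) <- paste0("s", 1:4)
  expr <- expression_matrix(v)
  ann <- structure(
    data.frame(feature_id = c("p1", "p2", "p3"),
               gene_symbol = c("GSK3B", "GSK3B", "OTHER"),
               description = "", stringsAsFactors = FALSE),
    class = c("feature_annotation", "data.frame"))
  expect_identical(resolve_seed(expr, ann, "p3"), "p3")
  # p2 has the larger variance among GSK3B probes
  expect_identical(resolve_seed(expr, ann, "GSK3B"), "p2")
  expect_identical(resolve_seed(expr, ann, "gsk3b"), "p2")
  expect_error(resolve_seed(expr, ann, "NOSUCH"),
               class = "screenet_lookup_error")
})

test_that("seed resolution breaks variance ties lexicographically", {
  v <- rbind(pB = c(1, 2, 3), pA = c(3, 2, 1))
  colnames(v) <- paste0("s", 1:3)
  expr <- expression_matrix(v)
  ann <- data.frame(feature_id = c("pB", "pA"), gene_symbol = "G",
                    description = "", stringsAsFactors = FALSE)
  expect_identical(resolve_seed(expr, ann, "G"), "pA")
})

test_that("pearson_r matches hand-evaluated and oracle values", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, x)$r, 1.0)
  expect_equal(pearson_r(x, -x)$r, -1.0)
  # frozen from the textbook formula: r = 4 / sqrt(5 * 5)
  got <- pearson_r(x, c(1, 3, 2, 4))
  expect_equal(got$r, 0.8, tolerance = 1e-15)
  expect_identical(got$n_pairs, 4L)
  expect_error(pearson_r(x, c(1, 2)), class = "screenet_validation_error")
})

test_that("pearson_r handles missingness, short vectors and flat input", {
  x <- c(1, 2, NA, 4, 5)
  y <- c(2, NA, 3, 8, 10)
  got <- pearson_r(x, y)
  expect_identical(got$n_pairs, 3L)
  expect_equal(got$r, oracle_pearson(x, y), tolerance = 1e-12)
  expect_true(is.na(pearson_r(c(1, 2, NA), c(1, 2, 3))$r))        # n < 3
  expect_true(is.na(pearson_r(rep(1, 5), c(1, 2, 3, 4, 5))$r))    # flat
})

test_that("pearson_r is symmetric and affine-equivariant", {
  set.seed(101)
  for (i in 1:20) {
    x <- rnorm(30)
    y <- rnorm(30)
    r_xy <- pearson_r(x, y)$r
    expect_identical(r_xy, pearson_r(y, x)$r)
    expect_equal(pearson_r(2.5 * x + 1, y)$r, r_xy, tolerance = 1e-12)
    expect_equal(pearson_r(-0.7 * x + 3, y)$r, -r_xy, tolerance = 1e-12)
  }
})

test_that("analytic p-value matches t-density quadrature and is monotone", {
  expect_equal(correlation_p_analytic(0, 20), 1.0)
  expect_equal(correlation_p_analytic(0.55, 76),
               oracle_p_quadrature(0.55, 76), tolerance = 1e-10)
  expect_equal(correlation_p_analytic(-0.3, 40),
               oracle_p_quadrature(-0.3, 40), tolerance = 1e-10)
  expect_lt(correlation_p_analytic(0.6, 76), correlation_p_analytic(0.55, 76))
  expect_identical(correlation_p_analytic(1, 10), .Machine$double.xmin)
  expect_error(correlation_p_analytic(0.5, 2),
               class = "screenet_validation_error")
})

test_that("permutation p-value is deterministic and hits the 1/(B+1) floor", {
  x <- rnorm(30)
  p1 <- correlation_p_permutation(x, x, n_permutations = 199, rng_seed = 5)
  p2 <- correlation_p_permutation(x, x, n_permutations = 199, rng_seed = 5)
  expect_identical(p1, p2)
  expect_equal(p1, 1 / 200)
  expect_error(correlation_p_permutation(x, x, n_permutations = 50),
               class = "screenet_validation_error")
})

test_that("permutation and analytic p-values agree within Monte-Carlo error", {
  set.seed(202)
  n <- 50
  for (rho in c(0, 0.3, 0.6)) {
    z <- rnorm(n)
    x <- rho * z + sqrt(1 - rho^2) * rnorm(n)
    B <- 2000
    p_perm <- correlation_p_permutation(x, z, n_permutations = B, rng_seed = 7)
    obs <- pearson_r(x, z)
    p_ana <- correlation_p_analytic(obs$r, obs$n_pairs)
    mc_err <- 3 * sqrt(max(p_ana, 1 / B) * (1 - p_ana) / B)
    expect_lt(abs(p_perm - p_ana), mc_err + 2 / B)
  }
})

test_that("run_screen excludes the seed, applies strict threshold, sorts passing", {
  spec <- small_spec(rng_seed = 9)
  ds <- simulate_dataset(spec, 120, "unit")
  cfg <- screen_config("SEED", r_threshold = 0.55)
  sr <- run_screen(ds$expr, NULL, cfg)
  expect_false("SEED" %in% sr$records$feature_id)
  expect_identical(nrow(sr$records), nrow(ds$expr$values) - 1L)
  # strict inequality at the boundary
  expect_identical(sr$records$passes,
                   !is.na(sr$records$r) & abs(sr$records$r) > 0.55 &
                     sr$records$n_pairs >= 10L)
  # all module genes should pass at expected |r| = 0.8
  module <- setdiff(ds$truth$gene[ds$truth$label == "module"], "SEED")
  expect_true(all(module %in% sr$passing_ids))
  # passing_ids sorted by descending |r|
  r_by_id <- abs(sr$records$r[match(sr$passing_ids, sr$records$feature_id)])
  expect_true(all(diff(r_by_id) <= 0))
  # vectorized screen agrees with the scalar op
  for (fid in sr$records$feature_id[1:5]) {
    expect_equal(sr$records$r[sr$records$feature_id == fid],
                 pearson_r(ds$expr$values[fid, ], ds$expr$values["SEED", ])$r,
                 tolerance = 1e-12)
  }
})

test_that("a pure-noise dataset yields essentially no passing features", {
  set.seed(303)
  v <- matrix(rnorm(300 * 76), 300,
              dimnames = list(sprintf("n%03d", 1:300), sprintf("s%02d", 1:76)))
  expr <- expression_matrix(v)
  sr <- run_screen(expr, NULL, screen_config("n001"))
  expect_lte(length(sr$passing_ids), 1L)
})

test_that("passing count is monotone non-increasing in the threshold", {
  spec <- small_spec(rng_seed = 12, loading = 1)   # expected |r| = 0.5
  ds <- simulate_dataset(spec, 80, "mono")
  counts <- vapply(c(0.3, 0.45, 0.55, 0.7, 0.9), function(thr) {
    length(run_screen(ds$expr, NULL,
                      screen_config("SEED", r_threshold = thr))$passing_ids)
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("zero-variance features survive the screen as undefined, not errors", {
  v <- rbind(seedf = rnorm(10), flat = rep(3, 10), ok = rnorm(10))
  colnames(v) <- paste0("s", 1:10)
  sr <- run_screen(expression_matrix(v), NULL,
                   screen_config("seedf", min_pairs = 3))
  flat_row <- sr$records[sr$records$feature_id == "flat", ]
  expect_true(is.na(flat_row$r))
  expect_false(flat_row$passes)
  expect_identical(flat_row$direction, 0L)
})

test_that("screen TSV serialisation is deterministic", {
  spec <- small_spec(rng_seed = 21, n_background_genes = 10L)
  ds <- simulate_dataset(spec, 40, "det")
  sr <- run_screen(ds$expr, NULL, screen_config("SEED"))
  f1 <- tempfile(); f2 <- tempfile()
  write_screen_tsv(sr, f1)
  write_screen_tsv(sr, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(f1)[1],
                   "feature_id\tgene_symbol\tn_pairs\tr\tp_analytic\tp_permutation\tpasses")
})
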