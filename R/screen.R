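# Per-dataset seed-gene correlation screen.
#
# Every non-seed feature is correlated (Pearson) to the seed feature over
# pairwise-complete samples; a feature passes when |r| exceeds the
# threshold strictly (default 0.55) and enough complete pairs support it.

#' Screen configuration
#'
#' @param seed Gene symbol or explicit feature id of the seed gene (the query
#'   gene all transcripts are correlated against).
#' @param r_threshold Absolute-correlation threshold, strictly between 0 and
#'   1. A feature passes only if `|r| > r_threshold` (strict: the boundary
#'   value fails). Default 0.55.
#' @param p_method `"analytic"` (Student-t transform), `"permutation"`, or
#'   `"both"`.
#' @param n_permutations Number of permutations when permutation p-values are
#'   requested (>= 99).
#' @param min_pairs Minimum pairwise-complete sample count for a correlation
#'   to be defined (>= 3; default 10).
#' @param rng_seed Integer seed driving permutation p-values.
#' @return A `screen_config` list.
#' @export
screen_config <- function(seed, r_threshold = 0.55,
                          p_method = c("analytic", "permutation", "both"),
                          n_permutations = 10000L, min_pairs = 10L,
                          rng_seed = 1L) {
  p_method <- match.arg(p_method)
  if (!is.character(seed) || length(seed) != 1L || !nzchar(seed)) {
    abort_validation("`seed` must be a single non-empty gene symbol or feature id")
  }
  if (!(r_threshold > 0 && r_threshold < 1)) {
    abort_validation("`r_threshold` must lie strictly between 0 and 1")
  }
  if (min_pairs < 3L) abort_validation("`min_pairs` must be >= 3")
  if (p_method != "analytic" && n_permutations < 99L) {
    abort_validation("`n_permutations` must be >= 99")
  }
  structure(
    list(seed = seed, r_threshold = r_threshold, p_method = p_method,
         n_permutations = as.integer(n_permutations),
         min_pairs = as.integer(min_pairs), rng_seed = as.integer(rng_seed)),
    class = "screen_config"
  )
}

#' Resolve a seed symbol or feature id to a single feature
#'
#' An explicit feature id wins. Otherwise, among features annotated to the
#' symbol, the feature with the highest variance over non-missing samples is
#' chosen (the best-behaved probe); variance ties break to the
#' lexicographically smallest feature id.
#'
#' @param expr An [expression_matrix()].
#' @param annotation A [read_annotation()] table (may be `NULL` when `seed`
#'   is a feature id).
#' @param seed Symbol or feature id.
#' @return The resolved feature id (character scalar).
#' @export
resolve_seed <- function(expr, annotation, seed) {
  fids <- feature_ids(expr)
  if (seed %in% fids) return(seed)
  if (!is.null(annotation)) {
    hits <- annotation$feature_id[annotation$gene_symbol == toupper(seed)]
    hits <- intersect(hits, fids)
    if (length(hits)) {
      vars <- apply(expr$values[hits, , drop = FALSE], 1L, stats::var, na.rm = TRUE)
      vars[is.na(vars)] <- -Inf
      best <- hits[vars == max(vars)]
      return(sort(best)[[1L]])
    }
    sym <- unique(annotation$gene_symbol)
    near <- sym[order(utils::adist(toupper(seed), sym))][seq_len(min(5L, length(sym)))]
    abort_lookup(sprintf(
      "seed '%s' matches no feature; nearest symbols: %s",
      seed, paste(near, collapse = ", ")
    ))
  }
  abort_lookup(sprintf("seed '%s' matches no feature id", seed))
}

#' Pearson correlation over pairwise-complete observations
#'
#' Returns the correlation and the number of complete pairs it is based on.
#' When fewer than `min_pairs` complete pairs exist, or either vector has
#' zero variance over them, `r` is `NA` (undefined) rather than an error, so
#' flat probes never abort a screen.
#'
#' @param x,y Numeric vectors of equal length.
#' @param min_pairs Minimum complete-pair count (>= 3).
#' @return List with elements `r` and `n_pairs`.
#' @export
pearson_r <- function(x, y, min_pairs = 3L) {
  if (length(x) != length(y)) abort_validation("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < min_pairs) return(list(r = NA_real_, n_pairs = n))
  xs <- x[ok]; ys <- y[ok]
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
    return(list(r = NA_real_, n_pairs = n))
  }
  list(r = stats::cor(xs, ys), n_pairs = n)
}

#' Analytic two-sided p-value for a Pearson correlation
#'
#' Uses the exact null distribution of `t = r * sqrt((n - 2) / (1 - r^2))`,
#' Student t with `n - 2` degrees of freedom. `r = +-1` is clamped to the
#' smallest positive double rather than zero.
#'
#' @param r Correlation(s) in \[-1, 1\]; `NA` propagates.
#' @param n_pairs Complete-pair count(s), >= 3.
#' @return p-value(s) in (0, 1\].
#' @export
correlation_p_analytic <- function(r, n_pairs) {
  if (any(n_pairs < 3L, na.rm = TRUE)) abort_validation("n_pairs must be >= 3")
  n_pairs <- rep_len(n_pairs, length(r))
  p <- rep(NA_real_, length(r))
  ext <- !is.na(r) & abs(r) >= 1
  p[ext] <- .Machine$double.xmin
  reg <- !is.na(r) & abs(r) < 1
  if (any(reg)) {
    tt <- r[reg] * sqrt((n_pairs[reg] - 2) / (1 - r[reg]^2))
    p[reg] <- 2 * stats::pt(-abs(tt), df = n_pairs[reg] - 2)
  }
  out <- pmin(p, 1)
  out[!is.na(out) & out <= 0] <- .Machine$double.xmin
  out
}

#' Permutation p-value for a Pearson correlation
#'
#' Permutes `y` over the complete pairs `B` times with a seeded generator and
#' reports `(1 + #{|r_perm| >= |r_obs|}) / (1 + B)` — never exactly zero, and
#' deterministic given `rng_seed`. The caller's RNG state is untouched.
#'
#' @param x,y Numeric vectors of equal length.
#' @param n_permutations Number of permutations `B` (>= 99).
#' @param rng_seed Integer seed.
#' @param min_pairs Minimum complete-pair count.
#' @return Scalar p-value in (0, 1\], or `NA` if `r` is undefined.
#' @export
correlation_p_permutation <- function(x, y, n_permutations = 10000L,
                                      rng_seed = 1L, min_pairs = 3L) {
  if (n_permutations < 99L) abort_validation("n_permutations must be >= 99")
  obs <- pearson_r(x, y, min_pairs = min_pairs)
  if (is.na(obs$r)) return(NA_real_)
  ok <- !is.na(x) & !is.na(y)
  xs <- x[ok]; ys <- y[ok]
  n <- length(xs)
  # centred/scaled once; |r| of a permutation is then a plain inner product
  xc <- xs - mean(xs)
  xc <- xc / sqrt(sum(xc^2))
  yc <- ys - mean(ys)
  yc <- yc / sqrt(sum(yc^2))
  r_abs <- abs(sum(xc * yc))
  hits <- with_stream_seed(rng_seed, {
    sum(vapply(seq_len(n_permutations), function(i) {
      abs(sum(xc * yc[sample.int(n)])) >= r_abs - 1e-15
    }, NA))
  })
  (1 + hits) / (1 + n_permutations)
}

#' Run a seed-gene correlation screen on one dataset
#'
#' Correlates every non-seed feature to the seed feature and applies the
#' absolute-correlation threshold. The seed feature itself is excluded from
#' the records and from passing counts.
#'
#' @param expr An [expression_matrix()].
#' @param annotation Optional [read_annotation()] table (needed to resolve a
#'   symbolic seed, and to attach gene symbols to records).
#' @param config A [screen_config()].
#' @return A `screen_result`: list with `dataset_id`, `seed_feature_id`,
#'   `config`, `records` (one row per non-seed feature: `feature_id`,
#'   `gene_symbol`, `n_pairs`, `r`, `p_analytic`, `p_permutation`,
#'   `direction`, `passes`) and `passing_ids` (sorted by descending `|r|`,
#'   ties lexicographic).
#' @export
run_screen <- function(expr, annotation = NULL, config) {
  stopifnot(inherits(expr, "expression_matrix"), inherits(config, "screen_config"))
  seed_id <- resolve_seed(expr, annotation, config$seed)
  v <- expr$values
  seed_vals <- v[seed_id, ]
  others <- setdiff(feature_ids(expr), seed_id)
  m <- v[others, , drop = FALSE]

  ok_seed <- !is.na(seed_vals)
  n_pairs <- rowSums(!is.na(m[, ok_seed, drop = FALSE]))
  r <- suppressWarnings(as.vector(
    stats::cor(t(m), seed_vals, use = "pairwise.complete.obs")
  ))
  r[n_pairs < config$min_pairs] <- NA_real_

  p_analytic <- rep(NA_real_, length(r))
  def <- !is.na(r)
  if (any(def)) {
    p_analytic[def] <- correlation_p_analytic(r[def], n_pairs[def])
  }

  p_perm <- rep(NA_real_, length(r))
  if (config$p_method %in% c("permutation", "both")) {
    for (i in which(def)) {
      p_perm[i] <- correlation_p_permutation(
        m[i, ], seed_vals,
        n_permutations = config$n_permutations,
        rng_seed = stream_seed(config$rng_seed, others[[i]]),
        min_pairs = config$min_pairs
      )
    }
  }

  sym <- annotation_symbols(annotation, others)
  passes <- !is.na(r) & abs(r) > config$r_threshold & n_pairs >= config$min_pairs
  records <- data.frame(
    feature_id = others,
    gene_symbol = sym,
    n_pairs = n_pairs,
    r = r,
    p_analytic = p_analytic,
    p_permutation = p_perm,
    direction = ifelse(is.na(r), 0L, as.integer(sign(r))),
    passes = passes,
    stringsAsFactors = FALSE
  )
  rownames(records) <- NULL
  pass_rec <- records[records$passes, , drop = FALSE]
  o <- order(-abs(pass_rec$r), pass_rec$feature_id)
  structure(
    list(dataset_id = expr$dataset_id, seed_feature_id = seed_id,
         seed_symbol = resolve_symbol(annotation, seed_id, config$seed),
         config = config, records = records,
         passing_ids = pass_rec$feature_id[o]),
    class = "screen_result"
  )
}

annotation_symbols <- function(annotation, feature_ids) {
  if (is.null(annotation)) return(toupper(feature_ids))
  idx <- match(feature_ids, annotation$feature_id)
  sym <- annotation$gene_symbol[idx]
  sym[is.na(sym)] <- toupper(feature_ids[is.na(sym)])
  sym
}

resolve_symbol <- function(annotation, feature_id, fallback) {
  if (!is.null(annotation)) {
    hit <- annotation$gene_symbol[match(feature_id, annotation$feature_id)]
    if (!is.na(hit) && nzchar(hit)) return(hit)
  }
  toupper(fallback)
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf(
    "<screen_result> %s: seed %s, %d features screened, %d passing (|r| > %g)\n",
    x$dataset_id, x$seed_feature_id, nrow(x$records), length(x$passing_ids),
    x$config$r_threshold
  ))
  invisible(x)
}

#' Write a screen result as TSV
#'
#' One row per screened feature, columns `feature_id`, `gene_symbol`,
#' `n_pairs`, `r`, `p_analytic`, `p_permutation`, `passes`.
#'
#' @param sr A `screen_result`.
#' @param path Output path.
#' @export
write_screen_tsv <- function(sr, path) {
  stopifnot(inherits(sr, "screen_result"))
  rec <- sr$records[, c("feature_id", "gene_symbol", "n_pairs", "r",
                        "p_analytic", "p_permutation", "passes")]
  write_tsv_deterministic(rec, path)
}

# shared deterministic TSV writer (fixed number formatting, no quoting)
write_tsv_deterministic <- function(df, path) {
  con <- try_open(path)
  on.exit(close(con))
  fmt <- function(v) {
    if (is.numeric(v) && !is.integer(v)) {
      ifelse(is.na(v), "NA", format(v, digits = 15, trim = TRUE))
    } else {
      ifelse(is.na(v), "NA", as.character(v))
    }
  }
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    cols <- lapply(df, fmt)
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}
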