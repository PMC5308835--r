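# Cross-dataset candidate intersection, concordance checking and ranking.
#
# Candidates are the features (or symbols) passing the screen in BOTH
# datasets; a candidate is concordant when its correlation to the seed has
# the same sign in both. With a genuine shared regulator, full sign
# concordance across independent datasets is expected.

#' Intersect two screen results into a candidate set
#'
#' At `level = "feature"`, match keys are feature ids (requires both datasets
#' on the same platform). At `level = "symbol"`, a symbol passes in a dataset
#' if any of its probes passes, and the probe with maximum `|r|` (ties:
#' lexicographically smallest probe id) represents it.
#'
#' @param a,b `screen_result` objects for the two datasets. Both must have
#'   screened the same seed symbol.
#' @param level Matching level, `"feature"` or `"symbol"`.
#' @return A `candidate_set`: `matching_level`, `records` (one row per
#'   common candidate with per-dataset r and p, `concordant`, `rank_score`),
#'   `counts` (`passing_1`, `passing_2`, `intersection`, `union`) and
#'   `concordance_fraction` (`NA` on an empty set, never a silent 1).
#' @export
intersect_screens <- function(a, b, level = c("feature", "symbol")) {
  stopifnot(inherits(a, "screen_result"), inherits(b, "screen_result"))
  level <- match.arg(level)
  if (!identical(toupper(a$seed_symbol), toupper(b$seed_symbol))) {
    abort_validation(sprintf(
      "screens target different seeds: '%s' vs '%s'",
      a$seed_symbol, b$seed_symbol
    ))
  }
  ra <- representative_records(a, level)
  rb <- representative_records(b, level)
  common <- sort(intersect(ra$match_key, rb$match_key))
  ia <- match(common, ra$match_key)
  ib <- match(common, rb$match_key)
  records <- data.frame(
    match_key = common,
    gene_symbol = ra$gene_symbol[ia],
    feature_id_1 = ra$feature_id[ia],
    r_1 = ra$r[ia],
    p_1 = ra$p[ia],
    feature_id_2 = rb$feature_id[ib],
    r_2 = rb$r[ib],
    p_2 = rb$p[ib],
    stringsAsFactors = FALSE
  )
  records$concordant <- records$r_1 * records$r_2 > 0
  records$rank_score <- pmin(abs(records$r_1), abs(records$r_2))
  rownames(records) <- NULL
  n1 <- nrow(ra); n2 <- nrow(rb); ni <- nrow(records)
  structure(
    list(
      matching_level = level,
      seed_symbol = a$seed_symbol,
      dataset_ids = c(a$dataset_id, b$dataset_id),
      records = records,
      counts = list(passing_1 = n1, passing_2 = n2,
                    intersection = ni, union = n1 + n2 - ni),
      concordance_fraction = if (ni) mean(records$concordant) else NA_real_
    ),
    class = "candidate_set"
  )
}

# one row per match key among the passing features of a screen
representative_records <- function(sr, level) {
  pass <- sr$records[sr$records$passes, , drop = FALSE]
  if (level == "feature") {
    out <- data.frame(
      match_key = pass$feature_id, gene_symbol = pass$gene_symbol,
      feature_id = pass$feature_id, r = pass$r, p = pass$p_analytic,
      stringsAsFactors = FALSE
    )
    return(out[order(out$match_key), , drop = FALSE])
  }
  pass <- pass[nzchar(pass$gene_symbol), , drop = FALSE]
  o <- order(pass$gene_symbol, -abs(pass$r), pass$feature_id)
  pass <- pass[o, , drop = FALSE]
  rep_rows <- pass[!duplicated(pass$gene_symbol), , drop = FALSE]
  data.frame(
    match_key = rep_rows$gene_symbol, gene_symbol = rep_rows$gene_symbol,
    feature_id = rep_rows$feature_id, r = rep_rows$r, p = rep_rows$p_analytic,
    stringsAsFactors = FALSE
  )
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf(
    "<candidate_set> %s level: %d + %d passing, %d common (union %d), concordance %s\n",
    x$matching_level, x$counts$passing_1, x$counts$passing_2,
    x$counts$intersection, x$counts$union,
    ifelse(is.na(x$concordance_fraction), "undefined",
           format(x$concordance_fraction, digits = 3))
  ))
  invisible(x)
}

#' Concordance fraction and discordant candidates
#'
#' @param cs A `candidate_set` from [intersect_screens()]; must be non-empty
#'   (an empty set raises an error rather than silently reporting 1.0).
#' @return List with `fraction` and the sorted `discordant` match keys.
#' @export
concordance_report <- function(cs) {
  stopifnot(inherits(cs, "candidate_set"))
  if (!nrow(cs$records)) {
    abort_validation("concordance is undefined on an empty candidate set")
  }
  list(
    fraction = mean(cs$records$concordant),
    discordant = sort(cs$records$match_key[!cs$records$concordant])
  )
}

#' Rank candidates by correlation magnitude
#'
#' `min_abs_r` (the default, conservative: a candidate is only as strong as
#' its weaker dataset) or `mean_abs_r`. Descending score, ties broken
#' lexicographically by match key.
#'
#' @param cs A `candidate_set`.
#' @param method `"min_abs_r"` or `"mean_abs_r"`.
#' @return The `candidate_set` with `records` reordered and `rank_score`
#'   recomputed.
#' @export
rank_candidates <- function(cs, method = c("min_abs_r", "mean_abs_r")) {
  stopifnot(inherits(cs, "candidate_set"))
  method <- match.arg(method)
  rec <- cs$records
  if (nrow(rec)) {
    rec$rank_score <- switch(
      method,
      min_abs_r = pmin(abs(rec$r_1), abs(rec$r_2)),
      mean_abs_r = (abs(rec$r_1) + abs(rec$r_2)) / 2
    )
    rec <- rec[order(-rec$rank_score, rec$match_key), , drop = FALSE]
    rownames(rec) <- NULL
  }
  cs$records <- rec
  cs$rank_method <- method
  cs
}

#' Write the candidate table as TSV
#'
#' Columns `match_key`, `symbol`, `r_ds1`, `p_ds1`, `r_ds2`, `p_ds2`,
#' `concordant`, `rank_score`, in rank order (candidates are ranked with
#' [rank_candidates()] first if they have not been). Deterministic: the same
#' candidate set always produces a byte-identical file. Discordant
#' candidates are flagged, not dropped.
#'
#' @param cs A `candidate_set`.
#' @param path Output path.
#' @export
write_candidate_table <- function(cs, path) {
  stopifnot(inherits(cs, "candidate_set"))
  if (is.null(cs$rank_method)) cs <- rank_candidates(cs)
  rec <- cs$records
  out <- data.frame(
    match_key = rec$match_key, symbol = rec$gene_symbol,
    r_ds1 = rec$r_1, p_ds1 = rec$p_1, r_ds2 = rec$r_2, p_ds2 = rec$p_2,
    concordant = rec$concordant, rank_score = rec$rank_score,
    stringsAsFactors = FALSE
  )
  write_tsv_deterministic(out, path)
}

#' Read back a written candidate table
#'
#' @param path Path to a TSV written by [write_candidate_table()].
#' @return Data frame with the written columns.
#' @export
read_candidate_table <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  utils::read.delim(path, stringsAsFactors = FALSE)
}
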