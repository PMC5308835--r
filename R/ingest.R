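# Readers and validators for expression matrices, feature annotations and
# gene-gene interaction evidence.

MISSING_TOKENS <- c("null", "na", "nan", "")

#' Construct an expression matrix
#'
#' The central data container of the package: a features x samples grid of
#' (log-scale) expression intensities with unique feature and sample
#' identifiers. Missing values are allowed; correlations are later computed
#' over pairwise-complete observations.
#'
#' @param values Numeric matrix, features in rows, samples in columns, with
#'   rownames (feature ids) and colnames (sample ids).
#' @param dataset_id Short label for the dataset.
#' @param log_scale Logical flag asserting the values are log-transformed
#'   intensities. The package never auto-detects the scale: silent transforms
#'   corrupt correlation screens, so the caller must state it.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, dataset_id = "dataset", log_scale = TRUE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort_validation("`values` must be a numeric matrix")
  }
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid)) {
    abort_validation("`values` must carry feature ids (rownames) and sample ids (colnames)")
  }
  if (anyDuplicated(fid)) {
    abort_validation(sprintf(
      "duplicate feature ids: %s",
      paste(unique(fid[duplicated(fid)]), collapse = ", ")
    ))
  }
  if (anyDuplicated(sid)) {
    abort_validation(sprintf(
      "duplicate sample ids: %s",
      paste(unique(sid[duplicated(sid)]), collapse = ", ")
    ))
  }
  if (ncol(values) < 3L) {
    abort_validation("at least 3 samples are required (Pearson p-values are undefined below n = 3)")
  }
  structure(
    list(values = values, dataset_id = dataset_id, log_scale = isTRUE(log_scale)),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf(
    "<expression_matrix> %s: %d features x %d samples (%d missing values)\n",
    x$dataset_id, nrow(x$values), ncol(x$values), sum(is.na(x$values))
  ))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

feature_ids <- function(expr) rownames(expr$values)
sample_ids <- function(expr) colnames(expr$values)

parse_expr_cell <- function(tokens) {
  out <- suppressWarnings(as.numeric(tokens))
  out[tolower(tokens) %in% MISSING_TOKENS] <- NA_real_
  bad <- is.na(out) & !(tolower(tokens) %in% MISSING_TOKENS)
  list(values = out, bad = bad)
}

unquote <- function(x) gsub('^"|"$', "", x)

read_lines_clean <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  sub("\r$", "", readLines(path, warn = FALSE))
}

apply_log2 <- function(values) {
  if (any(values < 0, na.rm = TRUE)) {
    abort_validation("negative values found; refusing to apply log2(x + 1)")
  }
  log2(values + 1)
}

# Shared body for the two tabular expression readers. `lines` carries the
# data block (header row first), `line_offset` maps block rows back to file
# line numbers for error messages.
parse_expression_block <- function(lines, line_offset, dataset_id, log2_transform) {
  if (length(lines) < 2L) abort_validation("expression table has no data rows")
  header <- unquote(strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]])
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  widths <- lengths(rows)
  n_col <- widths[[1L]]
  ragged <- which(widths != n_col)
  if (length(ragged)) {
    abort_format(sprintf(
      "ragged row at line %d: expected %d fields, found %d",
      line_offset + 1L + ragged[[1L]], n_col, widths[[ragged[[1L]]]]
    ))
  }
  if (length(header) == n_col) {
    samples <- header[-1L]          # leading corner cell (e.g. ID_REF)
  } else if (length(header) == n_col - 1L) {
    samples <- header               # bare sample-id header
  } else {
    abort_format(sprintf(
      "header at line %d has %d fields but data rows have %d",
      line_offset + 1L, length(header), n_col
    ))
  }
  if (n_col < 2L) abort_validation("expression table has no sample columns")
  fid <- unquote(vapply(rows, `[[`, "", 1L))
  cells <- unlist(lapply(rows, `[`, -1L), use.names = FALSE)
  parsed <- parse_expr_cell(unquote(cells))
  if (any(parsed$bad)) {
    bad_row <- (which(parsed$bad)[[1L]] - 1L) %/% (n_col - 1L) + 1L
    abort_format(sprintf(
      "non-numeric value at line %d", line_offset + 1L + bad_row
    ))
  }
  values <- matrix(parsed$values, nrow = length(rows), byrow = TRUE,
                   dimnames = list(fid, samples))
  if (log2_transform) values <- apply_log2(values)
  expression_matrix(values, dataset_id = dataset_id, log_scale = TRUE)
}

#' Read a GEO Series Matrix file
#'
#' Parses the table section of a GEO Series Matrix file (the block between
#' the `!series_matrix_table_begin` and `!series_matrix_table_end` markers).
#' All other metadata lines are ignored. Quoted tokens are unquoted and the
#' tokens `null`, `NA`, `NaN` and empty cells (case-insensitive) become
#' missing values.
#'
#' @param path Path to the Series Matrix file.
#' @param dataset_id Label for the dataset; defaults to the file name.
#' @param log2_transform Apply `log2(x + 1)` on load. Errors on negative
#'   input. Values are otherwise assumed to be log-scale already.
#' @return An [expression_matrix()].
#' @export
read_series_matrix <- function(path, dataset_id = NULL, log2_transform = FALSE) {
  lines <- read_lines_clean(path)
  beg <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
  end <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
  if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L) {
    abort_format(sprintf(
      "series matrix table markers missing or malformed in %s", path
    ))
  }
  if (is.null(dataset_id)) {
    dataset_id <- sub("\\.[^.]*$", "", basename(path))
  }
  parse_expression_block(lines[(beg + 1L):(end - 1L)], line_offset = beg,
                         dataset_id = dataset_id, log2_transform = log2_transform)
}

#' Read a plain TSV expression matrix
#'
#' First row: sample ids (with or without a leading corner label); first
#' column: feature ids. Missing-value tokens as in [read_series_matrix()].
#'
#' @inheritParams read_series_matrix
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(path, dataset_id = NULL, log2_transform = FALSE) {
  lines <- read_lines_clean(path)
  lines <- lines[nzchar(lines)]
  if (is.null(dataset_id)) dataset_id <- sub("\\.[^.]*$", "", basename(path))
  parse_expression_block(lines, line_offset = 0L,
                         dataset_id = dataset_id, log2_transform = log2_transform)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_tsv()]: round-tripping preserves values and
#' missing-cell positions exactly.
#'
#' @param expr An [expression_matrix()].
#' @param path Output path.
#' @export
write_expression_tsv <- function(expr, path) {
  stopifnot(inherits(expr, "expression_matrix"))
  con <- try_open(path)
  on.exit(close(con))
  writeLines(paste(c("feature_id", sample_ids(expr)), collapse = "\t"), con)
  body <- apply(expr$values, 1L, function(v) {
    paste(ifelse(is.na(v), "NA", format(v, digits = 17, trim = TRUE, scientific = FALSE)),
          collapse = "\t")
  })
  writeLines(paste(feature_ids(expr), body, sep = "\t"), con)
  invisible(path)
}

try_open <- function(path) {
  con <- tryCatch(file(path, open = "w"), error = function(e) NULL,
                  warning = function(w) NULL)
  if (is.null(con)) abort_io(sprintf("cannot open %s for writing", path))
  con
}

#' Read a feature annotation table
#'
#' Two-plus-column TSV mapping feature id (e.g. Affymetrix probeset id) to
#' gene symbol, with an optional description column. Lines starting with `#`
#' are skipped. Symbols are uppercased on load so matching across platforms
#' is case-insensitive; no alias resolution is attempted.
#'
#' @param path Path to the TSV file.
#' @return A `feature_annotation` data frame with columns `feature_id`,
#'   `gene_symbol`, `description`.
#' @export
read_annotation <- function(path) {
  lines <- read_lines_clean(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rows <- strsplit(lines, "\t", fixed = TRUE)
  if (length(rows) && any(lengths(rows) < 2L)) {
    # a trailing empty symbol field is legal ("id\t"), strsplit drops it
    rows <- lapply(rows, function(r) if (length(r) == 1L) c(r, "") else r)
  }
  fid <- vapply(rows, `[[`, "", 1L)
  sym <- toupper(vapply(rows, `[[`, "", 2L))
  desc <- vapply(rows, function(r) if (length(r) >= 3L) r[[3L]] else "", "")
  # drop a header row if present
  if (length(fid) && tolower(fid[[1L]]) %in% c("feature_id", "id", "probe_id", "id_ref")) {
    fid <- fid[-1L]; sym <- sym[-1L]; desc <- desc[-1L]
  }
  if (anyDuplicated(fid)) {
    dup <- unique(fid[duplicated(fid)])
    conflicting <- dup[vapply(dup, function(d) length(unique(sym[fid == d])) > 1L, NA)]
    if (length(conflicting)) {
      abort_validation(sprintf(
        "conflicting gene symbols for feature id(s): %s",
        paste(conflicting, collapse = ", ")
      ))
    }
    keep <- !duplicated(fid)
    fid <- fid[keep]; sym <- sym[keep]; desc <- desc[keep]
  }
  structure(
    data.frame(feature_id = fid, gene_symbol = sym, description = desc,
               stringsAsFactors = FALSE),
    class = c("feature_annotation", "data.frame")
  )
}

#' Construct interaction evidence from an edge table
#'
#' Normalises a gene-gene edge table into an undirected, deduplicated edge
#' set. Self-loops are dropped with a warning; `(a, b)` and `(b, a)` collapse
#' to one edge; when duplicate records disagree on the relation, `direct`
#' wins. Both `direct` and `indirect` relations count equally in network
#' growth and scoring; the distinction is kept for display only.
#'
#' @param edges Data frame with columns `gene_a`, `gene_b` and optionally
#'   `relation` (`"direct"` or `"indirect"`).
#' @param default_relation Relation assigned when the column is absent.
#' @return An `interaction_evidence` data frame.
#' @export
interaction_evidence <- function(edges, default_relation = "direct") {
  stopifnot(is.data.frame(edges))
  if (!all(c("gene_a", "gene_b") %in% names(edges))) {
    abort_validation("edge table needs columns gene_a and gene_b")
  }
  rel <- if ("relation" %in% names(edges)) tolower(edges$relation) else
    rep(default_relation, nrow(edges))
  rel[is.na(rel) | rel == ""] <- default_relation
  bad <- !(rel %in% c("direct", "indirect"))
  if (any(bad)) {
    abort_format(sprintf(
      "unknown relation value(s): %s", paste(unique(rel[bad]), collapse = ", ")
    ))
  }
  a <- toupper(as.character(edges$gene_a))
  b <- toupper(as.character(edges$gene_b))
  if (any(!nzchar(a)) || any(!nzchar(b))) abort_format("empty gene symbol in edge table")
  loops <- a == b
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop edge(s)", sum(loops)), call. = FALSE)
    a <- a[!loops]; b <- b[!loops]; rel <- rel[!loops]
  }
  ga <- pmin(a, b)
  gb <- pmax(a, b)
  key <- paste(ga, gb, sep = "\r")
  # direct wins over indirect on duplicates
  o <- order(key, rel)  # "direct" < "indirect" lexicographically
  ga <- ga[o]; gb <- gb[o]; rel <- rel[o]; key <- key[o]
  keep <- !duplicated(key)
  out <- data.frame(gene_a = ga[keep], gene_b = gb[keep], relation = rel[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("interaction_evidence", "data.frame"))
}

#' Read a gene-gene interaction edge list
#'
#' An open stand-in for proprietary interaction knowledge bases. Two dialects,
#' chosen explicitly by flag (never auto-detected): `"tsv"` with columns
#' `gene_a`, `gene_b`\[, `relation`\], and `"sif"` with
#' `gene_a relation gene_b` per line (whitespace-separated).
#'
#' @param path Path to the edge list.
#' @param dialect `"tsv"` or `"sif"`.
#' @param default_relation Relation used when a row omits it.
#' @return An [interaction_evidence()] edge set.
#' @export
read_edge_list <- function(path, dialect = c("tsv", "sif"),
                           default_relation = "direct") {
  dialect <- match.arg(dialect)
  lines <- read_lines_clean(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    return(interaction_evidence(data.frame(gene_a = character(), gene_b = character())))
  }
  if (dialect == "tsv") {
    rows <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(rows) < 2L)) {
      abort_format(sprintf(
        "malformed edge row at line %d", which(lengths(rows) < 2L)[[1L]]
      ))
    }
    first <- tolower(rows[[1L]])
    if (first[[1L]] == "gene_a") rows <- rows[-1L]
    if (!length(rows)) {
      return(interaction_evidence(data.frame(gene_a = character(), gene_b = character())))
    }
    df <- data.frame(
      gene_a = vapply(rows, `[[`, "", 1L),
      gene_b = vapply(rows, `[[`, "", 2L),
      relation = vapply(rows, function(r) if (length(r) >= 3L) r[[3L]] else
        default_relation, ""),
      stringsAsFactors = FALSE
    )
  } else {
    rows <- strsplit(trimws(lines), "[ \t]+")
    if (any(lengths(rows) != 3L)) {
      abort_format(sprintf(
        "malformed SIF row at line %d (need: gene relation gene)",
        which(lengths(rows) != 3L)[[1L]]
      ))
    }
    df <- data.frame(
      gene_a = vapply(rows, `[[`, "", 1L),
      gene_b = vapply(rows, `[[`, "", 3L),
      relation = vapply(rows, `[[`, "", 2L),
      stringsAsFactors = FALSE
    )
  }
  interaction_evidence(df, default_relation = default_relation)
}

#' Filter features by completeness and variance
#'
#' Retains features observed in at least `min_complete_fraction` of samples
#' whose variance over non-missing entries is at least `min_variance`.
#' Feature order is preserved. Useful before a screen to drop flat probes.
#'
#' @param expr An [expression_matrix()].
#' @param min_complete_fraction Minimum fraction of non-missing samples, in
#'   \[0, 1\].
#' @param min_variance Minimum sample variance (non-negative).
#' @return The filtered [expression_matrix()].
#' @export
filter_features <- function(expr, min_complete_fraction = 0, min_variance = 0) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (min_complete_fraction < 0 || min_complete_fraction > 1 || min_variance < 0) {
    abort_validation("invalid filter thresholds")
  }
  v <- expr$values
  n_obs <- rowSums(!is.na(v))
  frac <- n_obs / ncol(v)
  vars <- apply(v, 1L, stats::var, na.rm = TRUE)
  vars[is.na(vars)] <- 0  # < 2 observations: treat as zero-variance
  keep <- frac >= min_complete_fraction & vars >= min_variance
  if (!any(keep)) abort_validation("no features pass the filter")
  expression_matrix(v[keep, , drop = FALSE], dataset_id = expr$dataset_id,
                    log_scale = expr$log_scale)
}
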