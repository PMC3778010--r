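# Readers, writers and container constructors for all external formats:
# expression TSV (genes x samples), two-column growth TSV, GMT gene sets,
# clinical survival tables, and PI/dPI score tables.

#' Construct an expression panel
#'
#' An expression panel is the gene-by-sample matrix all proliferation scores
#' are computed on. Values are stored in log2 units; `is_log2` records whether
#' the source data were already on that scale.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Must carry
#'   unique, non-empty row and column names.
#' @param is_log2 Logical provenance flag: `TRUE` means `values` are stored as
#'   supplied, `FALSE` is not allowed here (use [read_expression()] or
#'   [ingest_expression()] to apply the log2 transform).
#' @return An object of class `expression_panel` with elements `gene_ids`,
#'   `sample_ids`, `values` and `is_log2`.
#' @export
expression_panel <- function(values, is_log2 = TRUE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("`values` must have row names (gene ids) and column names (sample ids)")
  .check_unique(gene_ids, "gene id")
  .check_unique(sample_ids, "sample id")
  if (!all(is.finite(values)))
    stop("expression panel contains non-finite values; drop or impute before construction")
  structure(
    list(gene_ids = gene_ids, sample_ids = sample_ids,
         values = values, is_log2 = isTRUE(is_log2)),
    class = "expression_panel"
  )
}

#' @export
print.expression_panel <- function(x, ...) {
  cat(sprintf("expression_panel: %d genes x %d samples (log2 units)\n",
              length(x$gene_ids), length(x$sample_ids)))
  invisible(x)
}

#' @export
dim.expression_panel <- function(x) dim(x$values)

.check_unique <- function(ids, what) {
  if (anyNA(ids) || any(!nzchar(ids)))
    stop(sprintf("missing/empty %s", what))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop(sprintf("duplicated %s: %s", what,
                 paste(utils::head(dup, 5L), collapse = ", ")))
  invisible(ids)
}

#' Apply the ingest policy to a raw expression matrix
#'
#' Genes with any missing value are dropped (with a message), and raw-scale
#' data are mapped to `log2(value + offset)`. Data already on log2 scale are
#' stored unchanged, so ingest is idempotent on log2 input.
#'
#' @param values numeric matrix with gene/sample dimnames.
#' @param is_log2 are the values already log2-transformed?
#' @param offset nonnegative pseudo-count added before the log2 transform
#'   (ignored when `is_log2 = TRUE`). Default 1.
#' @return An [expression_panel()].
#' @export
ingest_expression <- function(values, is_log2 = TRUE, offset = 1) {
  if (!is.numeric(offset) || length(offset) != 1L || offset < 0)
    stop("`offset` must be a single nonnegative number")
  keep <- apply(values, 1L, function(v) all(is.finite(v)))
  if (!all(keep)) {
    message(sprintf("dropping %d gene(s) with missing or non-finite values",
                    sum(!keep)))
    values <- values[keep, , drop = FALSE]
  }
  if (nrow(values) == 0L) stop("no genes left after dropping missing values")
  if (!is_log2) {
    if (any(values + offset <= 0))
      stop("log2 ingest requires value + offset > 0 for every cell")
    values <- log2(values + offset)
  }
  expression_panel(values, is_log2 = TRUE)
}

#' Read a gene-by-sample expression TSV
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers. Raw (non-log) data are transformed to `log2(value + offset)`
#' at ingest; genes with missing values are dropped with a message.
#'
#' @param path path to a tab-separated file.
#' @inheritParams ingest_expression
#' @return An [expression_panel()].
#' @export
read_expression <- function(path, is_log2 = TRUE, offset = 1) {
  if (!file.exists(path)) stop(sprintf("expression file not found: %s", path))
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop(sprintf("%s: need a gene id column plus >=1 sample column", path))
  gene_ids <- df[[1L]]
  .check_unique(gene_ids, sprintf("gene id in %s", basename(path)))
  sample_ids <- colnames(df)[-1L]
  vals <- matrix(NA_real_, nrow(df), ncol(df) - 1L,
                 dimnames = list(gene_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- df[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col) & nzchar(col) & !col %in% c("NA", "NaN"))
    if (length(bad))
      stop(sprintf("%s: non-numeric cell at gene '%s', sample '%s' (value '%s')",
                   basename(path), gene_ids[bad[1L]], sample_ids[j], col[bad[1L]]))
    vals[, j] <- num
  }
  ingest_expression(vals, is_log2 = is_log2, offset = offset)
}

#' Write an expression panel as TSV
#'
#' Values are written with 17 significant digits so a write/read round trip
#' reproduces the matrix exactly.
#'
#' @param panel an [expression_panel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(panel, path) {
  stopifnot(inherits(panel, "expression_panel"))
  m <- matrix(sprintf("%.17g", panel$values), nrow(panel$values),
              dimnames = dimnames(panel$values))
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct per-sample growth measurements
#'
#' @param sample_ids character vector of unique sample identifiers.
#' @param values strictly positive measurements.
#' @param kind `"growth_rate"` (per unit time) or `"doubling_time"` (time for
#'   the culture to double). The two are related by rate = ln(2) / doubling
#'   time; see [to_growth_rate()].
#' @return An object of class `growth_measurements`.
#' @export
growth_measurements <- function(sample_ids,
                                values,
                                kind = c("growth_rate", "doubling_time")) {
  kind <- match.arg(kind)
  sample_ids <- as.character(sample_ids)
  .check_unique(sample_ids, "sample id")
  if (length(values) != length(sample_ids))
    stop("`values` and `sample_ids` lengths differ")
  if (anyNA(values) || any(!is.finite(values)))
    stop("growth values must be finite")
  bad <- which(values <= 0)
  if (length(bad))
    stop(sprintf("non-positive growth value for sample '%s'", sample_ids[bad[1L]]))
  structure(list(sample_ids = sample_ids, values = as.numeric(values), kind = kind),
            class = "growth_measurements")
}

#' @export
print.growth_measurements <- function(x, ...) {
  cat(sprintf("growth_measurements: %d samples, kind = %s\n",
              length(x$sample_ids), x$kind))
  invisible(x)
}

#' Read a two-column growth TSV (sample id, value)
#'
#' @param path path to a headerless two-column tab-separated file.
#' @inheritParams growth_measurements
#' @return A [growth_measurements()] object.
#' @export
read_growth <- function(path, kind = c("growth_rate", "doubling_time")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop(sprintf("growth file not found: %s", path))
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = c("character", "character"))
  if (ncol(df) != 2L) stop(sprintf("%s: expected exactly 2 tab-separated columns", path))
  vals <- suppressWarnings(as.numeric(df[[2L]]))
  bad <- which(is.na(vals))
  if (length(bad))
    stop(sprintf("%s: non-numeric growth value for sample '%s'",
                 basename(path), df[[1L]][bad[1L]]))
  growth_measurements(df[[1L]], vals, kind)
}

#' Write growth measurements as a two-column TSV
#' @param growth a [growth_measurements()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_growth <- function(growth, path) {
  stopifnot(inherits(growth, "growth_measurements"))
  utils::write.table(
    data.frame(growth$sample_ids, sprintf("%.17g", growth$values)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (members are deduplicated).
#' @param categories optional character vector, one label per set (recycled if
#'   length 1); used for per-category size filtering and correction in
#'   [run_collection()].
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, categories = NULL) {
  if (!is.list(sets)) stop("`sets` must be a named list")
  if (length(sets)) .check_unique(names(sets), "set name")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  empty <- vapply(sets, length, 1L) == 0L
  if (any(empty))
    stop(sprintf("empty gene set(s): %s",
                 paste(names(sets)[empty], collapse = ", ")))
  if (is.null(categories)) categories <- rep("default", length(sets))
  if (length(categories) == 1L) categories <- rep(categories, length(sets))
  if (length(categories) != length(sets))
    stop("`categories` must have one entry per set")
  categories <- stats::setNames(as.character(categories), names(sets))
  structure(list(sets = sets, categories = categories),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets (%s)\n", length(x$sets),
              paste(unique(x$categories), collapse = ", ")))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. The description field is
#' kept as the set's category label. Duplicate members within a line are
#' deduplicated.
#'
#' @param path path to a GMT file. An empty file yields an empty collection.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("GMT file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(gene_set_collection(list()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 1L)
  if (any(nf < 3L))
    stop(sprintf("%s: line %d has fewer than 3 tab-separated fields",
                 basename(path), which(nf < 3L)[1L]))
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, "", 1L)
  gene_set_collection(sets, vapply(fields, `[[`, "", 2L))
}

#' Write a gene-set collection as GMT
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(seq_along(collection$sets), function(i) {
    paste(c(names(collection$sets)[i], collection$categories[i],
            collection$sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Construct a survival cohort
#'
#' @param expression an [expression_panel()] of clinical samples.
#' @param time positive follow-up times, one per sample (study time units).
#' @param event event indicator per sample: 1 = event observed, 0 = censored.
#' @return An object of class `survival_cohort`.
#' @export
survival_cohort <- function(expression, time, event) {
  stopifnot(inherits(expression, "expression_panel"))
  n <- length(expression$sample_ids)
  if (length(time) != n || length(event) != n)
    stop("`time` and `event` must have one entry per sample")
  if (anyNA(time) || any(time <= 0)) stop("`time` must be positive")
  if (!all(event %in% c(0, 1))) stop("`event` must be 0 (censored) or 1 (event)")
  structure(list(expression = expression, time = as.numeric(time),
                 event = as.integer(event)),
            class = "survival_cohort")
}

#' @export
print.survival_cohort <- function(x, ...) {
  cat(sprintf("survival_cohort: %d samples, %d events, %d genes\n",
              length(x$time), sum(x$event), length(x$expression$gene_ids)))
  invisible(x)
}

#' Read a clinical survival table
#'
#' Tab-separated, samples in rows: first column sample id, reserved numeric
#' columns `time` and `event`, every remaining column a gene. Expression is
#' ingested under the same log2 policy as panels.
#'
#' @param path path to the clinical TSV.
#' @param time_col,event_col names of the reserved columns.
#' @inheritParams ingest_expression
#' @return A [survival_cohort()].
#' @export
read_clinical <- function(path, is_log2 = TRUE, offset = 1,
                          time_col = "time", event_col = "event") {
  if (!file.exists(path)) stop(sprintf("clinical file not found: %s", path))
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c(time_col, event_col) %in% colnames(df)))
    stop(sprintf("%s: missing reserved column '%s' or '%s'",
                 basename(path), time_col, event_col))
  sample_ids <- as.character(df[[1L]])
  gene_cols <- setdiff(colnames(df)[-1L], c(time_col, event_col))
  if (!length(gene_cols)) stop(sprintf("%s: no gene columns", basename(path)))
  vals <- t(as.matrix(df[, gene_cols, drop = FALSE]))
  if (!is.numeric(vals)) stop(sprintf("%s: gene columns must be numeric", basename(path)))
  dimnames(vals) <- list(gene_cols, sample_ids)
  panel <- ingest_expression(vals, is_log2 = is_log2, offset = offset)
  survival_cohort(panel, df[[time_col]], df[[event_col]])
}

#' Write a survival cohort as a clinical TSV
#' @param cohort a [survival_cohort()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(cohort, path) {
  stopifnot(inherits(cohort, "survival_cohort"))
  m <- matrix(sprintf("%.17g", cohort$expression$values),
              nrow(cohort$expression$values),
              dimnames = dimnames(cohort$expression$values))
  df <- data.frame(sample_id = cohort$expression$sample_ids,
                   time = sprintf("%.17g", cohort$time),
                   event = cohort$event,
                   t(m), check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align an expression panel with growth measurements by sample id
#'
#' Both objects are restricted to their shared samples, in panel order.
#' Alignment is always by identifier, never by column position, to guard
#' against sample label mix-ups.
#'
#' @param panel an [expression_panel()].
#' @param growth a [growth_measurements()] object.
#' @return A list with elements `panel` and `growth`, both restricted to the
#'   shared samples. Fails if fewer than 3 samples are shared.
#' @export
align_panel_growth <- function(panel, growth) {
  stopifnot(inherits(panel, "expression_panel"),
            inherits(growth, "growth_measurements"))
  shared <- panel$sample_ids[panel$sample_ids %in% growth$sample_ids]
  if (length(shared) < 3L)
    stop(sprintf("only %d shared sample(s) between panel and growth; need >= 3",
                 length(shared)))
  dropped <- (length(panel$sample_ids) - length(shared)) +
    (length(growth$sample_ids) - length(shared))
  if (dropped > 0L)
    message(sprintf("alignment dropped %d unshared sample entries", dropped))
  gv <- growth$values[match(shared, growth$sample_ids)]
  list(panel = expression_panel(panel$values[, shared, drop = FALSE]),
       growth = growth_measurements(shared, gv, growth$kind))
}

#' Write a PI or dPI score table as TSV
#'
#' Columns: `gene_id`, `value`, `p_value`, `method`, `n`.
#'
#' @param table a `pi_table` or `dpi_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(table, path) {
  if (inherits(table, "pi_table")) {
    out <- data.frame(gene_id = table$gene_id,
                      value = sprintf("%.17g", table$pi),
                      p_value = sprintf("%.17g", table$p_value),
                      method = attr(table, "method"),
                      n = attr(table, "n"), stringsAsFactors = FALSE)
  } else if (inherits(table, "dpi_table")) {
    out <- data.frame(gene_id = table$gene_id,
                      value = sprintf("%.17g", table$dpi),
                      p_value = sprintf("%.17g", table$p_value),
                      method = "dpi",
                      n = attr(table, "n"), stringsAsFactors = FALSE)
  } else stop("`table` must be a pi_table or dpi_table")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a score table written by [write_score_table()]
#'
#' @param path path to the TSV.
#' @return A `pi_table` (for spearman/slope methods) or `dpi_table`.
#' @export
read_score_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("score table not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "value", "p_value", "method", "n")
  if (!all(need %in% colnames(df)))
    stop(sprintf("%s: expected columns %s", basename(path),
                 paste(need, collapse = ", ")))
  method <- unique(df$method)
  if (length(method) != 1L) stop("mixed `method` values in score table")
  if (method == "dpi") {
    tab <- data.frame(gene_id = as.character(df$gene_id), dpi = df$value,
                      p_value = df$p_value, stringsAsFactors = FALSE)
    class(tab) <- c("dpi_table", "data.frame")
  } else {
    tab <- data.frame(gene_id = as.character(df$gene_id), pi = df$value,
                      p_value = df$p_value,
                      flagged = !is.finite(df$value), stringsAsFactors = FALSE)
    class(tab) <- c("pi_table", "data.frame")
    attr(tab, "method") <- method
  }
  attr(tab, "n") <- unique(df$n)[1L]
  tab
}
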