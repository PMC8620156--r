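# Long-format per-observation count tables: one row per (sample, taxon)
# observation with the response count, the total-reads offset, categorical
# fixed-effect covariates and categorical grouping factors.

#' Construct an observation table
#'
#' Validates a long-format count table (one row per observation) and
#' records which columns play which role: the nonnegative integer
#' response, the positive total-reads offset (sequencing depth), the
#' categorical fixed-effect covariates and the categorical grouping
#' factors for random effects.
#'
#' @param data A data.frame.
#' @param count Name of the count column (nonnegative integers).
#' @param offset Name of the total-reads column (positive integers), or
#'   `NULL` when no offset is used.
#' @param fixed Character vector of fixed-effect factor columns.
#' @param random Character vector of grouping-factor columns.
#' @return The data.frame with class `observation_table` and role
#'   attributes; factor columns are converted to factors (reference
#'   level = lexicographically first level).
#' @export
observation_table <- function(data, count = "y", offset = "total_reads",
                              fixed = character(), random = character()) {
  stopifnot(is.data.frame(data))
  cols <- c(count, offset, fixed, random)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  y <- data[[count]]
  bad <- which(!is.finite(y) | y < 0 | y != floor(y))
  if (length(bad))
    stop(sprintf("column '%s' must be nonnegative integers; first bad row: %d",
                 count, bad[1]), call. = FALSE)
  if (!is.null(offset)) {
    tt <- data[[offset]]
    bad <- which(!is.finite(tt) | tt <= 0)
    if (length(bad))
      stop(sprintf("column '%s' must be positive; first bad row: %d",
                   offset, bad[1]), call. = FALSE)
  }
  for (f in c(fixed, random)) {
    data[[f]] <- factor(data[[f]])
    if (any(is.na(data[[f]])) || any(!nzchar(levels(data[[f]]))))
      stop(sprintf("factor column '%s' has missing or empty levels", f),
           call. = FALSE)
  }
  structure(data,
            class = c("observation_table", "data.frame"),
            count = count, offset = offset,
            fixed = fixed, random = random)
}

ot_roles <- function(table) {
  list(count = attr(table, "count"), offset = attr(table, "offset"),
       fixed = attr(table, "fixed"), random = attr(table, "random"))
}

#' Read / write a count table
#'
#' Reads a TSV or CSV count table into a validated
#' [observation_table()].  The format is inferred from the file
#' extension unless given.
#'
#' @param path File path.
#' @param format `"auto"`, `"tsv"` or `"csv"`.
#' @inheritParams observation_table
#' @return An [observation_table()] (for `read_counts`), or the path
#'   invisibly (for `write_counts`).
#' @export
read_counts <- function(path, format = c("auto", "tsv", "csv"),
                        count = "y", offset = "total_reads",
                        fixed = c("F1", "F2", "F3"),
                        random = c("G1", "G2")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  observation_table(df, count = count, offset = offset,
                    fixed = fixed, random = random)
}

#' @rdname read_counts
#' @param table An [observation_table()] or data.frame to write.
#' @export
write_counts <- function(table, path, format = c("auto", "tsv", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  sep <- if (format == "csv") "," else "\t"
  utils::write.table(table, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Truncate small counts to zero
#'
#' Applied before modelling OTU tables in which small nonzero counts are
#' likely read-alignment artefacts rather than true presence: counts
#' strictly below the threshold are set to zero.  Per-taxon thresholds
#' can override the default for named taxa.
#'
#' @param table A data.frame or [observation_table()].
#' @param threshold Default truncation threshold (counts `< threshold`
#'   become 0); 0 is the identity.
#' @param overrides Named integer vector of per-taxon thresholds.
#' @param taxon_col Column naming the taxon of each row; required when
#'   `overrides` is given.
#' @param count Name of the count column.
#' @return The table with truncated counts; the number of truncated
#'   cells is recorded in attribute `"n_truncated"`.
#' @examples
#' truncate_counts(data.frame(y = c(0, 9, 10, 11)), threshold = 10)
#' @export
truncate_counts <- function(table, threshold = 10, overrides = NULL,
                            taxon_col = NULL, count = attr(table, "count")) {
  if (is.null(count)) count <- "y"
  if (threshold < 0 || (!is.null(overrides) && any(overrides < 0)))
    stop("thresholds must be >= 0", call. = FALSE)
  thr <- rep_len(threshold, nrow(table))
  if (!is.null(overrides)) {
    if (is.null(taxon_col))
      stop("'taxon_col' is required when 'overrides' is given", call. = FALSE)
    for (taxon in names(overrides))
      thr[table[[taxon_col]] == taxon] <- overrides[[taxon]]
  }
  y <- table[[count]]
  changed <- y < thr & y > 0
  y[y < thr] <- 0L
  table[[count]] <- y
  attr(table, "n_truncated") <- sum(changed)
  table
}
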