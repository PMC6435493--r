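#' Construct an abundance table
#'
#' An abundance table is a samples-by-features numeric matrix with unique
#' sample ids as row names, unique feature ids as column names, and a mode
#' describing the scale of its values: raw sequence counts (`"counts"`),
#' per-sample relative abundances summing to 1 (`"relative"`), or arbitrary
#' real values produced by a transform such as the centered log-ratio or
#' habitat-filtering correction (`"transformed"`).
#'
#' @param values numeric matrix, samples as rows, features as columns.
#'   Row and column names are the sample and feature ids.
#' @param mode one of `"counts"`, `"relative"`, `"transformed"`.
#'   `NULL` (default) auto-detects: rows summing to 1 within `1e-6` are
#'   relative, non-negative values are counts, anything else is transformed.
#' @param sample_ids,feature_ids optional replacements for the dimnames.
#' @return an `abundance_table`: the matrix with a `mode` attribute.
#' @export
abundance_table <- function(values, mode = NULL, sample_ids = NULL,
                            feature_ids = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("abundance values must be numeric")
  if (nrow(values) == 0L || ncol(values) == 0L) stop("abundance table is empty")
  if (!is.null(sample_ids)) rownames(values) <- sample_ids
  if (!is.null(feature_ids)) colnames(values) <- feature_ids
  if (is.null(rownames(values)))
    rownames(values) <- paste0("S", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("F", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate feature ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (anyNA(values)) stop("abundance table contains missing values")
  if (is.null(mode)) mode <- detect_mode(values)
  mode <- match.arg(mode, c("counts", "relative", "transformed"))
  if (mode == "counts" && any(values < 0))
    stop("counts mode requires non-negative values")
  if (mode == "relative") {
    bad <- abs(rowSums(values) - 1) > 1e-9
    if (any(values < 0) || any(bad))
      stop("relative mode requires non-negative rows summing to 1; offending samples: ",
           paste(rownames(values)[bad], collapse = ", "))
  }
  structure(values, mode = mode, class = c("abundance_table", class(values)))
}

detect_mode <- function(values) {
  if (all(abs(rowSums(values) - 1) <= 1e-6) && all(values >= 0)) "relative"
  else if (all(values >= 0)) "counts"
  else "transformed"
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d features (mode: %s)\n",
              nrow(x), ncol(x), table_mode(x)))
  n <- min(nrow(x), 6L); m <- min(ncol(x), 6L)
  print(unclass(x)[seq_len(n), seq_len(m), drop = FALSE])
  if (nrow(x) > n || ncol(x) > m)
    cat(sprintf("... (%d rows, %d cols not shown)\n", nrow(x) - n, ncol(x) - m))
  invisible(x)
}

#' Mode of an abundance table
#' @param x an `abundance_table`.
#' @return `"counts"`, `"relative"` or `"transformed"`.
#' @export
table_mode <- function(x) attr(x, "mode", exact = TRUE)

sample_ids <- function(x) rownames(x)
feature_ids <- function(x) colnames(x)

# strip class/attrs for numeric work
table_values <- function(x) {
  y <- unclass(x)
  attr(y, "mode") <- NULL
  y
}

#' Read an abundance table from delimited text
#'
#' Expects a header row and an id column: with `orientation =
#' "samples-as-rows"` (default) the header holds feature ids and the first
#' column sample ids; `"features-as-rows"` reads the transpose. The returned
#' table is always samples-as-rows.
#'
#' @param path file path.
#' @param orientation `"samples-as-rows"` or `"features-as-rows"`.
#' @param delimiter field separator, default tab.
#' @param mode forced mode, or `NULL` to auto-detect (rows summing to 1
#'   within `1e-6` are relative).
#' @return an [abundance_table()].
#' @export
read_abundance_table <- function(path,
                                 orientation = c("samples-as-rows",
                                                 "features-as-rows"),
                                 delimiter = "\t", mode = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          row.names = NULL, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  if (nrow(df) == 0L || ncol(df) < 2L) stop("empty table in ", path)
  ids <- as.character(df[[1L]])
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    if (!is.numeric(body[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(body[[j]]))))[1L]
      stop(sprintf("non-numeric cell at row %s, column %s in %s",
                   ids[bad], colnames(body)[j], path))
    }
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  if (orientation == "features-as-rows") m <- t(m)
  abundance_table(m, mode = mode)
}

#' Write an abundance table as delimited text
#'
#' Inverse of [read_abundance_table()]: header row of feature ids, first
#' column of sample ids.
#'
#' @param x an `abundance_table`.
#' @param path output path.
#' @param delimiter field separator, default tab.
#' @param id_header name for the id column header cell.
#' @export
write_abundance_table <- function(x, path, delimiter = "\t",
                                  id_header = "sample_id") {
  df <- data.frame(id = rownames(x), table_values(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_header
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a sample-to-habitat map
#'
#' Two-column delimited text (sample id, habitat label); a header line is
#' detected and skipped if its first field is one of `sample`, `sample_id`,
#' `#SampleID` (case-insensitive).
#'
#' @param path file path.
#' @param delimiter field separator, default tab.
#' @return named character vector: habitat labels named by sample id.
#' @export
read_habitat_map <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = FALSE, sep = delimiter,
                          stringsAsFactors = FALSE, comment.char = "")
  if (ncol(df) < 2L) stop("habitat map needs two columns (sample, habitat)")
  if (tolower(sub("^#", "", df[1L, 1L])) %in% c("sample", "sample_id", "sampleid"))
    df <- df[-1L, , drop = FALSE]
  as_habitat_map(stats::setNames(as.character(df[[2L]]), as.character(df[[1L]])))
}

#' Write a sample-to-habitat map
#' @param habitats named character vector (habitat labels named by sample id).
#' @param path output path.
#' @export
write_habitat_map <- function(habitats, path) {
  utils::write.table(
    data.frame(sample_id = names(habitats), habitat = unname(habitats)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# validate a habitat map, optionally against a table's samples
as_habitat_map <- function(habitats, x = NULL) {
  if (is.data.frame(habitats))
    habitats <- stats::setNames(as.character(habitats[[2L]]),
                                as.character(habitats[[1L]]))
  if (is.null(names(habitats)) || anyDuplicated(names(habitats)))
    stop("habitat map must name each sample exactly once")
  if (length(habitats) == 0L) stop("habitat map is empty")
  if (!is.null(x)) {
    missing <- setdiff(rownames(x), names(habitats))
    if (length(missing))
      stop("samples missing from habitat map: ",
           paste(missing, collapse = ", "))
    habitats <- habitats[rownames(x)]
  }
  habitats
}
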