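# Peak-table and metadata containers plus their delimited-text readers.
# A peak table is a samples x features intensity matrix whose feature
# identifiers are measured m/z values (optionally tagged with polarity);
# metadata joins sample identifiers to experimental variables.

.sniff_sep <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Construct a peak table
#'
#' @param intensities Numeric matrix, samples in rows, features in columns;
#'   missing values are `NA` (zeros are data).
#' @param feature_mz Numeric vector of feature m/z values; defaults to
#'   parsing the column names.
#' @param feature_polarity Character vector of `"+"`/`"-"`/`""` per feature.
#' @return A `peak_table` object.
#' @export
peak_table <- function(intensities, feature_mz = NULL, feature_polarity = NULL) {
  stopifnot(is.matrix(intensities), !is.null(rownames(intensities)))
  if (anyDuplicated(rownames(intensities))) {
    stop("duplicate sample identifiers", call. = FALSE)
  }
  if (is.null(feature_mz)) {
    hdr <- colnames(intensities)
    feature_polarity <- ifelse(grepl("[+-]$", hdr), substring(hdr, nchar(hdr)), "")
    feature_mz <- suppressWarnings(as.numeric(sub("[+-]$", "", hdr)))
    bad <- which(is.na(feature_mz) | feature_mz <= 0)
    if (length(bad)) {
      stop("feature header(s) not parseable as positive m/z: ",
           paste(hdr[bad], collapse = ", "), call. = FALSE)
    }
  }
  if (is.null(feature_polarity)) feature_polarity <- rep("", ncol(intensities))
  stopifnot(length(feature_mz) == ncol(intensities),
            all(feature_mz > 0),
            all(intensities >= 0 | is.na(intensities)))
  structure(list(intensities = intensities,
                 feature_mz = as.numeric(feature_mz),
                 feature_polarity = feature_polarity),
            class = "peak_table")
}

#' @export
print.peak_table <- function(x, ...) {
  cat("<peak_table> ", nrow(x$intensities), " samples x ",
      ncol(x$intensities), " features; ",
      sum(is.na(x$intensities)), " missing cells\n", sep = "")
  invisible(x)
}

#' @export
dim.peak_table <- function(x) dim(x$intensities)

#' Read a peak table from delimited text
#'
#' First column: sample identifiers. Remaining headers: m/z values,
#' optionally suffixed `+` or `-` for polarity (e.g. `263.1117+`). Empty
#' cells and `"NA"` are recorded as missing, never as zero; `"0"` is data.
#'
#' @param path CSV or TSV file, decimal point only.
#' @param transpose If `TRUE`, the file stores features in rows and samples
#'   in columns and is transposed on read.
#' @return A [peak_table()].
#' @export
read_peak_table <- function(path, transpose = FALSE) {
  raw <- utils::read.table(path, header = TRUE, sep = .sniff_sep(path),
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("", "NA"), comment.char = "")
  ids <- as.character(raw[[1]])
  mat <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  if (transpose) {
    mat <- t(mat)
  }
  if (anyDuplicated(rownames(mat))) {
    stop("duplicate sample identifiers: ",
         paste(unique(rownames(mat)[duplicated(rownames(mat))]), collapse = ", "),
         call. = FALSE)
  }
  peak_table(mat)
}

#' Read a sample metadata table
#'
#' Accepts a delimited file with one sample-identifier column (named
#' `sample`, `sample_id`, `id`, or the MetaboLights-style `"Sample Name"`;
#' matching is case-insensitive) and at least one experimental variable.
#' Variable columns that parse fully as numbers become numeric; all others
#' become factors.
#'
#' @param path CSV or TSV file.
#' @return A `data.frame` with attribute `sample_col`; sample identifiers in
#'   the identified column, one row per sample.
#' @export
read_metadata <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = .sniff_sep(path),
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("", "NA"), comment.char = "")
  aliases <- c("sample", "sample_id", "sample name", "id", "sample.name")
  hit <- which(tolower(names(raw)) %in% aliases)
  if (!length(hit)) {
    stop("no sample-identifier column found (expected one of: sample, ",
         "sample_id, 'Sample Name', id)", call. = FALSE)
  }
  if (ncol(raw) < 2L) stop("metadata needs at least one variable column",
                           call. = FALSE)
  sample_col <- names(raw)[hit[1]]
  raw[[sample_col]] <- as.character(raw[[sample_col]])
  if (anyDuplicated(raw[[sample_col]])) {
    stop("duplicate sample identifiers in metadata", call. = FALSE)
  }
  for (nm in setdiff(names(raw), sample_col)) {
    v <- raw[[nm]]
    num <- suppressWarnings(as.numeric(v))
    raw[[nm]] <- if (!anyNA(num[!is.na(v)])) num else factor(v)
  }
  attr(raw, "sample_col") <- sample_col
  raw
}

# align metadata rows to peak-table samples; every peak-table sample must be
# present exactly once
.join_meta <- function(pt, meta) {
  sc <- attr(meta, "sample_col") %||% names(meta)[1]
  ids <- rownames(pt$intensities)
  idx <- match(ids, meta[[sc]])
  if (anyNA(idx)) {
    stop("samples missing from metadata: ",
         paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  m <- meta[idx, , drop = FALSE]
  attr(m, "sample_col") <- sc
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Subset samples of a peak table and its metadata consistently
#'
#' @param pt A [peak_table()].
#' @param meta Metadata table covering the peak-table samples.
#' @param predicate Either a logical vector over the (aligned) metadata rows
#'   or a function `meta -> logical`.
#' @return List with elements `peaks` and `meta`, features unchanged. An
#'   empty selection is an error.
#' @export
subset_samples <- function(pt, meta, predicate) {
  m <- .join_meta(pt, meta)
  keep <- if (is.function(predicate)) predicate(m) else predicate
  stopifnot(is.logical(keep), length(keep) == nrow(m))
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) stop("predicate selects no samples", call. = FALSE)
  pt2 <- pt
  pt2$intensities <- pt$intensities[keep, , drop = FALSE]
  m2 <- m[keep, , drop = FALSE]
  attr(m2, "sample_col") <- attr(m, "sample_col")
  list(peaks = pt2, meta = m2)
}

#' Write a peak table to delimited text
#' @param pt A [peak_table()].
#' @param path Output CSV path. Missing values are written as empty cells.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(pt, path) {
  hdr <- paste0(format(pt$feature_mz, trim = TRUE, digits = 10),
                pt$feature_polarity)
  df <- data.frame(sample = rownames(pt$intensities),
                   pt$intensities, check.names = FALSE)
  names(df) <- c("sample", hdr)
  data.table::fwrite(df, path, sep = ",", na = "")
  invisible(path)
}
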