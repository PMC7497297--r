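# ppm-tolerance annotation of measured m/z values against an extended
# database: closed-interval window search on the (polarity, m/z) index,
# isotope filtering and ppm-error ranking.

#' ppm tolerance window around an m/z value
#'
#' Closed interval `[mz*(1 - ppm*1e-6), mz*(1 + ppm*1e-6)]`; the half-width
#' is proportional to m/z, which is what makes ppm the scale-free accuracy
#' unit of high-resolution MS.
#'
#' @param mz Positive m/z value(s).
#' @param ppm Positive tolerance in parts per million.
#' @return Two-column matrix with columns `lo`, `hi`.
#' @examples
#' ppm_window(100, 10)
#' @export
ppm_window <- function(mz, ppm) {
  stopifnot(all(mz > 0), ppm > 0)
  cbind(lo = mz * (1 - ppm * 1e-6), hi = mz * (1 + ppm * 1e-6))
}

.empty_hits <- function() {
  data.frame(query_mz = numeric(0), source = character(0),
             compound_id = character(0), name = character(0),
             formula = character(0), adduct = character(0),
             isotope = character(0), theoretical_mz = numeric(0),
             ppm_error = numeric(0), rank = integer(0),
             stringsAsFactors = FALSE)
}

#' Annotate one m/z value against an extended database
#'
#' Returns every variant row of the selected source databases whose
#' theoretical m/z lies inside the closed ppm window around the query
#' (boundary values included), optionally restricted to main-peak (`M0`)
#' isotopes, sorted by absolute signed ppm error
#' (`1e6 * (query - theoretical)/theoretical`) with deterministic
#' lexicographic tie-breaking on (source, compound id, adduct name).
#'
#' @param db An `extended_db`.
#' @param mz Query m/z (single positive value).
#' @param ppm Tolerance in ppm (default 2, the accuracy regime of DI-MS).
#' @param polarity `"+"`, `"-"` or `"both"`.
#' @param sources Character vector of source labels to search, or `NULL` for
#'   all. An empty selection is an error.
#' @param main_peak_only If `TRUE`, isotopologue rows (label != `"M0"`) are
#'   filtered out before ranking.
#' @return Hit table with columns `query_mz, source, compound_id, name,
#'   formula, adduct, isotope, theoretical_mz, ppm_error, rank`; zero rows if
#'   nothing matches.
#' @examples
#' \dontrun{search_mz(db, 264.1190, ppm = 2, polarity = "+")}
#' @export
search_mz <- function(db, mz, ppm = 2, polarity = c("both", "+", "-"),
                      sources = NULL, main_peak_only = FALSE) {
  stopifnot(inherits(db, "extended_db"), is.numeric(mz), length(mz) == 1L,
            mz > 0, ppm > 0)
  polarity <- match.arg(polarity)
  if (!is.null(sources) && !length(sources)) {
    stop("no source databases selected", call. = FALSE)
  }
  pols <- if (polarity == "both") c("+", "-") else polarity
  win <- ppm_window(mz, ppm)
  rows <- integer(0)
  for (p in pols) {
    idx <- db$index[[p]]
    if (!length(idx$rows)) next
    lo_i <- findInterval(win[, "lo"], idx$mz, left.open = TRUE) + 1L
    hi_i <- findInterval(win[, "hi"], idx$mz)
    if (hi_i >= lo_i) rows <- c(rows, idx$rows[lo_i:hi_i])
  }
  v <- db$variants[rows, , drop = FALSE]
  if (!is.null(sources)) v <- v[v$source %in% sources, , drop = FALSE]
  if (main_peak_only) v <- v[v$isotope == "M0", , drop = FALSE]
  if (!nrow(v)) return(.empty_hits())
  cm <- db$compounds[match(v$compound_id, db$compounds$id), , drop = FALSE]
  hits <- data.frame(query_mz = mz, source = v$source,
                     compound_id = v$compound_id, name = cm$name,
                     formula = cm$formula, adduct = v$adduct,
                     isotope = v$isotope, theoretical_mz = v$mz,
                     ppm_error = 1e6 * (mz - v$mz) / v$mz,
                     stringsAsFactors = FALSE)
  ord <- order(abs(hits$ppm_error), hits$source, hits$compound_id, hits$adduct)
  hits <- hits[ord, , drop = FALSE]
  hits$rank <- seq_len(nrow(hits))
  rownames(hits) <- NULL
  hits
}

#' Annotate a batch of m/z queries
#'
#' Runs [search_mz()] for each query; results are identical to the serial
#' loop regardless of the worker count (workers beyond one use forked
#' processes where the platform supports them). Per-query errors are caught
#' and reported in the result rather than aborting the batch.
#'
#' @param db An `extended_db`.
#' @param queries Either a numeric vector of m/z values or a `data.frame`
#'   with columns `mz` and optionally `polarity`.
#' @param ppm,polarity,sources,main_peak_only Defaults applied to queries
#'   without their own polarity; see [search_mz()].
#' @param workers Number of parallel workers (default 1).
#' @return Named list of hit tables (or `try-error` conditions), one per
#'   query, names formatted from the query m/z.
#' @export
batch_search <- function(db, queries, ppm = 2, polarity = "both",
                         sources = NULL, main_peak_only = FALSE,
                         workers = 1L) {
  if (is.numeric(queries)) {
    if (!length(queries)) return(structure(list(), names = character(0)))
    queries <- data.frame(mz = queries, polarity = polarity)
  }
  if (!nrow(queries)) return(structure(list(), names = character(0)))
  if (is.null(queries$polarity)) queries$polarity <- polarity
  run_one <- function(i) {
    tryCatch(search_mz(db, queries$mz[i], ppm = ppm,
                       polarity = queries$polarity[i], sources = sources,
                       main_peak_only = main_peak_only),
             error = function(e) e)
  }
  idx <- seq_len(nrow(queries))
  res <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(idx, run_one, mc.cores = workers)
  } else {
    lapply(idx, run_one)
  }
  names(res) <- format(queries$mz, trim = TRUE)
  res
}

#' Re-rank hits by isotope and adduct status
#'
#' Post-annotation prioritization for follow-up validation: main-peak (`M0`)
#' records before isotopologues; within each, plain protonation/deprotonation
#' adducts (`[M+H]+`, `[M-H]-`) before salt adducts and dimers; within each
#' stratum, by absolute ppm error. The re-ranking is stable.
#'
#' @param hits A hit table from [search_mz()].
#' @return The same rows re-ordered, with `rank` rebuilt.
#' @export
prioritize_hits <- function(hits) {
  if (!nrow(hits)) return(hits)
  iso_rank <- ifelse(hits$isotope == "M0", 0L, 1L)
  adduct_rank <- ifelse(hits$adduct %in% c("[M+H]+", "[M-H]-"), 0L, 1L)
  ord <- order(iso_rank, adduct_rank, abs(hits$ppm_error))
  hits <- hits[ord, , drop = FALSE]
  hits$rank <- seq_len(nrow(hits))
  rownames(hits) <- NULL
  hits
}

#' Write a hit table to TSV
#' @param hits Hit table (or list of hit tables from [batch_search()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  if (is.list(hits) && !is.data.frame(hits)) {
    hits <- data.table::rbindlist(Filter(is.data.frame, hits))
  }
  data.table::fwrite(hits, path, sep = "\t")
  invisible(path)
}
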