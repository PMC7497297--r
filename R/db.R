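# Local extended-database build and storage. A build turns a compound table
# into variant rows (one per compound x adduct x isotopologue) stored under a
# single directory: compounds.tsv, variants.tsv and meta.json. Range queries
# run against an in-memory index sorted on (polarity, m/z), so a single build
# serves any ppm tolerance chosen at query time.

#' Import a user compound table
#'
#' Reads a delimited compound table (CSV or TSV, UTF-8, header row) into
#' compound records. Mandatory columns: `id`, `name`, `formula`. Optional:
#' `smiles`, `description`, `synonyms` (semicolon separated). Column matching
#' is case-insensitive and accepts the common aliases `identifier`/
#' `compound_id` for `id`.
#'
#' @param path Path to the delimited file.
#' @param source_label Database-of-origin label attached to every record.
#' @return A `data.frame` of compound records with columns `id`, `name`,
#'   `synonyms`, `formula`, `smiles`, `description`, `source`.
#' @export
import_compound_table <- function(path, source_label = "user") {
  raw <- utils::read.table(path, header = TRUE, sep = .sniff_sep(path),
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "", na.strings = c("", "NA"),
                           check.names = FALSE)
  nm <- tolower(names(raw))
  pick <- function(aliases) {
    hit <- which(nm %in% aliases)
    if (length(hit)) raw[[hit[1]]] else NULL
  }
  id <- pick(c("id", "identifier", "compound_id"))
  name <- pick(c("name", "compound_name", "display_name"))
  formula <- pick(c("formula", "molecular_formula"))
  missing_cols <- c("id", "name", "formula")[c(is.null(id), is.null(name),
                                               is.null(formula))]
  if (length(missing_cols)) {
    stop("compound table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dup <- unique(id[duplicated(id)])
  if (length(dup)) {
    stop("duplicate compound identifiers: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  blank <- function(x) if (is.null(x)) rep("", nrow(raw)) else {
    x[is.na(x)] <- ""; as.character(x)
  }
  data.frame(id = as.character(id), name = as.character(name),
             synonyms = blank(pick("synonyms")),
             formula = as.character(formula),
             smiles = blank(pick("smiles")),
             description = blank(pick("description")),
             source = source_label, stringsAsFactors = FALSE)
}

#' Collapse and separate compound records by structure
#'
#' Records sharing an identical SMILES string are merged into one record:
#' the first-seen name becomes the display name, the synonym list becomes the
#' case-insensitive union of all names and prior synonyms, and descriptions
#' are concatenated after deduplication. Records with equal molecular
#' formulas but distinct SMILES remain separate rows (same formula, different
#' structure), and records without a SMILES are never merged.
#'
#' @param records Compound records as from [import_compound_table()].
#' @return Normalized compound records.
#' @export
normalize_compounds <- function(records) {
  if (!nrow(records)) return(records)
  has_smiles <- !is.na(records$smiles) & nzchar(records$smiles)
  keyed <- records[has_smiles, , drop = FALSE]
  loose <- records[!has_smiles, , drop = FALSE]
  if (nrow(keyed)) {
    groups <- split(seq_len(nrow(keyed)), factor(keyed$smiles,
                                                 levels = unique(keyed$smiles)))
    keyed <- do.call(rbind, lapply(groups, function(idx) {
      sub <- keyed[idx, , drop = FALSE]
      rec <- sub[1, , drop = FALSE]
      syn <- c(sub$name, unlist(strsplit(sub$synonyms, ";", fixed = TRUE)))
      syn <- trimws(syn)
      syn <- syn[nzchar(syn)]
      syn <- syn[!duplicated(tolower(syn))]
      syn <- setdiff(syn, rec$name)
      rec$synonyms <- paste(syn, collapse = ";")
      desc <- unique(sub$description[nzchar(sub$description)])
      rec$description <- paste(desc, collapse = " | ")
      rec
    }))
  }
  out <- rbind(keyed, loose)
  rownames(out) <- NULL
  out
}

#' Build an extended variant database
#'
#' Expands every compound into its adduct/isotopologue m/z variants and
#' writes the result to `store_path` (a directory holding `compounds.tsv`,
#' `variants.tsv` and `meta.json`). Rebuilding with the same path replaces
#' the previous content. Compounds whose formula does not parse are skipped
#' and listed in the build report; a table where more than half the formulas
#' fail to parse aborts the build, since that signals a malformed input.
#'
#' @param compounds Compound records ([import_compound_table()] /
#'   [normalize_compounds()]).
#' @param store_path Directory to (re)create for the store.
#' @param rules Adduct rule table.
#' @param specs Isotope spec table or `NULL` for main peaks only.
#' @param abundance_floor Minimum isotopologue relative abundance stored.
#' @return An `extended_db` object (also reloadable via [open_extended_db()])
#'   with elements `compounds`, `variants`, `meta` and `path`. `meta` records
#'   row counts, per-source compound counts, skipped compounds, a hash of the
#'   rule set and the element-table version.
#' @export
build_extended_db <- function(compounds, store_path,
                              rules = default_adduct_rules(),
                              specs = default_isotope_specs(),
                              abundance_floor = 1e-4) {
  .check_rules(rules)
  stopifnot(nrow(compounds) >= 1L)
  parsed <- lapply(compounds$formula, function(x) tryCatch(parse_formula(x),
                                                           error = function(e) NULL))
  ok <- !vapply(parsed, is.null, logical(1))
  skipped <- compounds$id[!ok]
  if (mean(!ok) > 0.5) {
    stop("more than 50% of compound formulas failed to parse (",
         sum(!ok), "/", length(ok), "); refusing to build from a malformed table",
         call. = FALSE)
  }
  if (length(skipped)) {
    message("skipping ", length(skipped), " compound(s) with unparseable formulas")
  }
  keep <- compounds[ok, , drop = FALSE]
  vlist <- lapply(seq_len(nrow(keep)), function(i) {
    v <- enumerate_variants(keep$formula[i], rules, specs, abundance_floor)
    if (!nrow(v)) return(NULL)
    cbind(data.frame(compound_id = keep$id[i], source = keep$source[i]), v)
  })
  variants <- data.table::rbindlist(vlist)
  data.table::setDF(variants)
  meta <- list(
    built = format(Sys.time(), tz = "UTC"),
    element_table = ELEMENT_TABLE_VERSION,
    rule_hash = .rule_hash(rules, specs),
    n_rules = nrow(rules),
    n_isotope_specs = if (is.null(specs)) 0L else nrow(specs),
    abundance_floor = abundance_floor,
    n_compounds = nrow(keep),
    n_variants = nrow(variants),
    compounds_per_source = as.list(table(keep$source)),
    skipped_compounds = as.list(skipped)
  )
  if (dir.exists(store_path)) unlink(store_path, recursive = TRUE)
  dir.create(store_path, recursive = TRUE)
  data.table::fwrite(keep, file.path(store_path, "compounds.tsv"), sep = "\t")
  data.table::fwrite(variants, file.path(store_path, "variants.tsv"), sep = "\t")
  jsonlite::write_json(meta, file.path(store_path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  .make_db(keep, variants, meta, store_path)
}

# stable content hash of the rule configuration, recorded in build metadata
.rule_hash <- function(rules, specs) {
  txt <- paste(c(apply(rules, 1, paste, collapse = "|"),
                 if (!is.null(specs)) apply(specs, 1, paste, collapse = "|")),
               collapse = "\n")
  # polynomial rolling hash (exact in doubles, reduced mod 2^31 - 1)
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.make_db <- function(compounds, variants, meta, path) {
  ord <- order(variants$polarity, variants$mz)
  variants <- variants[ord, , drop = FALSE]
  rownames(variants) <- NULL
  index <- lapply(c("+", "-"), function(p) {
    rows <- which(variants$polarity == p)
    list(rows = rows, mz = variants$mz[rows])
  })
  names(index) <- c("+", "-")
  structure(list(compounds = compounds, variants = variants,
                 meta = meta, path = path, index = index),
            class = "extended_db")
}

#' Open a previously built extended database
#'
#' @param store_path Directory written by [build_extended_db()].
#' @return An `extended_db` object with the (polarity, m/z) index rebuilt.
#' @export
open_extended_db <- function(store_path) {
  need <- file.path(store_path, c("compounds.tsv", "variants.tsv", "meta.json"))
  if (!all(file.exists(need))) {
    stop("not an extended-db store: ", store_path, call. = FALSE)
  }
  compounds <- data.table::fread(need[1], sep = "\t", data.table = FALSE,
                                 na.strings = NULL, colClasses = list(character = "id"))
  variants <- data.table::fread(need[2], sep = "\t", data.table = FALSE,
                                na.strings = NULL,
                                colClasses = list(character = "compound_id"))
  meta <- jsonlite::read_json(need[3], simplifyVector = TRUE)
  .make_db(compounds, variants, meta, store_path)
}

#' @export
print.extended_db <- function(x, ...) {
  cat("<extended_db> ", x$meta$n_compounds, " compounds, ",
      x$meta$n_variants, " variant m/z rows\n",
      "  store: ", x$path, "\n",
      "  rules: ", x$meta$n_rules, " adducts, ", x$meta$n_isotope_specs,
      " isotope specs (hash ", x$meta$rule_hash, ")\n",
      "  element table: ", x$meta$element_table, "\n", sep = "")
  invisible(x)
}
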