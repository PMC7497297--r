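# Seeded synthetic-data generators: random compound tables, evenly
# stratified query pools over the 60-600 m/z range, and two-group
# case/control peak experiments with planted differential features. Every
# generator is a pure function of its arguments plus the seed, so the whole
# annotation and statistics workflow is testable without any download.

.with_seed <- function(seed, expr) {
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# one random formula passing the golden-rule heuristics, by rejection
.random_formula <- function(constraints) {
  for (attempt in 1:200) {
    C <- sample(3:22, 1)
    H <- max(1L, round(C * stats::runif(1, 0.6, 2.4)))
    N <- sample(0:min(4, floor(C * 1.3)), 1)
    O <- sample(0:min(8, floor(C * 1.2)), 1)
    P <- sample(0:1, 1, prob = c(0.92, 0.08))
    S <- sample(0:1, 1, prob = c(0.9, 0.1))
    cn <- c(C = C, H = H, N = N, O = O, P = P, S = S)
    f <- as_formula(cn)
    if (all(apply_golden_rules(f, constraints))) return(f)
  }
  NULL
}

#' Generate a random compound table
#'
#' Draws `n` random CHNOPS formulas by rejection sampling against the
#' golden-rule heuristics, restricted so their `[M+H]+` m/z lies inside
#' `mz_range`. To stress deduplication, a configurable fraction of extra
#' records is injected sharing the SMILES of an earlier compound (synonym
#' duplicates) and another fraction sharing its formula under a distinct
#' SMILES (structural isomers). SMILES strings are synthetic placeholders
#' (unique tokens), not chemically meaningful structures.
#'
#' @param n Number of base compounds.
#' @param seed Integer seed.
#' @param mz_range Admissible `[M+H]+` m/z interval (default 60-600, the
#'   span of the query-pool design).
#' @param dup_smiles_rate,dup_formula_rate Injection rates for the two
#'   duplicate classes (fractions of `n`, default 0).
#' @param source_label Source tag for every record.
#' @return Compound records as in [import_compound_table()].
#' @export
gen_compound_db <- function(n, seed = 1L, mz_range = c(60, 600),
                            dup_smiles_rate = 0, dup_formula_rate = 0,
                            source_label = "synthetic") {
  stopifnot(n >= 1, mz_range[1] < mz_range[2])
  cons <- prediction_constraints()
  proton <- physical_constants()$proton_mz
  .with_seed(seed, {
    recs <- vector("list", n)
    i <- 0L; tries <- 0L
    while (i < n) {
      tries <- tries + 1L
      if (tries > 200L * n) {
        stop("element bounds admit too few valid formulas; gave up after ",
             tries, " rejections", call. = FALSE)
      }
      f <- .random_formula(cons)
      if (is.null(f)) next
      mz <- monoisotopic_mass(f) + proton
      if (mz < mz_range[1] || mz > mz_range[2]) next
      i <- i + 1L
      recs[[i]] <- data.frame(
        id = sprintf("SYN%05d", i),
        name = sprintf("synthetic-compound-%d", i),
        synonyms = "",
        formula = format_formula(f),
        smiles = sprintf("SMI{%s#%d}", format_formula(f), i),
        description = sprintf("synthetic record %d", i),
        source = source_label, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, recs)
    add <- list()
    n_dup_s <- round(n * dup_smiles_rate)
    if (n_dup_s > 0) {
      pick <- sample(n, n_dup_s, replace = TRUE)
      add$smiles <- data.frame(
        id = sprintf("SYNDS%04d", seq_len(n_dup_s)),
        name = sprintf("alias-of-%s", out$id[pick]),
        synonyms = "", formula = out$formula[pick],
        smiles = out$smiles[pick],
        description = "synonym duplicate", source = source_label,
        stringsAsFactors = FALSE)
    }
    n_dup_f <- round(n * dup_formula_rate)
    if (n_dup_f > 0) {
      pick <- sample(n, n_dup_f, replace = TRUE)
      add$formula <- data.frame(
        id = sprintf("SYNDF%04d", seq_len(n_dup_f)),
        name = sprintf("isomer-of-%s", out$id[pick]),
        synonyms = "", formula = out$formula[pick],
        smiles = sprintf("SMI{%s#iso%d}", out$formula[pick], seq_len(n_dup_f)),
        description = "structural isomer", source = source_label,
        stringsAsFactors = FALSE)
    }
    rbind(out, add$smiles, add$formula)
  })
}

#' Generate an evenly distributed m/z query pool
#'
#' `n` values stratified over `[lo, hi]`: the range is cut into `n` equal
#' strata and one value drawn uniformly within each, giving an even spread
#' with seeded jitter — the query-pool design used for search benchmarking.
#'
#' @param n Pool size (default 100).
#' @param lo,hi Range bounds (default 60 and 600 m/z).
#' @param seed Integer seed.
#' @return Numeric vector of length `n`, increasing, all inside `[lo, hi]`.
#' @export
gen_query_pool <- function(n = 100L, lo = 60, hi = 600, seed = 1L) {
  stopifnot(n >= 1, lo < hi)
  breaks <- seq(lo, hi, length.out = n + 1L)
  .with_seed(seed, stats::runif(n, breaks[-(n + 1L)], breaks[-1L]))
}

#' Simulate a two-group peak experiment with planted effects
#'
#' Log-normal intensity model: each feature has a log-scale baseline drawn
#' uniformly over `log(1e3)`-`log(1e5)` and a log-scale standard deviation
#' drawn from `sd_range`; samples are split into two equal groups and a
#' chosen subset of features is shifted upward by `effect` feature-sds in
#' group 2. Missing values are injected completely at random at
#' `missing_rate`. Feature m/z values are drawn from the 60-600 range.
#'
#' @param n_per_group Samples per group (default 20).
#' @param n_features Total features (default 200).
#' @param n_planted Number of differential features (default 10).
#' @param effect Shift in units of the feature's log-scale sd (default 2).
#' @param missing_rate MCAR missing fraction in \[0, 1) (default 0).
#' @param sd_range Range of per-feature log-scale sds (default 0.25-0.6).
#' @param seed Integer seed.
#' @return List with `peaks` (a [peak_table()]), `meta` (sample, group) and
#'   `truth` (`data.frame` of feature, planted flag).
#' @export
gen_peak_experiment <- function(n_per_group = 20L, n_features = 200L,
                                n_planted = 10L, effect = 2,
                                missing_rate = 0, sd_range = c(0.25, 0.6),
                                seed = 1L) {
  stopifnot(n_per_group >= 2, n_features >= 1, n_planted <= n_features,
            effect >= 0, missing_rate >= 0, missing_rate < 1)
  .with_seed(seed, {
    n <- 2L * n_per_group
    mz <- sort(stats::runif(n_features, 60, 600))
    mu <- stats::runif(n_features, log(1e3), log(1e5))
    sd_f <- stats::runif(n_features, sd_range[1], sd_range[2])
    planted <- sort(sample(n_features, n_planted))
    group <- rep(c("control", "case"), each = n_per_group)
    logx <- matrix(stats::rnorm(n * n_features,
                                mean = rep(mu, each = n),
                                sd = rep(sd_f, each = n)),
                   nrow = n, ncol = n_features)
    shift <- matrix(0, n, n_features)
    shift[group == "case", planted] <- rep(effect * sd_f[planted],
                                           each = n_per_group)
    x <- exp(logx + shift)
    if (missing_rate > 0) {
      x[stats::runif(length(x)) < missing_rate] <- NA_real_
    }
    rownames(x) <- sprintf("S%03d", seq_len(n))
    feats <- paste0(format(mz, trim = TRUE, digits = 10), "+")
    colnames(x) <- feats
    pt <- peak_table(x, feature_mz = mz,
                     feature_polarity = rep("+", n_features))
    meta <- data.frame(sample = rownames(x), group = group,
                       stringsAsFactors = FALSE)
    attr(meta, "sample_col") <- "sample"
    truth <- data.frame(feature = feats, mz = mz,
                        planted = seq_len(n_features) %in% planted,
                        stringsAsFactors = FALSE)
    list(peaks = pt, meta = meta, truth = truth)
  })
}

#' Search-performance report over a database-size sweep
#'
#' Builds nested databases of the requested compound counts (each smaller
#' database is a prefix of the largest, so match counts are monotone in
#' size), runs every pool query against each, and reports per-size median
#' query latency and per-query match counts. Timings are informational only:
#' nothing here asserts on wall-clock.
#'
#' @param db_sizes Increasing integer vector of compound counts.
#' @param pool Numeric m/z query pool (see [gen_query_pool()]).
#' @param ppm Search tolerance.
#' @param seed Seed for the compound generator.
#' @param store_dir Scratch directory for the builds (default a tempdir).
#' @return List with `summary` (per size: rows, median/total seconds) and
#'   `matches` (per size x query: matches found).
#' @export
scaling_harness <- function(db_sizes, pool, ppm = 2, seed = 1L,
                            store_dir = tempfile("scaling")) {
  stopifnot(!is.unsorted(db_sizes))
  if (!length(pool)) {
    return(list(summary = data.frame(n_compounds = integer(0)),
                matches = data.frame()))
  }
  compounds <- gen_compound_db(max(db_sizes), seed = seed)
  dir.create(store_dir, recursive = TRUE, showWarnings = FALSE)
  summaries <- list(); match_rows <- list()
  for (sz in db_sizes) {
    db <- build_extended_db(compounds[seq_len(sz), , drop = FALSE],
                            file.path(store_dir, paste0("db", sz)))
    times <- matches <- numeric(length(pool))
    for (i in seq_along(pool)) {
      t0 <- proc.time()[["elapsed"]]
      hits <- search_mz(db, pool[i], ppm = ppm, polarity = "both")
      times[i] <- proc.time()[["elapsed"]] - t0
      matches[i] <- nrow(hits)
    }
    summaries[[as.character(sz)]] <- data.frame(
      n_compounds = sz, n_rows = db$meta$n_variants,
      median_query_s = stats::median(times), total_s = sum(times),
      total_matches = sum(matches))
    match_rows[[as.character(sz)]] <- data.frame(
      n_compounds = sz, query_mz = pool, matches = matches)
  }
  list(summary = do.call(rbind, c(summaries, make.row.names = FALSE)),
       matches = do.call(rbind, c(match_rows, make.row.names = FALSE)))
}
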