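# Minimal statistics layer between a peak table and the annotation step:
# normalization, imputation, per-feature two-group tests with FDR control,
# fold changes, and hypergeometric overlap tests for comparing hit lists.

#' Normalize a peak table
#'
#' Sample normalization, transformation and feature scaling applied in that
#' order, mirroring the usual untargeted-MS preprocessing chain.
#'
#' @param pt A [peak_table()].
#' @param method Sample normalization: `"none"`, `"total-sum"` (each row is
#'   divided by its sum) or `"median"` (divided by its median).
#' @param transform `"none"` or `"log10"` (applies `log10(x + 1)`).
#' @param scale Feature scaling: `"none"`, `"auto"` (centre, divide by sd)
#'   or `"pareto"` (centre, divide by sqrt(sd)).
#' @return A normalized [peak_table()].
#' @export
normalize_peaks <- function(pt, method = c("none", "total-sum", "median"),
                            transform = c("none", "log10"),
                            scale = c("none", "auto", "pareto")) {
  method <- match.arg(method); transform <- match.arg(transform)
  scale <- match.arg(scale)
  x <- pt$intensities
  if (method != "none") {
    denom <- switch(method,
                    "total-sum" = rowSums(x, na.rm = TRUE),
                    "median" = apply(x, 1, stats::median, na.rm = TRUE))
    zero <- which(!is.finite(denom) | denom == 0)
    if (length(zero)) {
      stop("cannot ", method, "-normalize all-zero sample(s): ",
           paste(rownames(x)[zero], collapse = ", "), call. = FALSE)
    }
    x <- sweep(x, 1, denom, "/")
  }
  if (transform == "log10") x <- log10(x + 1)
  if (scale != "none") {
    mu <- colMeans(x, na.rm = TRUE)
    sd_ <- apply(x, 2, stats::sd, na.rm = TRUE)
    div <- switch(scale, auto = sd_, pareto = sqrt(sd_))
    div[div == 0 | !is.finite(div)] <- 1  # constant features left centred
    x <- sweep(sweep(x, 2, mu, "-"), 2, div, "/")
  }
  pt$intensities <- x
  pt
}

#' Impute missing intensities
#'
#' Three strategies: `"half-min"` replaces each feature's missing cells with
#' half its minimum observed value (the fast default for left-censored MS
#' data); `"knn"` averages each missing cell over the `k` nearest samples
#' (Euclidean distance on shared observed features); `"rf"` runs iterative
#' random-forest regression per incomplete feature (initialized at half-min,
#' capped at `rf_iter` sweeps). Observed entries are never altered, and the
#' stochastic strategies are reproducible given `seed`.
#'
#' @param pt A [peak_table()].
#' @param strategy `"half-min"`, `"knn"` or `"rf"`.
#' @param seed Integer seed for the stochastic strategies.
#' @param k Neighbour count for `"knn"`.
#' @param rf_iter Sweep cap for `"rf"`.
#' @return A complete [peak_table()]; features with no observed value at all
#'   are dropped with a warning.
#' @export
impute_missing <- function(pt, strategy = c("half-min", "knn", "rf"),
                           seed = 1L, k = 5L, rf_iter = 3L) {
  strategy <- match.arg(strategy)
  x <- pt$intensities
  all_missing <- colSums(!is.na(x)) == 0L
  if (any(all_missing)) {
    warning("dropping ", sum(all_missing), " feature(s) with no observed values",
            call. = FALSE)
    x <- x[, !all_missing, drop = FALSE]
    pt$feature_mz <- pt$feature_mz[!all_missing]
    pt$feature_polarity <- pt$feature_polarity[!all_missing]
  }
  if (!anyNA(x)) { pt$intensities <- x; return(pt) }

  half_min <- function(m) {
    for (j in which(colSums(is.na(m)) > 0L)) {
      m[is.na(m[, j]), j] <- min(m[, j], na.rm = TRUE) / 2
    }
    m
  }

  if (strategy == "half-min") {
    x <- half_min(x)
  } else if (strategy == "knn") {
    obs <- !is.na(x)
    filled <- x
    for (i in which(rowSums(!obs) > 0L)) {
      d <- vapply(seq_len(nrow(x)), function(j) {
        shared <- obs[i, ] & obs[j, ]
        if (i == j || !any(shared)) return(Inf)
        sqrt(mean((x[i, shared] - x[j, shared])^2))
      }, numeric(1))
      nb <- order(d)[seq_len(min(k, sum(is.finite(d))))]
      for (jf in which(!obs[i, ])) {
        vals <- x[nb, jf]
        filled[i, jf] <- if (all(is.na(vals))) min(x[, jf], na.rm = TRUE) / 2
                         else mean(vals, na.rm = TRUE)
      }
    }
    x <- filled
  } else {  # rf
    old_seed <- globalenv()$.Random.seed
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()))
    set.seed(seed)
    miss <- is.na(x)
    orig <- x
    x <- half_min(x)
    incomplete <- which(colSums(miss) > 0L)
    for (it in seq_len(rf_iter)) {
      for (j in incomplete) {
        train <- which(!miss[, j])
        test <- which(miss[, j])
        predictors <- x[, -j, drop = FALSE]
        fit <- randomForest::randomForest(
          x = predictors[train, , drop = FALSE], y = x[train, j],
          ntree = 100)
        x[test, j] <- stats::predict(fit, predictors[test, , drop = FALSE])
      }
    }
    x[!miss] <- orig[!miss]
  }
  pt$intensities <- x
  pt
}

#' Per-feature two-group t-tests with FDR control
#'
#' Welch (unequal-variance) two-sample t-test per feature, or a paired t-test
#' when `paired = TRUE` (samples matched by order within each level).
#' Raw p-values are adjusted across all tested features by
#' Benjamini-Hochberg (or Bonferroni). Features that are constant within
#' both groups (or with constant paired differences) are flagged and left
#' untested rather than reported with an unstable statistic.
#'
#' @param pt A [peak_table()].
#' @param meta Metadata table covering the samples.
#' @param variable Name of a metadata variable with exactly two levels.
#' @param paired Paired test (requires equal group sizes; pairs matched by
#'   within-group order).
#' @param adjust `"BH"` (default) or `"bonferroni"`.
#' @return `data.frame` with one row per feature: `feature`, `mz`,
#'   `polarity`, `mean_1`, `mean_2` (per level, raw scale), `statistic`,
#'   `p_value`, `p_adjusted`, `log2_fc`, `constant` flag. Ordered as the
#'   peak-table features.
#' @export
ttest_all <- function(pt, meta, variable, paired = FALSE,
                      adjust = c("BH", "bonferroni")) {
  adjust <- match.arg(adjust)
  m <- .join_meta(pt, meta)
  g <- m[[variable]]
  if (is.null(g)) stop("metadata variable not found: ", variable, call. = FALSE)
  g <- factor(g)
  if (nlevels(g) != 2L) {
    stop("variable '", variable, "' has ", nlevels(g),
         " levels; two-group tests need exactly 2 (use multivariate methods ",
         "for more)", call. = FALSE)
  }
  lv <- levels(g)
  i1 <- which(g == lv[1]); i2 <- which(g == lv[2])
  if (length(i1) < 2L || length(i2) < 2L) {
    stop("need at least 2 samples per level", call. = FALSE)
  }
  if (paired && length(i1) != length(i2)) {
    stop("paired test needs equal group sizes", call. = FALSE)
  }
  x <- pt$intensities
  n_feat <- ncol(x)
  stat <- p <- rep(NA_real_, n_feat)
  constant <- logical(n_feat)
  for (j in seq_len(n_feat)) {
    a <- x[i1, j]; b <- x[i2, j]
    degenerate <- if (paired) stats::sd(b - a, na.rm = TRUE) == 0
                  else stats::sd(a, na.rm = TRUE) == 0 &&
                       stats::sd(b, na.rm = TRUE) == 0
    if (is.na(degenerate) || degenerate) { constant[j] <- TRUE; next }
    tt <- tryCatch(
      if (paired) stats::t.test(b, a, paired = TRUE)
      else stats::t.test(b, a, var.equal = FALSE),
      error = function(e) NULL)
    if (is.null(tt)) { constant[j] <- TRUE; next }
    stat[j] <- unname(tt$statistic)
    p[j] <- tt$p.value
  }
  p_adj <- rep(NA_real_, n_feat)
  tested <- !is.na(p)
  p_adj[tested] <- stats::p.adjust(p[tested], method = adjust)
  mean1 <- colMeans(x[i1, , drop = FALSE], na.rm = TRUE)
  mean2 <- colMeans(x[i2, , drop = FALSE], na.rm = TRUE)
  out <- data.frame(
    feature = paste0(format(pt$feature_mz, trim = TRUE, digits = 10),
                     pt$feature_polarity),
    mz = pt$feature_mz, polarity = pt$feature_polarity,
    mean_1 = mean1, mean_2 = mean2,
    statistic = stat, p_value = p, p_adjusted = p_adj,
    log2_fc = log2(mean2 / mean1),
    constant = constant, stringsAsFactors = FALSE)
  names(out)[names(out) == "mean_1"] <- paste0("mean_", lv[1])
  names(out)[names(out) == "mean_2"] <- paste0("mean_", lv[2])
  rownames(out) <- NULL
  out
}

#' Per-feature log2 fold change of group means
#'
#' Computed on the raw (un-log-transformed) intensity scale as
#' `log2(mean(level2) / mean(level1))`, level order taken from the metadata
#' factor. A zero denominator yields an infinite fold change that is flagged
#' (`fc_undefined`) so volcano plots can exclude it.
#'
#' @inheritParams ttest_all
#' @return `data.frame` with `feature`, `mz`, `log2_fc`, `fc_undefined`.
#' @export
fold_change <- function(pt, meta, variable) {
  m <- .join_meta(pt, meta)
  g <- factor(m[[variable]])
  stopifnot(nlevels(g) == 2L)
  lv <- levels(g)
  x <- pt$intensities
  m1 <- colMeans(x[g == lv[1], , drop = FALSE], na.rm = TRUE)
  m2 <- colMeans(x[g == lv[2], , drop = FALSE], na.rm = TRUE)
  fc <- log2(m2 / m1)
  data.frame(
    feature = paste0(format(pt$feature_mz, trim = TRUE, digits = 10),
                     pt$feature_polarity),
    mz = pt$feature_mz, log2_fc = fc,
    fc_undefined = !is.finite(fc), stringsAsFactors = FALSE)
}

#' Volcano-plot input from test results
#'
#' @param stats A result from [ttest_all()].
#' @return `data.frame` of `(feature, log2_fc, neg_log10_p)` pairs, with
#'   undefined fold changes and untested features removed.
#' @export
volcano_data <- function(stats) {
  keep <- is.finite(stats$log2_fc) & !is.na(stats$p_adjusted)
  data.frame(feature = stats$feature[keep], log2_fc = stats$log2_fc[keep],
             neg_log10_p = -log10(stats$p_adjusted[keep]),
             stringsAsFactors = FALSE)
}

#' Hypergeometric significance of an overlap between two hit lists
#'
#' Upper-tail probability `P(X >= |A intersect B|)` with
#' `X ~ Hypergeometric(universe, |A|, |B|)`, computed by exact summation of
#' the hypergeometric mass function — the test behind Venn-diagram overlap
#' significance when comparing significant-feature lists across analyses or
#' subsets.
#'
#' @param list_a,list_b Vectors of feature identifiers (duplicates removed).
#' @param universe Either the universe size (single integer) or the universe
#'   as a vector, in which case membership of both lists is checked.
#' @return Single p-value in (0, 1].
#' @examples
#' hypergeom_overlap(letters[1:10], letters[6:15], 26)
#' @export
hypergeom_overlap <- function(list_a, list_b, universe) {
  a <- unique(list_a); b <- unique(list_b)
  if (length(universe) == 1L && is.numeric(universe)) {
    N <- as.integer(universe)
  } else {
    u <- unique(universe)
    out_a <- setdiff(a, u); out_b <- setdiff(b, u)
    if (length(out_a) || length(out_b)) {
      stop("list element(s) outside the universe: ",
           paste(c(out_a, out_b), collapse = ", "), call. = FALSE)
    }
    N <- length(u)
  }
  nA <- length(a); nB <- length(b); k <- length(intersect(a, b))
  stopifnot(nA <= N, nB <= N, k <= min(nA, nB))
  kmax <- min(nA, nB)
  sum(stats::dhyper(k:kmax, nA, N - nA, nB))
}
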