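# Molecular-formula deduction from accurate mass: the annotation route for
# m/z values with no database hit. Candidates are enumerated by depth-first
# branch-and-bound over element counts with residual-mass pruning, then
# filtered by Seven-Golden-Rules style heuristics (element-count ranges,
# RDBE validity, element ratios). Rules that need isotope-pattern intensities
# or MS/MS spectra are out of scope here.

#' Constraints for formula enumeration
#'
#' @param elements Elements to enumerate over (default CHNOPS).
#' @param ppm Mass tolerance in ppm.
#' @param max_counts Named integer vector of hard per-element caps; elements
#'   not named are capped by the mass-scaled default
#'   `floor(mass / element_mass) + 1`. Defaults cap P at 6 and S at 8.
#' @param check_counts,check_rdbe,check_ratios Toggles for the three rule
#'   families (all on by default).
#' @param ratio_bounds List of element-ratio limits; defaults follow the
#'   common-range heuristics: H/C in \[0.2, 3.1\], N/C <= 1.3, O/C <= 1.2,
#'   P/C <= 0.3, S/C <= 0.8. Ratio rules apply only to carbon-containing
#'   formulas.
#' @param allow_radicals If `TRUE`, half-integer RDBE (odd-electron species)
#'   is not rejected; default `FALSE` (neutral even-electron assumption).
#' @param max_candidates Abort threshold for runaway enumerations.
#' @return A `prediction_constraints` list.
#' @export
prediction_constraints <- function(elements = c("C", "H", "N", "O", "P", "S"),
                                   ppm = 3,
                                   max_counts = c(P = 6L, S = 8L),
                                   check_counts = TRUE,
                                   check_rdbe = TRUE,
                                   check_ratios = TRUE,
                                   ratio_bounds = list(
                                     HC = c(0.2, 3.1), NC = c(0, 1.3),
                                     OC = c(0, 1.2), PC = c(0, 0.3),
                                     SC = c(0, 0.8)),
                                   allow_radicals = FALSE,
                                   max_candidates = 10000L) {
  stopifnot(all(elements %in% .ELEMENTS$elements), ppm > 0)
  for (b in ratio_bounds) stopifnot(b[1] <= b[2], all(b >= 0))
  structure(list(elements = elements, ppm = ppm, max_counts = max_counts,
                 check_counts = check_counts, check_rdbe = check_rdbe,
                 check_ratios = check_ratios, ratio_bounds = ratio_bounds,
                 allow_radicals = allow_radicals,
                 max_candidates = as.integer(max_candidates)),
            class = "prediction_constraints")
}

# mass-scaled upper bound on the count of one element
.element_cap <- function(el, mass, constraints) {
  cap <- floor(mass / .ELEMENTS$mono_mass[[el]]) + 1L
  if (el %in% names(constraints$max_counts)) {
    cap <- min(cap, constraints$max_counts[[el]])
  }
  as.integer(cap)
}

#' Neutral mass from an observed ionic m/z
#'
#' Inverts the adduct relation: `M = (z*mz + q*m_e - added + removed) / x`.
#' This is the exact inverse of [adduct_mz()] for every rule.
#'
#' @param mz Observed m/z (> 0).
#' @param rule A single adduct rule.
#' @return Neutral monoisotopic mass in u.
#' @examples
#' neutral_mass_from_mz(264.1190117, default_adduct_rules()[1, ])
#' @export
neutral_mass_from_mz <- function(mz, rule) {
  stopifnot(is.numeric(mz), all(mz > 0))
  q <- if (rule$polarity == "+") rule$z else -rule$z
  delta <- monoisotopic_mass(rule$added) - monoisotopic_mass(rule$removed)
  M <- (rule$z * mz + q * ELECTRON_MASS - delta) / rule$x
  if (any(M < -1e-9)) {
    stop("adduct ", rule$name, " is inconsistent with m/z ", mz,
         " (negative neutral mass)", call. = FALSE)
  }
  pmax(M, 0)
}

#' Apply Golden-Rules style heuristics to one formula
#'
#' Three rule families: (1) element counts within mass-scaled ranges;
#' (2) RDBE non-negative and, for neutral even-electron molecules,
#' integer-valued; (3) element ratios within common-range bounds (H/C, N/C,
#' O/C, P/C, S/C), applied only when the formula contains carbon.
#'
#' @param f Formula (string or parsed).
#' @param constraints A [prediction_constraints()] object.
#' @return Named logical vector `c(count_range, rdbe_valid, ratios)` plus an
#'   attribute `rdbe` with the computed value. Disabled rules report `TRUE`.
#' @examples
#' apply_golden_rules("C9H17N3O6", prediction_constraints())
#' @export
apply_golden_rules <- function(f, constraints = prediction_constraints()) {
  f <- as_formula(f)
  cnt <- function(e) if (e %in% names(f)) as.numeric(f[[e]]) else 0
  mass <- monoisotopic_mass(f)

  count_ok <- TRUE
  if (constraints$check_counts) {
    for (el in names(f)) {
      if (f[[el]] > .element_cap(el, mass, constraints)) count_ok <- FALSE
    }
  }

  r <- rdbe(f)
  rdbe_ok <- TRUE
  if (constraints$check_rdbe) {
    rdbe_ok <- r >= 0
    if (!constraints$allow_radicals && abs(r - round(r)) > 1e-9) rdbe_ok <- FALSE
  }

  ratio_ok <- TRUE
  if (constraints$check_ratios && cnt("C") > 0) {
    rb <- constraints$ratio_bounds
    chk <- function(num, bounds) num / cnt("C") >= bounds[1] &&
      num / cnt("C") <= bounds[2]
    ratio_ok <- chk(cnt("H"), rb$HC) && chk(cnt("N"), rb$NC) &&
      chk(cnt("O"), rb$OC) && chk(cnt("P"), rb$PC) && chk(cnt("S"), rb$SC)
  }

  structure(c(count_range = count_ok, rdbe_valid = rdbe_ok, ratios = ratio_ok),
            rdbe = r)
}

#' Enumerate candidate molecular formulas for a neutral mass
#'
#' Complete enumeration of formulas over the constraint elements whose
#' monoisotopic mass falls inside the ppm window, by depth-first search in
#' decreasing element-mass order with residual-mass pruning: a branch is cut
#' as soon as its partial mass exceeds the window or the remaining elements
#' cannot reach it; the lightest element's count is solved directly from the
#' residual window at the leaf. Candidates failing any enabled golden rule
#' are dropped unless `verbose = TRUE`.
#'
#' @param neutral_mass Target neutral mass (u), in (0, 2000].
#' @param constraints A [prediction_constraints()] object.
#' @param verbose If `TRUE`, rule-failing candidates are kept, with their
#'   per-rule flags, instead of being dropped.
#' @return `data.frame` with columns `formula`, `mass`, `ppm_error`, `rdbe`,
#'   `count_range`, `rdbe_valid`, `ratios`, `pass`, sorted by absolute ppm
#'   error (ties by formula string). Errors out above
#'   `constraints$max_candidates` raw window hits.
#' @examples
#' enumerate_formulas(18.0105646, prediction_constraints(ppm = 5))
#' @export
enumerate_formulas <- function(neutral_mass,
                               constraints = prediction_constraints(),
                               verbose = FALSE) {
  stopifnot(neutral_mass > 0, neutral_mass <= 2000)
  tol <- neutral_mass * constraints$ppm * 1e-6
  lo <- neutral_mass - tol
  hi <- neutral_mass + tol

  els <- constraints$elements
  masses <- .ELEMENTS$mono_mass[els]
  ord <- order(masses, decreasing = TRUE)
  els <- els[ord]; masses <- masses[ord]
  caps <- vapply(els, .element_cap, integer(1),
                 mass = neutral_mass, constraints = constraints)
  n_el <- length(els)
  lightest <- masses[n_el]

  acc <- new.env(parent = emptyenv())
  acc$rows <- vector("list", 256L)
  acc$n <- 0L
  push <- function(counts) {
    acc$n <- acc$n + 1L
    if (acc$n > constraints$max_candidates) {
      stop("candidate count exceeds ", constraints$max_candidates,
           "; narrow the ppm tolerance or element bounds", call. = FALSE)
    }
    if (acc$n > length(acc$rows)) acc$rows <- c(acc$rows, vector("list", length(acc$rows)))
    acc$rows[[acc$n]] <- counts
  }

  counts <- integer(n_el)
  descend <- function(level, partial) {
    if (level == n_el) {
      # solve the lightest element's count from the residual window
      k_lo <- ceiling((lo - partial) / lightest - 1e-12)
      k_hi <- floor((hi - partial) / lightest + 1e-12)
      k_lo <- max(k_lo, 0L)
      k_hi <- min(k_hi, caps[n_el])
      if (k_hi >= k_lo) {
        for (k in k_lo:k_hi) {
          counts[n_el] <<- as.integer(k)
          push(counts)
        }
        counts[n_el] <<- 0L
      }
      return(invisible())
    }
    remaining_max <- sum(masses[(level + 1):n_el] * caps[(level + 1):n_el])
    k_max <- min(caps[level], floor((hi - partial) / masses[level] + 1e-12))
    if (k_max < 0) return(invisible())
    for (k in 0:k_max) {
      p2 <- partial + k * masses[level]
      if (p2 > hi + 1e-12) break
      if (p2 + remaining_max < lo - 1e-12) next  # cannot reach the window
      counts[level] <<- as.integer(k)
      descend(level + 1L, p2)
    }
    counts[level] <<- 0L
    invisible()
  }
  descend(1L, 0)

  if (acc$n == 0L) {
    return(data.frame(formula = character(0), mass = numeric(0),
                      ppm_error = numeric(0), rdbe = numeric(0),
                      count_range = logical(0), rdbe_valid = logical(0),
                      ratios = logical(0), pass = logical(0)))
  }
  rows <- acc$rows[seq_len(acc$n)]
  out <- do.call(rbind, lapply(rows, function(cn) {
    names(cn) <- els
    f <- as_formula(cn)
    m <- monoisotopic_mass(f)
    flags <- apply_golden_rules(f, constraints)
    data.frame(formula = format_formula(f), mass = m,
               ppm_error = 1e6 * (neutral_mass - m) / m,
               rdbe = attr(flags, "rdbe"),
               count_range = flags[["count_range"]],
               rdbe_valid = flags[["rdbe_valid"]],
               ratios = flags[["ratios"]],
               pass = all(flags), stringsAsFactors = FALSE)
  }))
  if (!verbose) out <- out[out$pass, , drop = FALSE]
  out <- out[order(abs(out$ppm_error), out$formula), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Formula candidates for an observed m/z under an assumed adduct
#'
#' Convenience wrapper: invert the adduct to a neutral mass, then enumerate.
#'
#' @param mz Observed m/z.
#' @param adduct Adduct name from the active rule table.
#' @param constraints A [prediction_constraints()] object.
#' @param rules Adduct rule table in which to look up `adduct`.
#' @inheritParams enumerate_formulas
#' @return As [enumerate_formulas()].
#' @export
predict_formula <- function(mz, adduct = "[M+H]+",
                            constraints = prediction_constraints(),
                            rules = default_adduct_rules(),
                            verbose = FALSE) {
  i <- match(adduct, rules$name)
  if (is.na(i)) stop("unknown adduct: ", adduct, call. = FALSE)
  M <- neutral_mass_from_mz(mz, rules[i, ])
  if (M <= 0) stop("adduct ", adduct, " implies a non-positive neutral mass",
                   call. = FALSE)
  enumerate_formulas(M, constraints, verbose = verbose)
}
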