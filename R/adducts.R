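# Adduct rules and isotope specifications: the symbolic transformations that
# map a neutral monoisotopic mass onto the ionic m/z values stored in the
# extended database.

#' Default adduct rule set
#'
#' Twenty ionization rules spanning both polarities, following the de-facto
#' standard adduct table of ESI mass spectrometry (protonation, alkali
#' adducts, ammonium, water loss, dimers, doubly charged species, solvent
#' adducts in positive mode; deprotonation, halide and organic-acid adducts
#' in negative mode). Each rule maps a neutral mass `M` to
#' `(x*M + added - removed - q*m_e) / z` where `q = +z` in positive and `-z`
#' in negative mode.
#'
#' @return A `data.frame` with columns `name`, `polarity` (`"+"`/`"-"`),
#'   `x` (molecular multiplier), `z` (charge magnitude), `added` and
#'   `removed` (formula strings).
#' @examples
#' default_adduct_rules()[1:3, ]
#' @export
default_adduct_rules <- function() {
  rules <- rbind(
    data.frame(name = "[M+H]+",        polarity = "+", x = 1L, z = 1L, added = "H",     removed = ""),
    data.frame(name = "[M+Na]+",       polarity = "+", x = 1L, z = 1L, added = "Na",    removed = ""),
    data.frame(name = "[M+K]+",        polarity = "+", x = 1L, z = 1L, added = "K",     removed = ""),
    data.frame(name = "[M+NH4]+",      polarity = "+", x = 1L, z = 1L, added = "NH4",   removed = ""),
    data.frame(name = "[M+H-H2O]+",    polarity = "+", x = 1L, z = 1L, added = "H",     removed = "H2O"),
    data.frame(name = "[M+2Na-H]+",    polarity = "+", x = 1L, z = 1L, added = "Na2",   removed = "H"),
    data.frame(name = "[M+2H]2+",      polarity = "+", x = 1L, z = 2L, added = "H2",    removed = ""),
    data.frame(name = "[M+H+Na]2+",    polarity = "+", x = 1L, z = 2L, added = "HNa",   removed = ""),
    data.frame(name = "[2M+H]+",       polarity = "+", x = 2L, z = 1L, added = "H",     removed = ""),
    data.frame(name = "[2M+Na]+",      polarity = "+", x = 2L, z = 1L, added = "Na",    removed = ""),
    data.frame(name = "[M+CH3OH+H]+",  polarity = "+", x = 1L, z = 1L, added = "CH5O",  removed = ""),
    data.frame(name = "[M+ACN+H]+",    polarity = "+", x = 1L, z = 1L, added = "C2H4N", removed = ""),
    data.frame(name = "[M-H]-",        polarity = "-", x = 1L, z = 1L, added = "",      removed = "H"),
    data.frame(name = "[M+Cl]-",       polarity = "-", x = 1L, z = 1L, added = "Cl",    removed = ""),
    data.frame(name = "[M+FA-H]-",     polarity = "-", x = 1L, z = 1L, added = "CHO2",  removed = ""),
    data.frame(name = "[M+Ac-H]-",     polarity = "-", x = 1L, z = 1L, added = "C2H3O2", removed = ""),
    data.frame(name = "[M-2H]2-",      polarity = "-", x = 1L, z = 2L, added = "",      removed = "H2"),
    data.frame(name = "[M+Na-2H]-",    polarity = "-", x = 1L, z = 1L, added = "Na",    removed = "H2"),
    data.frame(name = "[M+Br]-",       polarity = "-", x = 1L, z = 1L, added = "Br",    removed = ""),
    data.frame(name = "[2M-H]-",       polarity = "-", x = 2L, z = 1L, added = "",      removed = "H")
  )
  rules
}

#' Default isotopologue specifications
#'
#' Single-label heavy-isotope substitutions tracked alongside each adduct's
#' main peak: 13C (up to three substitutions), 2H, 15N, 18O, 34S and 37Cl
#' (one each). Mass shifts are the exact heavy-minus-light isotope mass
#' differences from the pinned element table; abundances are natural
#' fractions used in the per-element binomial intensity model.
#'
#' @return A `data.frame` with columns `label`, `element`, `shift` (u per
#'   substitution), `abundance` and `n_max`.
#' @export
default_isotope_specs <- function() {
  iso <- function(el, heavy_row, n_max) {
    tab <- .ELEMENTS$isotopes[[el]]
    tab <- tab[order(tab$mass), ]
    light <- tab$mass[which.max(tab$abundance)]
    data.frame(element = el,
               shift = tab$mass[heavy_row] - light,
               abundance = tab$abundance[heavy_row],
               n_max = n_max)
  }
  specs <- rbind(
    cbind(label = "13C",  iso("C", 2L, 3L)),
    cbind(label = "2H",   iso("H", 2L, 1L)),
    cbind(label = "15N",  iso("N", 2L, 1L)),
    cbind(label = "18O",  iso("O", 3L, 1L)),
    cbind(label = "34S",  iso("S", 3L, 1L)),
    cbind(label = "37Cl", iso("Cl", 2L, 1L))
  )
  specs
}

.check_rules <- function(rules) {
  need <- c("name", "polarity", "x", "z", "added", "removed")
  miss <- setdiff(need, names(rules))
  if (length(miss)) stop("adduct rule table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(rules$name)) stop("duplicate adduct rule names", call. = FALSE)
  stopifnot(all(rules$x >= 1L), all(rules$z >= 1L),
            all(rules$polarity %in% c("+", "-")))
  invisible(rules)
}

#' Read adduct rules or isotope specs from a delimited file
#'
#' Adduct files need columns `name, polarity, x, z, added, removed`; isotope
#' files need `label, element, n_max` (mass shift and abundance are filled
#' from the pinned element table). Tab or comma separated, header row.
#'
#' @param path File path.
#' @return A rule/spec `data.frame` in the same layout as the defaults.
#' @export
read_adduct_rules <- function(path) {
  rules <- utils::read.table(path, header = TRUE, sep = .sniff_sep(path),
                             stringsAsFactors = FALSE, na.strings = c("NA"))
  .check_rules(rules)
  rules$added <- ifelse(is.na(rules$added), "", rules$added)
  rules$removed <- ifelse(is.na(rules$removed), "", rules$removed)
  rules
}

#' @rdname read_adduct_rules
#' @export
read_isotope_specs <- function(path) {
  specs <- utils::read.table(path, header = TRUE, sep = .sniff_sep(path),
                             stringsAsFactors = FALSE)
  need <- c("label", "element", "n_max")
  miss <- setdiff(need, names(specs))
  if (length(miss)) stop("isotope spec table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  defaults <- default_isotope_specs()
  idx <- match(specs$label, defaults$label)
  if (anyNA(idx)) stop("unknown isotope label(s): ",
                       paste(specs$label[is.na(idx)], collapse = ", "),
                       call. = FALSE)
  out <- defaults[idx, ]
  out$n_max <- as.integer(specs$n_max)
  rownames(out) <- NULL
  out
}

#' Ionic m/z of an adduct of a neutral mass
#'
#' Computes `(x*M + mass(added) - mass(removed) - q*m_e) / z`, where `q` is
#' `+z` for positive and `-z` for negative polarity: attached electrons are
#' counted, so the result is charge-corrected to true m/z.
#'
#' @param M Neutral monoisotopic mass (u), `M >= 0`.
#' @param rule A single adduct rule (one row of [default_adduct_rules()] or a
#'   list with the same fields).
#' @return m/z in u per unit charge. Non-positive results (possible for
#'   removal rules on very small `M`) return `NA` with a warning.
#' @examples
#' adduct_mz(263.1117352, default_adduct_rules()[1, ])  # [M+H]+ -> 264.1190
#' @export
adduct_mz <- function(M, rule) {
  stopifnot(is.numeric(M), all(M >= 0))
  delta <- monoisotopic_mass(rule$added) - monoisotopic_mass(rule$removed)
  q <- if (rule$polarity == "+") rule$z else -rule$z
  mz <- (rule$x * M + delta - q * ELECTRON_MASS) / rule$z
  bad <- mz <= 0
  if (any(bad)) {
    warning("adduct ", rule$name, " yields non-positive m/z for ",
            sum(bad), " mass(es); discarded", call. = FALSE)
    mz[bad] <- NA_real_
  }
  mz
}

# binomial relative abundance of the k-th isotopologue vs the main peak:
# C(n, k) * (p / (1 - p))^k with n heavy-substitutable atoms
.iso_rel_abundance <- function(n, k, p) {
  choose(n, k) * (p / (1 - p))^k
}

#' Isotopologue variants of one adduct
#'
#' For each isotope specification whose element occurs in the neutral
#' formula, generates records at `base_mz + k*shift/z` for
#' `k = 1..min(n_max, count)`, with predicted relative abundance from a
#' per-element binomial model: the probability mass at `k` substitutions over
#' `x*count` atoms, divided by the mass at zero. Cross-element doubly-heavy
#' species are not generated. Variants below the abundance floor are dropped.
#'
#' @param f Neutral formula (string or parsed).
#' @param base_mz Main-peak m/z from [adduct_mz()].
#' @param rule The adduct rule that produced `base_mz`.
#' @param specs Isotope spec table; default [default_isotope_specs()].
#' @param abundance_floor Minimum predicted relative abundance kept
#'   (default `1e-4`).
#' @return `data.frame` with columns `isotope`, `mz`, `abundance`; zero rows
#'   if nothing qualifies.
#' @export
isotope_variants <- function(f, base_mz, rule,
                             specs = default_isotope_specs(),
                             abundance_floor = 1e-4) {
  f <- as_formula(f)
  out <- list()
  for (i in seq_len(nrow(specs))) {
    sp <- specs[i, ]
    n_atoms <- if (sp$element %in% names(f)) rule$x * f[[sp$element]] else 0L
    if (n_atoms < 1L) next
    for (k in seq_len(min(sp$n_max, n_atoms))) {
      ab <- .iso_rel_abundance(n_atoms, k, sp$abundance)
      if (ab < abundance_floor) break
      out[[length(out) + 1L]] <- data.frame(
        isotope = paste0(sp$label, k),
        mz = base_mz + k * sp$shift / rule$z,
        abundance = ab
      )
    }
  }
  if (!length(out)) {
    return(data.frame(isotope = character(0), mz = numeric(0),
                      abundance = numeric(0)))
  }
  do.call(rbind, out)
}

#' Enumerate all adduct/isotopologue variants of one compound
#'
#' One main-peak (`"M0"`) record per adduct rule plus the isotopologue
#' records of [isotope_variants()], in deterministic order (rule order, then
#' isotope label order, then substitution count).
#'
#' @param formula Neutral formula string.
#' @param rules Adduct rule table (default the shipped twenty rules).
#' @param specs Isotope spec table, or `NULL` to skip isotopologues.
#' @param abundance_floor Passed to [isotope_variants()].
#' @return `data.frame` with columns `adduct`, `isotope`, `polarity`,
#'   `charge` (signed), `mz`, `abundance`.
#' @examples
#' v <- enumerate_variants("C9H17N3O6", specs = NULL)
#' v[v$adduct == "[M+H]+", ]
#' @export
enumerate_variants <- function(formula,
                               rules = default_adduct_rules(),
                               specs = default_isotope_specs(),
                               abundance_floor = 1e-4) {
  f <- as_formula(formula)
  M <- monoisotopic_mass(f)
  out <- vector("list", nrow(rules))
  for (i in seq_len(nrow(rules))) {
    rule <- rules[i, ]
    mz0 <- suppressWarnings(adduct_mz(M, rule))
    if (is.na(mz0)) next
    q <- if (rule$polarity == "+") rule$z else -rule$z
    rec <- data.frame(adduct = rule$name, isotope = "M0",
                      polarity = rule$polarity, charge = q,
                      mz = mz0, abundance = 1.0)
    if (!is.null(specs) && nrow(specs)) {
      iso <- isotope_variants(f, mz0, rule, specs, abundance_floor)
      if (nrow(iso)) {
        rec <- rbind(rec, data.frame(adduct = rule$name, isotope = iso$isotope,
                                     polarity = rule$polarity, charge = q,
                                     mz = iso$mz, abundance = iso$abundance))
      }
    }
    out[[i]] <- rec
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(adduct = character(0), isotope = character(0),
                      polarity = character(0), charge = integer(0),
                      mz = numeric(0), abundance = numeric(0))
  }
  rownames(out) <- NULL
  out
}
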