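# Shared fixtures, built in code at test time.

# small compound table anchored by creatine riboside (C9H17N3O6) plus a pair
# of structural isomers and a synonym duplicate, covering every dedup path
toy_compounds <- function() {
  data.frame(
    id = c("T1", "T2", "T3", "T4", "T5", "T6"),
    name = c("creatine riboside", "glucose", "fructose", "dextrose",
             "alanine", "taurine"),
    synonyms = c("", "", "", "", "", ""),
    formula = c("C9H17N3O6", "C6H12O6", "C6H12O6", "C6H12O6",
                "C3H7NO2", "C2H7NO3S"),
    smiles = c("SMI-CR", "SMI-GLC", "SMI-FRU", "SMI-GLC", "SMI-ALA", ""),
    description = c("top lung-cancer feature", "a sugar", "a sugar",
                    "commercial name for glucose", "an amino acid", ""),
    source = "toy", stringsAsFactors = FALSE)
}

write_toy_csv <- function(df = toy_compounds(), path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# extended db over the toy table, built fresh in a tempdir
toy_db <- function(specs = default_isotope_specs()) {
  build_extended_db(normalize_compounds(toy_compounds()),
                    tempfile("toydb"), specs = specs)
}

# random valid formula strings for round-trip properties
random_formula_string <- function() {
  els <- sample(element_table()$elements, sample(1:5, 1))
  counts <- sample(1:30, length(els), replace = TRUE)
  names(counts) <- els
  format_formula(counts)
}

# independent linear-scan search oracle: filters and orders the full variant
# table directly, no index involved
linear_scan_search <- function(db, mz, ppm = 2, polarity = "both",
                               main_peak_only = FALSE) {
  v <- db$variants
  if (polarity != "both") v <- v[v$polarity == polarity, , drop = FALSE]
  if (main_peak_only) v <- v[v$isotope == "M0", , drop = FALSE]
  lo <- mz * (1 - ppm * 1e-6); hi <- mz * (1 + ppm * 1e-6)
  v <- v[v$mz >= lo & v$mz <= hi, , drop = FALSE]
  if (!nrow(v)) return(v[, c("source", "compound_id", "adduct", "isotope", "mz")])
  ppm_err <- 1e6 * (mz - v$mz) / v$mz
  ord <- order(abs(ppm_err), v$source, v$compound_id, v$adduct)
  out <- v[ord, c("source", "compound_id", "adduct", "isotope", "mz")]
  rownames(out) <- NULL
  out
}

# exhaustive oracle for the overlap test: distribution of the overlap by
# enumerating every possible draw of list B over a small universe
enumerate_overlap_p <- function(N, nA, nB, k) {
  draws <- utils::combn(N, nB)
  A <- seq_len(nA)
  mean(apply(draws, 2, function(d) sum(d %in% A)) >= k)
}

# independent nested-loop formula enumerator over CHNOPS bounds (no pruning
# beyond the grid itself): the brute-force oracle
brute_force_formulas <- function(neutral_mass, constraints) {
  mono <- element_table()$mono_mass
  tol <- neutral_mass * constraints$ppm * 1e-6
  cap <- function(el) {
    k <- floor(neutral_mass / mono[[el]]) + 1L
    if (el %in% names(constraints$max_counts))
      k <- min(k, constraints$max_counts[[el]])
    k
  }
  grid <- expand.grid(C = 0:cap("C"), N = 0:cap("N"), O = 0:cap("O"),
                      P = 0:cap("P"), S = 0:cap("S"))
  base <- grid$C * mono[["C"]] + grid$N * mono[["N"]] + grid$O * mono[["O"]] +
    grid$P * mono[["P"]] + grid$S * mono[["S"]]
  keep <- base <= neutral_mass + tol
  grid <- grid[keep, , drop = FALSE]; base <- base[keep]
  out <- character(0)
  h_max <- cap("H")
  for (i in seq_len(nrow(grid))) {
    for (h in 0:h_max) {
      m <- base[i] + h * mono[["H"]]
      if (m > neutral_mass + tol) break
      if (m < neutral_mass - tol) next
      cn <- c(C = grid$C[i], H = h, N = grid$N[i], O = grid$O[i],
              P = grid$P[i], S = grid$S[i])
      f <- cn[cn > 0]
      if (!length(f)) next
      if (all(apply_golden_rules(f, constraints))) {
        out <- c(out, format_formula(f))
      }
    }
  }
  sort(out)
}
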