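# mzannotate

Putative metabolite annotation for untargeted (direct-infusion) mass
spectrometry in R.

High-resolution DI-MS measures tens of thousands of m/z values per sample at
part-per-million accuracy, but almost none of them arrive with an identity.
`mzannotate` implements the annotation core of that workflow as a library and
a small command-line tool:

- **Variant expansion.** Every compound in a user-supplied table is expanded
  into the theoretical m/z of its common ionized forms. For an adduct rule
  with multiplier *x*, charge *z* and attached/removed atoms, the ionic m/z
  of a neutral monoisotopic mass *M* is

  ```
  m/z = (x·M + m(added) − m(removed) − q·m_e) / z,   q = ±z
  ```

  with the electron mass *m_e* included so the values are charge-corrected.
  Twenty adduct rules across both polarities and single-label isotopologues
  (¹³C up to ×3, ²H, ¹⁵N, ¹⁸O, ³⁴S, ³⁷Cl) ship as defaults; both sets are
  replaceable from delimited files. Isotopologue relative abundances follow a
  per-element binomial model.
- **Indexed local database.** Expanded records are written to a plain-text
  store and searched through a (polarity, m/z) sorted index, so one build
  serves any tolerance chosen at query time. Records sharing a SMILES are
  collapsed into one row (names become synonyms); records sharing only a
  molecular formula stay separate.
- **ppm-tolerance search.** A query m/z matches every record inside the
  closed window `mz·(1 ± ppm·1e-6)`; hits are sorted by absolute signed ppm
  error (`1e6·(observed − theoretical)/theoretical`), optionally filtered to
  main-peak isotopes, and re-rankable by isotope/adduct status for follow-up
  prioritization.
- **Formula deduction.** For m/z values with no database hit, candidate
  molecular formulas are enumerated by branch-and-bound decomposition over
  CHNOPS (configurable) and filtered by Seven-Golden-Rules style heuristics:
  mass-scaled element-count ranges, ring-plus-double-bond validity
  (`RDBE = C + Si − (H+F+Cl+Br+I)/2 + (N+P)/2 + 1` must be a non-negative
  integer for neutral even-electron species), and element-ratio bounds
  (H/C ∈ [0.2, 3.1], N/C ≤ 1.3, O/C ≤ 1.2, P/C ≤ 0.3, S/C ≤ 0.8).
- **Statistics.** Normalization (total-sum/median, log10, auto/Pareto
  scaling), imputation (half-minimum, k-NN, iterative random forest), Welch
  or paired t-tests with Benjamini–Hochberg FDR control, raw-scale log2 fold
  changes, volcano inputs, and exact hypergeometric tests for the overlap of
  two hit lists.
- **Synthetic data.** Seeded generators for compound tables, stratified
  query pools over 60–600 m/z, and two-group log-normal peak experiments
  with planted effects, so the full pipeline runs and tests offline.

## Worked example

The classic anchor for this workflow is the urinary lung-cancer marker
creatine riboside, first seen as an unidentified feature at a nominal 264 m/z
and later identified as the [M+H]+ adduct of C9H17N3O6.

```r
library(mzannotate)

compounds <- data.frame(
  id = c("HMDB62", "SYN1"), name = c("creatine riboside", "decoy"),
  synonyms = "", formula = c("C9H17N3O6", "C12H22O11"),
  smiles = c("SMI-CR", "SMI-DEC"), description = "", source = "demo")

db <- build_extended_db(compounds, tempfile("demo"))
db
#> <extended_db> 2 compounds, 260 variant m/z rows
#>   rules: 20 adducts, 6 isotope specs (hash 7c16890e)
#>   element table: IUPAC-2013/CODATA-2014

search_mz(db, 264.1190, ppm = 2, polarity = "+")[
  , c("name", "adduct", "isotope", "theoretical_mz", "ppm_error", "rank")]
#>                name adduct isotope theoretical_mz   ppm_error rank
#> 1 creatine riboside [M+H]+      M0        264.119 -0.04440446    1
```

The hit's theoretical m/z is 264.1190117 (monoisotopic mass 263.1117353 plus
a proton's 1.0072765), 0.044 ppm below the query — well inside the 2 ppm
tolerance typical of DI-MS. The same feature is recoverable with no database
at all:

```r
predict_formula(264.1190, adduct = "[M+H]+",
                constraints = prediction_constraints(ppm = 3))
#>     formula     mass   ppm_error rdbe
#> 1 C9H17N3O6 263.1117 -0.04457445    3
#> 2 C11H24NP3 263.1122 -1.66173061    2
```

The true formula ranks first by ppm error; both candidates pass the element
ratio and RDBE rules.

The same operations are available from a shell:

```sh
Rscript inst/cli/mzannotate.R build-db --compounds compounds.csv --out store
Rscript inst/cli/mzannotate.R search --db store --mz 264.1190 --ppm 2 --polarity +
Rscript inst/cli/mzannotate.R predict-formula --mz 264.1190 --adduct "[M+H]+"
```

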