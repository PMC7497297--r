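---
title: "Annotation methods: mass arithmetic, database search, formula deduction and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mzannotate)
```

## The problem

Direct-infusion mass spectrometry measures the mass-to-charge ratio of
everything that ionizes in a sample, at roughly part-per-million accuracy,
without chromatographic separation. The result is a peak table whose feature
names are bare m/z values. Putting putative identities on those values —
metabolite annotation — means matching each measured m/z against the
theoretical m/z of known compounds in all the ionized forms they commonly
take, or, failing that, deducing which molecular formulas could produce the
mass at all. Annotation at this level is putative (MSI level 2): any
identity still needs confirmation with an authentic standard.

`mzannotate` implements that annotation core plus the minimal statistics
needed to decide *which* features are worth annotating.

## Mass arithmetic

All masses derive from a pinned element table (monoisotopic masses and
stable-isotope abundances, identifier `IUPAC-2013/CODATA-2014`), recorded in
every database build so stored m/z values stay traceable. The table covers
C, H, N, O, P, S, Na, K, Cl, Br, F, I and Si.

Formulas are plain concatenations of symbols and counts ("expanded"
formulas, the dialect of HMDB-style exports); parenthesized subgroups,
hydrates and charge suffixes are deliberately unsupported, and parsing is
order-insensitive with Hill-order formatting as the canonical output.

An adduct rule $(x, z, \mathrm{added}, \mathrm{removed}, \pm)$ maps a
neutral monoisotopic mass $M$ to

$$ m/z \;=\; \frac{x M + m(\mathrm{added}) - m(\mathrm{removed}) - q\,m_e}{z},
\qquad q = \pm z . $$

The electron-mass term matters: leaving it out biases every singly charged
ion by about 2 ppm at 264 m/z, the same order as the matching tolerance.
The inverse mapping (`neutral_mass_from_mz()`) is exact, which the tests
assert to $10^{-9}$ u for every shipped rule.

The default rule set has 20 entries — protonation, alkali and ammonium
adducts, water loss, sodium exchange, doubly charged species, dimers and
the methanol/acetonitrile solvent adducts in positive mode; deprotonation,
chloride, bromide, formate and acetate adducts, double deprotonation and
the dimer in negative mode. It follows the de-facto standard ESI adduct
tables; both the adduct and isotope sets are loadable from delimited files
per build, and the build metadata stores a content hash of whatever set was
used.

## Isotopologues

For each adduct's main peak (`M0`), single-label heavy-isotope records are
generated: ¹³C up to three substitutions, and one each of ²H, ¹⁵N, ¹⁸O,
³⁴S, ³⁷Cl. The m/z offset per substitution is the exact heavy-minus-light
isotope mass difference divided by the charge. Relative abundance uses a
per-element binomial model: with $n = x \cdot \mathrm{count}$ substitutable
atoms of heavy-isotope fraction $p$, the $k$-substitution record's
abundance relative to the main peak is
$\binom{n}{k} \left(p/(1-p)\right)^k$ — e.g. $\approx 0.097$ for the ¹³C₁
peak of a 9-carbon compound. Records below an abundance floor (default
$10^{-4}$) are dropped. Cross-element doubly heavy species (¹³C₁¹⁵N₁) are
intentionally not generated; they are far below the floor for
metabolite-sized molecules, and single labels match the variant naming
users of this kind of tool expect. Full isotope-pattern convolution is out
of scope.

## The extended database and search

A build expands every parseable compound, writes `compounds.tsv`,
`variants.tsv` and `meta.json` under one store directory, and keeps an
in-memory index of variant rows sorted by (polarity, m/z); range queries
are answered by binary search (`findInterval`), which the tests prove
equivalent — hits *and* order — to an exhaustive linear scan. The store is
plain text rather than a SQLite file: a relational driver adds nothing to a
two-table schema whose only query is a range scan, and text keeps builds
diffable and portable. Rebuilding a store replaces it; compounds whose
formula fails to parse are skipped and listed in the build report, and a
table where the majority fails aborts, since that signals a malformed
input rather than a few bad rows.

Deduplication happens before the build, at the record level: rows with an
identical SMILES string are one compound (first-seen name wins, other
names become synonyms, case-insensitively deduplicated; descriptions are
concatenated), rows with the same formula but different SMILES are
different compounds, and rows without SMILES are never merged. SMILES are
compared as exact strings — canonicalization would need a cheminformatics
backend and makes merging non-deterministic across backends.

Search uses a *closed* ppm window, `mz · (1 ± ppm · 10^{-6})`; boundary
records are included (the conventional choice, and the testable one).
The default tolerance is 2 ppm, matching the accuracy regime of DI-MS
instruments; it is a query parameter, never baked into the build. Hits are
ranked by absolute signed ppm error with deterministic lexicographic
tie-breaks (source, compound id, adduct), so output order is total and
reproducible. Ranking is joint across selected source databases, with the
source reported per hit. A main-peak filter drops isotopologue rows before
ranking; `prioritize_hits()` re-ranks for follow-up validation — main peaks
before isotopologues, plain (de)protonation before salts and dimers, ppm
error last.

## Formula deduction

When no database hit exists, `enumerate_formulas()` finds every formula
over the constraint elements (default CHNOPS) whose monoisotopic mass lies
inside the ppm window. The search is depth-first over elements in
decreasing mass order with residual-mass pruning: a branch dies as soon as
its partial mass overshoots the window or the remaining elements cannot
reach it, and the lightest element's count is solved directly from the
residual at the leaf. This is complete within bounds (the test suite
checks equality with a nested-loop brute force over the same grid) and
fast enough in pure R — milliseconds per mass below 400 u.

Candidates are then filtered by the rule families that depend only on the
formula itself:

- **Element-count ranges**, scaled with mass (`count ≤ mass/element_mass
  + 1`), with hard caps P ≤ 6 and S ≤ 8;
- **RDBE validity**: $\mathrm{RDBE} \ge 0$ and integer-valued, under the
  neutral even-electron assumption (radicals toggleable);
- **Element ratios**: H/C ∈ [0.2, 3.1], N/C ≤ 1.3, O/C ≤ 1.2, P/C ≤ 0.3,
  S/C ≤ 0.8, applied only to carbon-containing formulas (H₂O must not be
  rejected for lacking carbon).

Rules that require isotope-pattern intensities or MS/MS spectra are out of
scope by design: this package annotates from accurate mass alone. The
ratio defaults are the common-range heuristics of the formula-filtering
literature and are fully configurable; RDBE uses fixed common valences
(C=4, N=3, O=2, P=3, S=2), ignoring hypervalent states, which is the
convention for this filter family. A candidate cap (default 10,000) turns
runaway tolerance settings into an instructive error instead of a hang.

## Statistics

The statistics layer is intentionally minimal — enough to get from a peak
table to a ranked list of features worth annotating:

- `normalize_peaks()`: total-sum or median sample normalization, then
  optional `log10(x+1)`, then auto or Pareto feature scaling.
- `impute_missing()`: half-minimum (default; fast, appropriate for
  left-censored MS intensities), k-NN over samples, or iterative
  random-forest regression (3 sweeps, seeded — the slowest and the one to
  choose under intensity-dependent missingness).
- `ttest_all()`: Welch's t by default — pooled-variance tests are less
  robust to unequal group variances and the cost of Welch is nil —
  or a paired t; Benjamini–Hochberg FDR across all tested features
  (Bonferroni selectable). Constant features are flagged, not tested.
- `fold_change()`: raw-scale `log2(mean₂/mean₁)` even when testing on the
  log scale, the standard volcano convention; zero-mean denominators are
  flagged sentinels excluded from volcano input.
- `hypergeom_overlap()`: exact upper-tail hypergeometric probability of
  the observed overlap between two hit lists, for Venn-style comparison
  of analyses or subsets; the universe defaults to whatever feature set
  the caller supplies (typically all tested features) and may be given
  as a count or as an explicit membership vector.

## Synthetic data: what it emulates and what it does not

The generators exist so that every operation is testable offline, and they
define the package's study conditions:

- `gen_compound_db()` rejection-samples CHNOPS formulas until they pass
  the ratio/RDBE rules and their [M+H]+ falls in 60–600 m/z; duplicate
  records (shared SMILES, and shared formula under distinct SMILES) can be
  injected to stress both deduplication paths. SMILES are synthetic unique
  tokens, labelled as such — they exercise exact-string merging, not
  chemistry.
- `gen_query_pool()` draws one value per equal-width stratum over
  60–600 m/z (100 by default), the query-pool design used for search
  benchmarking.
- `gen_peak_experiment()` simulates two groups of log-normal feature
  intensities: per-feature log-scale baselines uniform on
  $[\log 10^3, \log 10^5]$, log-scale standard deviations uniform on
  [0.25, 0.6], planted features shifted by `effect` feature-sds in the
  case group (default 2, a moderate, detectable effect at n = 20/group),
  and completely-at-random missingness. Defaults (20 samples/group, 200
  features, 10 planted) give a compact experiment with non-trivial power.

Real DI-MS data differ in ways the model deliberately omits: correlated
features (adducts and isotopologues of one metabolite co-vary), batch and
drift effects, intensity-dependent (not MCAR) missingness, and heavy-tailed
noise. Passing tests therefore demonstrate the *correctness of the
computations* — calibration of the t-test under the null, recovery of
planted effects, round-trip annotation of stored variants — not
performance claims about any particular instrument or cohort.

- `scaling_harness()` builds nested databases over a size sweep and
  reports per-size match counts and query latencies. Timings are reported,
  never asserted: wall-clock is a property of the host, not the code.

## Numerical and design choices

- Stored m/z are 8-byte doubles; ppm windows are computed at query time,
  never pre-rounded into the store.
- The boundary of the ppm window is inclusive on both sides; window
  comparisons in the enumeration use a $10^{-12}$ guard so that
  floating-point dust cannot flip a boundary decision.
- Tie-breaks everywhere are lexicographic and documented, making every
  ranked output a total order (bit-reproducible across runs and worker
  counts; `batch_search()` with forked workers is asserted identical to
  the serial loop).
- Seeds: every stochastic operation takes an explicit seed and restores
  the caller's RNG state, so library use never perturbs a session's
  random stream. The CLI propagates `--seed` to all stochastic steps.
- Degenerate inputs fail loudly with the offending token in the message:
  unknown element symbols, missing mandatory columns, duplicate
  identifiers, all-zero samples under total-sum normalization, adducts
  inconsistent with an observed m/z.
- Test problem sizes (500-compound round-trip, 10⁴-row scan-equivalence,
  20 oracle masses, 200 null replicates) were chosen as the smallest sizes
  at which the properties are meaningfully exercised.

## Known limitations

- No retention-time or MS/MS matching; ranking beyond
  ppm/isotope/adduct status is out of scope, as is any probabilistic
  annotation score.
- Charge states beyond |z| = 2 are absent from the default rules (add
  your own rule file for higher charge).
- The isotope model is single-label per element; fine structure and
  cross-element convolution are not modelled.
- Public-database parsers are out of scope: one generic compound-table
  importer replaces them, and users point it at whatever export they have.
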