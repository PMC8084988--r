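---
title: "Methods: Kendrick oligomer analysis, compound classes, metaproteome quantitation and enrichment calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Kendrick oligomer analysis, compound classes, metaproteome quantitation and enrichment calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tanninflow)
```

`tanninflow` analyzes anoxic soil-reactor experiments in which a
structurally defined condensed tannin (CT) — a proanthocyanidin polymer of
flavan-3-ol (epicatechin/catechin) units joined by C4→C8 interflavan bonds,
average degree of polymerization 16 and average molecular weight ~4600 Da —
is added to live, autoclaved and unamended soil slurries, and its fate is
followed with FTICR-MS, LC–MS metabolomics and genome-resolved
metaproteomics. This vignette documents the models and procedures the
package implements, the parameters that matter, the design choices made
where the design was genuinely open, and what the synthetic-data tests do
and do not demonstrate.

## The CT oligomer model

An n-mer is modeled as n C15H14O6 flavan-3-ol units minus two hydrogens per
interflavan bond:

$$\mathrm{C}_{15n}\,\mathrm{H}_{12n+2}\,\mathrm{O}_{6n}.$$

The −2 H per C4→C8 bond is standard proanthocyanidin chemistry; it
reproduces the known procyanidin B-type dimer composition (C30H26O12) and
the printed DP-16 average molecular weight (4614 Da, i.e. 4600 to the
nearest 100). Catechin and epicatechin are constitutional isomers, so the
terminal catechin unit needs no special handling in mass space. Ions are
negative-mode deprotonated species only, [M−H]⁻ and [M−2H]²⁻, matching
direct-injection negative-mode FTICR acquisition; adducts and in-source
fragments are out of scope. Atomic masses are hard-coded CODATA/IUPAC
values; `ct_constants()` provides an explicit override hook for testing.

## Kendrick mass defect analysis

Peaks are rescaled so the repeat unit has integer Kendrick mass:

$$\mathrm{KM} = \frac{m}{z}\times\frac{290}{290.079038},\qquad
\mathrm{NM} = \lceil \mathrm{KM}\rceil,\qquad
\mathrm{KMD} = \mathrm{NM}-\mathrm{KM}.$$

"Round up" is implemented as the ceiling. This choice guarantees
KMD ∈ [0, 1) for every positive m/z and places the ¹²C monoisotopic polymer
line at KMD ≈ 0, which is the convention the oligomer-region annotations
assume. For multiply charged polymer ions the isotopologue lines separate
by 1/z KMD: doubly-charged ions with an odd ¹³C count sit ~0.5 KMD above
the main line, while even counts return to it. `isotopic_split_check()`
verifies this separation per (n, z) group; it uses *circular* means on the
unit KMD interval because high ¹³C counts can wrap a line across the 0/1
boundary, where an arithmetic mean would be meaningless.

Peak classification (`classify_peaks()`) is a nearest-match search of each
observed m/z against the theoretical ladder of (n, z, ¹³C) species, with a
part-per-million tolerance. The oligomer "regions" drawn on published
Kendrick plots are realized as this ladder matching, not as hand-drawn
rectangles; `oligomer_regions()` derives plot-annotation rectangles from
ladder m/z extents ± tolerance and the two parity bands (0 ± 0.05 and
0.5 ± 0.05 KMD). Defaults that matter:

- `tol_ppm = 3` (FTICR-class mass accuracy). The original instrument
  tolerance is not documented anywhere we could verify, so the value is
  exposed as a parameter rather than buried.
- ties between equally close ladder entries break deterministically to
  lower n, then lower z, then lower ¹³C count.
- no intensity threshold is applied before classification; intensities are
  carried through untouched.

Hexagon-binned KMD plots are exported as rectangular-bin long-format
counts (`hexbin_kmd()`); true hexagon rendering is a plotting concern left
to the user.

## CHO formula assignment and van Krevelen classes

`assign_formula()` does an exhaustive CcHhOo enumeration within element
bounds and a ppm tolerance, filtered by: non-negative integer double-bond
equivalents (DBE = C − H/2 + 1, which forces H even), 0 ≤ O:C ≤ 1.2 and
0.3 ≤ H:C ≤ 2.5. Candidates are ranked by |ppm error| with lexicographic
(C, H, O) tie-breaks. This is a deliberately simple stand-in for full
isotope-aided formula assignment software: it is restricted to C/H/O
because the compound-class rule uses only those counts, and it makes no
attempt at isotopic-fine-structure scoring. Neutral mass is reconstructed
from negative-mode m/z assuming [M−H]⁻.

Compound classes are half-open H:C × O:C windows applied first-match-wins
(`default_class_table()`): lipid-, protein-, amino-sugar-, carbohydrate-,
unsaturated-hydrocarbon-, lignin-, tannin- and condensed-aromatic-like.
The table is the one in common use for dissolved-organic-matter van
Krevelen classification and is fully user-overridable via a JSON file; the
"-like" suffixes signal that these are heuristic regions, not identities.
Relative abundances are count-based percentages of classified peaks per
sample ("percent of identified peaks"); intensity weighting is available
behind `weight = "intensity"`. A sample with no classifiable peaks is
reported as missing rather than as zeros.

## Metaproteome quantitation

The protein database is a FASTA whose headers carry the gene's origin
(`mag=MAG_007` or `mag=unbinned:scaffold_123`). Peptide→protein mapping is
exact substring containment (I/L distinct by default); the partially
tryptic semantics of the upstream spectral search live upstream and are
not re-implemented. Identified proteins are classified three ways:

- **binned_unique** — has ≥1 observed peptide mapping only to it, and the
  gene lies in a MAG;
- **unbinned_unique** — same, but the gene lies on an unbinned scaffold;
- **non_unique** — identified only through peptides shared with other
  proteins.

Two readings of the "at least two unique peptides per protein" filter are
possible. The default counts *distinct observed peptides* per protein,
because non-unique proteins are a reported class and would be annihilated
by a literal protein-unique reading; the stricter reading is available via
`identification_filter(count = "protein_unique")`.

Spectral counts of shared peptides are attributed to every mapped protein
(no parsimony apportionment). The rationale: non-unique hits are reported
as their own class rather than razored away, and the MAG-contribution
profiles use only binned-unique proteins, which shared peptides cannot
affect. NSAF is computed per sample as (SpC/L) normalized to sum to one
over all quantified proteins. MAG contributions are percentages of the
binned-unique spectral-count pool per sample (peptide-count weighting
behind a flag), and samples are clustered on those profiles with
Bray–Curtis dissimilarity and average linkage — neither is documented for
the original analysis, so both are parameters with those defaults, and
sample order is fixed before clustering so ties resolve deterministically.

MAG presence uses coverage = reads_per_base × 151 bp (the sequencing read
length): a MAG is present in a sample iff breadth ≥ 0.75 AND
coverage ≥ 3×, both inclusive, and present in a treatment iff present at
any of its timepoints. The rule is monotone in both inputs by
construction.

## Enrichment calling on metabolite areas

Per timepoint, each compound's biotic-minus-autoclaved difference in mean
log2 peak area is tested with a moderated two-sample t statistic. Full
empirical-Bayes machinery is intentionally not reproduced; instead each
compound's pooled variance is shrunk toward the across-compound mean with
`prior_df` pseudo-degrees of freedom (default 4):

$$s^2_{\mathrm{mod}} = \frac{d_0\,\bar s^2 + d\,s^2}{d_0 + d},\qquad
t = \frac{\Delta}{s_{\mathrm{mod}}\sqrt{1/n_1 + 1/n_2}},\qquad
t \sim t_{d_0+d}.$$

`prior_df = 0` reduces exactly to the textbook pooled-variance t test
(verified against `t.test` in the suite). Significance is the joint rule
p < 0.05 AND log2FC > 1.5, with "log2FC > 1.5" read on the log2 scale
(≈2.8-fold), matching the usual linear-model convention. No
multiple-testing correction is applied by default, matching the stated
threshold rule; Benjamini–Hochberg per timepoint is available behind
`adjust = "BH"`. Degenerate zero-variance compounds with no shrinkage
available get p = 0 when means differ and p = 1 when they do not. No
replicate blocking is modeled — the design is treated as independent
triplicates at each timepoint.

## The synthetic study and what it shows

The generators in `scenario_config()` emulate the reactor study's inputs
at desk scale, and their defaults *are* the study conditions the analysis
assumes:

- three treatments (biotic +CT, autoclaved +CT, unamended) × eight
  timepoints (days 0–20) × three replicates;
- CT ion ladders per treatment schedule: penta/hexamers throughout, small
  oligomers (n ≤ 4) from day 10 in biotic soil but only at day 20 in
  autoclaved soil, nothing in unamended soil; ¹³C counts drawn binomially
  from the oligomer's carbon count at 0.0107 abundance (capped at 4,
  higher orders being negligible at these CHO sizes); 1 ppm Gaussian mass
  jitter; lognormal intensities (intensities are carried, never used for
  classification);
- matrix noise peaks drawn from fixed CHO formula pools of the van
  Krevelen classes, with the carbohydrate-like weight declining linearly
  in biotic soil; class composition per sample is apportioned
  deterministically so planted trends are exactly recoverable;
- a metabolite roster (CT monomers, quercetin, C6–C3/C6–C2 phenolics,
  DOPA, a disaccharide, short-chain fatty acids) with planted log2 fold
  changes — monomer-type enrichment at day 10, late-phase compounds at
  days 14–20, a disaccharide declining identically in biotic and unamended
  soil — on lognormal replicate areas;
- a toy protein database (5 MAGs × 8 random 300-residue proteins with
  K/R frequency boosted so tryptic peptides stay observable, two unbinned
  scaffold genes, and one sequence duplicated across two MAGs so no
  peptide can be unique to either copy), with per-sample spectral counts
  drawn multinomially along phase-structured MAG trajectories — a
  Kosakonia-like MAG at 80% of the binned-unique pool in phase 2
  (days 3–7), Holophaga/Sporomusales-like MAGs dominating phase 3 — and
  3000 spectra per sample;
- coverage tables tied to the planted shares, plus records placed exactly
  on, just below, and just above the presence thresholds.

Every generator emits a ground-truth table; recovery tests consume only
the generated inputs and compare against the truth afterwards. A fixed
seed gives bit-identical output.

What passing these tests shows: the equations and rules are implemented
correctly, planted signals of realistic effect size are recovered at the
stated tolerances (≥95% ion recovery at 1 ppm jitter / 3 ppm tolerance;
phase-2 dominance within 2 percentage points; type-I error of the
unmoderated test within the binomial 99% interval of 0.05 on 1,000 null
compounds), and the pipeline is deterministic. What it does not show: the
generators make no attempt at real FTICR matrix complexity (tens of
thousands of correlated peaks, isotope intensity ratios, space-charge
calibration drift), real strain-level peptide sharing beyond the planted
duplicate, chromatographic or ionization biases, or upstream search-engine
FDR behavior — conclusions about real data still require the usual
instrument-level quality control.

## Numerical choices and degenerate inputs

- KMD separations are compared modulo 1 with circular means (wrap-around
  at the 0/1 boundary).
- Classification ties break to (lower n, lower z, lower ¹³C); formula
  ranking ties break lexicographically in (C, H, O).
- Presence thresholds are inclusive (breadth = 0.75, coverage = 3.0 count
  as present).
- Empty peak lists and no-doubly-charged-assignment cases return empty
  tables, not errors; an all-zero spectral-count sample and nonpositive
  areas are rejected with the offending record named.
- `run_all()` refuses to overwrite a non-empty output directory without
  `force = TRUE`, aborts with the failing stage's name, skips the presence
  stage with a warning when no coverage table is supplied, and logs every
  effective parameter plus input MD5 checksums.

Problem sizes throughout the test suite are the default scenario above
(~9,400 peaks, 44 proteins, ~30 samples per assay), chosen so the full
suite documents the method's behavior in well under a minute while keeping
every planted effect at the size the analysis is designed to detect.

## Known limitations

- The CHO assigner is not a replacement for isotope-aided formula
  assignment software on real spectra; above ~500 Da, CHO candidate
  density grows and the top candidate should be treated as putative.
- NSAF with shared-count attribution double-counts shared spectra across
  proteins within a sample; comparisons should therefore stay within the
  uniqueness class of interest (as the MAG profiles do).
- The moderated test assumes equal variances between the two treatments
  and independence across replicates; strong mean–variance trends would
  call for a trend-aware prior, which is not implemented.
- Hydrolysable tannins, lignin monomers, adducts and in-source fragments
  are outside the ion model; peaks from such species will be unassigned or
  land in the van Krevelen classes.
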