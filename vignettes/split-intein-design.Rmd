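---
title: "Designing split-intein trans-splicing experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing split-intein trans-splicing experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splitintein)
```

## The problem

Naturally split inteins of the DnaE family (Ssp, Npu, Ava and relatives)
ligate two separately expressed protein halves into one mature protein and
excise themselves in the process. This protein trans-splicing is the
workhorse for delivering genes that exceed the packaging capacity of a
single AAV vector: the target protein is split into an N-half fused to the
intein's N-fragment and a C-half fused to the intein's C-fragment, the two
precursors are delivered separately, and the full-length protein is
restored inside the cell.

Where to split the target is the decisive design choice. The splicing
chemistry imposes a hard constraint — DnaE inteins need a cysteine
immediately downstream of the junction (the C+1 residue) to run the
nucleophilic attack that starts the reaction — and a softer, position
specific preference for the residues in the immediate neighbourhood.
Empirical screens that substituted every amino acid at each of the six
extein positions flanking the junction (N-3, N-2, N-1 on the N-side; C+1,
C+2, C+3 on the C-side) quantify that preference, and this package turns
such a table into a ranked list of candidate split sites.

## Split-site model

A split site \(k\) breaks the protein between residues \(k\) and
\(k + 1\) and is described by its 6-residue window
\(w(k) = p_{k-2} \dots p_{k+3}\) (1-based, inclusive). An *impact matrix*
\(M\) assigns one score per (flanking position, residue) pair; the site
score is the sum of its six per-position contributions:

\[
S(k) = \sum_{j=1}^{6} M\!\left(\text{pos}_j,\; w(k)_j\right).
\]

Additivity is the simplest aggregation rule consistent with per-position
substitution data, and it has convenient invariances that the test suite
checks: permuting matrix rows never changes a score, and adding a constant
\(c\) to every cell shifts every site score by exactly \(6c\) without
reordering anything. Sites are ranked by descending score with ties broken
by ascending position, so a scan is fully deterministic.

Enumeration covers every position with a complete window, \(k \in [3,
N-3]\), i.e. \(N-5\) sites for an \(N\)-residue protein. Published site
tables sometimes number the same physical junction one position
differently depending on whether the window or the break is indexed; this
package treats the window string as authoritative and always reports the
break as `k/k+1` under the convention above.

Three further rules are deliberate design choices:

* **The C+1 constraint filters, it does not score.** Scanning is
  unconstrained so that the full ranking (including catalytically dead
  sites) is visible; `filter_c1()` and `select_candidates()` apply the
  constraint afterwards and never reorder survivors. The default allowed
  set is `{C}` for DnaE; registries for other families default to the
  nucleophilic residues C/S/T/M.
* **Structure is annotation only.** A per-residue H/E/C track (DSSP
  8-class codes are collapsed G/H/I to H, E/B to E, rest to C) yields a
  majority label over the six window residues — ties resolve to
  `NON STRUCTED` — but never enters the numeric score. Local conformation
  demonstrably matters (a sequence-optimal site can still fail to restore
  a functional fold), yet available impact data does not quantify it, so
  the package surfaces it beside the score rather than mixing the two.
* **Candidates plus a negative control.** `select_candidates()` returns
  the top-`n` constraint-passing sites (three by default — testing several
  high-scoring sites is advisable precisely because structure effects are
  unmodelled) and one constraint-failing site as a negative control for
  the splicing reaction, by default the lowest-scoring failing site, with
  a user override for deliberate choices.

Missing matrix entries are imputed as 0 with a warning; a non-canonical
residue in a window is an error in strict mode and a 0 contribution
otherwise.

## From site to constructs

For a chosen split \(k\), `design_constructs()` assembles

* N-precursor: `extein[1..k] ++ N-intein ++ tag`
* C-precursor: `C-intein ++ extein[k+1..N] ++ tag`

plus a full-length positive control and tag-less, intein-less extein
halves as a self-assembly control. Tags (default 6xHis) go on the
C-terminus of both precursors so that anti-tag blotting sees every
precursor and the excised intein, and the spliced product loses both
tags — a clean readout of a completed reaction. No linker is inserted by
default (`linker` is configurable); the extein concatenation invariant
(`n_extein ++ c_extein == target`) is enforced by tests for every
combination, and `predict_products()` closes the mass balance
\(\mathrm{MW}_{\mathrm{Nprec}} + \mathrm{MW}_{\mathrm{Cprec}} =
\mathrm{MW}_{\mathrm{spliced}} + \mathrm{MW}_{\mathrm{intein}} +
2\,\mathrm{MW}_{\mathrm{tag}} - 2\,\mathrm{MW}_{\mathrm{H_2O}}\).
Molecular weights use average residue masses, the right resolution for
gel-based size assignment.

Back-translation is deterministic in both modes. `max-frequency` picks
each residue's most used codon; `gc-minimize` picks the lowest-GC codon
among those with relative frequency at least 0.10 (rare codons hurt
expression more than GC helps), breaking GC ties toward the more frequent
codon. The packaged human codon usage table carries rounded frequencies
renormalized at load; published usage tables differ slightly by source,
which never affects the round-trip guarantee
`translate_dna(back_translate(p)) == p`.

Cloning support is intentionally minimal: exact-match restriction
scanning (defaults BamHI `GGATCC`, HindIII `AAGCTT`; both palindromic, so
one strand suffices), flank addition that refuses inserts carrying an
internal site, and overlap-extension tiling in which consecutive
fragments share a fixed-length junction (default 20 nt) reported with its
melting temperature. Tm uses the Wallace rule \(2(A{+}T) + 4(G{+}C)\)
below 14 nt and \(64.9 + 41\,(GC - 16.4)/L\) otherwise — adequate for
flagging junctions that melt below a standard 60 °C annealing program,
not a nearest-neighbour estimate. Junction oligos all have the configured
length except possibly the last, which absorbs the remainder of the
division; reassembly from the recorded coordinates is exact by
construction and verified against random tilings.

## Assay models

**Dose-response.** Transduction efficiency against vector dose follows
the four-parameter logistic
\[
y(x) = d + \frac{a - d}{1 + (x/c)^b},
\]
with lower/upper asymptotes \(a, d\) (percent positive cells), inflection
dose \(c\) (viral genomes per cell; \(y(c) = (a+d)/2\)) and Hill slope
\(b\). The fit runs on \(\log c\) and \(\log x\) internally — doses span
orders of magnitude and the log parameterization keeps the Jacobian well
conditioned — via Levenberg–Marquardt least squares, starting from
\(a = \min y\), \(d = \max y\), \(c\) at the geometric mean dose,
\(b = 1\). \(R^2 = 1 - SS_{res}/SS_{tot}\) is computed on the response
scale against the raw points, unweighted. The closed-form inverse
\(x = c\,((a-d)/(y-d) - 1)^{1/b}\) gives dose-for-target-response
predictions and is only defined strictly between the asymptotes. Whether
to weight the fit or compute \(R^2\) on a transformed scale is a genuinely
open choice for percent data; the unweighted response-scale convention was
fixed here once and is what all reported numbers mean.

**qPCR standard curve.** Replicate threshold cycles are averaged per
dilution level (their SD is kept), mean Ct is regressed on
\(\log_{10}\) copies, and efficiency is
\(E = 10^{-1/\text{slope}} - 1\), so a slope of \(-3.3219\) is exactly
100%. Acceptance follows standard absolute-quantification practice:
\(r^2 > 0.9\), \(E\) within 85–100% inclusive, and per-level Ct SD at
most 0.2 cycles; each failed criterion is named. Titers invert the curve
(`10^((ct - intercept)/slope)`) and scale by dilution factor and volume;
unit conversion between copies per reaction and copies per mL is left to
those two factors because instrument volumes vary.

**Densitometry.** Band intensities are normalized as target over
housekeeping reference from the same lane, and fold changes are reported
at one decimal, the usual reporting convention.

## Synthetic data, and what passing tests do not show

The seeded generators make the whole pipeline testable offline:

* `sim_protein()` draws uniform residues — real proteins have biased
  composition, but none of the scanned arithmetic depends on it;
* `sim_impact_matrix()` draws Gaussian cell scores (default SD 1) and can
  plant a window by adding a +50 per-position bonus so that exactly one
  site dominates — a synthetic stand-in for an empirical screen, useful
  for ranking logic but carrying no biology;
* `sim_dose_response()` defaults to the six-dose ladder
  5e3…2e5 Vg/cell with \(a = 2\), \(d = 90\), \(c = 4 \times 10^4\),
  \(b = 1.5\) and Gaussian response noise — values typical of an AAV
  transduction series on a permissive cell line;
* `sim_standard_curve()` defaults to six ten-fold levels spanning
  \(10^4\)–\(10^9\) copies, three replicates, efficiency 0.92 and
  intercept 38, a realistic linearized-plasmid standard.

Every generator is a pure function of its seed (seeded via
`withr::with_seed`, leaving the caller's RNG untouched). The packaged
DnaE registry is likewise synthetic — correct half lengths and catalytic
anchor residues (N-half starts with Cys, C-half ends in Asn) but random
interiors, as the filename `dnae_registry_synthetic.fasta` states —
so construct arithmetic is exercised without shipping curated intein
sequences; replace it with your own registry for bench work.

Consequently, green tests certify the machinery: enumeration counts,
scoring equivalence with a brute-force oracle (random proteins up to 50
residues, 1,000 cases), filter/selection semantics, reconstruction and
mass-balance identities, codon round trips, exact tiling reassembly, and
parameter recovery for the assay models (noise-free fits recover
generating parameters to solver precision; with response noise of SD 2,
the median relative error of the fitted inflection dose across 200 seeded
replicates stays under 10%). They do not certify that a top-ranked site
will splice efficiently in cells: real impact matrices carry measurement
error, structure effects are unmodelled, and expression of the two
precursors is rarely balanced (design reports therefore carry the
advisory to dose N:C at roughly 2:1).

## Numerical choices and degenerate inputs

* Ranking ties break by ascending position; structure-majority ties go to
  `NON STRUCTED`; GC ties in codon choice go to the more frequent codon,
  then alphabetically.
* Proteins shorter than six residues scan to an empty site list with a
  warning rather than an error, so pipelines can map over mixed input.
* 4PL fitting refuses fewer than four points, non-positive doses, and
  constant responses; the standard curve refuses fewer than three levels
  and constant Ct.
* The efficiency bounds are inclusive at both ends; the linearity bound
  is exclusive (`r2 > 0.9`).
* Scan/oracle comparisons and round-trip checks in the test suite run at
  small problem sizes (proteins up to 50 residues for the 1,000-case
  equivalence sweep, 200 noisy dose-response replicates) — large enough
  to exercise every branch while keeping the default suite quick.

## Known limitations

* The additive score ignores interactions between flanking positions;
  screens measure single substitutions, so non-additive epistasis between
  extein residues is invisible to the model.
* Secondary-structure annotation needs an externally supplied track (a
  crystal/model-derived assignment); the package neither predicts
  structure nor fetches models.
* Tm formulas are deliberately simple; primer secondary structure,
  dimers and salt corrections are out of scope.
* Splicing kinetics are not modelled; intein choice on kinetic grounds is
  the user's, with the registry's free-text `kinetics_note` as a place to
  record it.
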