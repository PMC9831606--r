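---
title: "Methods behind knotopt: contact statistics, design selection and pharmacology for knottin optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind knotopt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knotopt)
```

knotopt implements the recurring quantitative steps of a structure-guided
optimization campaign for inhibitor-cystine-knot (knottin) peptides that
target the voltage-sensing domain II of NaV1.7: bookkeeping of the variant
series, contact statistics from structural frames of the
peptide--channel--membrane complex, post-processing of design-engine output
into constraints for the next round, concentration--response pharmacology,
and excitability summaries from patch-clamp experiments. This vignette
records the models, conventions and design choices, so that results are
interpretable without reading the source.

## Peptide variants and non-canonical residues

A variant is an ordered vector of residue codes over the 20 canonical amino
acids plus an extensible registry of non-canonical codes (norarginine,
norleucine, 2,4-dimethyl-phenylalanine, tert-butyl-cysteine). Every extended
code maps to a unique single display character for compact alignments
(norarginine prints as `X`); the display characters are deliberately taken
from letters with no canonical one-letter meaning so an alignment cell is
never ambiguous. FASTA export writes extended codes in square brackets
(`...R[norArg]LW...`) because no standard one-letter codes exist; the reader
inverts this, so sequence files stay machine-readable.

Residue numbering is 1-based everywhere, matching the standard mutation
notation (`Y1H`, `K28E`) used in optimization narratives. `apply_mutations()`
verifies the `from` residue of every mutation against the parent sequence and
aborts on mismatch; this catches the classic transcription drift where a
substitution is named relative to the wild type but applied to a later-round
design whose position has already changed. One such case exists in the
bundled PTx2 series: the final-round change is `Q1H` relative to PTx2-3127
(which already carries `Y1Q`), although it is naturally described as "Y1H" in
wild-type coordinates. The table of printed sequences is treated as ground
truth.

The scaffold check validates length and the six cysteine positions
{2, 9, 15, 16, 21, 25} only. Disulfide connectivity is deliberately not
modelled: the pairing of the scaffold cysteines is not an input we can
validate against, and nothing downstream depends on it.

## Fractional residue--environment contacts

For frames $f = 1..F$ and interacting chain pairs $p = 1..P$ (a four-fold
channel with one peptide per voltage sensor gives the default pairs
`A:E, B:F, C:G, D:H`), the fractional contact of peptide residue $i$ with
environment group $g$ is

$$\mathrm{fc}(i, g) = \frac{1}{FP} \sum_{f,p}
  \mathbf{1}\left[\min_{a \in i,\, b \in g} \lVert x_a - x_b \rVert
  \le c\right],$$

with cutoff $c = 3.5$ Å over heavy atoms. Two conventions needed fixing
where a verbal definition is ambiguous:

* **Binary indicator, not atom-pair count.** A (frame, pair) observation is
  "in contact" if *any* heavy-atom pair crosses the cutoff. The alternative
  (counting atom pairs) weights large residues and dense groups; the
  frequency-of-contact reading is the one we implement, and values are exact
  rationals `count / (F*P)` — rerunning on the same frames is bit-identical.
* **Shared groups, uniform denominator.** Membrane, water and ion atoms are
  shared across chain pairs, but each (frame, pair) still contributes one
  observation per residue and group, so every group — including the
  channel group, which is restricted to the paired chain — is normalized by
  the same $FP$ denominator.

Atom grouping is rule-based: peptide/channel by chain ID, water and ions by
residue name, and lipid split into head and tail by atom name. The POPC
head/tail partition (choline + phosphate + glycerol/ester atoms = head,
sn-1/sn-2 acyl carbons = tail) is an explicit table in the rules object and
serializes to YAML; it is an assumption of the analysis, not a universal
standard, which is why it ships inspectable rather than hard-coded.

Distance searches run through a uniform cell grid with edge length equal to
the cutoff; because the grid only prunes candidates and the same distance
kernel evaluates every surviving pair, the results are guaranteed identical
to the all-pairs search, and the test suite asserts that equality on random
point sets and whole profiles.

Polar-interaction detection is geometric. No hydrogen-bond criterion is
universal, so the defaults are conventional and configurable:
donor--acceptor heavy-atom distance ≤ 3.5 Å, plus a donor--H···acceptor
angle ≥ 120° when explicit hydrogens are present; side-chain charged N/O
pairs within 4.0 Å count as salt bridges.

## Design post-processing

Scorefiles use the whitespace `SCORE:` dialect with the tag in a trailing
`description` column. Both ranking criteria — total score and the interface
energy ΔΔG — are energies, so **lower is better**; this directionality is a
documented assumption. The selection cascade keeps the `n_score = 100`
lowest total scores, then the `n_ddg = 20` lowest ΔΔG among those. Ties
break by tag in lexicographic order, which makes the cascade a deterministic
function of the record set; the suite checks it against a brute-force
repeated-minimum oracle, set *and* order.

Position-weight matrices use exact count frequencies; information content is
$\log_2 20 - H_i$ bits with no small-sample correction by default (the
Miller--Madow term used by some logo tools is available as an option, and
only ever lowers the IC). Consensus is the per-position argmax with
alphabetical tie-break. An automated consensus cannot reproduce
expert-curated choices (e.g. deliberately picking a third-ranked residue for
chemical reasons); those remain manual inputs to the next round.

Resfile constraint generation encodes one round's policy: repack-only
(`NATAA`) positions, fixed identities (`PIKAA <res>`), and — the
membrane-specific rule — `NOTAA ED` at positions whose combined lipid
head + tail fractional contact reaches a threshold, so acidic residues are
never designed into the bilayer interface. The threshold is not a published
constant; 0.25 of observations is the shipped default and it is an exposed
parameter. Scaffold cysteines default to `NATAA` so a design run cannot
remove the disulfide scaffold, but the argument accepts an empty set: the
bundled second-round resfile leaves the cysteines on the default `PIKAA`
line (the design engine's own task operations protected them there), and
reproducing that file exactly requires opting out of the cysteine rule.

## Hill pharmacology

Concentration--response data are fit with the Hill equation with floor 0 and
ceiling 1 (complete block at saturation, consistent with full inhibition at
high dose; a free-top variant exists behind a flag for partial blockers):

$$f([L]) = \frac{[L]^h}{IC_{50}^h + [L]^h}
         = \mathrm{logistic}\!\left(h(\ln[L] - \ln IC_{50})\right).$$

The fit is least squares in $(\log IC_{50}, \log h)$ — the logistic form
makes scale-equivariance exact: multiplying all concentrations by $k$
multiplies the fitted $IC_{50}$ by $k$ and leaves $h$ unchanged, a property
the tests verify to optimizer precision. The point fit uses
`minpack.lm::nlsLM`; requirement of at least three distinct concentrations
(two if $h$ is fixed) mirrors the usual per-cell acceptance rule for potency
assays.

**Confidence intervals.** The 95% CI is a seeded case-resampling bootstrap
(B = 2000) — but the *studentized* (bootstrap-t) flavour on
$\log IC_{50}$, not the percentile interval. This was an evidence-driven
choice: at the typical per-peptide design size of ~15 points
(5 concentrations × 3 cells), Monte-Carlo calibration at
$IC_{50} = 7$ nM, $h = 1$, $\sigma = 0.05$ shows the percentile interval
covering ≈ 91% instead of 95% (basic, BCa, stratified and residual variants
do no better), while the studentized interval covers ≈ 94–95%. The
percentile and Wald intervals remain available via `ci_method` for
cross-checking. Bootstrap refits use a vectorized Levenberg--Marquardt
engine (closed-form 2×2 normal equations across all resamples at once)
warm-started at the point estimate; the test suite cross-checks it against
per-resample `nlsLM` fits.

Selectivity folds are $\lfloor IC_{50}^{subtype} / IC_{50}^{ref} \rfloor$ —
truncation toward zero, the convention that reproduces printed integer fold
tables (e.g. 382/3.8 → 100, not 101). Censored entries (`">150000"`)
propagate as mechanical lower bounds on the fold; note that folds computed
from *rounded, printed* IC50s can differ from folds computed on the
unrounded originals, so bound presentation in published tables need not
match the mechanical division. Potency rankings order by IC50 ascending,
stable under ties, with range entries (`"0.3-1.7"`) ordered by midpoint.

## Excitability summaries

Current traces are uniformly sampled records with the step onset as the time
reference. Window conventions, fixed because verbal descriptions like "from
0.4 to 1 ms" are ambiguous at 50 kHz: windows are half-open $[t_0, t_1)$,
aligned to sample times at or after $t_0$. Zero-subtraction removes the mean
of the 0.14 s immediately before the step. "Peak" means the extremum of the
signed trace — most negative under the default inward convention, with a
polarity flag. Drug-sensitive currents are samplewise differences of
zero-subtracted traces, so sensitive + resistant = total exactly.

Percent metrics (remaining APs, rheobase change) are rounded **half away
from zero** to one decimal — the convention of printed ephys tables (3/48 →
6.3%, where banker's rounding would print 6.2). Group summaries average the
per-cell one-decimal values and report mean and SEM (sample SD / √n), again
to one decimal; averaging the rounded per-cell values rather than the raw
ratios is the convention that reproduces the bundled table's printed
Average/SEM rows. Cells with zero baseline APs at a frequency have an
undefined remaining-AP percentage and are excluded from that frequency's
average (the bundled table contains none; the rule is forward-looking).
Exclusion of TTX-insensitive neurons is a per-cell flag supplied by the
analyst, never inferred. The optional two-group comparison is an unpaired
two-sided Student's t-test per (dose, frequency) group.

## Synthetic data: what it emulates and what it does not

Each generator produces data with the statistical structure its consumer
assumes, under one top-level seed that fans out to per-generator substreams
(`derive_seed`), so adding a generator never perturbs another's draws, and
identical settings give byte-identical files.

* `gen_complex_frames` plants an independent Bernoulli contact per (frame,
  chain-pair, residue, group) by placing one pseudo-atom of the group at
  2.5 Å (contact) or 8.0 Å (no contact) from the residue anchor. Residues
  sit 20 Å apart and chain-pair regions 100 Å apart, so planted states
  cannot collide and no retry logic is needed. This is deliberately minimal
  geometry: it validates classification and the estimator, not molecular
  realism — there is no actual membrane, no solvation shell, no correlated
  motion between frames.
* `gen_scorefile` draws jointly normal (total score, ΔΔG) at a chosen
  correlation; a planted motif is written into a guaranteed fraction of the
  records the cascade will select, so consensus recovery is testable by
  construction.
* `gen_dose_response` adds Gaussian noise to the Hill curve and clips to
  [0, 1]. Clipping (rather than resampling) slightly biases responses near
  saturation; real run-up/run-down artefacts and state-dependent binding
  kinetics are not modelled.
* `gen_ephys_table` thins AP trains binomially per frequency and scales
  rheobase by a planted multiplier with 5% log-normal noise; stimulus counts
  are 10 at 0.1 Hz and 120 at 1/3/10 Hz. Real cells' strong
  cell-to-cell heterogeneity in baseline excitability is represented only by
  the uniform rheobase draw.
* `gen_traces` builds currents as
  $a(1 - e^{-t/\tau_{act}})e^{-t/\tau_{inact}}$ components (fast ≈ 1 ms and
  slow ≈ 20 ms inactivation by default), which reproduces the
  fast-before-slow peak-time ordering and exact subtraction algebra but not
  channel gating.

Passing tests on these generators therefore demonstrates estimator
correctness and pipeline integrity under known truth; they do not
demonstrate robustness to the artefacts of real recordings or simulations.

## Problem sizes and numerical choices

The test and acceptance workloads use sizes chosen to make sampling error
small relative to the tolerances they check: contact recovery uses 500
frames × 4 chain pairs (2000 observations, binomial SE ≈ 0.010 at
p = 0.3, checked within 3 SE); bootstrap calibration uses 500 Monte-Carlo
replicates of B = 2000 resamples (SE of the coverage estimate ≈ 1
percentage point); the cascade check uses 1000 records against an
exhaustive oracle. Levenberg--Marquardt refits clamp $\log IC_{50}$ to the
data's log-concentration range ± 12 and $h$ to [0.001, 50] to keep
degenerate resamples finite; fold computation adds a 10⁻⁹ epsilon before
flooring so mathematically integer ratios are never floored down by
floating-point representation.

## Known limitations

* The contact statistic is binary per observation; an atom-count-weighted
  variant would emphasize buried residues differently and is not
  implemented.
* H-bond detection uses distance (+ angle when hydrogens exist) only; no
  energy or hybridization model.
* The consensus operation cannot reproduce expert overrides in historical
  design rounds.
* Selectivity folds from rounded printed IC50s can disagree with folds from
  unrounded measurements; the package computes the mechanical convention
  and documents it.
* The ephys module consumes AP counts and rheobase values; spike detection
  from raw voltage traces is out of scope.
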