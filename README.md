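# knotopt

Analytics for structure-guided optimization of knottin peptide inhibitors of
voltage-gated sodium channels.

NaV1.7 is the sodium-channel subtype that sets the firing threshold of
peripheral pain-sensing neurons, and inhibitor-cystine-knot (knottin)
tarantula toxins such as ProTx-II block it by binding the voltage-sensing
domain II at the membrane interface. Optimizing such a peptide is an
iterative campaign: analyze the peptide--channel--membrane interface,
constrain and run a protein-design engine, rank the designs, synthesize a
few, and measure potency, subtype selectivity and neuronal efficacy by
patch clamp. `knotopt` implements the recurring computational steps of that
loop as a tested R package, for structural biologists and channel
pharmacologists who currently re-write them as one-off scripts:

* **Variant bookkeeping** (`parse_variant_table`, `diff_variants`,
  `apply_mutations`, `validate_scaffold`) — 30-residue knottin variants over
  an extended residue alphabet (norArg, norLeu, ...), mutation notation, and
  scaffold-cysteine integrity checks.
* **Interface contact statistics** (`read_frames`, `fractional_contacts`,
  `find_polar_interactions`) — for multi-model structural frames, the
  fraction of (frame, chain-pair) observations in which a peptide residue
  has any heavy atom within 3.5 Å of a group (lipid head, lipid tail,
  water, channel), plus geometric H-bond/salt-bridge detection.
* **Design post-processing** (`read_scorefile`, `select_designs`,
  `build_pwm`, `consensus`, `parse_resfile`, `derive_constraints`) — the
  two-stage cascade (top 100 by total score, then top 20 by interface ΔΔG),
  consensus/logo matrices, and generation of per-position design
  constraints (PIKAA/NATAA/NOTAA resfiles) from contact profiles, e.g.
  disallowing acidic residues at lipid-facing positions.
* **Hill pharmacology** (`fit_hill`, `selectivity_matrix`,
  `rank_peptides`) — least-squares fits of
  f([L]) = [L]^h / (IC50^h + [L]^h) in log(IC50) space with seeded
  bootstrap confidence intervals, and integer fold-selectivity matrices
  with censoring ("> 150000") support.
* **Excitability summaries** (`zero_subtract`, `window_mean_density`,
  `peak_density_and_time`, `subtract_traces`, `remaining_ap_percent`,
  `rheobase_change_percent`, `summarize_cells`) — trace windowing,
  drug-sensitive current subtraction, and per-cell → group mean ± SEM
  tables of remaining-AP and rheobase-change percentages.
* **Synthetic data generators** (`gen_complex_frames`, `gen_scorefile`,
  `gen_dose_response`, `gen_ephys_table`, `gen_traces`) — seeded,
  byte-deterministic emulators of every input above with planted ground
  truth, so the whole pipeline is testable without any external data.

Small plain-text characterization tables of the PTx2 optimization series
(variant alignment, per-subtype IC50s, potency ranking, a per-cell human
DRG excitability table, and a design resfile) ship under
`inst/extdata/`; `knotopt_file()` lists and resolves them.

## Worked example

```r
library(knotopt)

## What distinguishes the lead design from the wild-type toxin?
v <- parse_variant_table(knotopt_file("ptx2_variants.tsv"))
diff_variants(v[["WT PTx2"]], v[["PTx2-3258"]])
#> <mutation_set> 9 mutation(s): Y1H,W7Q,S11K,E12D,M19F,V20R,K26R,K28E,W30L

## Subtype selectivity of PTx2-3258 from its measured IC50s
ic <- read.csv(knotopt_file("nav_ic50_selectivity.csv"))
selectivity_matrix(ic[ic$peptide == "PTx2-3258", c("subtype", "ic50_nM")])
#>    subtype ic50_nM fold_display
#> 1  hNav1.1  5013.0         1319
#> 5  hNav1.5 38315.0        10082
#> 6  hNav1.6   382.0          100
#> 7  hNav1.7     3.8            1
#> ...

## Fit a synthetic concentration-response experiment (true IC50 = 7 nM)
dr <- gen_dose_response(ic50 = 7, h = 1, noise_sd = 0.05, n_cells = 3, seed = 42)
fit_hill(dr, B = 2000, seed = 1)
#> <hill_fit> IC50 = 7.103 nM [6.105, 8.495] (95% bootstrap), h = 1, n = 15 point(s)

## Dose-dependent rheobase increase in the bundled human DRG table
cells <- read_ephys_cells(knotopt_file("drg_ephys_cells.csv"))
summarize_cells(cells, "rheobase_change")
#>       dose  n mean  sem
#> 1 baseline 10  0.0  0.0
#> 2     0.01 10  4.9  3.1
#> 3      0.1 10 13.5  5.1
#> 4        1 10 49.1 10.3
```

The mutation set is the lead design's nine substitutions relative to wild
type; the fold column is floor(IC50_subtype / IC50_ref) — note 382/3.8
prints 100, the floor, not the rounded 101. The fitted IC50 recovers the
planted 7 nM within its bootstrap interval, and the rheobase summary shows
the ~50% mean rheobase rise at 1 µM with its SEM over ten cells.

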