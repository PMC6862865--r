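# mitoquant

Quantification pipelines for the readouts of cell-based
mitochondrial-dynamics and autophagy studies — the kind of experiment where
α-synuclein overexpression fragments mitochondria, depresses respiration
and blocks autophagic flux, and an intervention (e.g. Drp1 inhibition) is
scored for rescue. The package implements the full arithmetic layer between
the raw measurements and the group statistics, plus seeded synthetic-data
generators with known ground truth so every procedure is validated by
parameter recovery.

Who it is for: bench scientists and analysts who have flux-plate exports,
fluorescence images, cytometry event lists or blot densitometry tables and
want the standard quantifications as reproducible, tested code instead of
spreadsheet formulas and interactive GUI clicks.

## What it computes

**Extracellular-flux bioenergetics.** From per-well OCR/ECAR traces of a
mito-stress-test run (basal → oligomycin → FCCP → rotenone/antimycin A):

- OCR_mito = OCR_tot − OCR_R/A; coupled respiration OCR_tot − OCR_oligo;
  proton leak; spare respiratory capacity SRC% = maximal/basal × 100;
- glycolytic proton production rate
  PPR_glyc = ECAR_tot/BP − OCR_mito · maxH⁺/O₂ · 10^(pH−pK₁)/(1+10^(pH−pK₁));
- ATP-rate partition
  ATP_ox = OCR_coupled · 2P/O_oxphos + OCR_mito · 2P/O_TCA and
  ATP_glyc = PPR_glyc · ATP/lactate + OCR_mito · 2P/O_glyc,
  with total ATP their exact sum;
- nuclei-stain (cell-density) normalization per well.

**Mitochondrial morphometry.** Otsu segmentation and the two moment-based
shape indices: roundness 4·Area/(π·Major²) and aspect ratio Major/Minor
(both → 1 for circular, fragmented mitochondria), with group mean ± SEM
summaries.

**Puncta and autophagy flux.** Multi-scale Laplacian-of-Gaussian puncta
detection (LC3, p62, proteinase-K-resistant α-syn), and tandem
mRFP-GFP-LC3 classification: autophagosomes = green vesicles,
autolysosomes = red − green per cell (GFP is quenched in acidic
autolysosomes).

**Cytometry and densitometry.** Percent-above-threshold gating against an
FCCP positive control (threshold = control 0.95-quantile), event location
statistics, and signal/loading-control ratio tables for plate-reader and
immunoblot quantification.

**Statistics.** One-way ANOVA followed by Newman–Keuls step-down post-hoc
testing on the studentized range (harmonic-mean n for unequal groups,
α = 0.05 default), and a report assembler producing deterministic
CSV/JSON/text bundles. `run_pipeline()` runs every stage end-to-end on
synthetic data and reproduces its report byte-for-byte under a fixed seed.

## Worked example

A noise-free synthetic well with true basal OCR 100, non-mitochondrial
OCR 20, coupled fraction 0.75 and maximal OCR 180 pmol O₂/min:

```r
library(mitoquant)
truth <- flux_truth(basal = 100, nonmito = 20, coupled_frac = 0.75,
                    maximal = 180, ecar = 10, noise_sd = 0)
plate <- generate_flux_plate(truth, seed = 1)
(summ <- summarize_phases(plate))
#>   well ocr_tot ocr_oligo ocr_max ocr_ra ocr_mito ocr_coupled ocr_leak src_pct
#> 1  W01     100        40     180     20       80          60       20     180
#>   ecar_tot
#> 1       10
compute_atp_rates(summ, constants = bioenergetic_constants(buffering_power = 0.1))
#>   well ppr_glyc atp_glyc atp_ox atp_total
#> 1  W01 23.75996 62.47996 317.68    380.16
```

Reading: of 100 pmol O₂/min basal respiration, 80 is mitochondrial (20
survives rotenone/antimycin), 60 is coupled to ATP synthesis (oligomycin-
sensitive) and 20 is proton leak; FCCP drives respiration to 180%
of basal (SRC). After removing the CO₂-derived acidification from ECAR,
glycolysis produces ~23.8 pmol H⁺/min, and the ATP partition attributes
~318 pmol ATP/min to oxidative phosphorylation versus ~62 to glycolysis —
an oxidative cell.

Group comparison of, say, oxidative ATP rates across three conditions:

```r
set.seed(1)
v <- c(rnorm(6, 320, 25), rnorm(6, 220, 25), rnorm(6, 300, 25))
g <- rep(c("control", "asyn", "asyn_siDrp1"), each = 6)
res <- anova_nk(data.frame(group = g, value = v))
res$anova
#>      term df        ss         ms        f            p
#> 1 between  2 23308.138 11654.0689 20.71537 4.834108e-05
#> 2  within 15  8438.711   562.5808       NA           NA
res$posthoc[, c("group1", "group2", "diff", "span", "q", "q_crit", "significant")]
#>        group1      group2     diff span        q   q_crit significant
#> 1        asyn     control 85.11712    3 8.790228 3.673378        TRUE
#> 2        asyn asyn_siDrp1 62.39138    2 6.443292 3.014325        TRUE
#> 3 asyn_siDrp1     control 22.72574    2 2.346936 3.014325       FALSE
```

The α-syn group differs from both others (q above the studentized-range
critical value at its span); the rescue group is indistinguishable from
control — the canonical protection pattern.

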