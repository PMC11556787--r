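---
title: "Models and methods behind degronscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind degronscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degronscan)
```

degronscan analyses sort-seq screens of randomized short-peptide libraries
fused to a tandem fluorescent timer (tFT). This vignette is the package's own
account of the models it implements, the parameters that matter, the design
choices that were genuinely open, and what the simulator does and does not
capture.

## The screen being modeled

A degenerate-codon cassette (five NNN codons by default) is inserted behind a
cleaved ER signal sequence so each cell expresses one pentapeptide fused to a
reporter carrying a fast-maturing GFP and a slow-maturing mCherry. Because
degradation removes protein before the slow fluorophore matures, the
mCherry/GFP ratio falls monotonically with turnover. Cells are gated (live,
single, fluorescence-positive) and the lowest few percent of the ratio
distribution — the "unstable" bin — is collected and amplicon-sequenced
alongside the unsorted input library. Destabilizing sequence features appear
as amino acids over-represented at specific peptide positions in the bin.

## The codon-count null

The expectation side of the enrichment ratio is purely combinatorial: under a
degenerate codon scheme the probability of amino acid $a$ at a randomized
position is the number of codons encoding $a$ in the scheme's codon set
divided by the size of the set. `position_null_distribution()` enumerates the
set and tallies translations, so NNN gives Ile $3/64$, Leu $6/64$, stop
$3/64$.

Two conventions were open and are fixed as follows:

* **Stop mass is carried, not renormalized away.** The screen's printed
  expectations (4.7%, 9.4%) are fractions of all 64 codons including stops,
  so the default distribution keeps a `"*"` entry. Conditioning on sense
  codons is an explicit option (`renormalize_sense = TRUE`), in which case
  every sense probability is scaled by $64/61$.
* **Uniform over codons, not organism codon usage.** The printed 3/64 and
  6/64 values force a uniform-codon null; a codon-usage-weighted null is
  deliberately out of scope.

Translation itself is a strict codon-table lookup over `{A,C,G,T}` (the
standard nuclear code by default, injectable for other codes). IUPAC
ambiguity codes are rejected: handling ambiguous bases is the extraction
stage's job, where they are counted and dropped.

## The simulator: what is planted and what is emulated

`sample_library()` draws inserts i.i.d. per nucleotide position from the
scheme's alphabets and gives each variant an abundance from a lognormal
(default `sdlog = 1`) to mimic the uneven clone sizes of a transformation;
Dirichlet and uniform abundances are available. An `exhaustive` mode
enumerates every peptide class with its codon multiplicity — the
infinite-sampling limit used as an oracle in tests.

**Stability rule.** Ground truth is a pure function of peptide sequence:
a neutral base rate (default $\ln 2 / 180\ \mathrm{min}^{-1}$, a stable
half-life of 3 h), multiplicative per-(position, amino acid) factors, and
optional motif factors. The default planted rule multiplies the rate by 8
for Ile or Leu at position 1, the signature this kind of screen is expected
to recover. Stop-containing (truncated) peptides get their own rate class,
defaulting to the unstable 8× rate: how truncations behave in a real
reporter is unknown, so they are segregated in all outputs rather than
silently merged. At these defaults the destabilized class has a ~22 min
half-life — unstable on the timescale of reporter maturation but not
instantaneous.

**tFT readout.** No published equations exist for the reporter, only the
fast/slow-maturation rationale, so the package uses the simplest model that
reproduces the monotone ratio–stability relationship: constant synthesis,
irreversible first-order maturation of each fluorophore ($m_g$ for GFP,
$m_c$ for mCherry, $m_c < m_g$), first-order degradation at rate $k$ acting
equally on mature and immature protein. At steady state the mature-fluorophore
ratio, normalized to $R(0) = 1$, is

$$R(k) = \frac{m_c\,(m_g + k)}{m_g\,(m_c + k)},$$

which decreases strictly in $k$ from 1 to $m_c/m_g$. Defaults take maturation
half-times of 6 min (a superfolder-class GFP) and 40 min (mCherry). Per-cell
observed log-ratios get Gaussian noise with standard deviation
`cell_noise_cv` (default 0.3, a typical flow-cytometry spread); cells fail
the live and fluorescence gates with configurable probabilities (defaults
0.05 and 0.10) and are excluded from sorting, as in the cytometer's gating
chain.

**Sorting.** The unstable bin is a sharp empirical quantile of the observed
log-ratio among gated cells (default fraction 0.04, matching the screen this
package models; in practice such gates are drawn by eye against stable and
unstable control strains, so the fraction is a configuration knob, not a
constant of nature). Bin membership is deterministic given the cell table.

**Reads.** Each read is `upstream_flank + insert + downstream_flank`
(default 101 + 15 + 101 = 217 bp; the default flanks are fixed arbitrary
sequences satisfying that geometry, since real flank sequences are
construct-specific and fully configurable). Sequencing error is
substitution-only, i.i.d. per base (default $10^{-3}$); indels are not
simulated because the extraction stage anchors at fixed spacing and real
pipelines of this kind drop misaligned reads anyway. Qualities use a
per-read model (read-level normal around Phred 35, clamped to [2, 40]);
since the only quality consumer is the read-mean filter, a per-base model
would add cost without changing any downstream statistic.

Not simulated, deliberately: scatter-based size/singlet gating physics, PCR
cycle-by-cycle amplification bias, paired-end merging, and growth competition
between sorting and sequencing. A real screen also regrows sorted cells
before DNA extraction; whether regrowth skews abundances cannot be inferred
from published information, so no growth bias is applied by default.
Consequently, passing tests demonstrate that the analysis recovers planted
signals under these idealizations — they do not certify robustness to PCR
jackpots, indel-rich chemistry, or growth distortion.

## Extraction

Reads failing the mean-quality filter (default Phred ≥ 20; a read-level
filter rather than per-base masking, the simplest defensible QC) are dropped
first. Anchoring then requires both constant anchors (by default the 20 nt
of flank adjacent to the variable region) to match within a Hamming
tolerance (default 1 mismatch each) at exactly the variable-region spacing;
zero or multiple candidate placements are anchor failures. Variable regions
containing non-ACGT bases are dropped as ambiguous; the rest are translated,
and stop-containing peptides are tallied separately from the sense count
table. The six report categories are disjoint and sum to the input read
count — an invariant the tests enforce, so no read can vanish silently.

Coordinates in `locate_flanks()` are 1-based inclusive: this is an R
package, and 1-based strings are what `substr()`, Biostrings and every
downstream consumer in this ecosystem expect. Duplicate reads are not
collapsed (the library design has no UMIs, so duplicates are
indistinguishable from true abundance).

## Enrichment, stops, and the two panels

`position_frequencies()` tallies read-weighted amino-acid occurrences per
position (each read counts once; a unique-peptide weighting exists for
diagnostics, since it is not documented which convention published tallies
of this kind use). Stop-containing peptides are excluded from the 20-row
matrix by default and reported separately; an `include_stops` switch adds
`"*"` as a 21st row.

Two fold panels are produced:

* **vs the codon null** (`enrichment_vs_null()`), raw frequencies by
  default — this is the panel on which the printed worked examples
  (17.7%/4.7% = 3.8-fold; 14.8%/9.4% = 1.6-fold) are reproduced exactly.
  Note one structural subtlety: because stop-containing peptides are
  excluded from the tally while the null keeps stop mass, every sense fold
  centers on $64/61 \approx 1.049$ rather than 1 even without selection.
  The sense-renormalized null removes this offset when a centered panel is
  wanted.
* **vs the input library** (`enrichment_vs_input()`), pseudocount-smoothed
  (default 0.5 reads per cell) so that finite input tallies cannot produce
  division blow-ups at desk scale; raw mode (`pseudocount = 0`) is used when
  reproducing printed ratios. This panel centers exactly on 1 at unselected
  positions, which makes it the reference for recovery checks.

The candidate score is the additive log-fold of a peptide's residues,
$\sum_p \log \mathrm{fold}(a_p, p)$, with ties broken by read count then
alphabetically. It is labeled heuristic in the outputs because the original
selections of this kind were made by eye; the score just formalizes "matches
the positional trends".

**Sampling unit and noise envelopes.** Reads of one library member are not
independent observations of its sequence: the effective number of
independent draws behind a frequency is the Kish effective sample size
$(\sum w)^2 / \sum w^2$ over distinct peptides' read counts
(`effective_sample_size()`). Confidence intervals for individual folds are
therefore bootstrapped by resampling distinct peptides with their counts
(`bootstrap_fold_ci()`), and the recovery tests build their noise envelopes
on the effective sample size with a Bonferroni-corrected 99% band across the
80 off-target cells. Using raw read counts as $n$ would understate the noise
roughly a hundredfold at the default depths.

## Half-life fitting

Chase series (translation shutoff followed by timed sampling) are fitted by
ordinary least squares of log intensity on time: first-order decay makes the
log-linear fit exact, it is stable with the 3–5 time points typical of band
quantification, and it is scale-invariant, so loading normalization conventions
do not matter. $k$ is minus the slope, the half-life is $\ln 2 / k$, and a
non-positive $k$ is reported as stable with infinite half-life. A fitted
rate whose total effect over the observed window is below $10^{-9}$ in log
intensity is snapped to zero so that perfectly flat series are flagged
stable rather than inheriting least-squares rounding noise. Nonlinear
fitting with a plateau term (for substrates with a degradation-resistant
fraction) was considered and left out of the default path: with 3–5 points
it is underdetermined, and the log-linear fit is the field's standard
practice for band intensities.

Ratio distributions are summarized geometrically (mean of log-ratios,
exponentiated, with log-scale SD), matching the log-normal shape of flow
ratios; an arithmetic variant exists for comparison with mean-of-ratio
reporting. Group inference (ANOVA, multiple comparisons) is intentionally
not wrapped — base R's `aov()`/`TukeyHSD()` already do it.

## Problem sizes and determinism

The package's own acceptance runs use 200,000 library variants, $10^6$
cells, a 4% bin and 500,000 reads per sample — a deliberate desk-scale
rendition of a screen with 1.2 million transformants and 13 million sorted
events, large enough that the planted position-1 signal is estimated with
tight intervals while a full run stays around a minute. Smaller unit-test
fixtures use a 20 + 15 + 20 nt geometry to keep the suite fast.

All randomness derives from one top-level seed fanned out deterministically
to per-stage seeds (library, cells, reads per sample); identical
configuration and seed reproduce byte-identical FASTQ and TSV outputs, and
the manifest records the configuration hash so any drift in parameters is
visible.

## Known limitations

* The tFT model is a steady-state idealization; it ignores maturation
  intermediates' photophysics, slow-fluorophore FRET, and expression-level
  dependence of the ratio.
* Substitution-only reads mean indel robustness of extraction is untested by
  construction (indel-bearing reads are dropped by design, not recovered).
* The enrichment model treats positions independently; pairwise couplings
  and motif models beyond whole-peptide regex factors are out of scope.
* Stop-containing peptides' biology (truncation before the reporter) is not
  modeled mechanistically — they are a configurable rate class, flagged and
  kept out of the main matrix.
* Candidate ranking orders peptides by positional trends only; it does not
  estimate per-peptide stability and should be read as a shortlist, not a
  measurement.
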