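---
title: "Models and methods behind syncomstats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind syncomstats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syncomstats)
library(dplyr)
```

# The scientific setting

Gnotobiotic synthetic-community (SynCom) experiments inoculate sterile-grown
plants with a defined mixture of cultured root-derived bacterial strains and
read out the assembled community by 16S rRNA (v5–v7) amplicon sequencing.
`syncomstats` implements the quantitative chain for a two-host design in
which strains isolated from *Lotus japonicus* ("Lj") and *Arabidopsis
thaliana* ("At") roots are paired by bacterial family — each family
contributes one strain from each host — so that the two half-communities are
taxonomically balanced. The questions this chain answers:

* Do strains reach higher relative abundance (RA) on the host species they
  were isolated from (**host preference**)?
* Are established communities resilient to late-arriving strains
  (**priority effects**), and is a strain's ability to invade linked to its
  host preference (**invasiveness**)?
* How much of the culture-independent community does a sequence-indexed
  culture collection actually capture (**recovery**)?

Because the real experiments require deposited sequencing data, every stage
here is paired with a synthetic-data generator whose ground truth is known
exactly; the tests and the acceptance script exercise the pipeline entirely
on generated data.

# The generative model

## Strain panels

`make_strain_panel()` builds `2 * n_per_host` strains in `n_families`
family pairs. Within a family, the two members' reference fragments differ
at 1 to `ceiling(0.03 * seq_len)` positions — distinguishable by exact
matching but similar enough to co-cluster at the 97% OTU level, like real
congeneric pairs. Between families, all sequences differ at
`family_divergence * seq_len` positions or more. The between-family
guarantee is enforced constructively: family backbone sequences are redrawn
until every backbone pair differs at `ceiling(family_divergence * seq_len) +
2 * ceiling(0.03 * seq_len)` positions, so the bound survives the
within-family mutations. All draws descend from one seed, so panels are
byte-reproducible.

## Community composition

For a sample of host $h$ in compartment $c$, strain $s$ has weight

$$w_s = b_s \cdot \phi_c(s, h) \cdot \pi(s),$$

where

* $b_s$ is a per-family **base abundance**, drawn once per experiment from a
  log-normal (meanlog 0, `base_sdlog` = 1) and shared by the two members of
  a family pair. The sharing preserves an exact Lj/At symmetry: with equal
  preference factors the expected aggregated RA of either half-community is
  exactly 0.5, which several tests rely on. The log-normal gives the
  realistic skewed rank-abundance profile seen in real SynCom outputs.
* $\phi_c(s,h)$ is the **host-preference factor**: `phi_root` (scalar or
  per-strain) when $s$ is native to $h$ and $c$ = root, `phi_rhizo`
  (default 1) in the rhizosphere, and always 1 in unplanted soil — the
  preference signal is confined to the root, matching where the biological
  effect is observed. In symbiosis-deficient (`nfr5`) hosts the root factor
  is attenuated to $1 + a(\phi - 1)$ with `nfr5_attenuation` $a \in [0,1]$
  (default 0.5), emulating a reduced-but-present effect.
* $\pi(s)$ is the **priority factor** (`pi_priority`, default 3) applied to
  first-inoculated (resident) strains in sequential designs; mixed-control
  samples have $\pi = 1$ for everyone.

Expected relative abundances are $w_s / \sum_t w_t$; observed counts are
**Dirichlet–multinomial**: a multinomial of size `depth` whose probability
vector is Dirichlet with mean equal to the expected RAs and total
concentration `overdispersion` (default 200; `Inf` recovers the plain
multinomial). This is the standard compositional noise model for microbiome
counts; concentration 200 corresponds to per-strain coefficients of
variation of roughly 30–50% at typical RAs, comparable to replicate
scatter in gnotobiotic systems. Under this model two useful closed forms
hold and are tested: a native strain's expected cognate/other RA ratio
equals `phi_root` exactly (the denominators match because bases are
paired), and the expected resident aggregated RA in a sequential design
with neutral preference is `pi_priority / (pi_priority + 1)`.

The defaults `phi_root = 4` and `pi_priority = 3` are calibration choices
for a regime with a clear but not overwhelming effect; the real per-strain
effect sizes are unknown.

## Reads and culture plates

`simulate_reads()` writes per-sample FASTQ files with exactly `count(s, f)`
copies of each reference fragment, each position independently substituted
at `sub_error_rate` (substitutions only, fixed read length — sufficient to
exercise a perfect-match mapper, which discards any mismatch regardless of
its type). `simulate_irl_plates()` emulates limiting-dilution isolation:
each well receives Poisson(`cells_per_well_mean`) founder cells drawn from
the community RAs, and well reads are multinomial over the founders' OTUs.
The Poisson conditional probability of a single-OTU well given non-emptiness
is the oracle the purity tests check against.

# Strain quantification

`extract_amplicon()` performs in-silico PCR with IUPAC-degenerate primers
(defaults: 799F `AACMGGATTAGATACCCKG`, 1192R `ACGTCATCCCCACCTTCC`), taking
the leftmost zero-mismatch forward match and the leftmost downstream match
of the reverse-complemented reverse primer. The leftmost rule and the
amplicon length cap (default 2,000 nt) make extraction deterministic.

`map_reads_exact()` assigns a read to a strain only when the read is
byte-identical to that strain's reference, full-length. Reads equal to two
or more references are counted as **ambiguous** and excluded rather than
split fractionally or given to a "top hit": at strain level a tie carries
no information about which strain produced the read, and reporting the tally
keeps the loss visible. Equality is strand-aware by default (merged reads
are assumed oriented); `revcomp = TRUE` enables reverse-complement matching,
and `trim` removes a constant-length prefix/suffix first. Mapped + unmapped
+ ambiguous always equals the read count, and `unmapped_summary()` reports
the fractions by compartment/host/experiment with Kruskal–Wallis p-values —
the sanity check that mapping loss is not confounded with the design.
Zero-read samples get missing (not zero) fractions.

# Culture-collection recovery

`greedy_cluster_otus()` is abundance-sorted greedy centroid clustering at
97% global identity (matches / global alignment length; match +1, mismatch
−1, gap opening 4, gap extension 1), with lexicographic tie-breaking so the
result is order-invariant. `filter_well_table()` applies the well and OTU
read filters with **inclusive** boundaries: a well with exactly 100 reads
is kept ("fewer than 100 removed"), an OTU whose best well count is exactly
10 is kept ("at least ten"). `recoverable_otus()` calls an OTU recoverable
when it is the top member of at least one well whose purity (top OTU share)
is ≥ 0.90, boundary inclusive. `recovery_report()` then gives the
percentage of abundant OTUs (RA ≥ 0.1%, inclusive) that are recoverable and
the accumulated natural RA of recovered OTUs; the accumulation covers *all*
recovered OTUs by default, with `abundant_only = TRUE` to restrict it,
since either reading of "accumulated RA of recovered OTUs" is defensible.
Cross-collection comparisons (host A profile against host B's collection)
use the same function with a different recoverable set.

# Community statistics

Relative abundances divide each sample by its total; zero-total samples are
flagged rather than silently normalized. Shannon diversity uses the natural
logarithm (the ecology-package convention). Bray–Curtis, PCoA (classical
scaling; negative eigenvalues are excluded from the variance denominator
and reported separately) and PERMANOVA follow vegan: the PERMANOVA p-value
is `(1 + #(perm F >= obs F)) / (1 + n_perm)` with 5,000 permutations by
default, optionally restricted within strata (e.g. experiment batches).
No rarefaction is applied before diversity; a minimum-depth filter is the
exposed alternative. Variance attribution across design factors is reported
through PERMANOVA R² rather than a constrained ordination — the ordination
is display-layer, the test statistic carries the inference.
`kruskal_dunn()` combines the tie-corrected Kruskal–Wallis test with Dunn's
z-tests on mean ranks, Benjamini–Hochberg adjustment and a compact letter
display (letters = maximal cliques of the not-significantly-different
graph). qPCR bacterial load is $2^{Ct_{plant} - Ct_{16S}}$.

# Host preference and invasion

The **host-preference index** of a strain is the ratio of its mean RA in
root samples of its cognate host over the other host, computed
independently per experiment over competition-context samples (mixed arms
of sequential experiments included). Strains with mean RA below 0.1% in
either host are excluded — the small-denominator guard — with the boundary
value retained, mirroring the other inclusive boundaries. Because filtered-in
strains have strictly positive means, no pseudocounts are needed and the
log transform is always defined.

Significance uses the two-sided Mann–Whitney test per strain (cognate
versus other host per-sample RAs), exact for group sizes up to 8 and
tie-corrected normal approximation above, with BH adjustment across strains
within an experiment (`alpha` default 0.05; the stricter 0.005 used in
some multiple-comparison contexts is available through the same argument,
and the two conventions are deliberately both exposed). All-tied strains
(e.g. absent everywhere) get p = 1 by convention.

The **invasiveness index** is the same ratio computed only from sequential
samples in which the strain's SynCom arrived second. `correlate_indices()`
takes Pearson correlation of the log2 indices — ratios are multiplicative,
so the log scale is the natural one; Spearman is exposed as an option since
the choice is not canonical — and a partial correlation given log2 mean RA,
which operationalizes "the link is not an abundance artefact".
`family_knockout()` removes one family at a time, renormalizes, and
re-tests native versus non-native aggregated RA per host, establishing that
community-level preference is not driven by a single taxon.

# Numerical and testing choices

* Sub-stream seeds: every simulator derives its RNG stream from
  `seed` and a fixed sub-stream index, so modules are independently
  reproducible and never share draws.
* Degenerate inputs error early and specifically: empty panels, overlapping
  resident/invader sets, all-zero vectors in Bray–Curtis, missing features,
  single groups in PERMANOVA.
* Test problem sizes: the simulation-based checks run at the study's scale —
  32 strains, 12 replicate root samples per host, sequencing depth $10^5$ —
  with 100–200 replicate simulations for calibration checks and 1,000
  simulations × 999 permutations for the p-value uniformity checks; these
  sizes give binomial/KS resolution comfortably finer than the effects
  being verified.
* Calibration bands are derived from their stated oracles before freezing:
  the null rejection band is the Binomial(200, 0.05) 95% interval over
  simulations; the null index-correlation thresholds come from the
  n ≈ 32 sampling distribution of Pearson's r (sd ≈ 0.18), whose
  two-sided mass below |r| = 0.3 is ≈ 0.90.
* The shared-factor correlation check uses per-strain preference factors
  2^N(2, 1.5): an attenuation analysis (signal spread vs. the ~0.5–0.8
  log2-unit measurement noise of the two indices at these sample sizes)
  shows the factor spread must dominate the noise for the recovery
  correlation to be informative; milder spreads mostly measure noise.

# What the simulations do and do not show

The generator reproduces the design structure (paired panels, compartments,
inoculation order, replicate structure), compositional overdispersion, and
read-level substitution errors. It does **not** model PCR/primer bias,
chimeras, indels, contamination, nodule compartments, or ecological
interactions beyond the two multiplicative factors — so green tests
demonstrate that the statistics recover the effects they define under a
faithful null/effect model, not that the biological effect sizes in real
data are as simulated. Printed values from the real experiments (e.g.
recovery percentages, the index correlation r = 0.89 reported for deposited
data) require those data and are deliberately out of scope; the pipeline
instead shows the corresponding *pattern* is recoverable at desk scale.

# Known limitations

* Perfect-match quantification discards all mismatching reads; at realistic
  per-base error rates most reads are unmapped (e.g. ≈ 63% at 1% per-base
  error on a 100-nt fragment) — acceptable when depth is high, but the
  unmapped fraction must be monitored via `unmapped_summary()`.
* Greedy OTU clustering is quadratic in the number of unique sequences; it
  is intended for well-table scale (hundreds of sequences), not for raw
  community data.
* The invasiveness index is noisier than the preference index because
  invaders are suppressed by the resident community; correlations between
  the two indices are attenuated accordingly at small replicate numbers.
* Compact letter displays are exponential in the worst case; they are
  intended for the handful of groups in a typical figure panel.
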