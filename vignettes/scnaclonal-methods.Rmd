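---
title: "Models and methods in scnaclonal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in scnaclonal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnaclonal)
```

# Scope

`scnaclonal` analyses clonal copy-number structure in chromosomally
complex tumors from very sparse single-cell DNA sequencing. Droplet
protocols sequence 300–2,500 cells per sample at 0.01X–0.05X coverage per
cell (about 0.02X on average): far too little to genotype loci, but
enough, when reads are pooled into megabase bins, to estimate each cell's
haplotype-specific integer copy numbers. The package covers the full
desk-top path around that idea:

1. **simulate** — a clonal copy-number evolution with full ground truth,
   and sparse binned observations from it;
2. **infer** — per-cell allele-specific copy-number calling from
   read-depth ratios (RDR) and phased B-allele frequencies (BAF);
3. **clones** — grouping cells into clones, excluding noisy cells, and
   building consensus profiles;
4. **metrics** — WGD-aware aberration statistics and locus-level LOH
   classification;
5. **phylo** — a maximum-parsimony interval-event phylogeny of the clone
   profiles;
6. **concord** — cross-sample concordance and correlation of copy-number
   profiles.

Every stage is driven by explicit parameters with defaults chosen for the
osteosarcoma-like regime the package targets: deletion-dominated
karyotypes, ploidies between 1.5 and 4, frequent whole-genome doubling
(WGD), and one dominant clone per sample.

# The simulator

The generator is first-class, tested code: it defines the study
conditions under which every downstream claim is verified.

**Clonal truth.** A rooted clone tree starts at the normal diploid
profile (every bin `(1,1)`). The founder clone receives
`n_truncal_events` interval events; each later clone attaches to an
existing clone (uniformly at random, or in a chain) and receives
`n_private_events` of its own. An interval event picks a chromosome
uniformly, a sub-interval uniformly among those of at least
`min_event_bins` bins, a haplotype uniformly, and a sign: loss with
probability `deletion_bias` (default 0.7, reflecting deletion-dominated
genomes in which 40–100% of the genome is deleted while amplifications
stay below ~40%). Losses that would push a haplotype below zero and
gains that would regain a fully lost haplotype are resampled, so loss of
heterozygosity (LOH) is irreversible by construction. With probability
`p_wgd` one uniformly chosen edge carries a whole-genome doubling
(both haplotypes of every bin times two) before its interval events.
Clone proportions default to a sorted symmetric Dirichlet draw and can be
fixed (the bundled analyses use 0.6/0.3/0.1, a dominant clone with two
subclones in the 5–20% range seen in this tumor type).
`min_private_span` optionally tops up private events until a clone
differs from its parent over a stated genome fraction, which is how the
"private events spanning at least 15% of the genome" condition of the
recovery analyses is expressed.

**Observations.** Each cell draws a label: `normal` (diploid) with
probability `normal_fraction`, `noise` with `noise_cell_fraction`, else a
tumor clone by the clone proportions. Per-bin read counts are Poisson
(negative binomial behind `overdispersion`) with mean proportional to bin
length times total copy number, normalised so a cell's expected total
equals its depth budget `coverage × genome / read_length` times a
lognormal per-cell factor (`depth_sd`). This keeps a closed-form per-bin
mean for tests. SNP-overlapping read totals are Poisson with mean
`snp_density × bin length × local coverage`; the default density of one
heterozygous SNP per 2 kb gives a few dozen SNP reads per 5 Mb bin at
0.02X, matching what phased low-coverage data provide. B-haplotype counts
are binomial with success probability `cnB/(cnA+cnB)` (0.5 in `(0,0)`
bins, where any residual reads are mismapped noise). Noisy cells take a
random clone profile with every bin independently resampled from
`{0..4}²` with probability 0.3 — a caricature of the degraded or doublet
cells that clone identification must reject.

**What the simulator does not model** — and hence what passing tests do
not show about real data: GC and mappability bias, replication timing,
barcode collisions and doublets, phasing switch errors, and focal events
below bin resolution. The caller is validated against this idealised
generative model, not against real sequencing artefacts.

**Genome.** The default coordinate system is 22 synthetic autosomes with
hg19-proportional lengths scaled to 500 Mb in total, tiled with 5 Mb
bins (~110 bins). This keeps simulations fast while leaving every
chromosome at least a few bins so interval events have geometry to act
on; `hg19_autosomes()` supplies the full-scale system (~590 bins at
5 Mb), which the phylogeny analyses use because event-boundary
collisions — two random events landing exactly adjacent and merging into
one parsimony event — are a discretisation artefact that a ~5-bin
chromosome makes common and a ~25-bin chromosome makes rare. The
single-cell bin size itself is a free parameter (`bin_size`); 5 Mb is a
sensible default for 0.02X data, where a bin then collects on the order
of a thousand reads.

# Per-cell copy-number calling

The caller is deliberately per-cell and simple; joint structure across
cells is the clone stage's job, which keeps the two stages independently
testable. This differs from joint single-cell callers, which pool cells
for scaling and clustering decisions.

**Signals.** RDR is the cell's bin read proportion divided by a
reference bin proportion; the reference comes from simulated
matched-normal (diploid) cells when at least five are present, else from
the pseudobulk of all cells — mirroring practice, where the matched
germline sample provides the diploid baseline. BAF is `b_count /
snp_total`, missing where no SNP reads fall; phase is taken as known
(the simulator provides it), so BAF is unfolded and `cnB` always refers
to the same physical haplotype.

**Scale fitting.** Since RDR is proportional to total copy number with
unknown factor, calling reduces to estimating one scale `s` per cell so
that `s × rdr` sits on integers consistent with the BAFs. Candidate
scales start at a ploidy grid (default 1.5–4 by 0.5, the observed range
in this tumor type). Each candidate is refined by two rounds of weighted
least squares against its own implied integer assignment before scoring —
necessary because the correct scale equals the cell's exact ploidy,
which usually falls between grid points; without refinement the doubled
solution (twice the true ploidy, always near an even grid point) would
win. Candidates are scored by the summed per-bin distance between
`s × rdr` and the nearest integer total achievable given the bin's BAF,
weighted by bin length and SNP depth; near-ties resolve toward the
lowest implied ploidy, which is what keeps a perfectly balanced diploid
cell from being called tetraploid. The genome-doubling ambiguity is real
(RDR and BAF are both invariant under doubling), and the tie rule is the
package's explicit, documented resolution.

**Calling.** Per bin, total `t = round(s × rdr)` clipped to
`[0, max_cn]` (default cap 8); the allele split minimises
`|cnB/t − baf|`, with missing BAF giving the most balanced split and
ties resolving toward `cnA ≥ cnB`. Reported ploidy is the
length-weighted mean of called totals, recomputable from the calls.

# Clone identification

Cells are compared by the length-weighted fraction of bins whose ordered
`(cnA, cnB)` pairs differ. Average-linkage agglomerative clustering is
cut at `error_rate` — default 0.12, the clone-identification error
tolerance appropriate for this coverage regime: a cell may disagree with
its clone over up to 12% of the genome before it stops being evidence
for that clone. The clustering algorithm itself is this package's
choice (a k-medoids alternative with silhouette-selected k sits behind
`method = "kmedoids"`); only the tolerance is externally anchored.
Clusters smaller than `min_clone_size` (default `max(5, 1%)` of cells,
sized so a 5–20% subclone of a 300–2,500-cell sample survives while
singleton artefacts do not) dissolve into a NOISY pool; consensus
profiles are the per-bin modal state of member cells with ties resolved
toward the medoid cell's state; and one reassignment pass returns any
NOISY cell within `error_rate` of a consensus. Cells are processed in
sorted-id order, making the output invariant to input order.
`noisy_cell_audit()` reports each excluded cell's nearest consensus and
distance — the control that no coherent rare clone was discarded:
genuinely noisy cells sit far beyond the tolerance from every consensus.

# WGD-aware metrics

The expected (baseline) state of a bin is `{1,1}` in a non-doubled tumor
and `{2,2}` in a doubled one. A profile is flagged doubled when more
than half its genome (length-weighted, threshold configurable) has both
haplotypes at 2 or more — a simple, testable decision rule in place of
the opaque internal heuristics of production callers. WGD is
decided at the tumor level (majority of cells) and applied to all cells,
with a per-cell override for tumors containing a doubled subclone.

Against that baseline: *aberrant* means the unordered pair differs from
the baseline; *deleted* means either allele is below the per-allele
baseline; *amplified* means either allele is above it (so `(2,0)` in a
non-doubled tumor is both). These rules commute with doubling: a profile
exactly twice a non-doubled one has identical deleted and amplified
fractions under its `{2,2}` baseline — an exact identity the tests
assert. The *subclonal* fraction of a cell is the genome share where its
state differs from the dataset's per-bin modal state. Locus status
(e.g. TP53, default hg19 coordinates shipped in `tp53_locus()`)
classifies the length-weighted majority state of overlapping bins as
`no_loh`, `loh` (one allele fully lost, total below baseline), or
`cn_loh` (one allele lost, retained allele at or above the baseline
total — the `{2,0}` states that total-copy-number analyses miss).

# Interval-event parsimony phylogeny

The parsimony unit is the interval event: ±1 copy of one haplotype over
a contiguous bin interval of one chromosome. The minimal number of
events transforming parent into child decomposes per chromosome and
haplotype into the classic segment recurrence — the sum over positions
of the positive increments of the needed per-bin change, losses and
gains counted separately — subject to LOH irreversibility: a haplotype
at 0 in the parent and positive in the child makes the child unreachable.
The implementation is validated exhaustively against breadth-first
search over the literal event graph (all ≤5-bin profile pairs with copy
numbers ≤3, plus random 10-bin pairs), with the BFS allowing
intermediate states above the profile maxima so it does not presuppose
the no-overshoot property it checks.

A whole-genome doubling costs one event and may occur at most once per
root path. On a doubled edge the pre-doubling profile `q` minimising
`events(parent→q) + 1 + events(2q→child)` is found exactly by a small
per-chromosome dynamic program — events before the doubling can be
cheaper than after (a single pre-doubling gain replaces two
post-doubling ones), so "double first" would be wrong.

`reconstruct_tree()` searches two exhaustive candidate families over up
to 8 clones, rooted at the diploid profile: (i) rooted binary
leaf-labelled topologies with unobserved ancestors, initialised per bin
and haplotype by a Sankoff pass with linear cost over the descendant
min–max candidate range (zero excluded wherever a descendant is
positive) and then improved by exact per-chromosome single-node Steiner
refinement — the per-bin initialisation ignores interval coupling, and
an ancestor state that lets an event merge with an adjacent segment can
be globally cheaper; and (ii) clone-attachment trees in which every node
is an observed clone, capturing chains (a clone ancestral to another
clone) without unobserved intermediates. Candidates are scored by exact
edge distances with the doubling placement resolved by a tree dynamic
program; zero-event edges touching an unobserved ancestor are
contracted; ties prefer fewer unobserved ancestors, then enumeration
order, making the output deterministic. The candidate-set restriction is
a documented heuristic bound on full Steiner parsimony; edge replay
(applying each edge's events to the parent reproduces the child exactly)
is guaranteed and tested, and unit-cost ±1 events are the cost model
(a `|delta|`-cost variant would change only relative edge lengths, not
feasibility).

Events on each edge are classified as `gain`; `del`; `loh` when the
affected haplotype ends fully lost over the event interval; `cn_loh`
when, additionally, the retained haplotype sits above the per-allele
baseline over most of that interval after the edge (the joint
loss-plus-gain that produces `(0,2)` from `(1,1)`); and `wgd`.

# Cross-sample concordance

`window_concordance()` restricts to bins where at least one sample is
aberrant under its own baseline and reports the fraction with equal
unordered allele pairs. When exactly one sample of a pair is doubled,
the doubled profile is halved (rounded) first, so a diagnosis/relapse
pair separated only by a doubling compares as concordant; the switch is
exposed because the choice is a modelling decision, not a forced one.
With zero qualifying windows the statistic is undefined (NA), never 0.
Whether "identical assignment" means allele-specific or total copy
number is not externally fixed; the allele-specific mode is the default
for single-cell consensus profiles and rounded totals serve the bulk
path.

For bulk-style comparison, segment tables are rasterised to 1,000 bp
windows of overlap-weighted median total copy number (midpoint at an
exact 50/50 straddle; uncovered windows missing), samples are correlated
with Pearson's r under pairwise-complete handling (`cor()` underneath),
and grouped by average-linkage clustering on `1 − r` with a strict-cut
threshold (threshold 0 keeps every sample separate). The 1,000 bp window
is kept as the bulk-path default and is configurable; it is far finer
than the single-cell analysis grid, which uses the analysis bins
directly. `simulate_sample_panel()` builds the related/unrelated sample
panel (two clones of one truth share its truncal events; clones of
different truths share nothing) on which within-pair correlation is
verified to exceed between-pair correlation.

# Numerical and design choices

* Coordinates are 0-based half-open everywhere internally and on disk
  (BED-compatible); 1-based inclusive input converts via `one_based =
  TRUE`. All outputs are plain-text TSV/Newick/YAML for diffability.
* All randomness flows from one seed through named per-stage substreams;
  reruns are byte-identical, which the tests assert on file checksums.
* Ties are deterministic by stated rules: lowest implied ploidy (scale
  fit), `cnA ≥ cnB` (allele split), medoid state (consensus), fewer
  ancestors then enumeration order (trees), smallest encoded state
  (modal profiles).
* Degenerate inputs have defined behaviour: zero-read cells are dropped
  with a warning, all-missing BAF falls back to an RDR-only objective,
  `(0,0)` bins use BAF 0.5, totals clip at `max_cn` with a message,
  empty concordance denominators yield NA.
* The problem sizes in the test-suite and acceptance analyses — ~110-bin
  scaled genome for calling/clustering work, the ~590-bin hg19-scale
  grid for tree recovery, 1,000 cells and 10 seeds for clone recovery,
  exhaustive 5-bin enumeration for the distance oracle — were chosen
  once as the smallest sizes at which each property is meaningfully
  exercised.
* Tree-recovery analyses condition the simulated truths on
  non-redundant events (the minimal event representation equals the
  generated events, checked on the truth before any reconstruction), so
  "90% truncal share" is well-defined in the same units the
  reconstruction reports; without that conditioning, coincidentally
  adjacent events merge and the generated count overstates the minimal
  one.

# Known limitations

* The caller is per-cell; it will not rescue cells whose individual
  signal is too sparse for an unambiguous scale, and it inherits the
  doubling ambiguity resolved only by the low-ploidy tie rule.
* Exhaustive tree search grows factorially; beyond 8 clones the
  function refuses, and at 7–8 clones it is slow. The candidate-set
  heuristic can in principle miss a Steiner-optimal ancestor
  configuration, though the exact per-edge distances and replay
  guarantee remain.
* At most one doubling per root path is modelled; repeated doublings or
  partial (chromosome-arm) doublings are outside the event taxonomy.
* Metrics and concordance operate at bin resolution; events smaller
  than one bin are invisible by construction.
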