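---
title: "Evaluating single-cell Hi-C data and computing 3D genome structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating single-cell Hi-C data and computing 3D genome structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`schic3d` implements the computational stack used to judge whether a
single-cell Hi-C experiment has produced data good enough to fold into a 3D
genome model, and then to produce that model. It covers four layers:

1. **Read processing** — from paired-end FASTQ to filtered, non-redundant
   chromatin contacts with a complete accounting of read-pair fates.
2. **Contact analysis** — genome-wide binned maps, cis/trans breakdowns, and
   contact-probability versus sequence-separation curves with polymer
   reference slopes.
3. **Structure calculation** — whole-genome particle models computed from a
   single cell's contacts by hierarchical simulated annealing.
4. **Model analysis** — superposition of repeat models by iterative weighted
   SVD and precision summaries as all-particle RMSD ranges.

A synthetic-data generator produces genomes, ground-truth conformations,
proximity contacts and raw read pairs with per-record truth labels, so every
layer is validated without external data.

# The read-processing model

A Hi-C library is a population of chimeric molecules: two restriction
fragments joined at a ligation junction. For an end-filled 5'-overhang
cutter such as MboI (`^GATC`) the junction reads `GATCGATC`; without
end-filling, sticky-end religation regenerates the bare site. The package
derives the junction from enzyme geometry (`junction_sequence()`), so both
protocol families are supported by a flag rather than hard-coded sequences.

Processing one cell (`process_cell()` / `cmd_process()`) runs:

1. **Clipping.** Reads running through the junction are truncated to the 5'
   portion plus the first half of the junction, which restores the native
   restriction terminus; the clipped prefix maps contiguously to the
   reference.
2. **Mapping.** Each end maps independently. The built-in mapper declares an
   end unique iff its full clipped sequence (or reverse complement) occurs
   exactly once in the genome — exact-occurrence semantics appropriate for
   synthetic genomes, implemented as a 16-bp seed scan plus full-length
   verification. For real libraries an external-aligner adapter ingests
   alignments and requires the best score to strictly beat the second best
   (the `-k 2`-style reporting convention). There is no silent fallback
   between backends.
3. **Classification.** Pairs are allocated to primary-enzyme (RE1) fragments
   and classified by the first matching rule: `unmapped`/`ambiguous`;
   `internal` (one fragment, inward-facing — no junction was crossed);
   `circular` (one fragment, outward-facing — self-circularisation);
   `adjacent` (neighbouring fragments — re-ligation); `too_small`/`too_large`
   (inferred molecule size outside 50–5000 bp); else `accepted`. The
   inferred size sums, over both ends, the distance from the mapped 5' base
   to the next cut site in the read's 3' direction, using the secondary
   enzyme's map (e.g. AluI) when one is supplied. Zero-length ties resolve
   to `internal`, as do same-strand same-fragment pairs, which carry no
   junction evidence either.
4. **Support.** Pairs are grouped by the unordered pair of fragment ends
   they connect (a fragment end is chromosome, fragment index, and the side
   the strand points to: `+` ligates at the fragment's 3' cut, `-` at its
   5' cut). Single-pair events are discarded; groups of two or more collapse
   to one contact with `support` = group size. Identical duplicate pairs
   count as support; no separate optical-duplicate handling is attempted.
5. **Promiscuity.** A fragment end joining more distinct contacts than the
   ploidy allows marks *all* its contacts as promiscuous and they are all
   excluded: such ends are evidence of spurious ligation, not a ranking
   problem. The operation is idempotent.

The QC report mirrors the per-cell accounting of a protocol-comparison
table: percent uniquely mapped (of input pairs), percent accepted and
percent promiscuous (both of unique pairs — the "filtered unique" stratum),
contact counts, and the cis <10 kb / cis ≥10 kb / trans breakdown of the
final contacts. Flags encode the working thresholds: >50% unique, ≥50%
accepted, and structure-readiness at >60,000 contacts with >5% trans.

Coordinates are 0-based half-open everywhere inside the package; the NCC
contact dialect (documented in the README) is written 1-based inclusive at
the I/O boundary.

# Contact analysis

`bin_contacts()` tallies contacts on a whole-genome concatenated axis
(default figure style: 5 Mb bins); the sparse upper triangle is stored so
the upper-triangle total equals the contact count.

`contact_probability_curve()` bins cis-contact separations into log-spaced
bins (at least 100 kb wide, starting at 100 kb — below that fragment-scale
artefacts dominate) and divides each bin by the number of available locus
pairs at that separation, because a chromosome of length $L$ offers
proportionally fewer pairs at large $s$. The curve is normalised to unit
sum; only its log-log slope is interpreted, against the polymer references
$\alpha = -1.0$ (fractal globule) and $\alpha = -1.5$ (equilibrium
globule). The slope is fitted by ordinary least squares on log10 midpoints
(`fit_powerlaw_slope()`). The absolute normalisation of published curves is
not reproduced — it is not needed for slope comparisons, and the package
validates the curve by exponent recovery: contacts sampled with a known
pair-level exponent are recovered within ±0.1 at 20,000 contacts.

# Structure calculation

The genome is modelled as chains of particles, one chain per chromosome,
each particle covering a fixed span of sequence. Contacts become flat-bottom
distance restraints between the particles containing their representative
positions; duplicate particle pairs collapse to a single restraint.
Distances are measured in units of the current particle radius:

* contact restraints: flat-bottom harmonic, bounds [0.8, 1.2] radii —
  "contacting chromatin touches";
* backbone bonds between sequential particles: the same flat-bottom form;
* excluded volume: a soft half-harmonic repulsion below 0.8 radii, so
  particles cannot superimpose.

Before structure calculation, `filter_isolated_contacts()` removes contacts
with no other contact within 2 Mb of both ends — single stray ligations
carry no reliable spatial information.

**Hierarchical annealing.** Models start from uniform-random coordinates in
a sphere (radius ∝ particle count^(1/3)) at the coarsest particle size
(default ladder 8, 4, 2, 0.4, 0.2 Mb, then 100 kb). Each stage minimises
the composite cost by annealed steepest descent: at each temperature of a
geometric ladder (5000 → 10, arbitrary units), particles take
force-proportional steps plus Gaussian noise scaled by √T, with per-step
displacement capped for stability; each stage ends in a zero-temperature
quench. Between stages particles subdivide: children are placed by linear
interpolation along the backbone at their genomic midpoints, coordinates are
rescaled by (size ratio)^(1/3) to the finer radius unit, and a small jitter
(0.1 radii) breaks symmetry without destroying the coarse solution.

Two deliberate engine choices deserve explanation:

* **Chromosome-hand branching.** Distance restraints are mirror-invariant
  within a chromosome, so each chromosome's hand is fixed only by its
  trans restraints to the rest of the genome, and a chain can freeze with
  one chromosome's hand inconsistent with the others' — a near-degenerate
  minimum. Because chain-to-chain cost variance swamps the small cost
  difference between hands, the engine resolves hands by a *paired*
  comparison: two stages before the end, each chain branches — for every
  chromosome after the first, a variant with that chromosome inverted
  through its centroid (an intra-chromosome isometry that flips hand) is
  briefly re-annealed and carried through the remaining stages with the
  same stage seeds and subdivision jitter — and the lower-final-cost
  branch is kept. In paired trials the branch consistent with the trans
  data wins by a margin well above the pairing noise.
* **Chain restarts.** Each model is additionally the lowest-final-cost
  result of three independent chains (`restarts = 3`), a safeguard
  against chains that freeze into poor minima for other reasons. Runs
  remain fully deterministic given the seed.
* **No global hand-fixing.** The overall chirality of each model is
  arbitrary; reflections are resolved (and flagged) at alignment time
  instead.

Particles with no contact restraints are retained — positioned by backbone
and repulsion only — and flagged `has_restraint = FALSE`, since regions
without mappable contacts are the least determined parts of any model.
Coordinates stay in particle-radius units; calibration to nanometres is out
of scope.

The defaults (40 temperatures × 200 steps, 1,500 quench steps, force
constants 25/25/50) were chosen so that a toy genome of 2 × 10 Mb at 100 kb
particles (200 particles, 3,000 contacts, 5 models) anneals in under two
minutes while satisfying the engine's physical invariants: monotone cost
decrease, backbone bonds within [0.5, 2] radii, and under 1% of non-bonded
pairs closer than 0.5 radii.

# Model superposition and precision

`align_pair()` superposes two coordinate sets by the Kabsch construction —
weighted centroid centring, optimal rotation from the SVD of the weighted
covariance with a proper-rotation correction — iterated with weights
$w_i = \exp(-d_i^2/\sigma^2)$, where $\sigma$ is the current weighted RMSD,
until convergence (tolerance 1e-6, at most 10 iterations). The Gaussian
kernel with $\sigma$ tied to the current RMSD is this package's choice (any
soft down-weighting of outlier particles behaves similarly), with the
weights floored at 0.1 so that no particle leaves the fit entirely — an
unfloored kernel self-sharpens on the best-agreeing region and can drag
the superposition away from the all-particle optimum. The choice is
validated by the invariants that iteration never inflates the final
unweighted RMSD by more than 5% over a single unweighted pass, and usually
deflates the superposition's sensitivity to poorly determined particles.
Weights affect only the superposition: the reported RMSD is always the
final unweighted all-particle value. Both the model and its mirror image
are aligned and the better fit returned with a `mirrored` flag, since
annealing hand is arbitrary.

`pairwise_precision()` summarises a family of repeat models as the M × M
matrix of pairwise all-particle RMSDs and its min–max range — the
structure's precision. `align_to_truth()` provides the synthetic-validation
view: per-particle deviations of each model from a known conformation.

# The synthetic-data generator

The generator is first-class, tested code; its defaults define the toy
study conditions used throughout the tests.

* `make_genome()` draws uniform-random A/C/G/T sequence (GATC density
  1/256, mean fragment 256 bp — the density of a real 4-cutter digest).
  Default 2 chromosomes × 10 Mb: small enough for minutes-scale runs, large
  enough that 40+ bp reads map uniquely with overwhelming probability.
* `make_conformation()` grows one confined, short-range self-avoiding
  random walk per chromosome (unit step, rejection below 0.8 radii against
  the last 30 particles) inside a territory sphere; territories are offset
  along a line. The density (sphere radius 0.75·n^(1/3)) and spacing (1.2
  territory radii) were chosen so territories are discrete (centroid
  separation exceeds the mean radius of gyration) yet intermingle enough
  that a realistic single-cell share of contacts (≳5–20%) is
  trans-chromosomal.
* `simulate_contacts()` samples particle pairs with probability
  ∝ exp(−(d/r_c)²) among pairs closer than 2·r_c (default capture radius
  1.2 radii — proximity ligation prefers touching loci; the precise kernel
  only mildly affects recovery tolerances). Each contact is realised as a
  ligation between one restriction-fragment end per particle. Ends are
  drawn without reuse, from internal fragments long enough to carry
  junction-spanning reads, and at least two fragments apart for cis pairs —
  so every clean contact is, by construction, classifiable as `accepted`
  and the promiscuity filter is triggered only by labelled noise. Because
  a two-chromosome toy genome has a single territory interface, the trans
  share fluctuates between conformations; `make_structure_cell()` redraws
  the conformation (deterministically) until the ≥5% trans condition of a
  structure-grade cell is met.
* `simulate_read_pairs()` builds chimeric molecules end-filled and ligated
  exactly as the chemistry would (the junction follows the enzyme's
  fill-in flag) and reads 70 bp from both molecule ends, with read offsets
  of 40–62 bp from the junction so reads always cross it and clip to ≥44
  mappable bases. Noise classes construct each filter's trigger geometry
  exactly: same-fragment inward and outward pairs, adjacent-fragment
  pairs, random cross-chromosome ligations with support 2 (they pass every
  filter — deliberately, as uniformly dispersed spurious contacts do in
  real data), shared-end triplets for the promiscuity filter, and
  singleton-support events for the support filter. A truth ledger labels
  every read pair.

What the generator does **not** emulate: sequencing errors, PCR/optical
duplicate structure, amplification chimeras, mappability variation,
copy-number and ploidy complications, and genuinely ambiguous geometry
(reads that straddle category boundaries). Passing its tests therefore
demonstrates that the filter cascade implements its rules exactly and that
structure calculation recovers conformations determined by clean data — not
that real libraries are free of edge cases the filters must arbitrate.

# Numerical choices and degenerate inputs

* Interval conventions: 0-based half-open positions; fragment lookup by
  binary search; the cis split at 10 kb is half-open (9,999 is short
  range).
* Digestion: ambiguity bases never match a site; palindromic sites are
  scanned on one strand (the implementation verifies palindromy and scans
  both strands otherwise).
* Ties: zero-length inferred molecules and same-strand same-fragment pairs
  classify as `internal`; coincident particles during annealing receive a
  random push; alignment of degenerate (collinear) geometry is an error.
* The separation curve requires at least one cis contact at or above
  100 kb; slope fitting requires three occupied bins.
* Structure runs with fewer than `min_contacts` (default 100) after the
  isolation filter proceed with a recorded warning — sparse cells produce
  valid but poorly determined models, which is precisely what the
  precision range is for.

# Problem sizes

The test-suite and acceptance fixtures use a 2 × 10 Mb genome at 100 kb
particles (200 particles), 3,000 clean contacts and 5 models for structure
work, 600 clean contacts plus labelled noise (≈2,200 read pairs) for
pipeline work, and 20,000 sampled contacts for slope recovery; smaller
2 × 2 Mb cells back the unit tests. These sizes were chosen so a full run
completes in a few minutes on one CPU while leaving each statistic
comfortably determined.

# Known limitations

* The built-in mapper is exact-match only; real reads need the external
  aligner adapter.
* Ambiguously mapping contacts are discarded, never rescued.
* The repulsion term is all-pairs O(N²) per step; fine for 10³–10⁴
  particles, not tuned for whole mammalian genomes at 100 kb in this
  implementation.
* Homologue disambiguation (ploidy > 1 structure calculation) is not
  attempted; the ploidy parameter only relaxes the promiscuity filter.
* Model coordinates are relative (particle radii) and unscaled.
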