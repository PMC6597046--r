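---
title: "Curating pedigreed SNP array genotypes: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating pedigreed SNP array genotypes: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedcurate)
```

# The problem

SNP array data for breeding germplasm of outbreeding, clonally propagated
diploid crops (apple, peach, sweet cherry and relatives) arrive with a
characteristic error spectrum: samples of poor DNA quality, unexpected
ploidy (triploids from unreduced gametes, aneuploids), duplicated or
mislabelled samples, wrong pedigree records, systematically miscalled
genotype clusters, sporadic call errors, and markers placed at wrong map
positions. Because every downstream use — parentage, QTL mapping,
haplotype catalogues — leans on Mendelian inheritance through the
recorded pedigree, these defects must be removed in an order that lets
each inheritance principle be applied safely: first make the material
diploid, reliable and correctly related; then enforce Mendelian
consistency marker by marker; then exploit linkage and phase; finally
aggregate to haploblocks and check inheritance again at that level.
`pedcurate` implements that workflow end to end, with a simulator that
generates fully specified cohorts so that every stage is testable
without array data.

The stage order is encoded in `CURATION_STAGES` and enforced by
`run_stage()`: sample QC → SNP filter → duplicates → parentage →
Mendelian consistency → phase/recombination diagnostics → haploblocks →
classification. Running a stage before its prerequisites is an error
(`force = TRUE` is the documented departure).

# Sample quality and ploidy from B-allele frequencies

The B-allele frequency (BAF) of a sample at a SNP is the fraction of
signal attributable to the B allele; a clean diploid clusters at 0, 0.5
and 1. Quality is the fraction of SNPs in the off-bands
[0.125, 0.375] ∪ [0.625, 0.875]: below 0.3% good, 0.3–3% intermediate,
above 3% bad, with boundary values assigned to the milder class (the
defining inequalities are strict). The upper band is taken symmetric to
the lower one.

Ploidy is read from the BAF histogram (0.02-wide bins, 3-bin smoothing,
local maxima holding at least 1% of the mass; these are implementation
choices made for determinism — the method itself does not prescribe a
peak finder). Expected heterozygous positions are `b_copies / ploidy`
(`expected_baf()`): {0, 1/3, 2/3, 1} for triploids,
{0, 1/4, 1/2, 3/4, 1} for tetraploids or diploid sample mixtures, and a
diploid pattern with shoulders at 1/3 and 2/3 for aneuploids. Two
deliberate behaviours:

* A sharp polyploid template match takes precedence over the quality
  gate. A true triploid necessarily has a large off-band fraction, so
  filtering on quality first would relabel every triploid "bad sample";
  a genuinely noisy sample cannot match a sharp template, so precedence
  is safe.
* In the per-chromosome scan only the trisomic heterozygous band at
  {1/3, 2/3} triggers the aneuploid call. The other candidate signal —
  a chromosome with *no* heterozygous band — is indistinguishable from
  an autozygous run, which inbred breeding material produces routinely;
  flagging it would misclassify healthy diploids. Monosomy is instead
  left to `segmental_scan()`, which finds chromosome segments whose
  parent–child error plus double-recombination count exceeds a multiple
  (default 5×) of the individual's genome-wide rate in 20 cM windows.

# Reliable SNP subset

`categorize_snps()` reproduces the five-way regrouping from call
statistics alone: robust (no-call < 5%, all three genotype classes),
two-cluster (no-call < 5%, AB plus one homozygote class), monomorphic
(a single homozygote class), failed (no-call > 50%, and conservatively
the undefined 5–50% band), and null-suspect. A marker whose only
observed class is AB is *failed*, not monomorphic: one observed allele
means one homozygote class; an all-heterozygote marker is a relabelled
cluster, not a monomorphic locus. Cluster-level intensity analysis is
out of scope; the categories operate purely on calls.

Null alleles (alleles producing no signal, so A/null is called AA and
null/null is missing) are detected from verified parent–child duos: a
marker is suspect when opposing-homozygote contradictions occur in at
least three *independent* duos — counted by a greedy cover over
individuals, because a single miscalled homozygous parent contradicts
every opposite-homozygote child at once while a segregating null acts
through several unrelated carriers — and when the marker's missingness
exceeds twice the data set's median (null homozygotes give no call).
Both refinements exist to keep the detector's false-positive rate near
zero in the presence of ordinary call errors.

# Duplicates

Pairwise identity is the identity-by-state fraction over co-called
markers (at least 500 by default); groups are the transitive closure of
pairs above 0.97. The IBS fraction stands in for a relatedness-based
IBD proportion deliberately: for near-identical clones the two agree,
and the threshold is calibrated so known duplicates exceed it.
Resolution follows trueness-to-type: identical records keep the first
id; differing records keep the member whose recorded parents verify;
two unselected seedlings of one family are both targeted for
re-sampling, as it cannot be decided which is true-to-type.

# Parentage verification and search

A parent–child (PC) error is a marker at which parent and child are
opposing homozygotes — for biallelic codominant calls, exactly the "no
shared allele" condition. The parent-parent-child (PPC) test is full
transmission feasibility (one allele from each parent must assemble the
child), which catches both AA × AA → AB and AA × BB → AA; the latter is
invisible to per-parent checks. The PPC count is never below either PC
count (provable from the feasibility table; tested by enumeration of
all 27 genotype triplets).

The PC rejection threshold is calibrated per data set: error counts for
all recorded duos versus 1000 random unrecorded pairs, threshold at the
rounded midpoint of the PC distribution's 99th percentile and the
random distribution's 1st percentile, rejecting counts at or above it,
with a floor of 1 so error-free data confirm rather than reject. In an
inbred pedigree the random set contains full sibs and grandparents, so
the distributions can genuinely touch; the calibration warns when the
chosen percentiles overlap and returns both distributions. The PPC
threshold is 110% of the maximum PPC count among trios whose two PC
relations are confirmed, rounded up.

Parent search ranks candidates below the PC threshold ascending; full
sibs of the child pass that screen structurally and are flagged, never
auto-confirmed. When the co-parent is confirmed, the pipeline re-ranks
by the joint PPC count with that co-parent — PC counts alone tie the
true parent with a shared grandparent in half-sib material. For an
ungenotyped parent whose own parents are genotyped,
`grandparent_test()` counts markers where the child's obligate allele
from that side is absent from both candidate grandparents (the
"AB+AA−AA" configuration contributes one error). A caveat inherited
from the biology: a triploid from an unreduced gamete receives a
parent's full allele set, so that parent's own parents also pass PC
screens — ploidy screening must precede parentage.

# Mendelian consistency by genotype elimination

`eliminate_genotypes()` is a Lange–Goradia-style constraint propagation:
each individual starts with its observed genotype or all three, and
nuclear families are swept until fixpoint, keeping parent genotypes only
if some pair leaves every child a feasible option and child genotypes
only if a surviving pair produces them. Sets shrink monotonically;
empty sets mean inconsistency. Propagation crosses generations (errors
show through ungenotyped intermediates) and handles inbreeding loops
without special cases. On pedigrees of up to 8 individuals the verdict
is tested equal to exhaustive enumeration over all genotype
assignments, on 1000 random pedigrees.

`find_inconsistencies()` localizes conflicts in two passes: a
vectorized family-local screen (duo opposing homozygotes, trio
feasibility) attributing each violation to its minimal edge — the duo
for an opposing pair, the trio otherwise — then elimination with the
locally flagged cells masked, catching cross-generation conflicts,
localized by leave-one-out (and, for multiple independent errors,
greedy) re-elimination. The full minimal conflicting set is reported
rather than attributing the error to one party by convention; a
compatibility summary per marker and per individual mirrors the
conventional consistency-report layout. `resolve_inconsistencies()`
blanks flagged calls — preferring the individual sitting on most
conflict edges at a marker, i.e. a miscalled parent rather than its
twelve children — and iterates to a consistent fixpoint.
`impute_forced()` then fills missing calls whose feasible set is a
singleton; imputation can never introduce a new inconsistency because
the filled genotype was in every relative's surviving combination.

# Phasing and Mendelian-consistent errors

Phasing is deterministic and deliberately conservative — ambiguity is
left unknown, never guessed:

1. **Trio logic.** Slots forced by genotype configurations (child
   homozygous; child heterozygous with a homozygous parent).
2. **Parent het sites from progeny.** For each parent, unphased
   heterozygous sites are oriented by votes from children whose
   transmitted allele and previous informative origin are known,
   requiring a strict margin of 2; the chain runs forward and backward
   independently and only agreeing assignments are kept (labels aligned
   first, as founder homolog labels are arbitrary — the convention is
   "first informative het site's A goes to homolog 1"). A chain flip
   must fool both directions and a 2-vote margin to survive.
3. **Double-heterozygote resolution.** A child site with both parents
   heterozygous is assigned only when the flanking informative origins
   in a parental meiosis agree on both sides; when the two parents'
   implied alleles coincide (both A or both B) the cell is recorded as
   a phase anomaly — such conflicts concentrate exactly where a
   genotype cluster was relabelled.

Recombination events are origin switches between consecutive
informative markers; a switch before the first informative marker is
undetectable by definition. Double recombinations are consecutive
events bracketing a deviant segment shorter than 10 cM (the
configurable window); a single-marker deviant segment is a singleton,
the signature of a Mendelian-consistent call error. On error-free
simulated cohorts the detected count per meiosis never exceeds the true
crossover count, and at least 99% of event intervals contain a true
crossover — the residue is true double crossovers falling between
informative sites, irreducible for interval-based detection, mirroring
the acceptance of verified true singletons in curated data sets.

Cause classification ranks the curation worklist: markers with signals
(singletons plus phase anomalies) in several individuals come first;
among them, a clear heterozygote excess over the Hardy–Weinberg
expectation marks a relabelled cluster (which simultaneously depletes
opposing-homozygote counts — the "suspiciously few errors" signature),
and its absence marks a wrong map position (a mispositioned marker
switches origin in exactly the meioses recombining between its stored
and true location). Markers with extreme heterozygote excess (> 0.2)
are cluster suspects even without recombination signals: a fully
relabelled homozygote class can leave no informative meiosis at all.
Isolated singletons rank last, ancestors before seedlings, and are
retained as possible true double crossovers. `evaluate_map_move()`
accepts a candidate reposition only if the total double-recombination
count strictly decreases and no meiosis gains one.

`resolve_phase_conflict()` implements the family-wide repair rule: when
most progeny of one parent share a singleton at a marker and one or two
informative sibs do not (those carrying the genuine recombination), the
exceptional sibs' calls at the pivot are blanked. Under this package's
own phasing that state is essentially unreachable — the margin-2
two-directional vote never lets one recombinant child orient a parent —
so the operation matters mainly for phase data imported from elsewhere;
it is tested against constructed diagnostic input.

# Haploblocks and haplotypes

Haploblocks are map segments with no observed recombination in selected
material (cultivars, selections, parents). Borders are placed
sequentially, smallest recombination interval first; an event whose
interval already contains a border is skipped (one border can account
for overlapping events), otherwise the border goes at the interval's cM
midpoint, snapped to the nearest marker gap, ties toward the lower-cM
side. The resulting cut set partitions every linkage group; by
construction no selected-material event lies strictly inside a block
(property-tested on random event sets). `split_block()` handles the
discovery of a within-block recombination in (possibly
ungenotyped-progenitor) selected material.

Haplotypes are integer-coded per block, codes assigned in order of
first appearance scanning individuals in input order (maternal slot
before paternal) so coding is deterministic. Strings with unknown
alleles stay codeless until `resolve_missing_haplotype()` matches them
against the transmitting parent's two haplotypes: a unique match is
adopted; two matches are decided by the nearest flanking block where
the inherited parental homolog is identifiable (minimizing
recombination); otherwise the slot stays unresolved. Converting the
coded matrix back to phased alleles reproduces the input at every
resolved position (tested).

The haploblock-level Mendelian check generalizes genotype elimination
to multi-allelic codes with one essential tolerance: a child code
absent from a parent is accepted if it is a single-crossover
recombinant of that parent's two haplotypes, because blocks are
recombination-free for *selected* material only and unselected
seedlings legitimately recombine inside them. Cross-generation
elimination runs for blocks with at most 8 distinct haplotypes (the
genotype space grows quadratically in the allele count); the local trio
screen runs for every block. Blocks whose codes contradict the
underlying SNP calls are reported with the offending marker and
individual — haplotype curation catching residual call errors.

# SNP classification

Each marker receives one type by precedence 7 > 6 > 5 > 4 > 3 > 2 > 1:
failed/removed (7), monomorphic (6), unmappable (5), null allele (4),
extra clusters (3), a relabelled cluster or ≥ 5% call editing (2),
clean (1). Retention is recorded separately from type: a null-allele
marker may be retained in one crop and excluded in another, and the
type describes the cluster phenomenon, not the decision. The run
manifest records the stage order and a telescoping retained/discarded
ledger (markers in = retained + discarded at every stage).

# The simulator

`simulate_population()` generates founders with per-marker B-allele
frequencies uniform on [0.1, 0.5] (guaranteeing informative markers),
multi-generation pedigrees built from full-sib families whose parent
pairs are sampled with reuse from the previous generation (producing
the half-sib structure of breeding germplasm), and meioses under the
Haldane model: crossover counts Poisson(length/100), positions uniform,
no interference. Interference would only reduce the background of true
close double crossovers, so its omission is conservative for singleton
diagnostics. Every meiosis, founder haplotype and injected error is
recorded in a truth ledger keyed by locus, so recovery can be scored
exactly; identical configuration and seed reproduce the cohort
bit-for-bit.

Injected error types mirror the observed taxonomy: uniform random
miscalls; cluster shifts relabelling the *major* homozygote class AB
for all individuals (the canonical mis-identified-cluster phenomenon;
shifting a rare class would corrupt ~1% of calls and be neither
detectable nor representative); null-allele markers with the silent
allele segregating from founders at frequency 0.2; wrong parent
records; duplicate columns with independent miscalls; triploids
receiving an unreduced crossover-bearing diploid gamete; bad-quality
samples (extra missingness, miscalls, BAF noise s.d. 0.12 against 0.02
for good samples); segmental deletions turning one segment hemizygous.
BAF is the true B-copy fraction plus truncated Gaussian noise.

The default validation scenario is 3 generations (12 founders, 8
families of 12 per generation, ≈ 205 individuals), 5 linkage groups of
100 cM × 200 markers, 1% miscalls, 2% cluster-shift markers, two wrong
parents, one duplicate pair, one triploid, two bad samples. Family and
founder counts are chosen once as realistic breeding-program values.
Test problem sizes elsewhere (e.g. 2–3 linkage groups, 60–400 markers
per group) are scaled to what each property needs.

What the simulator does *not* emulate — and hence what passing tests do
not show about real data: raw intensity space and cluster geometry (BAF
is generated directly from copy numbers; real cluster distortions are
messier than a clean class relabel), genotyping batch effects, crossover
interference, mutation and gene conversion, and population structure
beyond the explicit pedigree. Null-allele intensity signatures
(depressed total signal) are likewise outside the model; only their
call-level consequences are simulated.

# Numerical and degenerate-case choices

* Marker order ties broken by (linkage group, cM, bp, marker id);
  borders and phasing depend on a total order.
* Off-band and quality boundaries: values exactly at 0.3% / 3% go to
  the milder class; peak-template tolerance 0.05 BAF units.
* `pairwise_identity()` with fewer than `min_shared` co-called markers
  returns NA with a warning rather than a noisy estimate.
* `calibrate_pc_threshold()` never returns below 1; `overlap = TRUE`
  signals that the percentile bands touch.
* Map interpolation beyond terminal anchors extrapolates on the local
  slope, flags the result, and an optional cM cap declares distant
  targets unplaceable (type-5 candidates); linkage groups with fewer
  than two anchors are unplaceable.
* Zero-rate simulation reproduces the clean data exactly; empty inputs
  (no events, no duos, no flags) return empty, typed results.

# Known limitations

* Phasing trades completeness for correctness: roughly 1–2% of slots in
  dense double-heterozygote runs stay unknown, and meioses of parents
  with a single genotyped child are mostly uninformative.
* The null-allele detector requires several independent carrier
  families; rare nulls (or nulls in small cohorts) fall below its
  evidence threshold by design, and its power at frequency 0.2 is
  partial rather than complete.
* The map-suspect call identifies markers, not target positions;
  `evaluate_map_move()` verifies a candidate but the candidate comes
  from the analyst (or an external map).
* Multi-location markers (mapping to different places in different
  families) are only reachable through the map-suspect route, not
  modelled explicitly.
* All thresholds are calibrated on, and defaults chosen for, dense
  biallelic array data on diploids; the machinery does not extend to
  polyploid genotype calling itself (polyploids are detected and
  excluded, not curated).
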