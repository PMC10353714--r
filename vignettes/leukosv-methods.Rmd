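---
title: "Methods: somatic SV integration and recurrence analysis in BCP-ALL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic SV integration and recurrence analysis in BCP-ALL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`leukosv` implements the downstream analysis of an optical genome mapping
(OGM) workup of pediatric B-cell precursor acute lymphoblastic leukemia
(BCP-ALL), for the two most common subtypes: *ETV6::RUNX1*-translocated and
classical hyperdiploid (HD) leukemia. OGM calls structural variants (SVs)
from two independent pipelines — the de novo assembly (DN) and the more
VAF-sensitive rare variant pipeline (RVP) — plus a copy-number (CN) track
that contributes only large (>= 5 Mb) gains and losses. The package merges
these callsets per sample, removes germline events using the matched
non-leukemia sample, applies probe/size/blacklist filters, and then asks
cohort-level questions: which regions recur, which genes carry combined
SV + SNV "double hits", which copy-number risk profiles apply, which
translocations could produce fusion transcripts, and how the OGM callset
compares with conventional diagnostics (karyotype, FISH, SNP-array).

All intervals are 0-based half-open internally (BED arithmetic); the TSV
dialects on disk are 1-based inclusive, as coordinates are printed in
reports, and are converted on read and write. Printed event sizes are never
trusted: the reader recomputes the size from the coordinates, because
printed kilobase values routinely disagree with the printed span.

# The matching predicate

Nothing downstream works without a definition of "the same SV seen twice".
No public, exact specification of the dual-annotation windows used by the
OGM vendor software exists, so the predicate here is an explicit,
configurable contract (`match_params()`):

* type classes must be compatible — deletions pool with copy-number losses
  and duplications with gains; insertions, inversions and the two
  translocation classes only match themselves;
* interval calls match when the reciprocal overlap is >= 0.5 **or** both
  breakpoint distances are within the platform-pair tolerance
  (20 kb between two OGM callsets, 50 kb between OGM and array);
* interchromosomal translocations match when both breakend pairs agree
  within tolerance on matching chromosomes (in either order);
* karyotype and FISH events match at cytoband resolution: the reference
  band interval extended by one neighboring band.

Merging is deterministic: callsets are canonically sorted, candidate pairs
are generated with interval trees (GenomicRanges) padded by the largest
tolerance, then verified exactly, and assigned greedily one-to-one by
descending overlap with leftmost tie-breaks. The coordinates of a merged
DN/RVP pair are taken from the DN member, which is the primary assembly;
provenance records both callers. Greedy assignment is compared against
optimal bipartite matching in the test suite on instances drawn from the
dual-pipeline noise model (one callset a jittered replicate of the other
plus private extras); on that population it attains the optimum in
>= 99% of instances. On adversarial dense piles of mutually overlapping
intervals a greedy matcher can be suboptimal; such inputs do not arise
from per-sample SV callsets, which are sparse at genome scale.

# Filtering

Thresholds are inclusive and live in `pipeline_config()`:
array deletions/duplications need >= 20 probes and >= 50 kb; copy-neutral
LOH segments need >= 5 Mb; OGM calls need >= 500 bp (the platform's
resolution floor); translocations have no length and bypass size rules.
Focal calls overlapping immunoglobulin/T-cell-receptor loci, centromeres
or reference gaps are removed with a machine-readable reason
(physiological V(D)J rearrangements and alignment artifacts). Large and
whole-chromosome events are exempt from the blacklist overlap rule: an
arm-to-arm duplication or a trisomy necessarily crosses its centromere and
is not a centromeric artifact. The 5 Mb boundary separates focal from
large SVs throughout; spans covering >= 95% of their contig are treated as
whole-chromosome (aneuploidy) events.

# Minimal altered regions

Recurrence is patient-level: pass-filter somatic focal deletions,
duplications and insertions (SV type deliberately ignored, insertions as
1 bp-padded points) are clustered per chromosome by single-linkage
any-overlap, and each maximal subset of calls with a non-empty common
intersection becomes a candidate region; candidates supported by >= 3
distinct patients are reported as minimal altered regions (MARs), the
intersection of their supporting spans. The maximal subsets are found by
an elementary-segment sweep over the breakpoints, which is provably
equivalent to exhaustive subset enumeration (each maximal subset is the
cover set of some elementary segment) — the test suite asserts this
equivalence directly. A simple leftmost greedy split would miss
right-anchored maximal subsets (for spans A = [0,10), B = [5,20),
C = [15,30) both {A,B} and {B,C} are maximal); the sweep reports both.

MARs are annotated with target genes (gene body or promoter overlap;
the promoter is a strand-aware 2 kb window upstream of the 5' end —
conventional, configurable, and deliberately simple), or with the nearest
gene within 20 kb and a signed distance (negative = upstream), or as
intergenic-distal. A MAR is subtype-specific iff all supporting cases
share one subtype.

# Integration rules

**Double hits.** A gene in a patient is a double hit when at least one
somatic SV overlaps it (body, promoter, or a translocation breakend inside
it) and at least one somatic SNV/indel lies in the gene body. SNVs are
located positionally against the same gene models as the SVs, so the two
evidence streams cannot disagree about gene extents.

**IKZF1plus.** The poor-prognosis profile is a pure boolean of the
somatic deletion set: a deletion overlapping *IKZF1*, and one overlapping
*CDKN2A*, *CDKN2B*, *PAX5* or the PAR1 region, and none overlapping *ERG*.
PAR1 is a named interval record, not a gene. Whether the co-deletions must
be clonal is not specified anywhere authoritative; the rule is therefore
evaluated regardless of clonality and a `subclonal` flag is attached when
the best *IKZF1* deletion VAF is < 0.1, leaving interpretation to the user.

**Hyperdiploid risk.** Poor risk iff (no trisomy 17 and no trisomy 18) or
(trisomy 17 or 18 together with trisomy 5 or 20), over the per-chromosome
copy-state map. "Trisomy" is implemented as copy number >= 3: HD genomes
are gain-rich and the rule is about the presence of gains, so tetrasomy
qualifies. "Either 17 or 18" is read as inclusive-or; the exclusive
reading is available behind `hd_trisomy_exclusive` since the source
wording is ambiguous.

**Fusions.** OGM has label-scale breakpoint resolution, so fusion calls
are approximations by construction. For a translocation, genes overlapping
each breakend (or within 10 kb) are paired across the junction; a pair is
orientation-compatible when the retained sides and strands admit a
head-to-tail transcript. Compatibility is orientation-level only — no
codon-phase check is attempted, because the breakpoints are not exact.
Every candidate is labeled `putative`.

# The Mann-Whitney U convention

Subtype burden comparisons use a rank-sum test with midranks. For
nx + ny <= 12 the permutation distribution of U is enumerated exactly,
including under ties; the two-sided p-value is
P(|U − nx·ny/2| >= |u − nx·ny/2|), valid because the permutation
distribution is symmetric about nx·ny/2 under group-label exchange.
Larger samples use the normal approximation with tie-corrected variance
and continuity correction. `stats::wilcox.test` serves as an independent
cross-check in the tests (it cannot do exact inference under ties, which
is why the enumeration is implemented here). Reported percentages round
half-up (base `round()` is round-half-even), and fold changes are
reported at one decimal, half-up — the reporting conventions of the field.

# The cohort simulator

No patient data accompany the analysis, so the simulator is the package's
source of ground truth; its defaults *are* the study conditions and are
not tuned per run:

* 30 + 30 tumor/normal pairs; tumor blast fraction Uniform(0.70, 0.95);
  clonal somatic VAF ≈ blast/2; 15% of focal events subclonal with VAF
  Uniform(0.05, 0.20).
* *ETV6::RUNX1* tumors all carry the t(12;21) hallmark; 9/30 carry a
  3-way variant. HD tumors draw per-chromosome gains: tetrasomy 21 in
  29/30 (else trisomy), chromosome 14 always gained (tetrasomy in 6/30),
  the classic HD set {4, 6, 10, 17, 18} at probability 0.8, X at 0.6,
  5 at 0.10 and 20 at 0.15 — the last four are config defaults because no
  authoritative per-chromosome frequencies exist for them.
* Focal-deletion burdens are negative binomial (overdispersion consistent
  with the wide observed ranges): size 3 / mean 14.5 for *ETV6::RUNX1*
  (median 13, 99th percentile 43) and size 2.5 / mean 4.6 for HD
  (median 4, 99th percentile 16), truncated at >= 1. Background deletion
  sizes are log-normal with median 40.5 kb on [1 kb, 3.6 Mb].
* A recurrent-gene panel assigns per-case deletion probabilities
  (*ETV6* 0.27, *CDKN2A* 0.23, *PAX5* 0.22, ..., plus
  *ETV6::RUNX1*-specific genes such as *BTG1* 0.33 and *GPRC5A* 0.17);
  panel hits are full-gene deletions with 2–30 kb flanks and count toward
  the negative-binomial burden total. SNV/indel counts are negative
  binomial with medians ≈ 17 (long-tailed) and ≈ 13 per subtype, with
  subtype-specific gene weights (*NRAS*, *KRAS*, *CREBBP*, *FLT3*, ...).
* Germline SVs: Poisson(40) small events per genome, shared by tumor and
  normal.

**Caller emulation.** Each platform model drops event types it cannot
call, events below its detection limit (OGM 500 bp; low-density array
50 kb; high-density array 1 kb; karyotype 10 Mb), and events in its blind
regions (centromeres for OGM; a low-probe-density *IKZF1*-like gap for
the arrays). Surviving events are emitted with a probability that is
non-decreasing in VAF and size; the DN model additionally enforces a 0.15
assembly VAF floor that RVP does not have, which is what makes subclonal
events RVP-only. Emission draws are keyed by a hash of
(event id, platform) mixed with the run seed, so a germline event is
jointly emitted or jointly dropped in tumor and matched normal — without
this coupling, germline-subtraction tests would be flaky by construction.
Breakpoint jitter (SD 3 kb for OGM, one probe gap for arrays, scaled down
for events smaller than four jitter SDs) is keyed with the sample role so
the two assays of a pair differ realistically but stay within matching
tolerance. False calls are appended at low per-sample rates (0.1 DN,
0.3 RVP), reflecting that most artifacts are pipeline-private.

**What the simulator does not model.** No sequence-level data (no reads,
no molecules, no labels), no clustered fragile-site hotspots, no clonal
phylogenies, no copy-number-dependent VAF shifts, no batch effects.
Passing recovery tests therefore demonstrates that the pipeline's logic is
correct under realistic noise and detection asymmetries — not that it
would achieve the same recall on real OGM exports.

# Problem sizes and numerical choices

The bundled annotation is a synthetic, internally consistent stand-in
(real GRCh38 contig lengths; synthetic cytobands, gene models and
blacklist with key loci placed at their published coordinates); it is
labeled `*_synthetic` and is not a substitute for a real annotation in
production use. The recovery analyses run on the 30 + 30 cohort
(~120 assays, ~3,500 truth events), which keeps the full suite within a
couple of minutes on one core while leaving every per-case statistic at
the cohort's actual scale. Determinism: identical configuration and seed
give byte-identical outputs; permuting input row order never changes a
result (canonical sorts precede every greedy step); ties break leftmost.
Degenerate inputs are defined: empty callsets flow through every stage,
a Mann-Whitney test on all-identical values returns p = 1, and an
all-empty concordance input is an error rather than a silent zero.

# Known limitations

* The matching predicate is a declared contract, not a reconstruction of
  the vendor's internal windows; concordance numbers on real data will
  shift with `match_params()`.
* MAR detection has no background model (no GISTIC-style significance);
  recurrence is a plain >= 3-case count, so large cohorts will surface
  passenger regions.
* Fusion candidates are orientation-level approximations; reading-frame
  preservation is not assessed.
* CNN-LOH enters only through the array track; OGM cannot see it.
* The copy-state map reduces each chromosome to one integer; segmental
  aneuploidy mosaics are out of scope.
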