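---
title: "crefam: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{crefam: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crefam)
```

`crefam` packages the analysis chain used in comparative studies of plant
gene families — meta-expression, co-expression, promoter cis-element
comparison, distance phylogenetics, and interaction networks — together with
a ground-truthed synthetic-data generator. This vignette documents the
underlying models, the tunable parameters and why their defaults are what
they are, the numerical conventions, and what the synthetic data do and do
not establish about real data.

## Meta-expression and pattern classification

The expression container is a genes × samples matrix of log2-normalized
intensities plus a sample → tissue map. Missing values are disallowed by
construction: array compendia are complete per probe, and a probe absent
from a platform is represented as an absent row, never as zeros or NA. Tissue
profiles are arithmetic means of a gene's samples per tissue.

Field usage ("seed-preferential", "ubiquitously expressed", "very low level
overall") is descriptive rather than algorithmic, so the classification rule
is a design choice of this package:

* **suppressed** — every tissue mean below `floor` (default 6 log2 units, a
  level near the lower end of the 5–15 saturation range of a typical
  two-color-normalized array compendium);
* **tissue-preferential** — max tissue mean minus the *median of the
  remaining* tissue means at least `delta` (default 2 log2 units, i.e. a
  four-fold gap); the preferred tissue is the argmax, with ties resolved to
  the lexicographically smallest tissue label so calls are invariant to
  column order;
* **ubiquitous** — everything else.

Max-versus-median-of-rest was chosen over max-versus-second-highest because
it tolerates a gene being high in two related tissues (e.g. root and seed
embryo) while still flagging the dominant one, and over mean-based scores
because it is robust to a single outlying tissue. The score is reported for
every gene, so users can re-threshold without re-computation.

## Co-expression

Co-expression uses the Pearson product-moment correlation between sample
profiles (not tissue means: replicate-level structure carries information).
Constant profiles raise an explicit error rather than a silent NA or 0 —
a constant probe is a data problem the caller must see. `top_k_coexpressed`
ranks all other genes by PCC against a bait and returns the k best, with
exact ties broken by lexicographic gene id for determinism. qPCR helpers
implement the 2^−ΔCt and 2^−ΔΔCt quantifications.

## Promoter scanning

Cis-elements are named IUPAC degenerate consensi (the 13 shipped defaults
are classic plant elements: four ABA-responsive ABRE variants, the
TATCCA(Y) alpha-amylase/sugar-response elements and a GA-down element on the
seed/endosperm side; GA-responsive elements, a root-nodule organ-specific
element and two WUSCHEL-type homeobox elements on the root/embryo side).
Scanning conventions, each of which is configurable where ambiguity exists
in common practice:

* both strands by default — plant promoter elements are routinely annotated
  orientation-independently; presence for incidence purposes is ≥ 1 hit on
  either strand;
* all overlapping windows are counted, otherwise frequency ranking is
  ill-defined (`AAAA` scanned with `AA` has 3 hits);
* `N` in a *sequence* is missing data and matches nothing, including a
  pattern `N` (the underlying Biostrings matcher would let N match N; hits
  whose matched window contains a non-ACGT base are filtered out);
* coordinates are 0-based half-open internally; reports use the ATG-relative
  convention (−1 = base immediately upstream of the ATG).

Promoter regions are 2-kb upstream sequences, optionally extended by a first
intron/exon segment whose length is recorded in the BED regions file.

## Group-common and group-unique CREs

A motif is *common* to a promoter group when present in every member —
the only reading under which common-set sizes of 65 and 50 with 40 shared
give 25 and 10 unique elements across groups of five and six promoters.
Presence is ≥ 1 hit, not a count threshold. `compare_groups` is pure set
algebra over motif identities (positions are reported but not compared), and
a quorum mode (`⌈q·|G|⌉` members) is available for noisier data. The
monotonicity property — adding a member can only shrink a common set — is
tested.

## Phylogeny

Distances are p-distances under **complete deletion**: any column with a gap
in any row is removed for *all* pairs, so all pairs share one retained
column set. p-distance is not additive nor a metric; triangle violations
are permitted and not asserted. Neighbor joining follows Saitou–Nei on the
Q-criterion and is exact (topology and branch lengths) on additive inputs —
verified against matrices derived from random trees at tolerance 1e-9.

Numerical conventions:

* Q-matrix ties are broken toward the pair whose subtrees contain the
  lexicographically smallest taxon ids. Ties are real in bootstrap
  replicates (p-distances are discrete), so supports are invariant under
  order-preserving relabelings only — an arbitrary relabeling can flip which
  degenerate resolution is chosen.
* Negative branch-length estimates are clamped to 0 with the deficit
  transferred to the sibling branch, preserving the path length between the
  joined nodes.
* Bootstrap replicate r draws its columns under seed `seed + r`, so results
  are reproducible and independent of execution order; supports are the
  fraction of replicate trees containing each internal split of the
  full-alignment tree.

The package consumes pre-aligned FASTA. Multiple alignment itself is out of
scope: it is a solved upstream step (ClustalX/MAFFT-class tools), while the
distance/NJ/bootstrap chain is what the analyses here depend on. Subgroup
assignment gives each taxon the label of the path-length-nearest exemplar
and reports per-label monophyly (whether the label's taxa form an unrooted
split). Percent similarity between two proteins is computed from a global
Needleman–Wunsch alignment (BLOSUM62 by default) as positive-scoring columns
over all alignment columns, gaps included in the denominator.

## Interaction network

Interaction tables are consumed as hub/partner edge lists (database exports
in the style of interolog predictors); re-predicting interologs is out of
scope. The graph is undirected and simple — self-edges are dropped with a
warning, duplicate rows collapse into one edge with recorded multiplicity.
Node classes come from a fixed 11-label vocabulary (redox, amino-acid
metabolism, cell cycle/lipid/photosynthesis/development, DNA synthesis and
repair, protein degradation/PTM, RNA/transcription, signaling, abiotic
stress, transport, unknown, other). The co-expression overlay annotates each
edge with the PCC of its endpoints' profiles; the `coexpressed` flag is a
*strict* `PCC > 0.5` (a PCC of exactly 0.5 is not flagged), and an edge
with an endpoint missing from the expression matrix carries `NA` ("no
data"), never `FALSE`. Exports: SIF (`pp` interaction type), GraphML (all
attributes; logical NA flags travel as numeric NaN and are restored on
re-import), and node/edge TSVs with `NA` as the explicit missing token.
The hub summary reports distinct-partner degrees, the distinct-partner
union (union ≤ Σ degrees, equality iff partner sets are disjoint) and the
raw interaction-row count, since database exports are quoted in both
currencies.

## The synthetic-data generator

`synth_config()` fixes the simulated study conditions; one seed makes every
artifact byte-identical. Defaults: six tissues (leaf, shoot, root, flower,
pollen, seed), 6 replicates per tissue (a desk-scale stand-in for a
983-array compendium), intensities clipped to [5, 15] log2 units mimicking
array saturation, 2-kb promoters at GC 0.44 (typical of rice promoter
regions; the true background statistics of rice promoters are not pinned
down, so this is a free parameter), promoter groups of five and six genes,
four hubs of degrees 60/16/3/3 with 12/3/2/0 co-expressed partners, and a
4-clade × 5-taxon protein family.

**Expression.** Preferential genes are flat baselines (uniform 7–10) plus an
`effect_size` boost (default 4 log2) in the preferred tissue, plus two
planted-structure components: a per-tissue jitter (`tissue_profile_sd`,
default 0.75) giving each gene a multi-tissue signature, and a per-sample
condition response (`condition_sd`, default 1) reflecting that compendium
arrays are heterogeneous beyond tissue of origin. Members of a planted
co-expression block share one realized profile *and* one realized condition
response and differ only by i.i.d. noise (`noise_sd`, default 0.5); that is
what makes a block identifiable against unrelated genes preferential for
the same tissue, whose signatures and condition responses are independent.
With only six tissue means and no condition structure, same-tissue genes
would be statistically indistinguishable from block members — a genuine
property of low-dimensional profiles, not an implementation artifact. Both
structure components are disabled when `effect_size = 0` (no planted
structure at all). Suppressed genes sit uniformly in [5, 5.8], below the
classification floor.

**Promoters.** Backgrounds are i.i.d. nucleotides at the configured GC —
the simplest model under which per-motif false-positive rates are
analytically computable (`motif_presence_bound()` gives the union bound:
windows × per-window probability, both strands, capped at 1). Each group's
planted motifs are inserted once per promoter at recorded positions, as
uniform draws from the consensus expansion. Cross-group purity is enforced
by rejection-resampling the offending *background* window whenever the other
group's motif matches by chance; planted windows are never edited (editing
them would silently break planting truth), and a chance hit straddling a
planted window triggers a full re-draw of insert positions. Planting truth
is therefore exact and assertable: every planted motif occurs in every
promoter of its group and never in the other group's.

**Proteins.** A true tree of 4 clades (random binary within-clade subtrees,
branch lengths ~0.05 substitutions/site; stems of 0.4) hangs off a central
multifurcation. Sequences evolve by per-site Poisson substitution counts
with uniform replacement over the other 19 residues — adequate for
topology-recovery testing; empirical substitution matrices and indels are
deliberately out of scope, which also means the emitted sequences are an
alignment by construction.

**Interactions.** One hub per configured degree with disjoint partner sets
by default (an overlap fraction is available); rice-locus-style ids; classes
drawn from the 11-label vocabulary; three partners flagged as functionally
characterized. `gen_network_expression` engineers profiles so that exactly
the configured number of partners per hub exceeds PCC 0.5 (co-expressed
partners are noisy copies of the hub profile, re-drawn until PCC > 0.55;
all others are residualized against the hub profile, pinning their PCC at
~0), so overlay counts are exact by construction.

**What passing on synthetic data does not show.** The generator omits
probe-level effects, normalization artifacts, correlated background
composition (CpG islands, TA-richness near the TATA region), motif
positional preference, indel evolution and rate heterogeneity, and
database-scale motif catalogues (tens of motifs here versus hundreds in
PLACE/PLANTPAN-class catalogues, whose common-set sizes are therefore much
larger). Results on real data depend on those catalogue versions and on the
upstream normalization; the synthetic results validate the *algebra and
algorithms*, not any particular biological conclusion.

## Problem sizes and runtime envelope

The shipped test-and-acceptance workloads use: 200-replicate promoter
planting runs (2-kb promoters, groups of 5 and 6), 1000 random 2-kb
sequences × the 13-motif library for scanner/oracle equivalence, 100 random
additive matrices (4–8 taxa) for NJ exactness, a 20-protein 4-clade family
with 500 bootstrap replicates, and 100 compendium seeds (200 genes × 36
samples) for block/classification recovery. These sizes give stable
percentages while keeping a full run in minutes on one CPU; all of them
scale linearly if larger studies are needed.

## Known limitations

* The classification rule is a formalization choice; other defensible rules
  (z-score-based specificity, entropy measures) will call borderline genes
  differently. The reported score allows re-thresholding.
* NJ tie resolution is deterministic but label-dependent (see above); for
  additive or generic inputs ties do not arise.
* `group_common` in all-members mode is brittle to a single false-negative
  promoter hit; the quorum mode is the escape hatch.
* The union bound on background motif presence is loose for short motifs
  (it caps at 1 well before a 6-mer's true presence probability does), so
  contamination assertions built on it are conservative, not tight.
* Percent similarity depends on the substitution matrix and gap penalties;
  the 89%-class values quoted for real tandem duplicates are reproducible
  only under the original tool's scoring.
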