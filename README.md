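# crefam

Comparative regulatory analysis of plant gene families in R: meta-expression
profiling, Pearson co-expression grouping, degenerate promoter-motif
scanning, group-unique cis-regulatory element (CRE) calling, neighbor-joining
phylogenies with bootstrap supports, and protein-interaction networks
overlaid with co-expression.

## The problem

Tandemly duplicated genes often diverge in where they are expressed — one
copy seed-preferential, its neighbor root-preferential — and that divergence
must be encoded in their promoters. Given a tissue expression compendium, a
family phylogeny, promoter sequences and an interaction table, `crefam`
answers, for a gene family such as the rice peroxiredoxins:

* which family members are expressed where (meta-expression profiles,
  classified as ubiquitous / tissue-preferential / suppressed);
* which genes co-express with each family member (top Pearson correlation
  coefficient, PCC);
* which promoter elements are shared by *all* promoters of one co-expression
  group but absent from the other — the candidate CREs behind the divergent
  pattern;
* how the family partitions into subgroups on a distance-based phylogeny;
* which predicted protein interactions are supported by co-expression
  (PCC > 0.5).

A synthetic-data generator produces every input with known ground truth
(planted co-expression blocks, planted promoter motifs with enforced
cross-group purity, proteins evolved on a known 4-clade tree, hub-structured
interaction tables), so the whole pipeline is testable end to end.

## Methods at a glance

* **Meta-expression**: per-tissue means of log2 intensities; a gene is
  *tissue-preferential* when max(tissue mean) − median(remaining means) ≥ δ
  (default 2 log2 units), *suppressed* when all tissue means sit below a
  floor (default 6), *ubiquitous* otherwise.
* **Co-expression**: product-moment correlation r(x, y) between sample
  profiles; a bait's group is its k highest-PCC genes (deterministic
  lexicographic tie-break).
* **Motif scanning**: IUPAC degenerate consensi (Y = C/T, S = C/G, …)
  matched over both strands, all overlapping windows, N in the sequence
  matches nothing. Incidence = motif × promoter hit counts.
* **CRE set algebra**: common(G) = motifs present in every promoter of group
  G; unique(A) = common(A) \ common(B). With |common(A)| = 65,
  |common(B)| = 50 and 40 shared, this yields 25 and 10 group-unique CREs.
* **Phylogeny**: p-distances under complete deletion (columns gapped in any
  row are dropped for all pairs), Saitou–Nei neighbor joining (exact on
  additive distances), bootstrap over alignment columns (default 500
  replicates), subgroup assignment by nearest labeled exemplar with a
  monophyly check, and Needleman–Wunsch percent similarity.
* **Network**: undirected simple graph of hub–partner interactions; edges
  carry the PCC of their endpoints' expression profiles and a strict
  `PCC > 0.5` co-expression flag; exports to SIF / GraphML / TSV for
  Cytoscape-style viewers.

## Worked example

```r
library(crefam)
res <- run_workflow(synth_config(seed = 1), out_dir = "crefam_run")
```

```
[crefam] stage generate: seed 1
[crefam] stage expression: 200 genes x 6 tissues
[crefam] stage coexpr: baits G0001, G0006
[crefam] stage scan: 23 motifs x 11 promoters, 160 hits
[crefam] stage compare: |common A| 6, |common B| 5, unique A 4, unique B 3
[crefam] stage phylo: 20 taxa, 500 bootstrap replicates
[crefam] stage network: 86 nodes, 82 edges, partner union 82
[crefam] run complete: 21 files in crefam_run
```

The run simulates a 200-gene compendium over six tissues (leaf, shoot, root,
flower, pollen, seed) with two planted co-expression blocks around two
tandem-duplicate baits, 2-kb promoter groups of five and six genes with
planted group-specific motifs, a 20-protein family on a 4-clade tree, and a
hub-structured interaction table. Inspecting the results:

```r
res$coexpr$A          # the bait's co-expression group (true block recovered)
#>   gene_id       pcc
#> 1   G0004 0.9243339
#> 2   G0002 0.8980633
#> 3   G0005 0.8916590
#> 4   G0003 0.8863499

print(res$comparison) # group-unique CREs called from the incidence matrix
#> CRE comparison: |common A| = 6 | |common B| = 5 | shared = 2 |
#>   unique A = 4 | unique B = 3

res$network$summary$degrees       # hub degrees: 60 16 3 3
res$network$summary$union_partners  # 82 distinct interacting proteins
```

The four unique-A motifs are exactly the three planted seed/endosperm
elements plus their nested sub-motif; the co-expression group is the planted
block; the 82 = 60+16+3+3 distinct partners match the configured hub
structure. All outputs (tissue profiles, class calls, incidence matrix, CRE
report, Newick tree with integer bootstrap labels, SIF/GraphML network,
JSON run manifest with per-file checksums) land under `crefam_run/`.

A thin command-line wrapper is installed at
`system.file("cli", "crefam.R", package = "crefam")`
(`Rscript crefam.R demo --seed 1 --out run_dir`).

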