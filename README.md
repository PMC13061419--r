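# orthocell

Identification of **orthologous cell types** across species from single-cell
RNA-seq, and downstream analysis of how conserved gene expression and marker
genes are across a phylogeny.

Comparative single-cell studies face a circularity: cell types are matched
across species with marker genes, but marker genes themselves evolve.
`orthocell` implements a workflow that matches cell types *without* joint
embeddings or a fixed marker panel, then quantifies expression conservation
and marker transferability on the matched types. It is built for
four-species designs (the packaged default models two great apes and two
macaques) whose count matrices share a harmonized one-to-one gene
namespace.

## What it does

1. **High-resolution clustering** per species (Leiden on a kNN graph of a
   PCA embedding, resolution 2) — deliberately over-split so rare types
   survive matching.
2. **Reciprocal classification similarity**: a rank-correlation classifier
   (pseudobulk profiles, pairwise top-50 markers, Spearman with
   fine-tuning) is trained on each species in turn; the similarity of two
   clusters is the average of the two directional assignment fractions
   (within-species values come from an 80/20 split). A perfect reciprocal
   best hit scores 1.
3. **Orthologous cell type clusters (OCCs)**: average-linkage clustering on
   1 − similarity, cut at a user-chosen number of groups (dendrogram and
   silhouette diagnostics provided), pseudobulk-based merging at cut height
   0.1, exclusion of OCCs with < 800 cells present in < 3 species, and
   explicit, provenance-tracked splitting of over-merged OCCs.
4. **Presence–absence expression calls**: per gene × cell type × species,
   negative-binomial means/dispersions, quantile-based putative status,
   Firth-penalized logistic regression of status on detection fraction
   f solving `logit(p) = a + b·f` at p = 0.5 for the detection threshold
   `f* = −a/b`, harmonized as the maximum across species.
5. **Expression conservation** on a quartet tree with branch lengths
   scaled to sum to 1:

   `conservation(g) = (1/N_ct) · Σ_ct Σ_{b ∈ detected} bl_b`

   where the internal branch counts when at least one species of each
   clade expresses the gene in that cell type. Scores range from the
   smallest terminal branch length (0.075 on the packaged tree) to 1
   (identical detection in all four species). Cell type **specificity** is
   the number of shared cell types (max 7) a gene is expressed in.
6. **Marker genes**: zero-inflated quantile rank-score test + logistic
   membership test, detection-threshold / logFC > 0.01 / Δ > 0.01 filters,
   ranked by Δ (detection-fraction difference). Evaluated by rank-biased
   overlap (top 100, p = 0.9), top-k intersection patterns, and a kNN
   (k = 3) classifier over marker panels of size 1–30 with bootstrap F1
   intervals.
7. **A seeded multi-species simulator** with planted truth (markers,
   expression status, conservation) that every stage is tested against.

## Worked example

```r
library(orthocell)

cfg <- default_config(
  seed = 1L,
  qc = list(min_genes = 50),                       # simulated desk-scale depth
  simulate = list(n_genes = 400, n_cells_per_species = 420),
  match = list(n_occ = 7, min_cells = 100),
  evaluate = list(m_max = 5, n_boot = 20))
res <- run_pipeline(cfg, out_dir = "run1")

res$occ$occ_info
#> # A tibble: 7 x 4
#>   occ   n_cells n_species status
#>   <chr>   <int>     <int> <chr>
#> 1 OCC01     368         4 retained
#> 2 OCC02     304         4 retained
#> 3 OCC03     268         4 retained
#> 4 OCC04     236         4 retained
#> 5 OCC05     200         4 retained
#> 6 OCC06     168         4 retained
#> 7 OCC07     136         4 retained
```

Seven OCCs, each containing cells of all four simulated species: the seven
planted cell types were recovered as cross-species orthologous clusters.
Conservation scores for the called expression patterns then span the
expected range:

```r
summary(res$conservation$score)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.    NA's
#>  0.0750  0.6250  0.8786  0.7815  0.9714  1.0000       6
```

A gene detected only in one macaque scores 0.075 (the scaled macaque
terminal branch); genes detected in the same cell types in all four species
score 1. `autoplot()` methods exist for the similarity matrix, OCC
composition, conservation records and F1 curves; `tidy()`/`glance()`
summarize Firth threshold fits.

A thin command-line wrapper (`inst/exec/orthocell`) exposes the stages as
subcommands (`simulate`, `match`, `call`, `conserve`, `markers`,
`run-all`) over YAML configs for shell use.

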