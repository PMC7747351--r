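# ncplink

Prediction of latent metabolite–disease associations on a bipartite
network, for computational biologists who have a curated list of known
associations plus entity annotations (disease–gene, disease–symptom,
metabolite–enzyme tables) and want a ranked list of candidate pairs with
honest cross-validated performance estimates.

## The method

Given the binary adjacency matrix **A** (nd diseases × nm metabolites),
the package builds four base similarities:

- **DFS1** — Jaccard similarity of disease gene sets,
  `p / (p + q + r)` over shared / exclusive genes;
- **DFS2** / **MFS** — cosine similarity of TF-IDF-weighted symptom
  (disease) and enzyme (metabolite) profiles, with weights
  `w(i,f) = W(i,f) · log(n / n_f)`;
- **KD** / **KM** — Gaussian interaction profile (GIP) kernels on the
  rows / columns of A, `exp(−ω‖A_i − A_j‖²)` with bandwidth
  `ω = ω′ / mean‖profile‖²`.

These are fused by piecewise rules with three mixing weights
(α, β, γ ∈ [0,1]): DFS2 and DFS1 mix under α where DFS2 ≠ 0, the GIP
kernel fills the gaps scaled by β (diseases) or γ (metabolites). Every
pair is then scored by **network consistency projection**:

```
ncp(i,j) = ( SD_i·A_j / ‖A_j‖  +  A_i·SM_j / ‖A_i‖ ) / ( ‖SD_i‖ + ‖SM_j‖ )
```

Two further components address the label structure of the problem:

- **Spy negative mining** (positive–unlabeled learning): hide 10% of the
  positives, rescore with GIP-only similarities, take the minimum spy
  score as a threshold, and call unlabeled pairs below it negatives;
  repeated 100× and intersected, the surviving pairs are "reliable
  negatives" that every ranking demotes to the bottom.
- **Artificial bee colony search** over (α, β, γ), minimising
  `1 − AUC` of a frozen fivefold split with employed / onlooker / scout
  phases.

Evaluation is rank-based: LOOCV and repeated k-fold CV hold positives
out, rebuild all topology-dependent quantities from the masked matrix,
and rank held-out pairs against all unlabeled candidates (midrank
Mann–Whitney AUC).

## Worked example

A small synthetic dataset (10 diseases × 16 metabolites, 2 planted
blocks) ships with the package:

```r
library(ncplink)
d <- system.file("extdata", "synthetic_small", package = "ncplink")
cfg <- read_run_config(NULL, overrides = list(
  inputs = list(associations      = file.path(d, "associations.tsv"),
                disease_gene      = file.path(d, "disease_gene.tsv"),
                disease_symptom   = file.path(d, "disease_symptom.tsv"),
                metabolite_enzyme = file.path(d, "metabolite_enzyme.tsv"),
                diseases          = file.path(d, "diseases.tsv"),
                metabolites       = file.path(d, "metabolites.tsv")),
  spy = list(n_runs = 10L), out_dir = tempfile()))
sc  <- run_predict(cfg)
top <- read_scores(file.path(cfg$out_dir, "scores.tsv"))
head(subset(top, disease_id == "D001" & is_known == 0), 5)
```

```
 disease_id metabolite_id     score is_known is_reliable_negative
       D001         M0004 0.3808897        0                    0
       D001         M0008 0.3054954        0                    0
       D001         M0006 0.2988090        0                    0
       D001         M0016 0.1933350        0                    0
       D001         M0012 0.1920540        0                    0
```

The top-ranked unconfirmed partners for disease D001 (block 1) are
metabolites M0004/M0008/M0006 — all block-1 metabolites, i.e. the
planted structure is recovered; 6 pairs were flagged as reliable
negatives. Cross-validating the same configuration:

```r
cfg$cv <- list(mode = "kfold", k = 5L, n_repeats = 10L, seed = 1L)
run_evaluate(cfg)
#> fivefold AUC 0.7799 (sd 0.0312)
```

i.e. a held-out true association outranks a random unconfirmed pair
about 78% of the time on this small noisy fixture.

The same four stages are scriptable:

```sh
Rscript -e 'ncplink::ncplink_cli()' simulate --out data --seed 1
Rscript -e 'ncplink::ncplink_cli()' predict  --config run.yaml --out out
Rscript -e 'ncplink::ncplink_cli()' evaluate --config run.yaml --out out
Rscript -e 'ncplink::ncplink_cli()' optimize --config run.yaml --out out
```

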