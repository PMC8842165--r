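# mamthscreen

Analysis toolkit for pooled mammalian membrane two-hybrid (MaMTH-HTS)
protein–protein interaction screens and the functional assays used to
validate their hits, built around the CFTR (wild-type vs F508del)
interactome setting: a membrane bait screened against an ORFeome prey
library, with interaction signal read out as deep-sequencing counts of
prey cassettes after FACS enrichment.

## What it computes

* **Read quantification** — deterministic exact k-mer assignment of
  FASTQ reads to ORFs (`index_reference`, `assign_reads`,
  `quantify_screen`) and CPM normalization (`counts_to_cpm`).
* **Candidate calling** — the pooled-screen count filter: an ORF is a
  candidate interactor unless its count is below 3 in both technical
  replicates (`call_candidates`), with replicate-overlap robustness
  reporting (`replicate_overlap`).
* **Frequent-flier filtering** — promiscuous preys are detected across
  nine control-bait screens by the rank-product method: per-screen CPM
  ranks (highest CPM = rank 1), geometric-mean rank products,
  permutation p-values (default 100,000 column permutations) and
  Benjamini–Hochberg adjustment (`rank_product_test`,
  `flag_frequent_fliers`, `remove_fliers`).
* **Interactome comparison** — shared/unique bookkeeping between baits
  and deterministic edge-list export (`compare_baits`, `export_edges`).
* **Traffic screen** — high-content siRNA screen analysis: image QC
  (≥100 cells, in focus, non-negligible expression), per-well medians,
  5×5 well-neighbourhood Z-scores with a plate-level robust scale, and
  siRNA/gene calls at Z > +1 / Z < −1 including ambiguous-gene handling
  (`traffic_screen`).
* **Functional assays** — FLIPR membrane-potential metrics
  (max F/F₀ and F₁/F₋inh), forskolin-induced swelling AUC at 60 min,
  Ussing-chamber equivalent currents (Ieq = Vte/Rte) and Western-blot
  fold changes vs the calnexin loading control, with pooled-variance
  t-tests and one-way ANOVA (`flipr_fsk_response`, `fis_auc`,
  `ussing_metrics`, `wb_fold_change`, `normalize_and_test`).
* **Synthetic data** — seedable generators for all of the above
  (negative-binomial screen counts, gradient-bearing 384-well plates,
  FLIPR traces, swelling curves, Ussing recordings), so the pipeline is
  testable without raw data (`simulate_screen`,
  `simulate_control_screens`, `simulate_plate`, `simulate_trace`, ...).

See `vignettes/pipeline-methods.Rmd` for the statistical details and
the design decisions behind each stage.

## Worked example

```r
library(mamthscreen)

cfg <- screen_sim_config(n_orfs = 400, n_true_interactors = 10, n_fliers = 4, seed = 7)
screen   <- simulate_screen(cfg, "wtCFTR", emit_reads = FALSE)
controls <- simulate_control_screens(cfg)

cands <- call_candidates(screen$table, "wtCFTR", min_count = 3)
rp    <- rank_product_test(controls$matrix, n_iter = 2000, seed = 8)
clean <- remove_fliers(cands, flag_frequent_fliers(rp))

replicate_overlap(clean)
#> $n_total
#> [1] 40
#> $n_both
#> [1] 10
#> $percent_both
#> [1] 25

table(screen$truth$role[screen$truth$orf_id %in% clean$orf_ids])
#>      background true_interactor
#>              30              10
```

All 10 planted true interactors are recovered; the remaining candidates
are background ORFs that cleared the 3-read filter by chance in one
replicate (hence the modest replicate overlap at these simulation
settings), and all 4 planted fliers were flagged and removed. On
published-scale inputs the bookkeeping reproduces the familiar figures,
e.g. `report_percent(209, 224)` is `93`.

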