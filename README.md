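# degronscan

Discovery and quantification of C-terminal degrons in bacterial protein
families.

Bacterial aldehyde decarbonylases (ADs) — the enzymes that make alkanes in
cyanobacteria — are rapidly degraded in *E. coli* because their C-terminus
is a **degron**: a short peptide signal recognized by ATP-dependent
proteases (ClpAP and Lon for this family). The family consensus of that
signal, `RMSAYGLAAA`, resembles the ssrA tag (`CAANDENYALAA`) and limits
alkane titers by destabilizing the enzyme. `degronscan` implements the
comparative-genomics workflow that surfaces such a motif, and the
reporter-assay arithmetic that quantifies its activity, as a tested R
package for anyone hunting terminal degradation signals in a protein
family.

## What it computes

For a deduplicated family of sequences, the terminal profile is the
k × 20 frequency matrix over the last *k* residues (default k = 10),

    f_j(a) = (1/n) Σ_i 1[x_{i,j} = a],

its consensus is the per-position modal residue, and a position is
*conserved* when its modal frequency strictly exceeds 50%. Around this
statistic the package provides:

* **seq_io** — FASTA read/write (via Biostrings), exact-duplicate removal
  (`dedup_exact`), greedy identity clustering (`cluster_identity`);
* **align_phylo** — affine-gap global alignment (`global_align`, Rcpp
  core), p-distances, progressive MSA (`progressive_msa`), Saitou–Nei
  neighbor joining (`nj_tree`, exact on additive matrices), Felsenstein
  column bootstrap (`bootstrap_support`), clade medoid selection
  (`select_representatives`);
* **terminal_motif** — `extract_cterm`, `positional_frequency`,
  `consensus_motif`, `right_anchored_identity`, `composition_score`,
  `dipeptide_present`, and `degron_score` against a bundled catalogue
  (ADcon, ssrA, the ADpm terminal helix, the Euhalothece variant);
* **reporter_assay** — OD600 normalization, `percent_of_control` /
  `degradation_percent` at an endpoint hour, knockout `recovery_index`,
  post-peak `fit_decay_rate`, `fold_change` (truncated display, like the
  printed 5.47 for 90.9 → 16.6) and `net_effect`;
* **synthetic_data** — seeded families evolved along a Yule tree with a
  planted, slowly-evolving terminal motif plus injected duplicates, and
  reporter time courses with known decay kinetics — ground truth for
  every downstream stage;
* **pipeline_cli** — `run_sequence_pipeline` / `run_assay_pipeline` plus a
  command-line front end.

## Worked example

```r
library(degronscan)

fam <- simulate_family(family_sim_config(n_taxa = 12, root_length = 80,
                                         n_exact_duplicates = 4, seed = 7))
report <- run_sequence_pipeline(
  pipeline_config(out_dir = tempfile(), n_bootstrap = 50,
                  n_representatives = 3, seed = 7),
  family = fam)
#> [input] 16 records
#> [dedup:exact] 12 records retained
#> [msa] 12 rows x 80 columns
#> [tree] NJ + 50 bootstrap replicates
#> [representatives] t1, t10, t5
#> [consensus] RMSAYGLAAA (10/10 positions conserved)
print(report$degron_scores)
#> <degron_score> RMSAYGLAAA
#>   composition ({L,A,V,S}): 0.600
#>   vs ADcon        RMSAYGLAAA  identity 1.00
#>   vs ssrA         CAANDENYALAA  identity 0.20
#>   vs ADpm_helix   RMAAAALVS  identity 0.11
#>   vs Euhalothece  RMSAYGLREV  identity 0.70
```

The 16 input records collapse to the 12 distinct leaves (the 4 injected
duplicates are removed), and the consensus of the terminal window recovers
the planted motif with every position above the 50% rule. The identity
0.70 against the Euhalothece variant and 0.20 against ssrA are the
right-anchored comparisons; composition is the {L,A,V,S} fraction.

Degradation quantification on simulated tagged/untagged reporters:

```r
sim <- timecourse_sim_config(seed = 7)           # decay 0.2/h when tagged
tc <- rbind(simulate_timecourse(sim, tagged = TRUE),
            simulate_timecourse(sim, tagged = FALSE))
assay <- run_assay_pipeline(pipeline_config(out_dir = tempfile(),
                                            endpoint_time = 25),
                            timecourse = tc)
assay$degradation
#>          condition genotype percent_of_control degradation_percent
#> 1           tagged       WT           4.180192            95.81981
#> 2 untagged-control       WT         100.000000             0.00000
fold_change(90.9, 16.6)
#> <fold_change> 90.9 -> 16.6: 5.47-fold decrease
```

A tag decaying at 0.2/h leaves ~4% of the control signal after 25 h —
the same order as the strongest published degron readouts (94%
degradation at 25 h).

## Command line

```sh
Rscript inst/cli/degronscan.R simulate-family --out fam.fasta --seed 4
Rscript inst/cli/degronscan.R consensus --fasta fam.fasta --out cons.json
Rscript inst/cli/degronscan.R run-all --fasta fam.fasta --out-dir run1
```

Subcommands: `simulate-family`, `simulate-assay`, `dedup`, `align`,
`tree`, `profile`, `consensus`, `score`, `assay`, `run-all`. Exit codes:
0 success, 2 configuration error, 3 data error.

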