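# spheretrace

Tools for metabolically comparing two groups of glioma cell cultures or
tumours — typically IDH1-mutant versus IDH-wildtype gliomaspheres — from
two complementary kinds of evidence:

1. **Expression-level pathway enrichment.** KEGG-style modules are scored
   with gene-set enrichment analysis in which microarray probes are first
   *collapsed to Enzyme Commission (EC) activity nodes*: every probeset of
   every gene annotated to an EC competes, and the one with the largest
   absolute signal-to-noise ratio (SNR) represents that activity.  Modules
   are scored by the classic running-sum enrichment statistic, normalised
   against phenotype-permutation nulls (NES), filtered to 3–500 represented
   nodes, and two datasets' NES profiles can be intersected at a cut-off
   (|NES| > 1.2) to find concordantly enriched modules.
2. **Stable-isotope tracing.** Mass isotopologue distributions (MIDs) from
   LC-MS are natural-abundance corrected, normalised to an internal
   standard (norvaline) and cell number, and summarised as one fractional
   contribution ("percent label") per metabolite:
   `FC = sum(i * M_i) / (n * sum(M_i))`.  Downstream statistics cluster
   samples by their labeling profiles (with the adjusted Rand index against
   known genotype), screen metabolites by uncorrected two-tailed t tests,
   and test category over-representation (e.g. nucleotide precursors among
   the differentially labeled metabolites) with a 2×2 chi-square.  A dual
   glucose/deoxycytidine tracer module partitions DNA deoxycytidine signal
   into pre-existing, de novo (glucose-derived carbon shift) and salvage
   (three heavy nitrogens from [13C9,15N3]dC) sources.

Every pipeline input can be **simulated with known ground truth**
(`gen_expression_dataset()`, `gen_mid_panel()`, `gen_dual_tracer_panel()`),
so the whole analysis chain is validated end-to-end by parameter recovery.

## Worked example

Plant signal in two modules of a synthetic two-group dataset and recover
them by EC-collapsed GSEA:

```r
library(spheretrace)

pool <- sprintf("ec%03d", 1:80)
mods <- node_set_collection(setNames(split(pool, rep(1:10, each = 8)),
                                     sprintf("mod%02d", 1:10)))
ds <- gen_expression_dataset(300, c(10, 10), mods,
        expression_truth(c(mod01 = 1, mod02 = -1), effect_size = 2, seed = 42))
ranked <- collapse_to_nodes(ds)
enr <- run_gsea(ds, filter_modules(mods, ranked), n_perm = 1000, seed = 42)
head(enr[order(-abs(enr$nes)), ], 4)
#>  module n_nodes     es    nes       p     q enriched_in
#>   mod01       8  1.000  1.884 0.00200 0.010         MUT
#>   mod02       8 -1.000 -1.756 0.00199 0.010          WT
#>   mod06       8 -0.527 -1.274 0.19507 0.650          WT
#>   mod08       8  0.367  0.958 0.51509 0.956         MUT
```

The two planted modules top the table with |NES| ≈ 1.9 and permutation
p ≈ 0.002 in the planted directions; background modules stay near |NES| ≈ 1.

Trace a 50 % 13C-glucose labeling experiment and recover the planted
fractional contributions:

```r
mets <- data.frame(metabolite = c("pyruvate", "ribose5P", "citrate"),
                   formula = c("C3H4O3", "C5H11O8P", "C6H8O7"))
fc <- cbind(MUT = c(0.10, 0.15, 0.30), WT = c(0.30, 0.35, 0.30))
rownames(fc) <- mets$metabolite
panel <- gen_mid_panel(flux_truth(mets, fc, tracer_enrichment = 0.5,
                                  noise_sd = 0.02, seed = 7), n_replicates = 3)
idx <- labeling_index(correct_panel(panel))
round(idx, 3)
#>          MUT_r1 MUT_r2 MUT_r3 WT_r1 WT_r2 WT_r3
#> pyruvate  0.098  0.102  0.099 0.298 0.302 0.298
#> ribose5P  0.149  0.151  0.150 0.348 0.351 0.349
#> citrate   0.299  0.293  0.303 0.298 0.297 0.298

cluster_partition(idx, k = 2, labels = panel$samples$group)$ari
#> [1] 1
differential_labeling(idx, panel$samples$group)[, 1:6]
#>  metabolite mean_a mean_b      t        p significant
#>    pyruvate 0.0998  0.300 -114.1 3.54e-08        TRUE
#>    ribose5P 0.1500  0.349 -166.2 7.87e-09        TRUE
#>     citrate 0.2984  0.298    0.2 8.51e-01        FALSE
```

The two metabolites with a planted group difference are recovered
(uncorrected p < 0.05) and the samples partition perfectly by genotype
(ARI = 1); the unshifted metabolite is not flagged.

Partition DNA deoxycytidine into de novo versus salvage synthesis for a
"wildtype-like" (de novo share 0.8) and a "mutant-like" (0.5) group:

```r
wt  <- gen_dual_tracer_panel(source_truth(0.5, 0.40, 0.10, group = "WT",  seed = 11), 3)
mut <- gen_dual_tracer_panel(source_truth(0.5, 0.25, 0.25, group = "MUT", seed = 12), 3)
both <- dual_tracer_panel(rbind(wt$data, mut$data), rbind(wt$samples, mut$samples))
sf <- source_fractions(both)
subset(sf$group_summary, quantity == "denovo_share")
#>  group  mean      sd n ci_lo ci_hi     quantity
#>    MUT 0.501 0.02742 3 0.433 0.569 denovo_share
#>     WT 0.811 0.00557 3 0.797 0.825 denovo_share
```

The groups' 95 % confidence intervals do not overlap: the wildtype-like
group relies primarily on de novo synthesis while the mutant-like group
uses both routes about equally.

## Command line

A multi-stage run is described by one YAML/JSON config and executed with

```sh
Rscript -e 'spheretrace::spheretrace_main()' run --config run.yaml
```

(or via the installed `exec/spheretrace` launcher).  Subcommands
`simulate`, `gsea`, `concordance`, `mid`, `labeling-stats` and
`nucleotide-sources` run single stages; every run writes a `manifest.json`
with parameters, seeds and file checksums, and identical config + seed
reproduces identical outputs byte-for-byte.

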