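# pastree

Recognition of poly(A) signals (PAS) in human genomic DNA with an
omnivariate decision tree.

## The problem

Polyadenylation of pre-mRNA is directed by a PAS hexamer (canonically
`AATAAA`) upstream of the cleavage site. The same hexamers litter the
genome without any role in 3′-end formation (*pseudo-PAS*), so deciding
whether a genomic occurrence is functional must use the flanking sequence:
the GU/U-rich downstream element, the U-rich upstream element, and broader
compositional and structural biases. `pastree` classifies 206-nt windows
(100-nt flanks around the hexamer at window positions 100–105, 0-based) as
true PAS vs pseudo-PAS, separately for the 12 most common hexamer variants
(`AATAAA`/`ATTAAA` = PAS-strong; the ten rarer variants = PAS-weak).

## The method

1. **218-value feature encoding** per window: class log-odds scores from
   two position-specific dinucleotide weight matrices
   (Σⱼ log₂(p₍r(j),j₎/Pb₍r(j)₎)); a positional information-gain score
   (Gain(P) = E(P) − Σ_X w_X·E(P,X), summed against per-position class
   log-ratios); nucleotide frequencies at the 40 most discriminative
   positions; 25-nt window averages of 16 DNA structural profiles
   (A-philicity, protein–DNA twist, bendability, …); and compositional
   descriptors (mono/di frequencies, codon-frame frequencies, GC/AT skew,
   entropies, homopolymer runs). Features are min–max normalized to
   (−1, 1) with parameters fitted on training data only.
2. **Omnivariate decision tree**: a depth-3 binary skeleton whose internal
   nodes are heterogeneous classifiers — C4.5-style entropy tree, neural
   network, random forest, or ridge logistic regression — each fitted on
   the samples routed to it (predicted class 0 → left, 1 → right).
3. **Genetic algorithm** over the genome encoding (per-slot prune bit,
   family index, hyperparameter grid indices), scored by validation-split
   error rate, with tournament selection, uniform crossover, per-gene
   mutation and elitism.
4. **Protocol**: stratified 5-fold cross-validation with a 15% validation
   holdout per fold; for PAS-weak variants the training data is pooled
   with all records of the other nine weak variants; reported metric is
   `error rate = (FP+FN)/(TP+TN+FP+FN)` with size-weighted averages.

A synthetic generator (`default_profiles()` / `generate_dataset()`) plants
a hexamer in windows drawn from per-position nucleotide profiles with a
controllable `signal_strength`, so the whole pipeline is testable without
downloads. See `vignettes/pas-recognition-methods.Rmd` for the full model
description, parameter rationale and limitations.

## Worked example

```r
library(pastree)

# simulate a strong-signal dataset (150 true PAS + 150 pseudo-PAS)
ds <- generate_dataset(default_profiles("strong", signal_strength = 1),
                       150, 150, seed = 7)

# train: 15% validation holdout, GA over the omnivariate tree
model <- train_pas_model(ds,
                         ga_cfg = ga_config(population_size = 8,
                                            generations = 3, seed = 7),
                         tree_cfg = omni_tree_config(max_depth = 2),
                         seed = 7)
model$validation_error
#> [1] 0.09090909

# score held-out windows
held <- generate_dataset(default_profiles("strong", 1), 50, 50, seed = 99)
pred <- predict_pas(model, held)
head(pred, 3)
#>           id score    label
#> 1 true_00001     1 true_pas
#> 2 true_00002     1 true_pas
#> 3 true_00003     1 true_pas

rep <- eval_report(as.integer(held$label == "true_pas"),
                   as.integer(pred$label == "true_pas"))
sprintf("held-out error %.3f  FPR %.3f  FNR %.3f",
        rep$error_rate, rep$fpr, rep$fnr)
#> [1] "held-out error 0.060  FPR 0.100  FNR 0.020"
```

`score` is the fraction of true-PAS training samples at the tree leaf the
window reaches (1 = a pure true-PAS leaf); `label` thresholds the routed
leaf's majority. The held-out error (6% at full signal strength) reflects
the synthetic generator, not genomic benchmark difficulty.

A command-line wrapper covers the same pipeline:

```sh
inst/scripts/pastree simulate --out sim.fa --kind strong --seed 7
inst/scripts/pastree train --fasta sim.fa --out model.rds \
    --population 8 --generations 3 --seed 7
inst/scripts/pastree predict --model model.rds --fasta sim.fa --out pred.tsv
inst/scripts/pastree extract --genome hg19.fa --gtf gencode.polyAs.gtf \
    --out extracted/   # per-variant true/pseudo FASTAs + manifest
```

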