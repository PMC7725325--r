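# plastrans

Transmissibility annotation of plasmid DNA fragments from sequence
signatures.

## The problem

Plasmids move antibiotic-resistance and virulence genes through microbial
communities, but plasmidome assemblies are dominated by short contigs
(hundreds of bp) that rarely contain the relaxase gene or *oriT* by which
transmissible (conjugative / mobilizable) plasmids are normally recognized.
`plastrans` classifies plasmid fragments as **transmissible** vs
**non-transmissible** from sequence composition alone, for researchers
analysing plasmidome data — no marker-gene search, no database alignment.

Its biological basis is genome amelioration: plasmids drift toward their
hosts' sequence signatures, and a transmissible plasmid that has visited
many hosts carries a *blend* of signatures. The package implements this
idea at two levels:

1. **IEA** (information entropy of amino acid) — per genome and amino acid
   $i$ with $n_i \ge 2$ synonymous codons,

   $$\mathrm{IEA}_i = \sum_{j=1}^{n_i} p_{ij}\,\log_{n_i}\frac{1}{p_{ij}} \in [0,1],$$

   the base-$n_i$ Shannon entropy of synonymous-codon usage (1 = uniform,
   0 = single codon). There are 19 categories under the bacterial code:
   18 degenerate amino acids plus one stop category. Transmissible plasmids
   show systematically higher IEA.

2. **A two-branch convolutional classifier** — a fragment is encoded as
   (a) its six connected reading-frame triplet sequences, one-hot over the
   64 codons, and (b) its two connected strands, one-hot over the 4 bases.
   Each branch: 1-D convolution (512 kernels, length 6, ReLU) + masked
   global average pooling to 512 features; concatenated to 1024; batch
   norm / dense / batch norm head; sigmoid score in (0,1). Sequences longer
   than 400 bp are scored by a non-overlapping 400 bp scan window and the
   window scores are averaged. Scores above 0.5 are transmissible, and an
   uncertainty threshold `t` labels scores with `|s − 0.5| < t` as
   uncertain.

The network is implemented natively in R (no deep-learning backend): with
one-hot inputs, the length-6 convolution reduces exactly to indexed
embedding lookups, which keeps CPU training practical. A synthetic
benchmark generator (host usage tables of controlled divergence, mixture
vs single-host surrogate genomes, fragment strata A–D) makes the whole
method testable without downloading genome collections.

## Worked example

```r
library(plastrans)

# two divergent host signatures; a mixture genome and a single-host genome
tabs <- sample_usage_tables(2, divergence = 1, seed = 3)
g_mix  <- synth_genome(synthetic_genome_spec(10, c(60, 120), 0.1, tabs,
                                             "transmissible", seed = 11,
                                             genome_id = "mix"))
g_pure <- synth_genome(synthetic_genome_spec(10, c(60, 120), 0.1, tabs[1],
                                             "non-transmissible", seed = 12,
                                             genome_id = "pure"))

mean(iea_profile(g_mix)$iea,  na.rm = TRUE)   # 0.7507  blended usage: high entropy
mean(iea_profile(g_pure)$iea, na.rm = TRUE)   # 0.0578  one host: near-deterministic

# train a small classifier on fragments from these genomes
frags <- rbind(extract_fragments(g_mix,  c(100, 400), 300, seed = 1),
               extract_fragments(g_pure, c(100, 400), 300, seed = 2))
cfg <- model_config(kernels_triplet = 32, kernels_base = 32, hidden = 32,
                    batch_size = 64, max_epochs = 3, seed = 5)
model <- train_model(build_model(cfg), frags)

# held-out genomes, same host tables
g_mix2  <- synth_genome(synthetic_genome_spec(10, c(60, 120), 0.1, tabs,
                                              "transmissible", seed = 21,
                                              genome_id = "mix2"))
g_pure2 <- synth_genome(synthetic_genome_spec(10, c(60, 120), 0.1, tabs[1],
                                              "non-transmissible", seed = 22,
                                              genome_id = "pure2"))
test <- rbind(extract_fragments(g_mix2,  c(100, 400), 200, seed = 3),
              extract_fragments(g_pure2, c(100, 400), 200, seed = 4))
preds <- predict_sequences(model, setNames(test$sequence, test$fragment_id),
                           t = 0.05)
auc(preds$score, test$label)                  # 0.9907 on held-out genomes
```

The two IEA means show the signature contrast directly (0.75 vs 0.06: a
mixture of host signatures is near-maximally entropic, a single ameliorated
host near-deterministic), and the classifier separates 100–400 bp fragments
of held-out genomes with AUC 0.99 on this fully separable synthetic
benchmark.

The complete pipeline (simulate → train → predict → evaluate, with run
manifests) is one call:

```r
res <- run_pipeline(desk_config(out_dir = "run1", seed = 1))
res$report   # recall / precision / F1 / AUC per length group and threshold
```

A command-line wrapper with subcommands (`iea-compute`, `iea-compare`,
`simulate`, `train`, `predict`, `evaluate`, `pipeline`) is installed at
`exec/plastrans`.

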