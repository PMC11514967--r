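# motifcontrast

Why does a transcription factor (TF) bind one set of genomic sites in one
cell type, treatment, or paralog, and a different set in another? Two
ChIP-seq experiments for the same TF typically share the same canonical
binding motif, so the motif alone cannot explain the difference.
`motifcontrast` answers the question from sequence alone, for regulatory
genomicists comparing paired ChIP-seq experiments: it takes the peaks unique
to each experiment, aligns their sequences on the most likely binding site,
and weighs three kinds of sequence information in a single sparse logistic
model

    P(class 1 | s) = sigmoid( a * DM(s) + sum_i b_i * NE_i(s) + sum_j c_j * CF_j(s) )

where, for a 1-kb sequence *s* centred on the core binding site:

- **DM(s)** is the score of a *discriminative PWM*: the aligned K-bp core
  sites (plus 4 flanking bp on each side) are one-hot encoded and an
  L1-penalised logistic regression is fitted; its coefficient matrix
  `a_{k,j}` *is* a position weight matrix, and by convexity it is the
  optimal PWM for separating the two aligned site sets. It captures subtle
  per-position differences in the core motif itself.
- **NE_i(s)** are *nucleotidic environment* variables: the frequency of a
  short k-mer (2–4 bp) in a specific region around the site. Regions are
  unions of consecutive bins (7 bins over the 1 kb); for each k-mer the most
  class-discriminant region (folded AUROC) is found by exhaustive lattice
  enumeration, and 2-mers are greedily extended while the criterion
  improves.
- **CF_j(s)** are *co-factor* variables: the best log-odds score of another
  TF's PWM (from a motif library) within its most discriminant region
  (13 bins; region scores follow from per-bin best scores by a max() over
  the region lattice). The core site is masked (N's) before NE/CF analysis
  so neither channel can re-capture the core motif.

The model is trained with a LASSO penalty (glmnet, penalty chosen by
internal cross-validation) on a 70% training split; accuracy is the AUROC
on the held-out 30%. Setting each coefficient group to zero (no retraining)
and re-measuring the test AUROC gives the *importance profile* — how much
of the binding difference is explained by the core motif, the sequence
environment, and co-factors respectively. Companion outputs include
per-class PPMs of the aligned sites, a mirror logo of the signed
discriminative PWM, a Gini coefficient measuring its simplicity, Jaccard
distance between the peak sets, and a location report of the top variables.

A synthetic-data generator (`synth_config()` / `generate_dataset()`) plants
independently tunable core-position, k-mer/region and co-factor/region
signals over a 0-order background, emitting a toy genome FASTA + BED files
so the complete pipeline — peak partitioning, anchoring, rebalancing,
feature discovery, fitting — can be validated without any external data.

## Worked example

```r
library(motifcontrast)

## two-class synthetic dataset under the package's reference conditions:
## one discriminative core position (A: 0.8 vs 0.2), ACA enriched 1.4x in
## [-150, 500) of class 1, an 11-bp co-factor planted in [-250, 0) with
## probability 0.85 vs 0.15
ds  <- generate_dataset(synth_config(n_per_class = 1000, seed = 4))
fit <- motif_contrast(seqs = ds$aligned, library = synthetic_pfm_library(),
                      seed = 5)
summary(fit)
```

```
Differential binding-site model: class1 vs class2 
  1967 sequences (1377 train / 590 test)
  held-out AUROC: 0.933
  4 of 25 feature coefficients nonzero

Model variants (test AUROC):
  dm_only        0.788
  two_ppm        0.793
  full           0.933
  wo_dm          0.885
  wo_ne          0.895
  wo_cf          0.887
  cf_whole_seq   0.924

Ablation importance profile (AUROC loss): DM 0.047  NE 0.037  CF 0.045 
Discriminative PWM Gini coefficient: 0.982

Top variables (location report):
 rank                             variable type                identity ...
    1                                   DM   DM                      DM
    2 CF:SYN01_synthetic_motif_1@[-269,39)   CF SYN01_synthetic_motif_1
    3                    NE:ACA@[-214,500)   NE                     ACA
```

Reading the output: the full model separates held-out sequences of the two
classes with AUROC 0.93; the discriminative core PWM alone reaches 0.79 and
the generative two-PPM baseline does no better; removing any one
information channel costs 0.04–0.05 AUROC, so all three planted signals
contribute; and the LASSO-fitted PWM is sparse (Gini 0.98 — a few cells
carry everything, here the single planted discriminative position). The
location report (`fit$location`, or `plot(fit, type = "location")`) ranks
the variables: the top three are the DM variable, the planted co-factor
motif in a region covering [-250, 0), and the ACA k-mer over a region
covering [-150, 500) — exactly the three planted truths.

From BED files and a genome (the tool path):

```r
fit <- motif_contrast(bed_a = "expA.bed", bed_b = "expB.bed",
                      genome = "genome.fa",
                      target_motif = read_jaspar_library("TF_versions.pfm"),
                      library = "jaspar_pfm_dir/", seed = 1)
write_reports(fit, "out/")   # run.json, features.tsv, radar.tsv, ...
```

or from a shell: `Rscript inst/cli/motifcontrast.R --bed-a expA.bed
--bed-b expB.bed --genome genome.fa --target-motif tf.pfm --library pfms/
--out out/`.

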