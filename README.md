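# temporient

Analysis pipeline for temporal-orientation ("A-series") questionnaire
responses in Alzheimer's disease (AD), mild cognitive impairment (MCI)
and non-demented (ND) controls, with clustering of response patterns
and a regional cerebral-blood-flow (CBF) discriminant search.

## The problem and the method

Temporal orientation — knowing where events sit on the
past–present–future axis — degrades early in AD. In the paradigm this
package analyses, participants rate eleven sentences (each an adverb
of time plus a past- or present-tense verb) on a nine-point scale:
1 = far past, 5 = present, 9 = far future. The pipeline:

1. **Standard response.** The per-sentence mean among ND participants;
   sorted ascending it recovers the temporal order of the adverbs, and
   the "now" sentence anchors the scale at 5.
2. **Pivotal regression.** Each participant's ratings *y* are fitted
   against the standard scores *x* with a line constrained through the
   pivotal present point (5, 5):
   *y* = *k*(*x* − 5) + 5, with
   *k̂* = Σ(*x*ᵢ−5)(*y*ᵢ−5) / Σ(*x*ᵢ−5)². The slope *k* and the
   determination coefficient (the variance fraction explained by the
   line) summarise the response pattern; an intact responder sits at
   (1, 1).
3. **Clustering.** A full-covariance Gaussian mixture on the
   (slope, d.c.) plane, with the number of clusters selected by mean
   silhouette and 95% confidence ellipses at Mahalanobis radius 2.45.
4. **CBF screen.** One-way ANOVA of CBF across clusters in each of 24
   arterial territories (12 per hemisphere), Bonferroni-corrected at
   *P* < 0.05/24.
5. **Discriminant search.** Leave-one-out linear discriminant analysis
   of cluster membership, exhaustively over all 24 single territories
   and all 276 territory pairs, ranked by hit rate with confusion
   matrices.
6. **Patlak quantification.** For dynamic acquisitions, the influx
   constant K₁ (∝ CBF) and distribution volume V₀ from the linear
   portion of the Patlak plot, plus area-weighted ROI-to-territory
   aggregation.

No clinical data ship with the package; a seeded synthetic cohort
generator (`cohort_spec()`, `gen_responses()`, `gen_cbf()`,
`gen_tac()`) emulates the assumed statistical structure — three
response regimes (near-linear, coarse 1/5/9 grading, flat), CBF
declining across clusters with the strongest separation in the
bilateral pericallosal territories — so every stage is testable end to
end. See `vignettes/temporal-orientation-methods.Rmd` for the models,
parameter choices and limitations.

## Worked example

The `analysis/` directory holds the pipeline as numbered drivers
(`01_simulate.R` … `06_patlak.R`), writing tables under `results/`.
Equivalently in one call:

```r
library(temporient)
res <- run_pipeline(pipeline_config(seed = 1))
str(res$summary)
```

which prints (elided):

```
$ best_k             : int 3
$ cluster_sizes      : int [1:3] 15 20 20
$ mean_silhouette    : num 0.805
$ silhouette_over_0.5: num 0.982
$ n_significant      : int 21
$ best_model         : chr "pericallosal_right+pericallosal_left"
$ best_hit_rate      : num 0.873
```

Reading: the 55 synthetic participants cluster into **K = 3** response
patterns (silhouette selects 3 over 2..6; 98% of participants have
silhouette above 0.5, and here the clusters recover the generating
regimes exactly, adjusted Rand index 1.0); 21 of the 24 territories
pass the Bonferroni screen, the pericallosal territories most strongly
(right: F(2, 52) = 68.3); and the best leave-one-out discriminant of
cluster membership is the **bilateral pericallosal pair** at hit rate
0.873. The stage drivers print the same numbers with more detail
(silhouette trace, Tukey pairwise comparisons, the best model's
confusion matrix, Patlak recovery across noise levels).

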