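# mmnet — sex-stratified multimorbidity networks for diabetes cohorts

Multimorbidity — two or more chronic conditions in one patient beyond the
index disease — clusters differently across diabetes types and sexes, but
most network studies of disease co-occurrence in electronic health records
(EHR) cover type 2 diabetes only. `mmnet` implements, as a reusable and
fully tested R pipeline, a sex-stratified comparison of multimorbidity
networks between a type 1 diabetes (T1DM) cohort and a 1:1 sex- and
index-age-matched type 2 diabetes (T2DM) cohort: cohort construction from
long-format diagnosis records, descriptive comparison with standardized
mean differences, co-occurrence statistics and a data-driven significance
cut-off, weighted network topology, and between-network contrasts. Because
hospital-linkage databases of this kind are access restricted, the package
ships a seeded synthetic EHR generator with *planted* co-occurrence
structure, so every stage is validated end to end against known ground
truth.

## The statistics at the core

For conditions *i*, *j* within one diabetes-type × sex subgroup of *N*
patients, with marginal counts *cᵢ*, *cⱼ* and joint count *cᵢⱼ*:

- **Salton cosine index** — edge strength, sample-size free:
  `SCI_ij = c_ij / sqrt(c_i c_j)`
- **Phi coefficient** — the Pearson correlation of the two binary
  indicators: `Φ_ij = (c_ij N − c_i c_j) / sqrt(c_i c_j (N−c_i)(N−c_j))`
- **t-value** — `t_ij = Φ_ij sqrt(c_ij − 2) / sqrt(1 − Φ_ij²)`

The SCI cut-off is derived per subgroup: among the `q` pairs with
`c_ij > 0`, count the `e` pairs with `t > 1.96` and `c_ij` above the mean
joint count; the network keeps the top-`e` pairs ranked by SCI, so the SCI
network and the Φ-significance screen agree on the number of positive
associations. Network topology is summarised by degree, weighted degree
(sum of incident SCI), density, normalized harmonic centrality, and
PageRank hubs (damping 0.85). Contrasts between the four subgroup networks
are edge-set differences (A-not-in-B) and subgroup-unique pairs (edges
present in exactly one network).

## Worked example

A calibration scenario with one subgroup-unique planted pair per subgroup
(odds ratio 8, 10% margins, ~5,000 patients per subgroup):

```r
library(mmnet)
cfg <- recovery_scenario_config(seed = 1)
res <- run_pipeline(cfg)

res$assoc$T1DM_male$cutoff
#> N=4991 q=66 e=1 sci_cutoff=0.337

head(res$assoc$T1DM_male$pairs[order(-res$assoc$T1DM_male$pairs$sci), ], 3)
#>    code_i code_j c_i c_j c_ij   sci    phi     t
#> 1     C01    C02 499 487  166 0.337 0.2641 3.506
#> 60    C08    C12 520 715   86 0.141 0.0215 0.197
#> 38    C04    C12 519 715   81 0.133 0.0125 0.111

res$contrast$unique_pairs
#>      subgroup code_i code_j   sci
#> 1 T1DM_female    C03    C04 0.357
#> 2   T1DM_male    C01    C02 0.337
#> 3 T2DM_female    C07    C08 0.382
#> 4   T2DM_male    C05    C06 0.376
```

Reading this: in the male T1DM subgroup, 66 condition pairs co-occur at
least once (`q`), exactly one passes both significance criteria (`e`), and
the top-ranked pair by SCI is the planted pair C01–C02 (joint count 166
versus ~49 expected under independence; `t = 3.5` ≫ 1.96). Every planted
pair is recovered in its own subgroup and — being absent from the other
three edge sets — appears in the subgroup-unique report with its SCI.

The `analysis/` directory holds the numbered narrative drivers
(`01_simulate.R` … `07_recovery.R`) that run the same stages at full scale
(18,971 patients per cohort, the default calibration) and write all tables
under `results/`.

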