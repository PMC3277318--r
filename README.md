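# cgrmf — multifractal analysis of genome sequences via chaos game representation

`cgrmf` quantifies how unevenly the information content of a DNA sequence is
distributed, using the multifractal formalism.  It is aimed at genome
analysts who want a per-window statistic of sequence "aperiodicity" — in
the human genome this statistic tracks the local density of Alu
retroelements — together with the downstream machinery to relate it to
annotated features, average it per chromosome, and cluster chromosomes.

## The method

A sequence fragment is mapped into the unit square by the **Chaos Game
Representation** (CGR): starting from the center, each base moves the
current point halfway toward that base's corner (A = (0,0), C = (0,1),
G = (1,1), T = (1,0)), emitting one point per base.  Subsequence
frequencies become the local density of the resulting point cloud.

The cloud's **generalized (Rényi) dimension spectrum** is estimated by box
counting.  For a grid of boxes of side ε = 2⁻ᵏ, with Mᵢ points in box *i*
out of M₀ total,

    D_q = lim_{ε→0}  ln Σᵢ (Mᵢ/M₀)^q  /  [(q−1) ln ε]

and `dq_spectrum()` evaluates D_q as the least-squares slope of
ln Σ(Mᵢ/M₀)^q against (q−1)·ln ε across scales k = 1..6 (the q = 1 case
uses the entropy limit Σ(Mᵢ/M₀)ln(Mᵢ/M₀) against ln ε).  From the spectrum
follow the mass exponent τ(q) = (q−1)·D_q — linear for monofractals,
curved for multifractals — and the **multifractality degree**

    ΔD_q = max(D_q) − min(D_q),    q ∈ [−20, 20],

the package's central per-fragment statistic.  For uniform random
sequence all D_q = 2 and ΔD_q ≈ 0; biased or repeat-rich composition bends
the spectrum and raises ΔD_q.  The estimator is validated against the
exact spectrum of the biased chaos-game measure,
D_q = −log₂(Σ pᵢ^q)/(q−1), available in `analytic_dq()`.

Around the estimator the package implements the full analysis pipeline:
fragmentation of chromosomes into fixed 300-kb windows with an ambiguity
(N) filter, per-fragment counting of annotation intervals (Alu families,
LINE/MIR/MER/LTR, CpG islands, genes, exons, SNPs), simple and
multivariate regression of ΔD_q on feature densities, binning by range of
multifractality, two-threshold fragment classification, chromosome
averaging, complete-linkage/Pearson clustering of averaged spectra, and
region averaging — plus a synthetic-genome generator with planted,
mutated repeat copies and exact annotation truth so the whole pipeline is
testable without external data.

## Worked example

Simulate six 100-kb fragments carrying 0–50 planted copies of a mutated
300-bp repeat consensus, run the pipeline, and regress the
multifractality degree on the planted repeat count:

```r
library(cgrmf)

g  <- planted_repeat_genome(6, c(0, 10, 20, 30, 40, 50),
                            fragment_length = 100000, mutation_rate = 0.1,
                            seed = 42)
fr <- fragment_genome(g$records, fragment_length = 100000)
sp <- fragment_spectra(fr, k_range = 1:5)
sp[["frag006_00001"]]
#> Generalized dimension spectrum [frag006_00001]
#>   points: 100000;  scales k = 1..5;  q = -20..20
#>   D0 = 2.0000,  D1 = 1.9941,  D2 = 1.9879
#>   multifractality degree (max Dq - min Dq): 0.1751

ct  <- count_per_fragment(fr, g$intervals)
ft  <- assemble_feature_table(sp, ct, fr)
ft[, c("fragment_id", "alu_total", "delta_dq")]
#>     fragment_id alu_total   delta_dq
#> 1 frag001_00001         0 0.07185955
#> 2 frag002_00001        10 0.07612567
#> 3 frag003_00001        20 0.08052062
#> 4 frag004_00001        30 0.13370719
#> 5 frag005_00001        40 0.14793412
#> 6 frag006_00001        50 0.17505259

simple_regression(ft$alu_total, ft$delta_dq)
#> Linear fit: ft$delta_dq ~ ft$alu_total  (n = 6)
#>  (Intercept) ft$alu_total
#>     0.058159     0.002242
#> R2 = 0.9162,  p = 0.00271
```

The fragment with no planted repeats sits at the uniform-sequence noise
floor (ΔD_q ≈ 0.07); each additional block of near-identical repeat
copies concentrates CGR density and raises ΔD_q, and the regression
recovers the planted gradient (R² = 0.92).  With real genomes the same
flow starts from `read_fasta()` and `read_intervals()` instead of the
generator.

## Scope notes

The package analyzes point-CGR clouds of DNA only (no k-mer frequency
CGR variant, no RNA/protein alphabets, no wavelet or detrended
multifractal estimators, and no f(α) Legendre spectrum).  Headline
full-genome numbers require a human assembly plus its annotation files as
external inputs; everything shipped here runs on synthetic data.
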