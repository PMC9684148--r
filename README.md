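# chitopa

Simulation and fingerprint analysis of chitosan **patterns of
acetylation** (PA).

## The scientific problem

Chitosans are linear copolymers of N-acetylglucosamine (GlcNAc, `A`)
and glucosamine (GlcN, `D`). Beyond chain length (DP) and fraction of
acetylation (F<sub>A</sub>), their physicochemical and biological
behaviour depends on the *arrangement* of the `A` units along the
chain: random (Bernoullian), block-wise, or regular. Chitin
deacetylases (CDAs) acting in reverse mode on polyglucosamine can
produce non-random PAs, which are characterised experimentally by
<sup>13</sup>C-NMR dyad analysis and by enzymatic–mass-spectrometric
(EMS) fingerprinting with a sequence-specific chitinosanase.

`chitopa` provides the desk-scale computational counterpart of that
workflow, for polysaccharide scientists and method developers:

* **seeded generators** for chain ensembles with controlled DP
  distribution (Schulz–Zimm dispersity), F<sub>A</sub>, and PA
  (Bernoulli / first-order Markov / regular);
* a **kinetic Monte Carlo** simulator of reverse-mode CDA
  N-acetylation with per-subsite preference weights (presets for AnCDA,
  PesCDA, CnCDA4, PgtCDA);
* a **subsite-rule digestion engine** (chitinosanase DA/XX, chitinase
  ChiB, chitosanase Csn174, lysozyme, chitotriosidase presets);
* the **analytics**: dyad fractions and the deviation-from-randomness
  statistic
  P<sub>Σ</sub> = F<sub>AD</sub>/(F<sub>AA</sub>+F<sub>AD</sub>) +
  F<sub>DA</sub>/(F<sub>DD</sub>+F<sub>DA</sub>)
  (1 = random, &lt; 1 block-wise, → 2 alternating), simulated NMR dyad
  intensities, EMS-fingerprint F<sub>A</sub> estimation over the
  DP 2–10 window, and block-size profile inference from DA/XX products
  with number-/weight-average block sizes.

## Worked example

Simulate a block-PA chitosan like the enzymatically N-acetylated sample
(F<sub>A</sub> 0.33, DP<sub>n</sub> 800, Đ 1.9, P<sub>Σ</sub> 0.3) and
characterise it both ways:

```r
library(chitopa)

lens   <- sample_lengths(dp_spec("schulz_zimm", dpn = 800, dispersity = 1.9),
                         200, seed = 1)
blocky <- generate_markov(markov_pa_spec(fa = 0.33, p_sigma = 0.3),
                          lens, seed = 2)
dp_moments(blocky)
#> DPn = 789.6, DPw = 1585.4, dispersity = 2.008
dyad_fractions(blocky)
#> dyad fractions: AA 0.2613  AD 0.0663  DA 0.0663  DD 0.6060
#> P_AD = 0.2024, P_DA = 0.0986, P_sigma = 0.3011, F_A(dyad) = 0.3277
```

The pooled-dyad P<sub>Σ</sub> of 0.30 recovers the generator target: a
strongly block-wise PA. The same value is recovered through the
simulated NMR measurement (5 % intensity noise):

```r
p_sigma_from_intensities(simulate_intensities(blocky, noise_cv = 0.05,
                                              seed = 5))
#>   P_sigma       F_A
#> 0.3138804 0.3242456
```

EMS fingerprinting: digest with the DA/XX chitinosanase and infer block
sizes from the products (weight averages, end blocks excluded):

```r
products <- digest(blocky, preset_hydrolases()$chitinosanase, seed = 3)
average_block_sizes(infer_block_profile(products), "weight")
#>        A        D
#>  8.88427 18.99068
```

A random-PA control at the same F<sub>A</sub> gives weight-average
blocks of only A ≈ 2.0 and D ≈ 5.0 — the fingerprint separates the two
samples cleanly. The windowed (DP 2–10) F<sub>A</sub> estimate,
`estimate_fa(products)`, returns 0.44 here: on strongly blocky
substrates much product mass falls outside the DP 2–10 window and the
windowed estimator is visibly biased, which is a property of the
windowed fingerprint itself (on the random-PA control it returns
0.34 ± 0.03).

An end-to-end run (generate → digest → fingerprint → dyads) is
available as `run_pipeline()` or via the CLI:

```sh
chitopa generate --family markov --fa 0.33 --p-sigma 0.3 --dpn 800 \
        --dispersity 1.9 --n-chains 200 --seed 1 --out sample.fasta
chitopa digest --in sample.fasta --enzyme chitinosanase --out products.csv
chitopa fingerprint --in products.csv
```

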