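---
title: "Modelling the pattern of acetylation of chitosans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the pattern of acetylation of chitosans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chitopa)
```

## The model system

Chitosans are linear binary copolymers of N-acetylglucosamine (GlcNAc,
written `A`) and glucosamine (GlcN, written `D`). Their functional
behaviour is controlled by the degree of polymerisation (DP), the molar
fraction of acetylation ($F_A$), and — the focus of this package — the
*pattern of acetylation* (PA): how the `A` units are arranged along the
chain. Chemically N-acetylated or deacetylated chitosans have a
Bernoullian (random) PA; chitin deacetylases (CDAs) running in reverse
mode (N-acetylating polyglucosamine in excess acetate) can instead
produce block-wise or regular PAs, because their substrate clefts read
the neighbouring residues through subsite preferences.

All sequences in this package are written from the non-reducing end
(left) to the reducing end (right); subsite indexing, cleavage rules and
block stitching all derive from that single orientation convention.

## Dyad statistics and $P_\Sigma$

For the pooled dyad fractions $F_{AA}, F_{AD}, F_{DA}, F_{DD}$ (counted
within chains, never across chain boundaries, abundance-weighted — the
in-silico analogue of NMR integration over molecules), define

$$P_{AD} = \frac{F_{AD}}{F_{AA}+F_{AD}},\qquad
  P_{DA} = \frac{F_{DA}}{F_{DD}+F_{DA}},\qquad
  P_\Sigma = P_{AD} + P_{DA}.$$

For a random PA the dyads are product-form ($F_{XY} = F_X F_Y$) and
$P_\Sigma = 1$ identically; block-wise PAs give $P_\Sigma < 1$ and the
alternating limit gives $P_\Sigma = 2$. On a homopolymer one of the
denominators vanishes; the package defines that term as 0 with a
warning, keeping the statistic total on degenerate inputs rather than
failing.

```{r}
blocky <- generate_markov(markov_pa_spec(fa = 0.33, p_sigma = 0.3),
                          rep(800, 100), seed = 1)
p_sigma(dyad_fractions(blocky))
```

## Generators: the stated world of the synthetic data

**Chain lengths.** Real chitosan samples are polydisperse
($Đ = DP_w/DP_n \approx 1.8$–$1.9$). Lengths are drawn from the
Schulz–Zimm family — a gamma distribution with shape $z = 1/(Đ-1)$ and
mean $DP_n$, the standard two-moment polymer length model — rounded to
integers and clamped at a minimum DP of 2 (rounding bias is negligible
at $DP_n \ge 200$). The reference compositions used throughout the
tests are the two characterised samples: a block-PA chitosan
($F_A = 0.33$, $DP = 800$, $Đ = 1.9$, $P_\Sigma = 0.3$) and a random-PA
control ($F_A = 0.34$, $DP = 700$, $Đ = 1.8$). Headline DP values are
treated as number averages ($DP_n$); the source data do not specify
number- versus weight-average, and $DP_n$ is the natural mean of a
sampling distribution. Dispersity is computed on DP with unit monomer
mass: A and D differ by only 42 Da, and no molar-mass calibration is
attempted.

**Patterns.** Three PA families cover the observed spectrum:

* *Bernoulli*: residues i.i.d. with $\Pr(A) = F_A$ (random PA).
* *First-order Markov*, parameterised directly by the observables via
  $P_{AD} = (1-F_A)\,P_\Sigma$ and $P_{DA} = F_A\,P_\Sigma$, started
  from the stationary distribution. This is the *minimal* model
  consistent with a dyad-level $P_\Sigma$ target; whether real block-PA
  chitosans are first-order Markov is unknown (only dyads are measured),
  so the family is a parameterisation, not a mechanistic claim. The
  feasible range is $0 < P_\Sigma \le \min(1/F_A,\, 1/(1-F_A),\, 2)$,
  and $P_\Sigma = 1$ reduces exactly to the Bernoulli model.
* *Regular*: deterministic maximally even spacing of `A`
  (no seed — an exactly reproducible $P_\Sigma > 1$ reference).

## Bernoulli (random-PA) theory

Run lengths of an i.i.d. sequence are geometric: mean A-block
$1/(1-F_A)$, mean D-block $1/F_A$ (at $F_A = 0.33$ the mean GlcN block
is $3.03 \approx 3$). The per-monomer frequency of a GlcNAc block of
length $k$ is estimated as $F_A^k$ — at $F_A = 0.1$, $k = 7$ this is
$10^{-7}$, i.e. one heptamer per $10^7$ monomers or one per $10^4$
polymers of DP 1000. The exact interior-block-start probability
$(1-F_A)^2 F_A^k$ is exposed alongside, clearly labelled; the simple
$F_A^k$ form is the one used for order-of-magnitude expectations.

## Kinetic Monte Carlo N-acetylation

Reverse-mode CDA action is simulated with a Gillespie loop over all D
residues of the ensemble. A CDA has four subsites $\{-2\}$–$\{+1\}$
with $\{0\}$ holding the residue being acetylated; the event rate of
position $i$ is

$$r_i = k \prod_{s \in \{-2,-1,+1\}} w_s(\text{residue at } i+s),$$

with a neutral weight (1) for subsites beyond a chain end. Pseudo-time
is dimensionless ($k = 1$); the simulation stops when the ensemble
$F_A$ reaches the target (within one event). Because only qualitative
preferences are published for the four fungal CDAs, the preset weights
are package defaults in an editable JSON config — 10:1 for "prefers",
2:1 or 3:1 for "mild"/"slight" — and only their *orderings* are treated
as meaningful: acceptance checks assert
$P_\Sigma(\text{CnCDA4}) > P_\Sigma(\text{PgtCDA}) \ge 1 >
P_\Sigma(\text{PesCDA}) \approx P_\Sigma(\text{AnCDA})$, never
weight-derived values. With uniform weights the selected D sites are
exchangeable, so the stopped pattern is distributionally Bernoullian —
the chemical-control analogue and a cross-check against the Bernoulli
generator. Processivity is not modelled (each event is independent);
forward (deacetylation) mode is exposed behind the same engine by
symmetry but off by default.

## Subsite-specific digestion

Endo-hydrolases are modelled by allowed residue sets per subsite around
the scissile bond (between subsites $\{-1\}$ and $\{+1\}$), plus
occupancy requirements: a subsite that must be occupied deactivates
bonds too close to a chain end or to an earlier cut. Digestion runs to
completion (the analogue of a 24-h incubation) by repeatedly cleaving a
uniformly random cleavable bond and updating cleavability near the new
ends; the random order matters only where occupancy windows interact,
which is why the engine is seeded. Monomers and acetyl counts are
conserved exactly, for every enzyme and seed.

Preset rules: chitinosanase `DA/XX` ($\{-2\}$ D, $\{-1\}$ A); Csn174
($\{-1\}$ D, $\{+1\}$ D, occupancy $\{-2\}..\{+2\}$); ChiB and ChT
($\{-1\}$ A); lysozyme ($\{-2,-1,+1\}$ A). "Strongly favours" is
collapsed to an absolute requirement in the presets — this reproduces
the qualitative product classes (GlcN$_2$/GlcN$_3$ from chitosanase,
GlcNAc$_2$ dominance from chitinase on block-PA, fully-acetylated
dimers-to-tetramers from lysozyme on block-PA) without free
parameters. A `weighted` mode exists for softer preferences; since
digestion runs to completion it only biases the cleavage *order*, so
the limit products coincide with the absolute rule of the same support.

**Lysozyme occupancy window.** Lysozyme's cleft spans six subsites in
the literature. With occupancy only at residues $j-1..j+2$ the smallest
stable fully-acetylated fragment would be a trimer and tetramers would
never survive, contradicting the observed fully-acetylated
dimers-to-tetramers. The preset therefore requires one additional
occupied upstream subsite ($\{-3\}$), giving cleavable bonds
$3 \le j \le DP-2$ on an all-A chain; an isolated A-heptamer then
digests to $\{4,3\}$ or $\{3,2,2\}$. Under these defaults,
fully-acetylated DP-4 products imply GlcNAc blocks of length $\ge 6$
(rather than $\ge 7$); this is flagged, not resolved.

## EMS fingerprinting

The fingerprint stage normalises product abundances over the DP 2–10
window ("mass fractions" are interpreted as molar species fractions;
with unit monomer mass the difference from mass weighting is bounded by
the A/D mass ratio and out of scope). The $F_A$ estimator is
monomer-weighted, $\hat F_A = \sum x_p n_{A,p} / \sum x_p \mathrm{DP}_p$;
without a window it equals the substrate $F_A$ exactly (conservation),
and the windowed error is bounded by the excluded mass fraction, which
is asserted per run. On blocky substrates, window exclusion is larger
and the windowed estimate accordingly less accurate — a real limitation
of the windowed fingerprint, not of the implementation.

Block-size inference rests on the DA/XX lemma: every interior
chitinosanase product has the form $A^{a-1} D^d A$, so it witnesses one
A-block of size $a$ and one D-block of size $d$ — the trailing A of
each product is "donated" to the block counted by its successor. With
explicit product sequences the stitching is exact: the inferred profile
equals the direct run-length decomposition of the substrate, block for
block, for every chain and seed (a property test asserts this
equality). From composition alone, interior and non-reducing products
are still exactly determined; reducing-end products are ambiguous (an
`AADD` and an `ADDA` reducing product share one composition) and are
reconstructed via the lemma's canonical form. Blocks touching chain
ends are right-censored and therefore flagged terminal and excluded
from block-size averages by default; "average block size" defaults to
the weight average $\sum s^2 n_s / \sum s n_s$.

## Simulated NMR dyad analysis

`simulate_intensities` returns the four dyad peak areas proportional to
pooled dyad counts, optionally perturbed by independent log-normal
factors (median 1, CV as given). The estimator on noise-free
intensities equals the sequence statistic exactly; at CV 0.05 the bias
stays below 0.02 (checked over 200 replicates). The nitrous-acid
partial depolymerisation that precedes real NMR measurement is *not*
modelled and is assumed pattern-neutral at the dyad level — a flagged
assumption, since HNO2 cleaves at D units and could in principle bias
dyad frequencies.

## Measurement-noise model

MS abundances are semi-quantitative; the noise layer multiplies each
species abundance by an independent log-normal factor with median 1 and
the stated CV (defaults: CV 0.1 for MS emulation, 0.05 for NMR), then
re-normalises. Median-1 (rather than mean-1) factors keep the noise
symmetric on the log scale; the induced bias of the monomer-weighted
$F_A$ estimator is below 0.01 at CV 0.1 (checked over 100 replicates).

## What a green test does and does not establish

The generators emulate: Schulz–Zimm length dispersity, the three PA
families at $F_A$ 0.03–0.7, multiplicative MS noise, and additive-free
log-normal NMR intensity noise. They do not emulate: real molar masses
or SEC/light-scattering observables, ion response factors or
chromatography, enzyme kinetics in time (digestions are limit digests),
processive enzyme action, or any higher-order (triad-calibrated)
sequence structure. Parameter-recovery tests therefore establish
internal consistency of the estimators on the stated stochastic world —
they do not validate the first-order-Markov assumption against real
block-PA chitosan.

## Numerical and design choices

* Seeds: every stochastic routine takes an explicit `seed` and restores
  the caller's RNG stream; identical spec + seed reproduces ensembles
  byte-for-byte through FASTA round trips.
* Degenerate inputs: homopolymer $P_\Sigma$ terms are 0 with a warning;
  all-DP-1 ensembles error with "no dyads"; empty DP windows error.
* Bond indexing is 1-based; the bond index equals the position of its
  $\{-1\}$ residue; subsite $s$ maps to residue $j+s+1$ for $s<0$ and
  $j+s$ for $s>0$.
* The kinetic engine requires unit chain abundances (it flips
  individual molecules); generators produce unit abundances.
* Known limitations: windowed $F_A$ on strongly blocky substrates
  carries the window-exclusion bias discussed above; composition-only
  block inference is approximate for reducing-end products; CDA preset
  weights are placeholders pending quantitative subsite data.
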