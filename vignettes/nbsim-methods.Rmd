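---
title: "The nbsim multicellular neuroblastoma model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The nbsim multicellular neuroblastoma model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`nbsim` simulates a small region of a neuroblastic tumour as three coupled
model layers: a **continuous automaton** describing the microenvironment on
a voxel grid, **discrete cell agents** (neuroblasts and Schwann cells) whose
behaviour is decided by Bernoulli trials with conditional probabilities,
and a **centre-based mechanical model** that treats the agents as soft
spheres repelling in proportion to their overlap. This vignette documents
the model as implemented: its assumptions, the parameters that matter, the
numerical choices, the design decisions that were genuinely open, and what
the package's synthetic tests do and do not demonstrate about real tumours.

## The microenvironment layer

The spatial domain is a cube divided into voxels of side
$L_{voxel} = 30\,\mu m$; the per-axis voxel count is
$\lceil \text{side}/L_{voxel} \rceil$, so the physical domain is never
truncated (ceiling division was chosen because the reference domain of
2 mm is not an integer multiple of the voxel side). Each voxel carries an
11-component state: ten exact cell censuses (total/apoptotic/necrotic/living
neuroblasts and Schwann cells, matrix-producing Schwann cells, all cells)
plus the extracellular-matrix volume fraction $M \in [0,1]$. Voxel
membership is half-open, $[iL, (i+1)L)$, with the top face closed, so the
census is unambiguous and conserved.

Intercellular signalling is abstracted to a voxel neighbourhood rule: an
agent receives a juxtacrine (contact-dependent) signal proportional to the
source-cell count in its own voxel and a paracrine (diffusive) signal, ten
times weaker, proportional to the count summed over the up-to-six
orthogonally adjacent voxels (the 3-D von Neumann neighbourhood). Living
Schwann cells source the apoptotic ($3.04\times10^{-2}$ juxtacrine) and
differentiation ($5.21\times10^{-4}$) signals felt by neuroblasts; living
neuroblasts source the proliferation signal ($3.74\times10^{-3}$) felt by
Schwann cells. Signals are linear in source-cell counts.

Oxygen is a single global dimensionless scalar — the uniform, well-perfused
vasculature assumption — expressed on the reference scale
$C_{O_2,s} = 72$ mmHg (so internal level 1 corresponds to 72 mmHg). With
`static_O2 = 1` (the default) the level is frozen; with `static_O2 = 0` it
integrates the supply-minus-consumption balance. Each living agent consumes
$1.875\times10^{-13}$ moles/h. The moles-to-dimensionless conversion factor
is not derivable from the published scales (which mix a 272–3272 range, a
0.24 level, and a 0–1 range); it is therefore a configurable parameter
whose default, set at initialisation to
$1/(\text{initial consumption} \times T_{angc})$, makes the initial balance
condition — supply equals consumption, hence zero drift — exact for any
value, and drains the reserve on the 100 h angiogenesis time scale if the
supply is lost. Angiogenesis progress relaxes first-order, with time scale
$T_{angc} = 100$ h, toward a target proportional to the current number of
VEGF-producing neuroblasts (normalised by the initial living neuroblast
count); the supply rate relaxes toward the initial supply scaled by that
progress. Only the time scale is constrained by data; the first-order form
is the simplest dynamics consistent with it.

Matrix grows per voxel by the collagen output of its matrix-producing
Schwann cells, $0.71\,\mu m^3$ per cell-hour normalised by the voxel
volume, capped at 1. Matrix producers are defined as the living,
non-hypoxic Schwann agents (the sources do not constrain this subset).

## The agent layer

Each neuroblast carries four attribute groups: physical (position, radius,
net force, neighbour count, mobility), cellular (cycle phase and clock,
degree of differentiation, death flags and apoptosis clock, telomere units,
DNA status, metabolic flags), mutational (MYCN amplification, TERT
rearrangement, ATRX inactivation — mutually exclusive — plus ALK
activation/amplification, other MAPK/RAS mutations, and p53-pathway
inactivation), and molecular (20 Boolean gene-product activities).
Schwann agents have no gene products and no differentiation state, being
taken as fully differentiated.

The population structure is 24 subclones: four clones (wild-type,
MYCN-amplified, TERT-rearranged, ATRX-inactivated) times six combinations
of MAPK/RAS state (none / ALK / other) and p53 inactivation. Within a
clone, offsets 1–3 carry wild-type p53 and offsets 4–6 the inactivated
pathway; this ordering matches the reported dominance of subclones 1–3,
13–15 and 19–21 (p53-intact) and the fitness of the ALK-mutated,
p53-intact members (2, 14, 20).

### The gene-product rule table

Each hour, product $X$ becomes active iff its regulatory conditions hold,
a Bernoulli trial at its expression level $E_X$ succeeds, and no
drug-inhibition draw vetoes it; products with violated conditions are
inactive that hour. The full supplementary rule set of the source model is
not in the published main text, so the wiring below is a reconstruction
anchored to the mechanisms the text does state, shipped as an explicit,
configurable table:

* **MYCN**: always eligible; probability $E_{MYCN} = 0.94$ in a
  MYCN-amplified, ALK-mutated cell; otherwise a configurable
  `E_MYCN_other` (default $E_{MYCN}/2$ — the level for other
  MYCN/ALK combinations is unpublished).
* **MAPK/RAS**: probability $E_{MR,1} = 0.38$ if MYCN-amplified,
  $E_{MR,2} = 0$ if MAPK-mutated without amplification, and a configurable
  wild-type baseline `E_MR_wt` (default 0; the published note cites an
  external study without printing the value).
* **p53**: eligible unless the pathway is inactivated; probability
  $E_{p53} = 0.20$, halved when MYCN is active in a MYCN-amplified cell
  (the phenomenological negative MYCN–p53 link).
* **CHK1** responds to impaired DNA; **p73** requires active CHK1;
  **CDS1** responds to unreplicated DNA; **CDC25C** requires CHK1 and CDS1
  inactive (cycle arrest); **p21/p27** require active p53 (and p73 does
  not enable them).
* **HIF** requires hypoxia; **BNIP3, IAP2, VEGF** require active HIF;
  **JAB1** is always eligible; **ID2** requires active MYCN.
* **BCL** is eligible unless BNIP3 is active, and **BAK/BAX** is always
  eligible. These two eligibilities are the package's own choices: with
  both expression levels fixed at 1 and no condition, BCL would be
  permanently active and the caspase rule below could never fire. Making
  BNIP3 (the hypoxia-induced BCL antagonist) the switch keeps the
  apoptotic machinery live exactly in the stressed regime.
* **CAS** requires (p53 or p73 active) and BCL inactive and (BAK/BAX
  active or a non-zero apoptotic signal).
* **Telomerase** requires TERT rearrangement or active MYCN; **ALT**
  requires ATRX inactivation — the three near-mutually-exclusive telomere
  maintenance routes.

### DNA, death, telomeres, cycling

Normal DNA is damaged with probability 0.77/h under hypoxia and 0.64/h
under active chemotherapy in S phase, and becomes unreplicated with
0.43/h under hypoxia in S phase (damage takes priority when both fire;
the spontaneous rate is zero). Neuroblasts repair impaired DNA in any hour
in which p53 or p73 is active — the published account gives the mechanism
("p53 repairs its DNA") but no probability, so repair is deterministic
given the flag; Schwann cells repair damaged/unreplicated DNA with the
printed 0.77/0.89 hourly probabilities.

A living cell initiates apoptosis when CAS is active, with probability
0.26/h while its DNA is damaged, or by a Bernoulli trial at the
Schwann-derived apoptotic signal. Apoptosis reverts with 0.96/h while the
apoptosis clock is under $T_{apop} = 3$ h and is irreversible afterwards
(only the time scale is published; the hard cut-off is the package's
choice). An apoptotic cell undergoes secondary necrosis with 0.2/h.
Necrosis initiates with an oxygen-dependent hourly probability

$$p_{nec}(C) = \min\!\left(1,\; \frac{2\,P_{necro,r}}{1 + (C/C_{O_2,50})^4}\right),$$

a sigmoidal dose–response in which only the half-point
$C_{O_2,50} = 1.2$ mmHg is published. The prefactor is calibrated so that
entry at the half-point equals the recovery probability
$P_{necro,r} = 0.99$, which makes the two-state entry/recovery balance sit
at exactly 50% necrotic under sustained exposure at $C_{O_2,50}$ (the
published meaning of that parameter); the fourth-power slope is a
conventional steep-switch choice. Necrotic cells emit a necrotic signal
into their von Neumann neighbourhood with probability 0.5768/h; each hit
received triggers necrosis with a configurable probability
`P_necro_sig` (default 0.1 — the receiving-side rule is unpublished).
Apoptotic or necrotic cells are removed with $P_{lysis} = 0.35$/h; living
cells are never removed.

Telomeres start at 60 units, shorten by one per division (floored at 0),
and lengthen by one with probability 0.09/h while telomerase or ALT is
active (capped at 60).

Cycling is gated by an hourly progression probability — 0.05 for
neuroblasts, damped linearly by the degree of differentiation
(a differentiated tumour behaves less aggressively; the linear factor
$1 - deg_{diff}$ is the simplest monotone choice), and 0.03 for Schwann
cells, raised additively by the neuroblast-derived proliferation signal.
No progression occurs while hypoxic or ATP-starved. Phase boundaries at
12/6/4/2 h (G1/S/G2/M) enforce checkpoints: G1→S needs p21 and p27
inactive and telomeres above the critical 20 units (or an active
maintenance route); S→G2 needs replicated DNA and CDS1 inactive; G2→M
needs CDC25C active and undamaged DNA. Schwann cells, having no gene
products, face only the DNA and telomere conditions. The radius
interpolates from $L_{cell}/2 = 5.5\,\mu m$ so the volume doubles across
G1+G2; completing M divides the cell, resetting both to the G1 start and
placing the daughter at $L_{cell}/2$ in a uniformly random direction
(the resulting overlap is resolved by the next mechanics step). All agents
start a simulation at the beginning of G1 — the cell diameter is defined
at the cycle start and agents are created with default attributes.

Hypoxia is declared below a configurable fraction (default 0.1) of the
reference oxygen scale, and a cell at zero oxygen is nourished only if the
glycolytic yield (0.0667 of oxidative phosphorylation) exceeds a
configurable ATP threshold (default 0.1, i.e. glycolysis alone is
insufficient). Neither cut-off is published.

## The mechanical layer

Cell pairs closer than the sum of their radii overlap by
$\delta = R_1 + R_2 - \lVert r_1 - r_2 \rVert$ and repel with the linear
force $F = k_1 \delta$ ($k_1 = 2.2\times10^{-3}$ N/m; interactions are
ignored at or below the overlap floor $L_{overlap} = 0$). Forces from all
neighbours within the search radius $L_{nghbr} = 17.33\,\mu m$ are summed;
for a mobile agent whose neighbour count (including itself) exceeds
$N_{nghbr,max} = 2$ the sum is magnified by $k_2 = 2$ (contact
inhibition). Motion is overdamped: per axis, the displacement in one 36 s
force-resolution step is $F\,\Delta t / (\mu (1 + M))$ with
$\mu = 0.4$ N·s/m and $M$ the local matrix fraction. The relaxation loop
repeats force evaluation, Euler displacement and boundary enforcement
until the largest per-agent displacement falls below 0.01 µm or 100
iterations (one agent-hour of 36 s steps) are spent; neither the tolerance
nor the cap is published, and the defaults bracket the reported iteration
range. Neighbour search uses a spatial hash with cell size $L_{nghbr}$;
an $O(N^2)$ reference summation is kept in R and the two are held equal in
tests. Coincident centres receive a deterministic seeded jitter direction
before force evaluation. Agents beyond the cubic boundary have their
overshoot reversed and scaled by $k_4 = 2$; the domain may expand, up to
$k_3 = 1.26$ times its initial side per dimension, when the agent count
exceeds the capacity of the matrix-free space at the tissue density
$\rho = 9.39\times10^{-5}\,\mu m^{-3}$ (the expansion factor is published,
the trigger is the package's choice). All agents default to mobile — the
attribute is recorded but no assignment rule is published.

## The step loop and determinism

One time step is one hour: neuroblasts are evaluated (sense → gene
products → telomere maintenance → DNA → differentiation → death and
removal → cycle attempt → division), then Schwann agents likewise, then
the mechanical model is relaxed, then the automaton is updated (census,
necrotic-signal emission, oxygen, angiogenesis, matrix). Agents are
evaluated serially in creation order; because every agent senses the
census recorded at the end of the previous step, the package computes the
updates as vectorised draws in that same order, which yields the identical
trajectory while keeping the single-RNG-stream determinism contract:
a (configuration, seed) pair fully determines the run, bitwise. Daughters
created mid-step are first evaluated in the following step. Whether
dead-but-unremoved agents exert forces is not specified in the sources;
they do here, until removal frees their space.

Chemotherapy inhibits six products (CHK1, JAB1, HIF, MYCN, telomerase,
p53) during active windows; the default window pattern follows two-week
cycles across the 3024 h induction course, with configurable
probabilities, since per-drug values are unpublished. A drug combination
is a 20-entry inhibition-probability vector applied at every step; an
inhibition draw suppresses its product for the current hour only (no
cumulative pharmacology).

## Experiment designs and analysis

The four shipped experiment presets encode the published designs: (1)
1200 virtual tumours with Latin-hypercube oxygen and Schwann fraction
(0.05–0.5) and random 24-way composition, cellularity 0.8, 10 runs each;
(2) 1000 Latin-hypercube gene-expression profiles over six levels at
oxygen 0.24 and Schwann fraction 0.28; (3) ten tumours crossing
MYCN-amplified fractions {0, 25, 50, 75, 100}% with two oxygen levels,
100 runs each; (4) four single-clone tumours (cellularity 1, Schwann
fraction 0.11) times 5000 Latin-hypercube drug combinations whose ten
runs take oxygen at ten regular intervals in [0, 1]. The preset-1 oxygen
range samples the published dimensionless 272–3272 interval and
normalises by its upper bound, the package's resolution of the mixed
published scales. Every preset accepts a volume scale factor: full-scale
runs (~6×10⁵–7.5×10⁵ agents over 3024 h) are far beyond a single CPU, and
the package's own tests exercise the model at ~5×10³ agents over 200 h,
which preserves densities, signal ranges and rates while shrinking only
the domain.

The analysis layer classifies runs (no living neuroblasts → regression;
otherwise mean differentiation ≥ 0.9 → differentiation; else progression
— counts only, never volumes) and ensembles by strict majority
(unclassified otherwise; the published "more than five of ten" rule is
read as a general strict majority). Clonal enrichment is the final over
initial fractional composition. Drug combinations are ineffective above
90% of the untreated baseline and effective below 1000 living neuroblasts
— read proportionally, below 10⁻³ of the baseline, at reduced scale so
the partition is invariant under proportional rescaling; intermediate
combinations are excluded from the merged analysis set. Bootstrap
confidence intervals are percentile intervals over resampled means or
medians (the published "medium" is read as "median"; the
composition-robustness preset uses means of 10-of-100 resamples, the
clonal-competition analysis medians). The round-one calibration metric —
the residual sum of squared cell-count ratios at 0/24/48/72/96/168 h —
is implemented as `calibration_rss()`; the six-round calibration
tournament itself needs external datasets and is out of scope. PCA is
delegated to `stats::prcomp`, Ward clustering to `stats::hclust`
(`ward.D2`) cut at two clusters, silhouettes to `cluster::silhouette`;
t-tests and ANOVA are deliberately not re-implemented.

## What the synthetic tests show — and what they do not

The test suite validates the implementation against closed-form values
(force law, Euler step, census, signal strengths, matrix increments),
independent oracles (an $O(N^2)$ force summation, a per-agent census
tally, enumeration of the subclone lattice), binomial recovery of every
stochastic gate at $n = 10^4$ within $\pm 3\sigma$, and the published
mechanical displacement bounds (< 0.55 µm per 36 s force step, < 11 µm
per hour) in a reduced nominal simulation of ~5000 agents over 200 h.
These checks demonstrate that the mechanism is implemented as specified
and is numerically stable at desk scale. They do not demonstrate clinical
realism: the generator emulates uniform random geometry, a uniform
vasculature, and static gene-expression levels, none of which hold in a
real tumour; full-scale emergent results (ensemble outcome distributions
over 1200 tumours, drug-trial hit counts, subclone extinction times)
require population sizes and run lengths this package does not attempt on
a CPU.

## Known limitations

Cell–cell adhesion, immune agents, per-voxel oxygen diffusion and
pharmacokinetics are deliberately out of scope, as in the source model.
The gene-product rule table is a faithful-but-uncertain reconstruction of
an unpublished supplement; every uncertain entry is a parameter or a
documented rule that a user can override. The oxygen scale conversion,
hypoxia/ATP cut-offs, necrotic-signal reception, wild-type MAPK/RAS and
non-ALK MYCN expression levels, NB DNA-repair probabilities and the
domain-expansion trigger are package-level defaults in the same sense.
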