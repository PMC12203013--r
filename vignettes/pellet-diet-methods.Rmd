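---
title: "Models and methods behind pelletdiet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pelletdiet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pelletdiet)
library(dplyr)
```

`pelletdiet` reconstructs small-vertebrate prey communities from barn-owl
pellet dissections and asks two monitoring questions of them: is a target
taxon present at a roost, and how many pellets does a survey need before a
non-detection is informative? This vignette lays out the models, the
parameters that matter, the numerical choices, and what the synthetic data
generator does and does not emulate.

## From elements to individuals (MNI)

The observation unit is one pellet's per-taxon counts of paired diagnostic
elements: left and right dentaries for mammals, beaks and skulls for birds.
The minimum number of individuals in a pellet is the larger of the two
paired counts — one left and two right dentaries imply at least two
animals. Site-level abundance sums per-pellet MNI; incidence counts pellets
whose MNI for the taxon is at least one. Three conventions to be aware of:

- Juvenile and adult material are pooled into a single taxon count before
  the records reach this package.
- A taxon represented only by non-paired fragments (all element counts
  zero) contributes MNI 0 and drops out: only dentaries, beaks and skulls
  are counted.
- Reptiles and frogs identified to order can carry dentary counts and
  receive an MNI by the same max rule, but they are excluded from the IRI
  and the diversity indices, which are restricted to taxa identifiable to
  species (mammals and birds).

MNI is deliberately a lower bound: when elements of distinct individuals
are lost asymmetrically, `max(L, R)` undercounts. The generator (below)
reproduces exactly this loss process, which is what makes parameter
recovery testable.

## Diet ranking (IRI)

Per site, each included taxon gets

- `N%` — its share of individuals,
- `V%` — its biomass share `n_i m_i / Σ n_j m_j`, with `m_i` a mean adult
  body mass from a reference table (mass is the volume proxy; no
  digestibility or energetic correction is applied),
- `FO%` — the percentage of pellets containing it,

and the composite `IRI_i = (N%_i + V%_i) × FO%_i`, reported raw and as a
share of the site total. The composite dampens the biases of each component
alone: numerically dominant but tiny prey, heavy but rare prey, and
ubiquitous trace prey all rank differently under the three components.
`V%` requires a mass for every included taxon and refuses to guess —
a missing mass is an error naming the taxon.

## Diversity

Shannon's `H = −Σ p_i ln p_i` (natural log; `0 ln 0 := 0`) and Pielou's
evenness `J = H / ln S`. Both are computed twice per site: over all
identifiable species and over mammals only, the two scopes such studies
conventionally report. `J` is undefined at richness 1 and is returned as
`NA` with a warning, never coerced to 0 — a monoculture and a perfectly
uneven community are different statements. Values are kept at full
precision internally; tables are conventionally printed at 3 significant
figures.

## Detection effort

The binomial trial is the pellet. The per-pellet presence rate `p` is
estimated as pellet incidence over pellets examined — not from individual
counts, since several individuals in one pellet are still one detection
opportunity. Then `p_n = 1 − (1 − p)^n` and the minimum effort at
confidence `c` is the smallest integer with `p_n > c` (strict, following
the `p_n > 0.99` convention), computed in closed form and then adjusted by
a one-step walk to guard the strict boundary against floating-point edge
cases. The contract `p_{n*} > c ≥ p_{n*−1}` is fuzz-tested across the
parameter space.

Two published conventions deserve a caution. Efforts read off plotted
curves are often quoted at the plotting grid's resolution (25-pellet
steps); this package always reports the exact integer `n*`, so its values
need not match curve read-offs. And printed per-site prey percentages in
such studies sometimes use denominators that cannot be reconstructed from
the same table's totals; the package reports proportions over all prey and
over mammals only, and does not attempt to match any particular printed
percentage.

## Rarefaction and extrapolation (q = 0)

Interpolated richness is the exact combinatorial expectation
`S(m) = S_obs − Σ_i C(n−x_i, m)/C(n, m)` (abundance data; the incidence
analogue replaces individuals with sampling units, i.e. pellets).
Binomial coefficients are evaluated through `lchoose()` so large samples
cannot overflow, with `C(a, b) = 0` for `a < b`. The asymptote is Chao1
(`S_obs + ((n−1)/n) f1²/(2 f2)`, or the bias-corrected
`((n−1)/n) f1(f1−1)/2` when there are no doubletons) or its incidence
analogue Chao2, and extrapolation follows the standard unseen-species
form `S_obs + f̂0 [1 − (1 − f1/(n f̂0 + f1))^{m*}]`. Only richness
(Hill order q = 0) is implemented; curves default to a grid out to 200,
the conventional plotting range for pellet studies of this size. Interpolation
is validated against exhaustive subset enumeration (n ≤ 12) and against
vegan's implementation of the same formula; the extrapolation's limit is
checked against the Chao estimate. Note that vegan's `estimateR()` applies
a different bias-correction variant of Chao1 (`f1(f1−1)/(2(f2+1))` without
the `(n−1)/n` factor), so the two disagree by design on singleton-rich
samples; the forms used here follow the rarefaction/extrapolation
framework's classic-plus-correction convention stated above.

## Composition tests

Mammal communities (and, separately, habitat-category areas) are compared
between every pair of sites as a 2 × k table. The exact p-value conditions
on both margins: all admissible tables are enumerated recursively, each
weighted by its multivariate hypergeometric probability, and tables no
more probable than the observed one are summed. Ties are compared with a
relative tolerance of 1e-7 so float ordering cannot flip a table in or
out. When the enumeration would exceed a configurable budget, a
Monte-Carlo route samples margin-preserving tables (`stats::r2dtable`)
and reports `(1 + #extreme)/(1 + n_mc)`, which is never exactly zero. The
exact route is validated against `stats::fisher.test` across all 2 × 2
tables with total ≤ 20 and random 2 × k tables; the Monte-Carlo route is
checked for convergence to the enumerated value.

Bonferroni multiplies each raw p by the number of pairs actually tested
(36 for nine sites), never by a global constant. Habitat areas are
continuous, and an exact test needs counts: areas are discretised to whole
km² by default (configurable resolution, recorded on the matrix). This
discretisation is a package decision — reasonable, but a choice — so
habitat-test p-values should be read as ordinal evidence, not exact
probabilities.

## Likelihood classification

Sites are classed against a habitat distribution model: inside the
"likely to occur" zone → high; inside only the "may occur" zone → medium;
outside both → low. Historical records are metadata and never enter the
rule. The pipeline's headline table tallies target presence by these
classes, which is how a pellet survey validates (or embarrasses) the
model.

## The synthetic generator

Each pellet draws its prey count from a zero-truncated Poisson — a pellet
exists because the owl ate something, so the zero class is removed; a
plain Poisson is available by flag. Each individual is assigned a taxon by
the site's multinomial composition, and each of its two paired elements
survives digestion, fragmentation and bench recovery independently with
probability `element_retention`. Observed MNI is then a lower bound on the
ledgered truth, with equality at retention 1 — the same information loss
the max rule faces in real material.

The default nine-site study fixes the network's design quantities: pellet
counts 100, 24, 100, 100, 40, 100, 100, 100 and 31 (695 in total, 495
excluding the two sites sourced from external datasets), likelihood
classes two high / four medium / three low, and per-site per-pellet prey
rates chosen so expected individuals match the study's totals (e.g. 106
individuals from 100 pellets at the plague site). Compositions are the
package's own choices, fixed once: a long-haired rat plague dominating
most sites (above 95% of individuals at two of them), the target dunnart
at the two high-likelihood sites (33.1% and 3.8% of individuals) and two
of the four medium-likelihood sites (2.9%, 2.3%), and one refuge-like site
where dasyurids and native mice dominate instead. Element retention
defaults to 0.9, a realistic recovery rate for dentaries in owl pellets.
Each site draws from its own substream (a stable hash of the site id mixed
with the global seed), so adding a site never perturbs another's data.

What the generator does **not** emulate: prey selectivity by the owl
(assignment is proportional sampling, matching the opportunistic-hunting
assumption and offering no selectivity dial because the monitoring design
offers none), temporal structure across collection events, pellet decay or
sub-fossil age mixture, and spatial structure within the hunting range.
Passing recovery tests therefore show the pipeline is correct under
random sampling with element loss — not that field collections satisfy
those assumptions.

`presence_rate_truth()` gives the generator-truth detection rate. The
closed form thins the taxon probability by per-individual detectability
`d = 1 − (1 − r)²` inside the probability generating function of the
(zero-truncated) Poisson: `P(absent) = (e^{λ(1−pd)} − 1)/(e^λ − 1)`. The
derivation holds for any retention, so the closed form is the default and
the Monte-Carlo route (same generative rules, ≥ 1e5 pellets) serves as the
independent cross-check rather than the primary path.

## Numerical and design choices, in brief

- CSV interchange is UTF-8, comma-separated, header required, ISO-8601
  dates; records are long (one row per site/pellet/taxon/element), with
  zero-count rows legal and ignored.
- Coordinates are optional so confidential sites can be carried.
- `min_pellets()` uses strict `>`; reported at unit-pellet resolution.
- Rarefaction uses log-space binomial coefficients; `C(a,b) = 0` for
  `a < b`.
- Fisher ties use 1e-7 relative tolerance; Monte-Carlo p-values use the
  add-one convention.
- Evenness at richness 1 is `NA` + warning, not 0.
- Bootstrap confidence intervals for rarefaction are not implemented; the
  curves and asymptotes are point estimates.
- Problem sizes in the test suite (sites of tens to a few hundred pellets,
  enumeration oracles at n ≤ 12, Monte-Carlo at 1e4–1e6) were chosen as
  the smallest sizes at which the statistical checks have power.

## Worked check

```{r example}
st <- generate_study(default_study_scenarios(), seed = 17)
rep <- run_pipeline(st$records, default_mass_table(), st$sites, seed = 17)
rep$presence_by_likelihood
filter(rep$diversity, site_id == "goolma", scope == "all")
```

The plague site's diversity collapses towards zero exactly as a
two-species, 99%-dominated community must (`H` near 0, evenness near 0),
and the presence tallies by likelihood class are the pipeline's headline
output.
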