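# pelletdiet

Barn owls are efficient, non-invasive samplers of small vertebrates: the
indigestible bone, fur and feather they regurgitate as pellets beneath a
roost preserves a record of the surrounding prey community. `pelletdiet`
turns dissected pellet contents into the standard quantitative outputs of an
owl-pellet diet study, with a particular focus on establishing
presence/absence of a threatened target taxon (a dunnart, *Sminthopsis
douglasi*) across a network of roost sites and deciding how many pellets a
survey needs. It is aimed at ecologists and threatened-species monitoring
programs working from per-pellet skeletal-element counts.

## What it computes

- **MNI (minimum number of individuals).** Per pellet and taxon, the larger
  of the two paired-element counts: `MNI = max(left dentaries, right
  dentaries)` for mammals, `max(beaks, skulls)` for birds. Site abundance is
  the sum of per-pellet MNI; incidence is the number of pellets containing
  the taxon.
- **IRI (Index of Relative Importance).** Diet ranking per site,
  `IRI_i = (N%_i + V%_i) × FO%_i`, where `N%` is the numerical share of
  individuals, `V%` the biomass share `n_i m_i / Σ n_j m_j` (mean adult body
  mass as the volume proxy), and `FO%` the percentage of pellets containing
  the taxon. Only taxa identifiable to species (mammals and birds) enter.
- **Diversity.** Shannon's index `H = −Σ p_i ln p_i` and Pielou's evenness
  `J = H / ln S`, reported for all identifiable species and for mammals
  only.
- **Detection effort.** A binomial presence model per pellet: with presence
  rate `p` (pellet incidence / pellets examined), the chance of at least
  one detection in `n` pellets is `p_n = 1 − (1 − p)^n`, and the minimum
  effort for a confident single detection is the smallest `n` with
  `p_n > 0.99` (or any other confidence level).
- **Rarefaction and extrapolation** of species richness (Hill order q = 0),
  abundance- and incidence-based, with Chao1/Chao2 asymptotes: exact
  combinatorial interpolation `S(m) = S_obs − Σ_i C(n−x_i, m)/C(n, m)` and
  the standard unseen-species extrapolation.
- **Composition tests.** Pairwise Fisher exact tests (2 × k, full
  enumeration with a Monte-Carlo fallback) between sites for mammal
  communities and for habitat-category composition, Bonferroni-adjusted
  over the pairs actually tested.
- **Synthetic studies.** A generator with known ground truth — multinomial
  species composition, zero-truncated Poisson prey counts per pellet,
  independent loss of paired elements — so every stage of the pipeline can
  be exercised and calibrated without field data.

## Worked example

```r
library(pelletdiet)

st  <- generate_study(default_study_scenarios(), seed = 17)
rep <- run_pipeline(st$records, default_mass_table(), st$sites, seed = 17)
rep
#> Pellet-diet study report
#>   sites: 9  pellets: 695
#>   target taxon: Sminthopsis douglasi present at 4 site(s)
#>   presence by likelihood class:
#>     high   2/2
#>     medium 2/4
#>     low    0/3
```

The nine simulated roosts contribute 695 pellets; the target dunnart is
recovered at both high-likelihood sites, two of four medium-likelihood
sites and no low-likelihood site — the presence-by-likelihood summary that
validates a habitat model. Per-site results are plain tibbles:

```r
dplyr::filter(rep$diversity, site_id == "goolma")
#>   site_id scope   shannon_h evenness richness individuals
#> 1 goolma  all        0.0943    0.136        2         105
#> 2 goolma  mammals    0.0943    0.136        2         105

dplyr::filter(rep$effort, site_id %in% c("toorak", "nelia"))
#>   site_id taxon                confidence n_star
#> 1 nelia   Sminthopsis douglasi       0.95     29
#> 2 nelia   Sminthopsis douglasi       0.99     44
#> 3 toorak  Sminthopsis douglasi       0.95      8
#> 4 toorak  Sminthopsis douglasi       0.99     12
```

At the plague-dominated site (`goolma`) diversity collapses towards zero;
at the site where the dunnart is a third of prey individuals (`toorak`) a
dozen pellets already give better than 99% detection probability, while a
sparse population (`nelia`) needs 44. Curves come back as objects with
`tidy()`, `glance()` and `autoplot()` methods:

```r
asm <- assemblage(st$records)
dc  <- detection_curve(dplyr::filter(asm, site_id == "toorak"),
                       "Sminthopsis douglasi")
autoplot(dc)
rc  <- rarefaction_curve(dplyr::filter(asm, site_id == "toorak"),
                         mode = "incidence")
autoplot(rc)
```

A thin command-line wrapper (`inst/cli/pelletdiet.R`) exposes `simulate`
and `report` subcommands over the same functions.

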