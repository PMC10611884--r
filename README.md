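# pdst — rank pesticide active ingredients by aquatic risk

Freshwater ecosystems downstream of intensive agriculture — the streams of
Queensland's sugar-cane catchments draining to the Great Barrier Reef are the
motivating case — receive pesticide active ingredients (PAIs) in runoff.
Farmers, agronomists and resellers choosing between registered products need
a transparent way to tell which active ingredient poses less risk to those
waterways. `pdst` implements a pesticide decision support tool that scores
each PAI with a single, continuous **aquatic risk** value built from readily
available inputs (label application rate, K<sub>OC</sub>, soil and water
half-lives, a chronic ecotoxicity threshold), so alternatives can be ranked
rather than binned into coarse risk classes.

## The model

For each active ingredient:

**Measure of effect** (exposure-to-toxicity surrogate, ML/ha):

```
effect = maximum application rate (umol PAI/ha) / threshold (umol/ML)
```

the megalitres of water needed per hectare to dilute the applied dose down to
the threshold. The threshold is a freshwater default guideline value (DGV)
where one exists, otherwise an ecotoxicity threshold value (ETV) derived from
chronic species toxicity data: with at least 5 species from 4 taxonomic
groups, a species sensitivity distribution (SSD; log-logistic for small
datasets, Burr III otherwise) is fitted and the PC95 — the 5th percentile,
protecting 95% of species — is used (PC99 for potential biomagnifiers with
log K<sub>OW</sub> ≥ 4); with fewer data, the lowest species value is divided
by an assessment factor.

**Measure of mobility and persistence** (days² × proportion):

```
mobility = DT50_soil × DT50_water × proportion transported
proportion transported = max(0, (-10.076 · log10(Koc) + 39.123) / 100)
```

where the transported proportion comes from a linear regression of
experimental runoff losses (rainfall-simulation trials on a hydrosol soil)
on log<sub>10</sub> K<sub>OC</sub>.

**Aquatic risk** is the product `effect × mobility`, reported on the
conventional `risk / 100` scale. It is a unitless ranking score — a
likelihood that a PAI reaches a waterway and causes harm — not a predicted
concentration. Band or spot spraying of a fraction *f* of the field scales
the rate, and hence the risk, by exactly *f*; tank-mix risks are summed as an
indicative total.

## Worked example

```r
library(pdst)
tab  <- pdst_reference_data()          # 47 PAIs, 48 formulation rows
risk <- pdst_compute(tab)              # max label rate, broadcast regime
head(risk[order(risk$rank_by_risk),
          c("label", "effect", "mobility_persistence",
            "aquatic_risk_reported")], 8)
```

```
             label   effect mobility_persistence aquatic_risk_reported
         cadusafos  2197801                  182               4000001
      chlorpyrifos 21276551                    4                851059
              MSMA     5831                 1354                 78952
      clothianidin     1724                 3938                 67891
       metolachlor     3757                 1170                 43957
          fipronil     5618                  777                 43652
 imidacloprid (SR)     4167                 1046                 43587
           ametryn    20000                  155                 31000
```

The organophosphate insecticides cadusafos and chlorpyrifos head the
ranking: both combine extreme toxicity (effect in the millions of ML/ha)
with enough mobility to reach waterways. A large `effect` with tiny
`mobility` (chlorpyrifos) and the reverse (clothianidin) can yield similar
risks — that trade-off is why the scalar product is used.

Comparing two PSII-inhibiting herbicides:

```r
a <- lookup_pai(risk, "atrazine"); b <- lookup_pai(risk, "amicarbazone")
compare_pais(a, b)
#> verdict: b_dominates | preferred: b     (risks 889916 vs 106750)
```

Amicarbazone sits below and to the left of atrazine on both axes, so it
poses the lower aquatic risk. A 10% band-spray regime
(`pdst_compute(tab, regime = spray_regime("band", 0.10))`) divides every
risk by exactly 10; `tank_mix_risk()` sums components (diuron + hexazinone:
337008 + 611520 = 948528).

A command-line interface wrapping these functions ships at `inst/cli/pdst`
(`pdst compute | compare | tankmix | plot | derive-etv | calibrate`).

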