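# Default configuration for ecotoxicity threshold derivation.
#
# auto_distribution_threshold: below this number of species the SSD engine
# fits a log-logistic; at or above it, a Burr III.
auto_distribution_threshold: 8

# Assessment factors applied to the single lowest species value when the
# minimum-data rule for an SSD is not met, keyed by the endpoint class of
# that lowest value. These defaults are an editable reconstruction of common
# guideline practice, not values fixed by the scoring scheme itself.
assessment_factors:
  chronic: 10
  chronic_estimated: 20
  converted_acute: 100

# Mode-of-action groups treated as "most sensitive" when a toxicity dataset
# is declared bimodal: phototrophs for herbicides, arthropods for
# insecticides. Empty means no subsetting is defined for that class.
sensitive_groups:
  herbicide: [phototroph]
  insecticide: [arthropod]
  fungicide: []
  nematicide: []

# Reliability rubric: points accumulate monotonically with the number of
# species, number of taxonomic groups, endpoint quality and SSD fit quality;
# class cutoffs map total points to a reliability class.
reliability_rubric:
  species_thresholds: [5, 8, 15, 30]
  group_thresholds: [4, 6]
  endpoint_points:
    all_converted_acute: 0
    mixed: 1
    all_chronic: 2
  fit_points:
    poor: 0
    acceptable: 1
    good: 2
  class_cutoffs:
    very_low: 0
    low: 2
    moderate: 4
    high: 7
    very_high: 9
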