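Package: sdmbaseline
Title: Historical Community Baselines from Presence-Only Species Distribution Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs historical community composition for a focal
    watershed from presence-only occurrence records. Provides quality
    filtering of museum-style occurrence data (georeferencing-error radius,
    collection year, voucher status), grid snapping and deduplication,
    L1-regularized maximum-entropy habitat suitability models fitted over
    environmental layer stacks with a replicated train/test scheme, ROC/AUC
    and binomial omission validation with a three-criterion model acceptance
    rule, extraction of per-species maximum suitability inside a focal
    watershed to form a modeled community table, and assemblage comparison
    via Bray-Curtis dissimilarity and Mantel permutation tests. A synthetic
    landscape and virtual-species simulator supplies ground-truth data so
    every pipeline stage can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    mgcv,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
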