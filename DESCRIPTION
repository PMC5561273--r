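Package: hostdiscrim
Title: Linking Aphid Host-Race Discrimination to Untargeted Leaf Metabolomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline connecting electrical penetration graph (EPG)
    behavioural profiles of pea aphid host races to untargeted MALDI-TOF leaf
    metabolomes. Cleans per-recording EPG feature tables (imputation,
    zero-inflation filter, correlation pruning) and summarises host acceptance
    as phloem-ingestion time (E2) and a linear-discriminant score (LD1);
    derives per-species discrimination and overall-acceptability scores; bins
    peak lists into 0.2-Da m/z bins normalised to percent total ion count;
    ranks bins by random-forest importance under response uncertainty using
    repeated draws from the score means and standard errors, with jack-knife
    stability analysis; and putatively annotates important bins by
    monoisotopic adduct mass matching. A synthetic-data generator with planted
    signal compounds makes every stage testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
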