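Package: cnescreen
Title: Genome-Wide Screen for Lineage-Specific Divergence of Conserved
    Non-Coding Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects conserved non-coding elements (CNEs) that diverged
    specifically in trait-loss lineages (for example, limbless snakes or
    vision-impaired subterranean mammals). Reconstructs ancestral CNE
    sequences under a Jukes-Cantor model, computes branch-length-normalized
    sequence identities, screens for lineage-specific divergence with global
    and local Z-scores, and estimates false discovery rates from a
    simulation null and a sister-lineage control. Downstream analyses
    include GREAT-style regulatory-domain gene association, one-sided
    Fisher enrichment with subsampling Z-scores, and position weight matrix
    occupancy scoring with GC-matched cutoffs to quantify transcription
    factor motif decay. A synthetic-data module simulates CNE evolution
    along a phylogeny with planted relaxation of selection on trait-loss
    branches, providing ground truth for calibration and power analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    IRanges,
    S4Vectors,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
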