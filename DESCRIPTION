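Package: epihotspot
Title: Differential DNA Methylation, DMR Classification and Epimutation
    Hotspot Analysis for Family-Structured Cohorts
Version: 0.1.0
Authors@R:
    person("Epihotspot", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for reduced-representation bisulfite
    sequencing (RRBS) differential-methylation analysis in small,
    family-structured patient/control cohorts. Calls differentially
    methylated CpGs with a replicate-aware binomial likelihood-ratio test,
    builds differentially methylated region (DMR) tiles by merging,
    ambiguity removal and symmetric extension, classifies tiles as shared
    or family-specific, computes odds-ratio enrichments over chromatin
    annotations and TSS-distance bins, associates regions to genes by a
    basal-plus-extension regulatory-domain rule, joins DMRs with
    differential expression (quadrant count ratio) and lamina-associated
    domain (LAD) redistribution, and tests epimutation-hotspot proximity
    against matched random backgrounds. Ships a seeded synthetic-methylome
    generator with planted DMRs so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
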