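Package: nickhdr
Title: Dual-Cas9 Nickase HDR Editing-Outcome Analysis from Long-Read Amplicons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and quantification tools for dual-Cas9-nickase (D10A)
    homology-directed repair of point variants, modelled on correction of the
    junctional epidermolysis bullosa hotspot LAMB3 c.1903C>T. Enumerates PAM-out
    paired-nickase guides, designs single-stranded oligodeoxynucleotide repair
    templates with silent blocking and bridging SNVs, classifies amplicon
    sequencing reads into perfect HDR, imperfect HDR, indel and unedited
    outcomes, profiles kilobase-scale on-target deletions from long amplicons
    (including alleles that evade short-amplicon genotyping), compares
    off-target sites between control and edited samples, and quantifies
    exon inclusion and template-SNV incorporation in cDNA reads. A seedable
    Nanopore-like read simulator with explicit PCR primer-capture logic
    provides ground-truth mixtures for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
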