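Package: radpopgen
Title: Population Genetics of RAD-Seq Genotype Catalogs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing diploid SNP genotype catalogs produced by
    reduced-representation sequencing (RAD-seq/ddRAD-seq) of structured
    populations such as clonally propagated crop varieties. Computes per-site
    and per-population summary statistics (major-allele frequency, observed
    and expected heterozygosity, sample-size-corrected nucleotide diversity,
    inbreeding coefficient), discovers private and common non-reference
    alleles with diagnostic-marker filters, scans two-group contrasts (for
    example disease-resistant versus susceptible accessions) for
    group-specific alleles, estimates pairwise FST (Weir-Cockerham and
    Hudson), summarises per-chromosome locus density, and simulates genotype
    catalogs with planted truth for validation. Includes a command-line
    interface mirroring the workflow of the Stacks 'populations' program.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
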