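Package: parshift
Title: Simulation and Inference of an NAHR-Mediated Pseudoautosomal Boundary Shift
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse a pseudoautosomal-region length
    polymorphism created by non-allelic homologous recombination (NAHR)
    between two short paralogous LTR repeats on the human X and Y
    chromosomes. Provides a parameterized synthetic X/Y genome builder with
    full truth records, a site-level read-count simulator, allele-frequency
    profiling with heterozygous-band segmentation and breakpoint
    delineation, paralogous-sequence-variant (PSV) junction typing of
    fusion-repeat amplicons, Y-STR based TMRCA estimation with calendar
    conversion, and an end-to-end pipeline from simulated rearrangement to
    recovered call set.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
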