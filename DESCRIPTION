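Package: taqing
Title: Detection and Simulation of Multiplexed Double-Strand-Break Genome
    Rearrangements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects and classifies large-scale genome rearrangements on a
    dual-haplotype hybrid reference built from two diverged parental genomes:
    aneuploidy and large copy-number variants from binned read depth with
    array-CGH concordance, break-induced repair and short gene conversion
    from reciprocal zero/double coverage on the two haplotypes, and
    translocation breakpoints from soft-clipped and discordant read evidence
    with repair-mechanism classification (direct religation of cohesive
    restriction-site overhangs, microhomology-mediated end joining, and
    repeat-mediated homologous recombination).  Also provides
    small-variant post-filters, an empirical 3D-proximity
    resampling null for translocation partner distances, summary reporting,
    and a simulator of restriction-enzyme-induced genome restructuring that
    emits mechanism-faithful truth sets, coverage tracks, array log-ratios,
    junction read evidence and a synthetic 3D chromosome coordinate model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
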