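Package: mitocodon
Title: Mitochondrial Genome Organization, Codon Usage Bias and Repeat Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterization toolkit for annotated (insect) mitochondrial
    genomes: gene-organization arithmetic on circular genomes (sizes,
    intergenic spacers, overlaps, strand partition), nucleotide composition
    and AT/GC strand-asymmetry skews per region, codon usage analysis under
    the invertebrate mitochondrial code (RSCU, amino-acid frequencies,
    GC12/GC3/GC3s, Wright's effective number of codons with the ENc-plot
    expected curve, PR2-bias coordinates, neutrality regression),
    Nei-Gojobori Ka/Ks estimation with Jukes-Cantor correction,
    sliding-window nucleotide diversity, and repeat detection
    (MISA-threshold microsatellites, maximal exact dispersed repeats in four
    orientation classes, tandem-unit decomposition, stem-loop candidates).
    Includes seedable generators for synthetic annotated genomes, codon sets
    and omega-divergent codon alignments with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    tools,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
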