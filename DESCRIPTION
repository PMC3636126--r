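Package: plastcomp
Title: Comparative and Phylogenetic Analysis of Chloroplast Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for the comparative analysis of annotated
    chloroplast (plastid) genomes. Parses GenBank flat files and simple CSV
    annotation dialects, extracts the eleven plastome feature classes,
    compares feature content between genomes, computes alignment-free
    base-base correlation (BBC) feature vectors and maximal-exact-match
    based genome distances D = -log2(Nmat/Lmax), builds neighbor-joining
    trees with Newick/Nexus and PHYLIP/MEGA/Nexus matrix writers, transfers
    annotations to draft genomes by seeded local alignment, and simulates
    quadripartite plastomes (LSC + IRa + SSC + IRb) evolved along known
    trees for fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    phangorn,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
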