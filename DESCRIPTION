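Package: ldgrid
Title: Large-Scale Mean Linkage Disequilibrium from Relatedness-Matrix Moments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates mean linkage disequilibrium (LD) over large genomic
    grids -- whole genome, per chromosome, between chromosomes, and
    high-resolution within-chromosome bins -- from second moments of genetic
    relatedness matrices (GRMs) in O(n^2 m) time instead of the O(n m^2)
    cost of exhaustive pairwise r2. Includes the associated sampling
    variances, a scaled inter-chromosomal LD index, an LD-decay regression
    of chromosomal LD on inverse SNP count, a population-structure
    surrogate based on the top GRM eigenvalue, PLINK binary genotype
    input/output, a genotype simulator with controlled LD-block
    architecture, and exhaustive brute-force oracles for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
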