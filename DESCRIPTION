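Package: epistabu
Title: Epistasis Detection by Genetic-Tabu Search over Bayesian Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects epistatic interactions between SNP loci and a binary
    case-control phenotype by learning a Bayesian network over loci and
    phenotype with a genetic algorithm whose crossover and mutation operators
    carry tabu-search memory. Candidate networks are scored by the Bayesian
    Information Criterion; the initial population is seeded from a bitwise
    mutual-information screen of locus combinations against the phenotype.
    Includes a GAMETES-style simulator of purely epistatic two- and
    three-locus penetrance models for calibration and benchmarking, a
    chi-square prefilter for large inputs, and command-line entry points.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
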