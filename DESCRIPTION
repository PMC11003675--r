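Package: serann
Title: Self-Replicating Artificial Neural Networks Under Wright-Fisher Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates populations of self-replicating artificial neural
    networks (SeRANNs): individuals whose heritable material is a fixed-length
    bit-string genotype, decoded to a network-architecture phenotype by a
    pre-trained "ribosomal" autoencoder codec. Each individual is trained both
    to classify images (its fertility) and to copy its own genotype (its
    replication task), so mutations arise endogenously as replication errors.
    Populations evolve under a Wright-Fisher model with fertility selection,
    survival selection on decodable phenotypes, and drift. Includes a
    stochastic architecture generator, the autoencoder codec with a relaxed
    Bernoulli latent code, the evolutionary engine, and estimators for
    mutation rates, fitness, the distribution of fitness effects, mutational
    robustness, pairwise epistasis, and allele-frequency trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
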