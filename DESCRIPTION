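Package: regomax
Title: Reduced Google Matrix Analysis of Signed Directed Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Google matrix tools for directed protein-protein interaction
    networks with activation/inhibition link signs. Builds the damped
    column-stochastic Google matrix, computes PageRank and CheiRank, and
    implements the reduced Google matrix (REGOMAX) decomposition
    GR = Grr + Gpr + Gqr for a node subset via either a direct Schur-complement
    solve or a spectral series. Includes the bifunctional "Ising" doubling of
    signed networks with split PageRank and magnetization, an exact PageRank
    sensitivity derivative with respect to single-link perturbations of the
    reduced matrix, selection of external influencer proteins by aggregate
    sensitivity, friend/follower interaction diagrams, linear and power-law
    fits of sensitivity against PageRank, and a seeded generator of
    MetaCore-like synthetic networks for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
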