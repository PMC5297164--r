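Package: paretorank
Title: Prioritising Implementation Barriers from Expert Rank-Order Ballots
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decision support for prioritising barriers to the implementation
    of evidence-based clinical care. Expert panellists each supply complete
    rank-order ballots over a behaviour's barriers on two attributes (how
    influential each barrier is in preventing the behaviour, and how difficult
    it would be to overcome). Ballots are aggregated into tie-permitting group
    rankings with Condorcet-consistent voting rules on the pairwise-majority
    graph (Schulze beatpath by default; Copeland and exact Kemeny-Young
    alternatives), and barriers are classified as most desirable, desirable or
    least desirable targets by weak Pareto dominance on the two group ranks,
    with quadrant scatter plots. Includes a Mallows-model panel simulator for
    end-to-end validation, bundled fixtures from a published acute stroke-care
    expert panel survey, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
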