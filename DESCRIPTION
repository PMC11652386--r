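Package: snpcc
Title: Case-Control Single-SNP Association Testing with FPRP and BFDP
    Noteworthiness Screening
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for candidate-gene case-control association studies of
    biallelic SNPs. Reads and validates genotype count tables or per-subject
    genotype records, tests each cohort for Hardy-Weinberg equilibrium with
    the 1-df chi-squared goodness-of-fit test, builds the six classical 2x2
    genetic contrasts (additive 1 and 2, dominant, recessive, overdominant,
    allelic), estimates odds ratios with Woolf confidence intervals and Wald
    z-test p-values (with Haldane-Anscombe correction for zero cells), and
    screens findings for noteworthiness via the false-positive report
    probability (FPRP) and the Bayesian false discovery probability (BFDP)
    from Wakefield's approximate Bayes factor, across a grid of prior
    probabilities. Includes a multinomial genotype simulator with controls
    in Hardy-Weinberg equilibrium and cases tilted by genotype-specific odds
    ratios, for calibration and power experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
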