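#' Allele frequencies of a cohort
#'
#' Sample allele frequencies from genotype counts:
#' `freq_ref = (2 n_ref_hom + n_het) / (2n)`.
#'
#' @param counts A [genotype_counts()] object.
#' @return Named numeric vector `c(ref = , alt = )` summing to 1.
#' @examples
#' allele_frequency(genotype_counts(81, 96, 33))  # ref = 258/420
#' @export
allele_frequency <- function(counts) {
  stopifnot(inherits(counts, "genotype_counts"))
  ac <- allele_counts(counts)
  ac / (2 * counts$n)
}

#' Hardy-Weinberg expected genotype counts
#'
#' Expected genotype class counts `(p^2 n, 2pq n, q^2 n)` under random
#' mating, with `p` the sample reference-allele frequency. The expectations
#' sum to `n` by construction.
#'
#' @param counts A [genotype_counts()] object.
#' @return Named numeric triple (`ref_hom`, `het`, `alt_hom`).
#' @export
expected_genotype_counts <- function(counts) {
  stopifnot(inherits(counts, "genotype_counts"))
  p <- allele_frequency(counts)[["ref"]]
  q <- 1 - p
  c(ref_hom = p^2, het = 2 * p * q, alt_hom = q^2) * counts$n
}

#' Hardy-Weinberg equilibrium chi-squared test
#'
#' Goodness-of-fit test of the observed genotype counts against their
#' Hardy-Weinberg expectation: `X^2 = sum (obs - exp)^2 / exp` over the
#' three genotype classes, referred to a chi-squared distribution with one
#' degree of freedom (the allele frequency is estimated from the data). No
#' continuity correction is applied.
#'
#' A monomorphic cohort (only one allele observed) has nothing to test;
#' rather than abort a batch run it yields a flagged degenerate result with
#' `X^2 = 0`, `p = 1` and a warning.
#'
#' @param counts A [genotype_counts()] object.
#' @return An object of classes `hwe_test` and `htest` with components
#'   `statistic`, `parameter` (df = 1), `p.value`, `observed`, `expected`,
#'   `allele_freq` and the logical `monomorphic`.
#' @examples
#' hwe_chi_square(genotype_counts(89, 100, 21))  # X^2 ~ 0.86, p ~ 0.354
#' @export
hwe_chi_square <- function(counts) {
  stopifnot(inherits(counts, "genotype_counts"))
  obs <- c(ref_hom = counts$n_ref_hom, het = counts$n_het,
           alt_hom = counts$n_alt_hom)
  freq <- allele_frequency(counts)
  mono <- freq[["ref"]] %in% c(0, 1)
  if (mono) {
    warning("monomorphic cohort (allele frequency ", freq[["ref"]],
            "): HWE test degenerate, X^2 = 0, p = 1", call. = FALSE)
    expected <- as.numeric(obs)
    names(expected) <- names(obs)
    chi2 <- 0
    p_value <- 1
  } else {
    expected <- expected_genotype_counts(counts)
    chi2 <- sum((obs - expected)^2 / expected)
    p_value <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  structure(
    list(statistic = c("X-squared" = chi2),
         parameter = c(df = 1),
         p.value = p_value,
         method = paste("Hardy-Weinberg equilibrium chi-squared",
                        "goodness-of-fit test (1 df)"),
         data.name = sprintf("genotype counts (%d, %d, %d)",
                             obs[[1L]], obs[[2L]], obs[[3L]]),
         observed = obs,
         expected = expected,
         allele_freq = freq,
         monomorphic = mono),
    class = c("hwe_test", "htest")
  )
}
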