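#' Configuration for the case-control genotype simulator
#'
#' The generative model mirrors a marginal case-control design at one
#' biallelic SNP: controls are drawn from the Hardy-Weinberg genotype
#' distribution at the control alternate-allele frequency, and case
#' genotype probabilities are the control probabilities tilted by
#' genotype-specific odds ratios (see [case_genotype_distribution()]).
#'
#' Defaults reflect a typical candidate-gene study of schizophrenia:
#' two cohorts of 210 subjects each, a control minor-allele frequency of
#' 0.34, and no effect (`or_het = or_hom = 1`).
#'
#' @param snp A [snp_info()] describing the simulated variant.
#' @param control_alt_freq Alternate-allele frequency in controls, in
#'   (0, 1).
#' @param or_het,or_hom Odds ratios of the heterozygote and the alternate
#'   homozygote relative to the reference homozygote (> 0). These are the
#'   estimands of the additive-1 and additive-2 models.
#' @param n_cases,n_controls Cohort sizes (>= 1).
#' @param seed Integer seed for bit-reproducible draws, or `NULL` to use
#'   the current RNG stream.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(snp = snp_info("sim1", gene = "SIM",
                                             ref_allele = "G",
                                             alt_allele = "A"),
                              control_alt_freq = 0.34,
                              or_het = 1, or_hom = 1,
                              n_cases = 210, n_controls = 210,
                              seed = NULL) {
  stopifnot(inherits(snp, "snp_info"),
            is.numeric(control_alt_freq), length(control_alt_freq) == 1L,
            control_alt_freq > 0, control_alt_freq < 1,
            is.numeric(or_het), or_het > 0,
            is.numeric(or_hom), or_hom > 0,
            n_cases >= 1, n_controls >= 1,
            n_cases == round(n_cases), n_controls == round(n_controls))
  structure(list(snp = snp, control_alt_freq = control_alt_freq,
                 or_het = or_het, or_hom = or_hom,
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "simulation_config")
}

.control_genotype_probs <- function(q) {
  p <- 1 - q
  c(ref_hom = p^2, het = 2 * p * q, alt_hom = q^2)
}

#' Case genotype distribution under genotype-specific odds ratios
#'
#' Controls follow Hardy-Weinberg proportions `f = (p^2, 2pq, q^2)` at the
#' control alternate-allele frequency `q`. Case probabilities are the
#' exposure-odds tilt `f * (1, or_het, or_hom)`, renormalised. Under this
#' construction the expected sample odds ratios of the additive-1 and
#' additive-2 contrasts converge to `or_het` and `or_hom` as the cohort
#' sizes grow, without any assumption about disease prevalence.
#'
#' @param config A [simulation_config()].
#' @return Named probability triple (`ref_hom`, `het`, `alt_hom`).
#' @examples
#' cfg <- simulation_config(control_alt_freq = 0.5, or_het = 1, or_hom = 9)
#' case_genotype_distribution(cfg)  # (1, 2, 9) / 12
#' @export
case_genotype_distribution <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  f <- .control_genotype_probs(config$control_alt_freq)
  w <- f * c(1, config$or_het, config$or_hom)
  w / sum(w)
}

#' Simulate a case-control cohort pair
#'
#' Draws control genotype counts from a multinomial at the Hardy-Weinberg
#' distribution and case counts from the tilted distribution of
#' [case_genotype_distribution()]. With a fixed `seed` in the config the
#' draw is bit-reproducible; the seed is recorded on the result for
#' provenance.
#'
#' @param config A [simulation_config()].
#' @param subjects If `TRUE`, also materialise per-subject records (with
#'   deterministic IDs `case_0001`, `ctrl_0001`, ...) as attribute
#'   `"subjects"` of the result, in the [read_subjects()] layout.
#' @return A [cohort_pair()]; attribute `"seed"` carries the seed used
#'   (or `NA` when drawn from the ambient RNG stream).
#' @examples
#' simulate_cohort_pair(simulation_config(seed = 1))
#' @export
simulate_cohort_pair <- function(config, subjects = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  f_ctrl <- .control_genotype_probs(config$control_alt_freq)
  f_case <- case_genotype_distribution(config)
  k_ctrl <- as.integer(stats::rmultinom(1L, config$n_controls, f_ctrl))
  k_case <- as.integer(stats::rmultinom(1L, config$n_cases, f_case))
  pair <- cohort_pair(config$snp,
                      cases = genotype_counts(k_case[1L], k_case[2L],
                                              k_case[3L]),
                      controls = genotype_counts(k_ctrl[1L], k_ctrl[2L],
                                                 k_ctrl[3L]))
  attr(pair, "seed") <- if (is.null(config$seed)) NA_integer_ else config$seed
  if (isTRUE(subjects)) {
    lab <- .genotype_labels(config$snp)
    geno_str <- c(paste0(config$snp$ref_allele, "/", config$snp$ref_allele),
                  paste0(config$snp$ref_allele, "/", config$snp$alt_allele),
                  paste0(config$snp$alt_allele, "/", config$snp$alt_allele))
    names(geno_str) <- names(lab)
    expand <- function(k, prefix, phenotype) {
      n <- sum(k)
      data.frame(
        subject_id = sprintf("%s_%04d", prefix, seq_len(n)),
        phenotype = phenotype,
        snp_id = config$snp$snp_id,
        genotype = rep(geno_str, times = k),
        stringsAsFactors = FALSE, row.names = NULL
      )
    }
    attr(pair, "subjects") <- rbind(expand(k_case, "case", "case"),
                                    expand(k_ctrl, "ctrl", "control"))
  }
  pair
}
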