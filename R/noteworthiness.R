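#' Configuration of the FPRP / BFDP noteworthiness screen
#'
#' Defaults follow the usual candidate-gene screening setup: a target odds
#' ratio of 1.5, FPRP prior probabilities 0.25, 0.1, 0.01, 0.001, 0.0001
#' with a noteworthiness cutoff of 0.2, and BFDP priors 0.01, 0.001,
#' 0.00001 with a cutoff of 0.8. A more permissive FPRP cutoff of 0.5 is
#' also in common use; pass `fprp_cutoff = 0.5` to adopt it.
#'
#' @param or_threshold Target odds ratio the screen is powered against
#'   (> 1; protective effects use its reciprocal internally).
#' @param priors Descending vector of prior probabilities of a true
#'   association, each in (0, 1), for the FPRP grid.
#' @param bfdp_priors Prior probabilities for the BFDP grid.
#' @param fprp_cutoff FPRP below this is flagged noteworthy.
#' @param bfdp_cutoff BFDP below this is flagged noteworthy.
#' @return An object of class `noteworthiness_config`.
#' @export
noteworthiness_config <- function(or_threshold = 1.5,
                                  priors = c(0.25, 0.1, 0.01, 0.001, 1e-4),
                                  bfdp_priors = c(0.01, 0.001, 1e-5),
                                  fprp_cutoff = 0.2,
                                  bfdp_cutoff = 0.8) {
  stopifnot(is.numeric(or_threshold), length(or_threshold) == 1L,
            or_threshold > 1,
            all(priors > 0 & priors < 1),
            all(bfdp_priors > 0 & bfdp_priors < 1),
            fprp_cutoff > 0, fprp_cutoff < 1,
            bfdp_cutoff > 0, bfdp_cutoff < 1)
  structure(list(or_threshold = or_threshold,
                 priors = sort(priors, decreasing = TRUE),
                 bfdp_priors = sort(bfdp_priors, decreasing = TRUE),
                 fprp_cutoff = fprp_cutoff, bfdp_cutoff = bfdp_cutoff),
            class = "noteworthiness_config")
}

#' Power to detect a target odds ratio at the observed significance level
#'
#' Two-sided rejection probability of the Wald z-test, evaluated under the
#' alternative that the true odds ratio equals `or_threshold` (or its
#' reciprocal for protective effects), at the significance level `alpha`.
#' With `theta1 = log(or_threshold)` and `z_a = qnorm(1 - alpha/2)`:
#' `power = pnorm(|theta1|/se - z_a) + pnorm(-|theta1|/se - z_a)`.
#' The second (discordant-tail) term is numerically negligible in
#' practice but keeps the two-sided formula exact.
#'
#' `alpha` is conventionally the *exact* observed p-value of the test
#' being screened, not its rounded printed form.
#'
#' @param se_log_or Standard error of the log odds ratio (> 0).
#' @param alpha Significance level in (0, 1], typically the exact observed
#'   two-sided p-value.
#' @param or_threshold Target odds ratio (> 1).
#' @param direction `"risk"` or `"protective"`; the two-sided power is
#'   symmetric in the direction, which is kept explicit for auditability.
#' @return Power, a probability.
#' @examples
#' # rs204993 CC vs TT: se = 0.3104, exact p = 8.4e-5 -> power ~ 0.004
#' tab <- build_model_table(read_counts_table(scz_example_counts())[[2]],
#'                          "additive2")
#' fit <- odds_ratio_test(tab)
#' power_at_threshold(fit$se_log_or, fit$p.value)
#' @export
power_at_threshold <- function(se_log_or, alpha, or_threshold = 1.5,
                               direction = c("risk", "protective")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(se_log_or), se_log_or > 0,
            is.numeric(or_threshold), or_threshold > 1)
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) {
    stop("'alpha' must be in (0, 1]; use the floored exact p-value",
         call. = FALSE)
  }
  theta1 <- log(or_threshold)
  if (direction == "protective") theta1 <- -theta1
  z_alpha <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(abs(theta1) / se_log_or - z_alpha) +
    stats::pnorm(-abs(theta1) / se_log_or - z_alpha)
}

#' False-positive report probability
#'
#' Wacholder's posterior probability that a reported association is a
#' false positive, given the observed significance level `alpha`, the
#' power `power` to detect the target odds ratio, and a prior probability
#' `prior` that the association is real:
#' `FPRP = alpha (1 - prior) / (alpha (1 - prior) + power * prior)`.
#'
#' @param alpha Observed significance level (exact p-value), in (0, 1].
#' @param power Power at the target odds ratio, in \[0, 1\]. A power of 0
#'   returns FPRP = 1 with a warning (the test cannot see the
#'   alternative).
#' @param prior Prior probability of a true association, in (0, 1\].
#'   Vectorised.
#' @return FPRP, same length as `prior`.
#' @examples
#' fprp(0.05, 0.8, 0.1)  # 0.045 / 0.125 = 0.36
#' @export
fprp <- function(alpha, power, prior) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha <= 1,
            is.numeric(power), length(power) == 1L, power >= 0, power <= 1,
            is.numeric(prior), all(prior > 0 & prior <= 1))
  if (power == 0) {
    warning("power is 0: FPRP = 1 (test cannot detect the alternative)",
            call. = FALSE)
    return(rep(1, length(prior)))
  }
  num <- alpha * (1 - prior)
  num / (num + power * prior)
}

#' Bayesian false discovery probability via Wakefield's approximate Bayes
#' factor
#'
#' Compares a point null (log OR = 0) against a normal prior on the log
#' odds ratio whose 97.5th percentile sits at the target odds ratio:
#' `W = (log(or_threshold) / qnorm(0.975))^2`. With `V = se^2` and
#' `z = log_or / se`, the approximate Bayes factor (null over alternative)
#' is `ABF = sqrt((V + W) / V) * exp(-z^2 W / (2 (V + W)))`, and with
#' prior odds of the null `PO = (1 - prior) / prior`,
#' `BFDP = ABF * PO / (1 + ABF * PO)`.
#'
#' @param log_or Estimated log odds ratio.
#' @param se_log_or Its standard error (> 0).
#' @param or_threshold Target odds ratio defining the prior spread
#'   (`or_threshold = 1` collapses the alternative onto the null, giving
#'   `ABF = 1` and `BFDP = PO / (1 + PO) = 1 - prior`).
#' @param prior Prior probability of a true association, in (0, 1).
#'   Vectorised.
#' @return A list with `abf` (scalar) and `bfdp` (same length as
#'   `prior`).
#' @export
bfdp <- function(log_or, se_log_or, or_threshold = 1.5, prior) {
  stopifnot(is.numeric(log_or), length(log_or) == 1L, is.finite(log_or),
            is.numeric(se_log_or), length(se_log_or) == 1L, se_log_or > 0,
            is.numeric(or_threshold), or_threshold >= 1,
            is.numeric(prior), all(prior > 0 & prior < 1))
  V <- se_log_or^2
  W <- (log(or_threshold) / stats::qnorm(0.975))^2
  z <- log_or / se_log_or
  abf <- sqrt((V + W) / V) * exp(-z^2 * W / (2 * (V + W)))
  po <- (1 - prior) / prior
  list(abf = abf, bfdp = abf * po / (1 + abf * po))
}

#' Noteworthiness screen for one association result
#'
#' Runs the full FPRP and BFDP screen for one fitted genetic model: the
#' exact (unrounded) p-value is taken as the observed significance level,
#' the screening direction is protective when the estimated OR is below 1
#' (ties broken as risk), power is computed at the configured target OR,
#' FPRP is tabulated over the prior grid and BFDP over its own grid, and
#' each cell is flagged noteworthy when it falls below the configured
#' cutoff.
#'
#' @param assoc An `or_test` from [odds_ratio_test()].
#' @param config A [noteworthiness_config()].
#' @return An object of class `noteworthiness` with components `model`,
#'   `alpha_observed`, `direction`, `power`, `fprp` (named by prior),
#'   `abf`, `bfdp` (named by prior), `noteworthy_fprp`, `noteworthy_bfdp`.
#' @examples
#' pairs <- read_counts_table(scz_example_counts())
#' fit <- odds_ratio_test(build_model_table(pairs[[2]], "additive2"))
#' evaluate_noteworthiness(fit)
#' @export
evaluate_noteworthiness <- function(assoc, config = noteworthiness_config()) {
  stopifnot(inherits(assoc, "or_test"),
            inherits(config, "noteworthiness_config"))
  alpha <- assoc$p.value
  direction <- if (assoc$estimate < 1) "protective" else "risk"
  pw <- power_at_threshold(assoc$se_log_or, alpha,
                           or_threshold = config$or_threshold,
                           direction = direction)
  fp <- fprp(alpha, pw, config$priors)
  names(fp) <- format(config$priors, scientific = FALSE, trim = TRUE,
                      drop0trailing = TRUE)
  bf <- bfdp(assoc$log_or, assoc$se_log_or,
             or_threshold = config$or_threshold, prior = config$bfdp_priors)
  bf_vals <- bf$bfdp
  names(bf_vals) <- format(config$bfdp_priors, scientific = FALSE,
                           trim = TRUE, drop0trailing = TRUE)
  structure(
    list(model = assoc$model, snp_id = assoc$snp_id,
         alpha_observed = alpha, direction = direction, power = pw,
         fprp = fp, abf = bf$abf, bfdp = bf_vals,
         noteworthy_fprp = fp < config$fprp_cutoff,
         noteworthy_bfdp = bf_vals < config$bfdp_cutoff,
         config = config),
    class = "noteworthiness"
  )
}

#' @export
print.noteworthiness <- function(x, ...) {
  cat(sprintf("<noteworthiness> %s, %s (%s direction)\n", x$snp_id, x$model,
              x$direction))
  cat(sprintf("  exact p = %.4g, power at OR %.3g = %.3f\n",
              x$alpha_observed, x$config$or_threshold, x$power))
  cat("  FPRP by prior (", sprintf("cutoff %.2g", x$config$fprp_cutoff),
      "):\n", sep = "")
  print(round(x$fprp, 3))
  cat(sprintf("  ABF = %.4g; BFDP by prior (cutoff %.2g):\n", x$abf,
              x$config$bfdp_cutoff))
  print(round(x$bfdp, 3))
  invisible(x)
}
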