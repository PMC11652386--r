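test_that("power at the target OR matches independent normal-CDF oracles", {
  # published contrast: rs204993 CC vs TT, exact-p convention
  fit <- odds_ratio_test(build_model_table(fixture_pair("rs204993"),
                                           "additive2"))
  pw <- power_at_threshold(fit$se_log_or, fit$p.value)
  expect_equal(pw, 0.00430488387, tolerance = 1e-8)
  expect_equal(round(pw, 3), 0.004)

  # boundary: |theta|/se equals the critical value -> power ~ 0.5
  alpha <- 0.05
  se <- log(1.5) / qnorm(1 - alpha / 2)
  expect_lt(abs(power_at_threshold(se, alpha) - 0.5), 1e-3)

  # protective contrast, frozen from a hand evaluation of the formula
  expect_equal(power_at_threshold(0.21537, 1.9e-4, direction = "protective"),
               0.0322065451, tolerance = 1e-7)
  # two-sided power is direction-symmetric
  expect_equal(power_at_threshold(0.3, 0.01, direction = "risk"),
               power_at_threshold(0.3, 0.01, direction = "protective"),
               tolerance = 1e-15)

  expect_error(power_at_threshold(0.3, 0), "alpha")
})

test_that("FPRP follows the closed form and its limits", {
  expect_equal(fprp(0.05, 0.8, 0.1), 0.36, tolerance = 1e-12)
  # certain alternative: no false-positive risk left
  expect_equal(fprp(0.05, 0.8, 1), 0)
  # vanishing prior forces FPRP to 1
  expect_gt(fprp(1e-6, 1, 1e-12), 0.999)
  expect_warning(out <- fprp(0.05, 0, 0.1), "power is 0")
  expect_equal(out, 1)
})

test_that("FPRP is strictly decreasing in prior and in power", {
  priors <- c(0.25, 0.1, 0.01, 0.001, 1e-4)
  vals <- fprp(0.01, 0.5, priors)
  expect_true(all(diff(vals) > 0))  # priors descend, FPRP ascends
  expect_true(all(vals > 0 & vals < 1))
  powers <- seq(0.05, 1, by = 0.05)
  by_power <- vapply(powers, function(pw) fprp(0.01, pw, 0.1), numeric(1))
  expect_true(all(diff(by_power) < 0))
})

test_that("Wakefield ABF and BFDP match the closed form and its limits", {
  # frozen independent evaluation of the closed form
  out <- bfdp(0.4, 0.2, or_threshold = 1.5, prior = 0.05)
  expect_equal(out$abf, 0.5116963871, tolerance = 1e-8)
  po <- 0.95 / 0.05
  expect_equal(out$bfdp, out$abf * po / (1 + out$abf * po),
               tolerance = 1e-12)

  # degenerate prior spread: threshold OR 1 collapses onto the null
  flat <- bfdp(0.4, 0.2, or_threshold = 1, prior = 0.3)
  expect_equal(flat$abf, 1)
  expect_equal(flat$bfdp, 1 - 0.3, tolerance = 1e-12)

  # null-centred estimate favours the null: BFDP above the prior-odds line
  z0 <- bfdp(0, 0.2, prior = 0.3)
  expect_gt(z0$abf, 1)
  expect_gt(z0$bfdp, 1 - 0.3)

  # monotone in the prior: rarer hypotheses give larger BFDP
  grid <- bfdp(0.5, 0.15, prior = c(0.01, 0.001, 1e-5))$bfdp
  expect_true(all(diff(grid) > 0))
})

test_that("the screen flags the published noteworthy pattern for rs204993 CC vs TT", {
  fit <- odds_ratio_test(build_model_table(fixture_pair("rs204993"),
                                           "additive2"))
  nw <- evaluate_noteworthiness(fit)
  expect_identical(nw$direction, "risk")
  expect_equal(round(nw$fprp[["0.25"]], 3), 0.055)
  expect_equal(round(nw$fprp[["0.1"]], 3), 0.149)
  # noteworthy (FPRP < 0.2) exactly at priors 0.25 and 0.1
  expect_identical(unname(nw$noteworthy_fprp),
                   c(TRUE, TRUE, FALSE, FALSE, FALSE))
})

test_that("a clearly null model is never noteworthy", {
  fit <- odds_ratio_test(build_model_table(fixture_pair("rs204993"),
                                           "overdominant"))
  expect_equal(fit$p.value, 0.8451, tolerance = 1e-3)
  nw <- evaluate_noteworthiness(fit)
  expect_true(all(nw$fprp >= 0.7))
  expect_false(any(nw$noteworthy_fprp))
})

test_that("the screen is invariant under exposure swapping", {
  fit <- odds_ratio_test(mk_table(30, 50, 45, 40))
  mir <- odds_ratio_test(mk_table(50, 30, 40, 45))
  a <- evaluate_noteworthiness(fit)
  b <- evaluate_noteworthiness(mir)
  expect_equal(a$power, b$power, tolerance = 1e-12)
  expect_equal(a$fprp, b$fprp, tolerance = 1e-12)
  expect_equal(a$abf, b$abf, tolerance = 1e-12)
  expect_equal(a$bfdp, b$bfdp, tolerance = 1e-12)
  expect_identical(setdiff(c(a$direction, b$direction), character(0)),
                   c("protective", "risk"))
})

test_that("an OR of exactly 1 is screened in the risk direction", {
  fit <- odds_ratio_test(mk_table(10, 10, 10, 10))
  nw <- evaluate_noteworthiness(fit)
  expect_identical(nw$direction, "risk")
  expect_false(any(nw$noteworthy_fprp))
})

test_that("configuration validates and exposes the permissive FPRP preset", {
  cfg <- noteworthiness_config(fprp_cutoff = 0.5)
  expect_equal(cfg$fprp_cutoff, 0.5)
  expect_error(noteworthiness_config(or_threshold = 1))
  expect_error(noteworthiness_config(priors = c(0.25, 1.2)))
})
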