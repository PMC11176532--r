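test_that("indirect effect follows the delta formula and its limits", {
  ind <- indirect_effect(0.2, 0.05, 0.5, 0.1)
  expect_equal(ind$indirect, 0.1)
  expect_equal(ind$se, sqrt(0.04 * 0.01 + 0.25 * 0.0025))
  expect_equal(ind$se, 0.03201562, tolerance = 1e-6)

  ind0 <- indirect_effect(0, 0.05, 0.5, 0.1)
  expect_equal(ind0$indirect, 0)
  expect_equal(ind0$se, 0.5 * 0.05)   # |b| * a_se
})

test_that("delta SE matches a Monte-Carlo product of normals for strong paths", {
  a <- 0.5; a_se <- 0.1; b <- 0.3; b_se <- 0.05   # |a|/a_se = 5
  set.seed(99)
  mc <- sd(rnorm(1e5, a, a_se) * rnorm(1e5, b, b_se))
  expect_equal(indirect_effect(a, a_se, b, b_se)$se, mc, tolerance = 0.05)
})

test_that("mediation proportion arithmetic, flooring and error cases", {
  p <- mediation_proportion(0.1, 0.032, 0.4)
  expect_equal(p$proportion, 25)
  expect_equal(p$ci_low, 100 * (0.1 - qnorm(0.975) * 0.032) / 0.4,
               tolerance = 1e-10)
  expect_equal(p$ci_low, 9.32, tolerance = 0.01)
  expect_equal(p$ci_high, 40.68, tolerance = 0.01)

  expect_equal(mediation_proportion(0, 0.01, 0.4)$proportion, 0)
  expect_error(mediation_proportion(0.1, 0.01, 0), "undefined")

  # positive point estimate with a negative lower bound is floored at 0%
  fl <- mediation_proportion(0.01, 0.03, 0.4)
  expect_equal(fl$ci_low, 0)
  expect_gt(fl$proportion, 0)

  # negative total: endpoints are re-ordered
  neg <- mediation_proportion(-0.1, 0.032, -0.4)
  expect_equal(neg$proportion, 25)
  expect_lt(neg$ci_low, neg$ci_high)
})

test_that("doubling a and halving b leaves indirect and proportion unchanged", {
  i1 <- indirect_effect(0.2, 0.05, 0.4, 0.08)
  i2 <- indirect_effect(0.4, 0.05, 0.2, 0.08)
  expect_equal(i1$indirect, i2$indirect)
  p1 <- mediation_proportion(i1$indirect, i1$se, 0.4)
  p2 <- mediation_proportion(i2$indirect, i2$se, 0.4)
  expect_equal(p1$proportion, p2$proportion)
})

test_that("noise-free structure decomposes total = direct + a*b exactly", {
  tr <- scenario_truth(a_true = 0.2, b_true = 0.4, direct_true = 0.32,
                       n_snp = 10, seed = 1)
  sc <- generate_mediation_scenario(tr)
  expect_equal(sc$truth$true_total, 0.4)
  expect_equal(sc$truth$true_proportion, 20)
})

test_that("the screen short-circuits, audits every candidate once, and applies the sign rule", {
  tr <- scenario_truth(a_true = 0.2, b_true = 0.4, direct_true = 0.32,
                       n_snp = 25, seed = 77)
  sc <- generate_mediation_scenario(tr)
  cfg <- analysis_config(seed = 77)
  scr <- screen_mediators(sc$exposure, sc$outcome,
                          list(mediator = sc$mediator,
                               decoy_null = sc$decoy_null,
                               decoy_reverse = sc$decoy_reverse),
                          sc$ld, config = cfg)
  expect_setequal(scr$audit$candidate,
                  c("mediator", "decoy_null", "decoy_reverse"))
  expect_equal(anyDuplicated(scr$audit$candidate), 0)
  expect_true(all(scr$audit$verdict %in% c("selected", "excluded")))
  # short-circuit: anything failing C1 has NA for C2-C4
  failed1 <- scr$audit[!is.na(scr$audit$reason) &
                         scr$audit$reason == "criterion_1", ]
  if (nrow(failed1) > 0) {
    expect_true(all(is.na(failed1$c2)))
    expect_true(all(is.na(failed1$c3)))
  }

  # candidate with no genome-wide hits is excluded as no_instruments
  weak <- sc$mediator
  weak$data$pval <- pmax(weak$data$pval, 1e-4)
  weak$trait_name <- "weak"
  scr2 <- screen_mediators(sc$exposure, sc$outcome, list(weak = weak),
                           sc$ld, config = cfg)
  expect_equal(scr2$audit$reason, "no_instruments")
})

test_that("sign-discordant paths are excluded at criterion 4", {
  # plant a mediator whose a and b are both positive but with a negative
  # total effect: direct = -0.6, a*b = +0.08 -> total = -0.52
  tr <- scenario_truth(a_true = 0.2, b_true = 0.4, direct_true = -0.6,
                       n_snp = 25, seed = 13)
  sc <- generate_mediation_scenario(tr)
  cfg <- analysis_config(seed = 13)
  scr <- screen_mediators(sc$exposure, sc$outcome,
                          list(mediator = sc$mediator), sc$ld, config = cfg)
  aud <- scr$audit[scr$audit$candidate == "mediator", ]
  expect_equal(aud$verdict, "excluded")
  expect_equal(aud$reason, "criterion_4")
})

test_that("run_mediation reproduces the planted proportion on one scenario", {
  tr <- scenario_truth(a_true = 0.2, b_true = 0.4, direct_true = 0.32,
                       n_snp = 30, seed = 1001)
  sc <- generate_mediation_scenario(tr)
  med <- run_mediation(sc$exposure, sc$mediator, sc$outcome, sc$ld,
                       config = analysis_config(seed = 1001))
  expect_equal(med$indirect, med$a$beta * med$b$beta, tolerance = 1e-12)
  expect_gt(med$proportion, 10)
  expect_lt(med$proportion, 30)
  expect_lt(med$ci_low, med$proportion)
  expect_gt(med$ci_high, med$proportion)
})
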