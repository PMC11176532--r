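test_that("Wald ratio arithmetic and the single-instrument IVW reduction", {
  est <- wald_ratio(0.2, 0.01, 0.04, 0.01)
  expect_equal(est$beta, 0.2)
  expect_equal(est$se, 0.05)

  null <- wald_ratio(0.2, 0.01, 0, 0.01)
  expect_equal(null$beta, 0)
  expect_equal(null$pval, 1)

  expect_error(wald_ratio(0, 0.01, 0.04, 0.01), "undefined")

  h1 <- make_hset(beta_exp = 0.2, beta_out = 0.04, se_out = 0.01)
  iv <- mr_ivw(h1)
  expect_true(iv$flagged)
  expect_equal(iv$estimate$beta, 0.2)
  expect_equal(iv$estimate$se, 0.05)
})

test_that("IVW matches the closed-form example and has zero Q on exact data", {
  h <- make_hset(beta_exp = c(0.10, 0.20, 0.30),
                 beta_out = c(0.025, 0.035, 0.070), se_out = 0.01)
  iv <- mr_ivw(h)
  expect_equal(iv$estimate$beta, 305 / 1400, tolerance = 1e-10)
  expect_equal(iv$estimate$se, 1 / sqrt(1400), tolerance = 1e-10)
  expect_equal(iv$q, 1.0535714, tolerance = 1e-6)
  # Q/(k-1) < 1 so the random-effects SE equals the fixed one
  expect_equal(iv$estimate$se, 1 / sqrt(1400), tolerance = 1e-12)

  exact <- make_hset(beta_exp = c(0.1, 0.2, 0.3),
                     beta_out = 0.2 * c(0.1, 0.2, 0.3), se_out = 0.01)
  ive <- mr_ivw(exact)
  expect_equal(ive$estimate$beta, 0.2, tolerance = 1e-12)
  expect_equal(ive$q, 0, tolerance = 1e-20)
  expect_equal(ive$q_pval, 1)
})

test_that("IVW equals weighted regression through the origin on random sets", {
  set.seed(11)
  for (i in 1:50) {
    k <- sample(3:30, 1)
    bx <- rnorm(k, 0.05, 0.03)
    by <- 0.2 * bx + rnorm(k, 0, 0.01)
    se_out <- runif(k, 0.005, 0.02)
    h <- make_hset(bx, by, se_out = se_out)
    fit <- mr_ivw(h, random_effects = FALSE)
    oracle <- lm(by ~ bx + 0, weights = 1 / se_out^2)
    expect_equal(fit$estimate$beta, unname(coef(oracle)), tolerance = 1e-10)
  }
})

test_that("IVW point estimate is invariant to rescaling all weights", {
  h <- make_hset(beta_exp = c(0.1, 0.2, 0.3),
                 beta_out = c(0.03, 0.02, 0.08), se_out = 0.01)
  h10 <- make_hset(beta_exp = c(0.1, 0.2, 0.3),
                   beta_out = c(0.03, 0.02, 0.08), se_out = 0.01 * sqrt(10))
  expect_equal(mr_ivw(h)$estimate$beta, mr_ivw(h10)$estimate$beta,
               tolerance = 1e-12)
})

test_that("Egger recovers exact affine data and is orientation invariant", {
  bx <- c(0.05, 0.1, 0.15, 0.2)
  by <- 0.05 + 0.2 * bx
  h <- make_hset(bx, by, se_out = 0.01)
  eg <- mr_egger(h)
  expect_equal(eg$estimate$beta, 0.2, tolerance = 1e-10)
  expect_equal(eg$intercept, 0.05, tolerance = 1e-10)
  expect_equal(eg$q, 0, tolerance = 1e-16)

  # flipping the sign of any row changes nothing
  h2 <- make_hset(c(-0.05, 0.1, 0.15, 0.2), c(-by[1], by[2:4]),
                  se_out = 0.01)
  eg2 <- mr_egger(h2)
  expect_equal(eg2$estimate$beta, eg$estimate$beta, tolerance = 1e-12)
  expect_equal(eg2$intercept, eg$intercept, tolerance = 1e-12)

  expect_error(mr_egger(make_hset(c(0.1, 0.2), c(0.02, 0.04))),
               "insufficient")
})

test_that("Egger with overdispersion matches the lm oracle", {
  set.seed(3)
  bx <- runif(12, 0.03, 0.2)
  by <- 0.02 + 0.25 * bx + rnorm(12, 0, 0.05)   # strongly overdispersed
  se_out <- runif(12, 0.005, 0.02)
  h <- make_hset(bx, by, se_out = se_out)
  eg <- mr_egger(h)
  ol <- summary(lm(by ~ bx, weights = 1 / se_out^2))
  # lm scales by sqrt(RSS_w / df) which here exceeds 1, so both agree
  expect_equal(eg$estimate$beta, unname(ol$coefficients["bx", 1]),
               tolerance = 1e-10)
  expect_equal(eg$estimate$se, unname(ol$coefficients["bx", 2]),
               tolerance = 1e-10)
  expect_equal(eg$intercept_se,
               unname(ol$coefficients["(Intercept)", 2]), tolerance = 1e-10)
  expect_equal(eg$estimate$pval, unname(ol$coefficients["bx", 4]),
               tolerance = 1e-10)
})

test_that("Egger intercept test is calibrated under no pleiotropy", {
  reject <- logical(2000)
  intercepts <- numeric(2000)
  set.seed(19)
  for (i in 1:2000) {
    k <- 20
    bx <- runif(k, 0.03, 0.15)
    se_out <- runif(k, 0.004, 0.008)
    by <- 0.2 * bx + rnorm(k, 0, se_out)
    eg <- mr_egger(make_hset(bx, by, se_out = se_out))
    reject[i] <- eg$intercept_pval < 0.05
    intercepts[i] <- eg$intercept
  }
  expect_lt(abs(mean(intercepts)), 3 * sd(intercepts) / sqrt(2000))
  # the dispersion floor (max(1, sqrt(Q/df))) never narrows the interval,
  # so the test is conservative: it rejects at roughly half the nominal
  # level and must never exceed it beyond binomial noise
  expect_gt(mean(reject), 0.01)
  expect_lt(mean(reject), 0.0625)
})

test_that("weighted median interpolates the weight-ordered ratios", {
  h <- make_hset(beta_exp = c(1, 1, 1), beta_out = c(0.1, 0.2, 0.9),
                 se_out = 0.01)
  wm <- mr_weighted_median(h, n_boot = 50, seed = 1)
  expect_equal(wm$beta, 0.2)    # middle ratio sits exactly at p = 0.5

  # degenerate: identical ratios, shrinking SEs -> estimate c, SE -> 0
  hc <- make_hset(beta_exp = c(0.1, 0.2, 0.3), beta_out = 0.3 * c(0.1, 0.2, 0.3),
                  se_exp = 1e-6, se_out = 1e-6)
  wmc <- mr_weighted_median(hc, n_boot = 200, seed = 2)
  expect_equal(wmc$beta, 0.3, tolerance = 1e-9)
  expect_lt(wmc$se, 1e-4)

  expect_error(mr_weighted_median(make_hset(c(1, 1), c(1, 1)), seed = 1),
               "insufficient")
  expect_error(mr_weighted_median(h, n_boot = 10), "seed")
})

test_that("weighted median always lies within the ratio range", {
  set.seed(5)
  for (i in 1:25) {
    k <- sample(3:20, 1)
    bx <- rnorm(k, 0.08, 0.03)
    bx[abs(bx) < 0.01] <- 0.02
    by <- rnorm(k, 0.02, 0.05)
    h <- make_hset(bx, by, se_out = runif(k, 0.005, 0.02))
    wm <- mr_weighted_median(h, n_boot = 20, seed = i)
    ratios <- by / bx
    expect_gte(wm$beta, min(ratios))
    expect_lte(wm$beta, max(ratios))
  }
})

test_that("Cochran's Q definitional properties", {
  q0 <- cochran_q(rep(0.2, 4), rep(1, 4), 0.2)
  expect_equal(q0$q, 0)
  expect_equal(q0$pval, 1)

  set.seed(13)
  r <- rnorm(10, 0.2, 0.1)
  w <- runif(10, 1, 5)
  center <- sum(w * r) / sum(w)
  q <- cochran_q(r, w, center)
  expect_equal(q$q, sum(w * (r - center)^2), tolerance = 1e-14)

  # duplicating a ratio never decreases Q (same center)
  q2 <- cochran_q(c(r, r[1]), c(w, w[1]), center)
  expect_gte(q2$q, q$q)
})

test_that("MR-PRESSO is a no-op without outliers and respects preconditions", {
  set.seed(2)
  bx <- runif(8, 0.05, 0.15)
  se_out <- rep(0.01, 8)
  by <- 0.2 * bx + rnorm(8, 0, se_out)
  h <- make_hset(bx, by, se_out = se_out)
  pr <- mr_presso(h, n_sim = 300, seed = 4)
  expect_true(pr$applicable)
  if (length(pr$outliers) == 0) {
    expect_equal(pr$corrected$beta, pr$raw$beta)
    expect_true(is.na(pr$distortion_pval))
  }
  small <- make_hset(c(0.1, 0.2, 0.3), c(0.02, 0.04, 0.06))
  expect_false(mr_presso(small, n_sim = 50, seed = 1)$applicable)
  expect_error(mr_presso(h), "seed")
})

test_that("MR-PRESSO flags a planted extreme-ratio outlier", {
  set.seed(31)
  k <- 20
  bx <- runif(k, 0.05, 0.15)
  se_out <- rep(0.008, k)
  by <- 0.3 * bx + rnorm(k, 0, se_out)
  by[7] <- 3 * bx[7]            # ratio 10x the others
  se_out[7] <- 0.004
  h <- make_hset(bx, by, se_out = se_out)
  pr <- mr_presso(h, n_sim = 500, seed = 8)
  expect_true("iv007" %in% pr$outliers)
  expect_lt(pr$global_pval, 0.05)
  expect_lt(abs(pr$corrected$beta - 0.3), abs(pr$raw$beta - 0.3))
  expect_false(is.na(pr$distortion_pval))
})

test_that("multivariable IVW recovers exact coefficients and reduces to IVW", {
  set.seed(17)
  k <- 12
  b1 <- runif(k, 0.03, 0.2)
  b2 <- runif(k, 0.03, 0.2)
  y <- 0.3 * b1 + 0.0 * b2
  mv <- list(beta_exp = cbind(E1 = b1, E2 = b2), beta_out = y,
             se_out = rep(0.01, k), exposures = c("E1", "E2"))
  fit <- mvmr_ivw(mv)
  expect_equal(fit$estimates$E1$beta, 0.3, tolerance = 1e-10)
  expect_equal(fit$estimates$E2$beta, 0.0, tolerance = 1e-10)

  # m = 1 reduces to univariable IVW
  y2 <- 0.3 * b1 + rnorm(k, 0, 0.01)
  mv1 <- list(beta_exp = cbind(E1 = b1), beta_out = y2,
              se_out = rep(0.01, k), exposures = "E1")
  h <- make_hset(b1, y2, se_out = 0.01)
  expect_equal(mvmr_ivw(mv1)$estimates$E1$beta, mr_ivw(h)$estimate$beta,
               tolerance = 1e-10)

  # collinear exposures are named in the error
  mvc <- list(beta_exp = cbind(E1 = b1, E2 = 2 * b1), beta_out = y,
              se_out = rep(0.01, k), exposures = c("E1", "E2"))
  expect_error(mvmr_ivw(mvc), "collinear")
})

test_that("MVMR recovers a planted direct effect controlled for the exposure", {
  hits <- 0
  for (s in 1:40) {
    tr <- scenario_truth(a_true = 0.2, b_true = 0.4, direct_true = 0.32,
                         n_snp = 20, seed = 300 + s)
    sc <- generate_mediation_scenario(tr)
    cfg <- analysis_config(seed = 300 + s)
    sel <- function(tbl) {
      fw <- filter_weak(clump(select_instruments(tbl, 5e-8), sc$ld))
      fw$kept$variant_id
    }
    ids <- union(sel(sc$exposure), sel(sc$mediator))
    mvset <- harmonize_mv(list(exposure = sc$exposure,
                               mediator = sc$mediator),
                          sc$outcome, ids)
    fit <- mvmr_ivw(mvset)
    est <- fit$estimates$mediator
    hits <- hits + (est$ci_low <= 0.4 && 0.4 <= est$ci_high)
  }
  # nominal coverage ~95%; bound is 90% less two binomial SDs at 40 reps
  expect_gte(hits, 34)
})

test_that("Egger with the intercept constrained to zero equals fixed-effect IVW", {
  set.seed(29)
  bx <- runif(10, 0.05, 0.2)
  se_out <- runif(10, 0.005, 0.02)
  by <- 0.25 * bx + rnorm(10, 0, se_out)
  h <- make_hset(bx, by, se_out = se_out)
  constrained <- lm(by ~ bx + 0, weights = 1 / se_out^2)
  expect_equal(mr_ivw(h)$estimate$beta, unname(coef(constrained)),
               tolerance = 1e-12)
})

test_that("CI width shrinks like 1/sqrt(k) on homogeneous data", {
  width <- function(k, seed) {
    set.seed(seed)
    bx <- rep(0.1, k)
    by <- 0.2 * bx + rnorm(k, 0, 0.01)
    e <- mr_ivw(make_hset(bx, by, se_out = 0.01), random_effects = FALSE)$estimate
    e$ci_high - e$ci_low
  }
  w1 <- width(25, 101)
  w4 <- width(100, 102)
  expect_equal(w1 / w4, 2, tolerance = 0.25)
})
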