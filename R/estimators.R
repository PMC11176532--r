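#' @name estimators
#' @title Causal estimators and sensitivity statistics
#'
#' @description
#' All estimators consume a [harmonized_set()] of per-variant effect pairs
#' (beta_exp, se_exp, beta_out, se_out). The inverse-variance weighted (IVW)
#' estimate is the weighted mean of per-variant ratio estimates
#' r_j = beta_out_j / beta_exp_j with weights w_j = beta_exp_j^2 / se_out_j^2,
#' equivalently weighted least squares of beta_out on beta_exp through the
#' origin. The multiplicative random-effects standard error inflates the
#' fixed-effect one by sqrt(Q / (k - 1)), floored at 1, so heterogeneity can
#' widen but never narrow the interval. MR-Egger adds a free intercept (the
#' directional-pleiotropy test) with t-based inference on k - 2 degrees of
#' freedom. The weighted median interpolates the weight-ordered ratios at
#' the 50% point and is consistent while valid instruments carry a majority
#' of weight; its standard error comes from a parametric bootstrap.
#' Ratio standard errors use the first-order delta approximation
#' se_out / |beta_exp| (no-measurement-error assumption in the exposure).
NULL

#' Construct an MR estimate record
#'
#' @param method Estimator name.
#' @param beta Causal effect (log-odds scale for a binary outcome).
#' @param se Standard error (> 0).
#' @param n_snp Number of instruments used.
#' @param df Degrees of freedom for the reference distribution; `Inf`
#'   (the default) gives normal inference, finite values give t.
#' @return Object of class `mr_estimate` with fields `method`, `beta`, `se`,
#'   `ci_low`, `ci_high`, `pval`, `or`, `or_ci_low`, `or_ci_high`, `n_snp`.
#' @export
mr_estimate <- function(method, beta, se, n_snp, df = Inf) {
  beta <- unname(beta)
  se <- unname(se)
  stopifnot(se > 0)
  crit <- if (is.finite(df)) stats::qt(0.975, df) else stats::qnorm(0.975)
  z <- beta / se
  pval <- if (is.finite(df)) 2 * stats::pt(-abs(z), df) else 2 * stats::pnorm(-abs(z))
  ci_low <- beta - crit * se
  ci_high <- beta + crit * se
  structure(list(method = method, beta = beta, se = se,
                 ci_low = ci_low, ci_high = ci_high, pval = pval,
                 or = exp(beta), or_ci_low = exp(ci_low),
                 or_ci_high = exp(ci_high), n_snp = n_snp, df = df),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: beta = %.4g (se %.4g), 95%% CI [%.4g, %.4g], p = %.3g, OR = %.4g, k = %d\n",
              x$method, x$beta, x$se, x$ci_low, x$ci_high, x$pval, x$or,
              x$n_snp))
  invisible(x)
}

hset_rows <- function(hset) {
  if (inherits(hset, "harmonized_set")) hset$rows else as.data.frame(hset)
}

#' Wald ratio for a single instrument
#'
#' @param beta_exp,se_exp Exposure effect and standard error.
#' @param beta_out,se_out Outcome effect and standard error.
#' @return An [mr_estimate()] with method `"wald_ratio"`.
#' @export
wald_ratio <- function(beta_exp, se_exp, beta_out, se_out) {
  if (beta_exp == 0) {
    stop("undefined ratio: exposure beta is 0", call. = FALSE)
  }
  mr_estimate("wald_ratio", beta_out / beta_exp, se_out / abs(beta_exp),
              n_snp = 1L)
}

#' Cochran's Q heterogeneity statistic
#'
#' Q = sum of w_j (r_j - center)^2, compared to a chi-square upper tail.
#'
#' @param ratios Per-instrument ratio estimates.
#' @param weights Inverse-variance weights.
#' @param center Pooled estimate the ratios are measured against.
#' @param df Degrees of freedom (default k - 1).
#' @return List with `q`, `df`, `pval`.
#' @export
cochran_q <- function(ratios, weights, center, df = length(ratios) - 1) {
  stopifnot(length(ratios) >= 2, length(ratios) == length(weights))
  q <- sum(weights * (ratios - center)^2)
  list(q = q, df = df, pval = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Inverse-variance weighted estimate (multiplicative random effects)
#'
#' @param hset A [harmonized_set()] (or a data frame with its row columns).
#' @param random_effects Inflate the standard error by
#'   `max(1, sqrt(Q / (k - 1)))`? Default `TRUE`.
#' @return List with `estimate` (an [mr_estimate()]), `q`, `q_df`, `q_pval`
#'   and `flagged` (`TRUE` when a single instrument forced a Wald-ratio
#'   fallback).
#' @export
mr_ivw <- function(hset, random_effects = TRUE) {
  r <- hset_rows(hset)
  k <- nrow(r)
  if (k == 0) stop("no instruments", call. = FALSE)
  if (k == 1) {
    est <- wald_ratio(r$beta_exp, r$se_exp, r$beta_out, r$se_out)
    est$method <- "ivw"
    return(list(estimate = est, q = NA_real_, q_df = NA_integer_,
                q_pval = NA_real_, flagged = TRUE))
  }
  w <- r$beta_exp^2 / r$se_out^2
  ratio <- r$beta_out / r$beta_exp
  beta <- sum(w * ratio) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  qh <- cochran_q(ratio, w, beta, df = k - 1)
  infl <- if (random_effects) max(1, sqrt(qh$q / (k - 1))) else 1
  est <- mr_estimate("ivw", beta, se_fixed * infl, n_snp = k)
  list(estimate = est, q = qh$q, q_df = qh$df, q_pval = qh$pval,
       flagged = FALSE)
}

#' MR-Egger regression
#'
#' Rows are first oriented so every exposure beta is non-negative (negating
#' both betas where needed), then beta_out is regressed on beta_exp with a
#' free intercept, weights 1/se_out^2. The intercept is the directional
#' horizontal-pleiotropy test; the slope is the causal estimate under the
#' InSIDE assumption. Standard errors carry the multiplicative
#' overdispersion factor `max(1, sqrt(Q_egger / (k - 2)))`; p-values and
#' intervals use the t distribution with k - 2 degrees of freedom.
#'
#' @param hset A [harmonized_set()] with at least 3 instruments.
#' @return List with `estimate` (slope, an [mr_estimate()]), `intercept`,
#'   `intercept_se`, `intercept_pval`, `q`, `q_df`, `q_pval`.
#' @export
mr_egger <- function(hset) {
  r <- hset_rows(hset)
  k <- nrow(r)
  if (k < 3) stop("insufficient instruments for MR-Egger (need >= 3)",
                  call. = FALSE)
  s <- sign(r$beta_exp)
  s[s == 0] <- 1
  bx <- r$beta_exp * s
  by <- r$beta_out * s
  w <- 1 / r$se_out^2

  X <- cbind(intercept = 1, slope = bx)
  XtW <- t(X * w)
  A <- XtW %*% X
  Ainv <- solve(A)
  coefs <- drop(Ainv %*% (XtW %*% by))
  res <- by - drop(X %*% coefs)
  q <- sum(w * res^2)
  df <- k - 2
  infl <- max(1, sqrt(q / df))
  ses <- sqrt(diag(Ainv)) * infl

  est <- mr_estimate("egger", coefs["slope"], ses["slope"], n_snp = k,
                     df = df)
  intercept_pval <- 2 * stats::pt(-abs(coefs["intercept"] / ses["intercept"]),
                                  df)
  list(estimate = est,
       intercept = unname(coefs["intercept"]),
       intercept_se = unname(ses["intercept"]),
       intercept_pval = unname(intercept_pval),
       q = q, q_df = df,
       q_pval = stats::pchisq(q, df, lower.tail = FALSE))
}

# interpolated weighted median of ratio estimates
weighted_median_point <- function(ratios, weights) {
  o <- order(ratios)
  r <- ratios[o]
  w <- weights[o] / sum(weights)
  p <- cumsum(w) - w / 2
  stats::approx(p, r, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' Weighted median estimate
#'
#' Ratio estimates are ordered and the estimate is the linear interpolation
#' of the cumulative-weight midpoints at 50%. Consistent when over half the
#' weight comes from valid instruments. The standard error is a parametric
#' bootstrap: each beta is resampled from a normal centred on its observed
#' value with its reported standard error, the estimate recomputed, and the
#' standard deviation over `n_boot` draws taken.
#'
#' @param hset A [harmonized_set()] with at least 3 instruments.
#' @param n_boot Bootstrap draws (default 1000).
#' @param seed Required RNG seed for the bootstrap; recorded in the output.
#' @return An [mr_estimate()] with method `"weighted_median"` and an extra
#'   `seed` field.
#' @export
mr_weighted_median <- function(hset, n_boot = 1000, seed) {
  if (missing(seed)) stop("seed is required for the bootstrap", call. = FALSE)
  r <- hset_rows(hset)
  k <- nrow(r)
  if (k < 3) stop("insufficient instruments for weighted median (need >= 3)",
                  call. = FALSE)
  w <- r$beta_exp^2 / r$se_out^2
  point <- weighted_median_point(r$beta_out / r$beta_exp, w)
  boot <- with_seed(seed, {
    bx <- matrix(stats::rnorm(n_boot * k, mean = rep(r$beta_exp, each = n_boot),
                              sd = rep(r$se_exp, each = n_boot)), n_boot, k)
    by <- matrix(stats::rnorm(n_boot * k, mean = rep(r$beta_out, each = n_boot),
                              sd = rep(r$se_out, each = n_boot)), n_boot, k)
    se_out2 <- rep(r$se_out^2, each = n_boot)
    wstar <- matrix(bx^2 / se_out2, n_boot, k)
    rstar <- by / bx
    vapply(seq_len(n_boot),
           function(b) weighted_median_point(rstar[b, ], wstar[b, ]),
           numeric(1))
  })
  se <- stats::sd(boot)
  if (se <= 0) se <- .Machine$double.eps
  est <- mr_estimate("weighted_median", point, se, n_snp = k)
  est$seed <- seed
  est
}

# leave-one-out IVW estimates (fixed-effect), vectorised
ivw_loo <- function(bx, by, w) {
  r <- by / bx
  (sum(w * r) - w * r) / (sum(w) - w)
}

#' MR-PRESSO pleiotropy residual sum of squares and outlier test
#'
#' The observed residual sum of squares is
#' RSS = sum_j w_j (beta_out_j - beta_hat_(-j) beta_exp_j)^2, with
#' w_j = 1/se_out_j^2 and beta_hat_(-j) the IVW estimate leaving variant j
#' out. `n_sim` datasets are simulated under the no-pleiotropy model
#' (beta_out_j* ~ N(beta_hat_(-j) beta_exp_j, se_out_j)), each scored with
#' its own leave-one-out estimates. The global p is the fraction of
#' simulated RSS at or above the observed one; per-variant outlier p-values
#' compare each observed weighted squared residual to its simulated
#' distribution and are Bonferroni-adjusted across instruments. When
#' outliers are flagged, the outlier-corrected IVW estimate is returned
#' together with a two-sided distortion p comparing the observed
#' corrected-minus-raw displacement against the same displacement on the
#' simulated datasets; with no outliers the corrected estimate equals the
#' raw IVW.
#'
#' @param hset A [harmonized_set()] with at least 4 instruments.
#' @param n_sim Number of simulated datasets (default 1000).
#' @param outlier_alpha Flagging threshold on the Bonferroni-adjusted
#'   per-variant p (default 0.05).
#' @param seed Required RNG seed.
#' @return List with `applicable`, `global_pval`, `outliers` (variant ids),
#'   `outlier_pvals`, `corrected` (an [mr_estimate()]), `distortion_pval`
#'   (`NA` when no outlier), `raw` (the uncorrected IVW estimate).
#' @export
mr_presso <- function(hset, n_sim = 1000, outlier_alpha = 0.05, seed) {
  if (missing(seed)) stop("seed is required for MR-PRESSO", call. = FALSE)
  r <- hset_rows(hset)
  k <- nrow(r)
  if (k < 4) {
    return(list(applicable = FALSE, global_pval = NA_real_,
                outliers = character(0), outlier_pvals = numeric(0),
                corrected = NULL, distortion_pval = NA_real_, raw = NULL))
  }
  bx <- r$beta_exp
  by <- r$beta_out
  se_out <- r$se_out
  w <- bx^2 / se_out^2        # ratio-scale weights for the IVW estimates
  wres <- 1 / se_out^2        # residual weights

  loo <- ivw_loo(bx, by, w)
  mu <- loo * bx
  res_obs <- wres * (by - mu)^2
  rss_obs <- sum(res_obs)

  sim <- with_seed(seed, {
    by_star <- matrix(stats::rnorm(n_sim * k, mean = rep(mu, each = n_sim),
                                   sd = rep(se_out, each = n_sim)), n_sim, k)
    r_star <- sweep(by_star, 2, bx, "/")
    wr_star <- sweep(r_star, 2, w, "*")
    swr <- rowSums(wr_star)
    loo_star <- sweep(-wr_star, 1, swr, "+")          # swr - w_j r*_j
    loo_star <- sweep(loo_star, 2, sum(w) - w, "/")
    mu_star <- sweep(loo_star, 2, bx, "*")
    res_star <- sweep((by_star - mu_star)^2, 2, wres, "*")
    list(by_star = by_star, wr_star = wr_star, swr = swr,
         res_star = res_star, rss_star = rowSums(res_star))
  })

  global_pval <- mean(sim$rss_star >= rss_obs)
  p_snp <- colMeans(sweep(sim$res_star, 2, res_obs, ">="))
  p_adj <- pmin(1, p_snp * k)
  flagged <- p_adj < outlier_alpha
  outliers <- r$variant_id[flagged]

  raw <- mr_ivw(r)$estimate
  if (any(flagged)) {
    kept <- r[!flagged, , drop = FALSE]
    corrected <- if (nrow(kept) >= 2) {
      mr_ivw(kept)$estimate
    } else if (nrow(kept) == 1) {
      mr_ivw(kept)$estimate
    } else {
      raw
    }
    disp_obs <- corrected$beta - raw$beta
    ivw_all_star <- sim$swr / sum(w)
    ivw_sub_star <- (sim$swr -
                       rowSums(sim$wr_star[, flagged, drop = FALSE])) /
      (sum(w) - sum(w[flagged]))
    disp_star <- ivw_sub_star - ivw_all_star
    distortion_pval <- mean(abs(disp_star) >= abs(disp_obs))
  } else {
    corrected <- raw
    distortion_pval <- NA_real_
  }
  list(applicable = TRUE, global_pval = global_pval, outliers = outliers,
       outlier_pvals = stats::setNames(p_adj, r$variant_id),
       corrected = corrected, distortion_pval = distortion_pval, raw = raw)
}

#' Multivariable IVW regression
#'
#' Weighted least squares of beta_out on the exposure-beta columns with no
#' intercept and weights 1/se_out^2; each coefficient is the direct effect
#' of that exposure conditional on the others. Standard errors carry the
#' multiplicative overdispersion `max(1, sqrt(Q / (k - m)))`. An
#' Egger-style intercept (same regression plus an intercept, rows oriented
#' so the first exposure's betas are non-negative) is reported as the
#' pleiotropy check.
#'
#' @param mvset An `mv_harmonized_set` from [harmonize_mv()], or a list with
#'   `beta_exp` (matrix), `beta_out`, `se_out` and optionally `exposures`.
#' @return List with `estimates` (named list of [mr_estimate()], one per
#'   exposure) and `sensitivity` (`q`, `q_df`, `q_pval`, `egger_intercept`,
#'   `intercept_se`, `intercept_pval`).
#' @export
mvmr_ivw <- function(mvset) {
  X <- as.matrix(mvset$beta_exp)
  y <- mvset$beta_out
  se_out <- mvset$se_out
  m <- ncol(X)
  k <- nrow(X)
  exp_names <- mvset$exposures %||% colnames(X) %||% paste0("exposure", 1:m)
  colnames(X) <- exp_names
  if (k < m + 1) stop("insufficient instruments: need at least m + 1 rows",
                      call. = FALSE)
  w <- 1 / se_out^2
  qrX <- qr(sqrt(w) * X)
  if (qrX$rank < m) {
    bad <- exp_names[qrX$pivot[(qrX$rank + 1):m]]
    stop("estimation error: collinear exposures (", paste(bad, collapse = ", "),
         ")", call. = FALSE)
  }
  XtW <- t(X * w)
  A <- XtW %*% X
  Ainv <- solve(A)
  coefs <- drop(Ainv %*% (XtW %*% y))
  res <- y - drop(X %*% coefs)
  q <- sum(w * res^2)
  df <- k - m
  infl <- max(1, sqrt(q / df))
  ses <- sqrt(diag(Ainv)) * infl
  estimates <- lapply(seq_len(m), function(j) {
    mr_estimate("mvmr_ivw", coefs[j], ses[j], n_snp = k)
  })
  names(estimates) <- exp_names

  # Egger-style intercept: orient on the first exposure
  s <- sign(X[, 1])
  s[s == 0] <- 1
  Xe <- cbind(intercept = 1, X * s)
  ye <- y * s
  XtWe <- t(Xe * w)
  Ae <- XtWe %*% Xe
  inter <- tryCatch({
    Aeinv <- solve(Ae)
    ce <- drop(Aeinv %*% (XtWe %*% ye))
    rese <- ye - drop(Xe %*% ce)
    qe <- sum(w * rese^2)
    dfe <- k - m - 1
    infe <- if (dfe > 0) max(1, sqrt(qe / dfe)) else 1
    se_i <- sqrt(Aeinv[1, 1]) * infe
    p_i <- if (dfe > 0) 2 * stats::pt(-abs(ce[1] / se_i), dfe) else NA_real_
    list(b = unname(ce[1]), se = se_i, p = p_i)
  }, error = function(e) list(b = NA_real_, se = NA_real_, p = NA_real_))

  list(estimates = estimates,
       sensitivity = list(q = q, q_df = df,
                          q_pval = stats::pchisq(q, df, lower.tail = FALSE),
                          egger_intercept = inter$b,
                          intercept_se = inter$se,
                          intercept_pval = inter$p))
}
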