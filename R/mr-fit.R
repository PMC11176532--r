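#' Fit the full set of two-sample MR estimators to a harmonized set
#'
#' The one-stop fitting function: runs IVW (always; a single instrument
#' degenerates to the Wald ratio, flagged), MR-Egger and the weighted
#' median (3+ instruments), Cochran's Q, the Egger intercept pleiotropy
#' test, and MR-PRESSO (4+ instruments), then picks the primary method by
#' the pleiotropy rule: MR-Egger when the intercept p is below
#' `pleiotropy_alpha`, IVW otherwise.
#'
#' @param hset A [harmonized_set()].
#' @param methods Estimators to run, subset of
#'   `c("ivw", "egger", "weighted_median")`; IVW always runs.
#' @param presso Run MR-PRESSO? Default `TRUE`.
#' @param n_boot Weighted-median bootstrap draws.
#' @param n_sim MR-PRESSO simulated datasets.
#' @param seed Root seed; the weighted-median and MR-PRESSO streams are
#'   derived from it deterministically.
#' @param pleiotropy_alpha Intercept-test threshold for switching the
#'   primary method to MR-Egger (default 0.05).
#' @return Object of class `mr_fit` with fields `data` (the harmonized
#'   set), `estimates` (named list of [mr_estimate()]), `sensitivity` (Q,
#'   Egger intercept, MR-PRESSO results), `primary_method`, `n_snp`,
#'   `flags`.
#' @seealso [mr_ivw()], [mr_egger()], [mr_weighted_median()], [mr_presso()]
#' @examples
#' truth <- scenario_truth(theta = 0.2, n_snp = 20, seed = 7)
#' fit <- mr_fit(simulate_harmonized(truth), seed = 7)
#' fit
#' coef(fit)
#' @export
mr_fit <- function(hset, methods = c("ivw", "egger", "weighted_median"),
                   presso = TRUE, n_boot = 1000, n_sim = 1000, seed = 1L,
                   pleiotropy_alpha = 0.05) {
  stopifnot(inherits(hset, "harmonized_set"))
  k <- nrow(hset$rows)
  if (k == 0) stop("no instruments to fit", call. = FALSE)
  flags <- character(0)
  estimates <- list()

  ivw <- mr_ivw(hset)
  estimates$ivw <- ivw$estimate
  if (ivw$flagged) flags <- c(flags, "single_instrument_wald_fallback")

  egger <- NULL
  if ("egger" %in% methods && k >= 3) {
    egger <- mr_egger(hset)
    estimates$egger <- egger$estimate
  } else if ("egger" %in% methods) {
    flags <- c(flags, "egger_unavailable")
  }
  if ("weighted_median" %in% methods && k >= 3) {
    estimates$weighted_median <-
      mr_weighted_median(hset, n_boot = n_boot,
                         seed = stage_seed(seed, "weighted_median"))
  }

  presso_res <- if (presso && k >= 4) {
    mr_presso(hset, n_sim = n_sim, seed = stage_seed(seed, "presso"))
  } else {
    list(applicable = FALSE, global_pval = NA_real_, outliers = character(0),
         corrected = NULL, distortion_pval = NA_real_, raw = NULL)
  }

  sensitivity <- list(
    q = ivw$q, q_df = ivw$q_df, q_pval = ivw$q_pval,
    egger_intercept = if (!is.null(egger)) egger$intercept else NA_real_,
    intercept_se = if (!is.null(egger)) egger$intercept_se else NA_real_,
    intercept_pval = if (!is.null(egger)) egger$intercept_pval else NA_real_,
    q_egger = if (!is.null(egger)) egger$q else NA_real_,
    q_egger_pval = if (!is.null(egger)) egger$q_pval else NA_real_,
    presso_applicable = isTRUE(presso_res$applicable),
    presso_global_pval = presso_res$global_pval,
    presso_outliers = presso_res$outliers,
    presso_corrected = presso_res$corrected,
    presso_distortion_pval = presso_res$distortion_pval)
  class(sensitivity) <- "mr_sensitivity"

  primary <- choose_primary_method(sensitivity$intercept_pval,
                                   alpha = pleiotropy_alpha)
  if (is.na(sensitivity$intercept_pval)) {
    flags <- c(flags, "intercept_unavailable")
  }
  if (!primary %in% names(estimates)) primary <- "ivw"

  structure(list(data = hset, estimates = estimates,
                 sensitivity = sensitivity, primary_method = primary,
                 n_snp = k, seed = seed, flags = flags),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Two-sample MR fit: %s -> %s (%d instruments)\n",
              x$data$exposure, x$data$outcome, x$n_snp))
  cat(sprintf("Primary method: %s\n", x$primary_method))
  tab <- do.call(rbind, lapply(x$estimates, function(e) {
    data.frame(beta = e$beta, se = e$se, ci_low = e$ci_low,
               ci_high = e$ci_high, pval = e$pval, or = e$or)
  }))
  print(round(tab, digits))
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, digits = 4, ...) {
  fit <- x$fit
  print(fit, digits = digits)
  s <- fit$sensitivity
  cat(sprintf("\nHeterogeneity: Cochran's Q = %.3f (df %d), p = %.3g\n",
              s$q, s$q_df, s$q_pval))
  if (!is.na(s$egger_intercept)) {
    cat(sprintf("Pleiotropy: Egger intercept = %.4g (se %.4g), p = %.3g\n",
                s$egger_intercept, s$intercept_se, s$intercept_pval))
  }
  if (isTRUE(s$presso_applicable)) {
    cat(sprintf("MR-PRESSO: global p = %.3g, %d outlier(s)",
                s$presso_global_pval, length(s$presso_outliers)))
    if (length(s$presso_outliers) > 0) {
      cat(sprintf(" [%s], distortion p = %.3g",
                  paste(s$presso_outliers, collapse = ", "),
                  s$presso_distortion_pval))
    }
    cat("\n")
  }
  if (length(fit$flags) > 0) {
    cat("Flags:", paste(fit$flags, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  vapply(object$estimates, function(e) e$beta, numeric(1))
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  methods <- if (missing(parm)) names(object$estimates) else parm
  out <- t(vapply(methods, function(m) {
    e <- object$estimates[[m]]
    crit <- if (is.finite(e$df)) stats::qt(1 - (1 - level) / 2, e$df) else
      stats::qnorm(1 - (1 - level) / 2)
    c(e$beta - crit * e$se, e$beta + crit * e$se)
  }, numeric(2)))
  colnames(out) <- paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %")
  out
}

# primary-model linear predictor: slope (+ Egger intercept on oriented rows)
primary_linear <- function(object) {
  est <- object$estimates[[object$primary_method]]
  intercept <- 0
  if (object$primary_method == "egger") {
    intercept <- object$sensitivity$egger_intercept
  }
  list(intercept = intercept, slope = est$beta)
}

#' @export
fitted.mr_fit <- function(object, ...) {
  r <- object$data$rows
  lin <- primary_linear(object)
  s <- sign(r$beta_exp)
  s[s == 0] <- 1
  # Egger's intercept lives on the orientation-positive scale
  s * (lin$intercept + lin$slope * abs(r$beta_exp))
}

#' @export
residuals.mr_fit <- function(object, type = c("weighted", "raw"), ...) {
  type <- match.arg(type)
  r <- object$data$rows
  res <- r$beta_out - fitted(object)
  if (type == "weighted") res / r$se_out else res
}

#' @export
predict.mr_fit <- function(object, newdata = NULL, ...) {
  lin <- primary_linear(object)
  bx <- if (is.null(newdata)) object$data$rows$beta_exp else newdata$beta_exp
  s <- sign(bx)
  s[s == 0] <- 1
  s * (lin$intercept + lin$slope * abs(bx))
}

#' @export
simulate.mr_fit <- function(object, nsim = 1, seed = NULL, ...) {
  r <- object$data$rows
  mu <- fitted(object)
  draw <- function() stats::rnorm(length(mu), mean = mu, sd = r$se_out)
  if (!is.null(seed)) {
    with_seed(seed, as.data.frame(replicate(nsim, draw())))
  } else {
    as.data.frame(replicate(nsim, draw()))
  }
}

#' Scatter plot of a two-sample MR fit
#'
#' Instrument effects with +/- 1 SE bars, the IVW line through the origin
#' and, when fitted, the MR-Egger line, on rows oriented to positive
#' exposure effects.
#'
#' @param x An `mr_fit` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mr_fit <- function(x, ...) {
  r <- x$data$rows
  s <- sign(r$beta_exp)
  s[s == 0] <- 1
  bx <- r$beta_exp * s
  by <- r$beta_out * s
  graphics::plot(bx, by, pch = 19,
                 xlab = sprintf("effect on %s", x$data$exposure),
                 ylab = sprintf("effect on %s", x$data$outcome),
                 main = sprintf("%s -> %s", x$data$exposure, x$data$outcome),
                 ...)
  graphics::segments(bx, by - r$se_out, bx, by + r$se_out, col = "grey60")
  graphics::segments(bx - r$se_exp, by, bx + r$se_exp, by, col = "grey60")
  graphics::abline(0, x$estimates$ivw$beta, col = "steelblue", lwd = 2)
  if (!is.null(x$estimates$egger)) {
    graphics::abline(x$sensitivity$egger_intercept, x$estimates$egger$beta,
                     col = "firebrick", lwd = 2, lty = 2)
  }
  graphics::legend("topleft",
                   legend = c("IVW", if (!is.null(x$estimates$egger)) "MR-Egger"),
                   col = c("steelblue", if (!is.null(x$estimates$egger)) "firebrick"),
                   lty = c(1, if (!is.null(x$estimates$egger)) 2), lwd = 2,
                   bty = "n")
  invisible(x)
}
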