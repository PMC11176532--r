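#' @name mediation
#' @title Mediator screening and product-of-coefficients mediation
#'
#' @description
#' Two-step MR mediation: the path `a` (exposure to mediator) and the total
#' effect come from univariable MR; the path `b` (mediator to outcome,
#' controlled for the exposure) comes from multivariable MR. The indirect
#' effect is the product `a * b` with a delta-method standard error, and
#' the mediation proportion is `indirect / total`, reported as a
#' percentage with the total treated as fixed.
#'
#' Candidate mediators pass a four-criterion screen before any proportion
#' is computed: (1) the mediator causally affects the outcome in UVMR;
#' (2) it retains a direct effect on the outcome controlled for the
#' exposure in MVMR; (3) the exposure causally affects the mediator but not
#' vice versa; (4) the indirect effect points the same way as the total
#' effect. Criteria are evaluated in order and short-circuit on first
#' failure, with every verdict recorded in an audit table.
NULL

#' Delta-method indirect effect
#'
#' `indirect = a * b`, with
#' `se = sqrt(a^2 * b_se^2 + b^2 * a_se^2)`.
#'
#' @param a,a_se Exposure-to-mediator effect and its standard error.
#' @param b,b_se Mediator-to-outcome direct effect and its standard error.
#' @return List with `indirect` and `se`.
#' @export
indirect_effect <- function(a, a_se, b, b_se) {
  list(indirect = a * b,
       se = sqrt(a^2 * b_se^2 + b^2 * a_se^2))
}

#' Mediation proportion with a fixed-total interval
#'
#' `proportion = indirect / total`, with the 95% interval
#' `(indirect +/- 1.96 se) / total` (endpoints ordered), all reported as
#' percentages. When the point estimate is positive but the lower endpoint
#' is negative, the reported lower bound is floored at 0%.
#'
#' @param indirect,indirect_se Indirect effect and its standard error.
#' @param total Total effect (must be nonzero).
#' @return List with `proportion`, `ci_low`, `ci_high` (percent).
#' @export
mediation_proportion <- function(indirect, indirect_se, total) {
  if (total == 0) stop("undefined proportion: total effect is 0",
                       call. = FALSE)
  prop <- 100 * indirect / total
  ci <- sort(100 * (indirect + c(-1, 1) * stats::qnorm(0.975) * indirect_se) /
               total)
  if (prop > 0 && ci[1] < 0) ci[1] <- 0
  list(proportion = prop, ci_low = ci[1], ci_high = ci[2])
}

# UVMR of `from` on `to`: primary-method estimate for reporting plus the
# IVW p-value used by the criterion tests (the compound "Egger-if-
# pleiotropy then test the slope" rule over-rejects under the null because
# intercept and slope are anti-correlated; see the methods vignette)
uvmr_primary <- function(from_table, to_table, ld, confounders, config,
                         verbose = FALSE) {
  pair <- run_pair(from_table, to_table, ld, confounders, config,
                   verbose = verbose)
  if (is.null(pair$fit)) return(NULL)
  list(estimate = pair$fit$estimates[[pair$primary_method]],
       ivw_pval = pair$fit$estimates$ivw$pval,
       method = pair$primary_method, pair = pair)
}

# MVMR of outcome on (exposure, mediator); returns the mediator's direct
# effect and the full result
mvmr_direct <- function(exposure_table, mediator_table, outcome_table, ld,
                        confounders, config) {
  sel <- function(tbl) {
    prep <- prepare_instruments(tbl, ld, confounders, config,
                                verbose = FALSE)
    prep$instruments$variant_id
  }
  ids <- union(sel(exposure_table), sel(mediator_table))
  if (length(ids) < 3) return(NULL)
  tabs <- list(exposure_table, mediator_table)
  names(tabs) <- c(exposure_table$trait_name, mediator_table$trait_name)
  mvset <- harmonize_mv(tabs, outcome_table, ids)
  if (length(mvset$variant_id) < ncol(mvset$beta_exp) + 1) return(NULL)
  fit <- mvmr_ivw(mvset)
  list(direct = fit$estimates[[mediator_table$trait_name]],
       exposure_direct = fit$estimates[[exposure_table$trait_name]],
       sensitivity = fit$sensitivity, mvset = mvset)
}

#' Four-criterion mediator screen
#'
#' Evaluates, for each candidate: (C1) UVMR candidate-to-outcome with IVW
#' p below `alpha`; (C2) MVMR direct effect of the candidate on the
#' outcome controlled for the exposure, p below `alpha`; (C3) UVMR
#' exposure-to-candidate IVW p below `alpha` and candidate-to-exposure IVW
#' p at or above `alpha`; (C4) `sign(a * b)` equal to the sign of the
#' total exposure-to-outcome effect. Evaluation short-circuits at the
#' first failing criterion; unevaluated criteria are recorded as `NA`.
#' Candidates without usable instruments are excluded with reason
#' `no_instruments`. Criterion verdicts deliberately use the IVW p-value
#' rather than the pleiotropy-switched primary method: the compound
#' "Egger-if-intercept-significant" rule over-rejects null relationships
#' (intercept and slope are anti-correlated under the null), which would
#' inflate both false exclusions at C3 and false inclusions at C1; the
#' reported effect estimates still follow the primary-method rule.
#'
#' @param exposure_table,outcome_table [summary_table()] objects.
#' @param candidates Named list of candidate-mediator [summary_table()]s.
#' @param ld An [ld_table()].
#' @param confounders Optional confounder table.
#' @param config An [analysis_config()]; `alpha_nominal` is the screening
#'   level.
#' @param verbose Log stage counts?
#' @return List with `selected` (names of candidates passing all four),
#'   `audit` (one row per candidate: criterion outcomes and verdict) and
#'   `details` (per-candidate a/b/total estimates for the survivors).
#' @export
screen_mediators <- function(exposure_table, outcome_table, candidates,
                             ld, confounders = NULL,
                             config = analysis_config(), verbose = FALSE) {
  alpha <- config$alpha_nominal
  total <- uvmr_primary(exposure_table, outcome_table, ld, confounders,
                        config, verbose)
  if (is.null(total)) {
    stop("exposure has no usable instruments for the total effect",
         call. = FALSE)
  }
  audit <- list()
  details <- list()
  selected <- character(0)
  for (name in names(candidates)) {
    cand <- candidates[[name]]
    row <- data.frame(candidate = name, c1 = NA, c2 = NA, c3 = NA, c4 = NA,
                      verdict = "excluded", reason = NA_character_,
                      stringsAsFactors = FALSE)
    prep <- prepare_instruments(cand, ld, confounders, config,
                                verbose = FALSE)
    if (!prep$eligible || nrow(prep$instruments) == 0) {
      row$reason <- "no_instruments"
      audit[[name]] <- row
      next
    }
    # C1: candidate -> outcome (UVMR)
    c1 <- uvmr_primary(cand, outcome_table, ld, confounders, config)
    row$c1 <- !is.null(c1) && c1$ivw_pval < alpha
    if (!isTRUE(row$c1)) {
      row$reason <- "criterion_1"
      audit[[name]] <- row
      next
    }
    # C2: direct candidate -> outcome controlled for exposure (MVMR)
    mv <- mvmr_direct(exposure_table, cand, outcome_table, ld, confounders,
                      config)
    row$c2 <- !is.null(mv) && mv$direct$pval < alpha
    if (!isTRUE(row$c2)) {
      row$reason <- "criterion_2"
      audit[[name]] <- row
      next
    }
    # C3: exposure -> candidate, but not the reverse
    a <- uvmr_primary(exposure_table, cand, ld, confounders, config)
    rev <- uvmr_primary(cand, exposure_table, ld, confounders, config)
    fwd_ok <- !is.null(a) && a$ivw_pval < alpha
    rev_ok <- is.null(rev) || rev$ivw_pval >= alpha
    row$c3 <- fwd_ok && rev_ok
    if (!isTRUE(row$c3)) {
      row$reason <- if (!fwd_ok) "criterion_3_forward" else "criterion_3_reverse"
      audit[[name]] <- row
      next
    }
    # C4: indirect effect points the same way as the total effect
    row$c4 <- sign(a$estimate$beta * mv$direct$beta) ==
      sign(total$estimate$beta)
    if (!isTRUE(row$c4)) {
      row$reason <- "criterion_4"
      audit[[name]] <- row
      next
    }
    row$verdict <- "selected"
    audit[[name]] <- row
    selected <- c(selected, name)
    details[[name]] <- list(a = a$estimate, b = mv$direct,
                            total = total$estimate,
                            exposure_direct = mv$exposure_direct)
  }
  list(selected = selected, audit = do.call(rbind, c(audit,
                                                     make.row.names = FALSE)),
       details = details, total = total$estimate)
}

#' Two-step MR mediation analysis for one mediator
#'
#' Computes `a` (exposure to mediator, UVMR primary method), `b` (mediator
#' to outcome controlled for the exposure, MVMR), the total effect
#' (exposure to outcome, UVMR primary method), the product-of-coefficients
#' indirect effect and the mediation proportion.
#'
#' @param exposure_table,mediator_table,outcome_table [summary_table()]
#'   objects.
#' @param ld An [ld_table()].
#' @param confounders Optional confounder table.
#' @param config An [analysis_config()].
#' @return Object of class `mr_mediation` with fields `exposure`,
#'   `mediator`, `outcome`, `a`, `b`, `total` ([mr_estimate()]s),
#'   `indirect`, `indirect_se`, `proportion`, `ci_low`, `ci_high`
#'   (percent).
#' @export
run_mediation <- function(exposure_table, mediator_table, outcome_table,
                          ld, confounders = NULL,
                          config = analysis_config()) {
  a <- uvmr_primary(exposure_table, mediator_table, ld, confounders, config)
  if (is.null(a)) stop("no usable instruments for exposure -> mediator",
                       call. = FALSE)
  total <- uvmr_primary(exposure_table, outcome_table, ld, confounders,
                        config)
  if (is.null(total)) stop("no usable instruments for exposure -> outcome",
                           call. = FALSE)
  mv <- mvmr_direct(exposure_table, mediator_table, outcome_table, ld,
                    confounders, config)
  if (is.null(mv)) stop("multivariable model could not be fitted",
                        call. = FALSE)
  ind <- indirect_effect(a$estimate$beta, a$estimate$se,
                         mv$direct$beta, mv$direct$se)
  prop <- mediation_proportion(ind$indirect, ind$se, total$estimate$beta)
  structure(list(exposure = exposure_table$trait_name,
                 mediator = mediator_table$trait_name,
                 outcome = outcome_table$trait_name,
                 a = a$estimate, b = mv$direct, total = total$estimate,
                 indirect = ind$indirect, indirect_se = ind$se,
                 proportion = prop$proportion, ci_low = prop$ci_low,
                 ci_high = prop$ci_high),
            class = "mr_mediation")
}

#' @export
print.mr_mediation <- function(x, ...) {
  cat(sprintf("Mediation: %s -> %s -> %s\n", x$exposure, x$mediator,
              x$outcome))
  cat(sprintf("  a  (exposure -> mediator):       %.4g (se %.4g)\n",
              x$a$beta, x$a$se))
  cat(sprintf("  b  (mediator -> outcome, MVMR):  %.4g (se %.4g)\n",
              x$b$beta, x$b$se))
  cat(sprintf("  total effect:                    %.4g (se %.4g)\n",
              x$total$beta, x$total$se))
  cat(sprintf("  indirect a*b: %.4g (se %.4g)\n", x$indirect, x$indirect_se))
  cat(sprintf("  proportion mediated: %.2f%% (95%% CI %.2f%%-%.2f%%)\n",
              x$proportion, x$ci_low, x$ci_high))
  invisible(x)
}
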