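#' @name pipeline
#' @title Bidirectional study orchestration
#'
#' @description
#' `run_pair()` executes one exposure-outcome analysis end to end:
#' instrument selection, clumping, F-filtering, confounder exclusion,
#' harmonization, estimation by all methods, sensitivity analysis, primary
#' method choice and significance labelling. `run_matrix()` runs every
#' ordered pair of two trait panels in both directions, isolating per-pair
#' failures, and writes per-direction results tables. Traits whose
#' candidate instruments are all weak (F at or below the threshold) are
#' flagged outcome-only and never used as exposures.
NULL

#' Analysis configuration
#'
#' @param p_threshold_default Instrument p-value threshold (default 5e-8).
#' @param p_threshold_relaxed Relaxed threshold for traits that yield too
#'   few instruments at the default (default 5e-6).
#' @param relaxed_traits Character vector of trait names using the relaxed
#'   threshold.
#' @param clump_r2 Clumping independence threshold (default 0.001).
#' @param clump_window_bp Clumping window (default 10 Mb).
#' @param f_min Weak-instrument F threshold (default 10).
#' @param alpha_nominal Nominal significance level (default 0.05).
#' @param n_tests_bonferroni Number of tests the Bonferroni correction
#'   divides the nominal level by (default 5, giving 0.01).
#' @param seed Root seed; all stochastic stages derive their streams from
#'   it by stage-name hashing.
#' @param n_boot Weighted-median bootstrap draws.
#' @param n_sim MR-PRESSO simulated datasets.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(p_threshold_default = 5e-8,
                            p_threshold_relaxed = 5e-6,
                            relaxed_traits = character(0),
                            clump_r2 = 0.001,
                            clump_window_bp = 1e7,
                            f_min = 10,
                            alpha_nominal = 0.05,
                            n_tests_bonferroni = 5,
                            seed = 1L,
                            n_boot = 1000,
                            n_sim = 1000) {
  stopifnot(p_threshold_default > 0, p_threshold_default < 1,
            p_threshold_relaxed > 0, p_threshold_relaxed < 1,
            clump_r2 >= 0, clump_r2 <= 1, clump_window_bp > 0,
            alpha_nominal > 0, alpha_nominal < 1,
            n_tests_bonferroni >= 1)
  structure(list(p_threshold_default = p_threshold_default,
                 p_threshold_relaxed = p_threshold_relaxed,
                 relaxed_traits = relaxed_traits,
                 clump_r2 = clump_r2, clump_window_bp = clump_window_bp,
                 f_min = f_min, alpha_nominal = alpha_nominal,
                 n_tests_bonferroni = n_tests_bonferroni,
                 seed = as.integer(seed), n_boot = n_boot, n_sim = n_sim),
            class = "analysis_config")
}

#' Primary-method rule
#'
#' IVW is the primary method; in the presence of directional pleiotropy
#' (Egger intercept p strictly below `alpha`) MR-Egger takes over. An
#' unavailable intercept (fewer than 3 instruments) falls back to IVW.
#'
#' @param intercept_pval Egger intercept p-value (may be `NA`).
#' @param alpha Pleiotropy threshold (default 0.05).
#' @return `"egger"` or `"ivw"`.
#' @export
choose_primary_method <- function(intercept_pval, alpha = 0.05) {
  if (is.na(intercept_pval)) return("ivw")
  if (intercept_pval < alpha) "egger" else "ivw"
}

#' Significance labelling with Bonferroni correction
#'
#' `"significant"` below the Bonferroni-corrected level
#' (`alpha_nominal / n_tests_bonferroni`, 0.05/5 = 0.01 by default),
#' `"nominal"` below the nominal level, `"null"` otherwise; both
#' comparisons are strict.
#'
#' @param pval P-value in `[0, 1]`.
#' @param config An [analysis_config()].
#' @return One of `"significant"`, `"nominal"`, `"null"`.
#' @export
label_significance <- function(pval, config = analysis_config()) {
  stopifnot(pval >= 0, pval <= 1)
  bonf <- config$alpha_nominal / config$n_tests_bonferroni
  if (pval < bonf) "significant"
  else if (pval < config$alpha_nominal) "nominal"
  else "null"
}

# selection threshold for a trait under a config
trait_threshold <- function(trait_name, config) {
  if (trait_name %in% config$relaxed_traits) config$p_threshold_relaxed
  else config$p_threshold_default
}

# select -> clump -> F-filter -> confounder-exclude, with an audit trail
prepare_instruments <- function(exposure_table, ld, confounders, config,
                                verbose = TRUE) {
  note <- function(...) if (verbose) message(sprintf(...))
  thr <- trait_threshold(exposure_table$trait_name, config)
  cand <- select_instruments(exposure_table, thr)
  note("[%s] %d candidates at p < %g", exposure_table$trait_name,
       nrow(cand), thr)
  clumped <- clump(cand, ld, config$clump_r2, config$clump_window_bp)
  note("[%s] %d after clumping", exposure_table$trait_name, nrow(clumped))
  fw <- filter_weak(clumped, config$f_min)
  note("[%s] %d strong instruments (mean F %.1f)",
       exposure_table$trait_name, nrow(fw$kept),
       if (is.nan(fw$mean_f)) 0 else fw$mean_f)
  audit <- data.frame(variant_id = character(0), stage = character(0),
                      reason = character(0))
  weak <- setdiff(clumped$variant_id, fw$kept$variant_id)
  if (length(weak) > 0) {
    audit <- rbind(audit, data.frame(variant_id = weak, stage = "f_filter",
                                     reason = "weak_instrument"))
  }
  conf <- exclude_confounder_snps(fw$kept, confounders, 5e-8)
  if (nrow(conf$removed) > 0) {
    audit <- rbind(audit, data.frame(variant_id = conf$removed$variant_id,
                                     stage = "confounder",
                                     reason = conf$removed$reason))
    note("[%s] %d removed as confounder-associated",
         exposure_table$trait_name, nrow(conf$removed))
  }
  list(instruments = conf$kept, eligible = fw$eligible, mean_f = fw$mean_f,
       counts = c(candidates = nrow(cand), clumped = nrow(clumped),
                  strong = nrow(fw$kept), final = nrow(conf$kept)),
       audit = audit)
}

#' Run one exposure-outcome MR analysis
#'
#' @param exposure_table,outcome_table [summary_table()] objects.
#' @param ld An [ld_table()].
#' @param confounders Optional confounder-association data frame
#'   (see [read_confounder_table()]).
#' @param config An [analysis_config()].
#' @param direction Label recorded in the result (default `"forward"`).
#' @param verbose Log per-stage instrument counts to stderr?
#' @return Object of class `mr_pair` with fields `exposure`, `outcome`,
#'   `direction`, `fit` (an [mr_fit()] or `NULL`), `primary_method`,
#'   `significance`, `eligibility` (`"ok"` or `"outcome_only"`), `counts`,
#'   `audit`.
#' @export
run_pair <- function(exposure_table, outcome_table, ld,
                     confounders = NULL, config = analysis_config(),
                     direction = "forward", verbose = TRUE) {
  prep <- prepare_instruments(exposure_table, ld, confounders, config,
                              verbose)
  base <- list(exposure = exposure_table$trait_name,
               outcome = outcome_table$trait_name,
               direction = direction, counts = prep$counts,
               audit = prep$audit, mean_f = prep$mean_f)
  if (!prep$eligible || nrow(prep$instruments) == 0) {
    if (verbose) {
      message(sprintf("[%s] exposure-ineligible (weak or no instruments)",
                      exposure_table$trait_name))
    }
    return(structure(c(base, list(fit = NULL, primary_method = NA_character_,
                                  significance = NA_character_,
                                  eligibility = "outcome_only")),
                     class = "mr_pair"))
  }
  hset <- harmonize(prep$instruments, outcome_table,
                    exposure_name = exposure_table$trait_name)
  if (nrow(hset$dropped) > 0) {
    base$audit <- rbind(base$audit,
                        data.frame(variant_id = hset$dropped$variant_id,
                                   stage = "harmonize",
                                   reason = hset$dropped$reason))
  }
  base$counts <- c(base$counts, harmonized = nrow(hset$rows))
  if (nrow(hset$rows) == 0) {
    return(structure(c(base, list(fit = NULL, primary_method = NA_character_,
                                  significance = NA_character_,
                                  eligibility = "no_overlap")),
                     class = "mr_pair"))
  }
  fit <- mr_fit(hset, n_boot = config$n_boot, n_sim = config$n_sim,
                seed = stage_seed(config$seed,
                                  paste(base$exposure, base$outcome,
                                        direction, sep = "|")),
                pleiotropy_alpha = config$alpha_nominal)
  primary_p <- fit$estimates[[fit$primary_method]]$pval
  structure(c(base, list(fit = fit, primary_method = fit$primary_method,
                         significance = label_significance(primary_p, config),
                         eligibility = "ok")),
            class = "mr_pair")
}

#' @export
print.mr_pair <- function(x, ...) {
  cat(sprintf("MR pair [%s]: %s -> %s\n", x$direction, x$exposure, x$outcome))
  if (is.null(x$fit)) {
    cat(sprintf("  not estimated: %s\n", x$eligibility))
  } else {
    e <- x$fit$estimates[[x$primary_method]]
    cat(sprintf("  primary %s: OR %.3f (95%% CI %.3f-%.3f), p = %.3g [%s]\n",
                x$primary_method, e$or, e$or_ci_low, e$or_ci_high, e$pval,
                x$significance))
  }
  invisible(x)
}

# results rows (one per method) for a fitted pair; outlier-corrected IVW
# appended alongside the raw estimates when MR-PRESSO flagged outliers
pair_results_rows <- function(pair) {
  if (is.null(pair$fit)) return(NULL)
  binary <- pair$fit$data$outcome_binary
  rows <- do.call(rbind, lapply(pair$fit$estimates, function(e) {
    results_row(e, pair$exposure, pair$outcome, binary)
  }))
  s <- pair$fit$sensitivity
  if (isTRUE(s$presso_applicable) && length(s$presso_outliers) > 0) {
    corr <- s$presso_corrected
    corr$method <- "presso_corrected"
    rows <- rbind(rows, results_row(corr, pair$exposure, pair$outcome, binary))
  }
  rows$direction <- pair$direction
  rows$primary <- rows$method == pair$primary_method
  rows$significance <- ifelse(rows$primary, pair$significance, NA_character_)
  rownames(rows) <- NULL
  rows
}

# sensitivity rows mirroring the usual published layout (Cochran's Q,
# intercept p, MR-PRESSO outlier count and global p); the overlap-corrected
# confirmatory column is recorded as a placeholder so table shape is stable
pair_sensitivity_row <- function(pair) {
  if (is.null(pair$fit)) return(NULL)
  s <- pair$fit$sensitivity
  pc <- s$presso_corrected
  data.frame(exposure = pair$exposure, outcome = pair$outcome,
             direction = pair$direction,
             cochran_q = s$q, p_cochran_q = s$q_pval,
             p_intercept = s$intercept_pval,
             presso_or = if (!is.null(pc)) pc$or else NA_real_,
             presso_ci_low = if (!is.null(pc)) pc$or_ci_low else NA_real_,
             presso_ci_high = if (!is.null(pc)) pc$or_ci_high else NA_real_,
             presso_p = if (!is.null(pc)) pc$pval else NA_real_,
             n_outlier = length(s$presso_outliers),
             p_global_test = s$presso_global_pval,
             overlap_corrected = NA_real_,
             stringsAsFactors = FALSE)
}

#' Run every ordered pair of two trait panels, both directions
#'
#' Forward: each trait in `panel_a` as exposure against each trait in
#' `panel_b` as outcome. Reverse: the roles swapped. A trait whose
#' instruments are all weak is skipped as an exposure (recorded in
#' `skipped`) but still serves as an outcome. Per-pair failures are caught,
#' recorded, and do not stop the run.
#'
#' @param panel_a,panel_b Named lists of [summary_table()] objects.
#' @param ld An [ld_table()].
#' @param confounders Optional confounder table.
#' @param config An [analysis_config()].
#' @param out_dir Optional directory; when given, `forward.tsv`,
#'   `reverse.tsv`, `sensitivity.tsv` are written there (numbers at 6
#'   significant digits, byte-stable for a fixed seed).
#' @param verbose Log stage counts?
#' @return Object of class `mr_matrix`: list with `results` (list of
#'   [run_pair()] results), `skipped` (data frame of trait, direction,
#'   reason), `failures` (data frame of pair, error).
#' @export
run_matrix <- function(panel_a, panel_b, ld, confounders = NULL,
                       config = analysis_config(), out_dir = NULL,
                       verbose = FALSE) {
  results <- list()
  skipped <- data.frame(trait = character(0), direction = character(0),
                        reason = character(0))
  failures <- data.frame(pair = character(0), error = character(0))

  directions <- list(forward = list(exp = panel_a, out = panel_b),
                     reverse = list(exp = panel_b, out = panel_a))
  for (dir_name in names(directions)) {
    dd <- directions[[dir_name]]
    for (ename in names(dd$exp)) {
      prep <- prepare_instruments(dd$exp[[ename]], ld, confounders, config,
                                  verbose = verbose)
      if (!prep$eligible || nrow(prep$instruments) == 0) {
        skipped <- rbind(skipped,
                         data.frame(trait = ename, direction = dir_name,
                                    reason = "outcome_only"))
        next
      }
      for (oname in names(dd$out)) {
        key <- sprintf("%s->%s (%s)", ename, oname, dir_name)
        res <- tryCatch(
          run_pair(dd$exp[[ename]], dd$out[[oname]], ld, confounders,
                   config, direction = dir_name, verbose = verbose),
          error = function(e) e)
        if (inherits(res, "error")) {
          failures <- rbind(failures,
                            data.frame(pair = key,
                                       error = conditionMessage(res)))
        } else {
          results[[key]] <- res
        }
      }
    }
  }

  out <- structure(list(results = results, skipped = skipped,
                        failures = failures, config = config),
                   class = "mr_matrix")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (dir_name in c("forward", "reverse")) {
      sel <- Filter(function(p) p$direction == dir_name, results)
      rows <- do.call(rbind, lapply(sel, pair_results_rows))
      write_results_table(rows, file.path(out_dir,
                                          paste0(dir_name, ".tsv")))
    }
    sens <- do.call(rbind, lapply(results, pair_sensitivity_row))
    if (is.null(sens)) {
      sens <- data.frame()
    } else {
      num <- vapply(sens, is.numeric, logical(1))
      sens[num] <- lapply(sens[num], function(x) fmt6(x))
    }
    utils::write.table(sens, file.path(out_dir, "sensitivity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
  }
  out
}

#' @export
print.mr_matrix <- function(x, ...) {
  cat(sprintf("MR matrix: %d pair results, %d trait(s) outcome-only, %d failure(s)\n",
              length(x$results), nrow(x$skipped), nrow(x$failures)))
  for (p in x$results) print(p)
  invisible(x)
}
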