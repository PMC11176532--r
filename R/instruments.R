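#' @name instruments
#' @title Instrument selection and harmonization
#'
#' @description
#' Genetic instruments are selected from an exposure summary table by
#' p-value thresholding (genome-wide 5e-8, or a relaxed 5e-6 for traits with
#' few hits), pruned to approximate linkage equilibrium by greedy clumping
#' (r-squared < 0.001 within 10 Mb), strength-filtered on the F-statistic
#' (threshold 10), screened against known confounder associations
#' (p < 5e-8), and finally aligned to the outcome table's effect alleles.
NULL

#' Select instruments by p-value threshold
#'
#' Keeps exactly the rows with `pval < p_threshold`, in their original order.
#'
#' @param table A [summary_table()].
#' @param p_threshold Selection threshold in (0, 1).
#' @return Data frame of variant rows (possibly empty).
#' @export
select_instruments <- function(table, p_threshold = 5e-8) {
  stopifnot(inherits(table, "summary_table"),
            p_threshold > 0, p_threshold < 1)
  out <- table$data[table$data$pval < p_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy LD clumping
#'
#' Candidates are visited in ascending p-value order (ties broken by
#' `variant_id`); a candidate is accepted iff no already-accepted variant on
#' the same chromosome within `window_bp` has r-squared at or above `r2_max`
#' with it. The accepted set is returned sorted by (chrom, pos).
#'
#' @param candidates Data frame of variant rows (one summary table's rows).
#' @param ld An [ld_table()].
#' @param r2_max Independence threshold (default 0.001).
#' @param window_bp Window in base pairs (default 10 Mb).
#' @return Data frame of index variants.
#' @export
clump <- function(candidates, ld, r2_max = 0.001, window_bp = 1e7) {
  if (nrow(candidates) == 0) return(candidates)
  cand <- candidates[order(candidates$pval, candidates$variant_id), ,
                     drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    for (j in kept) {
      if (cand$chrom[j] == cand$chrom[i] &&
          abs(cand$pos[j] - cand$pos[i]) <= window_bp &&
          ld_lookup(ld, cand$variant_id[i], cand$variant_id[j]) >= r2_max) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  out <- cand[kept, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Instrument-strength F-statistic
#'
#' The square of the Wald z, `(beta / se)^2`. Values above 10 are the usual
#' bar for a usable instrument.
#'
#' @param beta Effect estimate(s).
#' @param se Standard error(s), > 0.
#' @return F-statistic(s).
#' @export
f_statistic <- function(beta, se) {
  stopifnot(all(se > 0))
  (beta / se)^2
}

#' Filter weak instruments
#'
#' Keeps instruments with F above `f_min` and reports the mean F of the kept
#' set. A trait whose candidate instruments all fall at or below `f_min` is
#' flagged exposure-ineligible: it can still serve as an outcome but must
#' not be used as an exposure.
#'
#' @param candidates Data frame of variant rows (needs `beta`, `se`).
#' @param f_min Strength threshold (default 10).
#' @return List with `kept` (data frame, with an `f_stat` column), `mean_f`
#'   (mean F of kept set, `NaN` if empty) and `eligible` (logical).
#' @export
filter_weak <- function(candidates, f_min = 10) {
  f <- if (nrow(candidates) > 0) {
    f_statistic(candidates$beta, candidates$se)
  } else numeric(0)
  keep <- f > f_min
  kept <- candidates[keep, , drop = FALSE]
  kept$f_stat <- f[keep]
  rownames(kept) <- NULL
  list(kept = kept,
       mean_f = mean(f[keep]),
       eligible = any(keep))
}

#' Exclude instruments associated with confounders
#'
#' Removes any instrument having a confounder association at
#' `pval < p_threshold` in the supplied table; removal reasons name the
#' confounding trait. An empty table leaves the instrument set unchanged.
#'
#' @param candidates Data frame of variant rows.
#' @param confounder_table Data frame (`variant_id`, `trait`, `pval`) or
#'   `NULL`.
#' @param p_threshold Exclusion threshold (default 5e-8).
#' @return List with `kept` (data frame) and `removed` (data frame of
#'   `variant_id`, `reason`).
#' @export
exclude_confounder_snps <- function(candidates, confounder_table = NULL,
                                    p_threshold = 5e-8) {
  removed <- data.frame(variant_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  if (is.null(confounder_table) || nrow(confounder_table) == 0 ||
      nrow(candidates) == 0) {
    return(list(kept = candidates, removed = removed))
  }
  hits <- confounder_table[confounder_table$pval < p_threshold, , drop = FALSE]
  bad <- candidates$variant_id %in% hits$variant_id
  if (any(bad)) {
    ids <- candidates$variant_id[bad]
    reason <- vapply(ids, function(id) {
      traits <- unique(hits$trait[hits$variant_id == id])
      paste0("confounder:", paste(traits, collapse = ","))
    }, character(1))
    removed <- data.frame(variant_id = ids, reason = unname(reason),
                          stringsAsFactors = FALSE)
  }
  kept <- candidates[!bad, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, removed = removed)
}

#' Construct a harmonized exposure-outcome instrument set
#'
#' @param exposure_name,outcome_name Trait labels.
#' @param rows Data frame with columns `variant_id`, `effect_allele`,
#'   `other_allele` (exposure orientation), `beta_exp`, `se_exp`, `eaf_exp`,
#'   `beta_out`, `se_out`, `eaf_out`.
#' @param dropped Data frame (`variant_id`, `reason`) of variants excluded
#'   during alignment.
#' @param outcome_binary Is the outcome a binary trait (estimates reported
#'   as odds ratios)?
#' @return Object of class `harmonized_set`.
#' @export
harmonized_set <- function(exposure_name, outcome_name, rows,
                           dropped = data.frame(variant_id = character(0),
                                                reason = character(0)),
                           outcome_binary = TRUE) {
  needed <- c("variant_id", "effect_allele", "other_allele", "beta_exp",
              "se_exp", "eaf_exp", "beta_out", "se_out", "eaf_out")
  stopifnot(all(needed %in% names(rows)))
  if (nrow(rows) > 0) {
    stopifnot(all(rows$se_exp > 0), all(rows$se_out > 0))
  }
  if (any(rows$variant_id %in% dropped$variant_id)) {
    stop("validation error: variant present in both rows and dropped",
         call. = FALSE)
  }
  rownames(rows) <- NULL
  structure(list(exposure = exposure_name, outcome = outcome_name,
                 rows = rows[needed], dropped = dropped,
                 outcome_binary = isTRUE(outcome_binary)),
            class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized set: %s -> %s, %d instruments (%d dropped)\n",
              x$exposure, x$outcome, nrow(x$rows), nrow(x$dropped)))
  invisible(x)
}

#' Align outcome effects to the exposure's effect alleles
#'
#' For each exposure instrument found in the outcome table the outcome
#' effect is re-expressed on the exposure's effect allele:
#' matching alleles are kept as-is; swapped alleles negate the outcome beta
#' and reflect its allele frequency; alleles that match only after strand
#' complement are complemented first and then treated the same way.
#' Palindromic variants (A/T, C/G), where strand cannot be read from the
#' alleles, are oriented by allele frequency when both sides fall outside
#' the ambiguity window, and dropped as `palindromic_ambiguous` otherwise
#' (including when either frequency is missing). Instruments absent from the
#' outcome table are dropped as `missing_in_outcome`; irreconcilable allele
#' pairs as `allele_mismatch`. No proxy-variant search is attempted.
#'
#' @param exposure_rows Data frame of selected exposure instruments
#'   (canonical summary columns).
#' @param outcome_table A [summary_table()] for the outcome.
#' @param exposure_name Label for the exposure (defaults to "exposure").
#' @param eaf_window Allele-frequency ambiguity window for palindromic
#'   variants (default `c(0.42, 0.58)`).
#' @return A [harmonized_set()].
#' @export
harmonize <- function(exposure_rows, outcome_table,
                      exposure_name = "exposure",
                      eaf_window = c(0.42, 0.58)) {
  stopifnot(inherits(outcome_table, "summary_table"))
  out_data <- outcome_table$data
  idx <- match(exposure_rows$variant_id, out_data$variant_id)

  rows <- list()
  dropped <- list()
  for (i in seq_len(nrow(exposure_rows))) {
    ex <- exposure_rows[i, ]
    if (is.na(idx[i])) {
      dropped[[length(dropped) + 1]] <-
        data.frame(variant_id = ex$variant_id, reason = "missing_in_outcome")
      next
    }
    ou <- out_data[idx[i], ]
    e1 <- ex$effect_allele; e2 <- ex$other_allele
    o1 <- ou$effect_allele; o2 <- ou$other_allele
    beta_out <- ou$beta; eaf_out <- ou$eaf

    if (is_palindromic(e1, e2)) {
      if (!((o1 == e1 && o2 == e2) || (o1 == e2 && o2 == e1))) {
        dropped[[length(dropped) + 1]] <-
          data.frame(variant_id = ex$variant_id, reason = "allele_mismatch")
        next
      }
      ambiguous <- function(f) is.na(f) || (f >= eaf_window[1] && f <= eaf_window[2])
      if (ambiguous(ex$eaf) || ambiguous(eaf_out)) {
        dropped[[length(dropped) + 1]] <-
          data.frame(variant_id = ex$variant_id,
                     reason = "palindromic_ambiguous")
        next
      }
      if (o1 == e2) {           # nominal swap first
        beta_out <- -beta_out
        eaf_out <- 1 - eaf_out
      }
      # frequency is the only strand witness for palindromic alleles
      if ((ex$eaf - 0.5) * (eaf_out - 0.5) < 0) {
        beta_out <- -beta_out
        eaf_out <- 1 - eaf_out
      }
    } else {
      c1 <- allele_complement(o1); c2 <- allele_complement(o2)
      if (o1 == e1 && o2 == e2) {
        # direct match, nothing to do
      } else if (o1 == e2 && o2 == e1) {
        beta_out <- -beta_out
        eaf_out <- 1 - eaf_out
      } else if (c1 == e1 && c2 == e2) {
        # strand complement, same orientation
      } else if (c1 == e2 && c2 == e1) {
        beta_out <- -beta_out
        eaf_out <- 1 - eaf_out
      } else {
        dropped[[length(dropped) + 1]] <-
          data.frame(variant_id = ex$variant_id, reason = "allele_mismatch")
        next
      }
    }

    rows[[length(rows) + 1]] <- data.frame(
      variant_id = ex$variant_id,
      effect_allele = e1, other_allele = e2,
      beta_exp = ex$beta, se_exp = ex$se, eaf_exp = ex$eaf,
      beta_out = beta_out, se_out = ou$se,
      eaf_out = if (is.null(eaf_out)) NA_real_ else eaf_out,
      stringsAsFactors = FALSE)
  }

  empty_rows <- data.frame(variant_id = character(0),
                           effect_allele = character(0),
                           other_allele = character(0),
                           beta_exp = numeric(0), se_exp = numeric(0),
                           eaf_exp = numeric(0), beta_out = numeric(0),
                           se_out = numeric(0), eaf_out = numeric(0),
                           stringsAsFactors = FALSE)
  rows_df <- if (length(rows) > 0) do.call(rbind, rows) else empty_rows
  dropped_df <- if (length(dropped) > 0) {
    do.call(rbind, dropped)
  } else {
    data.frame(variant_id = character(0), reason = character(0))
  }
  harmonized_set(exposure_name, outcome_table$trait_name, rows_df, dropped_df,
                 outcome_binary = outcome_table$trait_type == "binary")
}

#' Joint harmonization for multivariable MR
#'
#' Aligns several exposures and the outcome to a common effect allele over a
#' shared instrument list. The first exposure table provides the reference
#' orientation; every instrument must be present in all tables
#' (complete-case), others are dropped with an audit reason.
#'
#' @param exposure_tables Named list of [summary_table()] objects.
#' @param outcome_table Outcome [summary_table()].
#' @param instrument_ids Character vector of instrument variant ids (the
#'   union of the per-exposure selections).
#' @param eaf_window Palindromic ambiguity window, as in [harmonize()].
#' @return Object of class `mv_harmonized_set` with fields `exposures`
#'   (names), `outcome`, `beta_exp` (matrix k x m), `se_exp` (matrix),
#'   `rows` (outcome-side data frame), `dropped`.
#' @export
harmonize_mv <- function(exposure_tables, outcome_table, instrument_ids,
                         eaf_window = c(0.42, 0.58)) {
  stopifnot(length(exposure_tables) >= 1, inherits(outcome_table, "summary_table"))
  exp_names <- names(exposure_tables) %||%
    paste0("exposure", seq_along(exposure_tables))
  ref <- exposure_tables[[1]]$data
  ref_rows <- ref[match(instrument_ids, ref$variant_id), , drop = FALSE]

  dropped <- data.frame(variant_id = character(0), reason = character(0))
  keep <- !is.na(ref_rows$variant_id)
  if (any(!keep)) {
    dropped <- rbind(dropped, data.frame(
      variant_id = instrument_ids[!keep],
      reason = paste0("missing_in_", exp_names[1])))
  }
  ref_rows <- ref_rows[keep, , drop = FALSE]

  # align every non-reference table (other exposures + outcome) to the
  # reference orientation using the pairwise rules
  aligned <- list()
  aligned[[exp_names[1]]] <- data.frame(variant_id = ref_rows$variant_id,
                                        beta = ref_rows$beta,
                                        se = ref_rows$se)
  tables <- c(exposure_tables[-1], list(.outcome = outcome_table))
  labels <- c(exp_names[-1], outcome_table$trait_name)
  for (t in seq_along(tables)) {
    h <- harmonize(ref_rows, tables[[t]], exposure_name = exp_names[1],
                   eaf_window = eaf_window)
    lost <- setdiff(ref_rows$variant_id, h$rows$variant_id)
    if (length(lost) > 0) {
      reasons <- h$dropped$reason[match(lost, h$dropped$variant_id)]
      dropped <- rbind(dropped, data.frame(
        variant_id = lost, reason = paste0(labels[t], ":", reasons)))
      keep_ids <- setdiff(ref_rows$variant_id, lost)
      ref_rows <- ref_rows[ref_rows$variant_id %in% keep_ids, , drop = FALSE]
      aligned <- lapply(aligned, function(a) a[a$variant_id %in% keep_ids, ,
                                               drop = FALSE])
      aligned[[t + 1]] <- data.frame(variant_id = h$rows$variant_id,
                                     beta = h$rows$beta_out,
                                     se = h$rows$se_out)
      aligned[[t + 1]] <- aligned[[t + 1]][
        aligned[[t + 1]]$variant_id %in% keep_ids, , drop = FALSE]
    } else {
      aligned[[t + 1]] <- data.frame(variant_id = h$rows$variant_id,
                                     beta = h$rows$beta_out,
                                     se = h$rows$se_out)
    }
  }
  # re-filter all aligned frames to the surviving complete-case ids
  final_ids <- ref_rows$variant_id
  aligned <- lapply(aligned, function(a) {
    a[match(final_ids, a$variant_id), , drop = FALSE]
  })

  m <- length(exposure_tables)
  beta_exp <- do.call(cbind, lapply(aligned[seq_len(m)], function(a) a$beta))
  se_exp <- do.call(cbind, lapply(aligned[seq_len(m)], function(a) a$se))
  colnames(beta_exp) <- colnames(se_exp) <- exp_names
  out_aligned <- aligned[[m + 1]]

  structure(list(exposures = exp_names,
                 outcome = outcome_table$trait_name,
                 variant_id = final_ids,
                 beta_exp = beta_exp, se_exp = se_exp,
                 beta_out = out_aligned$beta, se_out = out_aligned$se,
                 dropped = dropped,
                 outcome_binary = outcome_table$trait_type == "binary"),
            class = "mv_harmonized_set")
}
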