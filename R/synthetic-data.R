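#' @name synthetic-data
#' @title Summary-level GWAS simulation with planted causal structure
#'
#' @description
#' The generator works entirely at the summary-statistics level (two-sample
#' MR never sees individual genotypes): per-variant standard errors follow
#' the binomial-information formula `1 / sqrt(2 n maf (1 - maf))`, true
#' instrument effects are drawn from a normal and rejection-sampled to pass
#' the genome-wide threshold at the exposure sample size, observed effects
#' add sampling noise, and outcome effects are
#' `theta * beta_true + alpha + noise` with `alpha` a per-variant
#' horizontal-pleiotropy term (optionally correlated with instrument
#' strength to break the InSIDE assumption). Full tables add LD blocks and
#' null filler variants so clumping and harmonization are exercised, and a
#' mediation scenario plants an exposure-mediator-outcome path with decoy
#' candidates for the four-criterion screen.
NULL

#' Scenario ground truth
#'
#' @param theta True causal effect (log-odds per exposure unit).
#' @param mu_alpha,sigma_alpha Mean and SD of the directional-pleiotropy
#'   term added to instrument outcome effects.
#' @param inside_violated Correlate pleiotropy with instrument strength
#'   (breaks the InSIDE assumption)?
#' @param a_true,b_true,direct_true Mediation-path effects (exposure to
#'   mediator, mediator to outcome direct, exposure to outcome direct).
#' @param n_snp Number of instruments (per trait in the mediation
#'   scenario).
#' @param n_exp,n_out Effective GWAS sample sizes for the exposure and
#'   outcome sides.
#' @param maf_range Minor-allele-frequency range, within (0, 0.5].
#' @param sigma_x SD of the true instrument-effect distribution before
#'   thresholding.
#' @param p_threshold Threshold the true effects are conditioned to pass.
#' @param prop_invalid Fraction of instruments receiving large
#'   balanced-sign pleiotropy (the weighted-median breakdown scenario).
#' @param invalid_effect Magnitude of that pleiotropy (sign is random).
#' @param n_outlier Number of planted outlier instruments.
#' @param outlier_mult Ratio multiplier for the planted outliers (their
#'   outcome effect is `outlier_mult * theta * beta_true`).
#' @param outlier_se_mult Factor shrinking the outliers' outcome standard
#'   errors (small-SE outliers are the hard case for outlier tests).
#' @param seed RNG seed.
#' @return Object of class `scenario_truth`.
#' @export
scenario_truth <- function(theta = 0, mu_alpha = 0, sigma_alpha = 0,
                           inside_violated = FALSE,
                           a_true = 0, b_true = 0, direct_true = 0,
                           n_snp = 50, n_exp = 1e5, n_out = 1e5,
                           maf_range = c(0.1, 0.4), sigma_x = 0.05,
                           p_threshold = 5e-8,
                           prop_invalid = 0, invalid_effect = 0,
                           n_outlier = 0, outlier_mult = 10,
                           outlier_se_mult = 0.5, seed = 1L) {
  stopifnot(n_snp >= 1, sigma_alpha >= 0,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            p_threshold > 0, p_threshold < 1,
            prop_invalid >= 0, prop_invalid <= 1,
            n_outlier >= 0, n_outlier <= n_snp)
  structure(list(theta = theta, mu_alpha = mu_alpha,
                 sigma_alpha = sigma_alpha,
                 inside_violated = isTRUE(inside_violated),
                 a_true = a_true, b_true = b_true,
                 direct_true = direct_true,
                 n_snp = as.integer(n_snp), n_exp = n_exp, n_out = n_out,
                 maf_range = maf_range, sigma_x = sigma_x,
                 p_threshold = p_threshold,
                 prop_invalid = prop_invalid,
                 invalid_effect = invalid_effect,
                 n_outlier = as.integer(n_outlier),
                 outlier_mult = outlier_mult,
                 outlier_se_mult = outlier_se_mult,
                 seed = as.integer(seed)),
            class = "scenario_truth")
}

# per-allele SE from effective sample size and allele frequency
gwas_se <- function(n, maf) 1 / sqrt(2 * n * maf * (1 - maf))

# rejection-sample true effects passing |beta|/se > z_thr
draw_true_effects <- function(k, se, sigma_x, z_thr) {
  accept <- 2 * stats::pnorm(z_thr * se / sigma_x, lower.tail = FALSE)
  if (any(accept < 1e-6)) {
    stop("scenario error: rejection sampling infeasible ",
         "(sigma_x too small for the threshold at this sample size)",
         call. = FALSE)
  }
  beta <- numeric(k)
  need <- seq_len(k)
  while (length(need) > 0) {
    cand <- stats::rnorm(length(need), 0, sigma_x)
    ok <- abs(cand) / se[need] > z_thr
    beta[need[ok]] <- cand[ok]
    need <- need[!ok]
  }
  beta
}

# instrument-level quantities; assumes the RNG is already seeded
sim_core <- function(truth) {
  k <- truth$n_snp
  maf <- stats::runif(k, truth$maf_range[1], truth$maf_range[2])
  se_exp <- gwas_se(truth$n_exp, maf)
  se_out <- gwas_se(truth$n_out, maf)
  z_thr <- stats::qnorm(truth$p_threshold / 2, lower.tail = FALSE)
  beta_true <- draw_true_effects(k, se_exp, truth$sigma_x, z_thr)
  beta_exp <- beta_true + stats::rnorm(k, 0, se_exp)

  # pleiotropy is defined in the exposure-increasing allele orientation
  # (sign(beta_true) below): a directional mean shows up as a nonzero
  # Egger intercept after the usual orientation step rather than
  # cancelling across arbitrarily coded effect alleles
  alpha_oriented <- if (truth$inside_violated) {
    strength <- abs(beta_true)
    std <- (strength - mean(strength)) / max(stats::sd(strength), 1e-12)
    truth$mu_alpha + truth$sigma_alpha *
      (sqrt(1 - 0.8^2) * stats::rnorm(k) + 0.8 * std)
  } else {
    truth$mu_alpha + truth$sigma_alpha * stats::rnorm(k)
  }
  alpha <- sign(beta_true) * alpha_oriented
  invalid <- rep(FALSE, k)
  if (truth$prop_invalid > 0) {
    n_inv <- floor(truth$prop_invalid * k)
    idx <- sample.int(k, n_inv)
    invalid[idx] <- TRUE
    alpha[idx] <- alpha[idx] +
      truth$invalid_effect * sample(c(-1, 1), n_inv, replace = TRUE)
  }
  beta_out <- truth$theta * beta_true + alpha + stats::rnorm(k, 0, se_out)

  outlier <- rep(FALSE, k)
  if (truth$n_outlier > 0) {
    idx <- sample.int(k, truth$n_outlier)
    outlier[idx] <- TRUE
    se_out[idx] <- se_out[idx] * truth$outlier_se_mult
    beta_out[idx] <- truth$outlier_mult * truth$theta * beta_true[idx] +
      stats::rnorm(truth$n_outlier, 0, se_out[idx])
  }
  eaf <- ifelse(stats::runif(k) < 0.5, maf, 1 - maf)
  list(maf = maf, eaf = eaf, se_exp = se_exp, se_out = se_out,
       beta_true = beta_true, beta_exp = beta_exp, beta_out = beta_out,
       invalid = invalid, outlier = outlier, z_thr = z_thr)
}

#' Simulate an already-harmonized instrument set
#'
#' The fast path for calibration and recovery studies: draws the
#' instrument-level effect pairs directly (no filler variants, no allele
#' scrambling) under the scenario's generative model. True effects are
#' conditioned to pass the selection threshold; observed effects carry
#' sampling noise.
#'
#' @param truth A [scenario_truth()].
#' @return A [harmonized_set()]; the generating `scenario_truth` and the
#'   per-variant validity/outlier indicators are attached as attributes
#'   `truth`, `invalid`, `outlier`.
#' @export
simulate_harmonized <- function(truth) {
  stopifnot(inherits(truth, "scenario_truth"))
  core <- with_seed(truth$seed, sim_core(truth))
  k <- truth$n_snp
  rows <- data.frame(variant_id = sprintf("iv%03d", seq_len(k)),
                     effect_allele = "A", other_allele = "G",
                     beta_exp = core$beta_exp, se_exp = core$se_exp,
                     eaf_exp = core$eaf, beta_out = core$beta_out,
                     se_out = core$se_out, eaf_out = core$eaf,
                     stringsAsFactors = FALSE)
  hset <- harmonized_set("exposure", "outcome", rows,
                         outcome_binary = TRUE)
  attr(hset, "truth") <- truth
  attr(hset, "invalid") <- core$invalid
  attr(hset, "outlier") <- core$outlier
  hset
}

ALLELE_PAIRS <- local({
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  p <- expand.grid(a1 = names(comp), a2 = names(comp),
                   stringsAsFactors = FALSE)
  p <- p[p$a1 != p$a2, ]
  p$palindromic <- unname(comp[p$a1]) == p$a2
  p
})
PALINDROMIC_PAIRS <- ALLELE_PAIRS[ALLELE_PAIRS$palindromic, c("a1", "a2")]
NONPALINDROMIC_PAIRS <- ALLELE_PAIRS[!ALLELE_PAIRS$palindromic,
                                     c("a1", "a2")]

# draw allele pairs; ~16% palindromic so harmonization is exercised
draw_alleles <- function(n, p_palindromic = 0.16) {
  pal <- stats::runif(n) < p_palindromic
  out <- data.frame(a1 = character(n), a2 = character(n),
                    stringsAsFactors = FALSE)
  if (any(pal)) {
    i <- sample.int(nrow(PALINDROMIC_PAIRS), sum(pal), replace = TRUE)
    out[pal, ] <- PALINDROMIC_PAIRS[i, ]
  }
  if (any(!pal)) {
    i <- sample.int(nrow(NONPALINDROMIC_PAIRS), sum(!pal), replace = TRUE)
    out[!pal, ] <- NONPALINDROMIC_PAIRS[i, ]
  }
  out
}

# express a table's rows in a random allele representation (swap and/or
# strand flip) without changing the association they encode
scramble_orientation <- function(df) {
  n <- nrow(df)
  swap <- stats::runif(n) < 0.5
  if (any(swap)) {
    tmp <- df$effect_allele[swap]
    df$effect_allele[swap] <- df$other_allele[swap]
    df$other_allele[swap] <- tmp
    df$beta[swap] <- -df$beta[swap]
    df$eaf[swap] <- 1 - df$eaf[swap]
  }
  pal <- is_palindromic(df$effect_allele, df$other_allele)
  flip <- stats::runif(n) < 0.5 & !pal
  if (any(flip)) {
    df$effect_allele[flip] <- allele_complement(df$effect_allele[flip])
    df$other_allele[flip] <- allele_complement(df$other_allele[flip])
  }
  df
}

# keep palindromic allele frequencies clear of the ambiguity window
nudge_eaf <- function(eaf, pal, window = c(0.42, 0.58)) {
  low <- pal & eaf < 0.5 & eaf > window[1] - 0.005
  high <- pal & eaf >= 0.5 & eaf < window[2] + 0.005
  eaf[low] <- window[1] - 0.005
  eaf[high] <- window[2] + 0.005
  eaf
}

#' Generate a full exposure-outcome GWAS pair
#'
#' Produces complete summary tables with the statistical structure the
#' pipeline assumes: each planted instrument heads an LD block of
#' `block_size` variants (within-block r-squared uniform on 0.2-0.99, zero
#' between blocks) whose partners carry attenuated copies of the signal, so
#' clumping has real work to do; additional null blocks contribute filler
#' variants that never reach the selection threshold; allele
#' representations in the outcome table are scrambled (swaps and strand
#' flips, palindromic pairs included) so harmonization is exercised.
#' Observed instrument effects are re-drawn until they also pass the
#' selection threshold, making the planted instrument list recoverable by
#' the selection pipeline.
#'
#' @param truth A [scenario_truth()].
#' @param block_size Variants per LD block (default 5).
#' @param null_block_frac Null filler blocks as a fraction of instrument
#'   blocks (default 0.2).
#' @return List with `exposure`, `outcome` ([summary_table()]s), `ld`
#'   (an [ld_table()]) and `truth` (the input plus realized
#'   `instrument_ids`, `block` assignment and `beta_true`).
#' @export
generate_pair <- function(truth, block_size = 5, null_block_frac = 0.2) {
  stopifnot(inherits(truth, "scenario_truth"))
  with_seed(truth$seed, {
    core <- sim_core(truth)
    k <- truth$n_snp
    n_null <- max(2, ceiling(null_block_frac * k))
    n_block <- k + n_null
    per_block <- block_size

    n_var <- n_block * per_block
    block_id <- rep(seq_len(n_block), each = per_block)
    within <- rep(seq_len(per_block), n_block)
    is_index <- within == 1 & block_id <= k
    inst_of <- ifelse(block_id <= k, block_id, NA_integer_)

    chrom <- as.character(((block_id - 1) %% 22) + 1)
    pos <- 1e6 + ((block_id - 1) %/% 22) * 2.5e7 + (within - 1) * 5e3
    variant_id <- sprintf("rs%05d", seq_len(n_var))

    maf <- numeric(n_var)
    maf[is_index] <- core$maf
    others <- !is_index
    maf[others] <- stats::runif(sum(others), truth$maf_range[1],
                                truth$maf_range[2])
    se_exp <- gwas_se(truth$n_exp, maf)
    se_out <- gwas_se(truth$n_out, maf)
    se_out[is_index] <- core$se_out          # carries any outlier shrinkage

    # true exposure effects: index = planted, partners = attenuated by
    # sqrt(r2) with their index, null blocks = 0
    r2_with_index <- stats::runif(n_var, 0.2, 0.99)
    r2_with_index[within == 1] <- 1
    beta_true <- numeric(n_var)
    in_signal <- !is.na(inst_of)
    beta_true[in_signal] <- sqrt(r2_with_index[in_signal]) *
      core$beta_true[inst_of[in_signal]]

    beta_exp <- beta_true + stats::rnorm(n_var, 0, se_exp)
    beta_exp[is_index] <- core$beta_exp
    # condition the observed index effects to pass the threshold so the
    # planted list is recoverable by selection
    for (i in which(is_index)) {
      tries <- 0
      while (2 * stats::pnorm(-abs(beta_exp[i]) / se_exp[i]) >=
             truth$p_threshold) {
        beta_exp[i] <- beta_true[i] + stats::rnorm(1, 0, se_exp[i])
        tries <- tries + 1
        if (tries > 1000) {
          stop("scenario error: observed instrument cannot reach threshold",
               call. = FALSE)
        }
      }
    }

    alpha <- numeric(n_var)
    beta_out <- truth$theta * beta_true + alpha +
      stats::rnorm(n_var, 0, se_out)
    beta_out[is_index] <- core$beta_out      # includes pleiotropy/outliers

    alleles <- draw_alleles(n_var)
    eaf <- ifelse(stats::runif(n_var) < 0.5, maf, 1 - maf)
    pal <- is_palindromic(alleles$a1, alleles$a2)
    eaf <- nudge_eaf(eaf, pal)

    exp_df <- data.frame(variant_id = variant_id, chrom = chrom,
                         pos = as.integer(pos),
                         effect_allele = alleles$a1,
                         other_allele = alleles$a2,
                         eaf = eaf, beta = beta_exp, se = se_exp,
                         pval = pmax(2 * stats::pnorm(-abs(beta_exp) / se_exp),
                                     .Machine$double.xmin),
                         n = truth$n_exp, stringsAsFactors = FALSE)
    eaf_out <- pmin(pmax(eaf + stats::rnorm(n_var, 0, 0.005), 0.01), 0.99)
    eaf_out <- nudge_eaf(eaf_out, pal)
    out_df <- data.frame(variant_id = variant_id, chrom = chrom,
                         pos = as.integer(pos),
                         effect_allele = alleles$a1,
                         other_allele = alleles$a2,
                         eaf = eaf_out, beta = beta_out, se = se_out,
                         pval = pmax(2 * stats::pnorm(-abs(beta_out) / se_out),
                                     .Machine$double.xmin),
                         n = truth$n_out, stringsAsFactors = FALSE)
    out_df <- scramble_orientation(out_df)

    # within-block pairwise LD
    ld_rows <- do.call(rbind, lapply(seq_len(n_block), function(b) {
      ids <- variant_id[block_id == b]
      if (length(ids) < 2) return(NULL)
      cmb <- utils::combn(ids, 2)
      data.frame(id1 = cmb[1, ], id2 = cmb[2, ],
                 r2 = stats::runif(ncol(cmb), 0.2, 0.99),
                 stringsAsFactors = FALSE)
    }))

    truth_out <- truth
    truth_out$instrument_ids <- variant_id[is_index]
    truth_out$block <- block_id
    truth_out$signal_block <- block_id <= k
    truth_out$variant_id <- variant_id
    truth_out$beta_true <- beta_true

    list(exposure = summary_table("exposure", "binary", exp_df),
         outcome = summary_table("outcome", "binary", out_df),
         ld = ld_table(ld_rows),
         truth = truth_out)
  })
}

#' Generate an exposure-mediator-outcome mediation scenario
#'
#' Plants the two-step structure: the exposure affects the mediator
#' (path `a_true`), the mediator affects the outcome (path `b_true`) and
#' the exposure retains a direct outcome effect (`direct_true`), so the
#' true total effect is `direct_true + a_true * b_true` and the true
#' mediation proportion `a_true * b_true / total`. Two decoy candidates
#' exercise the screen: one with no exposure-to-candidate path
#' (`decoy_null`) and one that also causes the exposure
#' (`decoy_reverse`); both have real outcome effects so they survive the
#' earlier criteria and must be rejected at Criterion 3. Each trait has its
#' own independent instrument set; every table reports all variants with
#' scrambled allele representations.
#'
#' @param truth A [scenario_truth()] (fields `a_true`, `b_true`,
#'   `direct_true`, `n_snp` per trait, sample sizes, seed).
#' @param b_decoy Outcome effect of each decoy (default 0.3).
#' @param r_reverse Reverse-causal effect of `decoy_reverse` on the
#'   exposure (default 0.15; strong enough for the reverse test to detect,
#'   weak enough that the decoy's variants stay below the exposure's
#'   selection threshold).
#' @return List with `exposure`, `mediator`, `decoy_null`, `decoy_reverse`,
#'   `outcome` ([summary_table()]s), `ld` (empty [ld_table()]), `truth`
#'   (with `true_total` and `true_proportion` added).
#' @export
generate_mediation_scenario <- function(truth, b_decoy = 0.3,
                                        r_reverse = 0.15) {
  stopifnot(inherits(truth, "scenario_truth"))
  with_seed(truth$seed, {
    k <- truth$n_snp
    traits <- c("exposure", "mediator", "decoy_null", "decoy_reverse")
    n_var <- 4 * k
    owner <- rep(traits, each = k)
    variant_id <- sprintf("rs%05d", seq_len(n_var))
    chrom <- as.character(((seq_len(n_var) - 1) %% 22) + 1)
    pos <- as.integer(1e6 + ((seq_len(n_var) - 1) %/% 22) * 2e7)

    maf <- stats::runif(n_var, truth$maf_range[1], truth$maf_range[2])
    z_thr <- stats::qnorm(truth$p_threshold / 2, lower.tail = FALSE)
    # per-trait direct ("own-instrument") effects
    g <- numeric(n_var)
    for (tr in traits) {
      i <- owner == tr
      g[i] <- draw_true_effects(k, gwas_se(truth$n_exp, maf[i]),
                                truth$sigma_x, z_thr)
    }
    gX <- ifelse(owner == "exposure", g, 0)
    gM <- ifelse(owner == "mediator", g, 0)
    gD1 <- ifelse(owner == "decoy_null", g, 0)
    gD2 <- ifelse(owner == "decoy_reverse", g, 0)

    a <- truth$a_true; b <- truth$b_true; direct <- truth$direct_true
    tX <- gX + r_reverse * gD2               # decoy_reverse causes exposure
    tM <- a * tX + gM                        # exposure causes mediator
    tD1 <- gD1                               # no exposure path (a = 0 decoy)
    tD2 <- gD2 + a * gX                      # exposure also causes decoy 2
    tY <- direct * tX + b * tM + b_decoy * tD1 + b_decoy * gD2

    # one allele ground truth shared by every table; each non-reference
    # table then re-represents it with swaps and strand flips
    alleles <- draw_alleles(n_var)
    pal <- is_palindromic(alleles$a1, alleles$a2)
    eaf_true <- nudge_eaf(ifelse(stats::runif(n_var) < 0.5, maf, 1 - maf),
                          pal)
    make_table <- function(name, total_effect, n_eff, own,
                           condition_nonown = TRUE) {
      se <- gwas_se(n_eff, maf)
      beta <- total_effect + stats::rnorm(n_var, 0, se)
      # a trait's own instruments must pass the selection threshold and,
      # for tables instruments are drawn from, every other variant must
      # not: each trait's planted instrument set is then exactly what
      # selection recovers. The outcome table is never selected from and
      # is left unconditioned.
      idx <- if (condition_nonown) seq_len(n_var) else which(own)
      for (i in idx) {
        pass_wanted <- own[i]
        tries <- 0
        repeat {
          passes <- 2 * stats::pnorm(-abs(beta[i]) / se[i]) <
            truth$p_threshold
          if (passes == pass_wanted) break
          beta[i] <- total_effect[i] + stats::rnorm(1, 0, se[i])
          tries <- tries + 1
          if (tries > 1000) {
            if (pass_wanted) {
              stop("scenario error: instrument unrecoverable", call. = FALSE)
            }
            # overwhelming cross-trait signal: pin just below threshold
            beta[i] <- sign(total_effect[i]) * se[i] * z_thr * 0.99
            break
          }
        }
      }
      eaf <- nudge_eaf(pmin(pmax(eaf_true + stats::rnorm(n_var, 0, 0.005),
                                 0.01), 0.99), pal)
      df <- data.frame(variant_id = variant_id, chrom = chrom, pos = pos,
                       effect_allele = alleles$a1,
                       other_allele = alleles$a2, eaf = eaf, beta = beta,
                       se = se,
                       pval = pmax(2 * stats::pnorm(-abs(beta) / se),
                                   .Machine$double.xmin),
                       n = n_eff, stringsAsFactors = FALSE)
      if (name != "exposure") df <- scramble_orientation(df)
      summary_table(name, "binary", df)
    }
    tables <- list(
      exposure = make_table("exposure", tX, truth$n_exp,
                            owner == "exposure"),
      mediator = make_table("mediator", tM, truth$n_exp,
                            owner == "mediator"),
      decoy_null = make_table("decoy_null", tD1, truth$n_exp,
                              owner == "decoy_null"),
      decoy_reverse = make_table("decoy_reverse", tD2, truth$n_exp,
                                 owner == "decoy_reverse"),
      outcome = make_table("outcome", tY, truth$n_out, rep(FALSE, n_var),
                           condition_nonown = FALSE))

    truth_out <- truth
    truth_out$true_total <- direct + a * b
    truth_out$true_proportion <- 100 * a * b / (direct + a * b)
    truth_out$owner <- owner
    truth_out$variant_id <- variant_id
    c(tables, list(ld = ld_table(), truth = truth_out))
  })
}

#' Generate a confounder-association table for planted instruments
#'
#' Marks a seeded random fraction of the instruments with a confounder
#' association below the genome-wide threshold, so the exclusion stage has
#' deterministic work; `fraction = 0` yields an empty table (the exclusion
#' stage is then the identity).
#'
#' @param instrument_ids Character vector of instrument variant ids.
#' @param fraction Fraction to mark, in `[0, 1]`.
#' @param seed RNG seed.
#' @return Data frame (`variant_id`, `trait`, `pval`) with
#'   `round(fraction * k)` rows.
#' @export
generate_confounder_table <- function(instrument_ids, fraction, seed) {
  stopifnot(fraction >= 0, fraction <= 1)
  k <- length(instrument_ids)
  m <- round(fraction * k)
  if (m == 0) {
    return(data.frame(variant_id = character(0), trait = character(0),
                      pval = numeric(0)))
  }
  with_seed(seed, {
    ids <- sample(instrument_ids, m)
    data.frame(variant_id = ids,
               trait = sample(c("smoking", "alcohol", "education"), m,
                              replace = TRUE),
               pval = 10^(-stats::runif(m, 8.4, 20)),
               stringsAsFactors = FALSE)
  })
}
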