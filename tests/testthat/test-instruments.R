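test_that("p-value selection keeps exactly the sub-threshold rows in order", {
  tbl <- make_table(n = 2, pval = c(1e-9, 1e-7))
  expect_equal(nrow(select_instruments(tbl, 5e-8)), 1)
  expect_equal(nrow(select_instruments(tbl, 5e-6)), 2)
  tbl2 <- make_table(n = 5, pval = runif(5))
  expect_equal(select_instruments(tbl2, 1 - 1e-12)$variant_id,
               tbl2$data$variant_id)
})

test_that("clumping keeps the better variant in LD and respects the window", {
  cand <- make_variants(n = 2, pos = c(1000L, 2000L),
                        pval = c(1e-10, 1e-9))
  ld <- ld_table(data.frame(id1 = "rs001", id2 = "rs002", r2 = 0.9))
  kept <- clump(cand, ld)
  expect_equal(kept$variant_id, "rs001")

  far <- cand
  far$pos <- c(1000L, 1000L + 2e7)
  expect_equal(nrow(clump(far, ld)), 2)

  # different chromosomes are never clumped against each other
  other_chrom <- cand
  other_chrom$chrom <- c("1", "2")
  expect_equal(nrow(clump(other_chrom, ld)), 2)
})

test_that("clumping on a random block matches the greedy definition decision by decision", {
  set.seed(41)
  n <- 20
  cand <- make_variants(n = n, chrom = "2",
                        pos = as.integer(sort(sample.int(3e7, n))),
                        pval = runif(n, 1e-12, 1e-6))
  pairs <- t(combn(cand$variant_id, 2))
  ld <- ld_table(data.frame(id1 = pairs[, 1], id2 = pairs[, 2],
                            r2 = sample(c(0, 0.0005, 0.3, 0.9),
                                        nrow(pairs), replace = TRUE)))
  kept <- clump(cand, ld, r2_max = 0.001, window_bp = 1e7)

  # oracle: replay every accept/reject decision in p-order
  ord <- cand[order(cand$pval, cand$variant_id), ]
  accepted <- character(0)
  for (i in seq_len(nrow(ord))) {
    conflict <- FALSE
    for (a in accepted) {
      ar <- ord[ord$variant_id == a, ]
      if (ar$chrom == ord$chrom[i] &&
          abs(ar$pos - ord$pos[i]) <= 1e7 &&
          ld_lookup(ld, ord$variant_id[i], a) >= 0.001) conflict <- TRUE
    }
    if (!conflict) accepted <- c(accepted, ord$variant_id[i])
  }
  expect_setequal(kept$variant_id, accepted)
  # output sorted by position, and an independent set
  expect_equal(kept$pos, sort(kept$pos))
  if (nrow(kept) > 1) {
    cmb <- t(combn(seq_len(nrow(kept)), 2))
    viol <- abs(kept$pos[cmb[, 1]] - kept$pos[cmb[, 2]]) <= 1e7 &
      ld_lookup(ld, kept$variant_id[cmb[, 1]],
                kept$variant_id[cmb[, 2]]) >= 0.001
    expect_false(any(viol))
  }
})

test_that("F-statistic is the squared Wald z and matches p-value back-calculation", {
  expect_equal(f_statistic(0.1, 0.02), 25)
  expect_equal(f_statistic(0, 0.5), 0)
  set.seed(7)
  beta <- rnorm(50, 0, 0.05)
  se <- runif(50, 0.005, 0.02)
  p <- 2 * pnorm(-abs(beta / se))
  z2 <- qnorm(p / 2)^2          # invert the p-value
  expect_equal(f_statistic(beta, se), z2, tolerance = 0.05)
})

test_that("weak-instrument filtering applies the exposure-eligibility rule", {
  cand <- make_variants(n = 2, beta = c(0.1, 0.06), se = c(0.02, 0.02))
  # F = 25 and 9
  fw <- filter_weak(cand, f_min = 10)
  expect_equal(fw$kept$variant_id, "rs001")
  expect_equal(fw$mean_f, 25)
  expect_true(fw$eligible)

  weak <- make_variants(n = 3, beta = 0.01, se = 0.02)   # all F = 0.25
  fw2 <- filter_weak(weak, f_min = 10)
  expect_equal(nrow(fw2$kept), 0)
  expect_false(fw2$eligible)

  fw3 <- filter_weak(cand, f_min = 0)
  expect_equal(nrow(fw3$kept), nrow(cand))
})

test_that("confounder exclusion removes only sub-threshold associations", {
  cand <- make_variants(n = 3)
  conf <- data.frame(variant_id = c("rs001", "rs002"),
                     trait = c("smoking", "smoking"),
                     pval = c(1e-9, 1e-6))
  res <- exclude_confounder_snps(cand, conf, 5e-8)
  expect_equal(res$removed$variant_id, "rs001")
  expect_match(res$removed$reason, "smoking")
  expect_setequal(res$kept$variant_id, c("rs002", "rs003"))

  # empty table is the identity
  res2 <- exclude_confounder_snps(cand, NULL)
  expect_identical(res2$kept, cand)
  res3 <- exclude_confounder_snps(cand,
                                  data.frame(variant_id = character(0),
                                             trait = character(0),
                                             pval = numeric(0)))
  expect_equal(nrow(res3$removed), 0)
})

test_that("harmonization applies swap, complement and palindromic rules", {
  exp_rows <- make_variants(n = 1, effect_allele = "A", other_allele = "G",
                            beta = 0.10, eaf = 0.3)
  # swapped alleles: negate
  out_swapped <- make_table(n = 1, effect_allele = "G", other_allele = "A",
                            beta = -0.05, eaf = 0.7)
  h <- harmonize(exp_rows, out_swapped)
  expect_equal(h$rows$beta_out, 0.05)
  expect_equal(h$rows$eaf_out, 0.3)

  # strand complement, same orientation: T/C reads as A/G -> sign kept
  out_comp <- make_table(n = 1, effect_allele = "T", other_allele = "C",
                         beta = -0.05, eaf = 0.3)
  h2 <- harmonize(exp_rows, out_comp)
  expect_equal(h2$rows$beta_out, -0.05)

  # strand complement + swap: C/T reads as G/A -> negate
  out_comp_swap <- make_table(n = 1, effect_allele = "C", other_allele = "T",
                              beta = -0.05, eaf = 0.7)
  h2b <- harmonize(exp_rows, out_comp_swap)
  expect_equal(h2b$rows$beta_out, 0.05)
  expect_equal(h2b$rows$eaf_out, 0.3)

  # direct complement (no swap): C/T against G/A... use exposure G/A
  exp_ga <- make_variants(n = 1, effect_allele = "G", other_allele = "A",
                          beta = 0.10, eaf = 0.3)
  out_ct <- make_table(n = 1, effect_allele = "C", other_allele = "T",
                       beta = 0.04, eaf = 0.3)
  h3 <- harmonize(exp_ga, out_ct)
  expect_equal(h3$rows$beta_out, 0.04)

  # palindromic with ambiguous frequency is dropped
  exp_pal <- make_variants(n = 1, effect_allele = "A", other_allele = "T",
                           beta = 0.1, eaf = 0.5)
  out_pal <- make_table(n = 1, effect_allele = "A", other_allele = "T",
                        beta = 0.05, eaf = 0.5)
  h4 <- harmonize(exp_pal, out_pal)
  expect_equal(nrow(h4$rows), 0)
  expect_equal(h4$dropped$reason, "palindromic_ambiguous")

  # palindromic with informative, discordant frequencies is flipped
  exp_pal2 <- make_variants(n = 1, effect_allele = "A", other_allele = "T",
                            beta = 0.1, eaf = 0.2)
  out_pal2 <- make_table(n = 1, effect_allele = "A", other_allele = "T",
                         beta = 0.05, eaf = 0.8)
  h5 <- harmonize(exp_pal2, out_pal2)
  expect_equal(h5$rows$beta_out, -0.05)
  expect_equal(h5$rows$eaf_out, 0.2)

  # missing in outcome, irreconcilable alleles
  out_missing <- make_table(n = 1, variant_id = "other")
  h6 <- harmonize(exp_rows, out_missing)
  expect_equal(h6$dropped$reason, "missing_in_outcome")
  out_bad <- make_table(n = 1, effect_allele = "A", other_allele = "C")
  h7 <- harmonize(exp_rows, out_bad)
  expect_equal(h7$dropped$reason, "allele_mismatch")
})

test_that("harmonization is idempotent", {
  tr <- scenario_truth(theta = 0.2, n_snp = 12, seed = 91)
  gp <- generate_pair(tr)
  inst <- select_instruments(gp$exposure, 5e-8)
  h1 <- harmonize(inst, gp$outcome)
  # rebuild an outcome table from the harmonized rows (exposure orientation)
  out2 <- summary_table("outcome", "binary", data.frame(
    variant_id = h1$rows$variant_id, chrom = "1",
    pos = seq_len(nrow(h1$rows)) * 1000L,
    effect_allele = h1$rows$effect_allele,
    other_allele = h1$rows$other_allele,
    eaf = h1$rows$eaf_out, beta = h1$rows$beta_out, se = h1$rows$se_out,
    pval = 2 * pnorm(-abs(h1$rows$beta_out / h1$rows$se_out)),
    n = 1e5, stringsAsFactors = FALSE))
  h2 <- harmonize(inst[inst$variant_id %in% h1$rows$variant_id, ], out2)
  expect_equal(h2$rows$beta_out, h1$rows$beta_out, tolerance = 1e-12)
  expect_equal(h2$rows$eaf_out, h1$rows$eaf_out, tolerance = 1e-12)
})

test_that("selection pipeline recovers the planted signal blocks", {
  for (seed in c(5, 23)) {
    tr <- scenario_truth(theta = 0.2, n_snp = 15, seed = seed)
    gp <- generate_pair(tr)
    cand <- select_instruments(gp$exposure, 5e-8)
    kept <- clump(cand, gp$ld)
    fw <- filter_weak(kept)
    got <- fw$kept$variant_id
    blocks <- gp$truth$block[match(got, gp$truth$variant_id)]
    # exactly one variant per planted block, nothing from null blocks
    expect_equal(sort(blocks), seq_len(tr$n_snp))
    expect_true(all(gp$truth$signal_block[match(got, gp$truth$variant_id)]))
  }
})
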