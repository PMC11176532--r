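# in-code fixtures shared across the suite

# canonical variant data frame with sensible defaults
make_variants <- function(n = 3,
                          variant_id = sprintf("rs%03d", seq_len(n)),
                          chrom = "1",
                          pos = seq_len(n) * 1000L,
                          effect_allele = "A",
                          other_allele = "G",
                          eaf = 0.3,
                          beta = 0.1,
                          se = 0.02,
                          pval = NULL,
                          n_col = 1e5) {
  if (is.null(pval)) pval <- 2 * pnorm(-abs(beta / se))
  data.frame(variant_id = variant_id, chrom = chrom, pos = pos,
             effect_allele = effect_allele, other_allele = other_allele,
             eaf = eaf, beta = beta, se = se, pval = pval, n = n_col,
             stringsAsFactors = FALSE)
}

make_table <- function(..., name = "trait", type = "binary") {
  summary_table(name, type, make_variants(...))
}

# a harmonized set straight from effect vectors
make_hset <- function(beta_exp, beta_out, se_exp = 0.01, se_out = 0.01,
                      eaf = 0.3, outcome_binary = TRUE) {
  k <- length(beta_exp)
  se_exp <- rep_len(se_exp, k)
  se_out <- rep_len(se_out, k)
  harmonized_set("exposure", "outcome",
                 data.frame(variant_id = sprintf("iv%03d", seq_len(k)),
                            effect_allele = "A", other_allele = "G",
                            beta_exp = beta_exp, se_exp = se_exp,
                            eaf_exp = eaf, beta_out = beta_out,
                            se_out = se_out, eaf_out = eaf,
                            stringsAsFactors = FALSE),
                 outcome_binary = outcome_binary)
}
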