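# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic per-stage seed derived from a root seed and a stage label;
# kept below 2^31 - 1 so set.seed() always accepts it
stage_seed <- function(root, name) {
  h <- as.double(root %% 2147483647L)
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# evaluate `code` under a temporary RNG state so library calls do not
# perturb the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# strand complement for uppercase alleles
allele_complement <- function(a) {
  unname(c(A = "T", T = "A", C = "G", G = "C")[a])
}

is_palindromic <- function(a1, a2) allele_complement(a1) == a2

fmt6 <- function(x) {
  ifelse(is.na(x), NA_character_, formatC(signif(x, 6), format = "g", digits = 6))
}
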