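#' @name sumstats-io
#' @title Reading and writing GWAS summary statistics
#'
#' @description
#' Summary statistics travel as plain tab-separated tables, one row per
#' variant, following a GWAS-SSF-like header
#' (`variant_id`, `chromosome`, `base_pair_location`, `effect_allele`,
#' `other_allele`, `effect_allele_frequency`, `beta`, `standard_error`,
#' `p_value`, `n`). Other header dialects are mapped in through `column_map`.
#' Effect sizes are per-allele log-odds for binary traits and trait-SD units
#' for quantitative traits; positions are 1-based; alleles uppercase A/C/G/T.
#'
#' Allele frequency and sample size may be missing; they are recorded as `NA`,
#' never imputed. P-values of exactly zero (a common GWAS export underflow)
#' are clamped to the smallest positive double with a warning.
NULL

CANONICAL_COLUMNS <- c("variant_id", "chrom", "pos", "effect_allele",
                       "other_allele", "eaf", "beta", "se", "pval", "n")

#' Default header mapping for summary-statistics files
#'
#' Maps the canonical internal field names to the GWAS-SSF-like column
#' headers used on disk. Supply a modified copy to [read_summary_table()]
#' for files with other headers.
#'
#' @return Named character vector, names are internal fields, values are
#'   file headers.
#' @export
default_column_map <- function() {
  c(variant_id = "variant_id",
    chrom = "chromosome",
    pos = "base_pair_location",
    effect_allele = "effect_allele",
    other_allele = "other_allele",
    eaf = "effect_allele_frequency",
    beta = "beta",
    se = "standard_error",
    pval = "p_value",
    n = "n")
}

# per-row validation of variant association records; stops naming the first
# offending rows and fields
validate_variant_rows <- function(df) {
  required <- setdiff(CANONICAL_COLUMNS, c("eaf", "n"))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("configuration error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"eaf" %in% names(df)) df$eaf <- NA_real_
  if (!"n" %in% names(df)) df$n <- NA_real_
  df <- df[CANONICAL_COLUMNS]

  df$variant_id <- as.character(df$variant_id)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("eaf", "beta", "se", "pval", "n")) {
    df[[col]] <- as.numeric(df[[col]])
  }

  # clamp p == 0 before range validation (underflowed exports)
  zero_p <- !is.na(df$pval) & df$pval == 0
  if (any(zero_p)) {
    warning(sum(zero_p), " p-value(s) of exactly 0 clamped to ",
            format(.Machine$double.xmin), call. = FALSE)
    df$pval[zero_p] <- .Machine$double.xmin
  }

  problems <- character(0)
  flag <- function(bad, field, why) {
    if (any(bad)) {
      rows <- which(bad)
      problems <<- c(problems, sprintf("row %d: %s %s", utils::head(rows, 5), field, why))
    }
  }
  flag(is.na(df$se) | df$se <= 0, "se", "must be > 0")
  flag(is.na(df$pval) | df$pval <= 0 | df$pval > 1, "pval", "must be in (0, 1]")
  flag(!is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1), "eaf", "must be in (0, 1)")
  flag(!df$effect_allele %in% c("A", "C", "G", "T"), "effect_allele",
       "must be one of A/C/G/T")
  flag(!df$other_allele %in% c("A", "C", "G", "T"), "other_allele",
       "must be one of A/C/G/T")
  flag(df$effect_allele == df$other_allele, "effect_allele",
       "must differ from other_allele")
  flag(is.na(df$beta) | !is.finite(df$beta), "beta", "must be finite")
  flag(is.na(df$pos), "pos", "must be an integer position")
  if (length(problems) > 0) {
    stop("validation error: ", paste(problems, collapse = "; "), call. = FALSE)
  }
  if (anyDuplicated(df$variant_id)) {
    dup <- df$variant_id[duplicated(df$variant_id)][1]
    stop("validation error: duplicated variant_id '", dup, "'", call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Construct a summary-statistics table
#'
#' @param trait_name Trait label.
#' @param trait_type `"binary"` (betas are log-odds) or `"quantitative"`.
#' @param data Data frame with the canonical columns (`variant_id`, `chrom`,
#'   `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`,
#'   `n`); `eaf` and `n` optional.
#' @return Object of class `summary_table`.
#' @export
summary_table <- function(trait_name, trait_type = c("binary", "quantitative"),
                          data) {
  trait_type <- match.arg(trait_type)
  structure(list(trait_name = as.character(trait_name),
                 trait_type = trait_type,
                 data = validate_variant_rows(data)),
            class = "summary_table")
}

#' @export
print.summary_table <- function(x, ...) {
  cat(sprintf("GWAS summary table: %s (%s), %d variants\n",
              x$trait_name, x$trait_type, nrow(x$data)))
  print(utils::head(x$data, 6))
  invisible(x)
}

#' Read a GWAS summary-statistics TSV
#'
#' @param path File path.
#' @param trait_name Trait label; defaults to the file stem.
#' @param trait_type `"binary"` or `"quantitative"`.
#' @param column_map Named character vector mapping internal fields to file
#'   headers; see [default_column_map()].
#' @return A [summary_table()].
#' @export
read_summary_table <- function(path, trait_name = NULL,
                               trait_type = c("binary", "quantitative"),
                               column_map = default_column_map()) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  required <- setdiff(CANONICAL_COLUMNS, c("eaf", "n"))
  for (field in required) {
    header <- column_map[[field]] %||% field
    if (!header %in% names(raw)) {
      stop("configuration error: column '", header, "' (field '", field,
           "') not found in ", path, call. = FALSE)
    }
  }
  df <- data.frame(row.names = seq_len(nrow(raw)))
  for (field in CANONICAL_COLUMNS) {
    header <- column_map[[field]] %||% field
    if (header %in% names(raw)) df[[field]] <- raw[[header]]
  }
  summary_table(trait_name %||% sub("\\.[^.]*$", "", basename(path)),
                trait_type, df)
}

#' Write a summary table to TSV
#'
#' Inverse of [read_summary_table()] under the default column map.
#'
#' @param table A [summary_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(table, path) {
  stopifnot(inherits(table, "summary_table"))
  out <- table$data
  names(out) <- unname(default_column_map()[names(out)])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Construct a pairwise LD table
#'
#' Holds pairwise r-squared values. Lookup is symmetric, a variant with
#' itself is 1, unlisted pairs are 0.
#'
#' @param pairs Data frame with columns `id1`, `id2`, `r2`.
#' @return Object of class `ld_table`.
#' @export
ld_table <- function(pairs = data.frame(id1 = character(0),
                                        id2 = character(0),
                                        r2 = numeric(0))) {
  stopifnot(all(c("id1", "id2", "r2") %in% names(pairs)))
  pairs$id1 <- as.character(pairs$id1)
  pairs$id2 <- as.character(pairs$id2)
  pairs$r2 <- as.numeric(pairs$r2)
  if (any(is.na(pairs$r2))) {
    stop("validation error: non-numeric r2 in LD table", call. = FALSE)
  }
  if (any(pairs$r2 < 0 | pairs$r2 > 1)) {
    stop("validation error: r2 outside [0, 1] in LD table", call. = FALSE)
  }
  index <- stats::setNames(c(pairs$r2, pairs$r2),
                           c(paste(pairs$id1, pairs$id2, sep = "\r"),
                             paste(pairs$id2, pairs$id1, sep = "\r")))
  structure(list(pairs = pairs, index = index), class = "ld_table")
}

#' Symmetric LD lookup
#'
#' @param ld An [ld_table()].
#' @param id1,id2 Variant identifiers (`id2` may be a vector).
#' @return r-squared values; 1 on the diagonal, 0 for unlisted pairs.
#' @export
ld_lookup <- function(ld, id1, id2) {
  stopifnot(inherits(ld, "ld_table"))
  val <- unname(ld$index[paste(id1, id2, sep = "\r")])
  val[is.na(val)] <- 0
  val[id1 == id2] <- 1
  val
}

#' Read a long-format LD table (id1 TAB id2 TAB r2)
#'
#' @param path File path.
#' @return An [ld_table()].
#' @export
read_ld_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 3) stop("configuration error: LD table needs 3 columns",
                          call. = FALSE)
  names(raw)[1:3] <- c("id1", "id2", "r2")
  suppressWarnings(r2num <- as.numeric(raw$r2))
  if (any(is.na(r2num) & !is.na(raw$r2))) {
    stop("validation error: non-numeric r2 in ", path, call. = FALSE)
  }
  raw$r2 <- r2num
  ld_table(raw[c("id1", "id2", "r2")])
}

#' Write a pairwise LD table
#' @param ld An [ld_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ld_table <- function(ld, path) {
  stopifnot(inherits(ld, "ld_table"))
  utils::write.table(ld$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a confounder-association table
#'
#' Three tab-separated columns: `variant_id`, `trait`, `pval`. This is the
#' file-based replacement for an interactive variant-trait catalogue lookup;
#' it lists, per instrument, known associations with potential confounders.
#'
#' @param path File path.
#' @return Data frame with columns `variant_id`, `trait`, `pval`.
#' @export
read_confounder_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 3) stop("configuration error: confounder table needs 3 columns",
                          call. = FALSE)
  names(raw)[1:3] <- c("variant_id", "trait", "pval")
  raw$pval <- as.numeric(raw$pval)
  if (any(is.na(raw$pval) | raw$pval <= 0 | raw$pval > 1)) {
    stop("validation error: confounder pval outside (0, 1]", call. = FALSE)
  }
  raw[c("variant_id", "trait", "pval")]
}

RESULT_COLUMNS <- c("exposure", "outcome", "method", "nsnp", "beta", "se",
                    "ci_low", "ci_high", "pval", "or", "or_ci_low",
                    "or_ci_high")

#' Assemble a results row from an estimate
#'
#' @param est An [mr_estimate] object.
#' @param exposure,outcome Trait labels.
#' @param binary_outcome Report odds ratios? (`FALSE` leaves the OR columns
#'   `NA`, the convention for quantitative outcomes.)
#' @return One-row data frame with the fixed results-table columns.
#' @export
results_row <- function(est, exposure, outcome, binary_outcome = TRUE) {
  data.frame(exposure = exposure, outcome = outcome, method = est$method,
             nsnp = est$n_snp, beta = est$beta, se = est$se,
             ci_low = est$ci_low, ci_high = est$ci_high, pval = est$pval,
             or = if (binary_outcome) est$or else NA_real_,
             or_ci_low = if (binary_outcome) est$or_ci_low else NA_real_,
             or_ci_high = if (binary_outcome) est$or_ci_high else NA_real_,
             stringsAsFactors = FALSE)
}

#' Write a causal-estimate results table
#'
#' Fixed column order (`exposure`, `outcome`, `method`, `nsnp`, `beta`, `se`,
#' `ci_low`, `ci_high`, `pval`, `or`, `or_ci_low`, `or_ci_high`), numbers at
#' 6 significant digits. Odds-ratio columns are `NA` for quantitative
#' outcomes. An empty input writes a header-only file.
#'
#' @param rows Data frame of results rows (see [results_row()]), or an empty
#'   data frame / `NULL`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(rows, path) {
  if (is.null(rows) || nrow(rows) == 0) {
    rows <- stats::setNames(
      data.frame(matrix(character(0), nrow = 0, ncol = length(RESULT_COLUMNS))),
      RESULT_COLUMNS)
  }
  missing_cols <- setdiff(RESULT_COLUMNS, names(rows))
  if (length(missing_cols) > 0) {
    stop("configuration error: results rows missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- rows[RESULT_COLUMNS]
  for (col in c("beta", "se", "ci_low", "ci_high", "pval", "or",
                "or_ci_low", "or_ci_high")) {
    if (nrow(out) > 0) out[[col]] <- fmt6(as.numeric(out[[col]]))
  }
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("I/O error: cannot write ", path, call. = FALSE)
  })
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read back a results table written by [write_results_table()]
#' @param path File path.
#' @return Data frame with the fixed results columns.
#' @export
read_results_table <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
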