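# Match significance: residue-abundance product theta, the expectation
# function EF of random structural matches, and the EVD p-value.

#' Background amino-acid abundance table
#'
#' Loads a background frequency table (one row per amino acid, columns `aa`
#' and `freq`, tab-separated). The default table shipped with the package is
#' the Swiss-Prot amino-acid composition, normalized to sum to 1. The product
#' of the frequencies of a match's residue types (theta) feeds the
#' expectation function: matches made of abundant residue types are easier
#' to hit at random and therefore less significant.
#'
#' @param path TSV path; default: the shipped Swiss-Prot table.
#' @return an `abundance_table`: named numeric vector of 20 frequencies
#'   summing to 1, with attribute `source_id`.
#' @export
load_abundance <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "swissprot_abundance.tsv",
                        package = "sitematch")
    src <- "swissprot"
  } else {
    src <- basename(path)
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop(sitematch_error("sitematch_io_error",
                         sprintf("abundance table not found: %s", path)))
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("aa", "freq") %in% names(df))) {
    stop(sitematch_error("sitematch_format_error",
                         "abundance table needs columns 'aa' and 'freq'"))
  }
  freq <- stats::setNames(as.numeric(df$freq), aa_to1(df$aa))
  miss <- setdiff(aa_one_letter(), names(freq))
  if (length(miss)) {
    stop(sitematch_error("sitematch_format_error",
      sprintf("abundance table missing type(s): %s",
              paste(miss, collapse = ", "))))
  }
  if (abs(sum(freq) - 1) > 1e-6) {
    stop(sitematch_error("sitematch_format_error",
      sprintf("abundance frequencies sum to %.8f, not 1", sum(freq))))
  }
  structure(freq[aa_one_letter()], source_id = src,
            class = c("abundance_table", "numeric"))
}

#' Product of background abundances of a residue-type list
#'
#' @param types character vector of one-letter residue types.
#' @param table an `abundance_table` from [load_abundance()].
#' @return theta, the product of the frequencies (in (0, 1]; strictly
#'   decreasing as residues are appended).
#' @export
abundance_product <- function(types, table) {
  types <- aa_to1(types)
  prod(unname(table[types]))
}

#' Constants of the expectation function
#'
#' The expectation function
#' `EF(r) = theta * exp(a) * r^(b * (n - 1))`
#' estimates the number of random structural matches of `n` residues in a
#' background of non-catalytic structures with superposition RMSD at most
#' `r`, for a match whose residue types have abundance product `theta`. The
#' power-law exponent reflects the shape degrees of freedom of the matched
#' point set: n residues contribute 2n points, i.e. 6n - 6 internal
#' coordinates after removing rigid motion, so the configuration volume at
#' RMSD <= r scales as `r^(6(n-1))`; `b = 6` is therefore the geometric
#' default, and `exp(a)` is a scale constant calibrated against a decoy
#' background (the shipped value was fitted on this package's synthetic
#' decoy model; see the methods vignette). Constants are data, not code:
#' they live in a YAML config and can be replaced for a different
#' background. `b > 0` is required so that EF is strictly increasing in
#' RMSD; this is validated at load.
#'
#' @param path YAML path with numeric fields `a` and `b`; default: the
#'   shipped config.
#' @return an `evd_params` list with elements `a` and `b`.
#' @export
load_evd_params <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "evd_params.yaml", package = "sitematch")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop(sitematch_error("sitematch_io_error",
                         sprintf("EVD config not found: %s", path)))
  }
  p <- yaml::read_yaml(path)
  if (!is.numeric(p$a) || !is.numeric(p$b) || !is.finite(p$a) ||
      !is.finite(p$b) || p$b <= 0) {
    stop(sitematch_error("sitematch_format_error",
      "invalid EVD constants: need finite numeric a and b with b > 0 (EF must increase with RMSD)"))
  }
  structure(list(a = as.numeric(p$a), b = as.numeric(p$b)),
            class = "evd_params")
}

#' Significance of a structural match
#'
#' Converts a match's superposition RMSD into a p-value through an
#' extreme-value model: `EF(r)` estimates the expected number of random
#' matches scoring as well or better, and the probability of at least one
#' such random match is `p = 1 - exp(-EF)`. The p-value increases with the
#' RMSD and with the abundance product theta, so loose matches of common
#' residue types are penalized; a geometrically exact match (RMSD 0) has
#' p = 0. Effective theta may be supplied directly (e.g. summed over
#' substitution-matrix-allowed types per slot) instead of a type list.
#'
#' @param rmsd superposition RMSD of the match, Angstrom (>= 0).
#' @param types one-letter residue types of the match (used with `table`,
#'   and defining the match size `n`), or NULL when `theta` is given.
#' @param table an `abundance_table`.
#' @param params an `evd_params` object.
#' @param theta optional abundance product overriding `types`/`table`.
#' @param n match size (number of residues); defaults to `length(types)`.
#' @return a `significance_score` list: `rmsd`, `ef` (expected random match
#'   count), `p_value` (clamped to `[0, 1]`).
#' @export
match_pvalue <- function(rmsd, types = NULL, table = NULL,
                         params = load_evd_params(), theta = NULL,
                         n = length(types)) {
  if (rmsd < 0) {
    stop(sitematch_error("sitematch_value_error", "rmsd must be >= 0"))
  }
  if (is.null(theta)) {
    theta <- abundance_product(types, table)
  }
  if (is.null(n) || length(n) != 1L || n < 2L) {
    stop(sitematch_error("sitematch_value_error",
                         "match size n must be >= 2"))
  }
  ef <- theta * exp(params$a) * rmsd^(params$b * (n - 1L))
  p <- -expm1(-ef)
  p <- min(max(p, 0), 1)
  structure(list(rmsd = rmsd, ef = ef, p_value = p),
            class = "significance_score")
}

#' Format a p-value for reports
#'
#' Values below machine epsilon are printed as `"<2.3e-16"` (they are
#' indistinguishable from 0 at double precision).
#'
#' @param p numeric p-value(s).
#' @return character vector.
#' @export
format_pvalue <- function(p) {
  ifelse(p < .Machine$double.eps & p >= 0,
         ifelse(p == 0, "0.0", "<2.3e-16"),
         formatC(p, format = "e", digits = 3))
}
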