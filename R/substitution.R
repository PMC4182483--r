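# Substitution matrices for the substitution-matrix (SM) matching mode.

#' Substitution matrices
#'
#' A substitution matrix here is a symmetric, reflexive 0/1 relation over
#' the 20 amino-acid types: `S[i, j] = 1` means a residue of type `i` may
#' stand in for a template residue of type `j` during candidate filtering.
#' The identity matrix (no interchanges) is the default matching behaviour;
#' the SM mode exists to reproduce and study the substitution-matrix
#' approach to point mutations, whose combinatorial cost the subtemplate
#' expansion avoids.
#'
#' `substitution_matrix()` builds one from a list of allowed unordered type
#' pairs; `read_substitution_matrix()` reads a 20x20 0/1 TSV grid with
#' amino-acid header row and column.
#'
#' @param pairs list of length-2 character vectors of one-letter types,
#'   e.g. `list(c("H", "E"), c("H", "K"))`.
#' @return a 20x20 0/1 matrix with dimnames the one-letter codes.
#' @export
substitution_matrix <- function(pairs = list()) {
  aa <- aa_one_letter()
  m <- diag(1L, 20L)
  dimnames(m) <- list(aa, aa)
  for (p in pairs) {
    p <- aa_to1(p)
    stopifnot(length(p) == 2L)
    m[p[1], p[2]] <- m[p[2], p[1]] <- 1L
  }
  m
}

#' @rdname substitution_matrix
#' @param path TSV file path.
#' @export
read_substitution_matrix <- function(path) {
  if (!file.exists(path)) {
    stop(sitematch_error("sitematch_io_error",
                         sprintf("substitution matrix not found: %s", path)))
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  m <- as.matrix(df)
  validate_substitution_matrix(m)
}

validate_substitution_matrix <- function(m) {
  aa <- aa_one_letter()
  if (!all(dim(m) == c(20L, 20L)) || !setequal(rownames(m), aa) ||
      !setequal(colnames(m), aa)) {
    stop(sitematch_error("sitematch_format_error",
      "substitution matrix must be 20x20 with amino-acid row/column names"))
  }
  m <- m[aa, aa]
  storage.mode(m) <- "integer"
  if (!all(m %in% c(0L, 1L))) {
    stop(sitematch_error("sitematch_format_error",
                         "substitution matrix entries must be 0 or 1"))
  }
  if (!isTRUE(all.equal(m, t(m), check.attributes = FALSE))) {
    stop(sitematch_error("sitematch_format_error",
                         "substitution matrix must be symmetric"))
  }
  if (!all(diag(m) == 1L)) {
    stop(sitematch_error("sitematch_format_error",
                         "substitution matrix diagonal must be 1"))
  }
  m
}

# Types allowed to fill a slot of template type `to` under matrix `sm`
# (NULL sm = identity).
allowed_types <- function(to, sm = NULL) {
  if (is.null(sm)) return(to)
  names(which(sm[, to] == 1L))
}
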