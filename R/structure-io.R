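# Reading PDB structures and reducing residues to the two-point
# (C-alpha, furthest side-chain atom) representation.

#' Parse a PDB-format text into a structure model
#'
#' Reads ATOM records (first MODEL only) into a `structure_model`: an ordered
#' table of heavy atoms of the 20 standard amino acids. HETATM records,
#' waters, hydrogens and non-standard residues are excluded. When alternate
#' locations are present, the highest-occupancy altloc of each atom is kept
#' (ties broken by file order). Parsing is delegated to [bio3d::read.pdb()];
#' filtering and altloc resolution are applied on top.
#'
#' @param text PDB-format text: a single string or a character vector of
#'   lines, or the path of an existing file.
#' @param structure_id identifier recorded in the model (defaults to the file
#'   base name, or `"structure"` for literal text).
#' @return an object of class `structure_model`: a list with `structure_id`
#'   and `atoms` (data frame with chain, resno, icode, resid, elety, o,
#'   x, y, z; residue order follows file order).
#' @export
parse_pdb <- function(text, structure_id = NULL) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    path <- text
    if (is.null(structure_id)) {
      structure_id <- sub("\\.(pdb|ent)$", "", basename(path))
    }
  } else {
    if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1]]
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(text, path)
    if (is.null(structure_id)) structure_id <- "structure"
  }
  raw <- readLines(path, warn = FALSE)
  if (!any(startsWith(raw, "ATOM"))) {
    stop(sitematch_error("sitematch_parse_error",
      sprintf("no ATOM records in input '%s'", structure_id)))
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) {
      stop(sitematch_error("sitematch_parse_error",
        sprintf("PDB parse failure for '%s': %s", structure_id,
                conditionMessage(e))))
    })
  at <- pdb$atom
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  bad <- which(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))
  if (length(bad)) {
    stop(sitematch_error("sitematch_parse_error",
      sprintf("malformed coordinate field at atom serial %s (line with elety %s, residue %s %s%s)",
              at$eleno[bad[1]], at$elety[bad[1]], at$resid[bad[1]],
              at$chain[bad[1]], at$resno[bad[1]])))
  }
  keep <- at$type == "ATOM" &
    at$resid %in% names(aa_codes()) &
    !is_hydrogen(at$elety, at$elesy)
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0L) {
    stop(sitematch_error("sitematch_parse_error",
      sprintf("no standard amino-acid heavy atoms in input '%s'",
              structure_id)))
  }
  # altloc: within each (chain, resno, icode, elety) keep highest occupancy,
  # ties -> first in file order
  at$o[is.na(at$o)] <- 1
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(factor(key, levels = unique(key)), -at$o)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety,
                             sep = "\r")), , drop = FALSE]
  # restore file order
  at <- at[order(at$eleno), , drop = FALSE]
  atoms <- data.frame(chain = as.character(at$chain),
                      resno = as.integer(at$resno),
                      icode = as.character(at$insert),
                      resid = as.character(at$resid),
                      elety = as.character(at$elety),
                      o = as.numeric(at$o),
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- "A"
  new_structure_model(structure_id, atoms)
}

is_hydrogen <- function(elety, elesy) {
  sym <- toupper(ifelse(is.na(elesy), "", elesy))
  byname <- grepl("^[0-9]*[HD]", toupper(elety))
  ifelse(sym != "", sym %in% c("H", "D"), byname)
}

new_structure_model <- function(structure_id, atoms) {
  stopifnot(nrow(atoms) > 0L)
  structure(list(structure_id = structure_id, atoms = atoms),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  rk <- residue_keys(x)
  cat(sprintf("<structure_model> %s: %d residues, %d atoms\n",
              x$structure_id, length(unique(rk)), nrow(x$atoms)))
  invisible(x)
}

residue_keys <- function(s) {
  paste(s$atoms$chain, s$atoms$resno, s$atoms$icode, sep = ":")
}

#' Write a structure model back to PDB format
#'
#' Coordinates are written at the PDB field precision (3 decimals) via
#' [bio3d::write.pdb()].
#'
#' @param s a `structure_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  at <- s$atoms
  xyz <- as.numeric(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(pdb = NULL, file = path, xyz = xyz,
                   resno = at$resno, resid = at$resid, chain = at$chain,
                   insert = at$icode, elety = at$elety, o = at$o,
                   b = rep(0, nrow(at)))
  invisible(path)
}

#' Reduce a structure to residue points (C-alpha + furthest side-chain atom)
#'
#' Each residue is reduced to its C-alpha coordinate and the coordinate of
#' its furthest side-chain heavy atom (`fa`): the side-chain heavy atom
#' (excluding N, CA, C, O, OXT) maximizing Euclidean distance from the
#' C-alpha, with distance ties broken by atom-name order. Glycine, which has
#' no side-chain heavy atom, takes `fa` equal to its C-alpha. A residue
#' whose side-chain atoms are all absent from the file has `fa` marked
#' absent (`fa_present = FALSE`); such residues are excluded from template
#' matching, which is how missing side-chain data degrades prediction.
#' Residues lacking a C-alpha are dropped with a warning.
#'
#' @param s a `structure_model`.
#' @return a `residue_points` data frame with one row per residue: chain,
#'   resno, icode, aa (one-letter), ca_x/y/z, fa_x/y/z, fa_atom, fa_present.
#' @export
derive_residue_points <- function(s) {
  at <- s$atoms
  key <- paste(at$chain, at$resno, at$icode, sep = ":")
  idx <- split(seq_len(nrow(at)), factor(key, levels = unique(key)))
  rows <- lapply(idx, function(i) {
    res <- at[i, , drop = FALSE]
    ca <- which(res$elety == "CA")
    if (length(ca) == 0L) return(NULL)
    ca <- ca[1L]
    cav <- c(res$x[ca], res$y[ca], res$z[ca])
    side <- which(!(res$elety %in% BACKBONE_ATOMS))
    if (res$resid[1L] == "GLY") {
      fa <- cav; fa_atom <- "CA"; fa_present <- TRUE
    } else if (length(side) == 0L) {
      fa <- c(NA_real_, NA_real_, NA_real_); fa_atom <- NA_character_
      fa_present <- FALSE
    } else {
      d <- sqrt((res$x[side] - cav[1])^2 + (res$y[side] - cav[2])^2 +
                (res$z[side] - cav[3])^2)
      best <- side[d >= max(d) - 1e-12]
      best <- best[order(res$elety[best])][1L]
      fa <- c(res$x[best], res$y[best], res$z[best])
      fa_atom <- res$elety[best]; fa_present <- TRUE
    }
    data.frame(chain = res$chain[1L], resno = res$resno[1L],
               icode = res$icode[1L], aa = unname(aa_codes()[res$resid[1L]]),
               ca_x = cav[1], ca_y = cav[2], ca_z = cav[3],
               fa_x = fa[1], fa_y = fa[2], fa_z = fa[3],
               fa_atom = fa_atom, fa_present = fa_present,
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0L) {
    warning(sprintf("%d residue(s) without C-alpha dropped from %s",
                    dropped, s$structure_id))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  class(out) <- c("residue_points", "data.frame")
  out
}

point_ids <- function(points) {
  paste(points$chain, points$resno, points$icode, sep = ":")
}

ca_matrix <- function(points) {
  as.matrix(points[, c("ca_x", "ca_y", "ca_z")])
}

fa_matrix <- function(points) {
  as.matrix(points[, c("fa_x", "fa_y", "fa_z")])
}

#' In-silico alanine substitution of one residue
#'
#' Returns a copy of the structure in which the target residue is renamed
#' ALA and its side chain truncated to the C-beta atom (the alanine-scanning
#' operation used to build mutated test sets). Glycine and alanine targets,
#' and residues without a C-beta, are rejected.
#'
#' @param s a `structure_model`.
#' @param chain,resno,icode identity of the target residue.
#' @return a mutated `structure_model` copy.
#' @export
mutate_to_alanine <- function(s, chain, resno, icode = "") {
  at <- s$atoms
  hit <- at$chain == chain & at$resno == resno & at$icode == icode
  if (!any(hit)) {
    stop(sitematch_error("sitematch_lookup_error",
      sprintf("residue %s:%s:%s not found in %s", chain, resno, icode,
              s$structure_id)))
  }
  resid <- unique(at$resid[hit])
  if (resid[1L] %in% c("GLY", "ALA")) {
    stop(sitematch_error("sitematch_unsupported_mutation",
      sprintf("cannot alanine-substitute %s at %s:%s:%s", resid[1L],
              chain, resno, icode)))
  }
  if (!any(hit & at$elety == "CB")) {
    stop(sitematch_error("sitematch_unsupported_mutation",
      sprintf("residue %s:%s:%s has no CB atom", chain, resno, icode)))
  }
  drop <- hit & !(at$elety %in% c(BACKBONE_ATOMS, "CB"))
  at <- at[!drop, , drop = FALSE]
  hit <- at$chain == chain & at$resno == resno & at$icode == icode
  at$resid[hit] <- "ALA"
  new_structure_model(s$structure_id, at)
}

#' Read a catalytic-site annotation table
#'
#' Tab-separated file with one row per catalytic residue. Mandatory columns:
#' `structure_id`, `chain`, `seq_number`, `icode`, `res_type` (one- or
#' three-letter). Optional columns `family_id` and `ec_number` attach family
#' membership used for master-template selection (family defaults to the
#' structure id).
#'
#' @param path TSV file path.
#' @return data frame of annotation rows (res_type normalized to one-letter).
#' @export
read_site_annotations <- function(path) {
  if (!file.exists(path)) {
    stop(sitematch_error("sitematch_io_error",
                         sprintf("annotation file not found: %s", path)))
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  need <- c("structure_id", "chain", "seq_number", "icode", "res_type")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sitematch_error("sitematch_format_error",
      sprintf("annotation TSV missing column(s): %s",
              paste(miss, collapse = ", "))))
  }
  df$seq_number <- as.integer(df$seq_number)
  df$icode[is.na(df$icode)] <- ""
  df$res_type <- aa_to1(df$res_type)
  if (is.null(df$family_id)) df$family_id <- df$structure_id
  if (is.null(df$ec_number)) df$ec_number <- ""
  df
}
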