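# Active-site templates: construction from annotated structures, family
# master-template selection, and the n-1 subtemplate library expansion.

new_template <- function(template_id, points, source_structure = "",
                         ec_number = "", family_id = source_structure,
                         parent_template = NULL, excluded_residue = NULL) {
  stopifnot(inherits(points, "data.frame"))
  if (nrow(points) < 2L) {
    stop(sitematch_error("sitematch_value_error",
      sprintf("template '%s' needs at least 2 residues", template_id)))
  }
  if (!all(points$fa_present)) {
    stop(sitematch_error("sitematch_incomplete_site",
      sprintf("template '%s' has residue(s) with fa absent", template_id)))
  }
  ord <- order(points$chain, points$resno, points$icode)
  points <- points[ord, , drop = FALSE]
  rownames(points) <- NULL
  class(points) <- c("residue_points", "data.frame")
  structure(list(template_id = template_id,
                 source_structure = source_structure,
                 ec_number = ec_number,
                 family_id = family_id,
                 points = points,
                 parent_template = parent_template,
                 excluded_residue = excluded_residue),
            class = "site_template")
}

#' @export
print.site_template <- function(x, ...) {
  cat(sprintf("<site_template> %s (%s, family %s): %d residues [%s]%s\n",
              x$template_id, x$source_structure, x$family_id,
              nrow(x$points), paste(x$points$aa, collapse = ","),
              if (!is.null(x$parent_template))
                sprintf(" subtemplate of %s", x$parent_template) else ""))
  invisible(x)
}

template_size <- function(t) nrow(t$points)

template_signature <- function(t) {
  paste(nrow(t$points), paste(t$points$aa, collapse = ""), sep = ":")
}

is_subtemplate <- function(t) !is.null(t$parent_template)

#' Build a template from an annotated structure
#'
#' A template is the ordered set of C-alpha and furthest-side-chain-atom
#' coordinates of all catalytic residues of one enzyme. Residues are ordered
#' by (chain, seq_number, insertion code); every annotated residue must be
#' present in the structure with both points available, and its type must
#' agree with the annotation.
#'
#' @param s a `structure_model`.
#' @param site_rows annotation rows for this structure (see
#'   [read_site_annotations()]): columns chain, seq_number, icode, res_type,
#'   and optionally family_id, ec_number.
#' @param template_id identifier (defaults to the structure id).
#' @return a `site_template`.
#' @export
build_template <- function(s, site_rows, template_id = s$structure_id) {
  points <- derive_residue_points(s)
  ids <- point_ids(points)
  want <- paste(site_rows$chain, site_rows$seq_number, site_rows$icode,
                sep = ":")
  sel <- match(want, ids)
  if (anyNA(sel)) {
    stop(sitematch_error("sitematch_incomplete_site",
      sprintf("annotated residue(s) absent from %s: %s", s$structure_id,
              paste(want[is.na(sel)], collapse = ", "))))
  }
  sub <- points[sel, , drop = FALSE]
  if (!all(sub$fa_present)) {
    stop(sitematch_error("sitematch_incomplete_site",
      sprintf("annotated residue(s) in %s lack a side-chain (fa) atom: %s",
              s$structure_id,
              paste(want[!sub$fa_present], collapse = ", "))))
  }
  if (!all(sub$aa == site_rows$res_type)) {
    bad <- which(sub$aa != site_rows$res_type)
    stop(sitematch_error("sitematch_annotation_conflict",
      sprintf("residue type mismatch in %s at %s: structure %s vs annotation %s",
              s$structure_id, paste(want[bad], collapse = ","),
              paste(sub$aa[bad], collapse = ","),
              paste(site_rows$res_type[bad], collapse = ","))))
  }
  family <- if (!is.null(site_rows$family_id)) site_rows$family_id[1L] else s$structure_id
  ec <- if (!is.null(site_rows$ec_number)) site_rows$ec_number[1L] else ""
  new_template(template_id, sub, source_structure = s$structure_id,
               ec_number = ec, family_id = family)
}

template_coords <- function(t) {
  rbind(ca_matrix(t$points), fa_matrix(t$points))
}

#' RMSD between two comparable templates
#'
#' Least-squares rigid-superposition RMSD over the 2n points of two
#' templates (all C-alpha, then all fa, positional correspondence). The
#' templates must have equal size and identical residue-type sequences.
#'
#' @param a,b `site_template` objects.
#' @return RMSD in Angstrom.
#' @export
template_rmsd <- function(a, b) {
  if (template_signature(a) != template_signature(b)) {
    stop(sitematch_error("sitematch_incomparable_templates",
      sprintf("templates %s and %s are not comparable (size/type sequence)",
              a$template_id, b$template_id)))
  }
  superpose_rmsd(template_coords(a), template_coords(b))
}

#' Select the master template of a family
#'
#' The master template of a family is the member minimizing the mean RMSD to
#' all members of the family (the i = j zero term included; ties broken by
#' lexicographically smallest template id). Members whose size or residue
#' types disagree with the family's modal signature are excluded with a
#' warning, mirroring the practice of dropping families with inconsistent
#' residue counts.
#'
#' @param templates a list of `site_template` objects (one family).
#' @return the master `site_template`.
#' @export
select_master_template <- function(templates) {
  if (length(templates) == 0L) {
    stop(sitematch_error("sitematch_value_error", "empty family"))
  }
  sigs <- vapply(templates, template_signature, character(1))
  tab <- table(sigs)
  modal <- names(tab)[tab == max(tab)]
  modal <- sort(modal)[1L]
  keep <- sigs == modal
  if (!all(keep)) {
    warning(sprintf("excluding %d incomparable template(s): %s",
                    sum(!keep),
                    paste(vapply(templates[!keep], `[[`, "", "template_id"),
                          collapse = ", ")))
    templates <- templates[keep]
  }
  n <- length(templates)
  if (n == 1L) return(templates[[1L]])
  rm <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      rm[i, j] <- rm[j, i] <- template_rmsd(templates[[i]], templates[[j]])
    }
  }
  avg <- rowMeans(rm)
  ids <- vapply(templates, `[[`, "", "template_id")
  best <- which(avg <= min(avg) + 1e-12)
  templates[[best[order(ids[best])][1L]]]
}

#' Create a template library
#'
#' @param templates list of `site_template` objects with unique ids; every
#'   subtemplate's parent must be present.
#' @param metadata list of creation parameters kept with the library.
#' @return a `template_library`.
#' @export
template_library <- function(templates, metadata = list()) {
  ids <- vapply(templates, `[[`, "", "template_id")
  if (anyDuplicated(ids)) {
    stop(sitematch_error("sitematch_value_error",
      sprintf("duplicate template id(s): %s",
              paste(unique(ids[duplicated(ids)]), collapse = ", "))))
  }
  parents <- unlist(lapply(templates, `[[`, "parent_template"))
  orphan <- setdiff(parents, ids)
  if (length(orphan)) {
    stop(sitematch_error("sitematch_value_error",
      sprintf("subtemplate parent(s) missing from library: %s",
              paste(orphan, collapse = ", "))))
  }
  names(templates) <- ids
  structure(list(templates = templates, metadata = metadata),
            class = "template_library")
}

#' @export
print.template_library <- function(x, ...) {
  nsub <- sum(vapply(x$templates, is_subtemplate, logical(1)))
  cat(sprintf("<template_library> %d templates (%d subtemplates)\n",
              length(x$templates), nsub))
  invisible(x)
}

#' Expand a library with n-k subtemplates
#'
#' From each template of n residues, generates the subtemplates obtained by
#' removing k residues and adds them to the library (originals retained).
#' With the default k = 1 each template contributes exactly n subtemplates,
#' each omitting one residue, so the library grows by at most N_T x n_max
#' entries; for k > 1 the count grows combinatorially (exponentially as k
#' approaches n/2). Single point mutations being the biologically dominant
#' case, k = 1 is the default. Templates too small to expand (n - k below
#' `min_size`) are passed through unchanged.
#'
#' @param lib a `template_library`.
#' @param k number of residues removed per subtemplate (default 1).
#' @param min_size minimum allowed subtemplate size (default 2; three-residue
#'   sites then still yield usable two-residue subtemplates after a single
#'   mutation).
#' @return the extended `template_library`.
#' @export
expand_library <- function(lib, k = 1L, min_size = 2L) {
  stopifnot(k >= 1L, min_size >= 2L)
  subs <- list()
  for (t in lib$templates) {
    n <- template_size(t)
    if (n - k < min_size) next
    for (drop in as.data.frame(utils::combn(n, k))) {
      pts <- t$points[-drop, , drop = FALSE]
      excl <- point_ids(t$points[drop, , drop = FALSE])
      id <- paste0(t$template_id, "~minus-", paste(excl, collapse = "+"))
      subs[[length(subs) + 1L]] <-
        new_template(id, pts, source_structure = t$source_structure,
                     ec_number = t$ec_number, family_id = t$family_id,
                     parent_template = t$template_id,
                     excluded_residue = paste(excl, collapse = "+"))
    }
  }
  meta <- lib$metadata
  meta$k <- k
  meta$min_size <- min_size
  template_library(c(lib$templates, subs), metadata = meta)
}

LIBRARY_FORMAT <- "sitematch-template-library"
LIBRARY_VERSION <- 1L

template_to_json <- function(t) {
  res <- lapply(seq_len(nrow(t$points)), function(i) {
    p <- t$points[i, ]
    list(chain = p$chain, resno = p$resno, icode = p$icode, aa = p$aa,
         ca = c(p$ca_x, p$ca_y, p$ca_z),
         fa = c(p$fa_x, p$fa_y, p$fa_z),
         fa_atom = p$fa_atom)
  })
  jsonlite::toJSON(list(template_id = t$template_id,
                        source_structure = t$source_structure,
                        ec_number = t$ec_number,
                        family_id = t$family_id,
                        parent_template = t$parent_template,
                        excluded_residue = t$excluded_residue,
                        residues = res),
                   auto_unbox = TRUE, digits = NA, null = "null")
}

template_from_json <- function(line) {
  x <- jsonlite::fromJSON(line, simplifyVector = FALSE)
  need <- c("template_id", "residues")
  if (!all(need %in% names(x))) {
    stop(sitematch_error("sitematch_format_error",
                         "template record missing required fields"))
  }
  pts <- do.call(rbind, lapply(x$residues, function(r) {
    data.frame(chain = r$chain, resno = as.integer(r$resno),
               icode = r$icode, aa = r$aa,
               ca_x = r$ca[[1]], ca_y = r$ca[[2]], ca_z = r$ca[[3]],
               fa_x = r$fa[[1]], fa_y = r$fa[[2]], fa_z = r$fa[[3]],
               fa_atom = r$fa_atom, fa_present = TRUE,
               stringsAsFactors = FALSE)
  }))
  class(pts) <- c("residue_points", "data.frame")
  new_template(x$template_id, pts,
               source_structure = x$source_structure %||% "",
               ec_number = x$ec_number %||% "",
               family_id = x$family_id %||% "",
               parent_template = x$parent_template,
               excluded_residue = x$excluded_residue)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a template library (JSON-lines)
#'
#' One JSON header record (format name, version, template count, metadata)
#' followed by one template per line. The round trip is lossless, including
#' subtemplate lineage.
#'
#' @param lib a `template_library`.
#' @param path file path.
#' @return `write_library` returns `path` invisibly; `read_library` returns
#'   the `template_library`.
#' @export
write_library <- function(lib, path) {
  header <- jsonlite::toJSON(list(format = LIBRARY_FORMAT,
                                  version = LIBRARY_VERSION,
                                  n_templates = length(lib$templates),
                                  metadata = lib$metadata),
                             auto_unbox = TRUE, digits = NA)
  lines <- c(header,
             vapply(lib$templates, template_to_json, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  if (!file.exists(path)) {
    stop(sitematch_error("sitematch_io_error",
                         sprintf("library file not found: %s", path)))
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L) {
    stop(sitematch_error("sitematch_format_error", "empty library file"))
  }
  header <- tryCatch(jsonlite::fromJSON(lines[1L], simplifyVector = FALSE),
                     error = function(e) {
                       stop(sitematch_error("sitematch_format_error",
                         sprintf("bad library header: %s",
                                 conditionMessage(e))))
                     })
  if (!identical(header$format, LIBRARY_FORMAT)) {
    stop(sitematch_error("sitematch_format_error",
                         "not a template-library file"))
  }
  if (!identical(as.integer(header$version), LIBRARY_VERSION)) {
    stop(sitematch_error("sitematch_format_error",
      sprintf("unsupported library version %s", header$version)))
  }
  body <- lines[-1L]
  if (length(body) != header$n_templates) {
    stop(sitematch_error("sitematch_format_error",
      sprintf("library truncated: header promises %d templates, found %d",
              header$n_templates, length(body))))
  }
  templates <- lapply(body, function(l) {
    tryCatch(template_from_json(l), error = function(e) {
      stop(sitematch_error("sitematch_format_error",
        sprintf("bad template record: %s", conditionMessage(e))))
    })
  })
  template_library(templates,
                   metadata = lapply(header$metadata, identity))
}
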