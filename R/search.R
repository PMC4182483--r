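# Library-wide search with significance filtering and postprocessing.

#' Search configuration
#'
#' Bundles the tunable thresholds of a library search. The CMAD cutoff
#' defaults to 1.2 Angstrom, the standard setting for master-template
#' libraries; for extended (subtemplate) libraries a tighter cutoff of 0.4
#' is the recommended trade-off between random matches to the smaller
#' templates and lost mutated sites, and is kept as a separate default for
#' callers that switch on library type.
#'
#' @param cmad_cutoff CMAD acceptance threshold, Angstrom (default 1.2).
#' @param cmad_cutoff_extended recommended cutoff for extended libraries
#'   (default 0.4); informational unless the caller selects it.
#' @param p_threshold significance threshold (default 1e-4).
#' @param sm optional substitution matrix (default NULL: identity).
#' @param abundance an `abundance_table` (default: shipped Swiss-Prot).
#' @param evd an `evd_params` object (default: shipped constants).
#' @param k,min_size subtemplate expansion parameters carried for tools.
#' @return a `search_config` list.
#' @export
search_config <- function(cmad_cutoff = 1.2, cmad_cutoff_extended = 0.4,
                          p_threshold = 1e-4, sm = NULL,
                          abundance = NULL, evd = NULL,
                          k = 1L, min_size = 2L) {
  if (!is.numeric(cmad_cutoff) || cmad_cutoff <= 0 ||
      cmad_cutoff_extended <= 0) {
    stop(sitematch_error("sitematch_value_error",
                         "CMAD cutoffs must be > 0"))
  }
  if (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold >= 1) {
    stop(sitematch_error("sitematch_value_error",
                         "p_threshold must be in (0, 1)"))
  }
  if (!is.null(sm)) sm <- validate_substitution_matrix(sm)
  if (is.null(abundance)) abundance <- load_abundance()
  if (is.null(evd)) evd <- load_evd_params()
  structure(list(cmad_cutoff = cmad_cutoff,
                 cmad_cutoff_extended = cmad_cutoff_extended,
                 p_threshold = p_threshold, sm = sm,
                 abundance = abundance, evd = evd,
                 k = as.integer(k), min_size = as.integer(min_size)),
            class = "search_config")
}

# Effective abundance product of a template under a substitution matrix:
# per slot, the summed frequency of every type allowed to fill the slot.
# Reduces to the product of the template-type frequencies for identity SM.
effective_theta <- function(template, abundance, sm = NULL) {
  prod(vapply(template$points$aa, function(ty) {
    sum(abundance[allowed_types(ty, sm)])
  }, numeric(1)))
}

#' Search a query structure against a template library
#'
#' Runs [match_template()] for every library template, attaches the
#' extreme-value p-value of each match, keeps matches at or below the
#' significance threshold, removes subtemplate matches made redundant by
#' their parent ([postprocess_matches()]) and ranks the result by ascending
#' p-value, then ascending fa-CMAD, then template id.
#'
#' @param q a `structure_model` or `residue_points`.
#' @param lib a `template_library`.
#' @param cfg a [search_config()].
#' @return a ranked match data frame with columns template_id,
#'   parent_template, is_subtemplate, n, residues, res_aa, cmad_ca, cmad_fa,
#'   rmsd, theta, ef, p_value.
#' @export
site_search <- function(q, lib, cfg = search_config()) {
  if (!inherits(lib, "template_library") || length(lib$templates) == 0L) {
    stop(sitematch_error("sitematch_value_error", "empty template library"))
  }
  points <- if (inherits(q, "residue_points")) q else derive_residue_points(q)
  if (is.null(points) || nrow(points) == 0L) {
    stop(sitematch_error("sitematch_value_error",
                         "query structure has no residues"))
  }
  per_template <- lapply(lib$templates, function(t) {
    m <- match_template(points, t, cmad_cutoff = cfg$cmad_cutoff,
                        sm = cfg$sm)
    if (nrow(m) == 0L) return(NULL)
    theta <- effective_theta(t, cfg$abundance, cfg$sm)
    sig <- lapply(m$rmsd, match_pvalue, params = cfg$evd, theta = theta,
                  n = template_size(t))
    m$theta <- theta
    m$ef <- vapply(sig, `[[`, numeric(1), "ef")
    m$p_value <- vapply(sig, `[[`, numeric(1), "p_value")
    m
  })
  per_template <- per_template[!vapply(per_template, is.null, logical(1))]
  if (length(per_template) == 0L) {
    out <- empty_matches()
    out$theta <- numeric(0); out$ef <- numeric(0); out$p_value <- numeric(0)
    return(out)
  }
  all <- do.call(rbind, per_template)
  rownames(all) <- NULL
  all <- all[all$p_value <= cfg$p_threshold, , drop = FALSE]
  all <- postprocess_matches(all)
  all <- all[order(all$p_value, all$cmad_fa, all$template_id), , drop = FALSE]
  rownames(all) <- NULL
  all
}

#' Write matches as TSV
#'
#' @param matches a match data frame from [site_search()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_matches <- function(matches, path) {
  out <- matches
  if (nrow(out) > 0L) {
    out$p_value <- format_pvalue(out$p_value)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
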