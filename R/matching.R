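# Core search engine: candidate filtering, local-structure emulation,
# CMAD scoring with per-pair pruning, and the combinatorics of the
# substitution-matrix versus subtemplate approaches.

#' Filter query residues into per-slot candidate lists
#'
#' Slot j of a template accepts the query residues whose type equals the
#' template residue's type (or is interchangeable with it under a
#' substitution matrix). Residues whose fa atom is absent are excluded from
#' candidacy: a residue that cannot be represented by its two points cannot
#' take part in any local structure, which is exactly how a missing
#' side-chain atom in the query defeats full-template matching (subtemplates
#' omitting that residue then do the recovery).
#'
#' @param points a `residue_points` data frame (query).
#' @param template a `site_template`.
#' @param sm optional substitution matrix (see [substitution_matrix()]).
#' @return list of integer vectors (row indices into `points`), one per
#'   template slot, in structure order.
#' @export
filter_candidates <- function(points, template, sm = NULL) {
  lapply(template$points$aa, function(ty) {
    ok <- points$fa_present & points$aa %in% allowed_types(ty, sm)
    which(ok)
  })
}

# Depth-first enumeration of injective slot assignments, slot-major with
# candidates in the given order; `prune` is called as prune(i, j, ci, cj)
# for every already-fixed slot i when extending with candidate cj at slot j
# and must return TRUE to keep the branch.
assignments_dfs <- function(cands, n_items, prune = NULL) {
  n <- length(cands)
  out <- list()
  assign <- integer(n)
  used <- logical(n_items)
  rec <- function(j) {
    for (c in cands[[j]]) {
      if (used[c]) next
      if (!is.null(prune) && j > 1L) {
        ok <- TRUE
        for (i in seq_len(j - 1L)) {
          if (!prune(i, j, assign[i], c)) { ok <- FALSE; break }
        }
        if (!ok) next
      }
      assign[j] <<- c
      used[c] <<- TRUE
      if (j == n) out[[length(out) + 1L]] <<- assign else rec(j + 1L)
      used[c] <<- FALSE
    }
  }
  if (n > 0L && all(lengths(cands) > 0L)) rec(1L)
  if (length(out) == 0L) {
    matrix(integer(0), ncol = n)
  } else {
    do.call(rbind, out)
  }
}

#' Enumerate the local structures of a query against a template
#'
#' Every assignment of distinct query residues to template slots, given the
#' per-slot candidate lists from [filter_candidates()]. Order is
#' deterministic: slot-major, candidates in structure order.
#'
#' @param cands list of per-slot candidate index vectors.
#' @param points the query `residue_points` (defines the index space).
#' @return integer matrix, one row per local structure, one column per slot.
#' @export
enumerate_local_structures <- function(cands, points) {
  assignments_dfs(cands, nrow(points))
}

#' Combination counts for the substitution-matrix worked example
#'
#' Pure counting of candidate local structures (no geometry) under the
#' conventions of the substitution-matrix (SM) versus subtemplate
#' bookkeeping. The scenarios:
#' \describe{
#'   \item{`base`}{assignments of distinct query residues to slots under
#'     exact type equality.}
#'   \item{`single`}{one substitution `from` -> `to` is allowed: residues of
#'     type `from` also become candidates for every slot of type `to`.
#'     `counting = "total"` reports the whole scenario;
#'     `counting = "new"` reports only the combinations not already in the
#'     base scenario. Both conventions occur in the field's worked examples,
#'     so the choice is explicit rather than guessed.}
#'   \item{`simultaneous`}{residues of type `from` fill all the slots whose
#'     types are listed in `to` (one slot per listed type), with the
#'     assignment of the `from` residues to those slots counted as
#'     unordered; remaining slots are filled from their base candidates.}
#'   \item{`subtemplates`}{sum of base counts of every size n-k subtemplate
#'     of the template (`k = 1` by default).}
#' }
#'
#' @param query_types character vector of one-letter types of the query
#'   residues (each element is one distinct residue).
#' @param template_types character vector of template slot types, in order.
#' @param scenario one of `"base"`, `"single"`, `"simultaneous"`,
#'   `"subtemplates"`.
#' @param from,to substitution descriptor (see above).
#' @param counting for `"single"`: `"total"` or `"new"`.
#' @param k for `"subtemplates"`: residues removed per subtemplate.
#' @return integer count.
#' @export
count_combinations <- function(query_types, template_types,
                               scenario = c("base", "single", "simultaneous",
                                            "subtemplates"),
                               from = NULL, to = NULL,
                               counting = c("total", "new"), k = 1L) {
  scenario <- match.arg(scenario)
  counting <- match.arg(counting)
  qt <- aa_to1(query_types)
  tt <- aa_to1(template_types)
  nq <- length(qt)
  base_cands <- lapply(tt, function(y) which(qt == y))
  count <- function(cands) nrow(assignments_dfs(cands, nq))
  switch(scenario,
    base = count(base_cands),
    single = {
      stopifnot(!is.null(from), !is.null(to), length(to) == 1L)
      from <- aa_to1(from); to <- aa_to1(to)
      cands <- base_cands
      for (j in which(tt == to)) {
        cands[[j]] <- sort(union(cands[[j]], which(qt == from)))
      }
      total <- count(cands)
      if (counting == "total") total else total - count(base_cands)
    },
    simultaneous = {
      stopifnot(!is.null(from), !is.null(to), length(to) >= 2L)
      from <- aa_to1(from); to <- aa_to1(to)
      slots <- vapply(to, function(y) {
        j <- which(tt == y)
        if (length(j) == 0L) {
          stop(sitematch_error("sitematch_value_error",
            sprintf("template has no slot of type %s", y)))
        }
        j[1L]
      }, integer(1))
      cands <- base_cands
      for (j in slots) cands[[j]] <- which(qt == from)
      ordered <- count(cands)
      unordered <- ordered / factorial(length(slots))
      if (unordered != as.integer(unordered)) {
        stop(sitematch_error("sitematch_value_error",
          "ordered count not divisible; unordered convention inapplicable"))
      }
      as.integer(unordered)
    },
    subtemplates = {
      n <- length(tt)
      stopifnot(k >= 1L, n - k >= 1L)
      subs <- utils::combn(n, n - k)
      sum(apply(subs, 2L, function(keep) count(base_cands[keep])))
    })
}

empty_matches <- function() {
  data.frame(template_id = character(0), parent_template = character(0),
             is_subtemplate = logical(0), n = integer(0),
             residues = character(0), res_aa = character(0),
             cmad_ca = numeric(0), cmad_fa = numeric(0), rmsd = numeric(0),
             stringsAsFactors = FALSE)
}

#' Match a template against query residue points
#'
#' Enumerates the local structures of the query with incremental per-pair
#' pruning: a partial assignment is abandoned as soon as any corresponding
#' C-alpha or fa pairwise-distance deviation exceeds the CMAD cutoff.
#' Because a match is accepted only when every pair deviation is within the
#' cutoff, the per-pair gate implies the mean (CMAD) gate and pruning is
#' exact: the match set equals that of prune-free exhaustive enumeration.
#' Surviving local structures are scored with the C-alpha and fa CMADs and
#' the least-squares superposition RMSD of the 2n matched points.
#'
#' @param points query `residue_points`.
#' @param template a `site_template`.
#' @param cmad_cutoff CMAD acceptance threshold, Angstrom (> 0).
#' @param sm optional substitution matrix.
#' @param exhaustive if TRUE, skip pruning and test every enumerated local
#'   structure (the oracle path used in tests).
#' @return data frame of matches (one row each) with CMADs and RMSD;
#'   significance is attached by [site_search()].
#' @export
match_template <- function(points, template, cmad_cutoff = 1.2, sm = NULL,
                           exhaustive = FALSE) {
  if (cmad_cutoff <= 0) {
    stop(sitematch_error("sitematch_value_error", "cmad_cutoff must be > 0"))
  }
  cands <- filter_candidates(points, template, sm)
  n <- length(cands)
  if (any(lengths(cands) == 0L)) return(empty_matches())
  dca <- as.matrix(stats::dist(ca_matrix(points)))
  dfa <- as.matrix(stats::dist(fa_matrix(points)))
  tca <- as.matrix(stats::dist(ca_matrix(template$points)))
  tfa <- as.matrix(stats::dist(fa_matrix(template$points)))
  prune <- if (exhaustive) NULL else function(i, j, ci, cj) {
    abs(tca[i, j] - dca[ci, cj]) <= cmad_cutoff &&
      abs(tfa[i, j] - dfa[ci, cj]) <= cmad_cutoff
  }
  hits <- assignments_dfs(cands, nrow(points), prune)
  if (nrow(hits) == 0L) return(empty_matches())
  ids <- point_ids(points)
  pairs_t_ca <- tca[lower.tri(tca)]
  pairs_t_fa <- tfa[lower.tri(tfa)]
  rows <- lapply(seq_len(nrow(hits)), function(r) {
    a <- hits[r, ]
    qca <- dca[a, a, drop = FALSE][lower.tri(diag(n))]
    qfa <- dfa[a, a, drop = FALSE][lower.tri(diag(n))]
    if (any(abs(pairs_t_ca - qca) > cmad_cutoff) ||
        any(abs(pairs_t_fa - qfa) > cmad_cutoff)) return(NULL)
    c_ca <- cmad(pairs_t_ca, qca)
    c_fa <- cmad(pairs_t_fa, qfa)
    if (c_ca > cmad_cutoff || c_fa > cmad_cutoff) return(NULL)
    qpts <- rbind(ca_matrix(points)[a, , drop = FALSE],
                  fa_matrix(points)[a, , drop = FALSE])
    data.frame(template_id = template$template_id,
               parent_template = template$parent_template %||% NA_character_,
               is_subtemplate = is_subtemplate(template),
               n = n,
               residues = paste(ids[a], collapse = ","),
               res_aa = paste(points$aa[a], collapse = ","),
               cmad_ca = c_ca, cmad_fa = c_fa,
               rmsd = superpose_rmsd(template_coords(template), qpts),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty_matches())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Remove subtemplate matches made redundant by their parent
#'
#' A subtemplate match is dropped when the template it was derived from also
#' produced an accepted match covering a superset of its residues; this only
#' removes redundant output and does not change which sites are found.
#'
#' @param matches a match data frame (as from [match_template()] or
#'   [site_search()]).
#' @return the filtered data frame, order otherwise preserved.
#' @export
postprocess_matches <- function(matches) {
  if (nrow(matches) == 0L) return(matches)
  res_sets <- strsplit(matches$residues, ",", fixed = TRUE)
  drop <- vapply(seq_len(nrow(matches)), function(i) {
    if (!matches$is_subtemplate[i]) return(FALSE)
    parents <- which(matches$template_id == matches$parent_template[i])
    any(vapply(parents, function(j) {
      all(res_sets[[i]] %in% res_sets[[j]])
    }, logical(1)))
  }, logical(1))
  out <- matches[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}
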