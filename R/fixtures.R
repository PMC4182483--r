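# Synthetic data generation: decoy pseudo-structures, synthetic active-site
# templates, planted sites, and the 2x2 (mutation x library) benchmark grid.
# Everything is deterministic under a seed (R's default Mersenne-Twister via
# withr::with_seed), so the whole pipeline is testable without downloads.
# Decoys are geometric pseudo-chains, not physical models: the matching
# method only sees C-alpha/fa geometry and residue types, so realistic
# rotamers or sequence plausibility are deliberately out of scope.

random_unit <- function() {
  repeat {
    v <- stats::rnorm(3)
    nv <- sqrt(sum(v^2))
    if (nv > 1e-8) return(v / nv)
  }
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Atoms of one synthetic residue in the two-point representation: CA, a CB
# stub at 1.52 A towards fa, and the type's canonical terminal atom at fa.
# GLY gets CA only (fa := CA downstream); ALA's fa IS its CB.
residue_atoms <- function(chain, resno, icode, aa3, ca, fa) {
  elety <- "CA"; xs <- ca[1]; ys <- ca[2]; zs <- ca[3]
  if (aa3 == "ALA") {
    elety <- c(elety, "CB")
    xs <- c(xs, fa[1]); ys <- c(ys, fa[2]); zs <- c(zs, fa[3])
  } else if (aa3 != "GLY") {
    u <- (fa - ca); u <- u / sqrt(sum(u^2))
    cb <- ca + 1.52 * u
    elety <- c(elety, "CB", TERMINAL_ATOM[[aa3]])
    xs <- c(xs, cb[1], fa[1]); ys <- c(ys, cb[2], fa[2])
    zs <- c(zs, cb[3], fa[3])
  }
  data.frame(chain = chain, resno = resno, icode = icode, resid = aa3,
             elety = elety, o = 1, x = xs, y = ys, z = zs,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic active-site template
#'
#' Residue C-alphas are placed sequentially 5-9 Angstrom apart (pairwise
#' separation at least 4.5 Angstrom), with fa atoms 2.3-3.8 Angstrom from
#' each C-alpha in a random direction; types are drawn from the 20 standard
#' amino acids excluding alanine and glycine, so every planted residue is a
#' valid alanine-scanning target.
#'
#' @param n number of catalytic residues (default 3, the commonest site
#'   size in curated catalytic-site data).
#' @param seed integer seed.
#' @param template_id identifier.
#' @param family_id family label (defaults to the template id).
#' @param types optional explicit one-letter types (length n).
#' @return a `site_template` with synthetic provenance.
#' @export
make_template <- function(n = 3L, seed = 1L,
                          template_id = sprintf("SYNT-%03d", seed),
                          family_id = template_id, types = NULL) {
  stopifnot(n >= 2L)
  withr::with_seed(seed, {
    if (is.null(types)) {
      pool <- setdiff(aa_one_letter(), c("A", "G"))
      types <- sample(pool, n, replace = TRUE)
    }
    ca <- matrix(0, n, 3)
    for (i in seq_len(n)[-1L]) {
      repeat {
        cand <- ca[i - 1L, ] + random_unit() * stats::runif(1, 5, 9)
        if (all(sqrt(rowSums(sweep(ca[seq_len(i - 1L), , drop = FALSE], 2,
                                   cand)^2)) > 4.5)) break
      }
      ca[i, ] <- cand
    }
    fa <- ca + t(vapply(seq_len(n), function(i) {
      random_unit() * stats::runif(1, 2.3, 3.8)
    }, numeric(3)))
    pts <- data.frame(chain = "A", resno = seq_len(n) * 10L, icode = "",
                      aa = aa_to1(types),
                      ca_x = ca[, 1], ca_y = ca[, 2], ca_z = ca[, 3],
                      fa_x = fa[, 1], fa_y = fa[, 2], fa_z = fa[, 3],
                      fa_atom = unname(TERMINAL_ATOM[aa_to3(types)]),
                      fa_present = TRUE, stringsAsFactors = FALSE)
    class(pts) <- c("residue_points", "data.frame")
    new_template(template_id, pts, source_structure = template_id,
                 family_id = family_id)
  })
}

#' Generate a library of synthetic templates
#'
#' @param n_templates number of master templates.
#' @param sizes residue counts, recycled over templates (default 3).
#' @param seed integer seed.
#' @return a `template_library` of synthetic master templates, one family
#'   each.
#' @export
make_synthetic_library <- function(n_templates = 5L, sizes = 3L, seed = 1L) {
  sizes <- rep_len(sizes, n_templates)
  templates <- lapply(seq_len(n_templates), function(i) {
    make_template(sizes[i], seed = seed * 1000L + i,
                  template_id = sprintf("SYNT-%02d", i))
  })
  template_library(templates, metadata = list(generator = "synthetic",
                                              seed = seed))
}

#' Generate a decoy structure
#'
#' A self-avoiding pseudo-chain with consecutive C-alpha spacing
#' 3.8 +/- 0.1 Angstrom (no two C-alphas closer than 3.5), residue types
#' drawn from the background abundance table, and fa offsets 1.8-3.5
#' Angstrom from each C-alpha in a random direction. No planted site: decoys
#' stand in for the benchmark's negative group.
#'
#' @param n number of residues (>= 5).
#' @param seed integer seed.
#' @param abundance an `abundance_table` (default: shipped table).
#' @param structure_id identifier.
#' @return a `structure_model`.
#' @export
make_decoy <- function(n, seed, abundance = NULL,
                       structure_id = sprintf("DEC-%06d", seed)) {
  stopifnot(n >= 5L)
  if (is.null(abundance)) abundance <- load_abundance()
  withr::with_seed(seed, {
    repeat {
      ca <- matrix(NA_real_, n, 3)
      ca[1L, ] <- 0
      ok <- TRUE
      for (i in seq_len(n)[-1L]) {
        placed <- FALSE
        for (try in 1:60) {
          cand <- ca[i - 1L, ] + random_unit() * stats::runif(1, 3.7, 3.9)
          prev <- ca[seq_len(i - 2L), , drop = FALSE]
          if (i == 2L ||
              all(sqrt(rowSums(sweep(prev, 2, cand)^2)) > 3.5)) {
            ca[i, ] <- cand
            placed <- TRUE
            break
          }
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) break
    }
    types <- sample(names(abundance), n, replace = TRUE,
                    prob = as.numeric(abundance))
    atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
      aa3 <- aa_to3(types[i])
      fa <- ca[i, ] + random_unit() * stats::runif(1, 1.8, 3.5)
      residue_atoms("A", i, "", aa3, ca[i, ], fa)
    }))
    new_structure_model(structure_id, atoms)
  })
}

#' Plant a template's site into a structure
#'
#' Chooses `n` sequence-non-adjacent residues of the structure, retypes them
#' to the template's residue types and overwrites their atoms so that their
#' C-alpha and fa coordinates reproduce the template geometry after a random
#' rigid placement, plus optional iid Gaussian jitter emulating
#' within-family structural variation.
#'
#' @param s a `structure_model` (typically a decoy).
#' @param template a `site_template`.
#' @param jitter_sigma coordinate noise sd, Angstrom (default 0).
#' @param seed integer seed.
#' @return list with `structure` (the modified model) and `truth` (the
#'   planted residue ids `chain:resno:icode`).
#' @export
plant_site <- function(s, template, jitter_sigma = 0, seed = 1L) {
  nt <- template_size(template)
  withr::with_seed(seed, {
    points <- derive_residue_points(s)
    if (nrow(points) < 2L * nt + 1L) {
      stop(sitematch_error("sitematch_value_error",
        "structure too small to plant the site"))
    }
    repeat {
      idx <- sort(sample(nrow(points), nt))
      if (all(diff(idx) >= 2L)) break
    }
    rot <- random_rotation()
    tca <- ca_matrix(template$points)
    tfa <- fa_matrix(template$points)
    centre <- colMeans(tca)
    target <- colMeans(ca_matrix(points)[idx, , drop = FALSE])
    place <- function(m) {
      sweep(sweep(m, 2, centre) %*% t(rot), 2, target, `+`)
    }
    nca <- place(tca)
    nfa <- place(tfa)
    if (jitter_sigma > 0) {
      nca <- nca + matrix(stats::rnorm(length(nca), 0, jitter_sigma), ncol = 3)
      nfa <- nfa + matrix(stats::rnorm(length(nfa), 0, jitter_sigma), ncol = 3)
    }
    keys <- point_ids(points)
    at <- s$atoms
    atom_key <- paste(at$chain, at$resno, at$icode, sep = ":")
    chunks <- split(seq_len(nrow(at)), factor(atom_key, levels = unique(atom_key)))
    replaced <- stats::setNames(seq_along(idx), keys[idx])
    pieces <- lapply(names(chunks), function(k) {
      if (!is.na(replaced[k])) {
        j <- replaced[[k]]
        p <- points[idx[j], ]
        residue_atoms(p$chain, p$resno, p$icode, aa_to3(template$points$aa[j]),
                      nca[j, ], nfa[j, ])
      } else {
        at[chunks[[k]], , drop = FALSE]
      }
    })
    list(structure = new_structure_model(s$structure_id,
                                         do.call(rbind, pieces)),
         truth = keys[idx])
  })
}

#' Remove the side chain of one residue
#'
#' Deletes all side-chain heavy atoms of the target residue, leaving the
#' backbone; the residue's fa then becomes underivable (absent), emulating a
#' PDB entry whose relevant side-chain atoms were not resolved.
#'
#' @param s a `structure_model`.
#' @param chain,resno,icode target residue identity.
#' @return a modified `structure_model` copy.
#' @export
truncate_side_chain <- function(s, chain, resno, icode = "") {
  at <- s$atoms
  hit <- at$chain == chain & at$resno == resno & at$icode == icode
  if (!any(hit)) {
    stop(sitematch_error("sitematch_lookup_error",
      sprintf("residue %s:%s:%s not found in %s", chain, resno, icode,
              s$structure_id)))
  }
  drop <- hit & !(at$elety %in% BACKBONE_ATOMS)
  new_structure_model(s$structure_id, at[!drop, , drop = FALSE])
}

#' Build a complete synthetic benchmark
#'
#' Generates labeled positive queries (decoy chains with sites planted
#' round-robin from the library's master templates) and negative decoys;
#' optionally applies alanine scanning to the positives or deletes the side
#' chain of one site residue. The returned library contains the master
#' templates; expand it with [expand_library()] for the extended-library
#' arms of the benchmark grid.
#'
#' @param spec list of generation parameters:
#'   `n_residues` (default 150), `n_positives` (20), `n_negatives` (100),
#'   `templates` (a `template_library` or single `site_template`; default a
#'   5-template synthetic library of 3-residue sites),
#'   `jitter_sigma` (0), `mutation` (`"none"` or `"alanine_scan"`),
#'   `delete_fa_of` (site residue index whose side chain is removed in each
#'   positive, or NULL), `seed` (1).
#' @param out_dir optional directory; when given, writes the query PDB
#'   files, a `sites.tsv` annotation of the planted sites and a
#'   `manifest.tsv` (columns path, structure_id, label, truth_site,
#'   mutated_residue).
#' @return list with `queries` (list of `labeled_query`), `library`
#'   (master `template_library`) and `manifest` (data frame).
#' @export
make_benchmark <- function(spec = list(), out_dir = NULL) {
  defaults <- list(n_residues = 150L, n_positives = 20L, n_negatives = 100L,
                   templates = NULL, jitter_sigma = 0,
                   mutation = "none", delete_fa_of = NULL, seed = 1L)
  unknown <- setdiff(names(spec), names(defaults))
  if (length(unknown)) {
    stop(sitematch_error("sitematch_value_error",
      sprintf("unknown benchmark spec field(s): %s",
              paste(unknown, collapse = ", "))))
  }
  spec <- utils::modifyList(defaults, spec)
  if (!spec$mutation %in% c("none", "alanine_scan")) {
    stop(sitematch_error("sitematch_value_error",
      sprintf("unknown mutation mode '%s'", spec$mutation)))
  }
  lib <- spec$templates
  if (is.null(lib)) {
    lib <- make_synthetic_library(5L, 3L, seed = spec$seed)
  } else if (inherits(lib, "site_template")) {
    lib <- template_library(list(lib))
  }
  masters <- Filter(Negate(is_subtemplate), lib$templates)
  abundance <- load_abundance()
  positives <- lapply(seq_len(spec$n_positives), function(i) {
    t <- masters[[(i - 1L) %% length(masters) + 1L]]
    dec <- make_decoy(spec$n_residues, seed = spec$seed * 10000L + i,
                      abundance = abundance,
                      structure_id = sprintf("POS-%03d", i))
    planted <- plant_site(dec, t, jitter_sigma = spec$jitter_sigma,
                          seed = spec$seed * 10000L + i)
    st <- planted$structure
    if (!is.null(spec$delete_fa_of)) {
      id <- planted$truth[spec$delete_fa_of]
      parts <- strsplit(id, ":", fixed = TRUE)[[1L]]
      st <- truncate_side_chain(st, parts[1L], as.integer(parts[2L]),
                                if (length(parts) >= 3L) parts[3L] else "")
    }
    labeled_query(st, "POSITIVE", truth_site = planted$truth)
  })
  if (spec$mutation == "alanine_scan") {
    positives <- alanine_scan_set(positives, seed = spec$seed + 777L)
  }
  negatives <- lapply(seq_len(spec$n_negatives), function(i) {
    labeled_query(make_decoy(spec$n_residues,
                             seed = spec$seed * 10000L + 5000L + i,
                             abundance = abundance,
                             structure_id = sprintf("NEG-%03d", i)),
                  "NEGATIVE")
  })
  queries <- c(positives, negatives)
  manifest <- do.call(rbind, lapply(queries, function(q) {
    data.frame(path = paste0(q$structure$structure_id, ".pdb"),
               structure_id = q$structure$structure_id, label = q$label,
               truth_site = paste(q$truth_site, collapse = ","),
               mutated_residue = q$mutated_residue,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (q in queries) {
      write_pdb(q$structure, file.path(out_dir, paste0(q$structure$structure_id, ".pdb")))
    }
    sites <- do.call(rbind, lapply(queries, function(q) {
      if (q$label != "POSITIVE") return(NULL)
      pts <- derive_residue_points(q$structure)
      sel <- match(q$truth_site, point_ids(pts))
      data.frame(structure_id = q$structure$structure_id,
                 chain = pts$chain[sel], seq_number = pts$resno[sel],
                 icode = pts$icode[sel], res_type = pts$aa[sel],
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(sites, file.path(out_dir, "sites.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(queries = queries, library = lib, manifest = manifest)
}
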