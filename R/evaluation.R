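# Benchmark harness: labeled queries, in-silico alanine scanning,
# TP/FN/FP/TN classification and the confusion-matrix metrics.

#' Labeled benchmark query
#'
#' @param structure a `structure_model`.
#' @param label `"POSITIVE"` (carries a known catalytic site) or
#'   `"NEGATIVE"` (decoy).
#' @param truth_site character vector of residue ids (`chain:resno:icode`)
#'   of the catalytic site; required for positives.
#' @param mutated_residue id of the alanine-substituted residue, or NA.
#' @return a `labeled_query`.
#' @export
labeled_query <- function(structure, label = c("POSITIVE", "NEGATIVE"),
                          truth_site = character(0),
                          mutated_residue = NA_character_) {
  label <- match.arg(label)
  if (label == "POSITIVE" && length(truth_site) == 0L) {
    stop(sitematch_error("sitematch_value_error",
                         "POSITIVE query needs a non-empty truth_site"))
  }
  if (label == "NEGATIVE" && length(truth_site) > 0L) {
    stop(sitematch_error("sitematch_value_error",
                         "NEGATIVE query cannot carry a truth_site"))
  }
  if (!is.na(mutated_residue) && !(mutated_residue %in% truth_site)) {
    stop(sitematch_error("sitematch_value_error",
                         "mutated_residue must belong to truth_site"))
  }
  structure(list(structure = structure, label = label,
                 truth_site = truth_site,
                 mutated_residue = mutated_residue),
            class = "labeled_query")
}

#' Apply alanine scanning to a set of positive queries
#'
#' For each positive query, one uniformly chosen catalytic residue
#' (excluding glycine and alanine, which have no side chain to truncate) is
#' substituted by alanine via [mutate_to_alanine()]; the mutated residue is
#' recorded. Queries whose site has no mutable residue are skipped with a
#' warning. Deterministic given the seed.
#'
#' @param positives list of POSITIVE `labeled_query` objects, each with at
#'   least 3 catalytic residues.
#' @param seed integer RNG seed.
#' @return list of mutated `labeled_query` objects.
#' @export
alanine_scan_set <- function(positives, seed) {
  withr::with_seed(seed, {
    out <- lapply(positives, function(q) {
      stopifnot(inherits(q, "labeled_query"), q$label == "POSITIVE")
      if (length(q$truth_site) < 3L) {
        stop(sitematch_error("sitematch_value_error",
          sprintf("site of %s has fewer than 3 catalytic residues",
                  q$structure$structure_id)))
      }
      points <- derive_residue_points(q$structure)
      ids <- point_ids(points)
      site_aa <- points$aa[match(q$truth_site, ids)]
      mutable <- q$truth_site[!(site_aa %in% c("G", "A")) & !is.na(site_aa)]
      if (length(mutable) == 0L) {
        warning(sprintf("site of %s has no mutable residue; skipped",
                        q$structure$structure_id))
        return(NULL)
      }
      target <- if (length(mutable) == 1L) mutable else sample(mutable, 1L)
      parts <- strsplit(target, ":", fixed = TRUE)[[1L]]
      mut <- mutate_to_alanine(q$structure, parts[1L],
                               as.integer(parts[2L]),
                               if (length(parts) >= 3L) parts[3L] else "")
      labeled_query(mut, "POSITIVE", truth_site = q$truth_site,
                    mutated_residue = target)
    })
    out[!vapply(out, is.null, logical(1))]
  })
}

#' Classify one query's search result
#'
#' A positive query is a true positive when some reported match's residue
#' set exactly equals the truth site (`mode = "full"`) or exactly equals the
#' truth site minus the mutated residue (`mode = "non_mutated"`, the
#' criterion for subtemplate recovery of a mutated site: only the
#' non-mutated residues can be recovered); otherwise it is a false negative.
#' A negative query is a false positive when any match is reported,
#' otherwise a true negative.
#'
#' @param q a `labeled_query`.
#' @param matches the (already significance-filtered) match data frame from
#'   [site_search()].
#' @param mode `"full"` or `"non_mutated"`.
#' @return one of `"TP"`, `"FN"`, `"FP"`, `"TN"`.
#' @export
classify_query <- function(q, matches, mode = c("non_mutated", "full")) {
  mode <- match.arg(mode)
  if (q$label == "NEGATIVE") {
    return(if (nrow(matches) > 0L) "FP" else "TN")
  }
  target <- if (mode == "full") {
    q$truth_site
  } else {
    if (is.na(q$mutated_residue)) {
      stop(sitematch_error("sitematch_value_error",
        "mode 'non_mutated' requires a mutated_residue"))
    }
    setdiff(q$truth_site, q$mutated_residue)
  }
  if (nrow(matches) == 0L) return("FN")
  sets <- strsplit(matches$residues, ",", fixed = TRUE)
  hit <- any(vapply(sets, function(s) setequal(s, target), logical(1)))
  if (hit) "TP" else "FN"
}

#' Confusion-matrix performance metrics
#'
#' Sensitivity `tp/(tp+fn)`, accuracy `(tp+tn)/total`, precision
#' `tp/(tp+fp)` and the Matthews correlation coefficient
#' `(tp*tn - fp*fn)/sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`. A zero denominator
#' yields NaN with a warning for sensitivity/precision; for the MCC it
#' yields 0 by convention. Values are held at full precision; the print
#' method shows 3 decimals.
#'
#' @param tp,fn,fp,tn non-negative integer counts.
#' @param config optional list echoed into the report (cutoffs, library id).
#' @return a `performance_report` list: `counts`, `sn`, `acc`, `pr`, `mcc`,
#'   `config`.
#' @export
performance_metrics <- function(tp, fn, fp, tn, config = list()) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop(sitematch_error("sitematch_value_error",
                         "counts must be non-negative integers"))
  }
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator)", what))
      return(NaN)
    }
    num / den
  }
  sn <- ratio(tp, tp + fn, "sensitivity")
  acc <- ratio(tp + tn, tp + fn + fp + tn, "accuracy")
  pr <- ratio(tp, tp + fp, "precision")
  denom <- sqrt(prod(as.numeric(c(tp + fp, tp + fn, tn + fp, tn + fn))))
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  structure(list(counts = counts, sn = sn, acc = acc, pr = pr, mcc = mcc,
                 config = config),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("TP %d  FN %d  FP %d  TN %d\n", x$counts["tp"], x$counts["fn"],
              x$counts["fp"], x$counts["tn"]))
  cat(sprintf("Sn %.3f  Acc %.3f  Pr %.3f  MCC %.3f\n",
              x$sn, x$acc, x$pr, x$mcc))
  invisible(x)
}

#' Run a labeled benchmark
#'
#' Searches every labeled query against the library, classifies each
#' outcome and aggregates the confusion counts and metrics. A vector of
#' CMAD cutoffs may be supplied to sweep the threshold (one report per
#' cutoff), reproducing sensitivity-versus-CMAD curves on synthetic data.
#'
#' @param queries list of `labeled_query` objects.
#' @param lib a `template_library`.
#' @param cfg a [search_config()].
#' @param mode classification mode, see [classify_query()]; positives
#'   without a recorded mutation are always classified in `"full"` mode.
#' @param sweep optional numeric vector of CMAD cutoffs; when given, the
#'   return value is a named list of reports.
#' @return a list with `report` (a `performance_report`) and `per_query`
#'   (data frame: structure_id, label, outcome, n_matches, top_template,
#'   top_p); or a named list of such lists when sweeping.
#' @export
run_benchmark <- function(queries, lib, cfg = search_config(),
                          mode = c("non_mutated", "full"), sweep = NULL) {
  mode <- match.arg(mode)
  if (!is.null(sweep)) {
    out <- lapply(sweep, function(cut) {
      cfg2 <- cfg
      cfg2$cmad_cutoff <- cut
      run_benchmark(queries, lib, cfg2, mode = mode)
    })
    names(out) <- as.character(sweep)
    return(out)
  }
  rows <- lapply(queries, function(q) {
    matches <- tryCatch(site_search(q$structure, lib, cfg),
                        error = function(e) {
                          warning(sprintf("search failed for %s: %s",
                                          q$structure$structure_id,
                                          conditionMessage(e)))
                          empty_matches()
                        })
    qmode <- if (q$label == "POSITIVE" && is.na(q$mutated_residue)) {
      "full"
    } else {
      mode
    }
    outcome <- classify_query(q, matches, qmode)
    data.frame(structure_id = q$structure$structure_id, label = q$label,
               outcome = outcome, n_matches = nrow(matches),
               top_template = if (nrow(matches)) matches$template_id[1L] else NA,
               top_p = if (nrow(matches)) matches$p_value[1L] else NA,
               stringsAsFactors = FALSE)
  })
  per_query <- do.call(rbind, rows)
  tab <- table(factor(per_query$outcome, levels = c("TP", "FN", "FP", "TN")))
  report <- performance_metrics(tab[["TP"]], tab[["FN"]], tab[["FP"]],
                                tab[["TN"]],
                                config = list(cmad_cutoff = cfg$cmad_cutoff,
                                              p_threshold = cfg$p_threshold,
                                              mode = mode))
  list(report = report, per_query = per_query)
}
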