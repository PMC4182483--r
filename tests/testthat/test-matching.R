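test_that("CMAD matches hand-computed values and is symmetric", {
  expect_equal(cmad(c(3, 4, 5), c(3, 4, 5)), 0)
  expect_equal(cmad(c(3, 4, 5), c(4, 4, 5)), 1 / 3)
  expect_equal(cmad(c(4, 4, 5), c(3, 4, 5)), cmad(c(3, 4, 5), c(4, 4, 5)))
  expect_error(cmad(c(1, 2), c(1, 2, 3)), class = "sitematch_value_error")
  expect_error(cmad(numeric(0), numeric(0)), class = "sitematch_value_error")
})

test_that("candidate filtering follows the type worked example", {
  # query E1 E2 D1 K1 K2 H1 H2 against template (E, D, K)
  qaa <- c("E", "E", "D", "K", "K", "H", "H")
  pts <- data.frame(chain = "A", resno = seq_along(qaa) * 10L, icode = "",
                    aa = qaa, ca_x = seq_along(qaa) * 5, ca_y = 0, ca_z = 0,
                    fa_x = seq_along(qaa) * 5, fa_y = 3, fa_z = 0,
                    fa_atom = "XX", fa_present = TRUE,
                    stringsAsFactors = FALSE)
  class(pts) <- c("residue_points", "data.frame")
  t <- toy_template(c("E", "D", "K"))
  cands <- filter_candidates(pts, t)
  expect_equal(cands, list(c(1L, 2L), 3L, c(4L, 5L)))
  # substitution H<->E extends the E slot
  sm <- substitution_matrix(list(c("H", "E")))
  cands_sm <- filter_candidates(pts, t, sm)
  expect_equal(cands_sm[[1]], c(1L, 2L, 6L, 7L))
  expect_equal(cands_sm[[2]], 3L)
  # type absent from query -> empty slot
  t2 <- toy_template(c("E", "W"), id = "TW")
  expect_equal(lengths(filter_candidates(pts, t2)), c(2L, 0L))
  # fa-less residues are excluded from candidacy
  pts$fa_present[1] <- FALSE
  expect_equal(filter_candidates(pts, t)[[1]], 2L)
})

test_that("local-structure enumeration is injective, ordered, and matches an oracle", {
  pts <- data.frame(chain = "A", resno = 1:6, icode = "",
                    aa = c("E", "E", "D", "K", "K", "E"),
                    ca_x = 0, ca_y = 0, ca_z = 0, fa_x = 0, fa_y = 0,
                    fa_z = 0, fa_atom = "X", fa_present = TRUE,
                    stringsAsFactors = FALSE)
  class(pts) <- c("residue_points", "data.frame")
  t <- toy_template(c("E", "D", "K"))
  cands <- filter_candidates(pts, t)
  ls <- enumerate_local_structures(cands, pts)
  expect_equal(nrow(ls), enumeration_oracle(cands))
  expect_true(all(apply(ls, 1, anyDuplicated) == 0))
  # slot-major deterministic order: first slot varies slowest
  expect_equal(ls[, 1], rep(c(1L, 2L, 6L), each = 2))
  # random instances against the oracle
  for (seed in 1:8) {
    cands2 <- withr::with_seed(seed, {
      nslots <- sample(2:4, 1)
      lapply(seq_len(nslots), function(i) sort(sample(1:8, sample(1:5, 1))))
    })
    expect_equal(nrow(enumerate_local_structures(cands2, pts[rep(1, 8), ])),
                 enumeration_oracle(cands2))
  }
})

test_that("combination counting reproduces every scenario convention", {
  qt <- c("E", "E", "D", "K", "K", "H", "H")
  tt <- c("E", "D", "K")
  expect_equal(count_combinations(qt, tt, "base"), 4L)
  expect_equal(count_combinations(qt, tt, "single", from = "H", to = "E"),
               8L)
  expect_equal(count_combinations(qt, tt, "single", from = "H", to = "E",
                                  counting = "new"), 4L)
  expect_equal(count_combinations(qt, tt, "single", from = "H", to = "D",
                                  counting = "new"), 8L)
  expect_equal(count_combinations(qt, tt, "single", from = "H", to = "K",
                                  counting = "new"), 4L)
  expect_equal(count_combinations(qt, tt, "simultaneous", from = "H",
                                  to = c("E", "D")), 2L)
  expect_equal(count_combinations(qt, tt, "simultaneous", from = "H",
                                  to = c("E", "K")), 1L)
  expect_equal(count_combinations(qt, tt, "simultaneous", from = "H",
                                  to = c("D", "K")), 2L)
  expect_equal(count_combinations(qt, tt, "subtemplates", k = 1), 8L)
  expect_error(count_combinations(qt, tt, "simultaneous", from = "H",
                                  to = c("E", "W")),
               class = "sitematch_value_error")
})

test_that("an exactly planted site matches with zero CMAD and RMSD", {
  t <- make_template(3, seed = 21)
  planted <- plant_site(make_decoy(80, seed = 22), t, seed = 23)
  pts <- derive_residue_points(planted$structure)
  m <- match_template(pts, t, cmad_cutoff = 1.2)
  expect_gte(nrow(m), 1L)
  best <- m[which.min(m$cmad_fa), ]
  expect_equal(best$residues, paste(sort(planted$truth), collapse = ","))
  expect_equal(best$cmad_ca, 0, tolerance = 1e-9)
  expect_equal(best$cmad_fa, 0, tolerance = 1e-9)
  expect_equal(best$rmsd, 0, tolerance = 1e-7)
})

test_that("alanine mutation of a planted residue defeats the full template", {
  t <- make_template(3, seed = 24)
  planted <- plant_site(make_decoy(80, seed = 25), t, seed = 26)
  parts <- strsplit(planted$truth[1], ":", fixed = TRUE)[[1]]
  mut <- mutate_to_alanine(planted$structure, parts[1],
                           as.integer(parts[2]), "")
  m <- match_template(derive_residue_points(mut), t, cmad_cutoff = 1.2)
  expect_equal(nrow(m), 0L)
})

test_that("pruned matching equals exhaustive enumeration", {
  # random small instances: <= 5 slots, <= 6 candidates per slot
  for (seed in 1:10) {
    n_t <- withr::with_seed(seed, sample(2:5, 1))
    t <- make_template(n_t, seed = 400 + seed)
    # 60-residue decoys keep per-type candidate pools small (about 6)
    q <- derive_residue_points(make_decoy(60, seed = 500 + seed))
    for (cutoff in c(0.6, 1.2, 2.5)) {
      pruned <- match_template(q, t, cmad_cutoff = cutoff)
      exhaustive <- match_template(q, t, cmad_cutoff = cutoff,
                                   exhaustive = TRUE)
      expect_equal(pruned$residues, exhaustive$residues)
      expect_equal(pruned$cmad_fa, exhaustive$cmad_fa)
    }
  }
})

test_that("subtemplate CMAD never exceeds the parent on the induced correspondence", {
  for (seed in 1:6) {
    t <- make_template(4, seed = 600 + seed)
    planted <- plant_site(make_decoy(70, seed = 700 + seed), t,
                          jitter_sigma = 0.3, seed = 800 + seed)
    pts <- derive_residue_points(planted$structure)
    parent <- match_template(pts, t, cmad_cutoff = 5)
    if (nrow(parent) == 0L) next
    best <- which.min(parent$cmad_fa)
    ext <- expand_library(template_library(list(t)))
    subs <- Filter(sitematch:::is_subtemplate, ext$templates)
    sub_best <- min(vapply(subs, function(s) {
      m <- match_template(pts, s, cmad_cutoff = 5)
      if (nrow(m) == 0L) Inf else min(m$cmad_fa)
    }, numeric(1)))
    expect_lte(sub_best, parent$cmad_fa[best] + 1e-9)
  }
})

test_that("redundant subtemplate matches are removed by postprocessing", {
  t <- make_template(3, seed = 31)
  lib <- expand_library(template_library(list(t)))
  planted <- plant_site(make_decoy(80, seed = 32), t, seed = 33)
  res <- site_search(planted$structure, lib,
                     search_config(cmad_cutoff = 1.2))
  expect_true(t$template_id %in% res$template_id)
  # no surviving subtemplate match is covered by the parent's residue set
  parent_rows <- res[res$template_id == t$template_id, ]
  sub_rows <- res[res$is_subtemplate, ]
  if (nrow(sub_rows) > 0L) {
    parent_sets <- strsplit(parent_rows$residues, ",")
    for (rs in strsplit(sub_rows$residues, ",")) {
      expect_false(any(vapply(parent_sets, function(ps) all(rs %in% ps),
                              logical(1))))
    }
  }
  # a subtemplate match without a parent match is retained
  parts <- strsplit(planted$truth[2], ":", fixed = TRUE)[[1]]
  mut <- mutate_to_alanine(planted$structure, parts[1],
                           as.integer(parts[2]), "")
  res_m <- site_search(mut, lib, search_config(cmad_cutoff = 0.4))
  expect_true(any(res_m$is_subtemplate))
  # empty input passes through
  expect_equal(nrow(postprocess_matches(res_m[0, ])), 0L)
})

test_that("search output is ranked by p-value, cmad_fa, then template id", {
  lib <- make_synthetic_library(4, 3, seed = 41)
  planted <- plant_site(make_decoy(90, seed = 42), lib$templates[[2]],
                        seed = 43)
  res <- site_search(planted$structure, expand_library(lib),
                     search_config(cmad_cutoff = 1.2))
  expect_gte(nrow(res), 1L)
  ord <- order(res$p_value, res$cmad_fa, res$template_id)
  expect_equal(ord, seq_len(nrow(res)))
  expect_error(site_search(planted$structure,
                           template_library(list(), list())),
               class = "sitematch_value_error")
})
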