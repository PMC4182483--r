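test_that("templates build from annotated structures with ordered residues", {
  t1 <- make_template(3, seed = 2, types = c("E", "D", "K"))
  dec <- make_decoy(40, seed = 2)
  planted <- plant_site(dec, t1, seed = 4)
  pts <- derive_residue_points(planted$structure)
  sel <- match(planted$truth, paste(pts$chain, pts$resno, pts$icode,
                                    sep = ":"))
  ann <- data.frame(structure_id = "x", chain = pts$chain[sel],
                    seq_number = pts$resno[sel], icode = pts$icode[sel],
                    res_type = pts$aa[sel], stringsAsFactors = FALSE)
  t2 <- build_template(planted$structure, ann, template_id = "built")
  expect_s3_class(t2, "site_template")
  expect_equal(nrow(t2$points), 3L)
  expect_equal(sort(t2$points$aa), sort(c("E", "D", "K")))
  # residues ordered by identity
  expect_equal(t2$points$resno, sort(t2$points$resno))
})

test_that("building a template from an incomplete or mistyped site errors", {
  s <- parse_pdb(c(pdb_atom_line(1, "CA", "SER", "A", 1, 0, 0, 0),
                   pdb_atom_line(2, "CB", "SER", "A", 1, 1.5, 0, 0),
                   pdb_atom_line(3, "CA", "GLU", "A", 2, 6, 0, 0),
                   "END"))
  ann <- data.frame(structure_id = "s", chain = "A", seq_number = c(1, 2),
                    icode = "", res_type = c("S", "E"),
                    stringsAsFactors = FALSE)
  # GLU at 2 has no side-chain atoms -> fa absent -> incomplete site
  expect_error(build_template(s, ann), class = "sitematch_incomplete_site")
  ann2 <- data.frame(structure_id = "s", chain = "A", seq_number = 1,
                     icode = "", res_type = "T", stringsAsFactors = FALSE)
  s2 <- parse_pdb(c(pdb_atom_line(1, "CA", "SER", "A", 1, 0, 0, 0),
                    pdb_atom_line(2, "CB", "SER", "A", 1, 1.5, 0, 0),
                    pdb_atom_line(3, "CA", "CYS", "A", 3, 6, 0, 0),
                    pdb_atom_line(4, "SG", "CYS", "A", 3, 7.5, 0, 0),
                    "END"))
  ann2 <- rbind(ann2, data.frame(structure_id = "s", chain = "A",
                                 seq_number = 3, icode = "", res_type = "C"))
  expect_error(build_template(s2, ann2),
               class = "sitematch_annotation_conflict")
  expect_error(build_template(s2, transform(ann2, seq_number = c(1, 99))),
               class = "sitematch_incomplete_site")
})

test_that("template RMSD is zero for self and rigid copies, and symmetric", {
  t1 <- toy_template(c("E", "D", "K"))
  expect_equal(template_rmsd(t1, t1), 0, tolerance = 1e-9)
  t2 <- transform_template(t1, angle = 1.1, axis = c(1, 2, 3),
                           shift = c(-4, 9, 2), id = "TOY2")
  expect_equal(template_rmsd(t1, t2), 0, tolerance = 1e-9)
  t3 <- toy_template(c("E", "D", "K"), id = "TOY3")
  t3$points$fa_z <- t3$points$fa_z + 0.8
  expect_equal(template_rmsd(t1, t3), template_rmsd(t3, t1),
               tolerance = 1e-12)
  expect_error(template_rmsd(t1, toy_template(c("E", "D"), id = "S")),
               class = "sitematch_incomparable_templates")
  expect_error(template_rmsd(t1, toy_template(c("E", "D", "R"), id = "R")),
               class = "sitematch_incomparable_templates")
})

test_that("master-template selection minimizes mean family RMSD", {
  # one exact copy of a reference plus jittered copies: the exact copy wins
  ref <- toy_template(c("E", "D", "K"), id = "REF")
  jitter_template <- function(t, id, seed, sigma = 0.5) {
    withr::with_seed(seed, {
      pts <- t$points
      for (col in c("ca_x", "ca_y", "ca_z", "fa_x", "fa_y", "fa_z")) {
        pts[[col]] <- pts[[col]] + rnorm(nrow(pts), 0, sigma)
      }
      sitematch:::new_template(id, pts, source_structure = id,
                               family_id = t$family_id)
    })
  }
  exact <- transform_template(ref, angle = 0.4, id = "EXACT")
  fam <- list(jitter_template(ref, "J1", 11), exact, jitter_template(ref, "J2", 12))
  expect_equal(select_master_template(fam)$template_id, "EXACT")
  # agreement with exhaustive evaluation on random families of size <= 6
  for (seed in 1:4) {
    fam2 <- lapply(1:5, function(i) jitter_template(ref, paste0("F", i),
                                                    seed * 100 + i, 0.3))
    got <- select_master_template(fam2)$template_id
    rm_tab <- sapply(fam2, function(a) sapply(fam2, function(b)
      template_rmsd(a, b)))
    want <- vapply(fam2, `[[`, "", "template_id")[which.min(colMeans(rm_tab))]
    expect_equal(got, want)
  }
})

test_that("master-template ties break to the smallest template id", {
  a <- toy_template(c("E", "D"), id = "B-COPY")
  b <- toy_template(c("E", "D"), id = "A-COPY")
  expect_equal(select_master_template(list(a, b))$template_id, "A-COPY")
})

test_that("incomparable family members are excluded with a warning", {
  fam <- list(toy_template(c("E", "D", "K"), id = "T1"),
              toy_template(c("E", "D", "K"), id = "T2"),
              toy_template(c("E", "D"), id = "ODD"))
  expect_warning(m <- select_master_template(fam), "incomparable")
  expect_true(m$template_id %in% c("T1", "T2"))
})

test_that("k=1 expansion adds exactly n subtemplates per template", {
  t3 <- make_template(3, seed = 5)
  lib <- template_library(list(t3))
  ext <- expand_library(lib, k = 1)
  expect_equal(length(ext$templates), 4L)
  subs <- Filter(sitematch:::is_subtemplate, ext$templates)
  expect_equal(length(subs), 3L)
  # each residue omitted exactly once
  excluded <- vapply(subs, `[[`, "", "excluded_residue")
  expect_setequal(excluded, sitematch:::point_ids(t3$points))
  expect_true(all(vapply(subs, sitematch:::template_size, 1L) == 2L))
})

test_that("expansion respects min_size and the N_T x n_max bound", {
  t3 <- make_template(3, seed = 6)
  t5 <- make_template(5, seed = 7)
  lib <- template_library(list(t3, t5))
  ext <- expand_library(lib, k = 1)
  expect_equal(length(ext$templates) - 2L, 8L)  # 3 + 5 subtemplates
  expect_lte(length(ext$templates) - 2L, 2L * 5L)
  # min_size gate: a 3-residue template yields nothing at min_size 3
  ext2 <- expand_library(template_library(list(t3)), k = 1, min_size = 3)
  expect_equal(length(ext2$templates), 1L)
})

test_that("expansion bound holds on randomized libraries", {
  for (seed in 1:5) {
    sizes <- withr::with_seed(seed, sample(2:6, 4, replace = TRUE))
    lib <- make_synthetic_library(4, sizes, seed = seed)
    ext <- expand_library(lib, k = 1)
    added <- length(ext$templates) - length(lib$templates)
    expect_lte(added, length(lib$templates) * max(sizes))
    # subtemplate completeness
    for (t in lib$templates) {
      if (sitematch:::template_size(t) - 1L < 2L) next
      subs <- Filter(function(s) identical(s$parent_template, t$template_id),
                     ext$templates)
      expect_setequal(vapply(subs, `[[`, "", "excluded_residue"),
                      sitematch:::point_ids(t$points))
    }
  }
})

test_that("k=2 expansion enumerates all size n-2 subsets", {
  t5 <- make_template(5, seed = 9)
  ext <- expand_library(template_library(list(t5)), k = 2, min_size = 2)
  expect_equal(length(ext$templates), 1L + choose(5, 2))
})

test_that("library files round-trip losslessly, lineage included", {
  lib <- expand_library(make_synthetic_library(3, c(3, 4, 2), seed = 10))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_library(lib, path)
  lib2 <- read_library(path)
  expect_equal(names(lib2$templates), names(lib$templates))
  for (id in names(lib$templates)) {
    a <- lib$templates[[id]]; b <- lib2$templates[[id]]
    expect_equal(b$points$aa, a$points$aa)
    expect_equal(as.matrix(b$points[, 5:10]), as.matrix(a$points[, 5:10]))
    expect_equal(b$parent_template, a$parent_template)
    expect_equal(b$excluded_residue, a$excluded_residue)
    expect_equal(b$family_id, a$family_id)
  }
})

test_that("truncated or foreign library files raise format errors", {
  lib <- make_synthetic_library(2, 3, seed = 11)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_library(lib, path)
  lines <- readLines(path)
  writeLines(lines[1:2], path)  # one template missing
  expect_error(read_library(path), class = "sitematch_format_error")
  writeLines(c("{\"format\": \"other\"}", lines[-1]), path)
  expect_error(read_library(path), class = "sitematch_format_error")
})
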