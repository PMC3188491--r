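# Template reading, annotation, and pseudomodel construction.

test_that("PDB round-trip preserves coordinates and chain selection works", {
  f <- fixture_fold()
  dir <- withr::local_tempdir()
  write_template_pdb(f$template, file.path(dir, "t.pdb"))
  ts <- read_pdb(file.path(dir, "t.pdb"), "A")
  expect_equal(length(ts), length(f$template))
  expect_equal(ts$sequence, f$template$sequence)
  expect_equal(ts$xyz$ca, f$template$xyz$ca, tolerance = 2e-3)
  expect_equal(ts$xyz$cb, f$template$xyz$cb, tolerance = 2e-3)
  expect_error(read_pdb(file.path(dir, "t.pdb"), "B"), "chain")
})

test_that("HETATM records and other chains are excluded", {
  pdbf <- system.file("examples/1hel.pdb", package = "bio3d")
  ts <- read_pdb(pdbf, "A")
  expect_true(all(ts$sequence %in% subalign:::AA20))
  expect_gt(length(ts), 100)
  # all residues carry CA
  expect_false(anyNA(ts$xyz$ca))
})

test_that("tetrahedral CB placement reproduces real side-chain geometry", {
  pdbf <- system.file("examples/1hel.pdb", package = "bio3d")
  ts <- read_pdb(pdbf, "A")
  have <- which(!is.na(ts$xyz$cb[, 1]) & !is.na(ts$xyz$n[, 1]) &
                  !is.na(ts$xyz$c[, 1]))
  err <- vapply(have, function(i)
    sqrt(sum((place_cb(ts$xyz$n[i, ], ts$xyz$ca[i, ], ts$xyz$c[i, ]) -
                ts$xyz$cb[i, ])^2)), 0)
  expect_lt(median(err), 0.15)
  expect_lt(max(err), 0.5)
})

test_that("DSSP parsing maps codes, enforces the run-length floor, and scales burial", {
  dir <- withr::local_tempdir()
  aa <- strsplit("AAAAAAALLLL", "")[[1]]
  ss <- strsplit("HHHHH  EEEE", "")[[1]]
  acc <- c(0, 10, 20, 129, 50, 60, 70, 0, 50, 100, 201)
  p <- write_dssp_fixture(file.path(dir, "a.dssp"), aa, ss, acc)
  d <- read_dssp(p)
  expect_equal(d$sse$kind, c("H", "E"))
  expect_equal(d$sse$start, c(1L, 8L))
  expect_equal(d$sse$end, c(5L, 11L))
  # ACC equal to the residue maximum -> burial 0; ACC 0 -> burial 1
  expect_equal(d$burial[4], 0)
  expect_equal(d$burial[11], 0)
  expect_equal(d$burial[1], 1)
  # run of length 2 is discarded
  ss2 <- strsplit("EE         ", "")[[1]]
  p2 <- write_dssp_fixture(file.path(dir, "b.dssp"), aa, ss2, acc)
  expect_equal(nrow(read_dssp(p2)$sse), 0L)
  # malformed header
  writeLines(c("not", "a dssp file"), file.path(dir, "c.dssp"))
  expect_error(read_dssp(file.path(dir, "c.dssp")), "DSSP")
})

test_that("DSSP annotation is rejected on sequence mismatch", {
  dir <- withr::local_tempdir()
  f <- fixture_fold()
  L <- length(f$template)
  aa <- rep("A", L)   # wrong sequence on purpose
  p <- write_dssp_fixture(file.path(dir, "m.dssp"), aa,
                          rep("H", L), rep(10, L))
  expect_error(annotate_template(f$template, dssp = p), "mismatch")
})

test_that("geometric SSE assignment recovers ideal elements and rejects coil", {
  # isolated ideal helix
  hx <- subalign:::element_ca("H", 12, 0, 1)
  ts <- template_structure(paste(rep("A", 12), collapse = ""), hx)
  g <- assign_sse_geometric(ts)
  expect_equal(nrow(g), 1L)
  expect_equal(g$kind, "H")
  expect_lte(g$start, 2L)
  expect_gte(g$end, 11L)
  # isolated ideal strand
  st <- subalign:::element_ca("E", 8, 0, 1)
  ts2 <- template_structure(paste(rep("V", 8), collapse = ""), st)
  g2 <- assign_sse_geometric(ts2)
  expect_equal(g2$kind, "E")
  # random coil: self-avoiding 3.8 A walk
  set.seed(4)
  ca <- matrix(0, 25, 3)
  for (i in 2:25) {
    repeat {
      s <- rnorm(3); s <- 3.8 * s / sqrt(sum(s^2))
      cand <- ca[i - 1, ] + s
      if (i < 3 || sqrt(sum((cand - ca[i - 2, ])^2)) > 4.5) break
    }
    ca[i, ] <- cand
  }
  ts3 <- template_structure(paste(rep("G", 25), collapse = ""), ca)
  expect_equal(nrow(assign_sse_geometric(ts3)), 0L)
})

test_that("geometric SSE labels agree with fixture ground truth", {
  tot <- 0L; agr <- 0L
  cases <- list(list("HHHH", 10), list("EEEE", 7),
                list("EEHH", c(7, 7, 10, 10)), list("HEEH", c(10, 7, 7, 10)))
  for (s in 1:5) for (cs in cases) {
    f <- make_fold(fold_spec(cs[[1]], cs[[2]]), seed = s)
    ts <- f$template
    tl <- sse_labels(ts$sse, length(ts))
    gl <- sse_labels(assign_sse_geometric(ts), length(ts))
    tot <- tot + length(tl)
    agr <- agr + sum(tl == gl)
  }
  expect_gte(agr / tot, 0.95)
})

test_that("sheet topology identifies paired and core strands", {
  f3 <- make_fold(fold_spec("EEE", 7), seed = 2)
  sh <- f3$template$sheet
  expect_equal(nrow(sh$pairs), 2L)
  expect_true(all(sh$pairs[, 2] - sh$pairs[, 1] == 1))
  expect_equal(sh$core, 2L)
  # all-helix bundle: no pairs
  fh <- make_fold(fold_spec("HHHH", 10), seed = 1)
  expect_equal(nrow(fh$template$sheet$pairs), 0L)
  # two-strand hairpin: one pair, no core strand
  f2 <- make_fold(fold_spec("EE", 7), seed = 3)
  expect_equal(nrow(f2$template$sheet$pairs), 1L)
  expect_length(f2$template$sheet$core, 0L)
})

test_that("burial is in [0,1], near zero for isolated residues, high in cores", {
  f <- fixture_fold()
  b <- f$template$burial
  expect_true(all(b >= 0 & b <= 1))
  # single isolated residue is fully exposed
  one <- template_structure("L", matrix(c(0, 0, 0), 1, 3),
                            n = matrix(c(-1.2, 0.5, 0), 1),
                            c = matrix(c(1.2, 0.5, 0), 1))
  expect_lt(compute_burial(one), 0.1)
  # deterministic
  expect_identical(compute_burial(f$template), compute_burial(f$template))
  # central residues of the fold are substantially buried
  mid <- which(!is.na(f$template$sse_id))
  expect_gte(max(b[mid]), 0.6)
})

test_that("pseudomodels copy template geometry and synthesize glycine CB", {
  f <- fixture_fold()
  ts <- f$template
  L <- length(ts)
  path <- cbind(1:L, 1:L)
  pm <- build_pseudomodel(ts, path, ts$sequence)
  expect_equal(nrow(pm$ca), L)
  expect_equal(pm$ca, ts$xyz$ca)
  expect_equal(pm$q_aa, ts$sequence)
  # empty alignment -> empty pseudomodel
  pm0 <- build_pseudomodel(ts, matrix(0L, 0, 2), ts$sequence)
  expect_length(pm0$t_idx, 0L)
  # pair count always equals path length
  sub <- path[seq(1, L, by = 3), , drop = FALSE]
  expect_equal(length(build_pseudomodel(ts, sub, ts$sequence)$t_idx), nrow(sub))
  # glycine query on a residue with known CB: synthesized pseudo-CB close
  q <- ts$sequence; q[5] <- "G"
  pm2 <- build_pseudomodel(ts, path, q)
  expect_lt(sqrt(sum((pm2$cb[5, ] - ts$xyz$cb[5, ])^2)), 0.2)
  # non-monotone path -> error
  bad <- rbind(c(2L, 5L), c(1L, 6L))
  expect_error(build_pseudomodel(ts, bad, ts$sequence), "increasing")
})

test_that("annotation JSON cache round-trips", {
  f <- fixture_fold()
  dir <- withr::local_tempdir()
  p <- file.path(dir, "ann.json")
  write_annotation_json(f$template, p)
  bare <- template_structure(f$template$sequence, f$template$xyz$ca,
                             f$template$xyz$n, f$template$xyz$c,
                             f$template$xyz$cb)
  ts <- read_annotation_json(bare, p)
  expect_equal(ts$sse, f$template$sse)
  expect_equal(ts$sheet$pairs, f$template$sheet$pairs)
  expect_equal(ts$burial, f$template$burial, tolerance = 1e-4)
})

test_that("chain breaks split the structure with a warning", {
  ca <- rbind(matrix(c(0, 0, 0, 3.8, 0, 0, 7.6, 0, 0), 3, 3, byrow = TRUE),
              matrix(c(50, 0, 0, 53.8, 0, 0), 2, 3, byrow = TRUE))
  expect_warning(ts <- template_structure("AAAAA", ca), "chain break")
  expect_equal(length(ts), 3L)
})
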