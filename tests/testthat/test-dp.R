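# Dynamic-programming kernels and the corridor finishing step.

test_that("optimal alignment of identical sequences is the identity path", {
  f <- fixture_fold()
  ts <- f$template
  q <- paste(ts$sequence, collapse = "")
  p <- optimal_align(q, ts)
  expect_equal(p[, 1], p[, 2], ignore_attr = TRUE)
  expect_equal(nrow(p), length(ts))
  expect_equal(attr(p, "dp_score"),
               score_path(p, q, ts))
})

test_that("optimal alignment matches the exhaustive oracle on tiny instances", {
  mod <- load_substitution_matrix()
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(3:6, 1); m <- sample(3:6, 1)
    q <- random_seq(n); t <- random_seq(m)
    S <- subalign:::score_grid(mod, q, t)
    for (ef in c(TRUE, FALSE)) {
      gp <- gap_scheme(open_x = sample(0:4, 1), ext_x = 1, ends_free = ef)
      ap <- c(oracle_all_paths(n, m), list(matrix(0L, 0, 2)))
      sc <- vapply(ap, oracle_score, 0, S, gp$open_x, gp$ext_x,
                   gp$open_y, gp$ext_y, ef)
      p <- optimal_align(q, t, mod, gp)
      expect_equal(attr(p, "dp_score"), max(sc))
    }
  }
})

test_that("all-negative scorers with free ends allow an empty aligned core", {
  mod <- load_substitution_matrix()
  # tryptophan against prolines scores negative everywhere
  p <- optimal_align("WWWW", "PPPP", mod, gap_scheme(ends_free = TRUE))
  expect_equal(nrow(p), 0L)
  expect_equal(attr(p, "dp_score"), 0)
})

test_that("delta-suboptimal ensembles equal the oracle in membership and score", {
  mod <- load_substitution_matrix()
  set.seed(32)
  for (rep in 1:20) {
    n <- sample(3:6, 1); m <- sample(3:6, 1)
    q <- random_seq(n); t <- random_seq(m)
    ef <- rep %% 2 == 0
    gp <- gap_scheme(open_x = 2, ext_x = 1, ends_free = ef)
    S <- subalign:::score_grid(mod, q, t)
    ap <- c(oracle_all_paths(n, m), if (!ef) list(matrix(0L, 0, 2)))
    sc <- vapply(ap, oracle_score, 0, S, 2, 1, 2, 1, ef)
    delta <- runif(1, 0, 5)
    keep <- sc >= max(sc) - delta - 1e-9
    got <- waterman_suboptimal(q, t, mod, gp, delta = delta, max_n = 1e5)
    expect_setequal(vapply(got$paths, path_key, ""),
                    vapply(ap[keep], path_key, ""))
    # scores re-verify exactly
    for (k in seq_along(got$paths)) {
      expect_equal(got$table$dp_score[k],
                   score_path(got$paths[[k]], q, t, mod, gp))
    }
  }
})

test_that("delta = 0 returns exactly the co-optimal set, truncation the top n", {
  mod <- load_substitution_matrix()
  w <- waterman_suboptimal("ARN", "ARN", mod, delta = 0, max_n = 100)
  expect_equal(length(w$paths), 1L)
  expect_equal(w$paths[[1]][, 1], 1:3, ignore_attr = TRUE)
  # huge delta, truncation at max_n keeps the highest-scoring paths
  w2 <- waterman_suboptimal("ARND", "ARND", mod, delta = 1e6, max_n = 10)
  expect_equal(length(w2$paths), 10L)
  expect_true(all(diff(w2$table$dp_score) <= 1e-9))
})

test_that("constrained ensembles are subsets of unconstrained at equal delta", {
  mod <- load_substitution_matrix()
  set.seed(33)
  for (rep in 1:6) {
    f <- make_fold(fold_spec("HH", c(6, 6), loop_lengths = 3), seed = 40 + rep)
    ts <- f$template
    q <- random_seq(length(ts) + sample(-3:3, 1))
    delta <- runif(1, 1, 6)
    un <- waterman_suboptimal(q, ts, mod, delta = delta, max_n = 1e4)
    cn <- constrained_waterman(q, ts, mod, delta = delta, max_n = 1e4)
    ku <- vapply(un$paths, path_key, "")
    kc <- vapply(cn$paths, path_key, "")
    expect_true(all(kc %in% ku))
    # the optimum is always present
    expect_equal(max(cn$table$dp_score), max(un$table$dp_score))
  }
})

test_that("a template without SSEs admits no branch points", {
  mod <- load_substitution_matrix()
  f <- fixture_fold()
  ts <- f$template
  no_sse <- ts
  no_sse$sse <- ts$sse[0, ]
  set.seed(34)
  q <- random_seq(30)
  cn <- constrained_waterman(q, no_sse, mod, delta = 10, max_n = 100,
                             sse = no_sse$sse)
  expect_equal(length(cn$paths), 1L)
  p <- optimal_align(q, ts, mod)
  expect_equal(path_key(cn$paths[[1]]), path_key(p))
})

test_that("corridors widen fragments by the margin and free the loops", {
  f <- fixture_fold()
  ts <- f$template
  fa <- list(frags = data.frame(sse = 1L, t_start = ts$sse$start[1],
                                q_start = ts$sse$start[1] + 2L,
                                len = ts$sse$end[1] - ts$sse$start[1] + 1L),
             covered_sses = 1L)
  fa <- subalign:::materialize_fas(list(fa))[[1]]
  co <- corridor_from_fragment_alignment(fa, ts, 60, margin = 3L)
  j <- ts$sse$start[1] + 2L
  expect_equal(co$hi[j] - co$lo[j] + 1L, 7L)         # band of width 7
  expect_equal(co$lo[j], j + 2L - 3L)
  # uncovered SSEs are excluded from matching
  expect_false(any(co$match_allowed[ts$sse$start[2]:ts$sse$end[2]]))
  # margin 0 pins the band to the diagonal
  co0 <- corridor_from_fragment_alignment(fa, ts, 60, margin = 0L)
  expect_equal(co0$lo[j], co0$hi[j])
  # two fragments: the loop region spans between their query ends
  fa2 <- list(frags = data.frame(sse = c(1L, 3L),
                                 t_start = ts$sse$start[c(1, 3)],
                                 q_start = ts$sse$start[c(1, 3)] + c(0L, 10L),
                                 len = 4L),
              covered_sses = c(1L, 3L))
  fa2 <- subalign:::materialize_fas(list(fa2))[[1]]
  co2 <- corridor_from_fragment_alignment(fa2, ts, 80, margin = 3L)
  gap <- (ts$sse$start[1] + 4L):(ts$sse$start[3] - 1L)
  expect_true(all(co2$lo[gap] >= ts$sse$start[1] + 3L - 3L))
  expect_true(all(co2$hi[gap] <= ts$sse$start[3] + 10L + 3L))
})

test_that("finishing a self-alignment fragment set recovers the identity on SSEs", {
  f <- fixture_fold()
  ts <- f$template
  q <- ts$sequence
  pot <- fixture_potential()
  mod <- load_substitution_matrix()
  w <- ts$sse$end - ts$sse$start + 1
  fa <- list(frags = data.frame(sse = ts$sse$index, t_start = ts$sse$start,
                                q_start = ts$sse$start, len = w),
             covered_sses = ts$sse$index)
  fa <- subalign:::materialize_fas(list(fa))[[1]]
  p <- finish_alignment(fa, ts, q, mod, pot, s4_config())
  sid <- ts$sse_id
  on_sse <- p[!is.na(sid[p[, 1]]), , drop = FALSE]
  expect_equal(on_sse[, 1], on_sse[, 2], ignore_attr = TRUE)
  expect_equal(sum(!is.na(sid)), nrow(on_sse))
  # the finished path lies inside its corridor
  co <- corridor_from_fragment_alignment(fa, ts, length(q), 3L)
  expect_true(all(p[, 2] >= co$lo[p[, 1]] & p[, 2] <= co$hi[p[, 1]]))
})

test_that("rank_and_emit deduplicates SSE-identical paths and honors N", {
  f <- fixture_fold()
  ts <- f$template
  q <- ts$sequence
  pot <- fixture_potential()
  mod <- load_substitution_matrix()
  ens <- suppressWarnings(s4_align(ts, q, N = 1, potential = pot))
  expect_equal(length(ens), 1L)
  ens10 <- suppressWarnings(s4_align(ts, q, N = 10, potential = pot))
  sid <- ts$sse_id
  keys <- vapply(ens10$paths, function(p) {
    s <- !is.na(sid[p[, 1]])
    paste(p[s, 1], p[s, 2], collapse = ";")
  }, "")
  expect_false(any(duplicated(keys)))
  # asking for more than exists warns and returns what there is
  expect_warning(s4_align(ts, q, N = 5000, potential = pot), "unique")
})

test_that("ensemble FASTA output round-trips the paths", {
  f <- fixture_fold()
  ts <- f$template
  q <- ts$sequence
  pot <- fixture_potential()
  ens <- suppressWarnings(s4_align(ts, q, N = 5, potential = pot))
  dir <- withr::local_tempdir()
  p <- file.path(dir, "ens.fasta")
  write_ensemble_fasta(ens, ts, q, p)
  back <- read_ensemble_fasta(p)
  expect_equal(length(back), length(ens))
  for (k in seq_along(back$paths)) {
    expect_equal(path_key(back$paths[[k]]),
                 path_key(subalign:::path_matrix(ens$paths[[k]])))
  }
})
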