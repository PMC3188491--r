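# Fragment-alignment enumeration and the modelability checks.

frag_row <- function(sse, t_start, q_start, len) {
  data.frame(sse = sse, t_start = t_start, q_start = q_start, len = len,
             raw = len, norm = 1, tier = "primary", origin = "top")
}

test_that("the loop-stretch rule follows the 3.3 A-per-residue bound", {
  f <- fixture_fold()
  ts <- f$template
  # synthetic distances: place two fragment endpoints at known CA distance
  d_act <- function(tp, tf) sqrt(sum((ts$xyz$ca[tf, ] - ts$xyz$ca[tp, ])^2))
  a <- frag_row(1, 5, 5, 3)      # ends at template 7, query 7
  # large query gap: q_f - q_p = 10 always passes short distances
  b10 <- frag_row(2, 20, 17, 3)  # q_f = 17 -> gap 10
  expect_identical(check_loop_length(a, b10, ts),
                   3.3 * 10 >= d_act(7, 20))
  # tiny query gap over a long distance fails
  b1 <- frag_row(2, 20, 9, 3)    # q_f = 9 -> gap 2
  expect_identical(check_loop_length(a, b1, ts), 3.3 * 2 >= d_act(7, 20))
  # directly contiguous fragments always pass (no loop to bridge)
  adj <- frag_row(2, 8, 8, 3)
  expect_true(check_loop_length(a, adj, ts))
  # out-of-order fragments are a caller error
  expect_error(check_loop_length(b10, a, ts), "order")
})

test_that("pure arithmetic of the stretch rule matches the stated examples", {
  # stand-alone template whose loop-flanking CA atoms sit exactly d apart
  mk <- function(d) {
    ca <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(3.8 + d, 0, 0),
                c(7.6 + d, 0, 0))
    suppressWarnings(template_structure("AAAA", ca, chain_break = 1e6))
  }
  a <- frag_row(1, 1, 1, 2); a$len <- 2
  # q_f - q_p = 10, d = 20 -> TRUE (33 >= 20)
  b <- frag_row(2, 3, 12, 2)
  expect_true(check_loop_length(a, b, mk(20)))
  # q_f - q_p = 4, d = 20 -> FALSE (13.2 < 20)
  b2 <- frag_row(2, 3, 6, 2)
  expect_false(check_loop_length(a, b2, mk(20)))
  # adjacent fragments, q_f - q_p = 1, d ~ 3.8 -> TRUE
  b3 <- frag_row(2, 3, 3, 2)
  expect_true(check_loop_length(a, b3, mk(3.8)))
})

test_that("coverage requires 10% of the shorter sequence", {
  expect_false(check_coverage(5, 60, 100))
  expect_true(check_coverage(6, 60, 100))
  expect_false(check_coverage(0, 60, 100))
  # boundary: exactly 10% passes
  expect_true(check_coverage(6, 60, 200))
})

test_that("strand rules: pairing preserved and core strands forced", {
  sheet3 <- list(pairs = rbind(c(1L, 2L), c(2L, 3L)), core = 2L)
  expect_false(check_strand_rules(c(1L, 3L), sheet3))   # core missing
  expect_true(check_strand_rules(c(1L, 2L), sheet3))
  expect_true(check_strand_rules(c(1L, 2L, 3L), sheet3))
  # a lone covered strand has lost all partners: rejected
  expect_false(check_strand_rules(2L, sheet3))
  # an isolated covered strand whose partners are all uncovered fails
  expect_false(check_strand_rules(1L, sheet3))
  sheet2 <- list(pairs = rbind(c(1L, 2L)), core = integer(0))
  expect_false(check_strand_rules(1L, sheet2))
  # helix-only template: vacuously true
  expect_true(check_strand_rules(c(1L, 2L), list(pairs = matrix(0L, 0, 2),
                                                 core = integer(0))))
})

test_that("contact order compares pseudomodel to template at the 65% ratio", {
  f <- fixture_fold()
  ts <- f$template
  all_sse <- which(!is.na(ts$sse_id))
  # identity coverage -> ratio 1 -> pass
  expect_true(check_contact_order(all_sse, ts))
  # two far-apart SSEs only (1 and 4 of the HEEH fold are 20+ A apart)
  far <- which(ts$sse_id %in% c(1L, 4L))
  expect_false(check_contact_order(far, ts))
  # single-SSE template has contact order 0: always passes
  hx <- subalign:::element_ca("H", 12, 0, 1)
  one <- template_structure(paste(rep("A", 12), collapse = ""), hx)
  one$sse <- data.frame(kind = "H", start = 1L, end = 12L, index = 1L)
  one$sse_id <- subalign:::sse_id_vector(one$sse, 12)
  one <- subalign:::complete_cb(one)
  expect_true(check_contact_order(1:12, one))
})

test_that("enumeration equals the brute-force subset oracle on small pools", {
  f <- fixture_fold()
  ts <- f$template
  mod <- load_substitution_matrix()
  cfg <- s4_config(min_coverage_frac = 0, contact_order_ratio_min = 0)
  set.seed(21)
  for (rep in 1:8) {
    q <- random_seq(45)
    sim <- build_similarity_matrix(q, ts, mod)
    pool <- subalign:::enumerate_all_fragments(sim, 3)
    # random small pool: <= 3 fragments in each of <= 4 SSEs
    keep <- unlist(lapply(split(seq_len(nrow(pool)), pool$sse), function(r)
      sample(r, min(3, length(r)))))
    pool <- pool[keep, , drop = FALSE]
    pool$tier <- "primary"; pool$origin <- "top"
    fas <- enumerate_fragment_alignments(pool, ts, q, cfg)
    used <- attr(fas, "fragments")
    got <- sort(vapply(fas, function(x)
      paste(used$sse[x$ids], used$t_start[x$ids], used$q_start[x$ids],
            collapse = "|"), ""))
    # oracle: all subsets, filter by monotonicity + loop rule + strand rules
    n <- nrow(used)
    want <- character(0)
    for (mask in 1:(2^n - 1)) {
      ids <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
      fr <- used[ids, , drop = FALSE]
      fr <- fr[order(fr$sse), , drop = FALSE]
      ok <- !anyDuplicated(fr$sse)
      if (ok && nrow(fr) > 1) {
        for (k in seq_len(nrow(fr) - 1)) {
          a <- fr[k, ]; b <- fr[k + 1, ]
          if (b$q_start <= a$q_start + a$len - 1 ||
              !check_loop_length(a, b, ts)) { ok <- FALSE; break }
        }
      }
      if (ok) ok <- check_strand_rules(fr$sse, ts$sheet)
      if (ok) want <- c(want, paste(fr$sse, fr$t_start, fr$q_start,
                                    collapse = "|"))
    }
    expect_setequal(got, sort(want))
  }
})

test_that("one fragment per SSE with all rules passing yields all subsets", {
  f3 <- make_fold(fold_spec("HHH", 10), seed = 3)
  ts <- f3$template
  q <- paste(ts$sequence, collapse = "")
  mod <- load_substitution_matrix()
  sim <- build_similarity_matrix(q, ts, mod)
  pool <- subalign:::enumerate_all_fragments(sim, 3)
  # keep only the identity diagonal of each SSE
  pool <- pool[pool$q_start == pool$t_start &
                 pool$len == (ts$sse$end[pool$sse] - ts$sse$start[pool$sse] + 1), ]
  pool$tier <- "primary"; pool$origin <- "top"
  cfg <- s4_config(min_coverage_frac = 0, contact_order_ratio_min = 0)
  fas <- enumerate_fragment_alignments(pool, ts, q, cfg)
  expect_length(fas, 7L)          # all non-empty subsets of 3 fragments
  expect_equal(attr(fas, "path_count"), 7)
})

test_that("the enumeration cap halts early but returns results", {
  f <- fixture_fold()
  ts <- f$template
  set.seed(22)
  q <- random_seq(40)
  mod <- load_substitution_matrix()
  sim <- build_similarity_matrix(q, ts, mod)
  pool <- select_primary(subalign:::enumerate_all_fragments(sim, 3), 4L,
                         40, length(ts))
  cfg <- s4_config(max_enumerated = 10, min_coverage_frac = 0,
                   contact_order_ratio_min = 0)
  fas <- enumerate_fragment_alignments(pool, ts, q, cfg)
  expect_lte(attr(fas, "tallies")["enumerated"], 10)
  expect_gt(length(fas), 0L)
})

test_that("every returned fragment alignment re-verifies all checks", {
  f <- fixture_fold()
  ts <- f$template
  set.seed(23)
  q <- random_seq(40)
  mod <- load_substitution_matrix()
  sim <- build_similarity_matrix(q, ts, mod)
  pool <- select_primary(subalign:::enumerate_all_fragments(sim, 3), 2L,
                         40, length(ts))
  cfg <- s4_config()
  fas <- tryCatch(enumerate_fragment_alignments(pool, ts, q, cfg),
                  error = function(e) list())
  fas <- subalign:::materialize_fas(fas)
  for (x in fas) {
    expect_true(all(diff(x$aligned_t) > 0))
    expect_true(all(diff(x$aligned_q) > 0))
    expect_true(check_coverage(x$n_aligned, 40, length(ts)))
    expect_true(check_strand_rules(x$covered_sses, ts$sheet))
    expect_true(check_contact_order(x$aligned_t, ts))
    expect_false(anyDuplicated(x$covered_sses) > 0)
  }
})
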