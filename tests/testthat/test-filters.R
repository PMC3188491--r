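# Core contacts, the percentile gate, and redundancy removal.

# A hand-built two-helix template with controllable burial: burial is
# overwritten directly since the filter consumes the annotation, not the
# geometry.
two_leucines <- function(d = 5, burial = c(0.8, 0.8)) {
  ca <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(d, 0, 6), c(d + 3.8, 0, 6))
  ts <- suppressWarnings(template_structure("LALA", ca, chain_break = 1e9))
  ts <- subalign:::complete_cb(ts)
  # place CBs explicitly at controlled separation
  ts$xyz$cb[1, ] <- c(0, 1, 0)
  ts$xyz$cb[3, ] <- c(0, 1, d)
  ts$sse <- data.frame(kind = "H", start = c(1L, 3L), end = c(2L, 4L),
                       index = 1:2)
  ts$sse_id <- subalign:::sse_id_vector(ts$sse, 4)
  ts$burial <- c(burial[1], 0.1, burial[2], 0.1)
  ts
}

test_that("core contacts require burial, proximity, and hydrophobicity", {
  ts <- two_leucines(d = 5)
  cc <- find_core_contacts(ts)
  expect_equal(nrow(cc), 1L)
  expect_equal(cc[1, ], c(1L, 3L), ignore_attr = TRUE)
  # one partner exposed -> no contact
  expect_equal(nrow(find_core_contacts(two_leucines(burial = c(0.8, 0.3)))), 0L)
  # boundary: burial exactly 0.6 counts as buried
  expect_equal(nrow(find_core_contacts(two_leucines(burial = c(0.6, 0.6)))), 1L)
  # CB separation at 6 A is not within 6 A
  expect_equal(nrow(find_core_contacts(two_leucines(d = 6))), 0L)
  # polar partner -> no contact
  ts2 <- two_leucines()
  ts2$sequence[3] <- "S"
  expect_equal(nrow(find_core_contacts(ts2)), 0L)
  # glycine counts as hydrophobic via its pseudo-CB
  ts3 <- two_leucines()
  ts3$sequence[3] <- "G"
  expect_equal(nrow(find_core_contacts(ts3)), 1L)
})

test_that("preserved core contacts require aligned hydrophobic query pairs", {
  ts <- two_leucines()
  cc <- find_core_contacts(ts)
  path <- cbind(1:4, 1:4)
  # identity with hydrophobic query at both ends
  expect_equal(count_preserved(path, cc, c("V", "A", "I", "A")), 1L)
  # polar query residue breaks preservation
  expect_equal(count_preserved(path, cc, c("V", "A", "S", "A")), 0L)
  # unaligned contact end
  expect_equal(count_preserved(cbind(1:2, 1:2), cc, c("V", "A")), 0L)
  expect_equal(count_preserved(matrix(0L, 0, 2), cc, c("V")), 0L)
  # template self-alignment preserves every contact
  expect_equal(count_preserved(path, cc, ts$sequence), nrow(cc))
})

test_that("percentile gate applies the 66/90 double threshold", {
  # craft measures whose ranks are controlled: n = 101 evenly spread
  n <- 101
  base <- seq_len(n)
  m <- data.frame(preserved = base, query_energy = -base,
                  template_energy = -base)
  keep <- percentile_gate(m)
  r <- (base - 1) / (n - 1) * 100
  expect_identical(keep, r >= 66 & r >= 90)  # perfectly correlated measures
  # candidate with ranks (70, 70, 95): kept
  m2 <- m
  m2$preserved[71] <- m2$preserved[71]      # rank 70
  expect_true(percentile_gate(m2)[96])      # ranks (95,95,95)
  # one measure below 66 drops the candidate even if others are high
  m3 <- data.frame(preserved = c(base, 200), query_energy = c(-base, 100),
                   template_energy = c(-base, -200))
  expect_false(tail(percentile_gate(m3), 1))
  # no measure above 90 drops the candidate
  mid <- data.frame(preserved = base, query_energy = -rev(base),
                    template_energy = -base)
  k <- percentile_gate(mid)
  # the 71st candidate has ranks (70, 30, 70): dropped
  expect_false(k[71])
})

test_that("degenerate gates pass: tiny sets and constant measures", {
  one <- data.frame(preserved = 3, query_energy = -1, template_energy = -2)
  expect_true(all(percentile_gate(one)))
  m <- data.frame(preserved = rep(0, 50), query_energy = -seq_len(50),
                  template_energy = -seq_len(50))
  k <- percentile_gate(m)
  # constant measure cannot gate; the two informative ones still do
  expect_true(k[50])
  expect_false(k[10])
})

test_that("gate survivor fraction stays within the percentile bound", {
  set.seed(12)
  for (rep in 1:5) {
    m <- data.frame(preserved = rnorm(400), query_energy = rnorm(400),
                    template_energy = rnorm(400))
    frac <- mean(percentile_gate(m))
    expect_lte(frac, 0.34)
  }
})

test_that("redundancy removal collapses equivalent fragment alignments", {
  f <- fixture_fold()
  ts <- f$template
  mk_fa <- function(q_offsets, score) {
    fr <- data.frame(sse = seq_along(q_offsets),
                     t_start = ts$sse$start[seq_along(q_offsets)],
                     q_start = ts$sse$start[seq_along(q_offsets)] + q_offsets,
                     len = 4L)
    list(frags = fr, fa_score = score,
         aligned_t = unlist(lapply(seq_len(nrow(fr)), function(i)
           fr$t_start[i]:(fr$t_start[i] + 3L))),
         aligned_q = unlist(lapply(seq_len(nrow(fr)), function(i)
           fr$q_start[i]:(fr$q_start[i] + 3L))),
         covered_sses = fr$sse)
  }
  a <- mk_fa(c(0, 0, 0), 10)
  b <- mk_fa(c(0, 0, 0), 8)          # identical placement, lower score
  out <- remove_redundant(list(a, b), length(ts))
  expect_length(out, 1L)
  expect_equal(out[[1]]$fa_score, 10)
  # a shift of 5 on one fragment exceeds the shift bound: both kept
  cshift <- mk_fa(c(5, 0, 0), 7)
  out2 <- remove_redundant(list(a, cshift), length(ts))
  expect_length(out2, 2L)
  # different SSE sets never collapse
  d <- mk_fa(c(0, 0), 6)
  out3 <- remove_redundant(list(a, d), length(ts))
  expect_length(out3, 2L)
  # shifts within 4 but IAD >= 1 keeps both
  e <- mk_fa(c(4, 4, 4), 5)
  out4 <- remove_redundant(list(a, e), length(ts))
  expect_length(out4, 2L)
  # idempotence
  again <- remove_redundant(out4, length(ts))
  expect_equal(length(again), length(out4))
})

test_that("batched measures agree with direct per-alignment evaluation", {
  f <- fixture_fold()
  ts <- f$template
  pot <- fixture_potential()
  set.seed(13)
  q <- random_seq(40)
  mod <- load_substitution_matrix()
  sim <- build_similarity_matrix(q, ts, mod)
  pool <- select_primary(subalign:::enumerate_all_fragments(sim, 3), 2L,
                         40, length(ts))
  cfg <- s4_config(min_coverage_frac = 0, contact_order_ratio_min = 0)
  fas <- enumerate_fragment_alignments(pool, ts, q, cfg)
  core <- find_core_contacts(ts)
  meas <- subalign:::fa_measures(fas, ts, q, pot, core)
  mat <- subalign:::materialize_fas(fas)
  pick <- seq(1, length(mat), length.out = min(6, length(mat)))
  for (k in round(pick)) {
    x <- mat[[k]]
    path <- cbind(x$aligned_t, x$aligned_q)
    pm <- build_pseudomodel(ts, path, q)
    expect_equal(meas$query_energy[k], query_energy(pm, ts, pot),
                 tolerance = 1e-9)
    expect_equal(meas$template_energy[k],
                 template_energy(path, ts, pot), tolerance = 1e-9)
    expect_equal(meas$preserved[k], count_preserved(path, core, q))
  }
})
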