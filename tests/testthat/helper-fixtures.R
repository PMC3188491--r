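# Shared fixtures and independent oracles for the test suite.

# session-cached small potential (training is deterministic)
fixture_potential <- local({
  pot <- NULL
  function() {
    if (is.null(pot)) pot <<- default_potential(n_structures = 12, seed = 42)
    pot
  }
})

# Exhaustive oracle: every non-empty monotone pairing of an n-residue
# query with an m-residue template, as (t, q) matrices.
oracle_all_paths <- function(n, m) {
  res <- list()
  rec <- function(pairs, i0, j0) {
    for (i in i0:n) for (j in j0:m) {
      np <- rbind(pairs, c(j, i))
      res[[length(res) + 1]] <<- np
      if (i < n && j < m) rec(np, i + 1, j + 1)
    }
  }
  rec(matrix(0L, 0, 2), 1L, 1L)
  res
}

# Independent path scorer for the oracle (no package DP code involved).
oracle_score <- function(p, S, open_x, ext_x, open_y, ext_y, ends_free) {
  gc <- function(g, o, e) if (g > 0) o + g * e else 0
  if (nrow(p) == 0) {
    if (ends_free) return(0)
    return(-gc(ncol(S), open_x, ext_x) - gc(nrow(S), open_y, ext_y))
  }
  sc <- sum(S[cbind(p[, 2], p[, 1])])
  if (nrow(p) > 1) {
    dj <- diff(p[, 1]) - 1L
    di <- diff(p[, 2]) - 1L
    sc <- sc - sum(vapply(dj, gc, 0, open_x, ext_x)) -
      sum(vapply(di, gc, 0, open_y, ext_y))
  }
  if (!ends_free) {
    sc <- sc - gc(p[1, 1] - 1L, open_x, ext_x) -
      gc(p[1, 2] - 1L, open_y, ext_y) -
      gc(ncol(S) - p[nrow(p), 1], open_x, ext_x) -
      gc(nrow(S) - p[nrow(p), 2], open_y, ext_y)
  }
  sc
}

path_key <- function(p) {
  if (nrow(p) == 0) return("EMPTY")
  paste(p[, 1], p[, 2], sep = ":", collapse = ";")
}

random_seq <- function(n) paste(sample(subalign:::AA20, n, TRUE), collapse = "")

# per-residue SSE label string of a template
sse_labels <- function(sse, L) {
  v <- rep("-", L)
  for (k in seq_len(nrow(sse))) v[sse$start[k]:sse$end[k]] <- sse$kind[k]
  v
}

# Small annotated fold reused across tests.
fixture_fold <- local({
  f <- NULL
  function() {
    if (is.null(f)) f <<- make_fold(fold_spec("HEEH", c(10, 7, 7, 10)), seed = 5)
    f
  }
})

# A deterministic DSSP-format fixture writer (classic column layout).
write_dssp_fixture <- function(path, aa, ss, acc, chain = "A",
                               bp1 = NULL, bp2 = NULL) {
  n <- length(aa)
  if (is.null(bp1)) bp1 <- rep(0L, n)
  if (is.null(bp2)) bp2 <- rep(0L, n)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "==== Secondary Structure Definition by the program DSSP ====",
    "REFERENCE FIXTURE",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N    N-H-->O    O-->H-N    TCO  KAPPA ALPHA  PHI   PSI    X-CA   Y-CA   Z-CA"
  ), con)
  for (i in seq_len(n)) {
    # exact classic columns: 1-5 idx, 6-10 resno, 12 chain, 14 aa,
    # 17 ss, 26-29 bp1, 30-33 bp2, 35-38 acc
    line <- sprintf("%5d%5d %s %s  %s        %4d%4d %4d",
                    i, i, chain, aa[i], ss[i], bp1[i], bp2[i], acc[i])
    writeLines(line, con)
  }
  invisible(path)
}
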