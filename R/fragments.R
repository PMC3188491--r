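# Fragment selection inside template SSE columns.
#
# A fragment is an ungapped diagonal alignment of a query segment to one
# template SSE column, spanning the full column width (truncated at the
# matrix edges, never below the minimum fragment length).  Primary
# fragments are the top-ranked diagonals per column by length-normalized
# score; secondary fragments fill the regions between primaries in
# non-consecutive SSEs (by diagonal adjacency, core-strand necessity, or
# plain score).

#' Enumerate all feasible fragments of one SSE column
#'
#' One fragment per diagonal of the column: each spans the full SSE
#' width, truncated at the query edges; diagonals truncated below
#' `min_len` are dropped.  Raw score is the sum of cell scores along the
#' diagonal; the normalized score divides by fragment length.
#'
#' @param sim a [build_similarity_matrix()] result.
#' @param sse_index SSE column (row of `sim$column_bounds`).
#' @param min_len minimum fragment length.
#' @return data frame with columns `sse`, `t_start`, `q_start`, `len`,
#'   `raw`, `norm`, `tier`, `origin`.
#' @export
enumerate_column_fragments <- function(sim, sse_index, min_len = 3L) {
  sse <- sim$column_bounds[sim$column_bounds$index == sse_index, ]
  stopifnot(nrow(sse) == 1)
  Lq <- nrow(sim$values)
  t0 <- sse$start; t1 <- sse$end
  w <- t1 - t0 + 1L
  out <- list()
  # off = q_start - t_start; every diagonal whose overlap with the query
  # can reach min_len
  for (off in seq(min_len - t1, Lq - t0 - min_len + 1L)) {
    qs <- t0 + off; qe <- t1 + off
    q_lo <- max(qs, 1L); q_hi <- min(qe, Lq)
    len <- q_hi - q_lo + 1L
    if (len < min_len) next
    ts_ <- q_lo - off
    qi <- q_lo:q_hi; ti <- ts_:(ts_ + len - 1L)
    raw <- sum(sim$values[cbind(qi, ti)])
    out[[length(out) + 1]] <- data.frame(
      sse = sse_index, t_start = ts_, q_start = q_lo, len = len,
      raw = raw, norm = raw / len,
      tier = NA_character_, origin = NA_character_)
  }
  if (!length(out))
    return(data.frame(sse = integer(0), t_start = integer(0),
                      q_start = integer(0), len = integer(0),
                      raw = numeric(0), norm = numeric(0),
                      tier = character(0), origin = character(0)))
  do.call(rbind, out)
}

# All fragments of all columns.
enumerate_all_fragments <- function(sim, min_len = 3L) {
  frs <- lapply(sim$column_bounds$index, enumerate_column_fragments,
                sim = sim, min_len = min_len)
  do.call(rbind, frs)
}

# Deterministic ranking within one SSE: by normalized score, ties broken
# by centrality of the diagonal, then by smaller q_start.
order_fragments <- function(fr, Lq, Lt) {
  center <- (Lq - Lt) / 2
  diag_off <- fr$q_start - fr$t_start
  order(-fr$norm, abs(diag_off - center), fr$q_start)
}

#' Select primary fragments
#'
#' Marks the top `k_per_sse` fragments of every SSE column (by
#' length-normalized score) as primary.  Ties are broken by the more
#' central diagonal, then by smaller query start.  Every SSE with at
#' least one feasible diagonal contributes at least one primary fragment.
#'
#' @param pool data frame from [enumerate_column_fragments()] /
#'   `enumerate_all_fragments`.
#' @param k_per_sse primaries per SSE (`k = 1` gives exactly the single
#'   best-normalized fragment per column).
#' @param Lq,Lt query and template lengths (for the centrality
#'   tie-break).
#' @return the pool with `tier` set to "primary" on selected rows.
#' @export
select_primary <- function(pool, k_per_sse = 4L, Lq, Lt) {
  stopifnot(nrow(pool) > 0)
  for (s in unique(pool$sse)) {
    rows <- which(pool$sse == s)
    ord <- rows[order_fragments(pool[rows, ], Lq, Lt)]
    take <- utils::head(ord, k_per_sse)
    pool$tier[take] <- "primary"
    pool$origin[take] <- "top"
  }
  pool
}

#' Select secondary fragments
#'
#' For every pair of already-selected fragments lying in non-consecutive
#' SSEs (in compatible query order), fills each intervening SSE with:
#' the best fragment on a nearby diagonal of a flanking selected fragment
#' (origin "adjacent", diagonal offset within `adjacent_tol`); the best
#' fragment of any intervening core strand (origin "core"); and the top
#' `score_extra` remaining fragments by normalized score (origin
#' "score").  Repeats until no region between non-consecutive selected
#' fragments is missing a candidate.  Pool growth stops once the total
#' number of enumerable fragment alignments would exceed
#' `max_total_alignments`.
#'
#' @param pool full fragment pool with primaries marked
#'   ([select_primary()]).
#' @param template annotated template (for core strands and the
#'   path-count cap).
#' @param config an [s4_config()].
#' @param Lq query length.
#' @return the pool with secondary selections marked; attribute
#'   `"path_count"` carries the final enumerable-alignment count.
#' @export
select_secondary <- function(pool, template, config, Lq) {
  core <- template$sheet$core %||% integer(0)
  sel <- function() which(!is.na(pool$tier))
  guard <- 0L
  repeat {
    guard <- guard + 1L
    added <- integer(0)
    cur <- sel()
    cf <- pool[cur, ]
    ord <- cur[order(cf$sse, cf$q_start)]
    # candidate additions collected with priority: adjacent > core > score
    cand <- list()
    for (a in ord) for (b in ord) {
      if (pool$sse[b] - pool$sse[a] < 2) next
      qa_end <- pool$q_start[a] + pool$len[a] - 1L
      if (pool$q_start[b] <= qa_end) next          # incompatible order
      for (s in (pool$sse[a] + 1L):(pool$sse[b] - 1L)) {
        rows <- which(pool$sse == s & is.na(pool$tier) &
                        pool$q_start > qa_end &
                        pool$q_start + pool$len - 1L < pool$q_start[b])
        in_region <- rows
        if (!length(in_region)) next
        # (a) adjacent: neighboring SSE of a flank, similar diagonal
        for (fl in c(a, b)) {
          if (abs(pool$sse[fl] - s) != 1L) next
          doff <- (pool$q_start[in_region] - pool$t_start[in_region]) -
            (pool$q_start[fl] - pool$t_start[fl])
          adj <- in_region[abs(doff) <= config$adjacent_diagonal_tol]
          if (length(adj)) {
            best <- adj[which.max(pool$norm[adj])]
            cand[[length(cand) + 1]] <- list(row = best, pri = 1, origin = "adjacent")
          }
        }
        # (b) core strand: must stay representable
        if (s %in% core) {
          best <- in_region[which.max(pool$norm[in_region])]
          cand[[length(cand) + 1]] <- list(row = best, pri = 2, origin = "core")
        }
        # (c) extra by score
        extra <- in_region[order(-pool$norm[in_region])]
        extra <- utils::head(extra, config$score_extra)
        for (e in extra)
          cand[[length(cand) + 1]] <- list(row = e, pri = 3, origin = "score")
      }
    }
    if (length(cand)) {
      pri <- vapply(cand, `[[`, 0, "pri")
      nrm <- vapply(cand, function(x) pool$norm[x$row], 0)
      for (k in order(pri, -nrm)) {
        r <- cand[[k]]$row
        if (!is.na(pool$tier[r])) next
        pool$tier[r] <- "secondary"
        pool$origin[r] <- cand[[k]]$origin
        added <- c(added, r)
      }
    }
    if (!length(added) || guard > 20L) break
  }

  # enforce the total-alignment cap by trimming lowest-priority additions:
  # secondaries first (score before core before adjacent), then excess
  # primaries; the single best primary of each SSE is never removed
  count <- count_fragment_alignments(pool[sel(), ], template)
  if (count > config$max_total_alignments) {
    cur <- sel()
    is_primary <- pool$tier[cur] == "primary"
    prim <- cur[is_primary]
    best_per_sse <- vapply(split(prim, pool$sse[prim]), function(rows)
      rows[which.max(pool$norm[rows])], 0L)
    extra_prim <- setdiff(prim, best_per_sse)
    sec <- cur[!is_primary]
    sec <- sec[order(match(pool$origin[sec], c("adjacent", "core", "score")),
                     -pool$norm[sec])]
    extra_prim <- extra_prim[order(-pool$norm[extra_prim])]
    keepable <- c(sec, extra_prim)        # droppable from the tail
    lo <- 0L; hi <- length(keepable)
    while (lo < hi) {
      mid <- (lo + hi + 1L) %/% 2L
      keep <- c(best_per_sse, keepable[seq_len(mid)])
      if (count_fragment_alignments(pool[keep, ], template) <=
          config$max_total_alignments) lo <- mid else hi <- mid - 1L
    }
    drop <- if (lo < length(keepable)) keepable[(lo + 1L):length(keepable)]
            else integer(0)
    pool$tier[drop] <- NA_character_
    pool$origin[drop] <- NA_character_
    count <- count_fragment_alignments(pool[sel(), ], template)
  }
  attr(pool, "path_count") <- count
  pool
}

#' Write a fragment pool as TSV (debugging/inspection)
#' @param pool fragment pool data frame.
#' @param path output file.
#' @export
write_pool_tsv <- function(pool, path) {
  utils::write.table(pool, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
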