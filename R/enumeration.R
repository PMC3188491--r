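# Exhaustive enumeration of fragment alignments with incremental
# modelability pruning.
#
# A fragment alignment is an N->C ordered chain of fragments, at most one
# per SSE, strictly increasing in both template and query coordinates.
# Monotonicity and the loop-stretch rule prune prefixes during the
# depth-first enumeration; coverage, strand-pairing and contact-order
# checks apply to completed chains.  Because the number of chains grows
# combinatorially, per-chain records are kept light (fragment ids plus
# completion measures); heavyweight quantities are computed via
# memoization and fragment-pair decomposition.

#' Loop-stretch check between two consecutive fragments
#'
#' The query residues between the fragments must be able to bridge the
#' template CA-CA distance at `stretch` Angstrom per residue:
#' `stretch * (q_f - q_p) >= d(t_p, t_f)`.  Fragments directly contiguous
#' in both sequences (no loop at all) pass unconditionally.
#'
#' @param frag_prev,frag_next single-row fragment records (must be in
#'   order: `frag_prev` precedes `frag_next` in both sequences).
#' @param template annotated template (CA coordinates).
#' @param stretch Angstrom bridged per query residue (default 3.3).
#' @return logical.
#' @export
check_loop_length <- function(frag_prev, frag_next, template, stretch = 3.3) {
  t_p <- frag_prev$t_start + frag_prev$len - 1L
  q_p <- frag_prev$q_start + frag_prev$len - 1L
  t_f <- frag_next$t_start
  q_f <- frag_next$q_start
  if (q_f <= q_p || t_f <= t_p)
    stop("check_loop_length: fragments are not in order")
  if (q_f - q_p == 1L && t_f - t_p == 1L) return(TRUE)
  ca <- template$xyz$ca
  if (anyNA(ca[c(t_p, t_f), ])) stop("missing CA coordinates")
  d <- sqrt(sum((ca[t_f, ] - ca[t_p, ])^2))
  stretch * (q_f - q_p) >= d
}

#' Coverage check for a completed fragment alignment
#'
#' At least `min_frac` of the shorter sequence must be aligned (only
#' template-SSE residues count, since fragments live in SSE columns).
#'
#' @param n_aligned total aligned residues in the fragment alignment.
#' @param query_len,template_len sequence lengths.
#' @param min_frac minimum fraction (default 0.10).
#' @return logical.
#' @export
check_coverage <- function(n_aligned, query_len, template_len,
                           min_frac = 0.10) {
  n_aligned >= min_frac * min(query_len, template_len)
}

#' Beta-strand pairing rules for a completed fragment alignment
#'
#' Rule 1: a template strand covered by the alignment that is paired in
#' the template must keep at least one of its partners covered.  Rule 2:
#' a core strand must be covered whenever two or more of its partners
#' are.
#'
#' @param covered_sses integer vector of SSE indices covered by the
#'   alignment.
#' @param sheet sheet topology (list `pairs`, `core`).
#' @return logical.
#' @export
check_strand_rules <- function(covered_sses, sheet) {
  pairs <- sheet$pairs
  if (!nrow(pairs)) return(TRUE)
  partners <- function(s)
    c(pairs[pairs[, 1] == s, 2], pairs[pairs[, 2] == s, 1])
  paired_strands <- unique(as.integer(pairs))
  for (s in intersect(covered_sses, paired_strands)) {
    if (!any(partners(s) %in% covered_sses)) return(FALSE)
  }
  for (s in sheet$core) {
    if (sum(partners(s) %in% covered_sses) >= 2 && !(s %in% covered_sses))
      return(FALSE)
  }
  TRUE
}

# Template contact map for the contact-order measure: CB within `cutoff`
# of a CB in a different SSE (SSE residues only).
contact_matrix <- function(template, cutoff = 6) {
  sid <- template$sse_id
  in_sse <- which(!is.na(sid))
  cb <- template$xyz$cb
  M <- matrix(FALSE, length(template), length(template))
  if (length(in_sse) >= 2) {
    D <- dist_xyz(cb[in_sse, , drop = FALSE], cb[in_sse, , drop = FALSE])
    diff_sse <- outer(sid[in_sse], sid[in_sse], "!=")
    M[in_sse, in_sse] <- D < cutoff & diff_sse
  }
  M
}

# Contact order of a set of aligned template SSE positions, counting only
# contacts between SSEs that are both covered.
contact_order_of <- function(idx, cmap, sid) {
  idx <- idx[!is.na(sid[idx])]
  if (!length(idx)) return(0)
  sub <- cmap[idx, idx, drop = FALSE]
  mean(rowSums(sub) > 0) * 100
}

#' Contact-order check for a completed fragment alignment
#'
#' Contact order here is the percentage of SSE residues whose CB lies
#' within 6 A of a CB in a different SSE.  For the pseudomodel it is
#' computed over the aligned SSE residues and covered SSEs only, and
#' compared against `ratio_min` times the template's own contact order.
#'
#' @param aligned_t aligned template positions of the fragment alignment.
#' @param template annotated template.
#' @param ratio_min minimum pseudomodel/template contact-order ratio.
#' @param cmap optional precomputed contact matrix.
#' @return logical.
#' @export
check_contact_order <- function(aligned_t, template, ratio_min = 0.65,
                                cmap = NULL) {
  if (is.null(cmap)) cmap <- contact_matrix(template)
  sid <- template$sse_id
  co_t <- contact_order_of(which(!is.na(sid)), cmap, sid)
  co_m <- contact_order_of(aligned_t, cmap, sid)
  co_m >= ratio_min * co_t
}

# Pairwise compatibility of pool fragments: b can directly follow a
# (monotone in both sequences, loop-stretch rule satisfied).
fragment_compat <- function(pool, template, stretch = 3.3) {
  n <- nrow(pool)
  C <- matrix(FALSE, n, n)
  if (n < 2) return(C)
  q_end <- pool$q_start + pool$len - 1L
  t_end <- pool$t_start + pool$len - 1L
  ca <- template$xyz$ca
  for (a in seq_len(n)) {
    after <- which(pool$sse > pool$sse[a] & pool$q_start > q_end[a])
    if (!length(after)) next
    dq <- pool$q_start[after] - q_end[a]
    dt <- pool$t_start[after] - t_end[a]
    d <- sqrt(colSums((t(ca[pool$t_start[after], , drop = FALSE]) -
                         ca[t_end[a], ])^2))
    ok <- (stretch * dq >= d) | (dq == 1L & dt == 1L)
    C[a, after[ok]] <- TRUE
  }
  C
}

# Number of enumerable chains (every non-empty chain counts), computed by
# DP over the compatibility DAG.
count_fragment_alignments <- function(pool, template, stretch = 3.3) {
  n <- nrow(pool)
  if (!n) return(0)
  ord <- order(pool$sse, pool$q_start)
  pool <- pool[ord, , drop = FALSE]
  C <- fragment_compat(pool, template, stretch)
  N <- rep(1, n)
  for (a in rev(seq_len(n))) {
    succ <- which(C[a, ])
    if (length(succ)) N[a] <- 1 + sum(N[succ])
  }
  sum(N)
}

# template spans of a fragment-id set (sorted template positions)
frag_spans <- function(used, ids) {
  unlist(lapply(ids, function(i) used$t_start[i]:(used$t_start[i] + used$len[i] - 1L)))
}

#' Enumerate fragment alignments
#'
#' Depth-first enumeration over the selected fragment pool: chains start
#' at any fragment (the N-terminal pseudo-fragment connects to every
#' fragment) and extend to any compatible downstream fragment.
#' Monotonicity and the loop-stretch rule are checked at every extension;
#' coverage, strand-pairing and contact-order checks are applied to each
#' completed chain.  Enumeration is deterministic (fragments visited in
#' `(sse, normalized score desc)` order) and stops after `max_enumerated`
#' chains.
#'
#' @param pool fragment pool (rows with non-NA `tier` are used).
#' @param template annotated template.
#' @param query query sequence.
#' @param config an [s4_config()].
#' @return list of fragment alignments, each a list with `ids` (row
#'   indices into the attribute `"fragments"` table), `fa_score`,
#'   `n_aligned`, `covered_sses`, and materialized `frags`, `aligned_t`,
#'   `aligned_q`.  Attributes: `"fragments"` (the ordered fragment
#'   table), `"tallies"` (counts per rejection reason), `"path_count"`.
#' @export
enumerate_fragment_alignments <- function(pool, template, query, config) {
  query <- as_aa_vector(query)
  used <- pool[!is.na(pool$tier), , drop = FALSE]
  if (!nrow(used)) stop("no viable fragment alignment: empty fragment pool")
  ord <- order(used$sse, -used$norm, used$q_start)
  used <- used[ord, , drop = FALSE]
  rownames(used) <- NULL
  n <- nrow(used)
  C <- fragment_compat(used, template, config$loop_stretch_factor)
  succ <- lapply(seq_len(n), function(a) which(C[a, ]))
  cmap <- contact_matrix(template, config$cb_contact_cutoff)
  sid <- template$sse_id
  co_t <- contact_order_of(which(!is.na(sid)), cmap, sid)
  Lq <- length(query); Lt <- length(template)

  cap <- config$max_enumerated
  chains <- vector("list", 1024L)
  count <- 0L
  stack <- vector("list", 64L)
  top <- 0L
  for (s in rev(seq_len(n))) {
    top <- top + 1L
    stack[[top]] <- s
  }
  while (top > 0L && count < cap) {
    chain <- stack[[top]]
    top <- top - 1L
    count <- count + 1L
    if (count > length(chains)) chains <- c(chains, vector("list", length(chains)))
    chains[[count]] <- chain
    sc <- succ[[chain[length(chain)]]]
    for (s2 in rev(sc)) {
      top <- top + 1L
      if (top > length(stack)) stack <- c(stack, vector("list", length(stack)))
      stack[[top]] <- c(chain, s2)
    }
  }
  chains <- chains[seq_len(count)]

  # completion filters (memoized where chains share structure)
  tallies <- c(enumerated = count, coverage = 0, strand = 0,
               contact_order = 0, kept = 0)
  min_aligned <- config$min_coverage_frac * min(Lq, Lt)
  lens <- used$len
  sses <- used$sse
  raws <- used$raw
  q_end <- used$q_start + used$len - 1L

  strand_memo <- new.env(parent = emptyenv())
  co_memo <- new.env(parent = emptyenv())
  sheet <- template$sheet
  keep <- logical(count)
  fa_score <- numeric(count)
  n_aligned <- integer(count)
  for (k in seq_len(count)) {
    ids <- chains[[k]]
    na <- sum(lens[ids])
    n_aligned[k] <- na
    if (na < min_aligned) { tallies["coverage"] <- tallies["coverage"] + 1; next }
    skey <- paste(sses[ids], collapse = ",")
    sok <- strand_memo[[skey]]
    if (is.null(sok)) {
      sok <- check_strand_rules(sses[ids], sheet)
      strand_memo[[skey]] <- sok
    }
    if (!sok) { tallies["strand"] <- tallies["strand"] + 1; next }
    ckey <- paste(used$t_start[ids], lens[ids], sep = ":", collapse = ";")
    co_m <- co_memo[[ckey]]
    if (is.null(co_m)) {
      co_m <- contact_order_of(frag_spans(used, ids), cmap, sid)
      co_memo[[ckey]] <- co_m
    }
    if (co_m < config$contact_order_ratio_min * co_t) {
      tallies["contact_order"] <- tallies["contact_order"] + 1; next
    }
    keep[k] <- TRUE
    ins <- if (length(ids) > 1)
      sum(pmax(used$q_start[ids[-1]] - q_end[ids[-length(ids)]] - 1L, 0L))
    else 0L
    fa_score[k] <- sum(raws[ids]) - config$insertion_penalty * ins
  }
  kept_idx <- which(keep)
  tallies["kept"] <- length(kept_idx)
  if (!length(kept_idx)) {
    dominant <- names(which.max(tallies[c("coverage", "strand", "contact_order")]))
    stop(sprintf(
      "no viable fragment alignment (enumerated %d; dominant rejection: %s; tallies: %s)",
      count, dominant,
      paste(sprintf("%s=%d", names(tallies), tallies), collapse = ", ")))
  }
  out <- lapply(kept_idx, function(k) {
    ids <- chains[[k]]
    list(ids = ids, fa_score = fa_score[k], n_aligned = n_aligned[k],
         covered_sses = sses[ids])
  })
  attr(out, "fragments") <- used
  attr(out, "tallies") <- tallies
  attr(out, "path_count") <- count_fragment_alignments(used, template,
                                                       config$loop_stretch_factor)
  out
}

# Materialize the heavyweight fields (frags table, aligned index vectors)
# of fragment alignments; used for gate survivors only.
materialize_fas <- function(fas, used = attr(fas, "fragments")) {
  lapply(fas, function(f) {
    if (!is.null(f$aligned_t)) return(f)
    fr <- if (is.null(f$frags)) used[f$ids, , drop = FALSE] else f$frags
    f$frags <- fr
    f$aligned_t <- unlist(lapply(seq_len(nrow(fr)), function(i)
      fr$t_start[i]:(fr$t_start[i] + fr$len[i] - 1L)))
    f$aligned_q <- unlist(lapply(seq_len(nrow(fr)), function(i)
      fr$q_start[i]:(fr$q_start[i] + fr$len[i] - 1L)))
    f
  })
}

# Internal query insertions of a fragment chain: query residues skipped
# between consecutive fragments (these sit between template residues;
# terminal overhangs are free).
internal_insertions <- function(fr) {
  if (nrow(fr) < 2) return(0L)
  q_end <- fr$q_start + fr$len - 1L
  sum(pmax(fr$q_start[-1] - q_end[-nrow(fr)] - 1L, 0L))
}
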