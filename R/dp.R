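# Dynamic-programming kernels: optimal global alignment, delta-suboptimal
# Waterman ensembles (unconstrained and SSE-boundary-constrained), and
# the corridor-restricted DP that finishes fragment alignments.
#
# Model: 3-state affine machine (M = aligned pair, X = deletion/template
# consumed, Y = insertion/query consumed) over grid nodes (i consumed
# query, j consumed template).  Gap runs are canonicalized (no X directly
# after Y) so each residue-pairing corresponds to exactly one state path.
# With free end gaps (the default), alignments start and end at aligned
# pairs and terminal overhangs cost nothing.  A gap of length g costs
# open + g * extend.

NEG <- -1e18

#' Gap scheme for the DP kernels
#'
#' @param open_x,ext_x open/extend penalties for deletions (template
#'   residue skipped), positive numbers.
#' @param open_y,ext_y penalties for insertions (query residue skipped).
#' @param ends_free if TRUE terminal gaps are free (end-gap-free global
#'   alignment); if FALSE all gaps are penalized.
#' @return a `gap_scheme` list.
#' @export
gap_scheme <- function(open_x = 10, ext_x = 1, open_y = open_x,
                       ext_y = ext_x, ends_free = TRUE) {
  structure(list(open_x = open_x, ext_x = ext_x,
                 open_y = open_y, ext_y = ext_y,
                 ends_free = ends_free), class = "gap_scheme")
}

# Backward state values BM/BX/BY over nodes (i = 0..n, j = 0..m, stored
# at [i+1, j+1]).  BM(i,j) = best score obtainable after having just
# emitted a pair at (i,j); analogous for gap states.  S is the n x m
# match-score matrix (masked NEG where matches are forbidden).
backward_dp <- function(S, gaps, node_valid = NULL) {
  n <- nrow(S); m <- ncol(S)
  ends_free <- gaps$ends_free
  BM <- matrix(NEG, n + 1, m + 1)
  BX <- matrix(NEG, n + 1, m + 1)
  BY <- matrix(NEG, n + 1, m + 1)
  endM <- if (ends_free) 0 else NEG
  jj <- seq_len(m + 1)
  kx <- (jj - 1) * gaps$ext_x              # column-index extension offsets
  for (i in n:0) {
    ri <- i + 1
    diag <- rep(NEG, m + 1)
    if (i < n) {
      diag[1:m] <- S[i + 1, ] + BM[ri + 1, 2:(m + 1)]
    }
    # BY: continue insertion run or leave via a pair
    AY <- diag
    if (!ends_free && i == n) AY[m + 1] <- max(AY[m + 1], 0)
    BYrow <- AY
    if (i < n) BYrow <- pmax(BYrow, BY[ri + 1, ] - gaps$ext_y)
    # BX: leave via pair or via opening an insertion; runs solved by
    # suffix-max along j
    AX <- diag
    if (i < n) AX <- pmax(AX, BY[ri + 1, ] - gaps$open_y - gaps$ext_y)
    if (!ends_free && i == n) AX[m + 1] <- max(AX[m + 1], 0)
    Tx <- AX - kx
    suf <- rev(cummax(rev(Tx)))
    BXrow <- suf + kx
    # BM
    BMrow <- pmax(diag, endM)
    if (!ends_free && i == n) BMrow[m + 1] <- max(BMrow[m + 1], 0)
    shiftBX <- c(BXrow[-1], NEG)
    BMrow <- pmax(BMrow, shiftBX - gaps$open_x - gaps$ext_x)
    if (i < n) BMrow <- pmax(BMrow, BY[ri + 1, ] - gaps$open_y - gaps$ext_y)
    if (!is.null(node_valid)) {
      bad <- !node_valid[ri, ]
      BMrow[bad] <- NEG; BXrow[bad] <- NEG; BYrow[bad] <- NEG
    }
    BM[ri, ] <- BMrow; BX[ri, ] <- BXrow; BY[ri, ] <- BYrow
  }
  list(BM = BM, BX = BX, BY = BY)
}

# Enumerate alignment paths within `delta` of the optimum.
# branch_cols: NULL (unconstrained) or logical over template coordinates
# 0..m (index j+1); where FALSE, only the locally best continuation may
# be taken.  Returns list(paths = list of (t,q) matrices, scores).
enum_paths <- function(S, gaps, delta, max_n, branch_cols = NULL,
                       collect_cap = NULL, allow_empty = FALSE,
                       node_valid = NULL, max_steps = 2e6) {
  n <- nrow(S); m <- ncol(S)
  eps <- 1e-9
  B <- backward_dp(S, gaps, node_valid)
  ends_free <- gaps$ends_free
  if (is.null(collect_cap)) collect_cap <- max(4L * max_n, 256L)
  steps <- 0L

  if (ends_free) {
    startv <- S + B$BM[2:(n + 1), 2:(m + 1), drop = FALSE]
    opt <- max(startv, if (allow_empty) 0 else NEG)
  } else {
    opt <- B$BM[1, 1]
  }
  if (opt <= NEG / 2) return(list(paths = list(), scores = numeric(0)))

  res_paths <- list()
  res_scores <- numeric(0)
  emit <- function(pairs, g) {
    res_paths[[length(res_paths) + 1]] <<- pairs
    res_scores[length(res_scores) + 1] <<- g
  }

  constrained <- !is.null(branch_cols)

  BM <- B$BM; BX <- B$BX; BY <- B$BY
  lim <- opt - delta - eps
  oxe <- gaps$open_x + gaps$ext_x; oye <- gaps$open_y + gaps$ext_y
  exx <- gaps$ext_x; eyy <- gaps$ext_y

  # iterative DFS over (state, i, j, g, pairs); states coded 1=M 2=X 3=Y
  walk <- function(state, i, j, g, pairs) {
    repeat {
      steps <<- steps + 1L
      if (steps > max_steps) return(invisible())
      if (length(res_paths) >= collect_cap) return(invisible())
      # candidate continuations: slot 1 = diag, 2 = X, 3 = Y
      v1 <- v2 <- v3 <- NEG; w1 <- w2 <- w3 <- 0
      if (i < n && j < m) {
        s1 <- S[i + 1, j + 1]
        if (s1 > NEG / 2) { w1 <- s1; v1 <- g + s1 + BM[i + 2, j + 2] }
      }
      if (j < m && state != 3L) {
        w2 <- if (state == 2L) -exx else -oxe
        v2 <- g + w2 + BX[i + 1, j + 2]
      }
      if (i < n) {
        w3 <- if (state == 3L) -eyy else -oye
        v3 <- g + w3 + BY[i + 2, j + 1]
      }
      end_feas <- g >= lim &&
        (if (ends_free) state == 1L else (i == n && j == m))
      f1 <- v1 >= lim; f2 <- v2 >= lim; f3 <- v3 >= lim
      if (constrained && !branch_cols[j + 1]) {
        # no branching here: single best continuation (or terminate)
        best_v <- max(v1, v2, v3)
        if (end_feas && g >= best_v - eps) { f1 <- f2 <- f3 <- FALSE }
        else if (f1 || f2 || f3) {
          f1 <- v1 >= best_v - eps
          f2 <- !f1 && v2 >= best_v - eps
          f3 <- !f1 && !f2 && v3 >= best_v - eps
        }
        if (end_feas && !(f1 || f2 || f3)) emit(pairs, g)
      } else if (end_feas) emit(pairs, g)
      nfeas <- f1 + f2 + f3
      if (nfeas == 0L) return(invisible())
      if (nfeas == 1L) {
        if (f1) {
          pairs <- rbind(pairs, c(j + 1L, i + 1L))
          g <- g + w1; i <- i + 1L; j <- j + 1L; state <- 1L
        } else if (f2) {
          g <- g + w2; j <- j + 1L; state <- 2L
        } else {
          g <- g + w3; i <- i + 1L; state <- 3L
        }
        next
      }
      if (f1) walk(1L, i + 1L, j + 1L, g + w1,
                   rbind(pairs, c(j + 1L, i + 1L)))
      if (f2 && length(res_paths) < collect_cap)
        walk(2L, i, j + 1L, g + w2, pairs)
      if (f3 && length(res_paths) < collect_cap)
        walk(3L, i + 1L, j, g + w3, pairs)
      return(invisible())
    }
  }

  empty_pairs <- matrix(integer(0), 0, 2)
  if (ends_free) {
    sv <- startv
    feas <- which(sv >= opt - delta - eps, arr.ind = TRUE)
    if (nrow(feas)) {
      v <- sv[feas]
      ord <- order(-v, feas[, 2], feas[, 1])
      feas <- feas[ord, , drop = FALSE]
      if (constrained) {
        inbranch <- branch_cols[feas[, 2] + 1]
        keep <- inbranch
        keep[1] <- TRUE                     # the best start is always taken
        feas <- feas[keep, , drop = FALSE]
      }
      for (r in seq_len(nrow(feas))) {
        i0 <- feas[r, 1]; j0 <- feas[r, 2]
        walk(1L, i0, j0, S[i0, j0],
             rbind(empty_pairs, c(j0, i0)))
        if (length(res_paths) >= collect_cap) break
      }
    }
    if (allow_empty && 0 >= opt - delta - eps) emit(empty_pairs, 0)
  } else {
    walk(1L, 0L, 0L, 0, empty_pairs)
  }

  if (!length(res_paths)) return(list(paths = list(), scores = numeric(0)))
  ord <- order(-res_scores)
  ord <- utils::head(ord, max_n)
  list(paths = lapply(res_paths[ord], path_matrix),
       scores = res_scores[ord], opt = opt)
}

# Branch mask over grid columns j = 0..m (index j+1) for the constrained
# samplers: alternate paths may be taken while moving between SSE and
# loop regions, i.e. at any node not strictly interior to an SSE.  A
# template without SSEs has no SSE/loop transitions, hence no branch
# points at all.
branch_mask <- function(sse, m) {
  if (is.null(sse) || nrow(sse) == 0) return(rep(FALSE, m + 1))
  j <- 0:m
  interior <- rep(FALSE, m + 1)
  for (k in seq_len(nrow(sse))) {
    interior <- interior | (j >= sse$start[k] & j + 1 <= sse$end[k])
  }
  !interior
}

template_seq_of <- function(template) {
  if (inherits(template, "template_structure")) template$sequence
  else as_aa_vector(template, "template sequence")
}

#' Optimal pairwise alignment
#'
#' Global maximum-score alignment under a score model and affine gap
#' scheme (free end gaps by default), with a deterministic high-road
#' tie-break.
#'
#' @param query query sequence.
#' @param template template sequence or [template_structure()].
#' @param model a `score_model`.
#' @param gaps a [gap_scheme()].
#' @return an alignment path: 2-column `(t, q)` matrix with attributes
#'   `dp_score`.
#' @export
optimal_align <- function(query, template, model = load_substitution_matrix(),
                          gaps = gap_scheme()) {
  S <- score_grid(model, query, template_seq_of(template))
  r <- enum_paths(S, gaps, delta = 0, max_n = 1L, allow_empty = TRUE)
  p <- r$paths[[1]]
  attr(p, "dp_score") <- r$scores[1]
  p
}

#' Delta-suboptimal Waterman alignment ensemble
#'
#' Enumerates all distinct alignments whose score is within `delta` of
#' the optimum (branching anywhere in the DP matrix), best-first,
#' truncated at `max_n`.
#'
#' @inheritParams optimal_align
#' @param delta score slack (same units as the scorer); `"auto"` doubles
#'   a small delta until at least `max_n` alignments exist, then keeps
#'   the top `max_n` by score.
#' @param max_n maximum ensemble size.
#' @return an `alignment_ensemble` (paths + scores).
#' @export
waterman_suboptimal <- function(query, template,
                                model = load_substitution_matrix(),
                                gaps = gap_scheme(), delta = 0,
                                max_n = 1000L) {
  S <- score_grid(model, query, template_seq_of(template))
  r <- auto_delta_enum(S, gaps, delta, max_n, branch_cols = NULL)
  new_ensemble(r$paths, data.frame(rank = seq_along(r$paths),
                                   dp_score = r$scores),
               method = "waterman")
}

#' SSE-boundary-constrained Waterman ensemble
#'
#' As [waterman_suboptimal()], but branching to an alternate path is only
#' allowed at template columns on an SSE/loop boundary (first or last
#' residue of an SSE); elsewhere the locally best continuation is forced.
#' The result is always a subset of the unconstrained ensemble at equal
#' delta.
#'
#' @inheritParams waterman_suboptimal
#' @param template a [template_structure()] with SSE annotation (or a
#'   plain sequence plus `sse` table).
#' @param sse optional SSE table overriding the template annotation.
#' @return an `alignment_ensemble`.
#' @export
constrained_waterman <- function(query, template,
                                 model = load_substitution_matrix(),
                                 gaps = gap_scheme(), delta = 0,
                                 max_n = 1000L, sse = NULL) {
  if (is.null(sse)) {
    if (!inherits(template, "template_structure") || is.null(template$sse))
      stop("constrained_waterman needs SSE annotation (template or sse=)")
    sse <- template$sse
  }
  S <- score_grid(model, query, template_seq_of(template))
  r <- auto_delta_enum(S, gaps, delta, max_n,
                       branch_cols = branch_mask(sse, ncol(S)))
  new_ensemble(r$paths, data.frame(rank = seq_along(r$paths),
                                   dp_score = r$scores),
               method = "constrained_waterman")
}

auto_delta_enum <- function(S, gaps, delta, max_n, branch_cols) {
  if (identical(delta, "auto")) {
    d <- 0.5
    repeat {
      r <- enum_paths(S, gaps, d, max_n, branch_cols = branch_cols)
      if (length(r$paths) >= max_n || d > 512) return(r)
      d <- d * 2
    }
  }
  enum_paths(S, gaps, delta, max_n, branch_cols = branch_cols)
}

#' Re-score an alignment path
#'
#' Recomputes the DP score of a path under a score model and gap scheme
#' (used by the invariants: every emitted path re-scores exactly).
#'
#' @param path alignment path.
#' @param query,template sequences.
#' @param model score model.
#' @param gaps gap scheme.
#' @return scalar score.
#' @export
score_path <- function(path, query, template,
                       model = load_substitution_matrix(),
                       gaps = gap_scheme()) {
  S <- score_grid(model, query, template_seq_of(template))
  p <- path_matrix(path)
  gapcost0 <- function(g, open, ext) if (g > 0) open + g * ext else 0
  if (!nrow(p)) {
    if (gaps$ends_free) return(0)
    n <- length(as_aa_vector(query)); m <- length(template_seq_of(template))
    return(-gapcost0(m, gaps$open_x, gaps$ext_x) -
             gapcost0(n, gaps$open_y, gaps$ext_y))
  }
  sc <- sum(S[cbind(p[, 2], p[, 1])])
  gapcost <- function(g, open, ext) if (g > 0) open + g * ext else 0
  if (nrow(p) > 1) {
    dj <- diff(p[, 1]) - 1L
    di <- diff(p[, 2]) - 1L
    sc <- sc - sum(vapply(dj, gapcost, 0, gaps$open_x, gaps$ext_x))
    sc <- sc - sum(vapply(di, gapcost, 0, gaps$open_y, gaps$ext_y))
  }
  if (!gaps$ends_free) {
    n <- length(as_aa_vector(query)); m <- length(template_seq_of(template))
    sc <- sc - gapcost(p[1, 1] - 1L, gaps$open_x, gaps$ext_x)
    sc <- sc - gapcost(p[1, 2] - 1L, gaps$open_y, gaps$ext_y)
    sc <- sc - gapcost(m - p[nrow(p), 1], gaps$open_x, gaps$ext_x)
    sc <- sc - gapcost(n - p[nrow(p), 2], gaps$open_y, gaps$ext_y)
  }
  unname(sc)
}

#' Corridor of a fragment alignment
#'
#' Per-template-position allowed query intervals: fragment diagonals
#' widened by `margin` inside covered SSEs; between fragments the loop
#' region spans from the preceding fragment's query end to the following
#' fragment's query start (widened by `margin`); template SSEs not in
#' the fragment alignment are excluded from matching (deletion forced).
#'
#' @param fa a fragment alignment (entry of
#'   [enumerate_fragment_alignments()]).
#' @param template annotated template.
#' @param query_len query length.
#' @param margin band half-width in residues (default 3).
#' @return list with `lo`, `hi` (length = template length) and
#'   `match_allowed` (logical).
#' @export
corridor_from_fragment_alignment <- function(fa, template, query_len,
                                             margin = 3L) {
  m <- length(template)
  lo <- rep(1L, m); hi <- rep(query_len, m)
  match_allowed <- rep(TRUE, m)
  fr <- fa$frags
  ord <- order(fr$t_start)
  fr <- fr[ord, , drop = FALSE]
  t_end <- fr$t_start + fr$len - 1L
  q_end <- fr$q_start + fr$len - 1L
  # uncovered SSE columns: deletion forced
  sid <- template$sse_id
  covered <- unique(fr$sse)
  match_allowed[!is.na(sid) & !(sid %in% covered)] <- FALSE
  for (k in seq_len(nrow(fr))) {
    cols <- fr$t_start[k]:t_end[k]
    dg <- fr$q_start[k] - fr$t_start[k]
    lo[cols] <- pmax(1L, cols + dg - margin)
    hi[cols] <- pmin(query_len, cols + dg + margin)
  }
  if (nrow(fr) > 1) {
    for (k in seq_len(nrow(fr) - 1L)) {
      gapcols <- (t_end[k] + 1L):(fr$t_start[k + 1L] - 1L)
      if (t_end[k] + 1L > fr$t_start[k + 1L] - 1L) next
      lo[gapcols] <- max(1L, q_end[k] - margin)
      hi[gapcols] <- min(query_len, fr$q_start[k + 1L] + margin)
    }
  }
  if (fr$t_start[1] > 1) {
    cols <- 1:(fr$t_start[1] - 1L)
    lo[cols] <- 1L
    hi[cols] <- min(query_len, fr$q_start[1] + margin)
  }
  if (t_end[nrow(fr)] < m) {
    cols <- (t_end[nrow(fr)] + 1L):m
    lo[cols] <- max(1L, q_end[nrow(fr)] - margin)
    hi[cols] <- query_len
  }
  lo <- cummax(lo)
  hi <- cummax(hi)
  if (any(lo > hi)) {
    bad <- which(lo > hi)[1]
    stop(sprintf("corridor admits no path at template position %d (inconsistent fragment alignment)", bad))
  }
  list(lo = lo, hi = hi, match_allowed = match_allowed)
}

# Apply a corridor to a score matrix and build the node-validity mask.
corridor_masks <- function(S, corridor) {
  n <- nrow(S); m <- ncol(S)
  for (j in seq_len(m)) {
    if (!corridor$match_allowed[j]) { S[, j] <- NEG; next }
    keep <- corridor$lo[j]:corridor$hi[j]
    mask <- rep(TRUE, n); mask[keep] <- FALSE
    S[mask, j] <- NEG
  }
  node_valid <- matrix(FALSE, n + 1, m + 1)
  node_valid[, 1] <- TRUE
  for (j in seq_len(m)) {
    rows <- max(0L, corridor$lo[j] - 1L):corridor$hi[j]
    node_valid[rows + 1L, j + 1L] <- TRUE
  }
  list(S = S, node_valid = node_valid)
}

#' Finish a fragment alignment into a full alignment
#'
#' Runs the constrained Waterman sampler inside the fragment alignment's
#' corridor (insertions carry the flat per-residue penalty, deletions are
#' free, terminal overhangs free), builds a pseudomodel for every
#' candidate, and returns the candidate with the lowest query energy.
#'
#' @param fa fragment alignment.
#' @param template annotated template.
#' @param query query sequence.
#' @param model score model.
#' @param pot a `distance_potential`.
#' @param config an [s4_config()].
#' @param ctx optional precomputed energy context (internal speedup).
#' @param S optional precomputed score grid.
#' @return alignment path with attributes `dp_score`, `query_energy`.
#' @export
finish_alignment <- function(fa, template, query, model, pot, config,
                             ctx = NULL, S = NULL) {
  query <- as_aa_vector(query)
  if (is.null(S)) S <- score_grid(model, query, template$sequence)
  if (is.null(ctx)) ctx <- make_energy_context(template, pot)
  fa <- materialize_fas(list(fa))[[1]]
  corridor <- corridor_from_fragment_alignment(fa, template, length(query),
                                               config$corridor_margin)
  masks <- corridor_masks(S, corridor)
  gaps <- gap_scheme(open_x = 0, ext_x = 0,
                     open_y = 0, ext_y = config$insertion_penalty,
                     ends_free = TRUE)
  branch <- branch_mask(template$sse, ncol(S))
  # delta grows (doubling) until the candidate set spans enough DISTINCT
  # secondary-structure pairings: in-corridor paths that differ only in
  # loop placement produce essentially equivalent models, so candidates
  # are deduplicated on their SSE-restricted residue pairs before the
  # energy selection
  sid <- template$sse_id
  sse_key <- function(p) {
    ins <- !is.na(sid[p[, 1]])
    paste(p[ins, 1], p[ins, 2], sep = ":", collapse = ";")
  }
  d <- config$finish_delta
  cap <- 3L * config$finish_max_n
  prev_uniq <- -1L
  repeat {
    r <- enum_paths(masks$S, gaps, d, cap,
                    branch_cols = branch, node_valid = masks$node_valid,
                    collect_cap = 2L * cap, max_steps = 4e4)
    keys <- vapply(r$paths, sse_key, "")
    uniq <- !duplicated(keys)
    nu <- sum(uniq)
    # stop when enough distinct pairings exist, delta is exhausted, or
    # widening delta no longer surfaces new pairings (saturation)
    if (nu >= config$finish_max_n || d > 64 || nu == prev_uniq) break
    prev_uniq <- nu
    d <- d * 2
  }
  if (!length(r$paths))
    stop("corridor admits no alignment path for this fragment alignment")
  cand <- utils::head(r$paths[uniq], config$finish_max_n)
  cand_scores <- utils::head(r$scores[uniq], config$finish_max_n)
  # the fragment alignment itself is always a candidate: corridor
  # sampling is asked to improve on it, never to replace it blindly
  fp <- path_matrix(cbind(fa$aligned_t, fa$aligned_q))
  if (!(sse_key(fp) %in% vapply(cand, sse_key, ""))) {
    cand <- c(cand, list(fp))
    cand_scores <- c(cand_scores, score_path(fp, query, template, gaps = gaps,
                                             model = model))
  }
  energies <- vapply(cand, function(p)
    ctx_energy(ctx, p[, 1], query[p[, 2]], p[, 2], p[, 1]), 0)
  # representative selection: statistical energy, regularized by the
  # similarity score so that an energy gain smaller than the score it
  # sacrifices (in the scorer's units) cannot override the alignment
  # evidence; with a perfectly resolving potential this reduces to the
  # plain lowest-energy choice
  sel_obj <- energies - config$energy_score_weight * cand_scores
  best <- which.min(sel_obj)
  p <- cand[[best]]
  attr(p, "dp_score") <- cand_scores[best]
  attr(p, "query_energy") <- energies[best]
  p
}

#' Rank fragment alignments and emit the final ensemble
#'
#' Processes fragment alignments in descending fragment-alignment score,
#' finishes each into a full alignment, and collects unique alignments
#' (two alignments are identical when they agree on all template-SSE
#' residue pairs) until `N` are found.
#'
#' @param fas list of fragment alignments (filtered).
#' @param template annotated template.
#' @param query query sequence.
#' @param model score model.
#' @param pot distance potential.
#' @param config an [s4_config()].
#' @param N ensemble size.
#' @return an `alignment_ensemble` with per-member scores.
#' @export
rank_and_emit <- function(fas, template, query, model, pot, config, N,
                          max_finishes = max(3L * N, 150L)) {
  ord <- order(-vapply(fas, `[[`, 0, "fa_score"))
  fas <- fas[ord]
  sid <- template$sse_id
  ctx <- make_energy_context(template, pot)
  S <- score_grid(model, query, template$sequence)
  keys <- character(0)
  paths <- list(); rows <- list()
  # the sweep is bounded: fragment alignments far down the score ranking
  # contribute duplicates overwhelmingly often, so emission stops after
  # max_finishes attempts even when N unique alignments were not reached
  for (k in seq_len(min(length(fas), max_finishes))) {
    if (length(paths) >= N) break
    p <- tryCatch(
      finish_alignment(fas[[k]], template, query, model, pot, config,
                       ctx = ctx, S = S),
      error = function(e) NULL)
    if (is.null(p)) next
    pm <- path_matrix(p)
    in_sse <- !is.na(sid[pm[, 1]])
    key <- paste(pm[in_sse, 1], pm[in_sse, 2], sep = ":", collapse = ";")
    if (key %in% keys) next
    keys <- c(keys, key)
    paths[[length(paths) + 1]] <- p
    rows[[length(rows) + 1]] <- data.frame(
      rank = length(paths),
      fa_score = fas[[k]]$fa_score,
      dp_score = attr(p, "dp_score"),
      query_energy = attr(p, "query_energy"),
      preserved = fas[[k]]$measures["preserved"] %||% NA_real_)
  }
  if (length(paths) < N)
    warning(sprintf("only %d unique alignments available (requested %d)",
                    length(paths), N))
  new_ensemble(paths, do.call(rbind, rows), method = "s4")
}
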