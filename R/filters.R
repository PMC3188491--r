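# Post-enumeration gates: preserved hydrophobic core contacts, the
# percentile gate over the three model-quality measures, and redundancy
# removal.

#' Find hydrophobic core contacts of a template
#'
#' A residue pair is a core contact when both residues are buried
#' (relative burial >= `burial_min`), their CB atoms are within
#' `cb_cutoff`, and both are hydrophobic (A, F, G, I, L, M, P, W, V, Y;
#' glycine uses its pseudo-CB).
#'
#' @param template annotated [template_structure()] (burial computed,
#'   CBs completed).
#' @param burial_min burial threshold (default 0.6).
#' @param cb_cutoff CB-CB distance cutoff in Angstrom (default 6).
#' @param min_sep minimum sequence separation (adjacent residues are
#'   trivially close; default 2).
#' @return two-column matrix of residue-index pairs (i < j).
#' @export
find_core_contacts <- function(template, burial_min = 0.6, cb_cutoff = 6,
                               min_sep = 2L) {
  if (is.null(template$burial)) stop("template burial not computed")
  template <- complete_cb(template)
  hyd <- which(is_hydrophobic(template$sequence) &
                 template$burial >= burial_min)
  if (length(hyd) < 2) return(matrix(integer(0), 0, 2))
  D <- dist_xyz(template$xyz$cb[hyd, , drop = FALSE],
                template$xyz$cb[hyd, , drop = FALSE])
  sel <- which(D < cb_cutoff & upper.tri(D), arr.ind = TRUE)
  pr <- cbind(hyd[sel[, 1]], hyd[sel[, 2]])
  pr <- pr[abs(pr[, 1] - pr[, 2]) >= min_sep, , drop = FALSE]
  pr[order(pr[, 1], pr[, 2]), , drop = FALSE]
}

#' Count preserved core contacts of an alignment
#'
#' A core contact is preserved when both template residues are aligned
#' and both aligned query residues are hydrophobic.
#'
#' @param aligned_t,aligned_q parallel vectors of aligned template and
#'   query indices (or a 2-column path matrix in `aligned_t`).
#' @param core_contacts matrix from [find_core_contacts()].
#' @param query query sequence.
#' @return integer count.
#' @export
count_preserved <- function(aligned_t, core_contacts, query,
                            aligned_q = NULL) {
  if (is.matrix(aligned_t) && is.null(aligned_q)) {
    p <- path_matrix(aligned_t)
    aligned_q <- p[, 2]; aligned_t <- p[, 1]
  }
  if (!nrow(core_contacts) || !length(aligned_t)) return(0L)
  query <- as_aa_vector(query)
  qmap <- rep(NA_integer_, max(core_contacts, aligned_t))
  qmap[aligned_t] <- aligned_q
  q1 <- qmap[core_contacts[, 1]]
  q2 <- qmap[core_contacts[, 2]]
  ok <- !is.na(q1) & !is.na(q2) &
    is_hydrophobic(query[q1]) & is_hydrophobic(query[q2])
  sum(ok)
}

# Percentile ranks in [0, 100]: linear rank/(n-1) interpolation, ties
# share the mean rank.  Degenerate cases rank everything 100: sets of
# fewer than two candidates, and constant measures (a measure that does
# not discriminate cannot gate).
percentile_ranks <- function(x) {
  n <- length(x)
  if (n < 2 || length(unique(x)) == 1L) return(rep(100, n))
  (rank(x, ties.method = "average") - 1) / (n - 1) * 100
}

#' Percentile gate over the three model-quality measures
#'
#' Candidates carry three measures: preserved core contacts,
#' query energy, template energy.  Energies are negated so that larger
#' always means better, percentile ranks are computed over the candidate
#' set per measure, and a candidate is kept iff all three ranks are at
#' least `lower` and at least one reaches `upper`.  Sets with fewer than
#' two candidates pass unchanged.
#'
#' @param measures data frame/matrix with columns `preserved`,
#'   `query_energy`, `template_energy` (one row per candidate).
#' @param lower,upper percentile thresholds (defaults 66 and 90).
#' @return logical vector: kept candidates.
#' @export
percentile_gate <- function(measures, lower = 66, upper = 90) {
  m <- as.data.frame(measures)
  n <- nrow(m)
  if (n < 2) return(rep(TRUE, n))
  r1 <- percentile_ranks(m$preserved)
  r2 <- percentile_ranks(-m$query_energy)
  r3 <- percentile_ranks(-m$template_energy)
  pmin(r1, pmin(r2, r3)) >= lower & pmax(r1, pmax(r2, r3)) >= upper
}

# Piecewise path implied by a fragment alignment: exact pairs inside
# fragments (loops are interpolated by the IAD step-function machinery).
fa_path <- function(fa) {
  path_matrix(cbind(fa$aligned_t, fa$aligned_q))
}

#' Remove redundant fragment alignments
#'
#' Sweeps candidates in descending score order; a candidate is dropped
#' iff some kept candidate covers the identical SSE set, every
#' corresponding fragment's diagonal differs by at most `shift_max`, and
#' the inter-alignment distance of the implied paths is below `iad_max`.
#'
#' @param fas list of fragment alignments
#'   ([enumerate_fragment_alignments()] entries).
#' @param template_len template length (IAD denominator).
#' @param shift_max maximum per-fragment diagonal shift (default 4).
#' @param iad_max IAD threshold (default 1.0).
#' @return the deduplicated list (descending score order).
#' @export
remove_redundant <- function(fas, template_len, shift_max = 4,
                             iad_max = 1.0) {
  if (length(fas) < 2) return(fas)
  ord <- order(-vapply(fas, `[[`, 0, "fa_score"))
  fas <- fas[ord]
  sse_key <- vapply(fas, function(f) paste(f$covered_sses, collapse = ","), "")
  diags <- lapply(fas, function(f) f$frags$q_start - f$frags$t_start)
  qfun <- lapply(fas, function(f)
    path_step_function(fa_path(f), template_len))
  kept <- logical(length(fas))
  for (i in seq_along(fas)) {
    dup <- FALSE
    for (j in which(kept & sse_key == sse_key[i])) {
      if (all(abs(diags[[i]] - diags[[j]]) <= shift_max) &&
          mean(abs(qfun[[i]] - qfun[[j]])) < iad_max) {
        dup <- TRUE
        break
      }
    }
    kept[i] <- !dup
  }
  fas[kept]
}

# Precomputed per-template energy context: distance-bin matrices per
# atom-role combo and a fast evaluator for aligned index sets.
make_energy_context <- function(template, pot, core_contacts = NULL) {
  template <- complete_cb(template)
  combos <- list(c("CA", "CA"), c("CB", "CB"), c("CA", "CB"))
  binm <- lapply(combos, function(cm) {
    D <- dist_xyz(template$xyz[[tolower(cm[1])]],
                  template$xyz[[tolower(cm[2])]])
    B <- floor(D / pot$bin_width) + 1L
    B[D >= pot$cutoff] <- NA_integer_
    B
  })
  list(binm = binm, pot = pot, sid = template$sse_id,
       tseq = template$sequence, core = core_contacts)
}

# Energy of an aligned set (t_idx, with residue types `types` and
# separation indices `sep_idx`, optionally `sep_idx2`) under an energy
# context.  SSE residues only; bonded-neighbor exclusion: separation >= 2
# in every supplied numbering.
ctx_energy <- function(ctx, t_idx, types, sep_idx, sep_idx2 = NULL) {
  keep <- !is.na(ctx$sid[t_idx])
  ti <- t_idx[keep]; ty <- types[keep]; si <- sep_idx[keep]
  s2 <- if (is.null(sep_idx2)) NULL else sep_idx2[keep]
  n <- length(ti)
  if (n < 2) return(0)
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  sep <- abs(si[ut[, 1]] - si[ut[, 2]])
  if (!is.null(s2)) sep <- pmin(sep, abs(s2[ut[, 1]] - s2[ut[, 2]]))
  cross <- ctx$sid[ti[ut[, 1]]] != ctx$sid[ti[ut[, 2]]]
  ut <- ut[sep >= 2L & cross, , drop = FALSE]
  if (!nrow(ut)) return(0)
  E <- ctx$pot$energy
  tot <- 0
  for (ci in 1:3) {
    B <- ctx$binm[[ci]]
    atoms <- list(c("CA", "CA"), c("CB", "CB"), c("CA", "CB"))[[ci]]
    pairs <- if (ci < 3) ut else rbind(ut, ut[, 2:1, drop = FALSE])
    b <- B[cbind(ti[pairs[, 1]], ti[pairs[, 2]])]
    ok <- !is.na(b)
    if (!any(ok)) next
    t1 <- pot_type_index(ty[pairs[ok, 1]], atoms[1])
    t2 <- pot_type_index(ty[pairs[ok, 2]], atoms[2])
    tot <- tot + sum(E[cbind(t1, t2, b[ok])])
  }
  tot
}

# Batched measures for a light fragment-alignment list (ids + fragment
# table attribute): preserved core contacts, query energy, template
# energy.  All three decompose over fragment pairs, so they are computed
# once per co-occurring fragment pair and summed per chain.
fa_measures <- function(fas, template, query, pot, core_contacts,
                        ctx = NULL) {
  query <- as_aa_vector(query)
  used <- attr(fas, "fragments")
  if (is.null(used)) stop("fa_measures needs the fragment-table attribute")
  if (is.null(ctx)) ctx <- make_energy_context(template, pot, core_contacts)
  nf <- nrow(used)
  E <- pot$energy
  sid <- ctx$sid
  spans <- lapply(seq_len(nf), function(i)
    used$t_start[i]:(used$t_start[i] + used$len[i] - 1L))
  qspans <- lapply(seq_len(nf), function(i)
    used$q_start[i]:(used$q_start[i] + used$len[i] - 1L))
  # per-fragment: SSE-member mask and query residue types
  hydq <- lapply(seq_len(nf), function(i) is_hydrophobic(query[qspans[[i]]]))

  pair_term <- function(ti, qi, tj, qj) {
    # energies between residue set i and residue set j (disjoint), plus
    # preserved core contacts; returns c(qe, te, pre)
    ki <- !is.na(sid[ti]); kj <- !is.na(sid[tj])
    ti2 <- ti[ki]; qi2 <- qi[ki]; tj2 <- tj[kj]; qj2 <- qj[kj]
    qe <- te <- 0
    if (length(ti2) && length(tj2)) {
      grid <- expand.grid(a = seq_along(ti2), b = seq_along(tj2))
      sepq <- abs(qi2[grid$a] - qj2[grid$b])
      sept <- abs(ti2[grid$a] - tj2[grid$b])
      for (ci in 1:3) {
        B <- ctx$binm[[ci]]
        atoms <- list(c("CA", "CA"), c("CB", "CB"), c("CA", "CB"))[[ci]]
        if (ci < 3) {
          b <- B[cbind(ti2[grid$a], tj2[grid$b])]
          okq <- !is.na(b) & sepq >= 2L & sept >= 2L
          okt <- !is.na(b) & sept >= 2L
          if (any(okq))
            qe <- qe + sum(E[cbind(pot_type_index(query[qi2[grid$a[okq]]], atoms[1]),
                                   pot_type_index(query[qj2[grid$b[okq]]], atoms[2]),
                                   b[okq])])
          if (any(okt))
            te <- te + sum(E[cbind(pot_type_index(ctx$tseq[ti2[grid$a[okt]]], atoms[1]),
                                   pot_type_index(ctx$tseq[tj2[grid$b[okt]]], atoms[2]),
                                   b[okt])])
        } else {
          for (ordr in 1:2) {
            aa <- if (ordr == 1) grid$a else grid$b
            bb <- if (ordr == 1) grid$b else grid$a
            tiA <- if (ordr == 1) ti2 else tj2
            tiB <- if (ordr == 1) tj2 else ti2
            qiA <- if (ordr == 1) qi2 else qj2
            qiB <- if (ordr == 1) qj2 else qi2
            b <- B[cbind(tiA[aa], tiB[bb])]
            okq <- !is.na(b) & sepq >= 2L & sept >= 2L
            okt <- !is.na(b) & sept >= 2L
            if (any(okq))
              qe <- qe + sum(E[cbind(pot_type_index(query[qiA[aa[okq]]], "CA"),
                                     pot_type_index(query[qiB[bb[okq]]], "CB"),
                                     b[okq])])
            if (any(okt))
              te <- te + sum(E[cbind(pot_type_index(ctx$tseq[tiA[aa[okt]]], "CA"),
                                     pot_type_index(ctx$tseq[tiB[bb[okt]]], "CB"),
                                     b[okt])])
          }
        }
      }
    }
    pre <- 0L
    if (nrow(core_contacts)) {
      hi <- ti[ki][hyd_at(qi[ki], query)]
      hj <- tj[kj][hyd_at(qj[kj], query)]
      if (length(hi) && length(hj)) {
        pre <- sum((core_contacts[, 1] %in% hi & core_contacts[, 2] %in% hj) |
                     (core_contacts[, 1] %in% hj & core_contacts[, 2] %in% hi))
      }
    }
    c(qe, te, pre)
  }

  intra_term <- function(f) {
    # a fragment lives inside one SSE: inter-element energies are zero
    ti <- spans[[f]]; qi <- qspans[[f]]
    ki <- !is.na(sid[ti])
    ti2 <- ti[ki]; qi2 <- qi[ki]
    qe <- 0
    te <- 0
    pre <- 0L
    if (nrow(core_contacts)) {
      h <- ti2[is_hydrophobic(query[qi2])]
      if (length(h) > 1)
        pre <- sum(core_contacts[, 1] %in% h & core_contacts[, 2] %in% h)
    }
    c(qe, te, pre)
  }

  # pass 1: per-chain unordered member-pair index lists (including the
  # diagonal) and the set of fragment pairs that actually co-occur
  nfa <- length(fas)
  pair_lists <- vector("list", nfa)
  for (k in seq_len(nfa)) {
    ids <- fas[[k]]$ids
    m <- length(ids)
    a <- rep(ids, times = seq(m, 1))
    b <- unlist(lapply(seq_len(m), function(j) ids[j:m]), use.names = FALSE)
    pair_lists[[k]] <- a + (b - 1L) * nf
  }
  faid <- rep.int(seq_len(nfa), lengths(pair_lists))
  lin_all <- unlist(pair_lists, use.names = FALSE)
  need <- unique(lin_all)

  # pass 2: compute the three terms once per co-occurring fragment pair
  Mq <- Mt <- Mp <- numeric(nf * nf)
  for (lin in need) {
    a <- ((lin - 1L) %% nf) + 1L
    b <- ((lin - 1L) %/% nf) + 1L
    v <- if (a == b) intra_term(a)
         else pair_term(spans[[a]], qspans[[a]], spans[[b]], qspans[[b]])
    Mq[lin] <- v[1]; Mt[lin] <- v[2]; Mp[lin] <- v[3]
  }

  # pass 3: one grouped sum per measure
  qe <- as.numeric(rowsum(Mq[lin_all], faid, reorder = TRUE))
  te <- as.numeric(rowsum(Mt[lin_all], faid, reorder = TRUE))
  pre <- as.integer(round(rowsum(Mp[lin_all], faid, reorder = TRUE)))
  data.frame(preserved = pre, query_energy = qe, template_energy = te)
}

hyd_at <- function(qi, query) is_hydrophobic(query[qi])
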