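# Alignment-ensemble evaluation: inter-alignment distance (IAD), FDS2,
# and ensemble diversity statistics.

# Extend an alignment path to a continuous query-position function q(t)
# over template positions 1..Lt: aligned pairs are exact, gaps are
# linearly interpolated between flanking pairs, unaligned termini are
# extrapolated at constant diagonal offset from the nearest aligned pair.
path_step_function <- function(path, template_len) {
  p <- path_matrix(path)
  if (!nrow(p)) return(rep(NA_real_, template_len))
  t <- seq_len(template_len)
  if (nrow(p) == 1) return(p[1, 2] + (t - p[1, 1]))
  q <- stats::approx(p[, 1], p[, 2], xout = t, rule = 1)$y
  first <- p[1, ]; last <- p[nrow(p), ]
  left <- t < first[1]
  right <- t > last[1]
  q[left] <- first[2] + (t[left] - first[1])
  q[right] <- last[2] + (t[right] - last[1])
  q
}

#' Inter-alignment distance (IAD)
#'
#' The area between two alignment paths drawn in the dynamic-programming
#' matrix, divided by the template length: the average number of query
#' residues a position is shifted between the two alignments (units:
#' residues).  Paths are extended to continuous functions of template
#' position (gaps linearly interpolated, termini extrapolated along the
#' diagonal).  An empty path yields the maximal-disagreement sentinel
#' `template_len`.
#'
#' @param path_a,path_b alignment paths (2-column `(t, q)` matrices)
#'   over the same sequences.
#' @param template_len template length.
#' @return non-negative scalar; 0 iff the extended paths coincide.
#' @export
iad <- function(path_a, path_b, template_len) {
  qa <- path_step_function(path_a, template_len)
  qb <- path_step_function(path_b, template_len)
  if (all(is.na(qa)) || all(is.na(qb))) return(as.numeric(template_len))
  mean(abs(qa - qb))
}

#' FDS2: fraction of SSE residues near their correct alignment
#'
#' Over template secondary-structure positions aligned in the correct
#' path, the percentage whose query partner in `path` lies within +/-2
#' of the correct partner.  Positions unaligned in `path` count as
#' misses.  Loop positions are excluded by construction.
#'
#' @param path candidate alignment path.
#' @param correct_path reference (structure-based) alignment path.
#' @param sse_mask logical vector over template positions (TRUE = SSE).
#' @return percentage in `[0, 100]`.
#' @export
fds2 <- function(path, correct_path, sse_mask) {
  cp <- path_matrix(correct_path)
  keep <- sse_mask[cp[, 1]]
  cp <- cp[keep, , drop = FALSE]
  if (!nrow(cp))
    stop("correct path has no aligned SSE positions; FDS2 undefined")
  p <- path_matrix(path)
  qmap <- rep(NA_integer_, length(sse_mask))
  if (nrow(p)) qmap[p[, 1]] <- p[, 2]
  partner <- qmap[cp[, 1]]
  hit <- !is.na(partner) & abs(partner - cp[, 2]) <= 2
  mean(hit) * 100
}

#' Ensemble statistics: sampling diversity and distance to a reference
#'
#' Computes the number of unique query residues sampled at each template
#' position across ensemble members, the IAD of every member against a
#' reference path, and summary statistics.
#'
#' @param ensemble list of alignment paths, or an `alignment_ensemble`.
#' @param reference_path reference (e.g. ground-truth) path.
#' @param template annotated template (or an integer template length).
#' @return list with `unique_counts` (per template position),
#'   `mean_unique`, `iad` (per member), `mean_iad`, `sd_iad`,
#'   `best_iad_member`, `best_fds2_member` and `best_fds2` (when SSE
#'   annotation is available).
#' @export
ensemble_stats <- function(ensemble, reference_path, template) {
  paths <- if (inherits(ensemble, "alignment_ensemble")) ensemble$paths
           else ensemble
  if (!length(paths)) stop("empty ensemble")
  Lt <- if (is.numeric(template)) as.integer(template) else length(template)
  counts <- integer(Lt)
  seen <- vector("list", Lt)
  for (p in paths) {
    pm <- path_matrix(p)
    if (!nrow(pm)) next
    for (r in seq_len(nrow(pm)))
      seen[[pm[r, 1]]] <- c(seen[[pm[r, 1]]], pm[r, 2])
  }
  counts <- vapply(seen, function(v) length(unique(v)), 0L)
  iads <- vapply(paths, iad, 0, path_b = reference_path,
                 template_len = Lt)
  out <- list(unique_counts = counts,
              mean_unique = mean(counts),
              iad = iads,
              mean_iad = mean(iads),
              sd_iad = stats::sd(iads),
              best_iad_member = which.min(iads))
  if (length(paths) < 2) out$sd_iad <- 0
  if (!is.numeric(template) && !is.null(template$sse_id)) {
    mask <- !is.na(template$sse_id)
    f <- vapply(paths, fds2, 0, correct_path = reference_path,
                sse_mask = mask)
    out$fds2 <- f
    out$best_fds2_member <- which.max(f)
    out$best_fds2 <- max(f)
  }
  out
}
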