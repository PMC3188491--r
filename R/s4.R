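# Main entry point: the structure-guided suboptimal alignment sampler.
#
# Pipeline: template SSE columns -> fragment pool (primary + secondary)
# -> exhaustive fragment-alignment enumeration with modelability pruning
# -> three-measure percentile gate and redundancy removal -> corridor-
# restricted DP finishing -> ranked ensemble of N unique full alignments.

#' Sampler configuration
#'
#' All tunable parameters of the pipeline, with their standard defaults.
#' Score-dimension thresholds (insertion penalty, finishing delta) are in
#' the units of the active scorer (half-bits for the bundled BLOSUM62).
#'
#' @param min_fragment_len minimum fragment length (residues).
#' @param k_per_sse primary fragments retained per SSE column.
#' @param adjacent_diagonal_tol diagonal offset (residues) within which a
#'   secondary fragment counts as "adjacent" to a flanking fragment.
#' @param score_extra extra score-selected secondary fragments per
#'   intervening SSE.
#' @param max_total_alignments fragment-pool growth stops once the number
#'   of enumerable fragment alignments would exceed this cap.
#' @param max_enumerated hard cap on explicitly enumerated fragment
#'   alignments (depth-first order is deterministic); sized so the
#'   downstream measure and redundancy stages stay interactive on
#'   single-domain templates.
#' @param min_coverage_frac minimum fraction of the shorter sequence that
#'   must be aligned (SSE residues only).
#' @param contact_order_ratio_min minimum pseudomodel/template
#'   contact-order ratio.
#' @param loop_stretch_factor Angstrom bridged per query loop residue.
#' @param cb_contact_cutoff CB-CB contact distance (A) for contact order
#'   and core contacts.
#' @param burial_min burial threshold for core contacts.
#' @param lower_percentile,upper_percentile percentile-gate thresholds.
#' @param redundancy_shift,redundancy_iad redundancy thresholds
#'   (fragment diagonal shift; inter-alignment distance).
#' @param redundancy_pool_max at most this many gate survivors (by
#'   descending score) enter the quadratic redundancy sweep; emission
#'   never reaches deeper for practical ensemble sizes.
#' @param corridor_margin half-width (residues) of the finishing band.
#' @param finish_delta score slack for in-corridor sampling.
#' @param finish_max_n candidate full alignments per fragment alignment.
#' @param insertion_penalty flat penalty per internal inserted query
#'   residue (terminal insertions free; deletions unpenalized).
#' @param energy_score_weight weight of the similarity score inside the
#'   finishing selection objective (energy - weight * score); 0 selects
#'   purely by statistical energy.
#' @param gap_open,gap_extend affine penalties for the DP baselines.
#' @return an `s4_config` list.
#' @export
s4_config <- function(min_fragment_len = 3L,
                      k_per_sse = 4L,
                      adjacent_diagonal_tol = 5L,
                      score_extra = 2L,
                      max_total_alignments = 1e7,
                      max_enumerated = 2e4,
                      min_coverage_frac = 0.10,
                      contact_order_ratio_min = 0.65,
                      loop_stretch_factor = 3.3,
                      cb_contact_cutoff = 6,
                      burial_min = 0.6,
                      lower_percentile = 66,
                      upper_percentile = 90,
                      redundancy_shift = 4,
                      redundancy_iad = 1.0,
                      redundancy_pool_max = 2000L,
                      corridor_margin = 3L,
                      finish_delta = 6,
                      finish_max_n = 20L,
                      insertion_penalty = 1.0,
                      energy_score_weight = 0,
                      gap_open = 10,
                      gap_extend = 1) {
  cfg <- as.list(environment())
  num <- vapply(cfg, is.numeric, TRUE)
  if (any(vapply(cfg[num], function(v) any(v < 0), TRUE)))
    stop("all configuration values must be non-negative")
  if (!(cfg$lower_percentile < cfg$upper_percentile &&
        cfg$upper_percentile < 100))
    stop("percentile thresholds must satisfy 0 < lower < upper < 100")
  structure(cfg, class = "s4_config")
}

new_ensemble <- function(paths, table, method, extra = list()) {
  obj <- c(list(paths = paths,
                table = if (is.null(table)) data.frame() else table,
                method = method),
           extra)
  class(obj) <- if (method == "s4") c("s4_ensemble", "alignment_ensemble")
                else "alignment_ensemble"
  obj
}

#' @export
length.alignment_ensemble <- function(x) length(x$paths)

#' @export
print.alignment_ensemble <- function(x, ...) {
  cat(sprintf("Alignment ensemble (%s): %d member(s)\n", x$method,
              length(x$paths)))
  if (nrow(x$table)) {
    cat("  top members:\n")
    print(utils::head(x$table, 5), row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.alignment_ensemble <- function(object, reference = NULL,
                                       template = NULL, ...) {
  cat(sprintf("%s ensemble, %d member(s)\n", object$method,
              length(object$paths)))
  lens <- vapply(object$paths, function(p) nrow(path_matrix(p)), 0L)
  cat(sprintf("  aligned pairs per member: min %d, median %.0f, max %d\n",
              min(lens), stats::median(lens), max(lens)))
  if (!is.null(reference)) {
    Lt <- if (is.null(template)) max(unlist(lapply(object$paths, function(p)
      path_matrix(p)[, 1])))
      else if (is.numeric(template)) template else length(template)
    st <- ensemble_stats(object, reference, if (is.null(template)) Lt else template)
    cat(sprintf("  IAD vs reference: best %.2f (member %d), mean %.2f, sd %.2f\n",
                min(st$iad), st$best_iad_member, st$mean_iad, st$sd_iad))
    if (!is.null(st$best_fds2))
      cat(sprintf("  best FDS2: %.1f%% (member %d)\n",
                  st$best_fds2, st$best_fds2_member))
  }
  invisible(object)
}

#' @export
as.data.frame.alignment_ensemble <- function(x, ...) x$table

#' Plot ensemble paths in the alignment matrix
#'
#' Draws every member path (template position vs query position) with
#' template SSE spans shaded, the standard way alignment samplers are
#' visualized.
#'
#' @param x an `alignment_ensemble`.
#' @param template optional annotated template (for SSE shading).
#' @param reference optional reference path drawn in red.
#' @param ... passed to [graphics::plot()].
#' @export
plot.alignment_ensemble <- function(x, template = NULL, reference = NULL,
                                    ...) {
  pm <- lapply(x$paths, path_matrix)
  pm <- pm[vapply(pm, nrow, 0L) > 0]
  if (!length(pm)) stop("nothing to plot: all paths empty")
  xl <- range(unlist(lapply(pm, function(p) p[, 1])))
  yl <- range(unlist(lapply(pm, function(p) p[, 2])))
  graphics::plot(NA, xlim = xl, ylim = yl, xlab = "template position",
                 ylab = "query position", ...)
  if (!is.null(template) && !is.null(template$sse)) {
    for (k in seq_len(nrow(template$sse)))
      graphics::rect(template$sse$start[k], yl[1], template$sse$end[k],
                     yl[2], col = grDevices::adjustcolor("grey80", 0.5),
                     border = NA)
  }
  for (p in pm)
    graphics::lines(p[, 1], p[, 2],
                    col = grDevices::adjustcolor("steelblue", 0.35))
  if (!is.null(reference)) {
    rp <- path_matrix(reference)
    graphics::lines(rp[, 1], rp[, 2], col = "red", lwd = 2)
  }
  invisible(x)
}

#' Structure-guided suboptimal alignment sampling
#'
#' Runs the full sampler: fragment selection in template SSE columns,
#' exhaustive fragment-alignment enumeration with modelability pruning,
#' the three-measure percentile gate (preserved core contacts, query
#' energy, template energy), redundancy removal, and corridor-restricted
#' DP finishing, returning the top `N` unique full alignments.
#'
#' @param template annotated [template_structure()] (run
#'   [annotate_template()] first).
#' @param query query sequence (string, letter vector, or FASTA path via
#'   [read_fasta()]).
#' @param N ensemble size.
#' @param model score model (default bundled BLOSUM62).
#' @param potential distance potential (default: trained once on the
#'   package's synthetic fold set and cached for the session).
#' @param config an [s4_config()].
#' @param max_template_len refuse templates longer than this (long
#'   chains make exhaustive enumeration impractical); raise explicitly
#'   to override.
#' @return an `s4_ensemble` (see [rank_and_emit()]): member paths plus a
#'   score table and per-stage filter tallies in `$tallies`.
#' @export
s4_align <- function(template, query, N = 100L,
                     model = load_substitution_matrix(),
                     potential = NULL,
                     config = s4_config(),
                     max_template_len = 350L) {
  if (!inherits(template, "template_structure"))
    stop("template must be a template_structure")
  if (is.null(template$sse) || is.null(template$burial))
    stop("template is not annotated; run annotate_template()")
  if (length(template) > max_template_len)
    stop(sprintf("template has %d residues (> %d); raise max_template_len to override",
                 length(template), max_template_len))
  if (nrow(template$sse) == 0)
    stop("template has no secondary structure elements; the sampler cannot run")
  query <- as_aa_vector(query, "query sequence")
  if (is.null(potential)) potential <- cached_default_potential()
  template <- complete_cb(template)

  sim <- build_similarity_matrix(query, template, model)
  pool <- enumerate_all_fragments(sim, config$min_fragment_len)
  if (!nrow(pool)) stop("no feasible fragments (query shorter than the minimum fragment length?)")
  pool <- select_primary(pool, config$k_per_sse, length(query), length(template))
  pool <- select_secondary(pool, template, config, length(query))

  fas <- enumerate_fragment_alignments(pool, template, query, config)
  tallies <- attr(fas, "tallies")

  core <- find_core_contacts(template, config$burial_min,
                             config$cb_contact_cutoff)
  meas <- fa_measures(fas, template, query, potential, core)
  keep <- percentile_gate(meas, config$lower_percentile,
                          config$upper_percentile)
  if (!any(keep)) {
    # degenerate candidate sets (strongly anti-correlated measures) can
    # leave the two-tier gate empty; fall back to the all-above-lower
    # arm, then to the best candidates by summed percentile rank
    r1 <- percentile_ranks(meas$preserved)
    r2 <- percentile_ranks(-meas$query_energy)
    r3 <- percentile_ranks(-meas$template_energy)
    keep <- pmin(r1, pmin(r2, r3)) >= config$lower_percentile
    if (!any(keep)) keep <- (r1 + r2 + r3) >= max(r1 + r2 + r3)
  }
  tallies["gated"] <- sum(keep)
  frag_tab <- attr(fas, "fragments")
  kidx <- which(keep)
  if (length(kidx) > config$redundancy_pool_max) {
    sc <- vapply(fas[kidx], `[[`, 0, "fa_score")
    kidx <- kidx[order(-sc)[seq_len(config$redundancy_pool_max)]]
  }
  surv <- materialize_fas(fas[kidx], frag_tab)
  for (k in seq_along(surv))
    surv[[k]]$measures <- c(preserved = meas$preserved[kidx][k],
                            query_energy = meas$query_energy[kidx][k],
                            template_energy = meas$template_energy[kidx][k])
  fas <- surv
  if (!length(fas))
    stop("no fragment alignment survived the percentile gate")

  fas <- remove_redundant(fas, length(template),
                          config$redundancy_shift, config$redundancy_iad)
  tallies["nonredundant"] <- length(fas)

  ens <- rank_and_emit(fas, template, query, model, potential, config, N)
  ens$tallies <- tallies
  ens$template_len <- length(template)
  ens$query_len <- length(query)
  ens$config <- config
  ens
}

# Session cache for the default trained potential.
.pkg_cache <- new.env(parent = emptyenv())

cached_default_potential <- function() {
  if (is.null(.pkg_cache$potential))
    .pkg_cache$potential <- default_potential()
  .pkg_cache$potential
}

#' Read the first sequence of a FASTA file
#' @param path FASTA file.
#' @return character vector of residue letters.
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readBStringSet(path)
  if (!length(s)) stop(sprintf("no sequences in %s", path))
  as_aa_vector(as.character(s[[1]]), basename(path))
}

#' Write an alignment ensemble as pairwise FASTA
#'
#' One record pair per member (template row, then query row, gapped),
#' rank and scores in the headers.
#'
#' @param ens an `alignment_ensemble`.
#' @param template template sequence or structure.
#' @param query query sequence.
#' @param path output file.
#' @export
write_ensemble_fasta <- function(ens, template, query, path) {
  tseq <- template_seq_of(template)
  qseq <- as_aa_vector(query)
  recs <- character(0)
  for (k in seq_along(ens$paths)) {
    p <- path_matrix(ens$paths[[k]])
    al <- path_to_gapped(p, tseq, qseq)
    score <- if (nrow(ens$table) >= k && !is.null(ens$table$dp_score))
      sprintf(" score=%.3f", ens$table$dp_score[k]) else ""
    recs <- c(recs,
              sprintf(">template|rank=%d%s", k, score), al$template,
              sprintf(">query|rank=%d%s", k, score), al$query)
  }
  writeLines(recs, path)
  invisible(path)
}

#' Read an ensemble written by [write_ensemble_fasta()]
#' @param path pairwise FASTA file.
#' @return an `alignment_ensemble`.
#' @export
read_ensemble_fasta <- function(path) {
  s <- Biostrings::readBStringSet(path)
  if (length(s) %% 2 != 0) stop("pairwise FASTA must hold record pairs")
  paths <- list()
  for (k in seq_len(length(s) / 2)) {
    trow <- strsplit(as.character(s[[2 * k - 1]]), "")[[1]]
    qrow <- strsplit(as.character(s[[2 * k]]), "")[[1]]
    ti <- cumsum(trow != "-")
    qi <- cumsum(qrow != "-")
    al <- which(trow != "-" & qrow != "-")
    paths[[k]] <- path_matrix(cbind(ti[al], qi[al]))
  }
  new_ensemble(paths, data.frame(rank = seq_along(paths)),
               method = "imported")
}

path_to_gapped <- function(p, tseq, qseq) {
  trow <- character(0); qrow <- character(0)
  ti <- 1L; qi <- 1L
  emit_cols <- function(tt, qq) {
    trow <<- c(trow, tt); qrow <<- c(qrow, qq)
  }
  for (r in seq_len(nrow(p))) {
    while (ti < p[r, 1]) { emit_cols(tseq[ti], "-"); ti <- ti + 1L }
    while (qi < p[r, 2]) { emit_cols("-", qseq[qi]); qi <- qi + 1L }
    emit_cols(tseq[ti], qseq[qi]); ti <- ti + 1L; qi <- qi + 1L
  }
  while (ti <= length(tseq)) { emit_cols(tseq[ti], "-"); ti <- ti + 1L }
  while (qi <= length(qseq)) { emit_cols("-", qseq[qi]); qi <- qi + 1L }
  list(template = paste(trow, collapse = ""),
       query = paste(qrow, collapse = ""))
}

#' Write the per-member score table as TSV
#' @param ens ensemble.
#' @param path output file.
#' @export
write_score_tsv <- function(ens, path) {
  utils::write.table(ens$table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
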