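# Distance-dependent statistical potential over CA/CB atoms of
# secondary-structure residues, with a finite-ideal-gas style reference
# state: e(i,j,r) = -eta * ln[ N(i,j,r) / ((r/r_cut)^alpha *
# (dr/dr_cut) * N(i,j,r_cut)) ].  Loop residues are excluded both from
# training counts and from energy evaluation; the energy is exactly zero
# at and beyond the cutoff bin.

POT_ATOMS <- c("CA", "CB")

pot_type_index <- function(aa, atom) {
  match(aa, AA20) + ifelse(atom == "CB", 20L, 0L)
}

#' Train a distance-dependent statistical potential
#'
#' Counts CA/CB atom pairs between secondary-structure residues of
#' DIFFERENT secondary-structure elements (sequence separation >=
#' `min_sep`), bins distances at `bin_width` up to `cutoff`, and converts
#' counts to energies with the distance-power reference state.  Pairs
#' within one element are excluded: their distances are fixed by the
#' regular backbone geometry and carry no packing information, yet would
#' dominate the counts.  Deterministic for a fixed input set.
#'
#' @param structures list of annotated [template_structure()] objects
#'   (at least 20 recommended for stable counts).
#' @param bin_width distance bin width (A).
#' @param cutoff interaction cutoff (A); the last bin is the reference.
#' @param alpha reference-state distance exponent.
#' @param eta temperature scale (relative ranking is what matters; 1).
#' @param pseudocount added to every bin count.
#' @param min_sep minimum residue-sequence separation for a counted pair.
#' @return object of class `distance_potential`: list with `energy`
#'   (40 x 40 x n_bins array, types = 20 aa x {CA, CB}), `bin_width`,
#'   `cutoff`, `alpha`, `counts`.
#' @export
train_potential <- function(structures, bin_width = 0.5, cutoff = 14.5,
                            alpha = 1.61, eta = 1, pseudocount = 5,
                            min_sep = 2L) {
  if (!length(structures)) stop("empty structure set")
  nb <- as.integer(round(cutoff / bin_width))
  ntype <- 40L
  counts <- array(0, c(ntype, ntype, nb))
  for (ts in structures) {
    ts <- complete_cb(ts)
    if (is.null(ts$sse_id)) stop("structures must carry SSE annotation")
    idx <- which(!is.na(ts$sse_id))
    if (length(idx) < 2) next
    for (a1 in POT_ATOMS) for (a2 in POT_ATOMS) {
      x1 <- ts$xyz[[tolower(a1)]][idx, , drop = FALSE]
      x2 <- ts$xyz[[tolower(a2)]][idx, , drop = FALSE]
      D <- dist_xyz(x1, x2)
      sep <- abs(outer(idx, idx, "-"))
      cross <- outer(ts$sse_id[idx], ts$sse_id[idx], "!=")
      sel <- which(sep >= min_sep & cross & D < cutoff, arr.ind = TRUE)
      if (!nrow(sel)) next
      t1 <- pot_type_index(ts$sequence[idx[sel[, 1]]], a1)
      t2 <- pot_type_index(ts$sequence[idx[sel[, 2]]], a2)
      bin <- pmin(floor(D[sel] / bin_width) + 1L, nb)
      # both orderings of each residue pair are covered by the atom-role
      # loop, so the table comes out symmetric
      lin <- t1 + (t2 - 1L) * ntype + (bin - 1L) * ntype * ntype
      tab <- tabulate(lin, nbins = ntype * ntype * nb)
      counts <- counts + array(tab, dim(counts))
    }
  }
  r_mid <- (seq_len(nb) - 0.5) * bin_width
  r_cut <- r_mid[nb]
  energy <- array(0, c(ntype, ntype, nb))
  ref <- counts[, , nb]
  # pseudocounts are distributed along the reference shape so that
  # sparsely observed type pairs regularize to zero energy instead of
  # acquiring large spurious values; with abundant data the estimator
  # converges to the plain count ratio
  for (b in seq_len(nb)) {
    z <- (r_mid[b] / r_cut)^alpha
    energy[, , b] <- -eta * log((counts[, , b] + pseudocount * z) /
                                  ((ref + pseudocount) * z))
  }
  energy[, , nb] <- 0
  tn <- c(paste0(AA20, ".CA"), paste0(AA20, ".CB"))
  dimnames(energy) <- list(tn, tn, NULL)
  structure(list(energy = energy, bin_width = bin_width, cutoff = cutoff,
                 alpha = alpha, eta = eta, counts = counts),
            class = "distance_potential")
}

#' @export
print.distance_potential <- function(x, ...) {
  cat(sprintf(
    "Distance potential: 40 atom types (20 aa x CA/CB), %d bins of %.2f A, cutoff %.1f A, alpha %.2f\n",
    dim(x$energy)[3], x$bin_width, x$cutoff, x$alpha))
  invisible(x)
}

#' Write a potential table as whitespace text
#' @param pot a `distance_potential`.
#' @param path output file.
#' @export
write_potential <- function(pot, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nb <- dim(pot$energy)[3]
  writeLines(c("# distance potential table",
               sprintf("alphabet %s", paste(AA20, collapse = "")),
               "atoms CA CB",
               sprintf("bin_width %g", pot$bin_width),
               sprintf("cutoff %g", pot$cutoff),
               sprintf("alpha %g", pot$alpha)), con)
  tn <- dimnames(pot$energy)[[1]]
  for (i in seq_len(40)) for (j in seq_len(40)) {
    writeLines(paste(tn[i], tn[j],
                     paste(sprintf("%.6g", pot$energy[i, j, ]), collapse = " ")),
               con)
  }
  invisible(path)
}

#' Read a potential table written by [write_potential()]
#' @param path table file.
#' @return a `distance_potential` (without counts).
#' @export
read_potential <- function(path) {
  lines <- readLines(path)
  meta <- lines[grepl("^(alphabet|atoms|bin_width|cutoff|alpha)\\b", lines)]
  fields <- lapply(meta, function(ln) strsplit(trimws(ln), "\\s+")[[1]])
  getv <- function(key) {
    hit <- fields[vapply(fields, function(f) f[1] == key, TRUE)]
    if (!length(hit)) stop(sprintf("potential table lacks '%s' header", key))
    hit[[1]][-1]
  }
  bin_width <- as.numeric(getv("bin_width"))
  cutoff <- as.numeric(getv("cutoff"))
  alpha <- as.numeric(getv("alpha"))
  nb <- as.integer(round(cutoff / bin_width))
  body <- lines[!grepl("^#", lines) &
                  !grepl("^(alphabet|atoms|bin_width|cutoff|alpha)\\b", lines) &
                  nzchar(trimws(lines))]
  energy <- array(0, c(40, 40, nb))
  tn <- c(paste0(AA20, ".CA"), paste0(AA20, ".CB"))
  dimnames(energy) <- list(tn, tn, NULL)
  for (ln in body) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    i <- match(f[1], tn); j <- match(f[2], tn)
    v <- as.numeric(f[-(1:2)])
    if (is.na(i) || is.na(j) || length(v) != nb || anyNA(v))
      stop(sprintf("malformed potential table row: '%s'",
                   substr(ln, 1, 40)))
    energy[i, j, ] <- v
  }
  structure(list(energy = energy, bin_width = bin_width, cutoff = cutoff,
                 alpha = alpha, eta = 1, counts = NULL),
            class = "distance_potential")
}

# Energy of a set of residues with given types on template geometry.
# idx: template residue indices (SSE members only are kept); types: amino
# acid letter per index; sep_idx (and optionally sep_idx2): indices used
# for the bonded-neighbor exclusion -- a pair is counted only when it is
# separated by at least min_sep in every supplied numbering.
residue_set_energy <- function(template, idx, types, sep_idx, pot,
                               min_sep = 2L, sep_idx2 = NULL) {
  keep <- !is.na(template$sse_id[idx])
  idx <- idx[keep]; types <- types[keep]; sep_idx <- sep_idx[keep]
  if (!is.null(sep_idx2)) sep_idx2 <- sep_idx2[keep]
  n <- length(idx)
  if (n < 2) return(0)
  E <- 0
  nb <- dim(pot$energy)[3]
  sep <- abs(outer(sep_idx, sep_idx, "-"))
  if (!is.null(sep_idx2))
    sep <- pmin(sep, abs(outer(sep_idx2, sep_idx2, "-")))
  sid <- template$sse_id[idx]
  cross <- outer(sid, sid, "!=")
  sep[!cross] <- 0L                        # same-element pairs excluded
  offdiag <- row(sep) != col(sep)
  # each unordered residue pair contributes once per atom-role combo:
  # (CA,CA) and (CB,CB) via the upper triangle, (CA,CB) via both
  # off-diagonal orderings (covering CB,CA as well)
  for (combo in list(c("CA", "CA"), c("CB", "CB"), c("CA", "CB"))) {
    a1 <- combo[1]; a2 <- combo[2]
    x1 <- template$xyz[[tolower(a1)]][idx, , drop = FALSE]
    x2 <- template$xyz[[tolower(a2)]][idx, , drop = FALSE]
    D <- dist_xyz(x1, x2)
    mask <- if (a1 == a2) upper.tri(D) else offdiag
    s <- which(sep >= min_sep & D < pot$cutoff & mask, arr.ind = TRUE)
    if (!nrow(s)) next
    t1 <- pot_type_index(types[s[, 1]], a1)
    t2 <- pot_type_index(types[s[, 2]], a2)
    bin <- pmin(floor(D[s] / pot$bin_width) + 1L, nb)
    E <- E + sum(pot$energy[cbind(t1, t2, bin)])
  }
  E
}

#' Query energy of a pseudomodel
#'
#' Statistical energy over all CA/CB atom pairs of distinct aligned
#' secondary-structure residues, using query amino-acid types on template
#' geometry.  Bonded neighbors are excluded in both numberings (sequence
#' separation >= 2 in the query AND in the template), so candidates that
#' differ only in gap placement are compared over the same pair set.
#'
#' @param pm a [build_pseudomodel()] result, or NULL-equivalent empty.
#' @param template the annotated template the pseudomodel came from.
#' @param pot a `distance_potential`.
#' @return scalar energy (0 for fewer than two residues).
#' @export
query_energy <- function(pm, template, pot) {
  if (!length(pm$t_idx)) return(0)
  if (anyNA(template$xyz$cb[pm$t_idx, 1]))
    stop("pseudomodel references template residues without CB coordinates")
  residue_set_energy(template, pm$t_idx, pm$q_aa, pm$q_idx, pot,
                     sep_idx2 = pm$t_idx)
}

#' Template energy of an alignment
#'
#' Statistical energy of the aligned template-residue subset with the
#' template's own amino-acid types (template-sequence separation >= 2).
#' Flags alignments whose covered SSE subset does not resemble a folded
#' unit (e.g. fragments scattered across domains).
#'
#' @param path alignment path (2-column `(t, q)` matrix) or a vector of
#'   aligned template indices.
#' @param template annotated template.
#' @param pot a `distance_potential`.
#' @return scalar energy.
#' @export
template_energy <- function(path, template, pot) {
  t_idx <- if (is.matrix(path)) path_matrix(path)[, 1] else as.integer(path)
  if (!length(t_idx)) return(0)
  residue_set_energy(template, t_idx, template$sequence[t_idx], t_idx, pot)
}

#' Train the package's default potential on synthetic folds
#'
#' Convenience used by examples and tests: builds a deterministic set of
#' idealized folds with [make_fold()] and trains on them.
#'
#' @param n_structures number of folds.
#' @param seed integer seed.
#' @param ... passed to [train_potential()].
#' @return a `distance_potential`.
#' @export
default_potential <- function(n_structures = 24L, seed = 42L, ...) {
  archetypes <- list(c("H", "H", "H", "H"), c("E", "E", "E", "E", "E"),
                     c("E", "E", "H", "H", "E"), c("H", "E", "E", "H"),
                     c("H", "H", "H", "H", "H"), c("E", "E", "E", "H", "H"))
  sts <- lapply(seq_len(n_structures), function(i) {
    arch <- archetypes[[(i - 1) %% length(archetypes) + 1]]
    lens <- with_seed(seed + i, ifelse(arch == "H", sample(9:13, length(arch), TRUE),
                                       sample(6:9, length(arch), TRUE)))
    make_fold(fold_spec(arch, lens), seed = seed + i)$template
  })
  train_potential(sts, ...)
}
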