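# Template structures: reduced per-residue representation (N, CA, C, CB),
# secondary-structure segmentation, beta-sheet topology, burial, and
# pseudomodel construction.
#
# Conventions: residue indices are 1-based; SSE intervals are closed
# [start, end]; helix kind "H", strand kind "E".

#' Construct a template structure object
#'
#' Low-level constructor used by the PDB reader and the synthetic fold
#' generator.  Coordinate matrices are L x 3 in Angstrom; missing atoms are
#' rows of NA.  Consecutive residues more than `chain_break` apart
#' (CA-CA) split the chain; only the first segment is kept, with a warning,
#' because all downstream geometry assumes a continuous chain.
#'
#' @param sequence character vector of one-letter residue codes (or a
#'   single string).
#' @param ca,n,c,cb L x 3 coordinate matrices (`n`, `c`, `cb` optional).
#' @param resno original residue numbers (bookkeeping only).
#' @param chain chain identifier (bookkeeping only).
#' @param chain_break CA-CA distance (A) above which a chain break is
#'   declared.
#' @return object of class `template_structure` with elements `sequence`,
#'   `xyz` (list of `n`, `ca`, `c`, `cb` matrices), `resno`, `chain`, and
#'   annotation slots (`sse`, `sse_id`, `sheet`, `burial`) initially NULL.
#' @export
template_structure <- function(sequence, ca, n = NULL, c = NULL, cb = NULL,
                               resno = NULL, chain = "A", chain_break = 4.5) {
  sequence <- as_aa_vector(sequence, "template sequence")
  L <- length(sequence)
  ca <- as.matrix(ca)
  stopifnot(nrow(ca) == L, ncol(ca) == 3)
  if (anyNA(ca)) stop("CA coordinates must be present for every residue")
  fill <- function(m) {
    if (is.null(m)) return(matrix(NA_real_, L, 3))
    m <- as.matrix(m); stopifnot(nrow(m) == L, ncol(m) == 3); m
  }
  n <- fill(n); c <- fill(c); cb <- fill(cb)
  dimnames(ca) <- dimnames(n) <- dimnames(c) <- dimnames(cb) <- NULL
  if (is.null(resno)) resno <- seq_len(L)

  if (L > 1) {
    gaps <- sqrt(rowSums((ca[-1, , drop = FALSE] - ca[-L, , drop = FALSE])^2))
    brk <- which(gaps > chain_break)
    if (length(brk)) {
      keep <- seq_len(brk[1])
      warning(sprintf(
        "chain break after residue %d (CA-CA %.1f A > %.1f); keeping first segment of %d residues",
        brk[1], gaps[brk[1]], chain_break, length(keep)))
      sequence <- sequence[keep]
      ca <- ca[keep, , drop = FALSE]; n <- n[keep, , drop = FALSE]
      c <- c[keep, , drop = FALSE]; cb <- cb[keep, , drop = FALSE]
      resno <- resno[keep]
      L <- length(keep)
    }
  }

  structure(list(
    sequence = sequence,
    xyz = list(n = n, ca = ca, c = c, cb = cb),
    resno = resno,
    chain = chain,
    sse = NULL, sse_id = NULL, sheet = NULL, burial = NULL
  ), class = "template_structure")
}

#' @export
length.template_structure <- function(x) length(x$sequence)

#' @export
print.template_structure <- function(x, ...) {
  cat(sprintf("Template structure: %d residues (chain %s)\n",
              length(x), x$chain))
  if (!is.null(x$sse)) {
    nh <- sum(x$sse$kind == "H"); ne <- sum(x$sse$kind == "E")
    cat(sprintf("  SSEs: %d helices, %d strands\n", nh, ne))
    if (!is.null(x$sheet) && nrow(x$sheet$pairs))
      cat(sprintf("  Sheet: %d strand pair(s), core strand(s): %s\n",
                  nrow(x$sheet$pairs),
                  if (length(x$sheet$core)) paste(x$sheet$core, collapse = ",")
                  else "none"))
  } else cat("  (no secondary-structure annotation)\n")
  if (!is.null(x$burial))
    cat(sprintf("  Burial: mean %.2f, %d residue(s) >= 0.6\n",
                mean(x$burial), sum(x$burial >= 0.6)))
  invisible(x)
}

# Complete missing CB atoms (e.g. glycine) with the tetrahedral pseudo-CB.
# Requires N and C; synthesizes them from the CA trace if absent.
complete_cb <- function(ts) {
  miss <- which(is.na(ts$xyz$cb[, 1]))
  if (!length(miss)) return(ts)
  if (anyNA(ts$xyz$n[, 1]) || anyNA(ts$xyz$c[, 1])) {
    bb <- approx_backbone(ts$xyz$ca)
    nafill <- function(have, synth) { i <- is.na(have[, 1]); have[i, ] <- synth[i, ]; have }
    ts$xyz$n <- nafill(ts$xyz$n, bb$n)
    ts$xyz$c <- nafill(ts$xyz$c, bb$c)
  }
  for (i in miss) {
    ts$xyz$cb[i, ] <- place_cb(ts$xyz$n[i, ], ts$xyz$ca[i, ], ts$xyz$c[i, ])
  }
  ts
}

#' Read a single protein chain from a PDB file
#'
#' Wraps [bio3d::read.pdb()].  Keeps ATOM records of the requested chain
#' with alternate-location code blank or "A"; HETATM and non-standard
#' residues are discarded.  Residues are ordered by appearance (insertion
#' codes follow file order).  Residues lacking a CA atom are dropped with
#' a warning.
#'
#' @param path PDB file.
#' @param chain_id chain identifier (default: first chain present).
#' @return a [template_structure()] without SSE/burial annotation.
#' @export
read_pdb <- function(path, chain_id = NULL) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (is.null(chain_id)) chain_id <- at$chain[1]
  at <- at[at$chain == chain_id, , drop = FALSE]
  if (!nrow(at)) stop(sprintf("chain '%s' not found in %s", chain_id, path))
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  aa1 <- suppressWarnings(bio3d::aa321(at$resid))
  at <- at[aa1 %in% AA20, , drop = FALSE]
  if (!nrow(at)) stop(sprintf("chain '%s' has no standard amino-acid ATOM records", chain_id))

  key <- paste(at$resno, at$insert)
  ord <- unique(key)
  L <- length(ord)
  seqv <- character(L); resno <- integer(L)
  get <- function(m) matrix(NA_real_, L, 3)
  xyz <- list(n = get(), ca = get(), c = get(), cb = get())
  idx <- split(seq_len(nrow(at)), factor(key, levels = ord))
  for (k in seq_len(L)) {
    rows <- idx[[k]]
    seqv[k] <- bio3d::aa321(at$resid[rows[1]])
    resno[k] <- at$resno[rows[1]]
    for (an in c("N", "CA", "C", "CB")) {
      r <- rows[at$elety[rows] == an]
      if (length(r)) {
        slot <- tolower(an)
        xyz[[slot]][k, ] <- c(at$x[r[1]], at$y[r[1]], at$z[r[1]])
      }
    }
  }
  no_ca <- is.na(xyz$ca[, 1])
  if (any(no_ca)) {
    warning(sprintf("dropping %d residue(s) without CA: %s",
                    sum(no_ca), paste(resno[no_ca], collapse = ",")))
    keep <- !no_ca
    seqv <- seqv[keep]; resno <- resno[keep]
    xyz <- lapply(xyz, function(m) m[keep, , drop = FALSE])
  }
  template_structure(seqv, ca = xyz$ca, n = xyz$n, c = xyz$c, cb = xyz$cb,
                     resno = resno, chain = chain_id)
}

# Turn a per-residue SSE code vector ("H"/"E"/"-") into the segment table,
# discarding runs shorter than min_len.
runs_to_sse <- function(code, min_len = 3L) {
  r <- rle(code)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values %in% c("H", "E") & r$lengths >= min_len
  sse <- data.frame(kind = r$values[keep], start = starts[keep],
                    end = ends[keep], stringsAsFactors = FALSE)
  sse$index <- seq_len(nrow(sse))
  sse
}

sse_id_vector <- function(sse, L) {
  id <- rep(NA_integer_, L)
  for (k in seq_len(nrow(sse))) id[sse$start[k]:sse$end[k]] <- sse$index[k]
  id
}

#' Read secondary structure and accessibility from a classic DSSP file
#'
#' Parses the fixed-column residue table of classic DSSP text output.
#' Codes H/G/I map to helix, E to strand, everything else to loop; runs
#' shorter than `min_len` are discarded.  Relative burial is
#' `1 - ACC / maxACC(aa)` clamped to `[0, 1]`, with maxACC from the
#' Tien et al. (2013) theoretical maxima (see `MAX_SASA`).  Beta-bridge
#' partner columns are returned so sheet topology can be derived from
#' DSSP rather than geometry when available.
#'
#' @param path DSSP file.
#' @param chain_id chain to extract (default: first chain in the table).
#' @param min_len minimum SSE run length.
#' @return list with `aa` (residue letters), `resno`, `sse` (segment
#'   table), `burial`, and `bridge` (two-column matrix of residue-index
#'   bridge partners, 0 = none).
#' @export
read_dssp <- function(path, chain_id = NULL, min_len = 3L) {
  lines <- readLines(path)
  hdr <- grep("^  #  RESIDUE", lines)
  if (!length(hdr)) stop("not a classic DSSP file (missing '  #  RESIDUE' header)")
  body <- lines[(hdr[1] + 1L):length(lines)]
  body <- body[nchar(body) >= 38]

  fld <- function(s, a, b) substr(s, a, b)
  chain <- trimws(fld(body, 12, 12))
  aa <- fld(body, 14, 14)
  ok <- aa != "!"                      # chain-break markers
  body <- body[ok]; chain <- chain[ok]; aa <- aa[ok]
  if (is.null(chain_id)) chain_id <- chain[1]
  sel <- chain == chain_id
  if (!any(sel)) stop(sprintf("chain '%s' not present in DSSP file", chain_id))
  body <- body[sel]; aa <- aa[sel]
  aa[aa %in% letters] <- "C"           # lower case = cystine bridge label

  resno <- suppressWarnings(as.integer(trimws(fld(body, 6, 10))))
  ss <- fld(body, 17, 17)
  acc <- suppressWarnings(as.numeric(trimws(fld(body, 35, 38))))
  bp1 <- suppressWarnings(as.integer(trimws(fld(body, 26, 29))))
  bp2 <- suppressWarnings(as.integer(trimws(fld(body, 30, 33))))
  if (anyNA(resno) || anyNA(acc))
    stop("malformed DSSP residue table (unparseable residue number or ACC field)")

  code <- ifelse(ss %in% c("H", "G", "I"), "H", ifelse(ss == "E", "E", "-"))
  maxacc <- MAX_SASA[aa]
  burial <- 1 - acc / maxacc
  burial <- pmin(pmax(burial, 0), 1)
  bp1[is.na(bp1)] <- 0L; bp2[is.na(bp2)] <- 0L

  list(aa = aa, resno = resno, sse = runs_to_sse(code, min_len),
       burial = unname(burial), bridge = cbind(bp1, bp2),
       dssp_index = suppressWarnings(as.integer(trimws(fld(body, 1, 5)))))
}

#' Assign secondary structure from CA geometry
#'
#' DSSP-free fallback.  A residue is labeled helix when the i -> i+4 CA
#' distance is near the ideal 6.2 A, and strand when the i -> i+2 CA
#' distance is near 6.7 A with low local curvature.  Runs shorter than
#' `min_len` are dropped.
#'
#' @param ts a [template_structure()].
#' @param helix_d,helix_tol target/tolerance for d(i, i+4) (A).
#' @param strand_d,strand_tol target/tolerance for d(i, i+2) (A).
#' @param min_len minimum SSE length.
#' @return SSE segment table (`kind`, `start`, `end`, `index`).
#' @export
assign_sse_geometric <- function(ts, helix_d = 6.2, helix_tol = 0.5,
                                 strand_d = 6.7, strand_tol = 0.6,
                                 min_len = 3L) {
  ca <- ts$xyz$ca
  L <- nrow(ca)
  if (L < 5) return(runs_to_sse(character(0), min_len))
  d_at <- function(off) {
    i <- seq_len(L - off)
    sqrt(rowSums((ca[i + off, , drop = FALSE] - ca[i, , drop = FALSE])^2))
  }
  d2 <- d_at(2); d3 <- d_at(3); d4 <- if (L >= 5) d_at(4) else numeric(0)

  code <- rep("-", L)
  # helix: two consecutive windows with near-ideal i->i+4 distance and
  # helical i->i+2 curvature (a single window can straddle a loop
  # boundary by chance; two in a row essentially cannot)
  h_ok <- abs(d4 - helix_d) <= helix_tol &
    abs(d2[seq_along(d4)] - 5.4) <= 0.6 &
    abs(d2[seq_along(d4) + 2] - 5.4) <= 0.6
  hw <- which(h_ok[-length(h_ok)] & h_ok[-1])
  for (i in hw) code[i:(i + 5)] <- "H"
  # strand: two consecutive near-extended i->i+2 windows with low
  # curvature over i->i+3 (extended-ish loops curve back by i+3) and a
  # near-planar CA pseudo-dihedral (the beta zigzag is planar; coil
  # stretches that happen to be extended are not)
  dih <- vapply(seq_len(max(L - 3, 0)), function(i) {
    b1 <- ca[i + 1, ] - ca[i, ]; b2 <- ca[i + 2, ] - ca[i + 1, ]
    b3 <- ca[i + 3, ] - ca[i + 2, ]
    n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
    atan2(sum(vcross(n1, n2) * b2) / vnorm(b2), sum(n1 * n2)) * 180 / pi
  }, 0)
  e_ok <- abs(d2 - strand_d) <= strand_tol
  e_ok[seq_along(d3)] <- e_ok[seq_along(d3)] & d3 >= 9.3
  e_ok[seq_along(dih)] <- e_ok[seq_along(dih)] & abs(dih) >= 140
  sw <- which(e_ok[-length(e_ok)] & e_ok[-1])
  for (i in sw) {
    span <- i:min(i + 4, L)
    if (!any(code[span] == "H")) code[span] <- "E"
  }
  runs_to_sse(code, min_len)
}

#' Derive beta-sheet topology (paired and core strands)
#'
#' Two strands are paired when at least `min_pairs` cross-strand residue
#' pairs have CA-CA distance below `cutoff`.  When DSSP bridge-partner
#' information is supplied it is used instead of the geometric criterion.
#' A core strand is one with at least two distinct pairing partners.
#'
#' @param ts annotated [template_structure()] (SSEs assigned).
#' @param cutoff CA-CA pairing distance (A).
#' @param min_pairs minimum qualifying residue pairs.
#' @param bridge optional DSSP bridge-partner matrix (residue indices).
#' @return list with `pairs` (2-column matrix of strand SSE indices) and
#'   `core` (integer vector of core-strand SSE indices).
#' @export
derive_sheet_topology <- function(ts, cutoff = 5.5, min_pairs = 2L,
                                  bridge = NULL) {
  sse <- ts$sse
  strands <- sse$index[sse$kind == "E"]
  pairs <- matrix(integer(0), 0, 2)
  if (length(strands) >= 2) {
    sid <- sse_id_vector(sse, length(ts))
    for (a in seq_along(strands)) {
      for (b in seq_along(strands)) {
        if (b <= a) next
        s1 <- strands[a]; s2 <- strands[b]
        i1 <- which(sid == s1); i2 <- which(sid == s2)
        if (!is.null(bridge)) {
          hits <- sum(bridge[i1, 1] %in% i2 | bridge[i1, 2] %in% i2)
        } else {
          hits <- sum(dist_xyz(ts$xyz$ca[i1, , drop = FALSE],
                               ts$xyz$ca[i2, , drop = FALSE]) < cutoff)
        }
        if (hits >= min_pairs) pairs <- rbind(pairs, c(s1, s2))
      }
    }
  }
  core <- integer(0)
  if (nrow(pairs)) {
    cnt <- table(c(pairs[, 1], pairs[, 2]))
    core <- sort(as.integer(names(cnt)[cnt >= 2]))
  }
  list(pairs = pairs, core = core)
}

#' Relative burial by Shrake-Rupley solvent accessibility
#'
#' Computes per-residue SASA over the available reduced atom set
#' (N, CA, C, CB) with a 1.4 A probe and a deterministic golden-spiral
#' sphere sampling, then normalizes against the same residue's SASA in
#' isolation (its reduced atoms only):
#' `rel_burial = 1 - SASA / SASA_isolated`, clamped to `[0, 1]`.  An
#' isolated residue therefore has burial exactly 0 regardless of the
#' reduced representation.  (Burial derived from DSSP accessibility uses
#' the published full-atom maxima instead; see [read_dssp()].)
#'
#' @param ts a [template_structure()].
#' @param probe probe radius (A).
#' @param n_points sphere points per atom (determinism: fixed spiral).
#' @return numeric vector of relative burial in `[0, 1]`.
#' @export
compute_burial <- function(ts, probe = 1.4, n_points = 100L) {
  L <- length(ts)
  atoms <- list()
  for (an in c("n", "ca", "c", "cb")) {
    m <- ts$xyz[[an]]
    ok <- which(!is.na(m[, 1]))
    if (length(ok))
      atoms[[an]] <- data.frame(res = ok, r = ATOM_RADII[[toupper(an)]],
                                x = m[ok, 1], y = m[ok, 2], z = m[ok, 3])
  }
  at <- do.call(rbind, atoms)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rad <- at$r + probe
  n_at <- nrow(at)
  sp <- sphere_points(n_points)
  sasa_atom <- numeric(n_at)
  sasa_iso <- numeric(n_at)   # occlusion by the residue's own atoms only
  D <- dist_xyz(xyz, xyz)
  for (i in seq_len(n_at)) {
    nb <- which(D[i, ] < rad[i] + rad & seq_len(n_at) != i)
    pts <- sweep(sp * rad[i], 2, xyz[i, ], "+")
    area <- 4 * pi * rad[i]^2
    if (length(nb)) {
      d2 <- dist_xyz(pts, xyz[nb, , drop = FALSE])
      covered <- d2 < rep(rad[nb], each = n_points)
      sasa_atom[i] <- area * mean(rowSums(covered) == 0)
      own <- at$res[nb] == at$res[i]
      sasa_iso[i] <- if (any(own))
        area * mean(rowSums(covered[, own, drop = FALSE]) == 0)
      else area
    } else {
      sasa_atom[i] <- area
      sasa_iso[i] <- area
    }
  }
  sasa <- vapply(seq_len(L), function(k) sum(sasa_atom[at$res == k]), 0)
  iso <- vapply(seq_len(L), function(k) sum(sasa_iso[at$res == k]), 0)
  burial <- 1 - sasa / iso
  unname(pmin(pmax(burial, 0), 1))
}

#' Annotate a template structure
#'
#' Fills the SSE table, sheet topology, and burial of a template, from a
#' DSSP file when given (codes, accessibility and bridge partners) or from
#' CA geometry and Shrake-Rupley SASA otherwise.
#'
#' @param ts a [template_structure()].
#' @param dssp optional path to a classic DSSP file for the same chain.
#' @param ... passed to [assign_sse_geometric()] / [compute_burial()].
#' @return the annotated `template_structure`.
#' @export
annotate_template <- function(ts, dssp = NULL, ...) {
  ts <- complete_cb(ts)
  if (!is.null(dssp)) {
    d <- read_dssp(dssp, chain_id = ts$chain)
    if (length(d$aa) != length(ts) || any(d$aa != ts$sequence)) {
      bad <- which(d$aa[seq_len(min(length(d$aa), length(ts)))] !=
                     ts$sequence[seq_len(min(length(d$aa), length(ts)))])
      stop(sprintf("DSSP/PDB sequence mismatch (lengths %d vs %d; first differing positions: %s)",
                   length(d$aa), length(ts),
                   paste(utils::head(bad, 5), collapse = ",")))
    }
    ts$sse <- d$sse
    ts$burial <- d$burial
    ts$sse_id <- sse_id_vector(ts$sse, length(ts))
    # DSSP bridge columns index DSSP's own running numbering
    bridge <- d$bridge
    map <- match(seq_len(max(d$dssp_index, 0L)), d$dssp_index)
    b <- apply(bridge, 2, function(col) {
      out <- rep(0L, length(col))
      nz <- col > 0 & col <= length(map)
      out[nz] <- map[col[nz]]
      out[is.na(out)] <- 0L
      out
    })
    ts$sheet <- derive_sheet_topology(ts, bridge = b)
  } else {
    ts$sse <- assign_sse_geometric(ts, ...)
    ts$sse_id <- sse_id_vector(ts$sse, length(ts))
    ts$burial <- compute_burial(ts)
    ts$sheet <- derive_sheet_topology(ts)
  }
  ts
}

#' Build a pseudomodel from a template and an alignment path
#'
#' Copies template backbone and CB coordinates for every aligned pair and
#' relabels them with the aligned query residue types; unaligned residues
#' are ignored.  Glycine query residues receive the tetrahedral pseudo-CB
#' (alanine-like geometry) if the template CB is missing; template CBs are
#' otherwise reused as-is.
#'
#' @param ts annotated [template_structure()].
#' @param path alignment path: 2-column matrix `(t, q)` of 1-based indices,
#'   both columns strictly increasing.
#' @param query query sequence (string or letter vector).
#' @return object of class `pseudomodel`: list with `t_idx`, `q_idx`,
#'   `q_aa`, `ca`, `cb`, `sse_id` (template SSE membership per pair).
#' @export
build_pseudomodel <- function(ts, path, query) {
  query <- as_aa_vector(query, "query sequence")
  path <- path_matrix(path)
  if (nrow(path)) {
    if (any(diff(path[, 1]) <= 0) || any(diff(path[, 2]) <= 0))
      stop("alignment path must be strictly increasing in both sequences")
    if (max(path[, 1]) > length(ts) || max(path[, 2]) > length(query) ||
        min(path) < 1)
      stop("alignment path indices out of range")
  }
  ts <- complete_cb(ts)
  t_idx <- path[, 1]; q_idx <- path[, 2]
  structure(list(
    t_idx = t_idx,
    q_idx = q_idx,
    q_aa = query[q_idx],
    ca = ts$xyz$ca[t_idx, , drop = FALSE],
    cb = ts$xyz$cb[t_idx, , drop = FALSE],
    sse_id = if (!is.null(ts$sse_id)) ts$sse_id[t_idx] else rep(NA_integer_, length(t_idx))
  ), class = "pseudomodel")
}

#' Write the annotation cache of a template as JSON
#'
#' Serializes SSEs, sheet topology and burial so downstream runs can skip
#' re-annotation.
#' @param ts annotated template.
#' @param path output JSON file.
#' @export
write_annotation_json <- function(ts, path) {
  obj <- list(
    length = length(ts),
    sequence = paste(ts$sequence, collapse = ""),
    sse = ts$sse,
    sheet_pairs = if (nrow(ts$sheet$pairs)) ts$sheet$pairs else matrix(integer(0), 0, 2),
    sheet_core = ts$sheet$core,
    burial = round(ts$burial, 4)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an annotation cache written by [write_annotation_json()]
#' @param ts template structure the annotation belongs to.
#' @param path JSON file.
#' @return annotated template.
#' @export
read_annotation_json <- function(ts, path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (obj$length != length(ts))
    stop("annotation JSON was computed for a different template length")
  ts <- complete_cb(ts)
  ts$sse <- as.data.frame(obj$sse)
  ts$sse_id <- sse_id_vector(ts$sse, length(ts))
  pairs <- obj$sheet_pairs
  if (length(pairs) == 0) pairs <- matrix(integer(0), 0, 2)
  ts$sheet <- list(pairs = matrix(as.integer(unlist(pairs)), ncol = 2),
                   core = as.integer(obj$sheet_core))
  ts$burial <- as.numeric(obj$burial)
  ts
}

# Coerce paths to a 2-column integer matrix (t, q).
path_matrix <- function(path) {
  if (is.null(path) || (is.matrix(path) && nrow(path) == 0) || length(path) == 0)
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("t", "q"))))
  m <- as.matrix(path)
  stopifnot(ncol(m) == 2)
  storage.mode(m) <- "integer"
  colnames(m) <- c("t", "q")
  m
}
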