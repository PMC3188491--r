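# Deterministic generator of idealized template folds and derived
# remote-homolog query sequences with known ground-truth alignments.
#
# Geometry is idealized (ideal helix / extended-strand parameters, loops
# laid on circular arcs with ~3.8 A CA steps) so every fixture is
# seed-reproducible and download-free.  Sequences are designed with a
# hydrophobic bias on buried faces so burial, core-contact and energy
# filters have realistic signal.

with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  } else {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Describe an idealized fold
#'
#' @param kinds character vector of element kinds, `"H"` (helix) or `"E"`
#'   (strand); a single string like `"HEEH"` is also accepted.
#' @param lengths residue count per element (recycled).
#' @param loop_lengths loop residue count between consecutive elements
#'   (recycled; automatically extended when geometry demands more).
#' @param helix_spacing,strand_spacing,mixed_spacing lateral packing
#'   distances in Angstrom between consecutive helix-helix, strand-strand
#'   and mixed element pairs.
#' @return a `fold_spec` list.
#' @export
fold_spec <- function(kinds, lengths = 10L, loop_lengths = 5L,
                      helix_spacing = 10, strand_spacing = 4.8,
                      mixed_spacing = 8) {
  if (length(kinds) == 1L && nchar(kinds) > 1L) kinds <- strsplit(kinds, "")[[1]]
  kinds <- toupper(kinds)
  stopifnot(all(kinds %in% c("H", "E")), length(kinds) >= 1)
  n <- length(kinds)
  lengths <- rep_len(as.integer(lengths), n)
  if (any(lengths < 3)) stop("SSE lengths must be >= 3")
  loops <- rep_len(as.integer(loop_lengths), max(n - 1L, 0L))
  structure(list(kinds = kinds, lengths = lengths, loop_lengths = loops,
                 helix_spacing = helix_spacing,
                 strand_spacing = strand_spacing,
                 mixed_spacing = mixed_spacing),
            class = "fold_spec")
}

# n coil-like loop points from p to q: a feasibility-constrained random
# walk with ~3.8 A CA steps, biased toward q and toward the bulge
# direction u.  Deterministic given the RNG state (callers seed it).
loop_walk <- function(p, q, n, u, step = 3.8) {
  g <- vnorm(q - p)
  # n intermediate points give n segments of `step` plus one final
  # segment of at most ~4.1 A; extend the loop until the gap is coverable
  while (g > step * n + 4.1) n <- n + 1L
  if (n == 0L) return(list(pts = matrix(0, 0, 3), n = 0L))
  pts <- matrix(NA_real_, n, 3)
  x <- p
  for (k in seq_len(n)) {
    rem <- n + 1L - k                     # steps remaining after this one
    placed <- FALSE
    for (trial in 1:60) {
      bias <- unitv(q - x)
      wob <- stats::rnorm(3, sd = 1.4) + u
      # first step kicks sideways (toward the bulge) so the loop does not
      # continue the exiting element's regular geometry
      dir <- if (k == 1L && trial <= 30L)
        unitv(u + unitv(wob) * 0.7 + bias * (trial / 30))
      else unitv(bias * (trial / 20) + unitv(wob))
      cand <- x + step * dir
      dq <- vnorm(q - cand)
      lo <- if (rem == 1L) 2.9 else 2.2
      hi <- if (rem == 1L) 4.2 else step * (rem - 1L) + 4.0
      if (dq >= lo && dq <= hi) { placed <- TRUE; break }
    }
    if (!placed) {
      # deterministic fallback: place the point at `step` from x with an
      # exact target distance to q (always geometrically feasible given
      # the windows enforced on earlier steps)
      dq0 <- vnorm(q - x)
      target <- if (rem == 1L) 3.55
                else min(max(dq0 - step, 2.9), step * (rem - 1L) + 3.5)
      u1 <- unitv(q - x)
      ref <- if (abs(u1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      u2 <- unitv(vcross(u1, ref))
      cost <- (dq0^2 + step^2 - target^2) / (2 * step * max(dq0, 1e-9))
      cost <- max(min(cost, 1), -1)
      cand <- x + step * (cost * u1 + sqrt(1 - cost^2) * u2)
    }
    pts[k, ] <- cand
    x <- cand
  }
  list(pts = pts, n = n)
}

# n points on a circular arc from p to q bulging toward u, with the n+1
# consecutive chords all equal; chord length solved to be near 3.8 A.
arc_points <- function(p, q, n, u, target = 3.8) {
  g <- vnorm(q - p)
  while (g / (n + 1) > 4.2) n <- n + 1L   # too far to bridge: lengthen loop
  if (n == 0L) return(list(pts = matrix(0, 0, 3), n = 0L))
  f <- function(theta) g * sin(theta / (2 * (n + 1))) / sin(theta / 2) - target
  if (f(1e-6) > 0) {
    # nearly straight reach: evenly spaced chords on the segment
    t <- seq_len(n) / (n + 1)
    return(list(pts = outer(t, q - p) + matrix(p, n, 3, byrow = TRUE), n = n))
  }
  theta <- stats::uniroot(f, c(1e-6, 2 * pi - 1e-3))$root
  R <- g / (2 * sin(theta / 2))
  e1 <- unitv(q - p)
  u2 <- u - e1 * sum(u * e1)           # orthogonalize u against e1
  if (vnorm(u2) < 1e-8) u2 <- vcross(e1, c(0, 0, 1)) + vcross(e1, c(0, 1, 0)) * 1e-3
  e2 <- unitv(u2)
  m <- (p + q) / 2
  o <- m - e2 * (R * cos(theta / 2))
  vP <- p - o
  nrm <- vcross(e1, e2)
  e2p <- unitv(vcross(nrm, vP))
  ang <- seq_len(n) * theta / (n + 1)
  pts <- t(vapply(ang, function(a) o + cos(a) * vP + sin(a) * (R * e2p),
                  numeric(3)))
  # orientation check: rotating by theta must land on q
  endp <- o + cos(theta) * vP + sin(theta) * (R * e2p)
  if (vnorm(endp - q) > 1e-6) {
    e2p <- -e2p
    pts <- t(vapply(ang, function(a) o + cos(a) * vP + sin(a) * (R * e2p),
                    numeric(3)))
  }
  list(pts = pts, n = n)
}

element_ca <- function(kind, len, x, dir) {
  i <- seq_len(len) - 1
  if (kind == "H") {
    theta <- dir * 100 * pi / 180 * i
    z <- 1.5 * i
    ca <- cbind(x + 2.3 * cos(theta), 2.3 * sin(theta), z)
  } else {
    z <- 3.4 * i
    ca <- cbind(rep(x, len), 0.85 * (-1)^i, z)
  }
  if (dir < 0) ca[, 3] <- max(ca[, 3]) - ca[, 3]
  ca
}

#' Generate an idealized template fold
#'
#' Places the elements of a [fold_spec()] side-by-side (antiparallel,
#' alternating chain direction), connects them with arc loops at ~3.8 A
#' CA steps, synthesizes backbone N/C and tetrahedral CB atoms, designs a
#' sequence with hydrophobic residues on buried faces, and annotates the
#' result (ground-truth SSEs, geometric sheet topology, computed burial).
#'
#' @param spec a [fold_spec()].
#' @param seed integer seed (sequence design is the only stochastic part).
#' @param dir optional directory: writes `<name>.pdb` and `<name>.json`
#'   (annotation cache) there.
#' @param name file stem used with `dir`.
#' @return list with `template` (annotated [template_structure()]),
#'   `truth_sse` (ground-truth segment table), `truth_pairs` (ground-truth
#'   strand adjacency, 2-column matrix of SSE indices), and `files`
#'   (written paths, if any).
#' @export
make_fold <- function(spec, seed = 1L, dir = NULL, name = "fold") {
  stopifnot(inherits(spec, "fold_spec"))
  n_el <- length(spec$kinds)
  spacing <- function(a, b) {
    if (a == "H" && b == "H") spec$helix_spacing
    else if (a == "E" && b == "E") spec$strand_spacing
    else spec$mixed_spacing
  }
  xs <- numeric(n_el)
  for (k in seq_len(n_el)[-1])
    xs[k] <- xs[k - 1] + spacing(spec$kinds[k - 1], spec$kinds[k])
  dirs <- rep_len(c(1, -1), n_el)

  ca_list <- vector("list", n_el)
  for (k in seq_len(n_el))
    ca_list[[k]] <- element_ca(spec$kinds[k], spec$lengths[k], xs[k], dirs[k])

  ca <- ca_list[[1]]
  code <- rep(spec$kinds[1], spec$lengths[1])
  for (k in seq_len(n_el)[-1]) {
    p <- ca[nrow(ca), ]
    q <- ca_list[[k]][1, ]
    # loops alternate the side they bulge to, so loops sharing an end of
    # the bundle stay apart
    bulge <- c(0, 2 * (-1)^k, if (dirs[k - 1] > 0) 0.8 else -0.8)
    arc <- with_seed(seed * 131L + k,
                     loop_walk(p, q, spec$loop_lengths[k - 1], bulge))
    ca <- rbind(ca, arc$pts, ca_list[[k]])
    code <- c(code, rep("-", arc$n), rep(spec$kinds[k], spec$lengths[k]))
  }
  L <- nrow(ca)

  # clash check between residues of different SSEs (loops are idealized
  # connectors and exempt)
  D <- dist_xyz(ca, ca)
  sep <- abs(outer(seq_len(L), seq_len(L), "-"))
  in_sse <- code != "-"
  sse_pair <- outer(in_sse, in_sse, "&")
  if (any(D[sep >= 3 & sse_pair] < 2.5))
    stop("fold specification produces steric clashes (CA-CA < 2.5 A)")

  bb <- approx_backbone(ca)
  cb <- matrix(NA_real_, L, 3)
  for (i in seq_len(L)) cb[i, ] <- place_cb(bb$n[i, ], ca[i, ], bb$c[i, ])

  # sequence design: hydrophobic residues go to positions that are
  # actually buried in the assembled fold (burial computed from the
  # geometry itself, so sequence and environment are self-consistent),
  # polar residues to exposed faces, flexible types to loops
  ts <- template_structure(paste(rep("A", L), collapse = ""),
                           ca = ca, n = bb$n, c = bb$c, cb = cb)
  burial <- compute_burial(ts)
  seqv <- with_seed(seed, {
    s <- character(L)
    hyd <- c(I = 5, L = 5, V = 5, F = 3, M = 2, A = 3, Y = 1, W = 1)
    pol <- c(E = 4, K = 4, R = 3, Q = 3, D = 3, N = 3, S = 3, T = 3, H = 1, A = 1)
    lp <- c(G = 4, S = 3, N = 2, D = 2, P = 2, T = 2, E = 1, K = 1)
    for (i in seq_len(L)) {
      w <- if (code[i] == "-") lp else if (burial[i] >= 0.5) hyd else pol
      s[i] <- sample(names(w), 1, prob = w)
    }
    s
  })

  ts$sequence <- seqv
  ts$sse <- runs_to_sse(code)
  ts$sse_id <- sse_id_vector(ts$sse, L)
  ts$burial <- compute_burial(ts)
  ts$sheet <- derive_sheet_topology(ts)

  # ground-truth strand adjacency: consecutive strand elements are packed
  truth_pairs <- matrix(integer(0), 0, 2)
  for (k in seq_len(n_el)[-1]) {
    if (spec$kinds[k - 1] == "E" && spec$kinds[k] == "E")
      truth_pairs <- rbind(truth_pairs, c(k - 1L, k))
  }
  # element k maps to SSE index k (all elements >= 3 residues)
  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    pdb_path <- file.path(dir, paste0(name, ".pdb"))
    json_path <- file.path(dir, paste0(name, ".json"))
    write_template_pdb(ts, pdb_path)
    write_annotation_json(ts, json_path)
    files <- c(pdb = pdb_path, json = json_path)
  }
  list(template = ts, truth_sse = ts$sse, truth_pairs = truth_pairs,
       files = files)
}

#' Write a template structure as a PDB file
#'
#' Emits ATOM records (N, CA, C, CB per residue) via [bio3d::write.pdb()].
#' @param ts a [template_structure()].
#' @param path output file.
#' @export
write_template_pdb <- function(ts, path) {
  aa3 <- bio3d::aa123(ts$sequence)
  rows <- list()
  for (i in seq_len(length(ts))) {
    for (an in c("N", "CA", "C", "CB")) {
      xyz <- ts$xyz[[tolower(an)]][i, ]
      if (anyNA(xyz)) next
      rows[[length(rows) + 1]] <- data.frame(
        elety = an, resid = aa3[i], chain = ts$chain, resno = ts$resno[i],
        x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
    }
  }
  at <- do.call(rbind, rows)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = at$resno, resid = at$resid, chain = at$chain,
                   elety = at$elety)
  invisible(path)
}

# loop runs (maximal non-SSE intervals strictly between two SSEs)
internal_loops <- function(ts) {
  sse <- ts$sse
  if (nrow(sse) < 2) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = sse$end[-nrow(sse)] + 1L, end = sse$start[-1] - 1L)[
    sse$end[-nrow(sse)] + 1L <= sse$start[-1] - 1L, , drop = FALSE]
}

#' Derive a remote-homolog query from a template
#'
#' Builds a query sequence from the template by (i) optionally deleting
#' terminal SSEs, (ii) planting insertions/deletions in internal loops,
#' and (iii) substituting aligned positions with a similarity-biased
#' process until the requested sequence identity (measured on aligned
#' positions) is reached exactly.  The surviving correspondences form the
#' ground-truth alignment path.  Deletions are shrunk if they would make
#' the truth path violate the loop-stretch rule on the template geometry,
#' so generated truths are always modelable.
#'
#' @param fold result of [make_fold()] (or a list with `$template`).
#' @param identity target fraction of identical aligned positions, in
#'   (0, 1].
#' @param indels data frame with columns `loop` (internal-loop ordinal)
#'   and `len` (positive = insertion into the query, negative = deletion
#'   of query residues), or an integer count of random loop indels.
#' @param delete_sse integer vector of SSE indices to delete from the
#'   query (restricted to terminal elements).
#' @param seed integer seed.
#' @param max_indel_len maximum |len| for randomly drawn indels.
#' @return list with `query` (letter vector), `truth` (2-column `(t, q)`
#'   path matrix), `identity` (realized), `template`.
#' @export
make_homolog <- function(fold, identity = 0.3, indels = 1L,
                         delete_sse = integer(0), seed = 1L,
                         max_indel_len = 4L) {
  ts <- if (inherits(fold, "template_structure")) fold else fold$template
  stopifnot(identity > 0, identity <= 1)
  L <- length(ts)
  loops <- internal_loops(ts)

  with_seed(seed + 1000L, {
    if (length(delete_sse)) {
      nsse <- nrow(ts$sse)
      if (!all(delete_sse %in% c(1L, nsse)))
        stop("SSE deletions are restricted to terminal elements")
    }
    if (is.numeric(indels) && length(indels) == 1L && !is.data.frame(indels)) {
      k <- as.integer(indels)
      if (k > 0 && nrow(loops) > 0) {
        pick <- sample(seq_len(nrow(loops)), min(k, nrow(loops)))
        indels <- data.frame(
          loop = pick,
          len = sample(c(-1, 1), length(pick), replace = TRUE) *
            sample(seq_len(max_indel_len), length(pick), replace = TRUE))
      } else indels <- data.frame(loop = integer(0), len = integer(0))
    }

    aligned_t <- seq_len(L)
    if (length(delete_sse)) {
      drop <- unlist(lapply(delete_sse, function(k) ts$sse$start[k]:ts$sse$end[k]))
      # also drop the adjoining terminal tail (loop outside the deleted SSE)
      for (k in delete_sse) {
        if (k == 1L) drop <- union(drop, seq_len(ts$sse$start[1] - 1L))
        else drop <- union(drop, seq(ts$sse$end[k] + 1L, L))
      }
      aligned_t <- setdiff(aligned_t, drop)
    }

    # loop deletions, shrunk until the truth obeys the loop-stretch rule
    del_t <- integer(0)
    ins_after_t <- integer(0)   # template position after which query insertion occurs
    ins_len <- integer(0)
    if (nrow(loops) && nrow(indels)) {
      for (r in seq_len(nrow(indels))) {
        lp <- indels$loop[r]
        if (lp < 1 || lp > nrow(loops)) next
        li <- loops$start[lp]:loops$end[lp]
        li <- intersect(li, aligned_t)
        len <- indels$len[r]
        if (len < 0) {
          take <- min(-len, length(li))
          while (take > 0) {
            mid <- (length(li) - take) %/% 2
            cand <- li[seq_len(take) + mid]
            rest <- setdiff(aligned_t, c(del_t, cand))
            if (loop_rule_ok_truth(ts, rest)) { del_t <- c(del_t, cand); break }
            take <- take - 1
          }
        } else if (len > 0 && length(li)) {
          ins_after_t <- c(ins_after_t, li[ceiling(length(li) / 2)])
          ins_len <- c(ins_len, len)
        }
      }
    }
    aligned_t <- setdiff(aligned_t, del_t)
    n_aligned <- length(aligned_t)
    if (n_aligned < 3) stop("homolog spec leaves too few aligned residues")

    # substitutions: exact count at similarity-biased replacements
    n_sub <- round((1 - identity) * n_aligned)
    if (identity < 1 && n_sub == 0) n_sub <- 1L
    sub_pos <- if (n_sub > 0) sample(aligned_t, n_sub) else integer(0)
    blo <- load_substitution_matrix("BLOSUM62")$matrix[AA20, AA20]
    q_aa <- ts$sequence
    for (p in sub_pos) {
      a <- q_aa[p]
      w <- exp(0.5 * blo[a, setdiff(AA20, a)])
      q_aa[p] <- sample(setdiff(AA20, a), 1, prob = w)
    }

    # assemble query: aligned residues in template order + insertions
    q_seq <- character(0)
    truth_t <- integer(0); truth_q <- integer(0)
    for (t in seq_len(L)) {
      if (t %in% aligned_t) {
        q_seq <- c(q_seq, q_aa[t])
        truth_t <- c(truth_t, t); truth_q <- c(truth_q, length(q_seq))
      }
      hit <- which(ins_after_t == t)
      if (length(hit)) {
        for (h in hit) {
          lp <- c(G = 2, S = 2, N = 1, D = 1, T = 1, P = 1, E = 1, K = 1, A = 1)
          q_seq <- c(q_seq, sample(names(lp), ins_len[h], replace = TRUE, prob = lp))
        }
      }
    }
    realized <- mean(q_seq[truth_q] == ts$sequence[truth_t])
    list(query = q_seq,
         truth = path_matrix(cbind(truth_t, truth_q)),
         identity = realized,
         template = ts)
  })
}

# Does an aligned-template-position set satisfy the loop-stretch rule at
# SSE granularity?  For consecutive covered SSEs, the query residues
# available between the last aligned position of one and the first of
# the next (insertions ignored: they only relax the bound) must be able
# to bridge the template CA-CA distance at 3.3 A per residue.
loop_rule_ok_truth <- function(ts, aligned_t) {
  aligned_t <- sort(aligned_t)
  q_of <- seq_along(aligned_t)               # query rank before insertions
  sid <- ts$sse_id[aligned_t]
  covered <- unique(sid[!is.na(sid)])
  if (length(covered) < 2) return(TRUE)
  for (k in seq_len(length(covered) - 1)) {
    a <- covered[k]; b <- covered[k + 1]
    ia <- max(which(sid == a)); ib <- min(which(sid == b))
    tp <- aligned_t[ia]; tf <- aligned_t[ib]
    dq <- q_of[ib] - q_of[ia]
    if (dq == 1 && tf - tp == 1) next
    d <- vnorm(ts$xyz$ca[tf, ] - ts$xyz$ca[tp, ])
    if (3.3 * dq < d) return(FALSE)
  }
  TRUE
}

#' Generate a benchmark of template/homolog pairs across identity bins
#'
#' Draws fold archetypes (helix bundles, beta sheets, mixed folds),
#' derives a homolog in each requested identity bin, and returns pairs
#' with their ground-truth alignments plus a manifest table.
#'
#' @param n_pairs total number of pairs.
#' @param identity_bins list of `c(lo, hi)` identity fractions; pairs are
#'   distributed across bins round-robin.
#' @param seed integer seed.
#' @param n_indels number of random loop indels per pair (vector sampled).
#' @param p_delete_sse probability that one terminal SSE is deleted.
#' @param dir optional output directory for the manifest TSV.
#' @return list with `pairs` (each: `template`, `query`, `truth`,
#'   `meta`) and `manifest` (data frame).
#' @export
make_benchmark <- function(n_pairs, identity_bins, seed = 1L,
                           n_indels = 1:3, p_delete_sse = 0.3,
                           dir = NULL) {
  if (!length(identity_bins)) stop("identity_bins must be a non-empty list")
  if (!is.list(identity_bins)) identity_bins <- list(identity_bins)
  archetypes <- list(
    c("H", "H", "H", "H"),
    c("E", "E", "E", "E", "E"),
    c("E", "E", "H", "H", "E"),
    c("H", "H", "H", "H", "H"),
    c("H", "E", "E", "E", "E", "H"),
    c("E", "E", "E", "H", "H")
  )
  pairs <- vector("list", n_pairs)
  rows <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    bin <- identity_bins[[(i - 1) %% length(identity_bins) + 1]]
    meta <- with_seed(seed + 17L * i, {
      arch <- archetypes[[sample(length(archetypes), 1)]]
      lens <- ifelse(arch == "H", sample(9:13, length(arch), TRUE),
                     sample(6:9, length(arch), TRUE))
      list(arch = arch, lens = lens,
           identity = stats::runif(1, bin[1], bin[2]),
           k_indel = sample(n_indels, 1),
           del = stats::runif(1) < p_delete_sse)
    })
    fold <- make_fold(fold_spec(meta$arch, meta$lens,
                                loop_lengths = sample_loops(seed + i)),
                      seed = seed + i)
    del <- with_seed(seed + 31L * i,
                     if (meta$del) sample(c(1L, nrow(fold$template$sse)), 1)
                     else integer(0))
    hm <- make_homolog(fold, identity = meta$identity, indels = meta$k_indel,
                       delete_sse = del, seed = seed + 101L * i)
    pairs[[i]] <- list(template = fold$template, query = hm$query,
                       truth = hm$truth,
                       meta = list(bin = bin, deleted_sse = del,
                                   identity = hm$identity))
    rows[[i]] <- data.frame(
      pair_id = i, fold = paste(meta$arch, collapse = ""),
      n_sse = length(meta$arch),
      template_len = length(fold$template),
      query_len = length(hm$query),
      identity_target = round(meta$identity, 3),
      identity_realized = round(hm$identity, 3),
      n_indels = meta$k_indel,
      deleted_sse = if (length(del)) del else NA_integer_,
      bin = sprintf("%.2f-%.2f", bin[1], bin[2]))
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  list(pairs = pairs, manifest = manifest)
}

sample_loops <- function(seed) with_seed(seed * 7L, sample(3:5, 1))
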