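# Small 3D geometry helpers (internal).

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Pairwise Euclidean distance matrix between the rows of two coordinate
# matrices (n x 3, m x 3).
dist_xyz <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Place a beta-carbon from backbone N, CA, C coordinates
#'
#' Ideal tetrahedral construction: the CB direction makes equal ~110.5
#' degree angles with the CA->N and CA->C bonds and is placed 1.53 A from
#' CA on the side that gives the L-configuration.  Used both to complete
#' residues lacking a CB in the input and to synthesize the pseudo-CB of
#' glycine (modeled on the alanine side-chain geometry).
#'
#' @param n,ca,c numeric length-3 backbone coordinates (Angstrom).
#' @param bond CA-CB bond length in Angstrom.
#' @return numeric length-3 CB coordinate.
#' @export
place_cb <- function(n, ca, c, bond = 1.53) {
  v1 <- unitv(n - ca)
  v2 <- unitv(c - ca)
  bis <- v1 + v2
  if (vnorm(bis) < 1e-8) {
    # Degenerate (collinear backbone): any perpendicular will do.
    ref <- if (abs(v1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    perp <- unitv(vcross(v1, ref))
    return(ca + bond * perp)
  }
  bis <- unitv(bis)
  perp <- unitv(vcross(v1, v2))
  cosg <- sum(bis * v1)                      # cosine of half the N-CA-C angle
  a <- cos(110.5 * pi / 180) / cosg          # component along the bisector
  a <- max(min(a, 0.99), -0.99)
  b <- sqrt(1 - a * a)                       # sign fixed: L-amino-acid chirality
  ca + bond * (a * bis + b * perp)
}

# Approximate backbone N and C positions from a CA trace.  N_i sits 1.46 A
# from CA_i toward CA_{i-1}; C_i sits 1.53 A toward CA_{i+1}.  Chain ends
# are mirrored.  Adequate for tetrahedral CB placement on synthetic CA-only
# structures; real structures carry their own N/C atoms.
approx_backbone <- function(ca) {
  L <- nrow(ca)
  if (L < 2) stop("need at least 2 residues to approximate a backbone")
  nmat <- matrix(NA_real_, L, 3)
  cmat <- matrix(NA_real_, L, 3)
  for (i in seq_len(L)) {
    prev_dir <- if (i > 1) ca[i - 1, ] - ca[i, ] else ca[i, ] - ca[i + 1, ]
    next_dir <- if (i < L) ca[i + 1, ] - ca[i, ] else ca[i, ] - ca[i - 1, ]
    nmat[i, ] <- ca[i, ] + 1.46 * unitv(prev_dir)
    cmat[i, ] <- ca[i, ] + 1.53 * unitv(next_dir)
  }
  list(n = nmat, c = cmat)
}

# Deterministic near-uniform points on the unit sphere (golden spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}
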