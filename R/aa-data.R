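# Amino-acid constants shared across the package.

#' @keywords internal
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Hydrophobic set used by the core-contact definition (glycine included).
HYDROPHOBIC <- c("A", "F", "G", "I", "L", "M", "P", "W", "V", "Y")

# Theoretical maximum solvent-accessible surface area per residue type
# (A^2), from Tien et al. 2013 (PLoS ONE 8:e80635), "theoretical" column.
# Used to convert absolute SASA into a relative burial fraction.
MAX_SASA <- c(
  A = 129, R = 274, N = 195, D = 193, C = 167, Q = 225, E = 223,
  G = 104, H = 224, I = 197, L = 201, K = 236, M = 224, F = 240,
  P = 159, S = 155, T = 172, W = 285, Y = 263, V = 174
)

# Van der Waals radii (A) for the reduced atom set kept per residue.
ATOM_RADII <- c(N = 1.55, CA = 1.70, C = 1.70, CB = 1.70, O = 1.52)

is_hydrophobic <- function(aa) aa %in% HYDROPHOBIC

check_aa <- function(aa, what = "sequence") {
  bad <- setdiff(unique(aa), c(AA20, "X"))
  if (length(bad)) {
    stop(sprintf("invalid amino-acid letter(s) in %s: %s",
                 what, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(aa)
}

# Split a sequence given as a single string or a character vector of
# one-letter codes into a validated character vector.
as_aa_vector <- function(x, what = "sequence") {
  if (length(x) == 1L && nchar(x) > 1L) x <- strsplit(x, "")[[1]]
  x <- toupper(as.character(x))
  check_aa(x, what)
  x
}
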