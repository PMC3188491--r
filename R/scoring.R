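# Residue-residue similarity scoring.  Any position-wise scorer can drive
# the sampler; two backends are provided: a substitution matrix (default
# BLOSUM62, half-bit units) and PSI-BLAST ASCII position-specific scoring
# matrices for one or both sequences.

#' Load a substitution matrix as a score model
#'
#' Reads an NCBI-format substitution matrix text file (or one bundled with
#' the package by name, e.g. `"BLOSUM62"`).  The resulting model scores a
#' query/template position pair by the matrix entry of the two amino
#' acids; the unknown residue `X` scores 0 against everything.
#'
#' @param name_or_path bundled matrix name or path to an NCBI-format file.
#' @return an object of class `score_model`.
#' @export
load_substitution_matrix <- function(name_or_path = "BLOSUM62") {
  path <- name_or_path
  if (!file.exists(path)) {
    path <- system.file("extdata", name_or_path, package = "subalign")
    if (path == "")
      stop(sprintf("no such matrix file or bundled matrix: '%s'", name_or_path))
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  rn <- vapply(rows, `[`, "", 1)
  vals <- lapply(rows, function(r) suppressWarnings(as.numeric(r[-1])))
  if (any(vapply(vals, anyNA, TRUE)))
    stop("malformed numeric field in substitution matrix")
  if (any(lengths(vals) != length(header)))
    stop("substitution matrix row lengths do not match the header")
  m <- do.call(rbind, vals)
  dimnames(m) <- list(rn, header)
  missing <- setdiff(AA20, intersect(rn, header))
  if (length(missing))
    stop(sprintf("substitution matrix lacks residue row(s): %s",
                 paste(missing, collapse = ",")))
  m <- m[AA20, AA20]
  if (any(m != t(m))) stop("substitution matrix is not symmetric")
  # Unknown-residue rule: X scores 0 against everything.
  full <- matrix(0, 21, 21, dimnames = list(c(AA20, "X"), c(AA20, "X")))
  full[AA20, AA20] <- m
  structure(list(kind = "matrix", matrix = full, name = basename(path)),
            class = "score_model")
}

#' Load a PSI-BLAST ASCII PSSM as a score model
#'
#' Parses the `-out_ascii_pssm` dialect (position rows with 20 log-odds
#' columns).  The model scores `(q, t)` by the query-profile row at
#' position `q` evaluated at the template amino acid.  When
#' `template_pssm` is also given, the score is the arithmetic mean of the
#' two cross-profile lookups.
#'
#' @param path PSSM file for the query sequence.
#' @param sequence the query sequence the PSSM belongs to.
#' @param template_pssm optional PSSM file for the template sequence.
#' @param template_sequence template sequence (required with
#'   `template_pssm`).
#' @return an object of class `score_model`.
#' @export
load_pssm <- function(path, sequence, template_pssm = NULL,
                      template_sequence = NULL) {
  prof_q <- parse_pssm(path, as_aa_vector(sequence, "query sequence"))
  prof_t <- NULL
  if (!is.null(template_pssm)) {
    if (is.null(template_sequence))
      stop("template_sequence is required when template_pssm is given")
    prof_t <- parse_pssm(template_pssm,
                         as_aa_vector(template_sequence, "template sequence"))
  }
  structure(list(kind = "pssm", query_profile = prof_q,
                 template_profile = prof_t, name = basename(path)),
            class = "score_model")
}

parse_pssm <- function(path, sequence) {
  lines <- readLines(path)
  # Data rows start with an integer position followed by a residue letter.
  data_rows <- grep("^\\s*\\d+\\s+[A-Z]\\s", lines)
  if (!length(data_rows)) stop(sprintf("no PSSM rows found in %s", path))
  rows <- lapply(seq_along(data_rows), function(k) {
    ln <- data_rows[k]
    f <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(f[3:22]))
    if (anyNA(v))
      stop(sprintf("malformed numeric field in PSSM at line %d", ln))
    v
  })
  prof <- do.call(rbind, rows)
  colnames(prof) <- AA20
  if (nrow(prof) != length(sequence))
    stop(sprintf("PSSM has %d rows but the sequence has %d residues",
                 nrow(prof), length(sequence)))
  prof
}

#' @export
print.score_model <- function(x, ...) {
  cat(sprintf("Score model: %s backend (%s)\n",
              x$kind, x$name %||% ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Score a full query x template grid under a score model.
score_grid <- function(model, query, template_seq) {
  query <- as_aa_vector(query, "query sequence")
  template_seq <- as_aa_vector(template_seq, "template sequence")
  if (model$kind == "matrix") {
    q <- ifelse(query %in% AA20, query, "X")
    t <- ifelse(template_seq %in% AA20, template_seq, "X")
    return(model$matrix[q, t, drop = FALSE] * 1)
  }
  # pssm backend
  qt <- model$query_profile[, template_seq, drop = FALSE]
  if (is.null(model$template_profile)) return(unname(qt))
  tq <- t(model$template_profile[, query, drop = FALSE])
  unname((qt + tq) / 2)
}

#' Build the column-structured similarity matrix
#'
#' Scores every query/template position pair under the model and attaches
#' the template SSE intervals as the column structure the fragment
#' sampler works in.
#'
#' @param query query sequence (string or letter vector).
#' @param template annotated [template_structure()].
#' @param model a `score_model`.
#' @return object of class `similarity_matrix`: list with `values`
#'   (L_query x L_template), `column_bounds` (the SSE table), `query`,
#'   `template_seq`.
#' @export
build_similarity_matrix <- function(query, template, model) {
  query <- as_aa_vector(query, "query sequence")
  if (is.null(template$sse))
    stop("template has no SSE annotation; run annotate_template() first")
  values <- score_grid(model, query, template$sequence)
  structure(list(values = values,
                 column_bounds = template$sse,
                 query = query,
                 template_seq = template$sequence),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("Similarity matrix: %d query x %d template positions, %d SSE column(s)\n",
              nrow(x$values), ncol(x$values), nrow(x$column_bounds)))
  invisible(x)
}
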