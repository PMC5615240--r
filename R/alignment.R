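# Aligned DNA matrices: construction, validation, I/O, column access,
# base-composition summaries and site-pattern compression.

# Full input alphabet: canonical bases, gap, and IUPAC ambiguity codes.
# Everything outside A/C/G/T is treated as fully missing in the likelihood.
.nuc_bases <- c("A", "C", "G", "T")
.nuc_alphabet <- c(.nuc_bases, "-", "U", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N", "?")

#' Construct an aligned nucleotide matrix
#'
#' Builds the alignment container used throughout the package: an `s x n`
#' character matrix over the DNA alphabet (A, C, G, T, gap `-` and IUPAC
#' ambiguity codes), one row per taxon.  Input is case-insensitive; the
#' stored matrix is upper case and `U` is mapped to `T`.
#'
#' @param seqs Character vector of aligned sequences, all the same length,
#'   or an `s x n` character matrix of single characters.
#' @param taxa Character vector of unique, non-empty taxon labels; defaults
#'   to `names(seqs)` (or rownames of a matrix input).
#' @return An object of class `"nucleotide_alignment"`: a list with elements
#'   `taxa`, `mat` (s x n character matrix), `s` and `n`.
#' @examples
#' aln <- nucleotide_alignment(c(a = "ACGT", b = "AC-T"))
#' aln$n
#' @export
nucleotide_alignment <- function(seqs, taxa = NULL) {
  if (is.matrix(seqs)) {
    if (is.null(taxa)) taxa <- rownames(seqs)
    mat <- toupper(seqs)
  } else {
    if (is.null(taxa)) taxa <- names(seqs)
    if (length(seqs) < 2L)
      stop("an alignment needs at least 2 sequences", call. = FALSE)
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) {
      bad <- which(lens != lens[1L])[1L]
      lab <- if (!is.null(taxa)) taxa[bad] else as.character(bad)
      stop(sprintf(
        "alignment rows have unequal lengths: taxon '%s' has %d sites, expected %d",
        lab, lens[bad], lens[1L]), call. = FALSE)
    }
    mat <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  }
  if (is.null(taxa) || any(!nzchar(taxa)))
    stop("taxon labels must be supplied and non-empty", call. = FALSE)
  taxa <- as.character(taxa)
  if (anyDuplicated(taxa))
    stop(sprintf("duplicate taxon label: '%s'",
                 taxa[duplicated(taxa)][1L]), call. = FALSE)
  if (nrow(mat) < 2L)
    stop("an alignment needs at least 2 sequences", call. = FALSE)
  if (ncol(mat) < 1L)
    stop("alignment has zero sites", call. = FALSE)
  mat[mat == "U"] <- "T"
  bad <- which(!(mat %in% .nuc_alphabet))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(mat)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(mat)) + 1L
    stop(sprintf(
      "illegal character '%s' in taxon '%s' at site %d",
      mat[bad[1L]], taxa[i], j), call. = FALSE)
  }
  dimnames(mat) <- list(taxa, NULL)
  structure(list(taxa = taxa, mat = mat, s = nrow(mat), n = ncol(mat)),
            class = "nucleotide_alignment")
}

#' @export
print.nucleotide_alignment <- function(x, ...) {
  cat(sprintf("Nucleotide alignment: %d taxa, %d sites\n", x$s, x$n))
  shown <- utils::head(x$taxa, 8L)
  for (t in shown) {
    seq <- paste(x$mat[t, seq_len(min(x$n, 50L))], collapse = "")
    cat(sprintf("  %-12s %s%s\n", t, seq, if (x$n > 50L) "..." else ""))
  }
  if (x$s > 8L) cat(sprintf("  ... and %d more taxa\n", x$s - 8L))
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Reads a multi-record FASTA file of pre-aligned DNA sequences.  Record
#' order is preserved; sequence validation (equal lengths, legal alphabet,
#' unique labels) happens on construction.
#'
#' @param path Path to a FASTA file.
#' @return A [nucleotide_alignment()] object.
#' @export
read_fasta_alignment <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  recs <- ape::read.FASTA(path)
  if (length(recs) == 0L) stop("no FASTA records found", call. = FALSE)
  seqs <- vapply(as.character(recs),
                 function(x) paste(x, collapse = ""), character(1))
  nucleotide_alignment(seqs, taxa = names(recs))
}

#' Write an alignment as FASTA
#'
#' @param aln A [nucleotide_alignment()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_fasta_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "nucleotide_alignment"))
  lines <- character(2L * aln$s)
  for (i in seq_len(aln$s)) {
    lines[2L * i - 1L] <- paste0(">", aln$taxa[i])
    lines[2L * i] <- paste(aln$mat[i, ], collapse = "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a relaxed PHYLIP alignment
#'
#' Accepts the relaxed PHYLIP dialect: a header line with the number of taxa
#' and the number of sites, then whitespace-separated name/sequence records,
#' either sequential (sequences may wrap over lines) or interleaved in
#' blocks.  The declared dimensions are enforced.
#'
#' @param path Path to a PHYLIP file.
#' @return A [nucleotide_alignment()] object.
#' @export
read_phylip_alignment <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("PHYLIP file too short", call. = FALSE)
  hdr <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(hdr) < 2L || anyNA(suppressWarnings(as.integer(hdr[1:2]))))
    stop("PHYLIP header must hold two integers: taxa and sites", call. = FALSE)
  s <- as.integer(hdr[1L]); n <- as.integer(hdr[2L])
  body <- lines[-1L]
  if (length(body) < s)
    stop(sprintf("PHYLIP dimension error: header declares %d taxa, found %d records",
                 s, length(body)), call. = FALSE)
  taxa <- character(s)
  seqs <- character(s)
  # First block: each of the first s lines starts with a taxon name.
  for (i in seq_len(s)) {
    parts <- strsplit(trimws(body[i]), "\\s+")[[1L]]
    taxa[i] <- parts[1L]
    seqs[i] <- paste(parts[-1L], collapse = "")
  }
  # Remaining lines: sequential wrap-around or interleaved blocks; either
  # way they are bare sequence chunks appended to taxa in rotation.
  extra <- body[-seq_len(s)]
  if (length(extra)) {
    for (j in seq_along(extra)) {
      chunk <- gsub("\\s+", "", extra[j])
      # Interleaved blocks may repeat the taxon name; strip it if present.
      parts <- strsplit(trimws(extra[j]), "\\s+")[[1L]]
      if (length(parts) > 1L && parts[1L] %in% taxa) {
        i <- match(parts[1L], taxa)
        seqs[i] <- paste0(seqs[i], paste(parts[-1L], collapse = ""))
      } else {
        i <- ((j - 1L) %% s) + 1L
        seqs[i] <- paste0(seqs[i], chunk)
      }
    }
  }
  lens <- nchar(seqs)
  if (any(lens != n))
    stop(sprintf(
      "PHYLIP dimension error: taxon '%s' has %d sites, header declares %d",
      taxa[which(lens != n)[1L]], lens[which(lens != n)[1L]], n), call. = FALSE)
  nucleotide_alignment(seqs, taxa = taxa)
}

#' Write an alignment in relaxed PHYLIP format
#'
#' @param aln A [nucleotide_alignment()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_phylip_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "nucleotide_alignment"))
  lines <- c(sprintf("%d %d", aln$s, aln$n),
             vapply(seq_len(aln$s), function(i)
               paste(aln$taxa[i], paste(aln$mat[i, ], collapse = "")),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Extract one alignment column
#'
#' Returns the site pattern at position `j` (1-based), in taxon order.
#'
#' @param aln A [nucleotide_alignment()].
#' @param j Site index in `1..n`.
#' @return Character vector of length `s`, named by taxon.
#' @export
site_column <- function(aln, j) {
  stopifnot(inherits(aln, "nucleotide_alignment"))
  if (length(j) != 1L || is.na(j) || j < 1L || j > aln$n)
    stop(sprintf("site index %s out of range 1..%d", as.character(j), aln$n),
         call. = FALSE)
  stats::setNames(aln$mat[, j], aln$taxa)
}

#' Per-taxon base composition
#'
#' Counts A, C, G, T occurrences in one taxon's row; gaps and all ambiguity
#' codes are pooled as `missing`.  The five counts always sum to `n`.
#'
#' @param aln A [nucleotide_alignment()].
#' @param taxon A taxon label present in the alignment.
#' @return Named integer vector `c(A, C, G, T, missing)`.
#' @export
composition_counts <- function(aln, taxon) {
  stopifnot(inherits(aln, "nucleotide_alignment"))
  if (!(taxon %in% aln$taxa))
    stop(sprintf("unknown taxon: '%s'", taxon), call. = FALSE)
  row <- aln$mat[taxon, ]
  counts <- vapply(.nuc_bases, function(b) sum(row == b), integer(1))
  c(counts, missing = aln$n - sum(counts))
}

# Integer state coding: A=1, C=2, G=3, T=4, NA = missing (gap or ambiguity).
state_matrix <- function(aln) {
  m <- match(aln$mat, .nuc_bases)
  dim(m) <- dim(aln$mat)
  rownames(m) <- aln$taxa
  m
}

# Collapse identical columns into weighted site patterns.  Returns integer
# pattern matrix (s x n_patterns), weights, and the site -> pattern map.
compress_patterns <- function(aln) {
  S <- state_matrix(aln)
  keys <- apply(S, 2L, paste, collapse = ",")
  uk <- unique(keys)
  idx <- match(keys, uk)
  first <- match(uk, keys)
  list(states = S[, first, drop = FALSE],
       weights = as.numeric(tabulate(idx, nbins = length(uk))),
       site_pattern = idx)
}

# Build an alignment from an integer state matrix (used by the simulator).
alignment_from_states <- function(states, taxa) {
  chars <- .nuc_bases[states]
  dim(chars) <- dim(states)
  nucleotide_alignment(chars, taxa = taxa)
}
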