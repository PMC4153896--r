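#' Circular genome objects
#'
#' A `circular_genome` is an immutable single-sequence genome of length `L`
#' whose coordinate arithmetic is modular: position `p` and `p + L` refer to
#' the same base.  Coordinates are 1-based inclusive; the canonical
#' representative of a position lies in `[1, L + 1)`.  Midpoints of
#' even-length elements are kept as exact half-integers.
#'
#' @param sequence Character scalar over the alphabet `A`, `C`, `G`, `T`, `N`
#'   (lower case is folded to upper case).
#' @param id Sequence identifier.
#' @return An object of class `circular_genome` with fields `id`, `sequence`
#'   and `length`.
#' @examples
#' g <- circular_genome("ACGTACGT", id = "toy")
#' genome_length(g)
#' @export
circular_genome <- function(sequence, id = "genome") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    abort("`sequence` must be a single character string.")
  }
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1L) {
    abort("Genome sequence must contain at least one base.")
  }
  bad <- stringi::stri_replace_all_regex(sequence, "[ACGTN]", "")
  if (nchar(bad) > 0L) {
    abort(paste0(
      "Genome sequence contains characters outside {A,C,G,T,N}: ",
      paste(unique(strsplit(bad, "")[[1]]), collapse = ", ")
    ))
  }
  structure(
    list(id = as.character(id), sequence = sequence, length = nchar(sequence)),
    class = "circular_genome"
  )
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf(
    "<circular_genome> %s: %s nt (circular)\n", x$id,
    format(x$length, big.mark = ",")
  ))
  comp <- genome_composition(x)
  cat("  composition:",
      paste(sprintf("%s=%.3f", comp$base, comp$fraction), collapse = " "),
      "\n")
  invisible(x)
}

#' @rdname circular_genome
#' @param genome A `circular_genome`.
#' @export
genome_length <- function(genome) {
  stopifnot(inherits(genome, "circular_genome"))
  genome$length
}

#' @rdname circular_genome
#' @export
genome_sequence <- function(genome) {
  stopifnot(inherits(genome, "circular_genome"))
  genome$sequence
}

#' Base composition of a genome
#'
#' Counts and fractions of `A`, `C`, `G`, `T` and (if present) `N` on the
#' deposited (reference) strand.
#'
#' @param genome A [circular_genome()].
#' @return A tibble with columns `base`, `count`, `fraction`.
#' @export
genome_composition <- function(genome) {
  stopifnot(inherits(genome, "circular_genome"))
  chars <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T", "N")
  counts <- vapply(bases, function(b) sum(chars == b), integer(1))
  keep <- counts > 0L | bases %in% c("A", "C", "G", "T")
  tibble(
    base = bases[keep],
    count = unname(counts[keep]),
    fraction = unname(counts[keep]) / genome$length
  )
}

#' Read a single-record FASTA file as a circular genome
#'
#' The record id is the FASTA header up to the first whitespace.  Exactly one
#' record is required; the sequence is folded to upper case and must use the
#' alphabet `A`, `C`, `G`, `T`, `N`.
#'
#' @param path Path to a FASTA file.
#' @return A [circular_genome()].
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("Could not parse FASTA file: ", conditionMessage(e)))
  )
  if (length(set) == 0L) abort("FASTA file contains no records.")
  if (length(set) > 1L) {
    abort(sprintf("FASTA file contains %d records; exactly one is required.", length(set)))
  }
  id <- strsplit(names(set)[1], "\\s+")[[1]][1]
  circular_genome(as.character(set[[1]]), id = id)
}

#' Write a circular genome to FASTA
#'
#' @param genome A [circular_genome()].
#' @param path Output path.
#' @param width Line width for the sequence.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  stopifnot(inherits(genome, "circular_genome"))
  set <- Biostrings::DNAStringSet(genome$sequence)
  names(set) <- genome$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Reverse complement of a DNA string
#'
#' Standard reverse complement over `A`, `C`, `G`, `T`, `N` (with `N`
#' mapping to `N`).  Vectorised over `seq`; the empty string maps to itself.
#'
#' @param seq Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("GGAT")
#' @export
reverse_complement <- function(seq) {
  .check_dna(seq)
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", toupper(seq)))
}

#' Base-wise complement (no reversal) of a DNA string
#'
#' @inheritParams reverse_complement
#' @return Character vector of complements.
#' @export
complement_sequence <- function(seq) {
  .check_dna(seq)
  chartr("ACGTN", "TGCAN", toupper(seq))
}

.check_dna <- function(seq) {
  if (!is.character(seq)) abort("DNA input must be a character vector.")
  bad <- stringi::stri_detect_regex(toupper(seq), "[^ACGTN]")
  if (any(bad, na.rm = TRUE)) {
    abort("DNA sequence contains characters outside {A,C,G,T,N}.")
  }
  invisible(seq)
}

#' Canonical circular coordinate
#'
#' Maps any (possibly fractional) position to its canonical representative in
#' `[1, L + 1)` on a circle of length `L`.
#'
#' @param p Numeric vector of positions (1-based; half-integers allowed).
#' @param L Genome length in nucleotides.
#' @return Numeric vector of canonical positions.
#' @export
canonical_position <- function(p, L) {
  stopifnot(L >= 1)
  ((p - 1) %% L) + 1
}

#' Circular distance between positions
#'
#' The length of the shorter of the two arcs between `a` and `b` on a circle
#' of length `L`; always in `[0, L/2]`.  Vectorised and recycled over `a`
#' and `b`.
#'
#' @param a,b Numeric vectors of positions.
#' @param L Genome length in nucleotides.
#' @return Numeric vector of distances in nucleotides.
#' @examples
#' circular_distance(1, 16569, L = 16569)
#' @export
circular_distance <- function(a, b, L) {
  stopifnot(L >= 1)
  d <- abs(a - b) %% L
  pmin(d, L - d)
}

#' Rotate positions around the circle
#'
#' Each position `p` maps to `((p - 1 + r) mod L) + 1`; fractional parts are
#' preserved and the multiset size is unchanged.
#'
#' @param points Numeric vector of positions.
#' @param r Integer rotation offset (any integer; reduced mod `L`).
#' @param L Genome length in nucleotides.
#' @return Numeric vector of rotated canonical positions.
#' @export
rotate_positions <- function(points, r, L) {
  stopifnot(L >= 1, length(r) == 1L)
  ((points - 1 + r) %% L) + 1
}
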