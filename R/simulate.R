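#' Base-composition presets
#'
#' `mtdna_composition()` is a strand-asymmetric profile resembling the
#' deposited (reference) strand of human mtDNA, which is guanine-poor (the
#' guanine-rich heavy strand is its complement).  `uniform_composition()` is
#' the symmetric 0.25 profile.  Both are plain named vectors, so any other
#' composition can be supplied directly.
#'
#' @return Named numeric probability vector over `A`, `C`, `G`, `T`.
#' @export
mtdna_composition <- function() {
  c(A = 0.309, C = 0.313, G = 0.131, T = 0.247)
}

#' @rdname mtdna_composition
#' @export
uniform_composition <- function() {
  c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
}

.check_composition <- function(composition) {
  if (!is.numeric(composition) || length(composition) != 4L ||
      is.null(names(composition)) ||
      !setequal(names(composition), c("A", "C", "G", "T"))) {
    abort("`composition` must be a named numeric vector over A, C, G, T.")
  }
  if (any(composition < 0) || abs(sum(composition) - 1) > 1e-9) {
    abort("Composition probabilities must be >= 0 and sum to 1 (within 1e-9).")
  }
  composition[c("A", "C", "G", "T")]
}

#' Generate a random circular genome
#'
#' Bases are drawn i.i.d. from `composition`; the result is bit-reproducible
#' from `seed`.
#'
#' @param L Genome length in nucleotides.
#' @param composition Named probability vector over `A`, `C`, `G`, `T`
#'   (see [mtdna_composition()]).
#' @param seed Integer seed (`NULL` uses the current RNG state).
#' @param id Genome identifier.
#' @return A [circular_genome()].
#' @export
generate_genome <- function(L, composition = mtdna_composition(),
                            seed = NULL, id = "synthetic") {
  stopifnot(L >= 1)
  composition <- .check_composition(composition)
  draw <- function() {
    paste(sample(names(composition), L, replace = TRUE, prob = composition),
          collapse = "")
  }
  seq <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  circular_genome(seq, id = id)
}

#' Shuffle a genome preserving base content
#'
#' Uniformly random permutation of the base multiset: nucleotide content
#' (and hence strand asymmetry) is preserved exactly, while all positional
#' structure is destroyed.  This is the null genome used when asking whether
#' a motif count exceeds what identical nucleotide content would produce.
#'
#' @param genome A [circular_genome()].
#' @param seed Integer seed (`NULL` uses the current RNG state).
#' @return A [circular_genome()] with the same composition.
#' @export
shuffle_genome <- function(genome, seed = NULL) {
  stopifnot(inherits(genome, "circular_genome"))
  chars <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
  draw <- function() paste(sample(chars), collapse = "")
  seq <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  circular_genome(seq, id = paste0(genome$id, "_shuffled"))
}

#' Plant sequences into a genome at known positions
#'
#' Overwrites bases circularly starting at each position (wrapping past the
#' origin if needed) and returns a new genome.  Planting is rejected if two
#' plants demand different bases at the same position.
#'
#' @param genome A [circular_genome()].
#' @param seq Character vector of sequences to plant.
#' @param position Numeric vector of 1-based start positions (recycled
#'   against `seq`).
#' @return A new [circular_genome()].
#' @export
plant_sequence <- function(genome, seq, position) {
  stopifnot(inherits(genome, "circular_genome"))
  .check_dna(seq)
  L <- genome$length
  n <- max(length(seq), length(position))
  seq <- rep_len(toupper(seq), n)
  position <- rep_len(position, n)
  if (any(nchar(seq) > L)) abort("Planted sequence longer than the genome.")
  chars <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
  written <- rep(NA_character_, L)
  for (i in seq_len(n)) {
    pl <- strsplit(seq[i], "", fixed = TRUE)[[1]]
    idx <- as.integer(canonical_position(position[i] + seq_along(pl) - 1, L))
    clash <- !is.na(written[idx]) & written[idx] != pl
    if (any(clash)) {
      abort(sprintf("Conflicting plants at position(s) %s.",
                    paste(head(idx[clash], 5), collapse = ", ")))
    }
    written[idx] <- pl
    chars[idx] <- pl
  }
  circular_genome(paste(chars, collapse = ""), id = genome$id)
}

#' Displacement distribution specification
#'
#' Describes how far a simulated breakpoint is displaced from its anchor
#' (a motif midpoint or repeat-unit midpoint).  The magnitude is drawn from
#' the stated distribution, the sign is uniform, and the signed displacement
#' is rounded to the nearest integer, half away from zero.
#'
#' @param dist `"uniform"` (magnitude uniform on `[0, max]`) or
#'   `"geometric"` (magnitude geometric with parameter `prob`).
#' @param max Maximum magnitude for the uniform distribution (nt).
#' @param prob Success probability for the geometric distribution.
#' @return A displacement spec list.
#' @export
displacement_spec <- function(dist = c("uniform", "geometric"),
                              max = 0, prob = 0.5) {
  dist <- match.arg(dist)
  list(dist = dist, max = max, prob = prob)
}

.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

.sample_displacement <- function(spec, n) {
  mag <- switch(spec$dist,
    uniform = stats::runif(n, 0, spec$max),
    geometric = stats::rgeom(n, spec$prob)
  )
  sgn <- sample(c(-1, 1), n, replace = TRUE)
  .round_half_away(sgn * mag)
}

#' Simulate deletion sets
#'
#' Generates `n` deletion records under one of three breakpoint models:
#' * `uniform`: both breakpoints drawn uniformly (distinct within a record)
#'   and ordered so `bp5 < bp3` — the null the rotational tests calibrate
#'   against;
#' * `motif_associated`: each breakpoint is a uniformly chosen motif
#'   midpoint plus a signed displacement from `displacement`;
#' * `repeat_mediated`: the two ends of each record are placed at the two
#'   unit midpoints of a uniformly chosen repeat pair (plus displacement).
#'
#' @param n Number of deletions.
#' @param L Genome length.
#' @param mode `"uniform"`, `"motif_associated"` or `"repeat_mediated"`.
#' @param motif_set Motif midpoints (required for `motif_associated`).
#' @param repeat_pairs Pair table from [enumerate_repeat_pairs()] (required
#'   for `repeat_mediated`).
#' @param displacement A [displacement_spec()].
#' @param seed Integer seed (`NULL` uses the current RNG state).
#' @return A deletion tibble with columns `id`, `bp5`, `bp3`; the seed and
#'   mode are recorded as attributes.
#' @export
simulate_deletions <- function(n, L,
    mode = c("uniform", "motif_associated", "repeat_mediated"),
    motif_set = NULL, repeat_pairs = NULL,
    displacement = displacement_spec("uniform", max = 0),
    seed = NULL) {
  mode <- match.arg(mode)
  if (n <= 0) abort("`n` must be positive.")
  draw <- function() {
    if (mode == "uniform") {
      bp5 <- integer(n); bp3 <- integer(n)
      for (i in seq_len(n)) {
        pr <- sort(sample.int(L, 2L))
        bp5[i] <- pr[1L]; bp3[i] <- pr[2L]
      }
    } else if (mode == "motif_associated") {
      mids <- motif_midpoints(motif_set %||% numeric(0))
      if (length(mids) == 0L) abort("`motif_set` is required (and nonempty) for motif_associated mode.")
      place <- function() {
        anchor <- mids[sample.int(length(mids), n, replace = TRUE)]
        as.integer(canonical_position(
          .round_half_away(anchor) + .sample_displacement(displacement, n), L))
      }
      bp5 <- place(); bp3 <- place()
      clash <- bp5 == bp3
      tries <- 0L
      while (any(clash) && tries < 50L) {
        anchor <- mids[sample.int(length(mids), sum(clash), replace = TRUE)]
        bp3[clash] <- as.integer(canonical_position(
          .round_half_away(anchor) +
            .sample_displacement(displacement, sum(clash)), L))
        clash <- bp5 == bp3
        tries <- tries + 1L
      }
      # degenerate motif source (e.g. a single midpoint with zero
      # displacement): nudge the 3' end off the anchor
      if (any(clash)) {
        bp3[clash] <- as.integer(canonical_position(bp3[clash] + 1, L))
      }
      # a deletion's 5' end is by convention the smaller coordinate
      swap <- bp5 > bp3
      tmp <- bp5[swap]; bp5[swap] <- bp3[swap]; bp3[swap] <- tmp
    } else {
      if (is.null(repeat_pairs) || nrow(repeat_pairs) == 0L) {
        abort("`repeat_pairs` is required (and nonempty) for repeat_mediated mode.")
      }
      pick <- sample.int(nrow(repeat_pairs), n, replace = TRUE)
      bp5 <- as.integer(canonical_position(
        .round_half_away(repeat_pairs$mid5[pick]) +
          .sample_displacement(displacement, n), L))
      bp3 <- as.integer(canonical_position(
        .round_half_away(repeat_pairs$mid3[pick]) +
          .sample_displacement(displacement, n), L))
      clash <- bp5 == bp3
      bp3[clash] <- as.integer(canonical_position(bp3[clash] + 1, L))
    }
    tibble(id = paste0("del", seq_len(n)), bp5 = bp5, bp3 = bp3)
  }
  out <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  attr(out, "mode") <- mode
  attr(out, "seed") <- seed
  out
}
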