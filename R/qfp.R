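#' Motif sets
#'
#' A motif set is a tibble of located sequence elements (one row per
#' element) carrying a `midpoint` column, plus attributes `motif_name`,
#' `genome_id` and `L` (genome length).  Statistical functions only consume
#' the midpoints; the remaining columns document the elements.
#'
#' @param elements Tibble of elements with at least a `midpoint` column.
#' @param name Motif set name (e.g. `"2G_intrastrand"`).
#' @param genome_id Identifier of the genome scanned.
#' @param L Genome length in nucleotides.
#' @return A `motif_set` tibble.
#' @export
new_motif_set <- function(elements, name, genome_id, L) {
  elements <- as_tibble(elements)
  if (nrow(elements) > 0 && !"midpoint" %in% names(elements)) {
    abort("Motif elements must have a `midpoint` column.")
  }
  structure(
    elements,
    motif_name = name, genome_id = genome_id, L = L,
    class = c("motif_set", class(tibble())))
}

#' @export
print.motif_set <- function(x, ...) {
  cat(sprintf(
    "<motif_set> %s on %s (L = %s): %d elements\n",
    attr(x, "motif_name") %||% "?", attr(x, "genome_id") %||% "?",
    format(attr(x, "L") %||% NA, big.mark = ","), nrow(x)
  ))
  NextMethod()
}

#' Extract motif midpoints
#'
#' @param x A `motif_set`, a data frame with a `midpoint` (or, for
#'   breakpoint tables, `position`) column, or a numeric vector of
#'   positions.
#' @return Numeric vector of midpoint positions.
#' @export
motif_midpoints <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (is.data.frame(x)) {
    if ("midpoint" %in% names(x)) return(as.numeric(x$midpoint))
    if ("position" %in% names(x)) return(as.numeric(x$position))
    abort("Data frame has no `midpoint` or `position` column.")
  }
  abort("Cannot extract positions from this object.")
}

#' Find maximal guanine tracts
#'
#' Returns all maximal runs of consecutive `G` of length at least `min_len`
#' in the frame of `seq` (treated as linear).  `N` bases terminate G-runs.
#'
#' @param seq A DNA string.
#' @param min_len Minimum run length (>= 2 for quadruplex scanning, but any
#'   value >= 1 is accepted here).
#' @return Tibble with columns `start`, `end`, `length`.
#' @examples
#' find_g_tracts("GGATGGGGTGGGGAGG", min_len = 2)
#' @export
find_g_tracts <- function(seq, min_len = 2L) {
  .check_dna(seq)
  stopifnot(length(seq) == 1L, min_len >= 1)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  if (length(chars) == 0L) {
    return(tibble(start = integer(), end = integer(), length = integer()))
  }
  r <- rle(chars == "G")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  tibble(start = starts[keep], end = ends[keep], length = r$lengths[keep])
}

# Flavoured run-end index: for each position the end of the maximal
# homogeneous run of its flavour (0 where the base is not a tract base).
.run_ends <- function(fl) {
  n <- length(fl)
  run_end <- integer(n)
  if (n == 0L) return(run_end)
  run_end[n] <- n
  if (n > 1L) {
    for (i in (n - 1L):1L) {
      run_end[i] <- if (fl[i] != 0L && fl[i + 1L] == fl[i]) run_end[i + 1L] else i
    }
  }
  run_end
}

# Core quadruplex-candidate dynamic programme on a linear character vector.
#
# A candidate is keyed by (start of first tract, end of last tract); its
# tetrad count is the maximum over 4-tract selections of the minimum tract
# length in the selection.  Tracts are homogeneous runs of a tract base
# ('G', or 'G'/'C' in duplex-derived interstrand mode where a C-run is a
# G-run on the complementary strand); consecutive selected tracts are
# separated by >= min_loop nucleotides (loop bases may themselves be G, so
# one long run may donate two tracts).  Only starts <= starts_limit seed
# candidates (used by the circular wrapper).
.qfp_candidates_linear <- function(chars, min_run, max_span, min_loop,
                                   flavors = "G", require_mixed = FALSE,
                                   starts_limit = length(chars)) {
  n <- length(chars)
  fl <- integer(n)
  if ("G" %in% flavors) fl[chars == "G"] <- 1L
  if ("C" %in% flavors) fl[chars == "C"] <- 2L
  run_end <- .run_ends(fl)
  starts <- which(fl != 0L & run_end - seq_len(n) + 1L >= min_run)
  starts <- starts[starts <= starts_limit]

  out_start <- integer(0); out_end <- integer(0); out_tet <- integer(0)
  for (s in starts) {
    wend <- min(s + max_span - 1L, n)
    W <- wend - s + 1L
    f_prev <- matrix(-1L, nrow = W, ncol = 3L)
    bmax <- min(run_end[s], wend)
    if (bmax >= s + min_run - 1L) {
      bb <- (s + min_run - 1L):bmax
      f_prev[bb - s + 1L, fl[s]] <- bb - s + 1L
    } else next
    for (t in 2:4) {
      best <- apply(f_prev, 2L, cummax)
      if (W == 1L) best <- matrix(best, nrow = 1L)
      f_t <- matrix(-1L, nrow = W, ncol = 3L)
      amin <- s + min_run + min_loop
      if (amin <= wend) {
        for (a in amin:wend) {
          if (fl[a] == 0L || run_end[a] < a + min_run - 1L) next
          prev_rel <- a - min_loop - 1L - s + 1L
          if (prev_rel < 1L) next
          pv <- best[prev_rel, ]
          if (all(pv < 0L)) next
          bmax <- min(run_end[a], wend)
          if (bmax < a + min_run - 1L) next
          abit <- fl[a]
          for (b in (a + min_run - 1L):bmax) {
            tl <- b - a + 1L
            brel <- b - s + 1L
            for (m in 1:3) {
              if (pv[m] < 0L) next
              nm <- bitwOr(m, abit)
              val <- min(pv[m], tl)
              if (val > f_t[brel, nm]) f_t[brel, nm] <- val
            }
          }
        }
      }
      f_prev <- f_t
    }
    vals <- if (require_mixed) f_prev[, 3L] else apply(f_prev, 1L, max)
    hit <- which(vals >= min_run)
    if (length(hit)) {
      out_start <- c(out_start, rep.int(s, length(hit)))
      out_end <- c(out_end, s + hit - 1L)
      out_tet <- c(out_tet, vals[hit])
    }
  }
  tibble(start = out_start, end = out_end, tetrads = out_tet)
}

#' Enumerate quadruplex-forming-potential candidates in a linear sequence
#'
#' Candidates are selections of four disjoint G-tracts, each of length at
#' least `min_run`, with at least `min_loop` nucleotides between consecutive
#' tracts (loop bases may be G, so a long G-run may donate two tracts split
#' by a 1-nt loop), spanning at most `max_span` nucleotides from the start
#' of the first tract to the end of the last.  Selections are collapsed to
#' elements keyed by that (start, end) pair; an element's tetrad count is the
#' maximum over its selections of the minimum tract length in the selection.
#'
#' @param seq A DNA string (treated as linear; see [find_intrastrand_qfp()]
#'   for circular scanning).
#' @param min_run Minimum G-run length: 2 for "2G" motifs, 3 for "3G".
#' @param max_span Maximum element length in nucleotides.
#' @param min_loop Minimum loop length between consecutive tracts.
#' @return Tibble with columns `start`, `end`, `span`, `tetrads`,
#'   `midpoint` (half-integers for even spans).
#' @examples
#' enumerate_qfp_candidates("GGGGGATGCGGGGG", min_run = 2)
#' @export
enumerate_qfp_candidates <- function(seq, min_run, max_span = 33L, min_loop = 1L) {
  .check_dna(seq)
  stopifnot(min_run %in% c(2L, 3L), min_loop >= 1, max_span >= 1)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  cand <- .qfp_candidates_linear(chars, min_run, max_span, min_loop)
  dplyr::mutate(cand,
    span = .data$end - .data$start + 1L,
    midpoint = (.data$start + .data$end) / 2,
    .after = "end"
  )
}

# TRUE where circular intervals (s1, span1) and (s2, span2) share a base.
.circ_overlap <- function(s1, span1, s2, span2, L) {
  d <- (s2 - s1) %% L
  (d <= span1 - 1) | (d >= L - span2 + 1)
}

#' Resolve overlapping QFP candidates to a non-overlapping set
#'
#' Iterative greedy selection modelling the two published element-choice
#' rules plus a median tie rule: repeatedly take the best remaining
#' candidate by (span ascending, tetrads descending, start ascending); when
#' the top rank is shared by several mutually overlapping candidates with
#' equal span and equal tetrads, emit one synthetic element whose midpoint is
#' the median of their midpoints; then drop every candidate overlapping the
#' emitted element and repeat.
#'
#' @param candidates Tibble from the candidate enumerator (one genome, one
#'   strand) with columns `start`, `span`, `tetrads`, `midpoint`.
#' @param L Genome length (candidates are circular intervals).
#' @return Tibble of pairwise non-overlapping elements with the input
#'   columns plus `n_merged` (number of tied candidates merged into the
#'   element; 1 for ordinary elements).
#' @export
resolve_qfp_overlaps <- function(candidates, L) {
  candidates <- as_tibble(candidates)
  need <- c("start", "span", "tetrads", "midpoint")
  if (!all(need %in% names(candidates))) {
    abort("`candidates` must have columns start, span, tetrads, midpoint.")
  }
  work <- dplyr::arrange(candidates, .data$span, dplyr::desc(.data$tetrads), .data$start)
  out <- list()
  while (nrow(work) > 0L) {
    top <- work[1L, ]
    tie_idx <- which(
      work$span == top$span & work$tetrads == top$tetrads &
        .circ_overlap(top$start, top$span, work$start, work$span, L)
    )
    # keep the maximal mutually-overlapping subset containing the top
    kept <- tie_idx[1L]
    for (i in tie_idx[-1L]) {
      ok <- all(.circ_overlap(work$start[i], work$span[i],
                              work$start[kept], work$span[kept], L))
      if (ok) kept <- c(kept, i)
    }
    grp <- work[kept, ]
    if (nrow(grp) > 1L) {
      rel_start <- ((grp$start - top$start + L / 2) %% L) - L / 2
      rel_mid <- ((grp$midpoint - top$start + L / 2) %% L) - L / 2
      hull_start <- top$start + min(rel_start)
      hull_end <- top$start + max(rel_start + grp$span - 1)
      hull_span <- hull_end - hull_start + 1
      el <- top
      el$start <- canonical_position(hull_start, L)
      el$span <- hull_span
      el$midpoint <- canonical_position(top$start + median(rel_mid), L)
      if ("end" %in% names(el)) el$end <- canonical_position(hull_start + hull_span - 1, L)
      el$n_merged <- nrow(grp)
    } else {
      el <- top
      el$n_merged <- 1L
    }
    out[[length(out) + 1L]] <- el
    keep <- !.circ_overlap(el$start, el$span, work$start, work$span, L)
    work <- work[keep, , drop = FALSE]
  }
  if (length(out) == 0L) {
    dplyr::mutate(candidates[0, ], n_merged = integer(0))
  } else {
    dplyr::bind_rows(out)
  }
}

# Circular candidate scan of one strand (reference frame of `chars`).
# Windows may wrap the origin; starts are reported in 1..L and ends may be
# returned as linear positions > L (end_linear) alongside canonical ones.
.scan_qfp_circular <- function(chars, L, min_run, max_span, min_loop,
                               flavors = "G", require_mixed = FALSE) {
  eff <- min(max_span, L)
  ext <- if (eff > 1L) c(chars, chars[seq_len(eff - 1L)]) else chars
  cand <- .qfp_candidates_linear(ext, min_run, eff, min_loop,
                                 flavors = flavors, require_mixed = require_mixed,
                                 starts_limit = L)
  span <- cand$end - cand$start + 1L
  tibble(
    start = cand$start,
    end_linear = cand$end,
    end = canonical_position(cand$end, L),
    span = span,
    tetrads = cand$tetrads,
    midpoint = canonical_position(cand$start + (span - 1) / 2, L)
  )
}

#' Scan a circular genome for intrastrand QFP elements
#'
#' Scans the deposited strand and its reverse complement circularly (windows
#' may wrap the origin), maps complement-strand hits back to reference
#' coordinates, resolves overlaps independently per strand, and returns the
#' union.  The strand with the higher G content is labelled `"heavy"` in
#' `strand_label` (in human mtDNA the heavy strand carries most guanines).
#'
#' @param genome A [circular_genome()].
#' @param min_run Minimum G-run length (2 or 3).
#' @param max_span,min_loop See [enumerate_qfp_candidates()].
#' @return A [new_motif_set()] tibble with columns `start`, `end`, `span`,
#'   `strand` (`reference`/`complement`), `strand_label` (`heavy`/`light`),
#'   `tier`, `tetrads`, `midpoint`, `n_merged`.
#' @export
find_intrastrand_qfp <- function(genome, min_run, max_span = 33L, min_loop = 1L) {
  stopifnot(inherits(genome, "circular_genome"), min_run %in% c(2L, 3L))
  L <- genome$length
  chars <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]

  ref <- .scan_qfp_circular(chars, L, min_run, max_span, min_loop)
  ref <- resolve_qfp_overlaps(ref, L)
  if (nrow(ref)) ref$strand <- "reference"

  rc_chars <- strsplit(reverse_complement(genome$sequence), "", fixed = TRUE)[[1]]
  comp <- .scan_qfp_circular(rc_chars, L, min_run, max_span, min_loop)
  if (nrow(comp)) {
    # complement-frame element [s', e'] occupies reference positions
    # L - e' + 1 .. L - s' + 1 (circularly)
    start_ref <- canonical_position(L - comp$end_linear + 1, L)
    comp$start <- start_ref
    comp$end <- canonical_position(start_ref + comp$span - 1, L)
    comp$end_linear <- start_ref + comp$span - 1
    comp$midpoint <- canonical_position(start_ref + (comp$span - 1) / 2, L)
  }
  comp <- resolve_qfp_overlaps(comp, L)
  if (nrow(comp)) comp$strand <- "complement"

  res <- dplyr::bind_rows(ref, comp)
  n_g <- sum(chars == "G"); n_c <- sum(chars == "C")
  ref_heavy <- n_g >= n_c
  tier <- paste0(min_run, "G")
  if (nrow(res)) {
    res$strand_label <- ifelse(
      (res$strand == "reference") == ref_heavy, "heavy", "light")
    res$tier <- tier
    res <- dplyr::select(
      res, "start", "end", "span", "strand", "strand_label",
      "tier", "tetrads", "midpoint", "n_merged")
    res <- dplyr::arrange(res, .data$start, .data$strand)
  } else {
    res <- tibble(start = numeric(), end = numeric(), span = numeric(),
                  strand = character(), strand_label = character(),
                  tier = character(), tetrads = integer(),
                  midpoint = numeric(), n_merged = integer())
  }
  new_motif_set(res, name = paste0(tier, "_intrastrand"),
                genome_id = genome$id, L = L)
}

#' Scan for duplex-derived interstrand (ddi) QFP elements
#'
#' Like the intrastrand scan, but the four G-runs may independently lie on
#' either strand of the duplex within one analysis window: in reference
#' coordinates a complementary-strand G-run is a C-run.  At least one run
#' from each strand is required (windows whose runs are all on one strand
#' belong to the intrastrand sets), and candidates whose interval overlaps
#' any resolved intrastrand element are removed before overlap resolution.
#'
#' @param genome A [circular_genome()].
#' @param min_run Minimum run length (2 or 3).
#' @param intrastrand The resolved intrastrand motif set for the same
#'   `min_run`, from [find_intrastrand_qfp()].
#' @param max_span,min_loop See [enumerate_qfp_candidates()].
#' @return A [new_motif_set()] tibble (strand `"interstrand"`).
#' @export
find_ddi_qfp <- function(genome, min_run, intrastrand,
                         max_span = 33L, min_loop = 1L) {
  stopifnot(inherits(genome, "circular_genome"), min_run %in% c(2L, 3L))
  L <- genome$length
  chars <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
  cand <- .scan_qfp_circular(chars, L, min_run, max_span, min_loop,
                             flavors = c("G", "C"), require_mixed = TRUE)
  if (nrow(cand) && nrow(intrastrand)) {
    drop <- vapply(seq_len(nrow(cand)), function(i) {
      any(.circ_overlap(cand$start[i], cand$span[i],
                        intrastrand$start, intrastrand$span, L))
    }, logical(1))
    cand <- cand[!drop, , drop = FALSE]
  }
  res <- resolve_qfp_overlaps(cand, L)
  tier <- paste0(min_run, "G")
  if (nrow(res)) {
    res$strand <- "interstrand"
    res$tier <- tier
    res <- dplyr::select(res, "start", "end", "span", "strand",
                         "tier", "tetrads", "midpoint", "n_merged")
    res <- dplyr::arrange(res, .data$start)
  } else {
    res <- tibble(start = numeric(), end = numeric(), span = numeric(),
                  strand = character(), tier = character(),
                  tetrads = integer(), midpoint = numeric(),
                  n_merged = integer())
  }
  new_motif_set(res, name = paste0(tier, "_ddi"), genome_id = genome$id, L = L)
}
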