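# Circular nearest-neighbour distance from each x to the point set `set`.
# Exact for half-integer set members; O((|x| + |set|) log |set|).
.nn_dist <- function(x, set, L) {
  if (length(set) == 0L) abort("Point set is empty.")
  ms <- sort(canonical_position(set, L))
  M <- length(ms)
  xs <- canonical_position(x, L)
  idx <- findInterval(xs, ms)
  prev <- ifelse(idx == 0L, ms[M] - L, ms[pmax(idx, 1L)])
  nxt <- ifelse(idx == M, ms[1L] + L, ms[pmin(idx + 1L, M)])
  pmin(xs - prev, nxt - xs)
}

#' Minimal-distance profile of a motif set
#'
#' For every integer genome position, the circular minimal distance to the
#' nearest motif midpoint.  Half-integer midpoints are handled exactly, so
#' profile values are multiples of 0.5.
#'
#' @param motif_midpoints Numeric vector of midpoints (or a motif set /
#'   data frame accepted by [motif_midpoints()]).
#' @param L Genome length.
#' @return Tibble with columns `position` (1..L) and `distance`.
#' @export
min_distance_profile <- function(motif_midpoints, L) {
  mids <- motif_midpoints(motif_midpoints)
  if (length(mids) == 0L) abort("Motif set is empty.")
  tibble(position = seq_len(L), distance = .nn_dist(seq_len(L), mids, L))
}

#' Mean minimal distance from one point set to another
#'
#' The arithmetic mean, over members of `from_set`, of the circular minimal
#' distance to the nearest member of `to_set`.  Deliberately asymmetric in
#' its arguments: the mean distance from breakpoints to motifs is not the
#' mean distance from motifs to breakpoints.
#'
#' @param from_set,to_set Numeric position vectors (or motif sets).
#' @param L Genome length.
#' @return Mean minimal distance in nucleotides.
#' @examples
#' mean_min_distance(c(1, 11), 1, L = 20)  # (0 + 10) / 2
#' mean_min_distance(1, c(1, 11), L = 20)  # 0
#' @export
mean_min_distance <- function(from_set, to_set, L) {
  fr <- motif_midpoints(from_set)
  to <- motif_midpoints(to_set)
  if (length(fr) == 0L || length(to) == 0L) abort("Point sets must be nonempty.")
  mean(.nn_dist(fr, to, L))
}

#' Chance probability of proximity under the rotational null
#'
#' The fraction of integer genome positions whose minimal distance to the
#' motif set is at most `D`: for a single breakpoint placed at every
#' possible position relative to the motif set, the portion of distances
#' `<= D`.  This is the per-trial success probability used by the binomial
#' enrichment test.
#'
#' @param to_set Motif midpoints (numeric vector or motif set).
#' @param D Distance threshold in nucleotides (>= 0).
#' @param L Genome length.
#' @return A probability in `[0, 1]`.
#' @export
chance_proximity_probability <- function(to_set, D, L) {
  stopifnot(D >= 0)
  mids <- motif_midpoints(to_set)
  if (length(mids) == 0L) abort("Motif set is empty.")
  mean(.nn_dist(seq_len(L), mids, L) <= D)
}

# Sum over `from` points of the nearest-neighbour distance to `to` rotated
# by every r in 0..L-1: returns numeric vector indexed by r + 1.  Distances
# to a set rotated by +r equal distances from the point shifted by -r, so
# each from-point contributes a circular shift of a precomputed profile.
# Grids are computed per distinct fractional part of `from`, keeping
# half-integer motif midpoints exact.
.rotation_distance_sums <- function(from, to, L) {
  fr <- canonical_position(from, L)
  frac <- round(fr - floor(fr), 9)
  total <- numeric(L)
  for (f in unique(frac)) {
    prof <- .nn_dist(seq_len(L) + f, to, L)
    for (p in floor(fr[frac == f])) {
      idx <- ((p - 1 - (0:(L - 1))) %% L) + 1
      total <- total + prof[idx]
    }
  }
  total
}
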