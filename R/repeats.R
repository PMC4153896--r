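#' Class transform for repeat scanning
#'
#' Transforms a k-mer according to a repeat class: `direct` leaves it
#' unchanged (ATC-ATC), `inverted` reverses it (ATC-CTA), `complementary`
#' complements base-wise without reversal (ATC-TAG), and
#' `inverted_complementary` reverse-complements it (ATC-GAT).
#'
#' @param words Character vector of k-mers.
#' @param repeat_class One of `"direct"`, `"inverted"`, `"complementary"`,
#'   `"inverted_complementary"`.
#' @return Character vector of transformed words.
#' @export
repeat_class_transform <- function(words,
    repeat_class = c("direct", "inverted", "complementary",
                     "inverted_complementary")) {
  repeat_class <- match.arg(repeat_class)
  switch(repeat_class,
    direct = words,
    inverted = stringi::stri_reverse(words),
    complementary = complement_sequence(words),
    inverted_complementary = reverse_complement(words)
  )
}

#' Find fixed-length repeat units on a circular genome
#'
#' A window start `i` qualifies if the class transform of the k-mer starting
#' at `i` occurs (exactly) at some other start `j != i` on the reference
#' strand; k-mers are circular.  Maximal runs of consecutive qualifying
#' starts are merged into one repeat unit whose interval runs from the first
#' qualifying start to the last qualifying start plus `k - 1`; the unit
#' midpoint is the interval midpoint.  Palindromic self-matches (possible in
#' the inverted and inverted-complementary classes) qualify only through a
#' partner start different from the window's own start.  `N` bases never
#' match in repeat comparison.
#'
#' @param genome A [circular_genome()].
#' @param k Word size in nucleotides (the published analyses use 11).
#' @param repeat_class See [repeat_class_transform()].
#' @return A [new_motif_set()] tibble with columns `unit`, `start`, `end`,
#'   `unit_length`, `k`, `repeat_class`, `midpoint` and a list column
#'   `partner_starts` (window starts elsewhere in the genome matching a
#'   window of the unit).
#' @export
find_repeats <- function(genome, k = 11L,
    repeat_class = c("direct", "inverted", "complementary",
                     "inverted_complementary")) {
  stopifnot(inherits(genome, "circular_genome"))
  repeat_class <- match.arg(repeat_class)
  L <- genome$length
  if (k < 1 || k > L) abort("`k` must satisfy 1 <= k <= genome length.")
  doubled <- paste0(genome$sequence,
                    substr(genome$sequence, 1L, min(k - 1L, L)))
  kmers <- substring(doubled, seq_len(L), seq_len(L) + k - 1L)
  has_n <- stringi::stri_detect_fixed(kmers, "N")
  twords <- repeat_class_transform(kmers, repeat_class)

  counts <- table(kmers[!has_n])
  n_t <- as.integer(counts[twords]); n_t[is.na(n_t)] <- 0L
  qualifying <- !has_n &
    ifelse(twords == kmers, n_t >= 2L, n_t >= 1L)

  empty <- new_motif_set(
    tibble(unit = integer(), start = numeric(), end = numeric(),
           unit_length = numeric(), k = integer(), repeat_class = character(),
           midpoint = numeric(), partner_starts = list()),
    name = paste0(repeat_class, "_repeats_k", k),
    genome_id = genome$id, L = L)
  if (!any(qualifying)) return(empty)

  if (all(qualifying)) {
    warn("Every window qualifies (degenerate repetitive genome); returning a single unit covering the genome.")
    blocks <- tibble(first = 1L, last = L)
  } else {
    r <- rle(qualifying)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    blocks <- tibble(first = starts[r$values], last = ends[r$values])
    # merge a block wrapping the origin
    if (nrow(blocks) > 1L && blocks$first[1] == 1L && blocks$last[nrow(blocks)] == L) {
      blocks$first[1] <- blocks$first[nrow(blocks)] - L
      blocks <- blocks[-nrow(blocks), , drop = FALSE]
    }
  }

  index <- split(seq_len(L), kmers)
  partner_of <- function(win_starts) {
    wins <- canonical_position(win_starts, L)
    ps <- lapply(wins, function(w) setdiff(index[[twords[w]]], w))
    sort(unique(unlist(ps, use.names = FALSE)))
  }

  units <- purrr::pmap(blocks, function(first, last) {
    wins <- first:last
    len <- min((last + k - 1L) - first + 1L, L)
    tibble(
      start = canonical_position(first, L),
      end = canonical_position(last + k - 1L, L),
      unit_length = len,
      midpoint = canonical_position(first + (len - 1) / 2, L),
      partner_starts = list(partner_of(wins))
    )
  })
  res <- dplyr::bind_rows(units)
  res <- dplyr::mutate(res,
    unit = dplyr::row_number(), k = as.integer(k),
    repeat_class = repeat_class, .before = 1L)
  res <- dplyr::relocate(res, "midpoint", .after = "repeat_class")
  new_motif_set(res, name = paste0(repeat_class, "_repeats_k", k),
                genome_id = genome$id, L = L)
}

#' Enumerate repeat unit pairs
#'
#' All unordered pairs of distinct repeat units (one class) that share a
#' class-transformed word match, oriented so that `unit5` precedes `unit3`
#' in the canonical linearisation of the circle from position 1 (by
#' midpoint).  A deletion mediated by the pair is expected to place its 5'
#' breakpoint near `unit5` and its 3' breakpoint near `unit3`.
#'
#' @param units A repeat motif set from [find_repeats()].
#' @return Tibble with columns `unit5`, `unit3`, `mid5`, `mid3`, `start5`,
#'   `start3` (one row per pair).
#' @export
enumerate_repeat_pairs <- function(units) {
  L <- attr(units, "L")
  units <- as_tibble(units)
  empty <- tibble(unit5 = integer(), unit3 = integer(),
                  mid5 = numeric(), mid3 = numeric(),
                  start5 = numeric(), start3 = numeric())
  if (nrow(units) == 0L) return(empty)
  if (!all(c("unit", "start", "end", "midpoint", "partner_starts") %in% names(units))) {
    abort("`units` must come from find_repeats().")
  }
  if (is.null(L)) abort("`units` must carry a genome length attribute (use find_repeats()).")
  # map every window start inside a unit to its unit id
  win_unit <- integer(0)
  for (i in seq_len(nrow(units))) {
    s <- units$start[i]
    len_windows <- units$unit_length[i] - units$k[i] + 1
    wins <- canonical_position(s + seq_len(len_windows) - 1, L)
    win_unit[as.character(wins)] <- units$unit[i]
  }
  links <- purrr::map(seq_len(nrow(units)), function(i) {
    ps <- units$partner_starts[[i]]
    partner_units <- unique(win_unit[as.character(ps)])
    partner_units <- partner_units[!is.na(partner_units) & partner_units != units$unit[i]]
    if (!length(partner_units)) return(NULL)
    tibble(a = units$unit[i], b = partner_units)
  })
  links <- dplyr::bind_rows(links)
  if (nrow(links) == 0L) return(empty)
  links <- dplyr::distinct(tibble(
    u1 = pmin(links$a, links$b), u2 = pmax(links$a, links$b)))
  mid <- setNames(units$midpoint, units$unit)
  st <- setNames(units$start, units$unit)
  first5 <- mid[as.character(links$u1)] <= mid[as.character(links$u2)]
  u5 <- ifelse(first5, links$u1, links$u2)
  u3 <- ifelse(first5, links$u2, links$u1)
  tibble(
    unit5 = u5, unit3 = u3,
    mid5 = unname(mid[as.character(u5)]), mid3 = unname(mid[as.character(u3)]),
    start5 = unname(st[as.character(u5)]), start3 = unname(st[as.character(u3)])
  )
}
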