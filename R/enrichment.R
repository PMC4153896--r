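#' Binomial enrichment p-value
#'
#' For `K` observed successes among `N` trials with chance probability `P`,
#' two conventions are provided.  `at_least_K` (the default) is the usual
#' upper-tail probability `P(X >= K) = 1 - F(K - 1; N, P)`.  `paper_literal`
#' is the form `1 - F(K; N, P)` used verbatim in some published analyses; it
#' equals `P(X > K)` and therefore returns 0 whenever `K = N`, even under
#' the null, which is why `at_least_K` is the default.  Both are reported in
#' the curve and both-ends outputs.
#'
#' @param K Observed count (vectorised).
#' @param N Number of trials.
#' @param P Chance probability per trial.
#' @param convention `"at_least_K"` or `"paper_literal"`.
#' @return Numeric vector of p-values.
#' @export
enrichment_pvalue <- function(K, N, P,
                              convention = c("at_least_K", "paper_literal")) {
  convention <- match.arg(convention)
  stopifnot(all(K >= 0), all(K <= N), all(P >= 0), all(P <= 1))
  switch(convention,
    at_least_K = pbinom(K - 1, N, P, lower.tail = FALSE),
    paper_literal = pbinom(K, N, P, lower.tail = FALSE)
  )
}

#' Per-distance enrichment curve with binomial p-values
#'
#' For each distance threshold `D = 0 ... d_max`, counts the members of
#' `from_set` whose circular minimal distance to `to_set` is `<= D` (`K`),
#' computes the rotational chance probability `P` of such proximity (see
#' [chance_proximity_probability()]), the expected count `N * P`, and
#' binomial p-values under both conventions.  Also reports the overall mean
#' minimal distance of the actual configuration and of the rotational
#' controls (the cumulative-distribution figure legend quantities).
#'
#' @param from_set,to_set Position vectors or motif sets.
#' @param L Genome length.
#' @param d_max Largest distance threshold (nt).
#' @param direction Label stored with the curve.
#' @return An `enrichment_curve` tibble with columns `D`, `K`, `N`, `P`,
#'   `expected`, `p_value` (`at_least_K`), `p_value_literal`; attributes
#'   `overall_actual_mean`, `overall_control_mean`, `direction`, `L`.
#' @export
enrichment_curve <- function(from_set, to_set, L, d_max = 50,
                             direction = "from_breakpoints_to_motifs") {
  fr <- motif_midpoints(from_set)
  to <- motif_midpoints(to_set)
  if (length(fr) == 0L || length(to) == 0L) abort("Point sets must be nonempty.")
  d_act <- .nn_dist(fr, to, L)
  prof <- .nn_dist(seq_len(L), to, L)
  N <- length(fr)
  D <- 0:d_max
  K <- vapply(D, function(d) sum(d_act <= d), numeric(1))
  P <- vapply(D, function(d) mean(prof <= d), numeric(1))
  points <- tibble(
    D = D, K = as.integer(K), N = N, P = P, expected = N * P,
    p_value = enrichment_pvalue(K, N, P, "at_least_K"),
    p_value_literal = enrichment_pvalue(K, N, P, "paper_literal")
  )
  sums <- .rotation_distance_sums(fr, to, L)
  structure(
    points,
    direction = direction, L = L,
    overall_actual_mean = sums[1L] / N,
    overall_control_mean = sum(sums[-1L]) / ((L - 1) * N),
    class = c("enrichment_curve", class(tibble()))
  )
}

#' @export
print.enrichment_curve <- function(x, ...) {
  cat(sprintf(
    "<enrichment_curve> %s (L = %s): actual mean %.1f nt, control mean %.1f nt\n",
    attr(x, "direction"), format(attr(x, "L"), big.mark = ","),
    attr(x, "overall_actual_mean"), attr(x, "overall_control_mean")
  ))
  NextMethod()
}

#' @rdname enrichment_curve
#' @param x,object An `enrichment_curve`.
#' @param ... Unused.
#' @export
tidy.enrichment_curve <- function(x, ...) as_tibble(x)

#' @rdname enrichment_curve
#' @export
glance.enrichment_curve <- function(x, ...) {
  tibble(
    direction = attr(x, "direction"),
    overall_actual_mean = attr(x, "overall_actual_mean"),
    overall_control_mean = attr(x, "overall_control_mean"),
    N = x$N[1],
    L = attr(x, "L"),
    d_max = max(x$D)
  )
}

#' @rdname enrichment_curve
#' @export
autoplot.enrichment_curve <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$D)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$K, linetype = "observed")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$expected, linetype = "control")) +
    ggplot2::scale_linetype_manual(NULL, values = c(observed = "solid", control = "dashed")) +
    ggplot2::labs(
      x = "minimal distance threshold D (nt)",
      y = "count with distance ≤ D",
      title = sprintf("Cumulative proximity (%s): e = %.1f, c = %.1f nt",
                      attr(object, "direction"),
                      attr(object, "overall_actual_mean"),
                      attr(object, "overall_control_mean"))
    ) +
    ggplot2::theme_minimal()
}

.new_both_ends_result <- function(D, n_close, N, P, mode, L, control_counts) {
  structure(
    list(
      D = D, n_close = n_close, N = N, P = P,
      p_value = enrichment_pvalue(n_close, N, P, "at_least_K"),
      p_value_literal = enrichment_pvalue(n_close, N, P, "paper_literal"),
      mode = mode, L = L, control_counts = control_counts
    ),
    class = "both_ends_result"
  )
}

#' Both-ends deletion proximity test (single motif set)
#'
#' A deletion qualifies when the circular minimal distances from *both* its
#' 5' and 3' breakpoints to the nearest motif midpoint are `<= D`.  The
#' chance probability per deletion is obtained exhaustively by rotating the
#' motif set through every nonzero 1-nt offset:
#' `P = sum(c_r) / ((L - 1) * N)` where `c_r` is the qualifying count under
#' rotation `r`.  The p-value is binomial as in [enrichment_pvalue()].
#'
#' @param deletions Deletion tibble with `bp5`, `bp3` columns.
#' @param motif_set Motif midpoints (numeric vector or motif set).
#' @param L Genome length.
#' @param D Both-ends distance threshold in nucleotides.
#' @return A `both_ends_result` (mode `"single_motif_set"`) with fields `D`,
#'   `n_close`, `N`, `P`, `p_value`, `p_value_literal`, `control_counts`.
#' @export
both_ends_enrichment <- function(deletions, motif_set, L, D = 10) {
  mids <- motif_midpoints(motif_set)
  if (nrow(deletions) == 0L || length(mids) == 0L) abort("Inputs must be nonempty.")
  q <- .nn_dist(seq_len(L), mids, L) <= D
  rr <- 0:(L - 1)
  counts <- integer(L)
  for (i in seq_len(nrow(deletions))) {
    i5 <- ((deletions$bp5[i] - 1 - rr) %% L) + 1
    i3 <- ((deletions$bp3[i] - 1 - rr) %% L) + 1
    counts <- counts + (q[i5] & q[i3])
  }
  N <- nrow(deletions)
  .new_both_ends_result(
    D = D, n_close = counts[1L], N = N,
    P = sum(counts[-1L]) / ((L - 1) * N),
    mode = "single_motif_set", L = L, control_counts = counts[-1L]
  )
}

# integer rotations r with circular_distance(bp, u + r) <= D, as canonical
# offsets in 0..L-1 (u may be half-integer)
.arc_rotations <- function(bp, u, D, L) {
  c0 <- bp - u
  lo <- ceiling(c0 - D)
  hi <- floor(c0 + D)
  if (hi < lo) return(integer(0))
  if (hi - lo + 1 >= L) return(0:(L - 1))
  (lo:hi) %% L
}

#' Both-ends deletion proximity test for repeat pairs
#'
#' A deletion qualifies when *some single repeat pair* has its 5' unit
#' midpoint within `D` of the deletion's 5' breakpoint and its 3' unit
#' midpoint within `D` of the same deletion's 3' breakpoint (ends are
#' matched in order).  Controls rotate the repeat unit set rigidly, pairs
#' preserved, through every nonzero 1-nt offset.  This is stricter than
#' [both_ends_enrichment()] on the pooled unit midpoints, which lets the two
#' ends match different pairs.
#'
#' @param deletions Deletion tibble with `bp5`, `bp3` columns.
#' @param repeat_pairs Pair table from [enumerate_repeat_pairs()] (columns
#'   `mid5`, `mid3`).
#' @param L Genome length.
#' @param D Both-ends distance threshold in nucleotides.
#' @return A `both_ends_result` (mode `"paired_repeats"`).
#' @export
paired_repeat_both_ends <- function(deletions, repeat_pairs, L, D = 10) {
  if (nrow(deletions) == 0L || nrow(repeat_pairs) == 0L) abort("Inputs must be nonempty.")
  if (!all(c("mid5", "mid3") %in% names(repeat_pairs))) {
    abort("`repeat_pairs` must have mid5 and mid3 columns (see enumerate_repeat_pairs()).")
  }
  counts <- integer(L)
  for (i in seq_len(nrow(deletions))) {
    qual <- logical(L)
    for (j in seq_len(nrow(repeat_pairs))) {
      r5 <- .arc_rotations(deletions$bp5[i], repeat_pairs$mid5[j], D, L)
      r3 <- .arc_rotations(deletions$bp3[i], repeat_pairs$mid3[j], D, L)
      common <- intersect(r5, r3)
      if (length(common)) qual[common + 1L] <- TRUE
    }
    counts <- counts + qual
  }
  N <- nrow(deletions)
  .new_both_ends_result(
    D = D, n_close = counts[1L], N = N,
    P = sum(counts[-1L]) / ((L - 1) * N),
    mode = "paired_repeats", L = L, control_counts = counts[-1L]
  )
}

#' @export
print.both_ends_result <- function(x, ...) {
  cat("<both_ends_result>", x$mode, "\n")
  cat(sprintf("  D = %g nt: %d of %d deletions close at both ends\n",
              x$D, x$n_close, x$N))
  cat(sprintf("  chance P = %.4g, expected = %.2f\n", x$P, x$P * x$N))
  cat(sprintf("  p (X >= K) = %.3g; p (literal 1 - F(K)) = %.3g\n",
              x$p_value, x$p_value_literal))
  invisible(x)
}

#' @rdname both_ends_enrichment
#' @param x A `both_ends_result`.
#' @param ... Unused.
#' @export
tidy.both_ends_result <- function(x, ...) {
  tibble(
    mode = x$mode, D = x$D, n_close = x$n_close, N = x$N, P = x$P,
    expected = x$P * x$N,
    p_value = x$p_value, p_value_literal = x$p_value_literal, L = x$L
  )
}

#' @rdname both_ends_enrichment
#' @export
glance.both_ends_result <- function(x, ...) tidy.both_ends_result(x)
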