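# Independent brute-force oracles used to validate the fast implementations.
# These deliberately avoid the package's internal algorithms: distances are
# minima over explicit clockwise/counterclockwise walks, rotational nulls
# are explicit loops over every rotation, and motif enumeration is an
# exhaustive search over tuples of tract intervals.

oracle_circ_dist <- function(a, b, L) {
  cw <- (b - a) %% L
  ccw <- (a - b) %% L
  pmin(cw, ccw)
}

oracle_nn_dist <- function(x, set, L) {
  vapply(x, function(xi) min(oracle_circ_dist(xi, set, L)), numeric(1))
}

oracle_mean_min <- function(from, to, L) {
  mean(oracle_nn_dist(from, to, L))
}

# distance matrix |from x to| under rotation r of `to`
.oracle_rot_mean <- function(from, to, L, r) {
  to_r <- ((to - 1 + r) %% L) + 1
  d <- outer(from, to_r, function(a, b) oracle_circ_dist(a, b, L))
  mean(apply(d, 1, min))
}

oracle_mda_p <- function(from, to, L) {
  actual <- .oracle_rot_mean(from, to, L, 0)
  controls <- vapply(1:(L - 1), function(r) .oracle_rot_mean(from, to, L, r), numeric(1))
  list(actual = actual, controls = controls,
       p = mean(controls <= actual + 1e-12))
}

oracle_profile <- function(set, L) {
  oracle_nn_dist(seq_len(L), set, L)
}

oracle_chance_P <- function(set, D, L) {
  mean(oracle_profile(set, L) <= D)
}

oracle_binom_tail <- function(K, N, P) {
  # direct summation of binomial mass for X >= K
  if (K > N) return(0)
  sum(choose(N, K:N) * P^(K:N) * (1 - P)^(N - (K:N)))
}

oracle_both_ends <- function(deletions, mids, L, D) {
  count_at <- function(r) {
    m_r <- ((mids - 1 + r) %% L) + 1
    d5 <- oracle_nn_dist(deletions$bp5, m_r, L)
    d3 <- oracle_nn_dist(deletions$bp3, m_r, L)
    sum(d5 <= D & d3 <= D)
  }
  counts <- vapply(0:(L - 1), count_at, numeric(1))
  list(n_close = counts[1],
       P = sum(counts[-1]) / ((L - 1) * nrow(deletions)),
       counts = counts)
}

oracle_paired_both_ends <- function(deletions, pairs, L, D) {
  count_at <- function(r) {
    m5 <- ((pairs$mid5 - 1 + r) %% L) + 1
    m3 <- ((pairs$mid3 - 1 + r) %% L) + 1
    qual <- vapply(seq_len(nrow(deletions)), function(i) {
      any(oracle_circ_dist(deletions$bp5[i], m5, L) <= D &
            oracle_circ_dist(deletions$bp3[i], m3, L) <= D)
    }, logical(1))
    sum(qual)
  }
  counts <- vapply(0:(L - 1), count_at, numeric(1))
  list(n_close = counts[1],
       P = sum(counts[-1]) / ((L - 1) * nrow(deletions)),
       counts = counts)
}

# Exhaustive QFP enumeration: every 4-tuple of disjoint all-G intervals with
# per-tract length >= min_run, inter-tract gaps >= min_loop and total span
# <= max_span.  Returns one row per (start-of-first, end-of-last) key with
# the best (max over tuples of min tract length) tetrad count.
oracle_qfp_keys <- function(chars, min_run, max_span = 33, min_loop = 1,
                            circular = FALSE) {
  n0 <- length(chars)
  if (circular) {
    eff <- min(max_span, n0)
    chars <- c(chars, chars[seq_len(eff - 1)])
    start_limit <- n0
  } else {
    start_limit <- n0
  }
  n <- length(chars)
  # all sub-tract intervals
  tr <- list()
  for (a in seq_len(n)) {
    b <- a
    while (b <= n && chars[b] == "G") {
      if (b - a + 1 >= min_run) tr[[length(tr) + 1]] <- c(a, b)
      b <- b + 1
    }
  }
  if (length(tr) < 4) {
    return(data.frame(start = numeric(0), end = numeric(0), tetrads = numeric(0)))
  }
  tr <- do.call(rbind, tr)
  tr <- tr[order(tr[, 1], tr[, 2]), , drop = FALSE]
  keys <- new.env()
  # plain ordered 4-tuple enumeration; the span bound only prunes tuples
  # that would fail the span test anyway
  for (i1 in which(tr[, 1] <= start_limit)) {
    a1 <- tr[i1, 1]; b1 <- tr[i1, 2]
    lim <- a1 + max_span - 1
    if (b1 > lim) next
    for (i2 in which(tr[, 1] >= b1 + min_loop + 1 & tr[, 2] <= lim)) {
      b2 <- tr[i2, 2]
      for (i3 in which(tr[, 1] >= b2 + min_loop + 1 & tr[, 2] <= lim)) {
        b3 <- tr[i3, 2]
        for (i4 in which(tr[, 1] >= b3 + min_loop + 1 & tr[, 2] <= lim)) {
          b4 <- tr[i4, 2]
          tet <- min(b1 - a1 + 1, b2 - tr[i2, 1] + 1,
                     b3 - tr[i3, 1] + 1, b4 - tr[i4, 1] + 1)
          key <- paste(a1, b4)
          old <- keys[[key]]
          if (is.null(old) || tet > old) keys[[key]] <- tet
        }
      }
    }
  }
  ks <- ls(keys)
  if (!length(ks)) {
    return(data.frame(start = numeric(0), end = numeric(0), tetrads = numeric(0)))
  }
  parts <- do.call(rbind, strsplit(ks, " "))
  out <- data.frame(start = as.numeric(parts[, 1]), end = as.numeric(parts[, 2]),
                    tetrads = vapply(ks, function(k) keys[[k]], numeric(1)))
  out[order(out$start, out$end), ]
}

# All-pairs brute-force qualifying window starts for repeat scanning.
oracle_repeat_starts <- function(genome, k, repeat_class) {
  L <- mitoqfp::genome_length(genome)
  doubled <- paste0(mitoqfp::genome_sequence(genome),
                    substr(mitoqfp::genome_sequence(genome), 1, k - 1))
  kmers <- substring(doubled, 1:L, 1:L + k - 1)
  tw <- mitoqfp::repeat_class_transform(kmers, repeat_class)
  has_n <- grepl("N", kmers, fixed = TRUE)
  which(vapply(seq_len(L), function(i) {
    if (has_n[i]) return(FALSE)
    any(kmers == tw[i] & seq_len(L) != i & !has_n)
  }, logical(1)))
}

# deterministic random DNA string
random_dna <- function(n, seed, prob = c(0.25, 0.25, 0.25, 0.25)) {
  withr::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
          collapse = ""))
}
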