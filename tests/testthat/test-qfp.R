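# The biophysically validated oligo panel: three mitochondrial 2G QFP
# sequences and matched controls with guanines mutated to ablate the motif.
oligo_panel <- list(
  A = "GGATGGGGTGGGGAGG", Ac = "AGATGGAGTGGAGAGG",
  B = "GGGGGATGCGGGGG",   Bc = "AGGAGATGCAGGAG",
  C = "GGAGGGTGGATGG",    Cc = "AGAGGGTAGATGG"
)

test_that("maximal G-tracts match a sliding-window oracle", {
  expect_equal(nrow(find_g_tracts("AAAA", 2)), 0)
  tr <- find_g_tracts(oligo_panel$A, 2)
  expect_equal(tr$start, c(1, 5, 10, 15))
  expect_equal(tr$end, c(2, 8, 13, 16))
  for (seed in 1:6) {
    s <- random_dna(300, seed, prob = c(0.2, 0.2, 0.4, 0.2))
    chars <- strsplit(s, "")[[1]]
    got <- find_g_tracts(s, 2)
    # oracle: starts where GG begins a maximal run
    is_g <- chars == "G"
    starts <- which(is_g & !c(FALSE, head(is_g, -1)))
    runs <- vapply(starts, function(a) {
      b <- a
      while (b < 300 && is_g[b + 1]) b <- b + 1
      b
    }, numeric(1))
    keep <- runs - starts + 1 >= 2
    expect_equal(got$start, starts[keep])
    expect_equal(got$end, unname(runs[keep]))
  }
})

test_that("candidate enumeration handles G-loops, tract inventories and tiers", {
  # a 5-G run donates two tracts split by a 1-nt G loop
  b <- enumerate_qfp_candidates(oligo_panel$B, 2)
  expect_equal(nrow(b), 1)
  expect_equal(c(b$start, b$end, b$tetrads), c(1, 14, 2))
  # only three tracts of >= 2 G: no candidate
  expect_equal(nrow(enumerate_qfp_candidates(oligo_panel$Ac, 2)), 0)
  # only two tracts of >= 3 G: no 3G candidate
  expect_equal(nrow(enumerate_qfp_candidates(oligo_panel$A, 3)), 0)
  a <- enumerate_qfp_candidates(oligo_panel$A, 2)
  expect_equal(c(a$start, a$end, a$midpoint), c(1, 16, 8.5))
})

test_that("every oligo with QFP is detected and every mutated control is not", {
  for (nm in c("A", "B", "C")) {
    expect_gte(nrow(enumerate_qfp_candidates(oligo_panel[[nm]], 2)), 1)
  }
  for (nm in c("Ac", "Bc", "Cc")) {
    expect_equal(nrow(enumerate_qfp_candidates(oligo_panel[[nm]], 2)), 0)
  }
})

test_that("emitted candidates re-validate their structural constraints", {
  for (seed in 1:10) {
    s <- random_dna(200, seed, prob = c(0.15, 0.15, 0.55, 0.15))
    cand <- enumerate_qfp_candidates(s, 2)
    if (nrow(cand) == 0) next
    expect_true(all(cand$span <= 33))
    expect_true(all(cand$tetrads >= 2))
    expect_equal(cand$midpoint, (cand$start + cand$end) / 2)
    chars <- strsplit(s, "")[[1]]
    # start and end of every candidate are G (tract boundaries)
    expect_true(all(chars[cand$start] == "G"))
    expect_true(all(chars[cand$end] == "G"))
    # 3G keys are a subset of 2G keys
    k3 <- enumerate_qfp_candidates(s, 3)
    if (nrow(k3)) {
      expect_true(all(paste(k3$start, k3$end) %in% paste(cand$start, cand$end)))
    }
  }
})

test_that("overlap resolution applies shorter-span, tetrad and median rules", {
  one <- tibble::tibble(start = 5, end = 20, span = 16, tetrads = 2, midpoint = 12.5)
  expect_equal(resolve_qfp_overlaps(one, 100)$start, 5)

  two <- tibble::tibble(start = c(5, 3), end = c(18, 22), span = c(14, 20),
                        tetrads = c(2, 3), midpoint = c(11.5, 12.5))
  kept <- resolve_qfp_overlaps(two, 100)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$span, 14)  # shorter span wins over higher tetrads

  # equal span, higher tetrads wins
  two2 <- tibble::tibble(start = c(5, 8), end = c(18, 21), span = c(14, 14),
                         tetrads = c(2, 3), midpoint = c(11.5, 14.5))
  expect_equal(resolve_qfp_overlaps(two2, 100)$tetrads, 3)

  # three tied mutually overlapping candidates collapse to the median midpoint
  tied <- tibble::tibble(start = c(6, 8, 9), end = c(14, 16, 17),
                         span = 9, tetrads = 2, midpoint = c(10, 12, 13))
  merged <- resolve_qfp_overlaps(tied, 100)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$midpoint, 12)
  expect_equal(merged$n_merged, 3L)

  # output intervals are pairwise non-overlapping on random candidate soups
  for (seed in 1:5) {
    s <- random_dna(400, seed, prob = c(0.1, 0.1, 0.7, 0.1))
    g <- circular_genome(s)
    res <- find_intrastrand_qfp(g, 2)
    if (nrow(res) < 2) next
    for (str in unique(res$strand)) {
      el <- res[res$strand == str, ]
      if (nrow(el) < 2) next
      for (i in seq_len(nrow(el) - 1)) {
        ov <- mitoqfp:::.circ_overlap(el$start[i], el$span[i],
                                      el$start[-i], el$span[-i], 400)
        expect_false(any(ov))
      }
    }
  }
})

test_that("planted oligos are recovered on the circular genome, controls are not", {
  bg <- paste(rep("A", 200), collapse = "")
  g <- plant_sequence(circular_genome(bg, "bg"), oligo_panel$A, 50)
  ms <- find_intrastrand_qfp(g, 2)
  expect_equal(nrow(ms), 1)
  expect_equal(ms$midpoint, 57.5)
  expect_equal(ms$strand, "reference")
  expect_equal(nrow(find_intrastrand_qfp(g, 3)), 0)

  gc <- plant_sequence(circular_genome(bg, "bg"), oligo_panel$Ac, 50)
  expect_equal(nrow(find_intrastrand_qfp(gc, 2)), 0)

  # complement-strand detection: plant the reverse complement
  gr <- plant_sequence(circular_genome(bg, "bg"),
                       reverse_complement(oligo_panel$B), 80)
  msr <- find_intrastrand_qfp(gr, 2)
  expect_equal(nrow(msr), 1)
  expect_equal(msr$strand, "complement")
  # element occupies reference positions 80..93, midpoint 86.5
  expect_equal(msr$midpoint, 86.5)
})

test_that("motifs wrapping the origin are found and scans are rotation invariant", {
  bg <- paste(rep("A", 120), collapse = "")
  g <- plant_sequence(circular_genome(bg, "bg"), oligo_panel$A, 115)
  ms <- find_intrastrand_qfp(g, 2)
  expect_equal(nrow(ms), 1)
  expect_equal(ms$start, 115)
  expect_equal(ms$midpoint, canonical_position(115 + 7.5, 120))

  # rotating the genome rotates the motif coordinates and nothing else
  s <- random_dna(300, 77, prob = c(0.15, 0.15, 0.55, 0.15))
  g1 <- circular_genome(s)
  for (r in c(13, 150)) {
    s2 <- paste0(substr(s, 300 - r + 1, 300), substr(s, 1, 300 - r))
    g2 <- circular_genome(s2)
    m1 <- find_intrastrand_qfp(g1, 2)
    m2 <- find_intrastrand_qfp(g2, 2)
    expect_equal(nrow(m1), nrow(m2))
    expect_setequal(
      round(canonical_position(m1$midpoint + r, 300), 2),
      round(m2$midpoint, 2))
  }
})

test_that("heavy strand is the G-richer strand regardless of deposit", {
  s <- paste0(paste(rep("GGAA", 30), collapse = ""), "TTTT")
  g <- circular_genome(s)
  ms <- find_intrastrand_qfp(g, 2)
  expect_true(all(ms$strand_label[ms$strand == "reference"] == "heavy"))
  g2 <- circular_genome(reverse_complement(s))
  ms2 <- find_intrastrand_qfp(g2, 2)
  expect_true(all(ms2$strand_label[ms2$strand == "reference"] == "light"))
})

test_that("ddi elements mix strands, exclude intrastrand hits and never overlap them", {
  bg <- paste(rep("A", 500), collapse = "")
  g <- plant_sequence(circular_genome(bg, "t"), "GGTTCCTTGGTTCC", 100)
  intra <- find_intrastrand_qfp(g, 2)
  expect_equal(nrow(intra), 0)
  ddi <- find_ddi_qfp(g, 2, intra)
  expect_equal(nrow(ddi), 1)
  expect_equal(ddi$strand, "interstrand")

  # four same-strand G-tracts belong to intrastrand, not ddi
  g2 <- plant_sequence(circular_genome(bg, "t"), oligo_panel$A, 100)
  intra2 <- find_intrastrand_qfp(g2, 2)
  expect_equal(nrow(intra2), 1)
  expect_equal(nrow(find_ddi_qfp(g2, 2, intra2)), 0)

  # exclusion property on random genomes
  for (seed in 1:5) {
    s <- random_dna(500, seed, prob = c(0.2, 0.3, 0.3, 0.2))
    gg <- circular_genome(s)
    ii <- find_intrastrand_qfp(gg, 2)
    dd <- find_ddi_qfp(gg, 2, ii)
    if (nrow(dd) == 0 || nrow(ii) == 0) next
    for (i in seq_len(nrow(dd))) {
      expect_false(any(mitoqfp:::.circ_overlap(dd$start[i], dd$span[i],
                                               ii$start, ii$span, 500)))
    }
  }
})
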