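mk_match <- function(sa, ea, sb, eb, spa = "A", spb = "B", sca = "s1",
                     scb = "s1", strand = "+") {
  data.frame(species_a = spa, scaffold_a = sca, start_a = sa, end_a = ea,
             species_b = spb, scaffold_b = scb, start_b = sb, end_b = eb,
             strand = strand, length = ea - sa, stringsAsFactors = FALSE)
}

test_that("projection attributes intervals to the right species and partner", {
  m <- mk_match(10, 70, 100, 160)
  pa <- project_matches(list(m), "A")
  pb <- project_matches(list(m), "B")
  expect_equal(pa$start, 10); expect_equal(pa$partner, "B")
  expect_equal(pb$start, 100); expect_equal(pb$partner, "A")
  expect_equal(nrow(project_matches(list(m), "C")), 0)

  # same locus in A matched by two partners -> two labeled intervals
  ms <- list(mk_match(10, 70, 100, 160, "A", "B"),
             mk_match(10, 70, 300, 360, "A", "C"))
  pa <- project_matches(ms, "A")
  expect_equal(nrow(pa), 2)
  expect_setequal(pa$partner, c("B", "C"))
})

test_that("merging joins overlaps transitively but not book-ended intervals", {
  g <- genome(c(s1 = rand_dna(400, seed = 51)), "A")
  iv <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(scaffold = "s1", start = m[, 1], end = m[, 2],
               partner = "B", match_id = paste0("x", seq_len(nrow(m))),
               stringsAsFactors = FALSE)
  }
  u <- merge_to_ucrs(iv(0, 60, 50, 120), g)
  expect_equal(nrow(u), 1)
  expect_equal(u$start, 0); expect_equal(u$end, 120)

  u <- merge_to_ucrs(iv(0, 50, 50, 100), g)
  expect_equal(nrow(u), 2)                    # adjacency is not overlap

  u <- merge_to_ucrs(iv(0, 60, 55, 110, 105, 160), g)
  expect_equal(nrow(u), 1)
  expect_equal(u$end, 160)
})

test_that("flanks are 50 bp, truncated at scaffold ends", {
  s <- rand_dna(300, seed = 52)
  g <- genome(c(s1 = s), "A")
  iv <- data.frame(scaffold = "s1", start = c(0, 200), end = c(60, 250),
                   partner = "B", match_id = c("m1", "m2"),
                   stringsAsFactors = FALSE)
  u <- merge_to_ucrs(iv, g, flank = 50)
  first <- u[u$start == 0, ]
  expect_identical(first$flank_left, "")
  expect_identical(first$flank_right, substr(s, 61, 110))
  expect_identical(first$sequence_with_flanks, substr(s, 1, 110))
  mid <- u[u$start == 200, ]
  expect_identical(mid$flank_left, substr(s, 151, 200))
  expect_identical(mid$flank_right, substr(s, 251, 300))
})

test_that("merge is idempotent, order-invariant and base-conserving", {
  g <- genome(c(s1 = rand_dna(2000, seed = 53)), "A")
  set.seed(54)
  for (rep in 1:25) {
    n <- sample(1:25, 1)
    st <- sample(0:1900, n, replace = TRUE)
    en <- pmin(2000, st + sample(5:120, n, replace = TRUE))
    iv <- data.frame(scaffold = "s1", start = st, end = en,
                     partner = sample(c("B", "C"), n, replace = TRUE),
                     match_id = paste0("m", 1:n), stringsAsFactors = FALSE)
    u1 <- merge_to_ucrs(iv, g)
    # idempotence: feed merged intervals back in
    iv2 <- data.frame(scaffold = u1$scaffold, start = u1$start, end = u1$end,
                      partner = "B", match_id = u1$ucr_id,
                      stringsAsFactors = FALSE)
    u2 <- merge_to_ucrs(iv2, g)
    expect_equal(u2[, c("start", "end")], u1[, c("start", "end")],
                 ignore_attr = TRUE)
    # order invariance
    u3 <- merge_to_ucrs(iv[sample(n), ], g)
    expect_equal(u3[, c("start", "end", "conserved_with")],
                 u1[, c("start", "end", "conserved_with")],
                 ignore_attr = TRUE)
    # base conservation
    covered <- function(df) {
      x <- rep(FALSE, 2000)
      for (j in seq_len(nrow(df))) x[(df$start[j] + 1):df$end[j]] <- TRUE
      x
    }
    expect_identical(covered(u1), covered(iv))
    # no two outputs overlap
    if (nrow(u1) > 1) {
      o <- order(u1$start)
      expect_true(all(u1$start[o][-1] >= u1$end[o][-nrow(u1)]))
    }
    # conserved_with equals union of source partners
    for (j in seq_len(nrow(u1))) {
      src <- iv$partner[iv$start < u1$end[j] & iv$end > u1$start[j]]
      expect_identical(u1$conserved_with[j],
                       paste(sort(unique(src)), collapse = ","))
    }
  }
})

test_that("call_ucrs merges per species across all pairwise comparisons", {
  gA <- genome(c(a1 = rand_dna(500, seed = 55)), "A")
  gB <- genome(c(b1 = rand_dna(500)), "B")
  gC <- genome(c(c1 = rand_dna(500)), "C")
  ms <- list(mk_match(10, 70, 100, 160, "A", "B", "a1", "b1"),
             mk_match(40, 120, 300, 380, "A", "C", "a1", "c1"))
  u <- call_ucrs(list(A = gA, B = gB, C = gC), ms)
  ua <- u[u$species == "A", ]
  expect_equal(nrow(ua), 1)                      # [10,70) + [40,120) overlap
  expect_equal(ua$start, 10); expect_equal(ua$end, 120)
  expect_identical(ua$conserved_with, "B,C")
  expect_equal(nrow(u[u$species == "B", ]), 1)
  expect_equal(nrow(u[u$species == "C", ]), 1)
})
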