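test_that("genome generation is deterministic and honors the GC model", {
  spec <- species_spec("A", 1, 10000, gc_content = 0.5)
  g1 <- generate_genome(spec, seed = 7)
  g2 <- generate_genome(spec, seed = 7)
  expect_identical(as.character(g1$seqs), as.character(g2$seqs))
  expect_false(identical(as.character(g1$seqs),
                         as.character(generate_genome(spec, seed = 8)$seqs)))

  at_only <- generate_genome(species_spec("B", 1, 2000, gc_content = 0), 1)
  expect_false(grepl("[GC]", as.character(at_only$seqs[[1]])))

  big <- generate_genome(species_spec("C", 1, 100000, gc_content = 0.5), 3)
  gc_obs <- Biostrings::letterFrequency(big$seqs[[1]], "GC",
                                        as.prob = TRUE)[1]
  se <- sqrt(0.5 * 0.5 / 1e5)
  expect_lt(abs(gc_obs - 0.5), 3 * se)

  expect_error(species_spec("D", 1, 0), "scaffold_length")
})

test_that("planted elements follow strand convention and truth bookkeeping", {
  gA <- generate_genome(species_spec("A", 1, 3000), 1)
  gB <- generate_genome(species_spec("B", 1, 3000), 2)
  pl <- list(plant_spec("e1", 60, list(
    A = list(scaffold = "A_scf1", start = 100, strand = "+"),
    B = list(scaffold = "B_scf1", start = 900, strand = "-"))))
  res <- plant_elements(list(A = gA, B = gB), pl, seed = 5)
  tr <- res$truth
  expect_equal(nrow(tr), 2)
  seg_a <- substr(as.character(res$genomes$A$seqs[[1]]), 101, 160)
  seg_b <- substr(as.character(res$genomes$B$seqs[[1]]), 901, 960)
  expect_identical(seg_b, revcomp_chr(seg_a))
  ep <- truth_exact_pairs(tr)
  expect_equal(nrow(ep), 1)
  expect_setequal(c(ep$species_a, ep$species_b), c("A", "B"))
})

test_that("a single substitution destroys the full-length exact match", {
  gA <- generate_genome(species_spec("A", 1, 2000), 3)
  gB <- generate_genome(species_spec("B", 1, 2000), 4)
  pl <- list(plant_spec("e1", 60, list(
    A = list(scaffold = "A_scf1", start = 500, strand = "+"),
    B = list(scaffold = "B_scf1", start = 500, strand = "+")),
    mutations = c(B = 1L)))
  res <- plant_elements(list(A = gA, B = gB), pl, seed = 11)
  expect_equal(nrow(truth_exact_pairs(res$truth)), 0)
  a <- substr(as.character(res$genomes$A$seqs[[1]]), 501, 560)
  b <- substr(as.character(res$genomes$B$seqs[[1]]), 501, 560)
  expect_false(identical(a, b))
  # longest shared exact diagonal run must now be < 60
  runs <- oracle_mems_one_strand(a, b, 1)
  expect_lt(max(runs$length), 60)
  expect_equal(sum(runs$length[runs$start_a == runs$start_b]), 59)
})

test_that("overlapping placements are rejected with the colliding ids", {
  g <- generate_genome(species_spec("A", 1, 1000), 1)
  gB <- generate_genome(species_spec("B", 1, 1000), 2)
  pl <- list(
    plant_spec("e1", 80, list(A = list(scaffold = "A_scf1", start = 100, strand = "+"),
                              B = list(scaffold = "B_scf1", start = 100, strand = "+"))),
    plant_spec("e2", 80, list(A = list(scaffold = "A_scf1", start = 150, strand = "+"),
                              B = list(scaffold = "B_scf1", start = 400, strand = "+"))))
  expect_error(plant_elements(list(A = g, B = gB), pl, seed = 1), "e1.*e2")
})

test_that("planted repeats have exact truth intervals and determinism", {
  g <- generate_genome(species_spec("A", 1, 2000), 1)
  pr <- plant_repeats(g, 1, seed = 2,
                      positions = data.frame(scaffold = "A_scf1", start = 100),
                      units = "AGT", copies = 10)
  expect_equal(pr$mask$start, 100)
  expect_equal(pr$mask$end, 130)
  expect_identical(substr(as.character(pr$genome$seqs[[1]]), 101, 130),
                   strrep("AGT", 10))

  none <- plant_repeats(g, 0, seed = 2)
  expect_identical(as.character(none$genome$seqs), as.character(g$seqs))
  expect_equal(nrow(none$mask), 0)

  r1 <- plant_repeats(g, 5, unit_length = 4, copies = 8, seed = 9)
  r2 <- plant_repeats(g, 5, unit_length = 4, copies = 8, seed = 9)
  expect_identical(as.character(r1$genome$seqs), as.character(r2$genome$seqs))
  expect_identical(r1$mask, r2$mask)
})

test_that("annotations honor the near-element placement rule", {
  g <- generate_genome(species_spec("A", 1, 50000), 1)
  el <- data.frame(scaffold = "A_scf1", start = c(10000, 30000),
                   end = c(10100, 30200))
  ann <- generate_annotations(g, 10, c("PF1", "PF2"),
                              placement_rule = "near_elements", seed = 4,
                              elements = el, near_distance = 1000,
                              near_fraction = 1.0, gene_length = 300)
  expect_gt(nrow(ann$genes), 0)
  # every element has at least one gene within 1 kb
  for (j in seq_len(nrow(el))) {
    gap <- pmax(0, pmax(el$start[j] - ann$genes$end,
                        ann$genes$start - el$end[j]))
    expect_true(any(gap <= 1000))
  }
  expect_true(all(ann$domains$domain %in% c("PF1", "PF2")))
  # non-overlap
  o <- order(ann$genes$start)
  s <- ann$genes$start[o]; e <- ann$genes$end[o]
  if (length(s) > 1) expect_true(all(s[-1] >= e[-length(e)]))

  empty <- generate_annotations(g, 0, "PF1", seed = 1)
  expect_equal(nrow(empty$genes), 0)
  expect_error(generate_annotations(g, 5, character(0), seed = 1), "empty")
})

test_that("protein families evolve under JTT with correct limits", {
  tr0 <- ape::read.tree(text = "(A:0,B:0,C:0);")
  fam <- evolve_protein_families(tr0, 1, 200, seed = 1)[[1]]
  expect_identical(fam["A", ], fam["B", ])
  expect_identical(fam["A", ], fam["C", ])

  tr <- ape::read.tree(text = "(A:0.25,B:0.25,C:0.5);")
  f1 <- evolve_protein_families(tr, 2, 100, seed = 3)
  f2 <- evolve_protein_families(tr, 2, 100, seed = 3)
  expect_identical(f1[[1]], f2[[1]])
  expect_identical(f1[[2]], f2[[2]])
  expect_false(identical(f1[[1]], f1[[2]]))  # independent families

  trneg <- tr; trneg$edge.length[1] <- -0.1
  expect_error(evolve_protein_families(trneg, 1, 10, seed = 1), "non-negative")
})

test_that("simulated divergence matches the JTT expected p-distance", {
  # expected proportion of differing sites at t = 0.5 from the transition
  # matrix: 1 - sum_a pi_a P_aa(t)
  model <- ultracons:::get_jtt()
  P <- ultracons:::jtt_prob(0.5, model)
  p_expect <- 1 - sum(model$pi * diag(P))
  tr <- ape::read.tree(text = "(A:0.25,B:0.25,C:5);")
  fam <- evolve_protein_families(tr, 1, 10000, seed = 17)[[1]]
  p_obs <- mean(fam["A", ] != fam["B", ])
  se <- sqrt(p_expect * (1 - p_expect) / 10000)
  expect_lt(abs(p_obs - p_expect), 3 * se)
})
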