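two_genomes <- function(a, b) {
  list(A = genome(c(sA = a), "A"), B = genome(c(sB = b), "B"))
}

test_that("identity and reverse-complement identity are single full matches", {
  set.seed(41)
  a <- rand_dna(200)
  gs <- two_genomes(a, a)
  m <- find_mems(gs$A, gs$B, 50)
  fw <- m[m$strand == "+", ]
  expect_equal(nrow(fw), 1)
  expect_equal(fw$start_a, 0); expect_equal(fw$length, 200)

  gs <- two_genomes(a, revcomp_chr(a))
  m <- find_mems(gs$A, gs$B, 50)
  mn <- m[m$strand == "-", ]
  expect_equal(nrow(mn), 1)
  expect_equal(mn$start_a, 0); expect_equal(mn$start_b, 0)
  expect_equal(mn$length, 200)
})

test_that("the length threshold excludes 49 bp and admits it at 30", {
  set.seed(42)
  seg <- rand_dna(49)
  # distinct boundary bases so the shared segment is exactly 49 bp
  a <- paste0(rand_dna(999), "A", seg, "A", rand_dna(950))
  b <- paste0(rand_dna(499), "C", seg, "C", rand_dna(1450))
  gs <- two_genomes(a, b)
  m50 <- find_mems(gs$A, gs$B, 50)
  expect_false(any(m50$start_a <= 1000 & m50$end_a >= 1049 &
                     m50$strand == "+"))
  m30 <- find_mems(gs$A, gs$B, 30)
  expect_true(any(m30$start_a <= 1000 & m30$end_a >= 1049 &
                    m30$start_b <= 500 & m30$strand == "+"))
})

test_that("find_mems equals the diagonal oracle on random planted instances", {
  set.seed(43)
  for (rep in 1:20) {
    n <- sample(300:900, 1)
    a <- rand_dna(n); b <- rand_dna(n)
    for (k in 1:3) {
      seg <- rand_dna(sample(c(60, 80, 120), 1))
      pa <- sample(n - nchar(seg), 1); pb <- sample(n - nchar(seg), 1)
      sb <- if (runif(1) < 0.5) seg else revcomp_chr(seg)
      a <- paste0(substr(a, 1, pa), seg, substr(a, pa + nchar(seg) + 1, n))
      b <- paste0(substr(b, 1, pb), sb, substr(b, pb + nchar(sb) + 1, n))
    }
    gs <- two_genomes(a, b)
    got <- find_mems(gs$A, gs$B, 50)
    want <- oracle_mems(a, b, 50)
    expect_identical(match_key(got), match_key(want))
  }
})

test_that("matches are symmetric between genome order and avoid N", {
  set.seed(44)
  seg <- rand_dna(70)
  a <- paste0(rand_dna(300), seg, rand_dna(300))
  b <- paste0(rand_dna(100), seg, rand_dna(500))
  # masked copy in b must not match
  bmask <- paste0(substr(b, 1, 250), strrep("N", 30), substr(b, 281, nchar(b)))
  gs <- two_genomes(a, b)
  ab <- find_mems(gs$A, gs$B, 50)
  ba <- find_mems(gs$B, gs$A, 50)
  expect_identical(sort(sprintf("%d:%d:%d", ab$start_a, ab$start_b, ab$length)),
                   sort(sprintf("%d:%d:%d", ba$start_b, ba$start_a, ba$length)))

  gs2 <- two_genomes(a, bmask)
  m2 <- find_mems(gs2$A, gs2$B, 50)
  bv <- strsplit(bmask, "")[[1]]
  for (r in seq_len(nrow(m2)))
    expect_false(any(bv[(m2$start_b[r] + 1):m2$end_b[r]] == "N"))
})

test_that("planted exact pairs are all recovered (truth round-trip)", {
  gA <- generate_genome(species_spec("A", 2, 5000), 1)
  gB <- generate_genome(species_spec("B", 1, 8000), 2)
  plants <- list(
    plant_spec("e1", 60, list(A = list(scaffold = "A_scf1", start = 500, strand = "+"),
                              B = list(scaffold = "B_scf1", start = 4000, strand = "+"))),
    plant_spec("e2", 90, list(A = list(scaffold = "A_scf2", start = 1000, strand = "+"),
                              B = list(scaffold = "B_scf1", start = 6000, strand = "-"))),
    plant_spec("e3", 55, list(A = list(scaffold = "A_scf1", start = 3000, strand = "-"),
                              B = list(scaffold = "B_scf1", start = 1000, strand = "+"))))
  res <- plant_elements(list(A = gA, B = gB), plants, seed = 6)
  m <- find_mems(res$genomes$A, res$genomes$B, 50)
  ep <- truth_exact_pairs(res$truth, 50)
  for (r in seq_len(nrow(ep))) {
    hit <- m$scaffold_a == ep$scaffold_a[r] & m$start_a == ep$start_a[r] &
      m$end_a == ep$end_a[r] & m$scaffold_b == ep$scaffold_b[r] &
      m$start_b == ep$start_b[r]
    expect_equal(sum(hit), 1)
  }
})

test_that("remasking trims or drops repeat-contaminated matches", {
  # pure tandem match is dropped
  arr <- strrep("AT", 30)
  gs <- two_genomes(paste0(rand_dna(100), arr, rand_dna(100)),
                    paste0(rand_dna(50), arr, rand_dna(150)))
  m <- find_mems(gs$A, gs$B, 50)
  expect_gt(nrow(m), 0)
  expect_equal(nrow(remask_matches(m, gs$A, 50)), 0)

  # internal tandem at [40, 60) of a 100 bp match: trimmed to [0, 40)
  set.seed(46)
  left <- paste0(rand_dna(39), "T")   # T borders keep the array at [40, 61)
  right <- paste0("T", rand_dna(39))
  mid <- strrep("CAG", 7)  # 21 bp tandem
  seg <- paste0(left, mid, right)   # 101 bp
  # distinct boundary bases: the match is exactly the 101 bp segment
  a <- paste0(rand_dna(199), "A", seg, "A", rand_dna(199))
  b <- paste0(rand_dna(299), "C", seg, "C", rand_dna(99))
  gs <- two_genomes(a, b)
  m <- find_mems(gs$A, gs$B, 50)
  m <- m[m$length > 90, , drop = FALSE]
  expect_equal(nrow(m), 1)
  t30 <- remask_matches(m, gs$A, 30, min_span = 18)
  expect_equal(t30$length, 40)
  expect_equal(t30$start_a, m$start_a)        # left flank kept
  expect_equal(t30$start_b, m$start_b)
  expect_equal(nrow(remask_matches(m, gs$A, 50, min_span = 18)), 0)

  # clean match unchanged
  set.seed(47)
  seg <- rand_dna(80)
  gs <- two_genomes(paste0(rand_dna(100), seg, rand_dna(100)),
                    paste0(rand_dna(200), seg, rand_dna(50)))
  m <- find_mems(gs$A, gs$B, 50)
  expect_identical(remask_matches(m, gs$A, 50), m)
})
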