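make_set <- function(seqs, id) seq_set(seqs, strain_id = id)

test_that("self-comparison of one sequence yields a single perfect hit", {
  s <- random_protein(100, seed = 1)
  a <- make_set(c(r1 = s), "A")
  h <- find_hits(a, a)
  expect_equal(nrow(h$hits), 1L)
  expect_equal(h$hits$length, 100L)
  expect_equal(h$hits$nid, 0L)
  expect_equal(h$hits$qs, 0L)
  expect_equal(h$hits$qe, 100L)
})

test_that("sequences sharing no k-mer give an empty hit set", {
  a <- make_set(c(r1 = strrep("A", 50)), "A")
  b <- make_set(c(r1 = strrep("W", 50)), "B")
  expect_equal(nrow(find_hits(a, b)$hits), 0L)
  # k larger than every sequence: empty, not an error
  short <- make_set(c(r1 = "ACDEF"), "S")
  expect_equal(nrow(find_hits(short, short, k = 10)$hits), 0L)
})

test_that("alphabet mismatch is an error", {
  a <- make_set(c(r1 = "ACDEFGHIKL"), "A")
  b <- seq_set(c(r1 = "ACGTACGTAC"), "B", alphabet = "dna")
  expect_error(find_hits(a, b), "alphabet")
})

test_that("hit finder matches the exhaustive ungapped alignment oracle", {
  sm <- gbdphylo:::.subst_matrix("protein")
  for (i in 1:20) {
    s1 <- random_protein(60, seed = 100 + i)
    set.seed(200 + i)
    s2 <- mutate_protein(s1, sample(60, 3))
    oracle <- brute_ungapped_best(s1, s2, sm)
    h <- find_hits(make_set(c(r = s1), "A"), make_set(c(r = s2), "B"))
    expect_gt(nrow(h$hits), 0L)
    top <- h$hits[which.max(h$hits$score), ]
    expect_equal(top$score, oracle$score)
    expect_equal(top$nid, oracle$nid)
    expect_equal(c(top$qs, top$qe, top$ss, top$se),
                 c(oracle$qs, oracle$qe, oracle$ss, oracle$se))
  }
})

test_that("single mismatch pair recovers the full-length hit", {
  s1 <- random_protein(60, seed = 5)
  s2 <- mutate_protein(s1, 30, seed = 6)
  h <- find_hits(make_set(c(r = s1), "A"), make_set(c(r = s2), "B"))
  top <- h$hits[which.max(h$hits$score), ]
  expect_equal(top$nid, 1L)
  sm <- gbdphylo:::.subst_matrix("protein")
  oracle <- brute_ungapped_best(s1, s2, sm)
  expect_equal(top$score, oracle$score)
})

test_that("trimming resolves overlaps greedily and recounts columns", {
  # non-overlapping hits survive unchanged
  s <- random_protein(200, seed = 9)
  a <- make_set(c(r1 = substr(s, 1, 80), r2 = substr(s, 101, 200)), "A")
  h <- trim_hits(find_hits(a, a))
  self <- h$hits[h$hits$qrec == h$hits$srec, ]
  expect_equal(nrow(self), 2L)
  expect_equal(sort(self$length), c(80L, 100L))

  # two identical-interval hits: only the higher-scoring survives
  hs <- find_hits(make_set(c(r = s), "A"), make_set(c(r = s), "B"))
  fake <- hs
  fake$hits <- rbind(hs$hits, transform(hs$hits, score = score - 10))
  trimmed <- trim_hits(fake)
  expect_equal(nrow(trimmed$hits), 1L)
  expect_equal(trimmed$hits$score, hs$hits$score)
})

test_that("partial overlap is trimmed to the residue and N recounted", {
  s1 <- random_protein(150, seed = 11)
  s2 <- mutate_protein(s1, c(40, 120), seed = 12)
  hs <- find_hits(make_set(c(r = s1), "A"), make_set(c(r = s2), "B"))
  # fabricate an overlapping pair: [0,100) strong, [50,150) weaker
  h1 <- hs$hits[1, ]
  a1 <- transform(h1, qs = 0L, qe = 100L, ss = 0L, se = 100L,
                  length = 100L, score = 500)
  a2 <- transform(h1, qs = 50L, qe = 150L, ss = 50L, se = 150L,
                  length = 100L, score = 400)
  fake <- hs; fake$hits <- rbind(a1, a2)
  out <- trim_hits(fake)$hits
  expect_equal(nrow(out), 2L)
  second <- out[out$qs == 100L, ]
  expect_equal(second$qe, 150L)
  expect_equal(second$length, 50L)
  # brute-force recount over columns 101..150
  c1 <- strsplit(s1, "")[[1]][101:150]
  c2 <- strsplit(s2, "")[[1]][101:150]
  expect_equal(second$nid, sum(c1 != c2))
})

test_that("gbdp distance follows -ln(1 - N/L) with per-hit summation", {
  s <- random_protein(300, seed = 13)
  a <- make_set(c(r = s), "A")
  hs <- trim_hits(find_hits(a, a))
  res <- gbdp_distance(hs)
  expect_equal(res$d, 0)          # identity
  expect_false(res$undefined)

  # random trimmed hit sets: distance equals independent summation
  for (i in 1:10) {
    s1 <- random_protein(400, seed = 300 + i)
    set.seed(400 + i)
    s2 <- mutate_protein(s1, sample(400, 25))
    hs <- trim_hits(find_hits(make_set(c(r = s1), "A"),
                              make_set(c(r = s2), "B")))
    res <- gbdp_distance(hs)
    N <- sum(hs$hits$nid); L <- sum(hs$hits$length)
    expect_equal(res$d, -log(1 - N / L))
  }
  expect_equal(-log(1 - 10 / 100), 0.105361, tolerance = 1e-5)
})

test_that("undefined distances are flagged and untrimmed input rejected", {
  a <- make_set(c(r1 = strrep("A", 50)), "A")
  b <- make_set(c(r1 = strrep("W", 50)), "B")
  hs <- trim_hits(find_hits(a, b))
  expect_true(gbdp_distance(hs)$undefined)
  expect_error(gbdp_distance(find_hits(a, a)), "trimmed")
})

test_that("distance matrix is symmetric, zero-diagonal and monotone", {
  tr <- simulate_tree(5, seed = 21)
  pr <- evolve_proteomes(tr, n_genes = 30, gene_length = 150,
                         substitution_rate = 0.1, seed = 22)
  dm <- distance_matrix(pr)
  expect_identical(dm, t(dm))
  expect_true(all(diag(dm) == 0))
  # duplicated genome gives off-diagonal zero
  dup <- pr[c(1, 1, 2)]
  dup[[2]]$strain_id <- "copy"
  dm2 <- distance_matrix(dup)
  expect_equal(dm2[1, 2], 0)
  # distances grow with simulated path length: whenever two tip pairs have
  # strictly different true path lengths, the estimated distances agree in order
  paths <- ape::cophenetic.phylo(tr)[rownames(dm), colnames(dm)]
  ut <- which(upper.tri(dm))
  dv <- dm[ut]; pv <- paths[ut]
  for (i in seq_along(dv)[-1]) for (j in seq_len(i - 1)) {
    if (abs(pv[i] - pv[j]) > 0.05)
      expect_equal(sign(dv[i] - dv[j]), sign(pv[i] - pv[j]))
  }
})

test_that("pseudo-bootstrap is seeded, and degenerate for single hits", {
  s1 <- random_protein(300, seed = 31)
  s2 <- mutate_protein(s1, c(50, 150, 250), seed = 32)
  g <- list(make_set(c(r = s1), "A"), make_set(c(r = s2), "B"))
  dm <- distance_matrix(g)
  r1 <- pseudo_bootstrap(dm, B = 20, seed = 5)
  r2 <- pseudo_bootstrap(dm, B = 20, seed = 5)
  expect_identical(r1, r2)
  # single hit per pair: every replicate equals the original distance
  hs <- attr(dm, "hitsets")[[1]]
  if (nrow(hs$hits) == 1L)
    expect_true(all(vapply(r1, function(m) m["A", "B"], numeric(1)) ==
                      dm["A", "B"]))
  # replicate mean approximates the plug-in estimate for a multi-hit pair
  tr <- simulate_tree(2, seed = 33)
  tr$edge.length <- c(0.5, 0.5)
  pr <- evolve_proteomes(tr, n_genes = 10, gene_length = 80,
                         substitution_rate = 0.2, seed = 34)
  dm3 <- distance_matrix(pr)
  reps <- pseudo_bootstrap(dm3, B = 1000, seed = 6)
  dvals <- vapply(reps, function(m) m[1, 2], numeric(1))
  # independent oracle: direct resampling from the stored hit table
  h <- attr(dm3, "hitsets")[[1]]$hits
  set.seed(99)
  oracle <- replicate(1000, {
    idx <- sample.int(nrow(h), nrow(h), replace = TRUE)
    -log(1 - sum(h$nid[idx]) / sum(h$length[idx]))
  })
  expect_lt(abs(mean(dvals) - mean(oracle)),
            3 * sqrt(var(oracle) / 1000 + var(dvals) / 1000))
})

test_that("dDDH mapping anchors 100 at identity and 70 at d70", {
  expect_equal(ddh_estimate(0), 100)
  expect_equal(ddh_estimate(0.09), 70)
  expect_equal(ddh_estimate(0.05),
               100 * exp(log(0.7) * 0.05 / 0.09))
  expect_error(ddh_estimate(-0.1), "non-negative")
  custom <- function(d) 100 - d
  expect_equal(ddh_estimate(2, mapping = custom), 98)
})

test_that("species delineation is transitive and order-invariant", {
  labs <- c("s1", "s2", "s3")
  m <- matrix(c(100, 89.8, 89.9, 89.8, 100, 91.6, 89.9, 91.6, 100), 3,
              dimnames = list(labs, labs))
  sp <- delineate_species(m)
  expect_equal(length(unique(sp)), 1L)

  # all below cut-off: every strain its own species
  m2 <- matrix(53.8, 3, 3, dimnames = list(labs, labs)); diag(m2) <- 100
  expect_equal(length(unique(delineate_species(m2))), 3L)

  # chain A-B, B-C joined, A-C distant: transitive closure to one species
  m3 <- matrix(c(100, 75, 40, 75, 100, 75, 40, 75, 100), 3,
               dimnames = list(labs, labs))
  sp3 <- delineate_species(m3)
  expect_equal(length(unique(sp3)), 1L)
  # independent graph-component oracle
  skip_if_not_installed("igraph")
  g <- igraph::graph_from_adjacency_matrix(m3 >= 70, mode = "undirected",
                                           diag = FALSE)
  expect_equal(length(unique(sp3)),
               igraph::components(g)$no)
  # order invariance
  perm <- c(3, 1, 2)
  sp_perm <- delineate_species(m3[perm, perm])
  expect_equal(sp_perm[labs], sp3[labs])
  expect_error(delineate_species(m3 * 2), "0, 100")
})

test_that("genome stats count residues and G+C with ambiguity excluded", {
  g <- seq_set(c(r = "GGCC"), "G", alphabet = "dna")
  expect_equal(genome_stats(g)$gc_percent, 100.0)
  g2 <- seq_set(c(r = "ATGC"), "G", alphabet = "dna")
  expect_equal(genome_stats(g2)$gc_percent, 50.0)
  g3 <- seq_set(c(r = "ATGCN"), "G", alphabet = "dna")
  st <- genome_stats(g3)
  expect_equal(st$gc_percent, 50.0)
  expect_equal(st$size, 5L)
  p <- seq_set(c(r = "ACDEF"), "P", alphabet = "protein")
  expect_null(genome_stats(p)$gc_percent)
})
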