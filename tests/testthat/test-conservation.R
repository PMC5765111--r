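test_that("equal-width discretization follows the stated binning", {
  expect_true(all(discretize(rep(3.3, 5)) == 0L))
  expect_equal(discretize(0:9, K = 10), 0:9)
  expect_equal(discretize(c(0, 0.04, 0.5, 1), K = 2), c(0L, 0L, 1L, 1L))
  expect_equal(discretize(c(2, NA, 4)), c(0L, NA, 9L))
  expect_error(discretize(c(1, Inf)), "non-finite")
})

test_that("parsimony scores match hand-worked cases", {
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(parsimony_score(tr, c(A = 0, B = 0, C = 1, D = 1)), 1L)
  expect_equal(parsimony_score(tr, c(A = 0, B = 0, C = 0, D = 0)), 0L)
  expect_equal(parsimony_score(tr, c(A = 0, B = 1, C = 0, D = 1)), 2L)
  # ordinal linear cost: states 0 and 2 on a cherry cost 2
  tr2 <- read_newick("(A:1,B:1);")
  expect_equal(parsimony_score(tr2, c(A = 0, B = 2), "ordinal(3)"), 2L)
  # missing values are free
  expect_equal(parsimony_score(tr, c(A = 0, B = NA, C = 1, D = NA)), 1L)
  expect_error(parsimony_score(tr, c(A = 0, B = 1, C = 0)), "tip")
  expect_error(parsimony_score(tr, c(A = .1, B = 1, C = 0, D = 1),
                               "continuous"), "discretized")
})

test_that("Fitch scores equal exhaustive enumeration on 5-tip trees", {
  labels <- paste0("t", 1:5)
  topos <- all_topologies(labels)
  expect_length(topos, 15L)
  unit_cost <- function(i, j) as.integer(i != j)
  for (tr in topos[c(1, 7, 15)]) {
    for (code in 0:31) {
      states <- setNames(as.integer(intToBits(code)[1:5]), labels)
      expect_equal(parsimony_score(tr, states, "binary"),
                   brute_parsimony(tr, as.list(states), 2, unit_cost))
    }
  }
})

test_that("Sankoff linear-cost scores equal exhaustive enumeration", {
  labels <- paste0("t", 1:5)
  topos <- all_topologies(labels)
  lin_cost <- function(i, j) abs(i - j)
  set.seed(42)
  for (tr in topos[c(3, 10)]) {
    for (rep in 1:20) {
      states <- setNames(sample(0:2, 5, replace = TRUE), labels)
      expect_equal(parsimony_score(tr, states, "ordinal(3)"),
                   brute_parsimony(tr, as.list(states), 3, lin_cost))
    }
  }
})

test_that("parsimony agrees with an independent phylogenetics library", {
  skip_if_not_installed("phangorn")
  set.seed(8)
  tr <- ape::rtree(12)
  for (rep in 1:10) {
    states <- setNames(sample(0:1, 12, replace = TRUE), tr$tip.label)
    pd <- phangorn::phyDat(matrix(as.character(states), ncol = 1,
                                  dimnames = list(names(states), NULL)),
                           type = "USER", levels = c("0", "1"))
    expect_equal(parsimony_score(tr, states, "binary"),
                 as.integer(phangorn::parsimony(tr, pd)))
  }
})

test_that("Fitch score never exceeds min(#zeros, #ones)", {
  set.seed(9)
  for (rep in 1:20) {
    tr <- ape::rtree(10)
    states <- setNames(sample(0:1, 10, replace = TRUE), tr$tip.label)
    if (length(unique(states)) < 2) next
    expect_lte(parsimony_score(tr, states, "binary"),
               min(sum(states == 0), sum(states == 1)))
  }
})

test_that("permutation test handles constant and clade-perfect characters", {
  tr <- simulate_tree(16, seed = 20)
  vals <- cbind(const = rep(1, 16),
                clade = rep(0, 16))
  rownames(vals) <- tr$tip.label
  # perfect binary split along one side of the root
  root_kids <- tr$edge[tr$edge[, 1] == 17, 2]
  below <- ape::extract.clade(tr, root_kids[1])$tip.label
  vals[below, "clade"] <- 1
  tab <- character_table(vals, c("binary", "binary"))
  res <- tip_permutation_test(tr, tab, M = 2000, seed = 21)
  expect_equal(res$p_value[res$character == "const"], 1.0)
  expect_lte(res$p_value[res$character == "clade"], 0.01)
  expect_equal(res$score[res$character == "clade"], 1)
  # p bounded below by 1/M and identity always counted
  expect_true(all(res$count_le >= 1))
  expect_true(all(res$p_value >= 1 / 2000 & res$p_value <= 1))
})

test_that("permutation p-values are reproducible under a fixed seed", {
  tr <- simulate_tree(10, seed = 30)
  tab <- evolve_characters(tr, 8, "bm", sigma2 = 2, seed = 31)
  r1 <- tip_permutation_test(tr, tab, M = 500, seed = 32)
  r2 <- tip_permutation_test(tr, tab, M = 500, seed = 32)
  expect_identical(r1, r2)
  r3 <- tip_permutation_test(tr, tab, M = 500, seed = 33)
  expect_false(identical(r1$p_value, r3$p_value))
  bad <- tab[1:9, , drop = FALSE]
  expect_error(tip_permutation_test(tr, character_table(
    bad, attr(tab, "kinds")), M = 100, seed = 1), "tips")
})

test_that("signal characters score lower p than noise characters", {
  tr <- simulate_tree(16, seed = 40)
  # rescale to unit depth so sigma2 is comparable across runs
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  bm <- evolve_characters(tr, 40, "bm", sigma2 = 4, seed = 41)
  noise <- evolve_characters(tr, 40, "noise", seed = 42)
  tab <- character_table(cbind(unclass(bm), unclass(noise)),
                         kinds = c(attr(bm, "kinds"), attr(noise, "kinds")),
                         panels = rep(c("bm", "noise"), each = 40))
  res <- tip_permutation_test(tr, tab, M = 500, seed = 43)
  expect_lt(median(res$p_value[res$panel == "bm"]),
            median(res$p_value[res$panel == "noise"]))
})

test_that("alpha summaries count thresholds per panel", {
  res <- data.frame(character = c("a", "b", "c"),
                    kind = "binary", panel = "P",
                    score = 1, M = 1000, count_le = c(5, 30, 200),
                    p_value = c(0.005, 0.03, 0.2))
  s <- summarize_alpha(res)
  expect_equal(s$n_significant, c(1L, 2L, 2L))
  expect_error(summarize_alpha(res[0, ]), "no results")
  # panel partition leaves total counts invariant
  res2 <- res; res2$panel <- c("P", "Q", "Q")
  s2 <- summarize_alpha(res2)
  for (a in unique(s$alpha))
    expect_equal(sum(s2$n_significant[s2$alpha == a]),
                 s$n_significant[s$alpha == a])
})

test_that("optional BH adjustment is monotone and defaults off", {
  tr <- simulate_tree(10, seed = 60)
  tab <- evolve_characters(tr, 12, "bm", sigma2 = 2, seed = 61)
  res <- tip_permutation_test(tr, tab, M = 200, seed = 62)
  expect_null(res$p_adjusted)
  res_bh <- tip_permutation_test(tr, tab, M = 200, seed = 62, bh = TRUE)
  expect_true(all(res_bh$p_adjusted >= res_bh$p_value))
  expect_identical(res_bh$p_value, res$p_value)
})
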