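tree_from_text <- function(txt) {
  tmp <- withr::local_tempfile(fileext = ".nwk",
                               .local_envir = parent.frame())
  writeLines(txt, tmp)
  read_newick(tmp)
}

test_that("Newick input yields the expected covariance bookkeeping", {
  tr <- tree_from_text("((A:1,B:1):1,C:2);")
  C <- phylo_covariance(tr)
  expect_equal(C[c("A", "B", "C"), c("A", "B", "C")],
               matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3,
                      dimnames = list(c("A", "B", "C"),
                                      c("A", "B", "C"))))
  star <- tree_from_text("(A:1,B:1,C:1);")
  expect_equal(unname(phylo_covariance(star)), diag(3))
  expect_error(tree_from_text("((A:1,A:1):1,C:2);"), "duplicate")
  expect_error(tree_from_text("((A,B),C);"), "branch lengths")
})

test_that("covariance entries equal MRCA depths on random trees", {
  set.seed(41)
  for (rep in 1:5) {
    tr <- simulate_tree(10, seed = 500 + rep)
    C <- phylo_covariance(tr)
    # independent path enumeration: node depths + pairwise MRCA
    depths <- ape::node.depth.edgelength(tr)
    mrca <- ape::mrca(tr)
    for (i in 1:10) for (j in 1:10) {
      expected <- if (i == j) depths[i] else depths[mrca[i, j]]
      expect_equal(C[tr$tip.label[i], tr$tip.label[j]], expected,
                   tolerance = 1e-12)
    }
  }
  bad <- simulate_tree(5, seed = 1)
  bad$edge.length[2] <- -0.1
  expect_error(phylo_covariance(bad), "negative")
})

test_that("Blomberg's K collapses to 1 on a star tree and is affine-invariant", {
  star <- tree_from_text("(A:1,B:1,C:1,D:1,E:1);")
  x <- c(A = 0.3, B = 1.2, C = -0.5, D = 2, E = 0.1)
  expect_equal(blomberg_k(x, star), 1, tolerance = 1e-12)
  tr <- tree_from_text("((A:1,B:1):1,(C:1,D:1):1);")
  y <- c(A = 1, B = 2, C = 7, D = 9)
  expect_equal(blomberg_k(3.7 * y - 11, tr), blomberg_k(y, tr),
               tolerance = 1e-12)
  expect_error(blomberg_k(c(A = 1, B = 1, C = 1, D = 1), tr),
               "constant")
})

test_that("K on the 4-taxon fixture matches independent computations", {
  tr <- tree_from_text("((A:1,B:1):1,(C:1,D:1):1);")
  y <- c(A = 1, B = 2, C = 7, D = 9)
  k <- blomberg_k(y, tr)
  expect_equal(k, k_oracle(y, tr), tolerance = 1e-12)
  # frozen value from phytools::phylosig, an independent implementation
  expect_equal(k, 1.619095477387, tolerance = 1e-9)
})

test_that("K_mult reduces to K and matches its brute-force oracle", {
  tr <- tree_from_text("(((A:1,B:1):0.5,C:1.5):0.5,(D:1,E:1):1);")
  set.seed(42)
  X <- matrix(round(rnorm(15), 3), 5, 3,
              dimnames = list(tr$tip.label, paste0("t", 1:3)))
  expect_equal(k_mult(X[, 1, drop = FALSE], tr),
               blomberg_k(X[, 1], tr), tolerance = 1e-12)
  expect_equal(k_mult(X, tr), kmult_oracle(X, tr), tolerance = 1e-12)
  star <- tree_from_text("(A:1,B:1,C:1,D:1,E:1);")
  expect_equal(k_mult(X, star), 1, tolerance = 1e-12)
})

test_that("permutation test honors its p-value contract and seed", {
  tr <- simulate_tree(20, seed = 7)
  x <- simulate_bm_traits(tr, 1, seed = 8)[, 1]
  r1 <- permutation_test(x, tr, n_permutations = 199, seed = 99)
  r2 <- permutation_test(x, tr, n_permutations = 199, seed = 99)
  expect_equal(r1$permutation_values, r2$permutation_values)
  expect_equal(r1$p_value,
               (1 + sum(r1$permutation_values >= r1$observed)) / 200)
  expect_gt(r1$p_value, 0)
  expect_equal(r1$statistic_name, "K")
  expect_error(permutation_test(x, tr, n_permutations = 199),
               "seed")
  expect_error(permutation_test(x, tr, n_permutations = 9, seed = 1),
               ">= 99")
})

test_that("strong Brownian signal is detected at the printed resolution", {
  # with the observed K above every permutation, the add-one rule gives
  # p = 1 / (n_perm + 1); 9999 permutations resolve p to 1e-4
  tr <- simulate_tree(40, seed = 17)
  x <- simulate_bm_traits(tr, 1, rate = 5, seed = 18)[, 1]
  r <- permutation_test(x, tr, n_permutations = 9999, seed = 19)
  expect_equal(r$n_permutations, 9999)
  if (all(r$permutation_values < r$observed))
    expect_equal(r$p_value, 1e-4)
  expect_lt(r$p_value, 0.01)
})

test_that("pPCA equals ordinary PCA on an equal-branch star tree", {
  star <- tree_from_text("(A:1,B:1,C:1,D:1,E:1,F:1,G:1);")
  set.seed(43)
  X <- matrix(rnorm(21), 7, 3, dimnames = list(star$tip.label, NULL))
  pp <- phylogenetic_pca(X, star)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(Xc) / 6, symmetric = TRUE)
  expect_equal(pp$eigenvalues, ev$values, tolerance = 1e-10)
  expect_equal(abs(unname(pp$pc_scores)), abs(unname(Xc %*% ev$vectors)),
               tolerance = 1e-10)
  expect_equal(unname(pp$phylogenetic_mean), unname(colMeans(X)),
               tolerance = 1e-12)
  expect_equal(sum(pp$eigenvalues), sum(diag(pp$evolutionary_covariance)),
               tolerance = 1e-10)
})

test_that("pPCA on the 5-taxon fixture matches the GLS oracle and phytools", {
  tr <- tree_from_text("(((A:1,B:1):0.5,C:1.5):0.5,(D:1,E:1):1);")
  set.seed(42)
  X <- matrix(round(rnorm(15), 3), 5, 3,
              dimnames = list(tr$tip.label, paste0("t", 1:3)))
  pp <- phylogenetic_pca(X, tr)
  orc <- ppca_oracle(X, tr)
  expect_equal(pp$eigenvalues, orc$values, tolerance = 1e-10)
  expect_equal(abs(unname(pp$pc_scores)), abs(unname(orc$scores)),
               tolerance = 1e-10)
  expect_equal(unname(pp$phylogenetic_mean), unname(orc$mean),
               tolerance = 1e-10)
  # frozen eigenvalues from phytools::phyl.pca (method = "BM")
  expect_equal(pp$eigenvalues,
               c(1.5992755028, 0.7182343257, 0.3141008157),
               tolerance = 1e-8)
  # frozen first-tip score row from phytools (compared up to sign)
  expect_equal(abs(unname(pp$pc_scores["A", ])),
               abs(c(-0.05323958, 1.4851789, 0.6265820)),
               tolerance = 1e-6)
})

test_that("singular covariance and mismatched tips raise errors", {
  tr <- tree_from_text("((A:0,B:0):1,(C:1,D:1):1);")  # identical rows
  X <- matrix(rnorm(8), 4, 2, dimnames = list(tr$tip.label, NULL))
  expect_error(phylogenetic_pca(X, tr), "singular|branch")
  tr2 <- tree_from_text("((A:1,B:1):1,(C:1,D:1):1);")
  rownames(X) <- c("A", "B", "C", "Z")
  expect_error(phylogenetic_pca(X, tr2), "do not match")
})

test_that("fossil tips graft onto the stem with sensible branch lengths", {
  tr <- simulate_tree(12, seed = 3)
  tr2 <- add_fossil_tip(tr, "CFMR")
  expect_equal(ape::Ntip(tr2), 13)
  expect_true("CFMR" %in% tr2$tip.label)
  C <- phylo_covariance(tr2)
  # stem attachment: the fossil shares no history with the crown tips
  expect_equal(max(abs(C["CFMR", setdiff(colnames(C), "CFMR")])), 0)
  expect_equal(C["CFMR", "CFMR"], mean(diag(phylo_covariance(tr))),
               tolerance = 1e-9)
  expect_error(add_fossil_tip(tr2, "CFMR"), "already present")
})
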