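test_that("phylo_vcv: toy bookkeeping and MRCA brute force", {
  tr <- suppressWarnings(read_tree(text = "((A:1,B:1):1,(C:2,D:2):0);"))
  C <- phylo_vcv(tr)
  expect_equal(C["A", "B"], 1)
  expect_equal(C["A", "A"], 2)
  expect_equal(C["A", "C"], 0)

  C2 <- phylo_vcv(star_tree(5, len = 3))
  expect_equal(unclass(C2), diag(3, 5), ignore_attr = TRUE)

  # brute force: shared depth = (d(root,i) + d(root,j) - d(i,j)) / 2
  tr3 <- simulate_yule_tree(20, 1, seed = 77)
  C3 <- phylo_vcv(tr3)
  n <- 20
  g <- igraph::graph_from_edgelist(apply(tr3$edge, 2, as.character))
  igraph::E(g)$weight <- tr3$edge.length
  root <- as.character(n + 1)
  dd <- igraph::distances(g, v = c(root, as.character(1:n)),
                          to = as.character(1:n))
  for (i in 1:n) for (j in 1:n) {
    expect_equal(C3[tr3$tip.label[i], tr3$tip.label[j]],
                 (dd[1, i] + dd[1, j] - dd[as.character(i), j]) / 2,
                 tolerance = 1e-10)
  }
})

test_that("blomberg_k: star tree gives K = 1 exactly, any trait", {
  tr <- star_tree(8, len = 2.5)
  set.seed(4)
  for (i in 1:5) {
    x <- setNames(rnorm(8), tr$tip.label)
    expect_equal(blomberg_k(tr, x, n_perm = 0)$K, 1, tolerance = 1e-12)
  }
})

test_that("blomberg_k matches an independent matrix-algebra oracle (4 tips)", {
  tr <- toy_tree()
  x <- setNames(c(0, 0, 1, 1), c("A", "B", "C", "D"))
  # hand-constructed covariance of ((A:1,B:1):1,(C:1,D:1):1)
  C <- rbind(c(2, 1, 0, 0), c(1, 2, 0, 0), c(0, 0, 2, 1), c(0, 0, 1, 2))
  iC <- solve(C)
  one <- rep(1, 4)
  a <- drop(t(one) %*% iC %*% x) / drop(t(one) %*% iC %*% one)
  r <- x - a
  mse0 <- sum(r^2) / 3
  mse <- drop(t(r) %*% iC %*% r) / 3
  expected_ratio <- (sum(diag(C)) - 4 / drop(t(one) %*% iC %*% one)) / 3
  k_hand <- (mse0 / mse) / expected_ratio
  expect_equal(blomberg_k(tr, x, n_perm = 0)$K, unname(k_hand),
               tolerance = 1e-12)
})

test_that("blomberg_k is invariant to affine trait transforms", {
  tr <- simulate_yule_tree(15, 1, seed = 8)
  x <- simulate_bm_trait(tr, 1, seed = 9)$species_means
  k0 <- blomberg_k(tr, x, n_perm = 0)$K
  expect_equal(blomberg_k(tr, 3.7 * x - 11, n_perm = 0)$K, k0,
               tolerance = 1e-10)
  expect_equal(blomberg_k(tr, -x, n_perm = 0)$K, k0, tolerance = 1e-10)
  expect_error(blomberg_k(tr, x * 0, n_perm = 0), "no variance")
})

test_that("blomberg_k permutation p is reproducible and +1-corrected", {
  tr <- simulate_yule_tree(12, 1, seed = 14)
  x <- simulate_bm_trait(tr, 1, seed = 15)$species_means
  r1 <- blomberg_k(tr, x, n_perm = 99, seed = 5)
  r2 <- blomberg_k(tr, x, n_perm = 99, seed = 5)
  expect_identical(r1$p_value, r2$p_value)
  expect_gte(r1$p_value, 1 / 100)
})

test_that("blomberg_k_me reduces to blomberg_k when sampling variance is 0", {
  tr <- simulate_yule_tree(10, 1, seed = 21)
  sim <- simulate_bm_trait(tr, 1.5, intraspecific_sd = 0, n_individuals = 3,
                           seed = 22)
  expect_warning(
    r_me <- blomberg_k_me(tr, sim$individuals, n_perm = 0),
    "falling back")
  r <- blomberg_k(tr, sim$species_means, n_perm = 0)
  expect_equal(r_me$K, r$K, tolerance = 1e-12)
})

test_that("blomberg_k_me handles singletons and deflates noisy species", {
  tr <- simulate_yule_tree(12, 1, seed = 31)
  sim <- simulate_bm_trait(tr, 1, intraspecific_sd = 0.4, n_individuals = 4,
                           seed = 32)
  ind <- sim$individuals
  # make one species a singleton -> pooled within-species variance message
  ind <- ind[!(ind$species == tr$tip.label[1] & ind$individual > 1), ]
  expect_message(r <- blomberg_k_me(tr, ind, n_perm = 0), "pooled")
  expect_true(is.finite(r$K) && is.finite(r$sigma))
})

test_that("fitch_steps: canonical counts, polytomies, exhaustive oracle", {
  tr <- read_tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(fitch_steps(tr, c(A = "0", B = "0", C = "1", D = "1")), 1L)
  expect_equal(fitch_steps(tr, c(A = "0", B = "1", C = "0", D = "1")), 2L)
  expect_equal(fitch_steps(tr, c(A = "x", B = "x", C = "x", D = "x")), 0L)
  expect_error(fitch_steps(tr, c(A = "0", B = "0", C = "1")), "unlabelled")

  # polytomy: Hartigan rule
  star <- star_tree(5)
  st <- setNames(c("a", "a", "a", "b", "b"), star$tip.label)
  expect_equal(fitch_steps(star, st), 2L)

  set.seed(51)
  for (rep in 1:15) {
    n <- sample(4:8, 1)
    tr <- simulate_yule_tree(n, 1, seed = rep)
    if (rep %% 3 == 0) tr <- ape::di2multi(tr, tol = 0.3)  # force polytomies
    k <- sample(2:3, 1)
    st <- setNames(sample(letters[1:k], n, replace = TRUE), tr$tip.label)
    expect_equal(fitch_steps(tr, st), fitch_oracle(tr, st),
                 info = sprintf("rep %d", rep))
  }
})

test_that("fitch_steps agrees with phangorn on binary trees", {
  set.seed(53)
  for (rep in 1:10) {
    n <- sample(6:14, 1)
    tr <- simulate_yule_tree(n, 1, seed = 100 + rep)
    st <- setNames(sample(c("a", "b", "c"), n, replace = TRUE), tr$tip.label)
    pd <- phangorn::phyDat(matrix(st[tr$tip.label], ncol = 1,
                                  dimnames = list(tr$tip.label, NULL)),
                           type = "USER", levels = c("a", "b", "c"))
    expect_equal(fitch_steps(tr, st), as.integer(phangorn::fitch(tr, pd)))
  }
})

test_that("maddison_slatkin: clustered states significant, degenerate handled", {
  tr <- read_tree(text = paste0(
    "(((t1:1,t2:1):1,(t3:1,t4:1):1):1,",
    "((t5:1,t6:1):1,(t7:1,t8:1):1):1);"))
  # 8-tip balanced: left clade all "a", right all "b" -> 1 step
  st <- setNames(rep(c("a", "b"), each = 4), paste0("t", 1:8))
  r <- maddison_slatkin(tr, st, n_perm = 999, seed = 3)
  expect_equal(r$observed_steps, 1L)
  expect_lte(r$p_value, 0.05)

  expect_warning(r2 <- maddison_slatkin(tr, setNames(rep("a", 8),
                                                     paste0("t", 1:8)),
                                        n_perm = 99, seed = 1), "single-state")
  expect_equal(r2$p_value, 1)
  expect_gte(r$p_value, 1 / 1000)   # +1 correction: never 0
})

test_that("k_per_atoll prunes per atoll and refuses < 4 species", {
  sim <- simulate_metacommunity(scenario_config(n_species = 12, seed = 61))
  tab <- k_per_atoll(sim$tree, sim$community,
                     setNames(as.numeric(sim$trait), names(sim$trait)),
                     n_perm = 99, seed = 2)
  expect_equal(nrow(tab), nlevels(sim$community$atoll_of_site))
  expect_true(all(tab$testable == (tab$n_species >= 4)))
  expect_true(all(is.finite(tab$K[tab$testable])))

  # tiny community: single atoll with 2 species -> not testable
  df <- data.frame(atoll = "a1", site = "s1", colony = c("c1", "c1"),
                   species = c("s1", "s2"), count = c(3, 2))
  comm <- nested_community(df)
  tr <- simulate_yule_tree(5, 1, seed = 1)
  tr$tip.label <- paste0("s", 1:5)
  tab2 <- k_per_atoll(tr, comm, setNames(1:5, paste0("s", 1:5)),
                      n_perm = 99, seed = 3)
  expect_false(tab2$testable[1])
  expect_true(is.na(tab2$K[1]))
})
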