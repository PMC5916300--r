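test_that("quadratic_entropy closed forms", {
  D <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(quadratic_entropy(c(a = 1, b = 0), D), 0)
  expect_equal(quadratic_entropy(c(a = 0.5, b = 0.5), D), 0.5)
  expect_equal(quadratic_entropy(c(a = 0.5, b = 0.5), D, halve = TRUE), 0.25)

  # Simpson identity: d == 1 off-diagonal -> QE = 1 - sum p^2
  set.seed(3)
  n <- 6
  D1 <- matrix(1, n, n) - diag(n)
  dimnames(D1) <- list(paste0("s", 1:n), paste0("s", 1:n))
  for (i in 1:100) {
    p <- rexp(n); p <- p / sum(p)
    expect_equal(quadratic_entropy(p, D1), 1 - sum(p^2), tolerance = 1e-12)
  }

  expect_error(quadratic_entropy(c(x = 1), D), "not in D")
})

test_that("pool_evenly weights units evenly however unbalanced", {
  # two colonies (1,0) and (0,1) in one site -> site vector (0.5, 0.5)
  df <- data.frame(atoll = "a", site = "s",
                   colony = c("c1", "c2"), species = c("sp1", "sp2"),
                   count = c(5, 3))
  pools <- pool_evenly(nested_community(df))
  expect_equal(unname(pools$site[1, ]), c(0.5, 0.5))

  # unbalanced atolls still weighted 1/2 each
  df2 <- rbind(
    data.frame(atoll = "a1", site = "s1", colony = "c1",
               species = "sp1", count = 10),
    data.frame(atoll = "a2", site = paste0("s", 1:3), colony = "c1",
               species = "sp2", count = c(1, 1, 1)))
  pools2 <- pool_evenly(nested_community(df2))
  expect_equal(unname(pools2$archipelago), c(0.5, 0.5))

  # identical colonies everywhere -> every pooled vector equals them
  df3 <- expand.grid(atoll = c("a1", "a2"), site = c("s1", "s2"),
                     colony = c("c1", "c2"), species = c("x", "y"),
                     stringsAsFactors = FALSE)
  df3$count <- ifelse(df3$species == "x", 3, 1)
  pools3 <- pool_evenly(nested_community(df3))
  expect_true(all(abs(pools3$colony[, "x"] - 0.75) < 1e-12))
  expect_equal(unname(pools3$archipelago), c(0.75, 0.25))
})

test_that("apportion_qe: degenerate designs behave as expected", {
  # identical colonies -> all betas 0, gamma = alpha
  df <- expand.grid(atoll = c("a1", "a2"), site = c("s1", "s2"),
                    colony = c("c1", "c2"), species = c("x", "y"),
                    stringsAsFactors = FALSE)
  df$count <- ifelse(df$species == "x", 3, 1)
  D <- matrix(1, 2, 2) - diag(2); dimnames(D) <- list(c("x", "y"), c("x", "y"))
  comp <- apportion_qe(nested_community(df), D)
  expect_equal(unname(comp[2:4]), rep(0, 3), tolerance = 1e-12)
  expect_equal(comp[["gamma"]], comp[["alpha_within_colony"]])

  # monodominant atolls with d == 1 -> alpha 0, beta_atolls = gamma
  df2 <- rbind(
    data.frame(atoll = "a1", site = "s1", colony = "c1", species = "x",
               count = 7),
    data.frame(atoll = "a2", site = "s1", colony = "c1", species = "y",
               count = 2))
  comp2 <- apportion_qe(nested_community(df2), D)
  expect_equal(comp2[["alpha_within_colony"]], 0)
  expect_equal(comp2[["beta_colonies_within_sites"]], 0)
  expect_equal(comp2[["beta_atolls"]], comp2[["gamma"]])
  expect_equal(comp2[["gamma"]], 0.5)  # p = (1/2, 1/2), d = 1
})

test_that("apportion_qe equals the recursive from-scratch oracle", {
  set.seed(11)
  for (rep in 1:20) {
    ds <- random_dataset(n_species = sample(5:10, 1), A = sample(2:4, 1))
    comp <- apportion_qe(ds$community, ds$D)
    oracle <- apportion_oracle(ds$community, ds$D)
    expect_equal(comp, oracle, tolerance = 1e-10)
    expect_equal(sum(comp[1:4]), comp[["gamma"]], tolerance = 1e-10)
  }
})

test_that("beta components are non-negative for Euclidean distances", {
  set.seed(13)
  for (rep in 1:50) {
    ds <- random_dataset(n_species = sample(5:12, 1), A = sample(2:4, 1),
                         euclidean = TRUE)
    comp <- apportion_qe(ds$community, ds$D)
    expect_true(all(comp[2:4] >= -1e-10))
  }
})

test_that("statistics are invariant to a consistent species relabelling", {
  set.seed(17)
  ds <- random_dataset(8, 2)
  comp <- apportion_qe(ds$community, ds$D)
  # relabel species consistently in community records and D
  map <- setNames(paste0("zz", sample(8)), ds$community$species)
  rec <- ds$community$records
  df <- data.frame(atoll = rec$atoll,
                   site = sub("^[^/]*/", "", rec$site),
                   colony = sub("^.*/", "", rec$colony),
                   species = unname(map[rec$species]), count = rec$count)
  D2 <- ds$D
  dimnames(D2) <- list(unname(map[rownames(ds$D)]),
                       unname(map[colnames(ds$D)]))
  comp2 <- apportion_qe(nested_community(df), D2)
  expect_equal(comp2, comp, tolerance = 1e-12)
})

test_that("ses_test is seed-reproducible and its nulls are level-specific", {
  set.seed(23)
  ds <- random_dataset(8, 3)
  for (lv in c("atolls", "sites_within_atolls", "colonies_within_sites")) {
    r1 <- ses_test(ds$community, ds$D, lv, n_perm = 99, seed = 42)
    r2 <- ses_test(ds$community, ds$D, lv, n_perm = 99, seed = 42)
    expect_identical(r1$null, r2$null)       # bit reproducible
    r3 <- ses_test(ds$community, ds$D, lv, n_perm = 199, seed = 43)
    # different seeds agree within Monte-Carlo error
    expect_lt(abs(r1$null_mean - r3$null_mean),
              6 * (r1$null_sd + r3$null_sd + 1e-12) / sqrt(99) + 1e-12)
    expect_equal(r1$p_value,
                 (1 + sum(abs(r1$null - r1$null_mean) >=
                            abs(r1$observed - r1$null_mean))) / 100)
  }
})

test_that("ses_test degenerate null: identical colonies everywhere", {
  df <- expand.grid(atoll = c("a1", "a2"), site = c("s1", "s2"),
                    colony = c("c1", "c2"), species = c("x", "y"),
                    stringsAsFactors = FALSE)
  df$count <- ifelse(df$species == "x", 30, 10)
  D <- matrix(1, 2, 2) - diag(2); dimnames(D) <- list(c("x", "y"), c("x", "y"))
  comm <- nested_community(df)
  r <- ses_test(comm, D, "atolls", n_perm = 99, seed = 1)
  expect_true(is.na(r$ses))       # undefined, not coerced to 0
  expect_equal(r$p_value, 1)
})

test_that("tqe_pqe_report: identical matrices give identical rows; shape fixed", {
  set.seed(29)
  ds <- random_dataset(8, 2)
  D2 <- ds$D
  rep <- tqe_pqe_report(ds$community, list(gene_a = ds$D, gene_b = D2),
                        n_perm = 99, seed = 7)
  expect_equal(rep[1, -1], rep[2, -1], ignore_attr = TRUE)
  expect_named(rep, c("source",
                      "ses_atolls", "p_atolls",
                      "ses_sites_within_atolls", "p_sites_within_atolls",
                      "ses_colonies_within_sites",
                      "p_colonies_within_sites"))
})

test_that("tqe_pqe_report prunes the community for genes missing species", {
  set.seed(31)
  ds <- random_dataset(8, 2)
  keep <- ds$community$species[1:6]
  Dsub <- ds$D[keep, keep]
  rep <- tqe_pqe_report(ds$community, list(full = ds$D, partial = Dsub),
                        n_perm = 99, seed = 5)
  expect_equal(nrow(rep), 2)
  expect_true(all(is.finite(as.numeric(rep[2, -1]))))
})
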