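test_that("gower_distance matches the definition on canonical cases", {
  # extremes: full quantitative range + nominal mismatch -> 1
  tr <- data.frame(size = c(2, 10), cat = c("X", "Y"),
                   row.names = c("u", "v"), stringsAsFactors = FALSE)
  D <- gower_distance(tr)
  expect_equal(D["u", "v"], 1.0)

  # identical rows -> 0
  tr2 <- data.frame(size = c(5, 5), cat = c("X", "X"),
                    row.names = c("u", "v"))
  expect_equal(gower_distance(tr2)["u", "v"], 0)
})

test_that("gower_distance equals the per-pair loop oracle on mixed traits", {
  set.seed(42)
  for (rep in 1:5) {
    tr <- data.frame(
      q1 = rnorm(5), q2 = c(runif(4), NA),
      cat = sample(letters[1:3], 5, replace = TRUE),
      row.names = paste0("sp", 1:5), stringsAsFactors = FALSE)
    D <- gower_distance(tr)
    O <- gower_oracle(tr, c("quantitative", "quantitative", "nominal"))
    expect_equal(unclass(D)[1:5, 1:5], O, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("gower_distance error handling: no-shared-trait pair, constant trait", {
  tr <- data.frame(q1 = c(1, NA, 2), q2 = c(NA, 1, 2),
                   row.names = paste0("s", 1:3))
  expect_error(gower_distance(tr), "no shared non-missing trait")
  trc <- data.frame(q1 = c(1, 1, 1), q2 = c(0, 1, 2),
                    row.names = paste0("s", 1:3))
  expect_warning(D <- gower_distance(trc), "constant")
  expect_equal(D["s1", "s3"], 1)  # only q2 left, full range
})

test_that("p_distance implements pairwise deletion of ambiguous sites", {
  al <- structure(c(a = "ACGT", b = "ACGA"), gene = "g")
  D <- p_distance(al)
  expect_equal(D["a", "b"], 0.25)
  expect_equal(attr(D, "n_sites")[1, 2], 4)

  al2 <- structure(c(a = "ACG-", b = "ACGA"), gene = "g")
  D2 <- p_distance(al2)
  expect_equal(D2["a", "b"], 0)
  expect_equal(attr(D2, "n_sites")[1, 2], 3)

  al3 <- structure(c(a = "ACGT", b = "ACGT"), gene = "g")
  expect_equal(p_distance(al3)["a", "b"], 0)

  # N and IUPAC codes are missing too
  al4 <- structure(c(a = "ANRT", b = "AAGT"), gene = "g")
  expect_equal(attr(p_distance(al4), "n_sites")[1, 2], 2)
})

test_that("p_distance equals a per-pair loop oracle and is column-permutation invariant", {
  set.seed(7)
  bases <- c("A", "C", "G", "T", "-", "N")
  seqs <- vapply(1:6, function(i)
    paste(sample(bases, 30, replace = TRUE, prob = c(rep(.22, 4), .06, .06)),
          collapse = ""), "")
  names(seqs) <- paste0("sp", 1:6)
  al <- structure(seqs, gene = "g")
  D <- suppressWarnings(p_distance(al))
  M <- do.call(rbind, strsplit(seqs, ""))
  for (i in 1:5) for (j in (i + 1):6) {
    ok <- M[i, ] %in% c("A", "C", "G", "T") & M[j, ] %in% c("A", "C", "G", "T")
    expected <- if (sum(ok) > 0) sum(M[i, ok] != M[j, ok]) / sum(ok) else NA
    expect_equal(unname(D[i, j]), expected)
  }
  perm <- sample(30)
  seqs_p <- vapply(seqs, function(s)
    paste(strsplit(s, "")[[1]][perm], collapse = ""), "")
  al_p <- structure(seqs_p, gene = "g")
  expect_equal(unclass(suppressWarnings(p_distance(al_p))), unclass(D),
               ignore_attr = TRUE)
})

test_that("concat_p_distance pools sites across genes", {
  # gene 1: 4 comparable sites, 0 differences; gene 2: 4 sites, 2 diffs
  g1 <- structure(c(a = "ACGT", b = "ACGT"), gene = "g1")
  g2 <- structure(c(a = "ACGT", b = "ACAA"), gene = "g2")
  D <- concat_p_distance(list(g1 = g1, g2 = g2))
  expect_equal(D["a", "b"], 2 / 8)  # site-count arithmetic: (0+2)/(4+4)

  # distances 0.0 and 0.5 on equal-length comparable regions -> 0.25
  h1 <- structure(c(a = "AAAA", b = "AAAA"), gene = "h1")
  h2 <- structure(c(a = "AAAA", b = "TTAA"), gene = "h2")
  expect_equal(concat_p_distance(list(h1, h2))["a", "b"], 0.25)

  # a species missing from gene 2 -> distance from gene 1 sites only
  m2 <- structure(c(a = "ACGT"), gene = "m2")
  Dm <- concat_p_distance(list(g1 = g1, m2 = m2))
  expect_equal(Dm["a", "b"], 0)
  expect_equal(attr(Dm, "n_sites")["a", "b"], 4)

  # single gene: identical to p_distance
  expect_equal(unclass(concat_p_distance(list(g2))["a", "b"]),
               unclass(p_distance(g2)["a", "b"]))
})

test_that("patristic_distance matches path sums and a graph oracle", {
  D <- patristic_distance(toy_tree())
  expect_equal(D["A", "B"], 2)
  expect_equal(D["A", "C"], 4)
  expect_true(all(patristic_distance(star_tree(3))[upper.tri(diag(3))] == 2))

  tr <- simulate_yule_tree(20, 1, seed = 99)
  D2 <- patristic_distance(tr)
  g <- igraph::graph_from_edgelist(apply(tr$edge, 2, as.character))
  igraph::E(g)$weight <- tr$edge.length
  sp <- igraph::distances(g, v = as.character(1:20),
                          to = as.character(1:20))
  dimnames(sp) <- list(tr$tip.label, tr$tip.label)
  expect_equal(unclass(D2), sp[rownames(D2), colnames(D2)],
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("is_euclidean classifies canonical cases", {
  ones <- matrix(1, 4, 4) - diag(4)
  dimnames(ones) <- list(paste0("s", 1:4), paste0("s", 1:4))
  expect_true(is_euclidean(ones)$euclidean)

  tr <- simulate_yule_tree(10, 1, seed = 5)
  D <- sqrt(patristic_distance(tr))
  expect_true(is_euclidean(D)$euclidean)

  # triangle-inequality violation cannot embed
  bad <- matrix(c(0, 1, 3, 1, 0, 1, 3, 1, 0), 3)
  dimnames(bad) <- list(paste0("s", 1:3), paste0("s", 1:3))
  res <- is_euclidean(bad)
  expect_false(res$euclidean)
  expect_lt(res$min_eigenvalue, 0)
})

test_that("all constructors yield symmetric zero-diagonal bounded matrices", {
  set.seed(1)
  for (rep in 1:200) {
    n <- sample(3:7, 1)
    tr <- data.frame(q = rnorm(n),
                     cat = sample(letters[1:2], n, replace = TRUE),
                     row.names = paste0("s", 1:n))
    D <- gower_distance(tr)
    expect_equal(D, t(D), ignore_attr = TRUE)
    expect_true(all(diag(D) == 0))
    expect_true(all(D >= 0 & D <= 1 + 1e-12))
  }
  for (rep in 1:200) {
    n <- sample(3:6, 1)
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T", "-"), 12, replace = TRUE),
            collapse = ""), "")
    names(seqs) <- paste0("s", 1:n)
    D <- suppressWarnings(p_distance(structure(seqs, gene = "g")))
    off <- D[upper.tri(D)]
    expect_true(all(is.na(off) | (off >= 0 & off <= 1)))
    expect_equal(D, t(D), ignore_attr = TRUE)
  }
})

test_that("distance CSV round trip", {
  D <- gower_distance(data.frame(q = c(1, 2, 4),
                                 row.names = paste0("s", 1:3)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_distance(D, f)
  D2 <- read_distance(f)
  expect_equal(unclass(D2), unclass(D), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(D2, "source"), "gower")
})
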