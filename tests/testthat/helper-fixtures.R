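# Fixtures are built in code; nothing is read from disk except what a
# test writes to tempdir() itself.

toy_tree <- function() reefQE::read_tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

star_tree <- function(n = 8, len = 1) {
  reefQE::read_tree(text = paste0(
    "(", paste(sprintf("t%d:%g", seq_len(n), len), collapse = ","), ");"))
}

# 2 atolls x 2 sites x 2 colonies x 3 species toy design
toy_community_df <- function() {
  expand <- expand.grid(atoll = c("A1", "A2"), site = c("s1", "s2"),
                        colony = c("c1", "c2"),
                        species = c("sp1", "sp2", "sp3"),
                        stringsAsFactors = FALSE)
  expand$count <- seq_len(nrow(expand)) %% 4 + 1
  expand
}

# random unbalanced nested community + random bounded distance matrix
random_dataset <- function(n_species, A, max_sites = 6, max_colonies = 4,
                           euclidean = FALSE) {
  sp <- paste0("sp", seq_len(n_species))
  recs <- list()
  for (a in seq_len(A)) {
    for (s in seq_len(sample.int(max_sites, 1))) {
      for (cc in seq_len(sample.int(max_colonies, 1))) {
        n_ind <- sample(5:40, 1)
        counts <- tabulate(sample.int(n_species, n_ind, replace = TRUE),
                           nbins = n_species)
        nz <- which(counts > 0)
        recs[[length(recs) + 1]] <- data.frame(
          atoll = paste0("a", a), site = paste0("s", s),
          colony = paste0("c", cc), species = sp[nz], count = counts[nz],
          stringsAsFactors = FALSE)
      }
    }
  }
  comm <- suppressWarnings(reefQE::nested_community(do.call(rbind, recs)))
  if (euclidean) {
    pts <- matrix(rnorm(n_species * 3), n_species)
    D <- as.matrix(stats::dist(pts))
  } else {
    D <- matrix(runif(n_species^2), n_species)
    D <- (D + t(D)) / 2
    diag(D) <- 0
  }
  dimnames(D) <- list(sp, sp)
  list(community = comm, D = D)
}

# independent per-pair Gower oracle, straight from the definition
gower_oracle <- function(traits, kinds) {
  sp <- rownames(traits)
  n <- length(sp)
  ranges <- lapply(traits, function(col)
    if (is.numeric(col)) diff(range(col, na.rm = TRUE)) else NA)
  d <- matrix(0, n, n, dimnames = list(sp, sp))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- 0; den <- 0
    for (t in seq_along(traits)) {
      xi <- traits[i, t]; xj <- traits[j, t]
      if (is.na(xi) || is.na(xj)) next
      if (kinds[t] == "quantitative") {
        if (ranges[[t]] == 0) next
        s <- abs(xi - xj) / ranges[[t]]
      } else {
        s <- as.numeric(xi != xj)
      }
      num <- num + s; den <- den + 1
    }
    d[i, j] <- num / den
  }
  d
}

# from-scratch even-weighted Rao decomposition, computed recursively from
# the records table (independent of the package's matrix engine)
apportion_oracle <- function(comm, D) {
  rec <- comm$records
  qe <- function(p) {
    p <- p / sum(p)
    drop(t(p) %*% D[names(p), names(p)] %*% p)
  }
  sp <- comm$species
  vec <- function(df) {
    v <- setNames(numeric(length(sp)), sp)
    agg <- tapply(df$count, df$species, sum)
    v[names(agg)] <- agg
    v / sum(v)
  }
  atolls <- unique(rec$atoll)
  alpha <- 0; beta_c <- 0; beta_s <- 0
  atoll_vecs <- list()
  for (a in atolls) {
    ra <- rec[rec$atoll == a, ]
    sites <- unique(ra$site)
    site_vecs <- list()
    a_alpha <- 0; a_beta_c <- 0
    for (s in sites) {
      rs <- ra[ra$site == s, ]
      colonies <- unique(rs$colony)
      cvecs <- lapply(colonies, function(cc) vec(rs[rs$colony == cc, ]))
      svec <- Reduce(`+`, cvecs) / length(cvecs)
      site_vecs[[s]] <- svec
      mean_cq <- mean(vapply(cvecs, qe, 0))
      a_alpha <- a_alpha + mean_cq
      a_beta_c <- a_beta_c + (qe(svec) - mean_cq)
    }
    avec <- Reduce(`+`, site_vecs) / length(site_vecs)
    atoll_vecs[[a]] <- avec
    alpha <- alpha + a_alpha / length(sites)
    beta_c <- beta_c + a_beta_c / length(sites)
    beta_s <- beta_s + (qe(avec) - mean(vapply(site_vecs, qe, 0)))
  }
  gvec <- Reduce(`+`, atoll_vecs) / length(atolls)
  A <- length(atolls)
  c(alpha_within_colony = alpha / A,
    beta_colonies_within_sites = beta_c / A,
    beta_sites_within_atolls = beta_s / A,
    beta_atolls = qe(gvec) - mean(vapply(atoll_vecs, qe, 0)),
    gamma = qe(gvec))
}

# exhaustive small-parsimony oracle: minimum changes over every ancestral
# state assignment
fitch_oracle <- function(tree, states) {
  states <- states[tree$tip.label]
  alph <- sort(unique(states))
  ntip <- length(tree$tip.label)
  internals <- (ntip + 1):(ntip + tree$Nnode)
  grid <- do.call(expand.grid,
                  rep(list(alph), length(internals)))
  best <- Inf
  edge <- tree$edge
  node_state <- character(ntip + tree$Nnode)
  node_state[seq_len(ntip)] <- states
  for (r in seq_len(nrow(grid))) {
    node_state[internals] <- as.character(unlist(grid[r, ]))
    changes <- sum(node_state[edge[, 1]] != node_state[edge[, 2]])
    best <- min(best, changes)
  }
  best
}

write_fasta <- function(seqs, path) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  path
}
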