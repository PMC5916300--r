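# Seeded synthetic-data generators: Yule trees, Brownian and Mk trait
# evolution with intraspecific replicates, noisy-patristic gene distances,
# and nested metacommunities assembled under neutral, environmental
# filtering or limiting-similarity regimes. Defaults mirror the field
# design the package targets: 4-5 atolls, 4-8 sites per atoll, 2-4
# colonies per site, ~20 individuals per colony, 15-20 species.

#' Simulate a pure-birth (Yule) tree
#'
#' Forward simulation: lineages split independently at rate `birth_rate`;
#' the process stops when `n` tips exist and all pendant branches are
#' extended to the stopping time, so the tree is ultrametric. Bit
#' reproducible per seed.
#'
#' @param n number of tips (>= 3).
#' @param birth_rate per-lineage speciation rate (> 0).
#' @param seed integer seed.
#' @return [ape::phylo] with tips `s1..sn`.
#' @export
simulate_yule_tree <- function(n, birth_rate = 1, seed) {
  if (n < 3) stop("n must be >= 3")
  if (birth_rate <= 0) stop("birth_rate must be > 0")
  if (missing(seed)) stop("seed is mandatory")
  withr_seed(seed, {
    # node: list(children = indices or NULL, time = birth time)
    nodes <- list(list(children = NULL, time = 0))
    live <- 1L
    t_now <- 0
    while (length(live) < n) {
      k <- length(live)
      t_now <- t_now + stats::rexp(1, rate = birth_rate * k)
      pick <- live[sample.int(k, 1)]
      c1 <- length(nodes) + 1L
      c2 <- length(nodes) + 2L
      nodes[[c1]] <- list(children = NULL, time = t_now)
      nodes[[c2]] <- list(children = NULL, time = t_now)
      nodes[[pick]]$children <- c(c1, c2)
      live <- c(setdiff(live, pick), c1, c2)
    }
    t_end <- t_now + stats::rexp(1, rate = birth_rate * n)
    tip_counter <- 0
    root_kids <- nodes[[1]]$children
    build <- function(i, parent_time) {
      nd <- nodes[[i]]
      if (is.null(nd$children)) {
        tip_counter <<- tip_counter + 1
        sprintf("s%d:%.10g", tip_counter, t_end - parent_time)
      } else {
        kids <- vapply(nd$children, build, "", parent_time = nd$time)
        sprintf("(%s):%.10g", paste(kids, collapse = ","),
                nd$time - parent_time)
      }
    }
    # the crown starts at the first split; no stem edge
    crown_time <- nodes[[root_kids[1]]]$time
    txt <- sprintf("(%s);", paste(
      vapply(root_kids, build, "", parent_time = crown_time),
      collapse = ","))
    ape::read.tree(text = txt)
  })
}

#' Simulate a Brownian-motion trait with intraspecific replicates
#'
#' Species means evolve by Brownian motion along the tree (increment
#' variance `sigma2 * branch length`); each species then yields
#' `n_individuals` measurements with Gaussian noise of the given SD.
#'
#' @param tree [ape::phylo] with branch lengths.
#' @param sigma2 Brownian rate (> 0, per unit branch length).
#' @param root_value trait value at the root.
#' @param intraspecific_sd within-species SD of individual measurements.
#' @param n_individuals individuals per species.
#' @param seed integer seed.
#' @return list: `species_means` (named vector, tip order) and
#'   `individuals` (data frame `species`/`individual`/`value`).
#' @export
simulate_bm_trait <- function(tree, sigma2, root_value = 0,
                              intraspecific_sd = 0, n_individuals = 1,
                              seed) {
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  if (missing(seed)) stop("seed is mandatory")
  withr_seed(seed, {
    ntip <- length(tree$tip.label)
    nnode <- ntip + tree$Nnode
    val <- numeric(nnode)
    root <- ntip + 1L
    val[root] <- root_value
    tr <- stats::reorder(tree, "cladewise")  # parents before children
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      len <- tr$edge.length[e]
      val[ch] <- val[par] + stats::rnorm(1, 0, sqrt(sigma2 * len))
    }
    means <- stats::setNames(val[seq_len(ntip)], tree$tip.label)
    ind <- data.frame(
      species = rep(tree$tip.label, each = n_individuals),
      individual = rep(seq_len(n_individuals), times = ntip),
      value = rep(means, each = n_individuals) +
        stats::rnorm(ntip * n_individuals, 0, intraspecific_sd),
      stringsAsFactors = FALSE)
    list(species_means = means, individuals = ind)
  })
}

#' Simulate a symmetric Mk discrete trait
#'
#' Continuous-time Markov chain with `k` states and equal exchange rates
#' `rate` along each branch (the k-state Jukes-Cantor). The root state is
#' uniform. Transition probability over a branch of length `t`:
#' `P(same) = 1/k + (1 - 1/k) exp(-k * rate * t)`.
#'
#' @param tree [ape::phylo] with branch lengths.
#' @param k_states number of states (>= 2); states are `"st1".."stk"`.
#' @param rate per-pair exchange rate (>= 0).
#' @param seed integer seed.
#' @return named character vector of tip states.
#' @export
simulate_mk_discrete <- function(tree, k_states = 4, rate = 0.5, seed) {
  if (k_states < 2) stop("k_states must be >= 2")
  if (rate < 0) stop("rate must be >= 0")
  if (missing(seed)) stop("seed is mandatory")
  withr_seed(seed, {
    ntip <- length(tree$tip.label)
    nnode <- ntip + tree$Nnode
    st <- integer(nnode)
    root <- ntip + 1L
    st[root] <- sample.int(k_states, 1)
    tr <- stats::reorder(tree, "cladewise")
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      len <- tr$edge.length[e]
      p_same <- 1 / k_states + (1 - 1 / k_states) *
        exp(-k_states * rate * len)
      if (stats::runif(1) < p_same) {
        st[ch] <- st[par]
      } else {
        st[ch] <- sample(setdiff(seq_len(k_states), st[par]), 1)
      }
    }
    stats::setNames(paste0("st", st[seq_len(ntip)]), tree$tip.label)
  })
}

#' Per-gene distance matrices as noisy patristic perturbations
#'
#' Robustness-harness stand-in for sequence evolution: each "gene" matrix
#' is the tree's patristic distance rescaled to `[0, 1]` plus symmetric
#' Gaussian noise of SD `noise_sd` (relative to the mean distance),
#' truncated at 0. Optionally drops species per gene to emulate failed
#' amplification.
#'
#' @param tree [ape::phylo] with branch lengths.
#' @param n_genes number of matrices.
#' @param noise_sd noise SD as a fraction of the mean off-diagonal
#'   distance (0 = exact copies).
#' @param drop_species optional list (length `n_genes`) of species to drop
#'   per gene.
#' @param seed integer seed.
#' @return named list `gene1..geneN` of distance matrices.
#' @export
simulate_gene_distances <- function(tree, n_genes = 4, noise_sd = 0.1,
                                    drop_species = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory")
  base <- patristic_distance(tree)
  base <- base / max(base)
  mu <- mean(base[upper.tri(base)])
  withr_seed(seed, {
    out <- lapply(seq_len(n_genes), function(g) {
      n <- nrow(base)
      E <- matrix(0, n, n)
      E[upper.tri(E)] <- stats::rnorm(n * (n - 1) / 2, 0, noise_sd * mu)
      E <- E + t(E)
      D <- pmax(base + E, 0)
      D <- as_distance_matrix(D, rownames(base), sprintf("pdist:gene%d", g))
      if (!is.null(drop_species) && length(drop_species) >= g &&
          length(drop_species[[g]])) {
        keep <- setdiff(rownames(D), drop_species[[g]])
        D <- as_distance_matrix(D[keep, keep], keep,
                                attr(D, "source"))
      }
      D
    })
    names(out) <- paste0("gene", seq_len(n_genes))
    out
  })
}

#' Default synthetic scenario configuration
#'
#' The stated world of the generator: 4 atolls, 4-8 sites per atoll, 2-4
#' colonies per site (the unbalanced field design), 20 individuals per
#' colony, a lognormal (0, 1) species-abundance distribution, Brownian
#' body-size-like trait, and a 4-state habitat-like Mk trait.
#'
#' @param n_species species-pool size.
#' @param assembly `"neutral"`, `"filtering"` or `"limiting"`.
#' @param ... overrides for any field of the returned list.
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(n_species = 20,
                            assembly = c("neutral", "filtering", "limiting"),
                            ...) {
  assembly <- match.arg(assembly)
  cfg <- list(
    n_species = n_species,
    birth_rate = 1,
    bm_sigma2 = 1,
    intraspecific_sd = 0.25,
    n_individuals = 5,
    mk_states = 4,
    mk_rate = 0.5,
    A = 4,
    sites_range = c(4L, 8L),
    colonies_range = c(2L, 4L),
    n_per_colony = 20,
    sad_meanlog = 0,
    sad_sdlog = 1,
    assembly = assembly,
    filtering = list(level = "site", optimum_spread = 2, h = 0.35),
    limiting = list(repulsion = 8),
    seed = 1L)
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  class(cfg) <- "scenario_config"
  cfg
}

#' Simulate a nested metacommunity under a named assembly regime
#'
#' * `neutral`: every colony draws its `N` individuals from one shared
#'   lognormal species-abundance distribution, independent of traits.
#' * `filtering`: each unit at `filtering$level` (atoll, site or colony)
#'   draws an environmental optimum `~ N(mean(trait), optimum_spread^2)`;
#'   a species' sampling weight is the SAD weight times
#'   `exp(-(trait - optimum)^2 / (2 h^2))`.
#' * `limiting`: colonies assemble sequentially; each arriving individual
#'   picks species `i` with weight downscaled by
#'   `exp(-repulsion * max_j sim(i, j))` over resident species `j`, with
#'   `sim = 1 - |trait_i - trait_j| / range`.
#'
#' @param config a [scenario_config()].
#' @param tree phylogeny (defaults to a fresh Yule tree).
#' @param trait named species trait vector driving filtering/limiting
#'   (defaults to a fresh Brownian trait on `tree`).
#' @return list: `community` ([nested_community]), `tree`, `trait`,
#'   `truth` (scenario label + drawn design + optima).
#' @export
simulate_metacommunity <- function(config = scenario_config(),
                                   tree = NULL, trait = NULL) {
  cfg <- config
  seed <- cfg$seed
  if (is.null(tree)) {
    tree <- simulate_yule_tree(cfg$n_species, cfg$birth_rate, seed = seed)
  }
  sp <- tree$tip.label
  if (is.null(trait)) {
    trait <- simulate_bm_trait(tree, cfg$bm_sigma2, 0,
                               cfg$intraspecific_sd, cfg$n_individuals,
                               seed = seed + 1)$species_means
  }
  if (!all(sp %in% names(trait))) stop("trait missing species")
  trait <- trait[sp]
  ns <- length(sp)

  withr_seed(seed + 2, {
    sad <- stats::rlnorm(ns, cfg$sad_meanlog, cfg$sad_sdlog)
    sad <- sad / sum(sad)
    # sample() treats a length-1 vector as 1:n; guard against it
    draw_range <- function(rng, k) {
      v <- seq(rng[1], rng[2])
      if (length(v) == 1) rep(v, k) else sample(v, k, replace = TRUE)
    }
    S_a <- draw_range(cfg$sites_range, cfg$A)
    tr_sd <- stats::sd(trait); if (!is.finite(tr_sd) || tr_sd == 0) tr_sd <- 1
    tr_rng <- diff(range(trait)); if (tr_rng == 0) tr_rng <- 1
    recs <- list()
    optima <- list()
    atoll_opt <- stats::rnorm(cfg$A, mean(trait),
                              cfg$filtering$optimum_spread * tr_sd)
    for (a in seq_len(cfg$A)) {
      for (s in seq_len(S_a[a])) {
        site_opt <- stats::rnorm(1, mean(trait),
                                 cfg$filtering$optimum_spread * tr_sd)
        n_col <- draw_range(cfg$colonies_range, 1)
        for (cc in seq_len(n_col)) {
          colony_opt <- stats::rnorm(1, mean(trait),
                                     cfg$filtering$optimum_spread * tr_sd)
          counts <- if (cfg$assembly == "neutral") {
            stats::rmultinom(1, cfg$n_per_colony, sad)[, 1]
          } else if (cfg$assembly == "filtering") {
            opt <- switch(cfg$filtering$level,
                          atoll = atoll_opt[a], site = site_opt,
                          colony = colony_opt)
            w <- sad * exp(-(trait - opt)^2 /
                             (2 * (cfg$filtering$h * tr_sd)^2))
            if (sum(w) == 0) w <- sad
            stats::rmultinom(1, cfg$n_per_colony, w / sum(w))[, 1]
          } else {
            assemble_limiting(sad, trait, tr_rng, cfg$n_per_colony,
                              cfg$limiting$repulsion)
          }
          optima[[length(optima) + 1]] <- data.frame(
            atoll = paste0("atoll", a), site = paste0("site", s),
            colony = paste0("colony", cc),
            optimum = switch(cfg$filtering$level, atoll = atoll_opt[a],
                             site = site_opt, colony = colony_opt))
          nz <- which(counts > 0)
          recs[[length(recs) + 1]] <- data.frame(
            atoll = paste0("atoll", a), site = paste0("site", s),
            colony = paste0("colony", cc), species = sp[nz],
            count = counts[nz], stringsAsFactors = FALSE)
        }
      }
    }
    df <- do.call(rbind, recs)
    comm <- suppressWarnings(nested_community(df))
    list(community = comm, tree = tree, trait = trait,
         truth = list(assembly = cfg$assembly, S_a = S_a, sad = sad,
                      optima = do.call(rbind, optima),
                      config = unclass(cfg)))
  })
}

# sequential repulsive assembly of one colony
assemble_limiting <- function(sad, trait, tr_rng, n, repulsion) {
  ns <- length(sad)
  counts <- integer(ns)
  sim <- 1 - abs(outer(trait, trait, "-")) / tr_rng
  for (ind in seq_len(n)) {
    residents <- which(counts > 0)
    w <- sad
    if (length(residents)) {
      maxsim <- apply(sim[, residents, drop = FALSE], 1, max)
      w <- sad * exp(-repulsion * maxsim)
    }
    if (sum(w) == 0) w <- sad
    pick <- sample.int(ns, 1, prob = w)
    counts[pick] <- counts[pick] + 1L
  }
  counts
}

#' Write a full synthetic scenario to disk
#'
#' Emits `tree.nwk`, `traits.csv` (individual-level), `community.csv` and
#' `truth.json` under `dir`, the on-disk contract consumed by the
#' pipeline.
#'
#' @param config [scenario_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, the list from [simulate_metacommunity()].
#' @export
write_scenario <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_metacommunity(config)
  ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  ind <- simulate_bm_trait(sim$tree, config$bm_sigma2, 0,
                           config$intraspecific_sd, config$n_individuals,
                           seed = config$seed + 1)$individuals
  hab <- simulate_mk_discrete(sim$tree, config$mk_states, config$mk_rate,
                              seed = config$seed + 3)
  ind$carapace_length <- exp(ind$value / max(abs(ind$value)) + 1)
  traits <- data.frame(species = ind$species,
                       carapace_length = ind$carapace_length,
                       habitat_assoc = habitat_levels[
                         (match(hab[ind$species], unique(hab)) - 1) %%
                           length(habitat_levels) + 1],
                       stringsAsFactors = FALSE)
  utils::write.csv(traits, file.path(dir, "traits.csv"), row.names = FALSE)
  write_community(sim$community, file.path(dir, "community.csv"))
  tr <- sim$truth
  tr$optima <- NULL
  jsonlite::write_json(tr, file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(sim)
}
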