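# Phylogenetic signal statistics: Blomberg's K for quantitative traits
# (with and without intraspecific measurement error) and the
# Maddison-Slatkin parsimony randomization test for nominal traits.

#' Brownian-motion phylogenetic covariance matrix
#'
#' `C[i, j]` is the shared root-to-MRCA branch length of tips i and j;
#' `C[i, i]` is the root-to-tip depth. Backed by [ape::vcv.phylo()].
#'
#' @param tree rooted [ape::phylo] with non-negative branch lengths.
#' @return symmetric positive semidefinite matrix, tips in tree order.
#' @export
phylo_vcv <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  ape::vcv.phylo(tree)
}

k_statistic <- function(x, C, invC = solve(C)) {
  n <- length(x)
  one <- rep(1, n)
  iC1 <- invC %*% one
  s1 <- sum(iC1)                       # 1' C^-1 1
  ahat <- sum(crossprod(x, iC1)) / s1  # GLS phylogenetic mean
  r <- x - ahat
  mse0 <- sum(r^2) / (n - 1)
  mse <- drop(crossprod(r, invC %*% r)) / (n - 1)
  expected <- (sum(diag(C)) - n / s1) / (n - 1)
  (mse0 / mse) / expected
}

#' Blomberg's K statistic for a quantitative trait
#'
#' `K = (MSE0/MSE) / E[MSE0/MSE]_BM` where `MSE0` is the trait variance
#' about the GLS phylogenetic mean and `MSE` the phylogenetically corrected
#' error. `K = 1` is the Brownian-motion expectation; `K < 1` means less
#' signal than Brownian, `K > 1` more. The p-value permutes trait values
#' across tips and is one-tailed on large K (signal = relatives more
#' similar than chance).
#'
#' @param tree rooted [ape::phylo] with branch lengths.
#' @param x named vector of species trait values (one per tip), or unnamed
#'   in tip order.
#' @param n_perm number of tip-label permutations; `0` skips the test.
#' @param seed integer seed (required when `n_perm > 0`).
#' @return list of class `k_result`: `K`, `sigma` (`NA`; see
#'   [blomberg_k_me()]), `p_value`, `n_perm`, `seed`,
#'   `used_measurement_error = FALSE`.
#' @export
blomberg_k <- function(tree, x, n_perm = 999, seed = NULL) {
  C <- phylo_vcv(tree)
  x <- align_trait(x, tree)
  n <- length(x)
  if (n < 4) stop("need >= 4 species")
  if (stats::var(x) == 0) stop("no variance: trait is constant")
  invC <- robust_inverse(C)
  k_obs <- k_statistic(x, C, invC)
  p <- NA_real_
  if (n_perm > 0) {
    if (is.null(seed)) stop("seed required when n_perm > 0")
    k_null <- withr_seed(seed, {
      vapply(seq_len(n_perm), function(i)
        k_statistic(x[sample.int(n)], C, invC), numeric(1))
    })
    p <- (1 + sum(k_null >= k_obs)) / (n_perm + 1)
  }
  structure(list(K = k_obs, sigma = NA_real_, p_value = p,
                 n_perm = n_perm, seed = seed,
                 used_measurement_error = FALSE),
            class = "k_result")
}

robust_inverse <- function(C) {
  out <- tryCatch(solve(C), error = function(e) NULL)
  if (is.null(out)) {
    message("covariance singular; adding 1e-10 jitter to the diagonal")
    out <- solve(C + diag(1e-10, nrow(C)))
  }
  out
}

align_trait <- function(x, tree) {
  if (!is.null(names(x))) {
    names(x) <- normalize_species(names(x))
    miss <- setdiff(tree$tip.label, names(x))
    if (length(miss)) stop("no trait value for tip(s): ",
                           paste(miss, collapse = ", "))
    x <- x[tree$tip.label]
  } else if (length(x) != length(tree$tip.label)) {
    stop("trait length does not match tips")
  }
  if (any(!is.finite(x))) stop("non-finite trait value")
  x
}

#' Blomberg's K with intraspecific measurement error
#'
#' Species means carry sampling variance `m_i = s_i^2 / n_i` from the
#' within-species replicates. The Brownian rate `sigma^2` is estimated by
#' maximum likelihood under `xbar ~ N(a 1, sigma^2 C + diag(m))` (the GLS
#' mean `a` is profiled out) and K is computed with `C` replaced by
#' `C + diag(m) / sigma^2`. Species with a single individual receive the
#' pooled within-species variance (logged via a message). With all
#' `m_i = 0` the function reduces exactly to [blomberg_k()] on the means.
#'
#' The permutation test shuffles the `(mean, sampling variance)` pairs
#' jointly across tips, re-estimating `sigma^2` each time.
#'
#' @param tree rooted [ape::phylo] with branch lengths.
#' @param individuals data frame with columns `species` and `value` (one
#'   row per individual).
#' @param n_perm permutations; `0` skips the test.
#' @param seed integer seed (required when `n_perm > 0`).
#' @return `k_result` with `sigma` = ML estimate of `sigma^2` and
#'   `used_measurement_error = TRUE`.
#' @export
blomberg_k_me <- function(tree, individuals, n_perm = 999, seed = NULL) {
  stopifnot(all(c("species", "value") %in% names(individuals)))
  individuals$species <- normalize_species(individuals$species)
  sp <- tree$tip.label
  miss <- setdiff(sp, individuals$species)
  if (length(miss)) stop("no individuals for tip(s): ",
                         paste(miss, collapse = ", "))
  xbar <- tapply(individuals$value, individuals$species, mean)[sp]
  ni <- tapply(individuals$value, individuals$species, length)[sp]
  s2 <- tapply(individuals$value, individuals$species,
               function(v) if (length(v) > 1) stats::var(v) else NA_real_)[sp]
  if (any(is.na(s2))) {
    pooled <- pooled_within_var(individuals)
    message(length(which(is.na(s2))),
            " species with a single individual given the pooled ",
            "within-species variance (", signif(pooled, 4), ")")
    s2[is.na(s2)] <- pooled
  }
  m <- as.numeric(s2 / ni)
  x <- as.numeric(xbar)

  if (all(m == 0)) {
    warning("all sampling variances are zero; falling back to blomberg_k")
    res <- blomberg_k(tree, stats::setNames(x, sp), n_perm = n_perm,
                      seed = seed)
    res$used_measurement_error <- TRUE
    return(res)
  }

  C <- phylo_vcv(tree)
  fit <- fit_sigma2(x, m, C)
  k_obs <- k_me_statistic(x, m, C, fit$sigma2)
  p <- NA_real_
  if (n_perm > 0) {
    if (is.null(seed)) stop("seed required when n_perm > 0")
    n <- length(x)
    k_null <- withr_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(n)
        f <- fit_sigma2(x[idx], m[idx], C)
        k_me_statistic(x[idx], m[idx], C, f$sigma2)
      }, numeric(1))
    })
    p <- (1 + sum(k_null >= k_obs)) / (n_perm + 1)
  }
  structure(list(K = k_obs, sigma = fit$sigma2, p_value = p,
                 n_perm = n_perm, seed = seed,
                 used_measurement_error = TRUE,
                 loglik = fit$loglik),
            class = "k_result")
}

pooled_within_var <- function(individuals) {
  spl <- split(individuals$value, individuals$species)
  ss <- 0; dfree <- 0
  for (v in spl) {
    if (length(v) > 1) {
      ss <- ss + sum((v - mean(v))^2)
      dfree <- dfree + length(v) - 1
    }
  }
  if (dfree == 0) 0 else ss / dfree
}

# Profiled log-likelihood of xbar under N(a1, s2*C + diag(m)); a profiled
# by GLS. Maximized over log(s2) in a wide bracket.
fit_sigma2 <- function(x, m, C) {
  n <- length(x)
  vx <- stats::var(x)
  if (vx == 0) stop("no variance: trait means are constant")
  negll <- function(ls2) {
    s2 <- exp(ls2)
    V <- s2 * C + diag(m, n)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    ldet <- 2 * sum(log(diag(ch)))
    iV1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
    iVx <- backsolve(ch, forwardsolve(t(ch), x))
    a <- sum(iVx) / sum(iV1)
    r <- x - a
    iVr <- backsolve(ch, forwardsolve(t(ch), r))
    0.5 * (ldet + drop(crossprod(r, iVr)))
  }
  lo <- log(1e-8 * vx); hi <- log(1e8 * vx)
  opt <- stats::optimize(negll, c(lo, hi), tol = 1e-10)
  if (!is.finite(opt$objective) || opt$objective >= 1e10) {
    stop("non-finite likelihood optimum in measurement-error model")
  }
  list(sigma2 = exp(opt$minimum), loglik = -opt$objective)
}

k_me_statistic <- function(x, m, C, sigma2) {
  Ceff <- C + diag(m / sigma2, length(x))
  k_statistic(x, Ceff, robust_inverse(Ceff))
}

#' @export
print.k_result <- function(x, ...) {
  cat(sprintf("Blomberg K = %.4g", x$K))
  if (isTRUE(x$used_measurement_error) && is.finite(x$sigma)) {
    cat(sprintf(", sigma^2 = %.4g", x$sigma))
  }
  if (is.finite(x$p_value)) {
    cat(sprintf(", p = %.4g (%d permutations)", x$p_value, x$n_perm))
  }
  cat("\n")
  invisible(x)
}

#' Minimum number of discrete-state changes on a tree (Fitch/Hartigan)
#'
#' Small-parsimony count of state changes for a nominal character, using
#' Hartigan's generalization of the Fitch rule so that polytomies are
#' handled exactly: at an internal node each state is scored by the number
#' of children whose optimal set contains it, and the node adds
#' `(number of children) - (maximum score)` changes.
#'
#' @param tree [ape::phylo] (branch lengths ignored).
#' @param states named character/factor vector of tip states, or unnamed
#'   in tip order. Every tip must be labelled.
#' @return integer minimum number of changes.
#' @export
fitch_steps <- function(tree, states) {
  states <- align_states(states, tree)
  alph <- sort(unique(states))
  k <- length(alph)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  # state-set membership per node, tips first
  sets <- matrix(FALSE, ntip + nnode, k)
  sets[cbind(seq_len(ntip), match(states, alph))] <- TRUE
  steps <- 0L
  tr <- stats::reorder(tree, "postorder")
  edges <- tr$edge
  # children grouped per internal node, visited in postorder
  for (node in unique(edges[, 1])) {
    ch <- edges[edges[, 1] == node, 2]
    score <- colSums(sets[ch, , drop = FALSE])
    best <- max(score)
    sets[node, ] <- score == best
    steps <- steps + length(ch) - best
  }
  as.integer(steps)
}

align_states <- function(states, tree) {
  states <- stats::setNames(as.character(states), names(states))
  if (!is.null(names(states))) {
    names(states) <- normalize_species(names(states))
    miss <- setdiff(tree$tip.label, names(states))
    if (length(miss)) stop("unlabelled tip(s): ",
                           paste(miss, collapse = ", "))
    states <- states[tree$tip.label]
  } else if (length(states) != length(tree$tip.label)) {
    stop("state vector length does not match tips")
  }
  if (any(is.na(states))) stop("unlabelled tip (NA state)")
  unname(states)
}

#' Maddison-Slatkin randomization test for a nominal trait
#'
#' Compares the observed minimum number of parsimony changes
#' ([fitch_steps()]) to the distribution obtained by shuffling tip states
#' (preserving state frequencies). Signal means *fewer* changes than the
#' null, so the p-value is one-tailed on small step counts:
#' `p = (1 + #\{null <= observed\}) / (n_perm + 1)`.
#'
#' @param tree [ape::phylo].
#' @param states tip states as in [fitch_steps()].
#' @param n_perm number of shuffles (>= 99).
#' @param seed integer seed.
#' @return list of class `ms_result`: `observed_steps`, `null_steps`
#'   (integer vector), `p_value`, `n_perm`, `seed`.
#' @export
maddison_slatkin <- function(tree, states, n_perm = 999, seed) {
  if (n_perm < 99) stop("n_perm must be >= 99")
  if (missing(seed)) stop("seed is mandatory")
  states <- align_states(states, tree)
  if (length(unique(states)) < 2) {
    warning("single-state trait: degenerate test")
    return(structure(list(observed_steps = 0L,
                          null_steps = integer(0), p_value = 1,
                          n_perm = n_perm, seed = seed),
                     class = "ms_result"))
  }
  obs <- fitch_steps(tree, states)
  n <- length(states)
  null <- withr_seed(seed, {
    vapply(seq_len(n_perm), function(i)
      fitch_steps(tree, states[sample.int(n)]), integer(1))
  })
  p <- (1 + sum(null <= obs)) / (n_perm + 1)
  structure(list(observed_steps = obs, null_steps = null, p_value = p,
                 n_perm = n_perm, seed = seed),
            class = "ms_result")
}

#' @export
print.ms_result <- function(x, ...) {
  cat(sprintf("Maddison-Slatkin: %d observed changes, p = %.4g (%d perms)\n",
              x$observed_steps, x$p_value, x$n_perm))
  invisible(x)
}

#' Blomberg's K per atoll
#'
#' Restricts the species pool to those present in each atoll's pooled
#' community, prunes the tree accordingly, and computes K (with
#' measurement error when individual-level data are supplied). Atolls with
#' fewer than 4 species are reported as not testable rather than tested.
#'
#' @param tree [ape::phylo].
#' @param comm [nested_community].
#' @param trait named species-mean vector, or a data frame
#'   `species`/`value` of individuals for the measurement-error variant.
#' @param n_perm,seed passed to the K functions.
#' @return data frame: `atoll`, `n_species`, `K`, `sigma`, `p_value`,
#'   `testable`.
#' @export
k_per_atoll <- function(tree, comm, trait, n_perm = 999, seed) {
  if (missing(seed)) stop("seed is mandatory")
  pools <- pool_evenly(comm)$atoll
  atolls <- rownames(pools)
  rows <- lapply(seq_along(atolls), function(i) {
    present <- colnames(pools)[pools[i, ] > 0]
    present <- intersect(present, tree$tip.label)
    if (length(present) < 4) {
      return(data.frame(atoll = atolls[i], n_species = length(present),
                        K = NA_real_, sigma = NA_real_, p_value = NA_real_,
                        testable = FALSE))
    }
    sub <- ape::keep.tip(tree, present)
    res <- if (is.data.frame(trait)) {
      ind <- trait[normalize_species(trait$species) %in% present, ,
                   drop = FALSE]
      blomberg_k_me(sub, ind, n_perm = n_perm, seed = seed + i)
    } else {
      blomberg_k(sub, trait[present], n_perm = n_perm, seed = seed + i)
    }
    data.frame(atoll = atolls[i], n_species = length(present),
               K = res$K, sigma = res$sigma, p_value = res$p_value,
               testable = TRUE)
  })
  do.call(rbind, rows)
}
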