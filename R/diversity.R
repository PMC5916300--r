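# Rao's quadratic entropy and its even-weighted additive apportionment
# over the unbalanced atoll / site / colony design, with scale-specific
# permutation null models and standardized effect sizes (SES).
#
# Even weighting: every colony counts 1/C_{a,s} within its site, every
# site 1/S_a within its atoll, every atoll 1/A in the archipelago,
# regardless of how many individuals or subunits it holds.

QE_LEVELS <- c("atolls", "sites_within_atolls", "colonies_within_sites")

#' Rao's quadratic entropy
#'
#' `QE(p, D) = sum_ij d_ij p_i p_j`: the expected dissimilarity between two
#' individuals drawn at random from relative abundances `p`.
#'
#' @param p named vector of relative abundances (sums to 1) over the
#'   species labelling `D`, or an unnamed vector aligned to `D`'s order.
#' @param D species-by-species distance matrix.
#' @param halve if `TRUE`, all `d_ij` are divided by 2 first (conventions
#'   differ between implementations; the default is no halving).
#' @return non-negative scalar.
#' @export
quadratic_entropy <- function(p, D, halve = FALSE) {
  check_distance(D, require_complete = FALSE)
  if (!is.null(names(p))) {
    miss <- setdiff(names(p)[p > 0], rownames(D))
    if (length(miss)) stop("species not in D: ", paste(miss, collapse = ", "))
    q <- stats::setNames(numeric(nrow(D)), rownames(D))
    q[names(p)] <- p
    p <- q
  } else if (length(p) != nrow(D)) {
    stop("length(p) does not match D")
  }
  if (abs(sum(p) - 1) > 1e-8) stop("p must sum to 1")
  touched <- which(p > 0)
  if (any(!is.finite(D[touched, touched]))) {
    stop("D has missing entries on the support of p")
  }
  v <- drop(crossprod(p, D %*% p))
  if (halve) v <- v / 2
  v
}

# Fast internal engine -----------------------------------------------------
# Works on the matrix form of a nested_community: Pcol (colony x species
# relative abundances), qcol (QE of each colony), site_of (factor over
# colonies), atoll_of_site (factor over sites). Grouping vectors may be
# permuted by the null models without touching Pcol.

colony_profiles <- function(comm) {
  X <- comm$X
  P <- X / rowSums(X)
  P
}

qe_rows <- function(P, D) rowSums((P %*% D) * P)

qe_components_engine <- function(Pcol, qcol, site_of, atoll_of_site, D) {
  C_s <- tabulate(site_of, nbins = nlevels(site_of))
  Psite <- rowsum(Pcol, site_of, reorder = TRUE) / C_s
  qsite <- qe_rows(Psite, D)
  abar_site <- drop(rowsum(qcol, site_of, reorder = TRUE)) / C_s

  S_a <- tabulate(atoll_of_site, nbins = nlevels(atoll_of_site))
  Patoll <- rowsum(Psite, atoll_of_site, reorder = TRUE) / S_a
  qatoll <- qe_rows(Patoll, D)
  qsite_bar <- drop(rowsum(qsite, atoll_of_site, reorder = TRUE)) / S_a
  abar_atoll <- drop(rowsum(abar_site, atoll_of_site, reorder = TRUE)) / S_a

  A <- nlevels(atoll_of_site)
  p <- colMeans(Patoll)
  gamma <- drop(crossprod(p, D %*% p))
  c(alpha_within_colony = sum(abar_atoll) / A,
    beta_colonies_within_sites = sum(qsite_bar - abar_atoll) / A,
    beta_sites_within_atolls = sum(qatoll - qsite_bar) / A,
    beta_atolls = gamma - sum(qatoll) / A,
    gamma = gamma)
}

align_D <- function(comm, D) {
  check_distance(D, require_complete = FALSE)
  miss <- setdiff(comm$species, rownames(D))
  if (length(miss)) {
    stop("community species missing from D: ", paste(miss, collapse = ", "))
  }
  D2 <- D[comm$species, comm$species, drop = FALSE]
  if (any(!is.finite(D2))) stop("D has missing entries for community species")
  D2
}

# site_of is a factor over colonies with levels "atoll/site"; the site ->
# atoll map must follow the *current* grouping. Helper rebuilds it.
atolls_of <- function(site_levels) {
  factor(sub("/[^/]*$", "", site_levels),
         levels = sort(unique(sub("/[^/]*$", "", site_levels))))
}

#' Evenly pooled abundance vectors at every level
#'
#' Within-colony relative abundances are averaged (not abundance-weighted)
#' up the hierarchy: sites are the plain mean of their colonies' vectors,
#' atolls the mean of their sites', and the archipelago the mean of the
#' atolls'. Each unit therefore carries even weight at its level however
#' unbalanced the design.
#'
#' @param comm a [nested_community].
#' @return list with matrices `colony`, `site`, `atoll` (rows are units,
#'   columns species) and the vector `archipelago`.
#' @export
pool_evenly <- function(comm) {
  Pcol <- colony_profiles(comm)
  C_s <- tabulate(comm$site_of, nbins = nlevels(comm$site_of))
  Psite <- rowsum(Pcol, comm$site_of, reorder = TRUE) / C_s
  S_a <- tabulate(comm$atoll_of_site, nbins = nlevels(comm$atoll_of_site))
  Patoll <- rowsum(Psite, comm$atoll_of_site, reorder = TRUE) / S_a
  list(colony = Pcol, site = Psite, atoll = Patoll,
       archipelago = colMeans(Patoll))
}

#' Additive apportionment of quadratic entropy across the nested design
#'
#' Decomposes the archipelago-level (gamma) quadratic entropy into a mean
#' within-colony alpha plus three beta components: among colonies within
#' sites, among sites within atolls, and among atolls. All units are
#' evenly weighted; the decomposition is exactly additive
#' (`alpha + betas == gamma`) for any unbalanced design.
#'
#' @param comm a [nested_community].
#' @param D species distance matrix covering the community's species.
#' @param halve divide all distances by 2 first (default `FALSE`).
#' @return named vector: `alpha_within_colony`,
#'   `beta_colonies_within_sites`, `beta_sites_within_atolls`,
#'   `beta_atolls`, `gamma`.
#' @export
apportion_qe <- function(comm, D, halve = FALSE) {
  D <- align_D(comm, D)
  if (halve) D <- D / 2
  Pcol <- colony_profiles(comm)
  qcol <- qe_rows(Pcol, D)
  qe_components_engine(Pcol, qcol, comm$site_of, comm$atoll_of_site, D)
}

# Null models ---------------------------------------------------------------
# Each null breaks structure only at the tested level:
#  * colonies_within_sites: pool the individuals of each site and deal them
#    back to that site's colonies at random, preserving colony totals.
#  * sites_within_atolls: shuffle colonies (with their contents) among the
#    sites of their atoll, preserving per-site colony counts.
#  * atolls: shuffle whole sites (with their colonies) among atolls,
#    preserving each atoll's site count.

null_colonies_within_sites <- function(X, site_of) {
  Xn <- X
  ns <- ncol(X)
  for (s in levels(site_of)) {
    rows <- which(site_of == s)
    if (length(rows) < 2) next
    sub <- X[rows, , drop = FALSE]
    sizes <- rowSums(sub)
    pool <- rep.int(rep(seq_len(ns), length(rows)), as.vector(t(sub)))
    pool <- pool[sample.int(length(pool))]
    stop_at <- cumsum(sizes)
    start_at <- c(1, stop_at[-length(stop_at)] + 1)
    for (k in seq_along(rows)) {
      Xn[rows[k], ] <- tabulate(pool[start_at[k]:stop_at[k]], nbins = ns)
    }
  }
  Xn
}

permute_within <- function(f, groups) {
  # permute the values of f within each level of `groups`
  out <- f
  for (g in levels(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1) out[idx] <- f[idx[sample.int(length(idx))]]
  }
  out
}

#' Permutation SES test for beta diversity at one spatial scale
#'
#' Compares the observed beta component at `level` against `n_perm`
#' datasets randomized under a null that breaks structure only at that
#' level (see Details), and reports the standardized effect size
#' `SES = (observed - mean(null)) / sd(null)` together with a two-sided
#' permutation p-value with the +1 correction. Positive SES indicates
#' clustering (units more differentiated than the null), negative SES
#' over-dispersion.
#'
#' @details Null models: `colonies_within_sites` pools each site's
#' individuals and reallocates them to that site's colonies preserving
#' colony totals; `sites_within_atolls` shuffles colonies among the sites
#' of their atoll preserving per-site colony counts; `atolls` shuffles
#' whole sites among atolls preserving each atoll's site count. Each null
#' is exchangeable under neutral assembly at the tested scale while
#' holding coarser and finer structure fixed.
#'
#' @param comm a [nested_community].
#' @param D species distance matrix.
#' @param level one of `"atolls"`, `"sites_within_atolls"`,
#'   `"colonies_within_sites"`.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed (mandatory; every draw is reproducible).
#' @param halve see [apportion_qe()].
#' @param keep_null retain the full null sample in the result.
#' @return list: `level`, `observed`, `null_mean`, `null_sd`, `ses`
#'   (`NA` if the null has zero variance), `p_value`, `n_perm`, `seed`,
#'   and `null` (vector) when `keep_null`.
#' @export
ses_test <- function(comm, D, level = QE_LEVELS, n_perm = 999, seed,
                     halve = FALSE, keep_null = TRUE) {
  level <- match.arg(level)
  if (n_perm < 99) stop("n_perm must be >= 99")
  if (missing(seed)) stop("seed is mandatory")
  D <- align_D(comm, D)
  if (halve) D <- D / 2
  comp_name <- switch(level,
    atolls = "beta_atolls",
    sites_within_atolls = "beta_sites_within_atolls",
    colonies_within_sites = "beta_colonies_within_sites")

  X <- comm$X
  site_of <- comm$site_of
  atoll_of_site <- comm$atoll_of_site
  Pcol <- X / rowSums(X)
  qcol <- qe_rows(Pcol, D)
  obs <- qe_components_engine(Pcol, qcol, site_of, atoll_of_site, D)[comp_name]

  # precomputed fixed quantities for the specialized per-level statistics
  A <- nlevels(atoll_of_site)
  C_s <- tabulate(site_of, nbins = nlevels(site_of))
  S_a <- tabulate(atoll_of_site, nbins = A)
  Psite0 <- rowsum(Pcol, site_of, reorder = TRUE) / C_s
  atoll_code <- as.integer(atoll_of_site)
  site_code <- as.integer(site_of)
  atoll_of_colony <- atoll_code[site_code]
  w_site <- 1 / (A * S_a[atoll_code])        # even weight of each site
  colony_by_atoll <- split(seq_along(site_code), atoll_of_colony)

  stat_atolls <- function(ao_code) {
    S <- tabulate(ao_code, nbins = A)
    Patoll <- rowsum(Psite0, ao_code, reorder = TRUE) / S
    qatoll <- qe_rows(Patoll, D)
    p <- colMeans(Patoll)
    drop(crossprod(p, D %*% p)) - mean(qatoll)
  }
  stat_sites <- function(so_code) {
    Psite <- rowsum(Pcol, so_code, reorder = TRUE) / C_s
    qsite <- qe_rows(Psite, D)
    Patoll <- rowsum(Psite, atoll_code, reorder = TRUE) / S_a
    qatoll <- qe_rows(Patoll, D)
    qsite_bar <- drop(rowsum(qsite, atoll_code, reorder = TRUE)) / S_a
    sum(qatoll - qsite_bar) / A
  }
  stat_colonies <- function(Xn) {
    Pn <- Xn / rowSums(Xn)
    qn <- qe_rows(Pn, D)
    Psite <- rowsum(Pn, site_code, reorder = TRUE) / C_s
    qsite <- qe_rows(Psite, D)
    abar <- drop(rowsum(qn, site_code, reorder = TRUE)) / C_s
    sum(w_site * (qsite - abar))
  }
  # fixed per-site individual pools for the colony-reallocation null
  ns <- ncol(X)
  site_rows <- split(seq_len(nrow(X)), site_code)
  site_pools <- lapply(site_rows, function(r)
    rep.int(rep(seq_len(ns), length(r)), as.vector(t(X[r, , drop = FALSE]))))
  site_sizes <- lapply(site_rows, function(r) rowSums(X[r, , drop = FALSE]))
  draw_colonies_null <- function() {
    Xn <- X
    for (s in seq_along(site_rows)) {
      rows <- site_rows[[s]]
      if (length(rows) < 2) next
      pool <- site_pools[[s]][sample.int(length(site_pools[[s]]))]
      stops <- cumsum(site_sizes[[s]])
      starts <- c(1, stops[-length(stops)] + 1)
      for (k in seq_along(rows)) {
        Xn[rows[k], ] <- tabulate(pool[starts[k]:stops[k]], nbins = ns)
      }
    }
    Xn
  }

  # local RNG state so seeded runs are bit-reproducible and isolated
  null <- withr_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      if (level == "colonies_within_sites") {
        stat_colonies(draw_colonies_null())
      } else if (level == "sites_within_atolls") {
        so <- site_code
        for (idx in colony_by_atoll) {
          if (length(idx) > 1) so[idx] <- so[idx][sample.int(length(idx))]
        }
        stat_sites(so)
      } else {
        stat_atolls(atoll_code[sample.int(length(atoll_code))])
      }
    }, numeric(1))
  })

  mu <- mean(null)
  sdv <- stats::sd(null)
  if (sdv > 0) {
    ses <- (obs - mu) / sdv
    p <- (1 + sum(abs(null - mu) >= abs(obs - mu))) / (n_perm + 1)
  } else {
    ses <- NA_real_   # undefined, never coerced to 0
    p <- (1 + sum(null == obs)) / (n_perm + 1)
    if (all(null == obs)) p <- 1
  }
  res <- list(level = level, observed = unname(obs), null_mean = mu,
              null_sd = sdv, ses = unname(ses), p_value = unname(p),
              n_perm = n_perm, seed = seed)
  if (keep_null) res$null <- null
  res
}

withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv, inherits = FALSE)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(seed)
  code
}

#' Table-shaped TQE / PQE report over several distance sources
#'
#' Runs [ses_test()] at the three spatial scales for each supplied distance
#' matrix (total traits, single traits, consensus phylogeny, individual
#' genes, ...) and assembles the rows into one grid: columns are SES and p
#' at each level, in the fixed order among atolls / among sites within
#' atolls / among colonies within sites. Rows sharing the same seed use
#' identical permutations, so two identical matrices yield identical rows.
#'
#' @param comm a [nested_community].
#' @param D_list named list of distance matrices (row labels of the
#'   report).
#' @param n_perm permutations per test.
#' @param seed integer master seed; the test at level k uses `seed + k - 1`
#'   for every row.
#' @param halve see [apportion_qe()].
#' @return data frame of class `qe_report` with columns `source`, then
#'   `ses_<level>` and `p_<level>` for the three levels; attribute `tests`
#'   holds the full [ses_test()] objects.
#' @export
tqe_pqe_report <- function(comm, D_list, n_perm = 999, seed, halve = FALSE) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(length(D_list) >= 1, !is.null(names(D_list)))
  tests <- list()
  rows <- lapply(names(D_list), function(nm) {
    D <- D_list[[nm]]
    # per-gene matrices may cover only a subset: prune community to shared pool
    shared <- intersect(comm$species, rownames(D))
    cm <- if (length(shared) < length(comm$species)) {
      filter_community(comm, shared)
    } else comm
    row <- list(source = nm)
    for (k in seq_along(QE_LEVELS)) {
      lv <- QE_LEVELS[k]
      t1 <- ses_test(cm, D, level = lv, n_perm = n_perm,
                     seed = seed + k - 1, halve = halve, keep_null = FALSE)
      tests[[nm]][[lv]] <<- t1
      row[[paste0("ses_", lv)]] <- t1$ses
      row[[paste0("p_", lv)]] <- t1$p_value
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "tests") <- tests
  class(out) <- c("qe_report", "data.frame")
  out
}
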