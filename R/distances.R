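# Species x species dissimilarity matrices feeding the quadratic-entropy
# machinery. All constructors go through as_distance_matrix(), which
# enforces exact symmetry, a zero diagonal and non-negativity.

as_distance_matrix <- function(d, labels, source, extra = NULL) {
  d <- as.matrix(d)
  dimnames(d) <- list(labels, labels)
  if (any(is.finite(d) & d < 0)) stop("negative dissimilarity")
  d <- (d + t(d)) / 2            # enforce exact symmetry
  diag(d) <- 0
  attr(d, "source") <- source
  for (nm in names(extra)) attr(d, nm) <- extra[[nm]]
  d
}

check_distance <- function(D, require_complete = TRUE) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("D must be square")
  if (is.null(rownames(D))) stop("D must have species labels")
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-12, check.attributes = FALSE)))
    stop("D must be symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("D must have zero diagonal")
  if (require_complete && any(!is.finite(D)))
    stop("D has missing entries (pairs with no comparable data)")
  invisible(TRUE)
}

#' Gower distance over mixed quantitative and nominal traits
#'
#' Computes the Gower dissimilarity between species from a species-level
#' trait table. For a quantitative trait `t`, the per-trait score is
#' `|x_it - x_jt| / R_t` with `R_t` the observed range in the supplied
#' table; for a nominal trait it is 0 on a match and 1 otherwise. Traits
#' with a missing value in either species are excluded for that pair and
#' the weights renormalized. All entries lie in `[0, 1]`.
#'
#' @param traits data frame with row names (or a `species` column) giving
#'   species; one column per trait. Numeric columns are treated as
#'   quantitative, character/factor columns as nominal, unless overridden.
#' @param kinds optional named character vector, values `"quantitative"` or
#'   `"nominal"`, overriding the type inferred from the column class.
#' @param weights optional named non-negative trait weights (default equal).
#' @return distance matrix with attribute `source = "gower"`.
#' @export
gower_distance <- function(traits, kinds = NULL, weights = NULL) {
  if ("species" %in% names(traits)) {
    rn <- normalize_species(traits$species)
    traits <- traits[setdiff(names(traits), "species")]
    rownames(traits) <- rn
  }
  if (nrow(traits) < 2) stop("need >= 2 species")
  if (ncol(traits) < 1) stop("need >= 1 trait")
  sp <- rownames(traits)
  n <- nrow(traits)
  tn <- names(traits)
  if (is.null(kinds)) {
    kinds <- vapply(traits, function(col)
      if (is.numeric(col)) "quantitative" else "nominal", "")
  } else {
    k <- vapply(traits, function(col)
      if (is.numeric(col)) "quantitative" else "nominal", "")
    k[names(kinds)] <- kinds
    kinds <- k
  }
  if (is.null(weights)) weights <- stats::setNames(rep(1, ncol(traits)), tn)
  w <- rep(1, ncol(traits)); names(w) <- tn
  w[names(weights)] <- weights
  if (any(w < 0)) stop("negative trait weight")

  num <- matrix(0, n, n)     # sum of w_t * s_t over usable traits
  den <- matrix(0, n, n)     # sum of w_t over usable traits
  for (j in seq_along(tn)) {
    x <- traits[[j]]
    ok <- !is.na(x)
    use <- outer(ok, ok, "&")
    if (kinds[j] == "quantitative") {
      x <- as.numeric(x)
      R <- diff(range(x, na.rm = TRUE))
      if (!is.finite(R) || R == 0) {
        warning("trait '", tn[j], "' is constant; dropped from Gower")
        next
      }
      s <- abs(outer(x, x, "-")) / R
    } else {
      x <- as.character(x)
      s <- 1 - outer(x, x, "==")
    }
    s[!use] <- 0
    num <- num + w[j] * s * use
    den <- den + w[j] * use
  }
  off <- upper.tri(den)
  if (any(den[off] == 0)) {
    idx <- which(den == 0 & off, arr.ind = TRUE)[1, ]
    stop("species pair with no shared non-missing trait: ",
         sp[idx[1]], " / ", sp[idx[2]])
  }
  d <- num / den
  d[!is.finite(d)] <- 0
  as_distance_matrix(d, sp, "gower")
}

# IUPAC-unambiguous bases; everything else (gaps, N, ambiguity codes) is
# treated as missing under pairwise deletion.
.unambig <- c("A", "C", "G", "T")

#' Raw nucleotide p-distance with pairwise deletion
#'
#' The proportion of aligned sites at which two sequences carry different
#' unambiguous bases, among the sites where both carry an unambiguous base
#' (A/C/G/T). Gaps, N and IUPAC ambiguity codes are excluded pairwise. The
#' per-pair count of compared sites is stored in attribute `n_sites`. A
#' pair with zero comparable sites gets `NA` (flagged missing); quadratic
#' entropy refuses matrices with missing entries.
#'
#' @param alignment named character vector of equal-length sequences (one
#'   element of the [read_alignments()] result).
#' @return distance matrix with attributes `source = "pdist:<gene>"` and
#'   `n_sites` (matrix of compared-site counts).
#' @export
p_distance <- function(alignment) {
  if (length(alignment) < 2) stop("need >= 2 sequences")
  gene <- attr(alignment, "gene")
  if (is.null(gene)) gene <- "gene"
  M <- do.call(rbind, strsplit(toupper(unname(alignment)), ""))
  rownames(M) <- names(alignment)
  ok <- matrix(M %in% .unambig, nrow(M), ncol(M))
  # comparable-site counts: crossprod of 0/1 indicator
  okn <- matrix(as.numeric(ok), nrow(M), ncol(M))
  nsites <- tcrossprod(okn)
  n <- nrow(M)
  diffs <- matrix(0, n, n)
  for (b in .unambig) {
    ib <- matrix(as.numeric(M == b), n, ncol(M))
    diffs <- diffs + tcrossprod(ib)   # matches on base b
  }
  # diffs currently holds #matching comparable sites
  diffs <- nsites - diffs
  d <- ifelse(nsites > 0, diffs / nsites, NA_real_)
  if (any(is.na(d[upper.tri(d)]))) {
    warning("pair(s) with zero comparable sites flagged as missing")
  }
  as_distance_matrix(d, rownames(M), paste0("pdist:", gene),
                     extra = list(n_sites = nsites))
}

#' p-distance over the concatenation of several gene alignments
#'
#' Pairwise deletion operates across the concatenated columns: species
#' missing a gene simply contribute no sites for that gene, and a pair's
#' distance is the pooled proportion of differing sites across whatever
#' genes both species have.
#'
#' @param alignments named list of alignments ([read_alignments()] output).
#' @return distance matrix with `source = "pdist:concat"`.
#' @export
concat_p_distance <- function(alignments) {
  if (length(alignments) < 1) stop("need >= 1 gene")
  sp <- sort(unique(unlist(lapply(alignments, names))))
  n <- length(sp)
  diffs <- matrix(0, n, n, dimnames = list(sp, sp))
  nsites <- matrix(0, n, n, dimnames = list(sp, sp))
  for (aln in alignments) {
    if (length(aln) < 2) next   # a single-species gene adds no pairs
    d1 <- p_distance(aln)
    ns <- attr(d1, "n_sites")
    idx <- match(rownames(d1), sp)
    ns0 <- ifelse(is.na(d1), 0, ns)
    diffs[idx, idx] <- diffs[idx, idx] +
      ifelse(is.na(d1), 0, d1) * ns0
    nsites[idx, idx] <- nsites[idx, idx] + ns0
  }
  d <- ifelse(nsites > 0, diffs / nsites, NA_real_)
  diag(d) <- 0
  if (any(is.na(d[upper.tri(d)]))) {
    warning("pair(s) with zero comparable sites across all genes")
  }
  as_distance_matrix(d, sp, "pdist:concat",
                     extra = list(n_sites = nsites))
}

#' Patristic distances from a tree
#'
#' Sum of branch lengths along the tip-to-tip path, via
#' [ape::cophenetic.phylo()].
#'
#' @param tree [ape::phylo] with branch lengths.
#' @return distance matrix with `source = "patristic"`.
#' @export
patristic_distance <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  d <- ape::cophenetic.phylo(tree)
  as_distance_matrix(d, rownames(d), "patristic")
}

#' Test whether a dissimilarity matrix is Euclidean-embeddable
#'
#' A matrix `d` is Euclidean iff the doubly centred Gower matrix of
#' `-d_ij^2 / 2` is positive semidefinite. Euclidean-embeddable
#' dissimilarities guarantee non-negative beta components in the quadratic
#' entropy decomposition.
#'
#' @param D distance matrix.
#' @param tol eigenvalue tolerance (default `1e-9`, scaled by the largest
#'   eigenvalue magnitude).
#' @return list with `euclidean` (logical) and `min_eigenvalue`.
#' @export
is_euclidean <- function(D, tol = 1e-9) {
  check_distance(D)
  n <- nrow(D)
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  ev <- eigen((G + t(G)) / 2, symmetric = TRUE, only.values = TRUE)$values
  scale <- max(abs(ev), 1)
  list(euclidean = min(ev) > -tol * scale, min_eigenvalue = min(ev))
}

#' Write / read a distance matrix as square CSV
#'
#' @param D distance matrix.
#' @param path CSV path; a metadata sidecar `<path>.json` stores the source.
#' @export
write_distance <- function(D, path) {
  utils::write.csv(as.data.frame(D), path, quote = FALSE)
  jsonlite::write_json(
    list(source = attr(D, "source"), labels = rownames(D)),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_distance
#' @export
read_distance <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  src <- "unknown"
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    src <- jsonlite::read_json(side)$source
  }
  D <- as_distance_matrix(as.matrix(df), rownames(df), src)
  check_distance(D, require_complete = FALSE)
  D
}
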