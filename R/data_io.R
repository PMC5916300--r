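#' @keywords internal
"_PACKAGE"

# Species identifiers are matched exactly after a normalization pass:
# trim, collapse internal whitespace, spaces -> underscores. Newick tip
# labels and FASTA headers disagree on spaces, CSVs on padding.

#' Normalize species identifiers
#'
#' Trims leading/trailing whitespace, collapses runs of internal whitespace,
#' and converts spaces to underscores so that identifiers from Newick, FASTA
#' and CSV sources compare equal.
#'
#' @param x character vector of raw identifiers.
#' @return character vector of normalized identifiers.
#' @export
normalize_species <- function(x) {
  x <- gsub("\\s+", " ", trimws(as.character(x)))
  gsub(" ", "_", x)
}

#' Read a rooted phylogeny from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] that validates the invariants the
#' downstream analyses rely on: unique tip labels, a single root, and
#' non-negative branch lengths. Polytomies are preserved; zero-length
#' branches are allowed with a warning.
#'
#' @param path path to a Newick file (or a Newick string via `text`).
#' @param text optional Newick string, used instead of `path`.
#' @return an [ape::phylo] object with normalized tip labels.
#' @export
read_tree <- function(path = NULL, text = NULL) {
  tr <- if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(path)
  if (is.null(tr)) {
    stop("failed to parse Newick from ",
         if (!is.null(text)) "text" else path)
  }
  validate_tree(tr)
}

validate_tree <- function(tr) {
  if (!inherits(tr, "phylo")) stop("not a 'phylo' object")
  tr$tip.label <- normalize_species(tr$tip.label)
  if (anyDuplicated(tr$tip.label)) {
    dups <- unique(tr$tip.label[duplicated(tr$tip.label)])
    stop("duplicate tip labels: ", paste(dups, collapse = ", "))
  }
  if (any(!nzchar(tr$tip.label))) stop("empty tip label")
  if (!is.null(tr$edge.length)) {
    if (any(!is.finite(tr$edge.length))) stop("non-finite branch length")
    if (any(tr$edge.length < 0)) stop("negative branch length")
    if (any(tr$edge.length == 0)) {
      warning("tree contains zero-length branches")
    }
  }
  tr
}

#' Read one or more aligned FASTA files
#'
#' Each file is one gene alignment. The species name is the first
#' whitespace-delimited token of the FASTA header. Within a file all
#' sequences must have equal length; species sets may differ between genes
#' (missing genes are permitted).
#'
#' @param paths character vector of FASTA file paths.
#' @param gene_names optional names for the genes; defaults to file base
#'   names without extension.
#' @return a named list of alignments; each alignment is a named character
#'   vector of equal-length uppercase sequences with attribute `gene`.
#' @export
read_alignments <- function(paths, gene_names = NULL) {
  if (is.null(gene_names)) {
    gene_names <- sub("\\.[^.]*$", "", basename(paths))
  }
  stopifnot(length(gene_names) == length(paths))
  out <- vector("list", length(paths))
  names(out) <- gene_names
  for (i in seq_along(paths)) {
    out[[i]] <- read_one_fasta(paths[[i]], gene_names[[i]])
  }
  out
}

read_one_fasta <- function(path, gene) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) stop("no FASTA records in ", path)
  starts <- hdr + 1L
  ends <- c(hdr[-1] - 1L, length(lines))
  seqs <- character(length(hdr))
  ids <- character(length(hdr))
  for (i in seq_along(hdr)) {
    ids[i] <- normalize_species(
      sub("^>\\s*(\\S+).*$", "\\1", lines[hdr[i]]))
    body <- if (starts[i] <= ends[i]) lines[starts[i]:ends[i]] else ""
    seqs[i] <- toupper(gsub("\\s", "", paste(body, collapse = "")))
  }
  if (anyDuplicated(ids)) {
    stop("duplicate species in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  lens <- nchar(seqs)
  if (any(lens == 0)) stop("empty sequence in ", path)
  if (length(unique(lens)) > 1) {
    bad <- ids[lens != lens[1]][1]
    stop("ragged alignment in ", path, ": record '", bad,
         "' has length ", lens[lens != lens[1]][1],
         " but first record has ", lens[1])
  }
  names(seqs) <- ids
  attr(seqs, "gene") <- gene
  seqs
}

#' Build a nested community from a data frame
#'
#' The core container of the package: abundance counts indexed by
#' (atoll, site, colony, species). Counts over duplicate rows are summed;
#' colonies whose total count is zero are dropped with a warning. Colony and
#' site identifiers are made globally unique internally as
#' `atoll/site/colony` triples, so input files may reuse `colony1` across
#' sites.
#'
#' @param df data frame with columns `atoll`, `site`, `colony`, `species`,
#'   `count` (non-negative integers).
#' @return an object of class `nested_community`: the aggregated `records`
#'   plus a colony-by-species count matrix `X`, the colony-to-site factor
#'   `site_of`, and the site-to-atoll factor `atoll_of_site`.
#' @export
nested_community <- function(df) {
  need <- c("atoll", "site", "colony", "species", "count")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  df <- df[need]
  for (col in c("atoll", "site", "colony", "species")) {
    df[[col]] <- normalize_species(df[[col]])
  }
  cnt <- df$count
  if (any(!is.finite(cnt))) stop("non-finite count")
  if (any(cnt < 0)) stop("negative count")
  if (any(cnt != round(cnt))) {
    stop("fractional abundances rejected: counts must be integers")
  }
  df$count <- as.integer(round(cnt))

  site_key <- paste(df$atoll, df$site, sep = "/")
  colony_key <- paste(site_key, df$colony, sep = "/")
  agg <- stats::aggregate(count ~ ., data = data.frame(
    atoll = df$atoll, site = site_key, colony = colony_key,
    species = df$species, count = df$count,
    stringsAsFactors = FALSE), FUN = sum)

  # drop empty colonies (total count 0) with a warning
  tot <- tapply(agg$count, agg$colony, sum)
  empty <- names(tot)[tot == 0]
  if (length(empty)) {
    warning("dropping ", length(empty), " empty colony(ies): ",
            paste(empty, collapse = ", "))
    agg <- agg[!(agg$colony %in% empty), , drop = FALSE]
  }
  if (nrow(agg) == 0) stop("community is empty after validation")

  colonies <- sort(unique(agg$colony))
  species <- sort(unique(agg$species))
  X <- matrix(0L, length(colonies), length(species),
              dimnames = list(colonies, species))
  X[cbind(match(agg$colony, colonies), match(agg$species, species))] <-
    X[cbind(match(agg$colony, colonies), match(agg$species, species))] +
    agg$count
  # duplicate (colony,species) rows already summed by aggregate()

  colony_site <- sub("/[^/]*$", "", colonies)
  sites <- sort(unique(colony_site))
  site_atoll <- sub("/[^/]*$", "", sites)
  obj <- list(
    records = agg[order(agg$colony, agg$species), , drop = FALSE],
    X = X,
    site_of = factor(colony_site, levels = sites),
    atoll_of_site = factor(site_atoll, levels = sort(unique(site_atoll))),
    species = species
  )
  class(obj) <- "nested_community"
  obj
}

#' @export
print.nested_community <- function(x, ...) {
  cat("nested_community:",
      nlevels(x$atoll_of_site), "atolls,",
      nlevels(x$site_of), "sites,",
      nrow(x$X), "colonies,",
      length(x$species), "species,",
      sum(x$X), "individuals\n")
  invisible(x)
}

#' Read a nested community abundance table from CSV
#'
#' @param path CSV file with header `atoll,site,colony,species,count`.
#' @return a [nested_community] object.
#' @export
read_community <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  comm <- nested_community(df)
  message(sprintf(
    "community: %d atolls, %d sites, %d colonies, %d species",
    nlevels(comm$atoll_of_site), nlevels(comm$site_of),
    nrow(comm$X), length(comm$species)))
  comm
}

#' Write a nested community back to CSV
#'
#' Round-trips exactly: `read_community(write_community(x, f))` reproduces
#' identical counts.
#'
#' @param comm a [nested_community].
#' @param path output CSV path.
#' @export
write_community <- function(comm, path) {
  rec <- comm$records
  out <- data.frame(
    atoll = rec$atoll,
    site = sub("^[^/]*/", "", rec$site),
    colony = sub("^.*/", "", rec$colony),
    species = rec$species,
    count = rec$count)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a species trait table from CSV
#'
#' One row per individual. Required columns: `species`, `carapace_length`
#' (mm, > 0), `habitat_assoc` (one of `hard_coral`, `free_living`,
#' `semi_symbiotic`, `sessile_invert`; constant within a species). Optional
#' gravid-female columns: `egg_count` plus `egg_long_diam_1..10` and
#' `egg_short_diam_1..10` in micrometres (NA for non-gravid individuals).
#'
#' @param path CSV path.
#' @return a data frame of class `trait_table`.
#' @export
read_traits <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_traits(df)
}

habitat_levels <- c("hard_coral", "free_living", "semi_symbiotic",
                    "sessile_invert")

validate_traits <- function(df) {
  if (!all(c("species", "carapace_length", "habitat_assoc") %in% names(df))) {
    stop("trait table needs columns species, carapace_length, habitat_assoc")
  }
  df$species <- normalize_species(df$species)
  if (any(!is.finite(df$carapace_length)) || any(df$carapace_length <= 0)) {
    stop("carapace_length must be positive")
  }
  bad <- setdiff(unique(df$habitat_assoc), habitat_levels)
  if (length(bad)) {
    stop("unknown habitat_assoc level(s): ", paste(bad, collapse = ", "))
  }
  per_sp <- tapply(df$habitat_assoc, df$species,
                   function(z) length(unique(z)))
  if (any(per_sp > 1)) {
    stop("habitat_assoc varies within species: ",
         paste(names(per_sp)[per_sp > 1], collapse = ", "))
  }
  class(df) <- c("trait_table", "data.frame")
  df
}

#' Cross-validate tree, alignments, traits and community
#'
#' Lists species present in the community but absent from the tree, the
#' trait table, or individual gene alignments; applies the configured drop
#' rule and returns the filtered, mutually consistent dataset together with
#' an exclusion log. Nothing is silently dropped: every exclusion carries a
#' reason. Species missing from *some* genes only are retained and flagged
#' per gene (per-gene analyses prune them).
#'
#' @param tree [ape::phylo] or NULL.
#' @param alignments named list from [read_alignments()], or NULL.
#' @param traits `trait_table` data frame or NULL.
#' @param community [nested_community].
#' @param drop one of `"missing_any_core"` (default: drop community species
#'   absent from the tree or the trait table) or `"none"` (report only).
#' @return list with elements `community`, `tree`, `traits`, `alignments`
#'   (filtered to the common pool), `exclusions` (data frame species/reason)
#'   and `gene_missing` (named list of species absent per gene).
#' @export
validate_dataset <- function(tree = NULL, alignments = NULL, traits = NULL,
                             community, drop = c("missing_any_core", "none")) {
  drop <- match.arg(drop)
  sp <- community$species
  excl <- data.frame(species = character(0), reason = character(0),
                     stringsAsFactors = FALSE)
  add_excl <- function(e, who, why) {
    if (length(who)) rbind(e, data.frame(species = who, reason = why,
                                         stringsAsFactors = FALSE)) else e
  }
  miss_tree <- if (!is.null(tree)) setdiff(sp, tree$tip.label) else character(0)
  miss_trait <- if (!is.null(traits)) {
    setdiff(sp, unique(traits$species))
  } else character(0)
  excl <- add_excl(excl, miss_tree, "absent_from_tree")
  excl <- add_excl(excl, miss_trait, "absent_from_traits")

  gene_missing <- list()
  if (!is.null(alignments)) {
    for (g in names(alignments)) {
      gene_missing[[g]] <- setdiff(sp, names(alignments[[g]]))
    }
  }

  keep <- sp
  if (drop == "missing_any_core") {
    keep <- setdiff(sp, unique(excl$species))
  }
  if (length(keep) < 2) stop("fewer than 2 species remain after validation")

  comm2 <- filter_community(community, keep)
  res <- list(
    community = comm2,
    tree = if (!is.null(tree)) {
      if (length(setdiff(tree$tip.label, keep))) {
        ape::keep.tip(tree, intersect(tree$tip.label, keep))
      } else tree
    },
    traits = if (!is.null(traits)) {
      traits[traits$species %in% keep, , drop = FALSE]
    },
    alignments = alignments,
    exclusions = excl,
    gene_missing = lapply(gene_missing, intersect, x = keep)
  )
  res$gene_missing <- lapply(gene_missing, function(m) intersect(m, keep))
  res
}

filter_community <- function(comm, keep) {
  rec <- comm$records
  rec <- rec[rec$species %in% keep, , drop = FALSE]
  if (nrow(rec) == 0) stop("no records left after filtering")
  df <- data.frame(
    atoll = rec$atoll,
    site = sub("^[^/]*/", "", rec$site),
    colony = sub("^.*/", "", rec$colony),
    species = rec$species, count = rec$count, stringsAsFactors = FALSE)
  suppressWarnings(nested_community(df))
}
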