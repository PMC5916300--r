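# One-command orchestration: inputs -> distances -> TQE/PQE apportionment
# with SES at three scales -> per-gene robustness -> phylogenetic signal
# globally and per atoll -> consolidated JSON/CSV report.

#' Read a pipeline configuration file
#'
#' YAML (`.yaml`/`.yml`, requires the \pkg{yaml} package) or JSON. Fields:
#' `tree`, `alignments` (vector of FASTA paths, optional), `traits`,
#' `community` (paths); `n_perm` and `seed` (mandatory); optional
#' `halve_distances` (default `FALSE`), `fecundity_mode` (`"measured"`,
#' `"interpolated"` or `"both"`, default `"both"`), `out_dir`.
#'
#' @param path config file path.
#' @return a validated config list.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML config requires the 'yaml' package; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (is.null(cfg$seed) || is.null(cfg$n_perm)) {
    stop("config must set seed and n_perm")
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg$n_perm <- as.integer(cfg$n_perm)
  if (is.null(cfg$halve_distances)) cfg$halve_distances <- FALSE
  if (is.null(cfg$fecundity_mode)) cfg$fecundity_mode <- "both"
  cfg$fecundity_mode <- match.arg(cfg$fecundity_mode,
                                  c("both", "measured", "interpolated"))
  for (f in c("tree", "traits", "community")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      stop("config path does not exist: ", cfg[[f]])
    }
  }
  cfg
}

#' Run the full community-assembly analysis
#'
#' Orchestrates the whole pipeline on loaded objects: cross-validation and
#' exclusion logging, Gower trait distances (total and per trait, with
#' the fecundity variants), genetic p-distances (per gene and
#' concatenated), the TQE/PQE SES grid at the three spatial scales,
#' per-gene robustness, Blomberg's K for the quantitative traits (with and
#' without measurement error, globally and per atoll) and the
#' Maddison-Slatkin test for habitat association.
#'
#' @param tree [ape::phylo].
#' @param traits `trait_table` of individuals ([read_traits()]).
#' @param community [nested_community].
#' @param alignments optional list from [read_alignments()]; when absent
#'   the phylogeny rows use patristic distances instead of p-distances.
#' @param n_perm permutations for every test.
#' @param seed master seed; stage seeds are derived as small fixed
#'   offsets.
#' @param halve_distances divide all distances by 2 before QE.
#' @param fecundity_mode `"both"`, `"measured"` or `"interpolated"`.
#' @return list of class `reef_report`: `table1` (TQE/PQE grid),
#'   `gene_robustness`, `table2` (per-atoll K), `signal` (global K and
#'   Maddison-Slatkin), `fecundity`, `exclusions`, `provenance`.
#' @export
run_full_analysis <- function(tree, traits, community, alignments = NULL,
                              n_perm = 999, seed, halve_distances = FALSE,
                              fecundity_mode = "both") {
  if (missing(seed)) stop("seed is mandatory")
  stage <- function(nm, code) {
    tryCatch(code, error = function(e)
      stop("stage '", nm, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  val <- stage("validate", validate_dataset(
    tree = tree, alignments = alignments, traits = traits,
    community = community))
  comm <- val$community
  tree <- val$tree
  traits <- val$traits

  # species-mean trait table
  body <- tapply(traits$carapace_length, traits$species, mean)
  habitat <- tapply(traits$habitat_assoc, traits$species, function(z) z[1])
  fec <- stage("fecundity", tryCatch(build_fecundity(traits),
                                     error = function(e) NULL))

  sp <- comm$species
  mk_df <- function(cols) {
    df <- as.data.frame(cols, stringsAsFactors = FALSE)
    rownames(df) <- sp
    df
  }
  trait_df <- mk_df(list(body_size = as.numeric(body[sp]),
                         habitat_assoc = as.character(habitat[sp])))
  fec_measured <- fec_interp <- NULL
  if (!is.null(fec)) {
    fm <- stats::setNames(rep(NA_real_, length(sp)), sp)
    fm[fec$species_means$species] <- fec$species_means$fecundity
    fec_measured <- fm
    if (!is.null(fec$interpolated)) {
      fi <- stats::setNames(fec$interpolated$fecundity,
                            fec$interpolated$species)[sp]
      fec_interp <- fi
    }
  }

  D_list <- list()
  tdf <- trait_df
  if (!is.null(fec_measured) && fecundity_mode != "interpolated") {
    tdf$fecundity <- as.numeric(fec_measured)
  }
  if (!is.null(fec_interp) && fecundity_mode == "interpolated") {
    tdf$fecundity <- as.numeric(fec_interp)
  }
  D_list$total_traits <- stage("distances", gower_distance(tdf))
  if (!is.null(fec_interp) && fecundity_mode == "both") {
    tdf2 <- trait_df
    tdf2$fecundity <- as.numeric(fec_interp)
    D_list$total_traits_interpolated_fecundity <- gower_distance(tdf2)
  }
  D_list$body_size <- gower_distance(trait_df["body_size"])
  D_list$habitat_association <- gower_distance(trait_df["habitat_assoc"])

  gene_sources <- character(0)
  if (!is.null(alignments) && length(alignments)) {
    D_list$consensus <- stage("pdistance", concat_p_distance(alignments))
    for (g in names(alignments)) {
      D_list[[g]] <- p_distance(alignments[[g]])
      gene_sources <- c(gene_sources, g)
    }
  } else if (!is.null(tree)) {
    D_list$consensus <- patristic_distance(tree)
    D_list$consensus <- D_list$consensus / max(D_list$consensus)
  }

  table1 <- stage("qe", tqe_pqe_report(
    comm, D_list, n_perm = n_perm, seed = seed,
    halve = halve_distances))
  # extension, clearly labelled: Holm correction across the three levels
  # of each row (the primary grid stays uncorrected)
  p_cols <- paste0("p_", QE_LEVELS)
  holm <- t(apply(table1[p_cols], 1, stats::p.adjust, method = "holm"))
  colnames(holm) <- paste0("p_holm_", QE_LEVELS)
  table1 <- cbind(table1, holm)

  robustness <- NULL
  if (length(gene_sources) >= 2) {
    robustness <- gene_robustness_summary(table1, consensus = "consensus",
                                          genes = gene_sources)
  }

  signal <- list()
  table2 <- NULL
  if (!is.null(tree)) {
    ind_body <- data.frame(species = traits$species,
                           value = traits$carapace_length)
    signal$body_size_k <- stage("signal", blomberg_k(
      tree, stats::setNames(as.numeric(body), names(body))[tree$tip.label],
      n_perm = n_perm, seed = seed + 11))
    signal$body_size_k_me <- blomberg_k_me(tree, ind_body,
                                           n_perm = n_perm, seed = seed + 12)
    if (!is.null(fec_measured) && sum(!is.na(fec_measured)) >= 4) {
      mtips <- names(fec_measured)[!is.na(fec_measured)]
      sub <- ape::keep.tip(tree, intersect(mtips, tree$tip.label))
      signal$fecundity_k <- blomberg_k(sub, fec_measured[sub$tip.label],
                                       n_perm = n_perm, seed = seed + 13)
    }
    signal$habitat_ms <- maddison_slatkin(
      tree, stats::setNames(as.character(habitat), names(habitat)),
      n_perm = n_perm, seed = seed + 14)
    table2 <- k_per_atoll(tree, comm, ind_body, n_perm = n_perm,
                          seed = seed + 20)
  }

  rep <- list(
    table1 = table1,
    gene_robustness = robustness,
    table2 = table2,
    signal = signal,
    fecundity = fec,
    exclusions = val$exclusions,
    gene_missing = val$gene_missing,
    provenance = list(seed = seed, n_perm = n_perm,
                      halve_distances = halve_distances,
                      fecundity_mode = fecundity_mode,
                      levels = QE_LEVELS,
                      alpha = 0.05))
  class(rep) <- "reef_report"
  rep
}

#' Gene-by-gene robustness summary
#'
#' For each gene row of a [tqe_pqe_report()] grid, agreement with the
#' consensus row: per-level SES sign agreement, significance agreement at
#' `alpha`, and the correlation of SES values across levels. A
#' Holm-corrected significance column is included as a clearly labelled
#' extension.
#'
#' @param table1 a `qe_report` data frame.
#' @param consensus name of the consensus row (default `"consensus"`).
#' @param genes names of the gene rows (default: all rows except the
#'   consensus and the trait rows).
#' @param alpha significance threshold (default 0.05).
#' @return data frame: `gene`, `sign_agreement`, `signif_agreement`,
#'   `ses_correlation`.
#' @export
gene_robustness_summary <- function(table1, consensus = "consensus",
                                    genes = NULL, alpha = 0.05) {
  stopifnot(consensus %in% table1$source)
  if (is.null(genes)) {
    genes <- setdiff(table1$source,
                     c(consensus, "total_traits", "body_size",
                       "habitat_association",
                       "total_traits_interpolated_fecundity"))
  }
  if (length(genes) < 2) stop("need >= 2 gene rows")
  ses_cols <- paste0("ses_", QE_LEVELS)
  p_cols <- paste0("p_", QE_LEVELS)
  cons <- table1[table1$source == consensus, , drop = FALSE]
  cs <- as.numeric(cons[ses_cols]); cp <- as.numeric(cons[p_cols])
  rows <- lapply(genes, function(g) {
    gr <- table1[table1$source == g, , drop = FALSE]
    gs <- as.numeric(gr[ses_cols]); gp <- as.numeric(gr[p_cols])
    data.frame(
      gene = g,
      sign_agreement = mean(sign(gs) == sign(cs)),
      signif_agreement = mean((gp < alpha) == (cp < alpha)),
      ses_correlation = if (stats::sd(gs) > 0 && stats::sd(cs) > 0) {
        stats::cor(gs, cs)
      } else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a `reef_report` to disk
#'
#' Emits `report.json`, `table1.csv` and (when present) `table2.csv` under
#' `dir`. The JSON is deterministic for a fixed config and seed: no
#' timestamps are recorded.
#'
#' @param report a `reef_report`.
#' @param dir output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  t1 <- report$table1
  attr(t1, "tests") <- NULL
  utils::write.csv(as.data.frame(t1), file.path(dir, "table1.csv"),
                   row.names = FALSE)
  if (!is.null(report$table2)) {
    utils::write.csv(report$table2, file.path(dir, "table2.csv"),
                     row.names = FALSE)
  }
  js <- list(
    table1 = as.data.frame(t1),
    table2 = report$table2,
    gene_robustness = report$gene_robustness,
    signal = lapply(report$signal, function(s)
      s[intersect(names(s), c("K", "sigma", "p_value", "observed_steps",
                              "n_perm"))]),
    exclusions = report$exclusions,
    provenance = report$provenance)
  jsonlite::write_json(js, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' @export
print.reef_report <- function(x, ...) {
  cat("reef_report\n")
  cat("TQE/PQE grid (SES, p at", paste(QE_LEVELS, collapse = " / "), "):\n")
  t1 <- x$table1; attr(t1, "tests") <- NULL
  print(as.data.frame(t1), digits = 3)
  if (!is.null(x$table2)) {
    cat("\nPer-atoll Blomberg K:\n")
    print(x$table2, digits = 3)
  }
  invisible(x)
}
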