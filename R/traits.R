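# Fecundity trait construction: egg volume from paired diameters,
# egg-size-adjusted egg number, and body-size interpolation to the full
# species pool. The adjustment is isolated in adjusted_fecundity() so an
# alternative formula can be swapped in without touching the pipeline.

#' Mean egg volume from paired diameters
#'
#' Each egg is modelled as a prolate spheroid with long axis `L` and two
#' short axes `S` (the third axis is not measured and is taken equal to the
#' short one): `V = (pi/6) L S^2`. Returns the mean over the measured eggs.
#'
#' @param long_diams,short_diams paired diameters (micrometres), typically
#'   10 eggs; at least 3 required. `long >= short` per egg.
#' @return mean egg volume in cubic micrometres.
#' @export
egg_volume <- function(long_diams, short_diams) {
  if (length(long_diams) != length(short_diams)) {
    stop("diameter vectors must be paired")
  }
  ok <- !is.na(long_diams) & !is.na(short_diams)
  L <- long_diams[ok]; S <- short_diams[ok]
  if (length(L) < 3) stop("fewer than 3 eggs measured")
  if (any(L <= 0) || any(S <= 0)) stop("egg diameters must be positive")
  if (any(L < S)) stop("long diameter smaller than short diameter")
  mean(pi / 6 * L * S^2)
}

#' Egg-size-adjusted fecundity
#'
#' Rescales a female's egg count by the ratio of her mean egg volume to
#' the cohort mean volume: `adjusted = egg_count * (V / Vbar)`. This is
#' the egg number expressed in units of average-sized eggs, so it is
#' invariant to the units in which volume is measured.
#'
#' @param egg_count integer egg count (> 0), vectorized.
#' @param mean_egg_volume mean egg volume per female, same length.
#' @param cohort_volumes mean egg volumes of all retained gravid females
#'   (defines the reference `Vbar`; length >= 2).
#' @return adjusted fecundity, same length as `egg_count`.
#' @export
adjusted_fecundity <- function(egg_count, mean_egg_volume, cohort_volumes) {
  if (length(cohort_volumes) < 2) stop("cohort of size < 2")
  if (any(egg_count <= 0)) stop("egg_count must be positive")
  if (any(mean_egg_volume <= 0) || any(cohort_volumes <= 0)) {
    stop("volumes must be positive")
  }
  egg_count * (mean_egg_volume / mean(cohort_volumes))
}

#' Diagnostic fits behind the fecundity adjustment
#'
#' Reproduces the exploratory analyses the adjustment is motivated by:
#' linear regressions (with ANOVA tables) of egg number on mean egg volume
#' and on female body size, plus a smooth line of best fit (a GAM via
#' \pkg{mgcv} when available and when there are enough females; otherwise
#' the linear fit, noted in the output). These diagnostics never alter the
#' adjustment itself.
#'
#' @param females data frame with columns `egg_count`, `mean_egg_volume`,
#'   `carapace_length`.
#' @return list of fit summaries: `lm_volume`, `lm_size` (coef, se,
#'   anova p), `smooth` (fitted values and the method used).
#' @export
fecundity_diagnostics <- function(females) {
  stopifnot(all(c("egg_count", "mean_egg_volume", "carapace_length")
                %in% names(females)))
  tidy_lm <- function(f) {
    fit <- stats::lm(f, data = females)
    an <- stats::anova(fit)
    list(coef = stats::coef(fit),
         se = summary(fit)$coefficients[, "Std. Error"],
         r_squared = summary(fit)$r.squared,
         anova_p = an[["Pr(>F)"]][1])
  }
  out <- list(
    lm_volume = tidy_lm(egg_count ~ mean_egg_volume),
    lm_size = tidy_lm(egg_count ~ carapace_length))
  n <- nrow(females)
  if (n >= 10 && requireNamespace("mgcv", quietly = TRUE)) {
    k <- max(3, min(5, n - 2))
    g <- mgcv::gam(egg_count ~ s(carapace_length, k = k), data = females)
    out$smooth <- list(method = "gam",
                       fitted = as.numeric(stats::fitted(g)))
  } else {
    fit <- stats::lm(egg_count ~ carapace_length, data = females)
    out$smooth <- list(method = "lm (too few females for a smoother)",
                       fitted = as.numeric(stats::fitted(fit)))
  }
  out
}

#' Interpolate fecundity to all species from body size
#'
#' Fits `log(adjusted fecundity) ~ log(body size)` by least squares on the
#' species with measured fecundity and predicts for the rest. Measured
#' species keep their observed means. Deterministic: the `seed` argument
#' is accepted for interface symmetry but unused.
#'
#' @param measured data frame with columns `species` and `fecundity`
#'   (species-mean adjusted fecundity); >= 3 species.
#' @param body_sizes named vector of body size for *all* species.
#' @param seed ignored (reserved).
#' @return data frame: `species`, `body_size`, `fecundity`, `measured`
#'   (logical); attributes `slope`, `slope_se`, `intercept`.
#' @export
interpolate_fecundity <- function(measured, body_sizes, seed = NULL) {
  stopifnot(all(c("species", "fecundity") %in% names(measured)))
  measured$species <- normalize_species(measured$species)
  names(body_sizes) <- normalize_species(names(body_sizes))
  if (nrow(measured) < 3) stop("interpolation unidentifiable: < 3 measured species")
  if (any(measured$fecundity <= 0)) stop("fecundity must be positive")
  miss <- setdiff(measured$species, names(body_sizes))
  if (length(miss)) stop("no body size for: ", paste(miss, collapse = ", "))
  fit <- stats::lm(log(fec) ~ log(size), data = data.frame(
    fec = measured$fecundity,
    size = as.numeric(body_sizes[measured$species])))
  cf <- stats::coef(fit)
  # exact power-law inputs are legitimate; silence the perfect-fit note
  se <- suppressWarnings(summary(fit))$coefficients[, "Std. Error"]
  sp <- names(body_sizes)
  pred <- exp(cf[1] + cf[2] * log(as.numeric(body_sizes)))
  out <- data.frame(species = sp, body_size = as.numeric(body_sizes),
                    fecundity = pred, measured = sp %in% measured$species,
                    stringsAsFactors = FALSE)
  keep <- match(measured$species, out$species)
  out$fecundity[keep] <- measured$fecundity
  attr(out, "slope") <- unname(cf[2])
  attr(out, "slope_se") <- unname(se[2])
  attr(out, "intercept") <- unname(cf[1])
  rownames(out) <- NULL
  out
}

#' Build the per-species fecundity trait from an individual trait table
#'
#' Convenience wrapper: extracts gravid females (rows with `egg_count`),
#' computes per-female mean egg volume from the `egg_long_diam_*` /
#' `egg_short_diam_*` columns, adjusts counts by egg size, averages to
#' species means, and (optionally) interpolates to all species by body
#' size.
#'
#' @param traits a `trait_table` ([read_traits()]).
#' @param interpolate also return body-size-interpolated values for all
#'   species.
#' @return list: `females` (per-female table with `adjusted_fecundity`),
#'   `species_means`, and `interpolated` (when requested).
#' @export
build_fecundity <- function(traits, interpolate = TRUE) {
  gr <- traits[!is.na(traits$egg_count), , drop = FALSE]
  if (nrow(gr) < 2) stop("fewer than 2 gravid females")
  longs <- grep("^egg_long_diam", names(traits), value = TRUE)
  shorts <- grep("^egg_short_diam", names(traits), value = TRUE)
  if (!length(longs) || length(longs) != length(shorts)) {
    stop("paired egg_long_diam_*/egg_short_diam_* columns required")
  }
  vols <- vapply(seq_len(nrow(gr)), function(i)
    egg_volume(as.numeric(gr[i, longs]), as.numeric(gr[i, shorts])),
    numeric(1))
  gr$mean_egg_volume <- vols
  gr$adjusted_fecundity <- adjusted_fecundity(gr$egg_count, vols, vols)
  sp_mean <- tapply(gr$adjusted_fecundity, gr$species, mean)
  out <- list(
    females = gr[c("species", "carapace_length", "egg_count",
                   "mean_egg_volume", "adjusted_fecundity")],
    species_means = data.frame(species = names(sp_mean),
                               fecundity = as.numeric(sp_mean),
                               stringsAsFactors = FALSE))
  if (interpolate) {
    body <- tapply(traits$carapace_length, traits$species, mean)
    out$interpolated <- interpolate_fecundity(
      out$species_means, stats::setNames(as.numeric(body), names(body)))
  }
  out
}
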