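#' Förster transfer efficiency at a given donor--acceptor distance
#'
#' The transfer efficiency of a single donor--acceptor pair falls with the
#' sixth power of their separation: `E = R0^6 / (R0^6 + r^6)`, where `R0` is
#' the Förster radius of the pair (the distance at which exactly half of the
#' donor's excitations are transferred).
#'
#' @param r Donor--acceptor distance in nm (> 0). Vectorised.
#' @param R0 Förster radius in nm (> 0). For a GFP--mCherry pair a typical
#'   value is about 5 nm.
#' @return Transfer efficiency in `[0, 1]`, strictly decreasing in `r`.
#' @examples
#' forster_efficiency(5, 5)   # 0.5 at r = R0
#' forster_efficiency(10, 5)  # 1/65
#' @export
forster_efficiency <- function(r, R0) {
  if (any(!is.finite(r)) || any(r <= 0)) {
    stop("`r` must be a positive finite distance (nm).", call. = FALSE)
  }
  if (any(!is.finite(R0)) || any(R0 <= 0)) {
    stop("`R0` must be a positive finite distance (nm).", call. = FALSE)
  }
  x <- (r / R0)^6
  1 / (1 + x)
}

#' Combine several independent transfer pathways of one donor
#'
#' A donor with more than one acceptor within range (for example the
#' intramolecular acceptor of a dual-tagged molecule plus the cross-partner
#' acceptor in a dimer) is depopulated by competing first-order pathways.
#' Rates, not probabilities, add: each single-pathway efficiency `e` is
#' converted to its rate relative to donor decay ("odds") `o = e / (1 - e)`,
#' the odds are summed, and the combined efficiency is
#' `sum(o) / (1 + sum(o))`.
#'
#' @param e_list Numeric vector of single-acceptor efficiencies, each in
#'   `[0, 1]`. An efficiency of exactly 1 denotes saturated transfer and
#'   yields a combined efficiency of 1.
#' @param rule `"rate"` (the default, physically correct for competing
#'   depopulation pathways) or `"or"`, the probabilistic-OR alternative
#'   `1 - prod(1 - e)` retained for sensitivity analysis.
#' @return Combined per-donor efficiency in `[0, 1]`; commutative in the
#'   pathway order and never below `max(e_list)`.
#' @examples
#' combine_acceptors(c(0.5, 0.5)) # 2/3
#' combine_acceptors(c(0.2, 0))   # 0.2
#' @export
combine_acceptors <- function(e_list, rule = c("rate", "or")) {
  rule <- match.arg(rule)
  if (length(e_list) == 0) return(0)
  if (any(!is.finite(e_list)) || any(e_list < 0) || any(e_list > 1)) {
    stop("every pathway efficiency must lie in [0, 1].", call. = FALSE)
  }
  if (any(e_list == 1)) return(1)
  if (rule == "or") return(1 - prod(1 - e_list))
  o <- sum(e_list / (1 - e_list))
  o / (1 + o)
}

#' Random assortment of dual-homotag molecules into dimer species
#'
#' When donor-only-tagged and acceptor-only-tagged molecules are co-expressed
#' and dimerize at random, dimers come in three species: donor/donor (GG),
#' donor/acceptor (GM, the only FRET-competent one) and acceptor/acceptor
#' (MM), with binomial frequencies `p^2`, `2p(1-p)` and `(1-p)^2`.
#'
#' @param p_gfp Probability that a molecule carries the donor homotag
#'   (`0.5` for the 1:1 co-expression the dual-tag vector enforces).
#' @return A tibble with columns `species` (`"GG"`, `"GM"`, `"MM"`) and
#'   `prob`, summing to 1.
#' @export
assort_2in1_dimers <- function(p_gfp) {
  if (!is.finite(p_gfp) || p_gfp < 0 || p_gfp > 1) {
    stop("`p_gfp` must lie in [0, 1].", call. = FALSE)
  }
  tibble::tibble(
    species = c("GG", "GM", "MM"),
    prob = c(p_gfp^2, 2 * p_gfp * (1 - p_gfp), (1 - p_gfp)^2)
  )
}

#' Transfer-model parameters for a donor/acceptor pair
#'
#' Bundles the molecular and instrumental parameters of the forward model.
#' Efficiencies may be given directly or derived from effective distances via
#' [forster_efficiency()]; supplying both a distance and the matching
#' efficiency is an error, because the Förster law then fixes the efficiency.
#'
#' @param E_intra Intramolecular transfer efficiency between the two tags of
#'   one dual-tagged molecule, in `[0, 1]`. Ignored (and disallowed) when
#'   `r_intra` is given.
#' @param E_inter Inter-monomer transfer efficiency across the dimer
#'   interface, in `[0, 1]`. Ignored (and disallowed) when `r_inter` is given.
#' @param r_intra,r_inter Optional effective donor--acceptor distances in nm;
#'   when supplied the corresponding efficiency is `forster_efficiency(r, R0)`.
#' @param R0 Förster radius in nm (default 5.0, the GFP--mCherry scale).
#' @param beta_bleed Fraction of donor emission collected in the acceptor
#'   detection band under donor excitation (spectral bleed-through), in
#'   `[0, 1)`.
#' @param alpha_direct Fraction of full acceptor excitation achieved by the
#'   donor excitation line (direct excitation crosstalk), in `[0, 1)`.
#' @param g_donor,g_acceptor Detector gain/brightness scales, in intensity
#'   units per fluorophore (> 0).
#' @return An object of class `fret_params`.
#' @export
fret_params <- function(E_intra = 0.15, E_inter = 0.30,
                        r_intra = NULL, r_inter = NULL, R0 = 5.0,
                        beta_bleed = 0.05, alpha_direct = 0.02,
                        g_donor = 1, g_acceptor = 1) {
  if (!is.finite(R0) || R0 <= 0) stop("`R0` must be > 0.", call. = FALSE)
  if (!is.null(r_intra)) {
    if (!missing(E_intra)) {
      stop("give `r_intra` or `E_intra`, not both: the Forster law fixes E.",
           call. = FALSE)
    }
    E_intra <- forster_efficiency(r_intra, R0)
  }
  if (!is.null(r_inter)) {
    if (!missing(E_inter)) {
      stop("give `r_inter` or `E_inter`, not both: the Forster law fixes E.",
           call. = FALSE)
    }
    E_inter <- forster_efficiency(r_inter, R0)
  }
  stopifnot(
    is.finite(E_intra), E_intra >= 0, E_intra <= 1,
    is.finite(E_inter), E_inter >= 0, E_inter <= 1,
    is.finite(beta_bleed), beta_bleed >= 0, beta_bleed < 1,
    is.finite(alpha_direct), alpha_direct >= 0, alpha_direct < 1,
    is.finite(g_donor), g_donor > 0,
    is.finite(g_acceptor), g_acceptor > 0
  )
  structure(
    list(E_intra = E_intra, E_inter = E_inter, R0 = R0,
         r_intra = r_intra, r_inter = r_inter,
         beta_bleed = beta_bleed, alpha_direct = alpha_direct,
         g_donor = g_donor, g_acceptor = g_acceptor),
    class = "fret_params"
  )
}

#' @export
print.fret_params <- function(x, ...) {
  cat("<fret_params>\n")
  cat(sprintf("  E_intra = %.4g, E_inter = %.4g (R0 = %.3g nm)\n",
              x$E_intra, x$E_inter, x$R0))
  cat(sprintf("  bleed-through beta = %.4g, direct excitation alpha = %.4g\n",
              x$beta_bleed, x$alpha_direct))
  cat(sprintf("  gains: donor %.3g, acceptor %.3g\n", x$g_donor, x$g_acceptor))
  invisible(x)
}

# dimer fractions that encode the genotype x UV photo-equilibrium defaults
.default_dimer_fraction <- function(genotype, uv, residual_monomer = 0.05) {
  switch(genotype,
    WT = if (uv) 0.15 else 0.85,
    constitutive_dimer = 0.95,
    constitutive_monomer = residual_monomer,
    stop("unknown genotype: ", genotype, call. = FALSE)
  )
}

#' Molecular ground truth of a tagged population
#'
#' Describes the dimer/monomer state of the tagged photoreceptor population
#' in one condition: the labelling scheme, the genotype, UV-B exposure and the
#' fraction of molecules residing in dimers. When `dimer_fraction` is omitted
#' it is derived from genotype and UV state: the wild type sits at a
#' dimer-rich photo-equilibrium in darkness (0.85) and monomerizes under UV-B
#' (0.15); the constitutive dimer stays at 0.95 and the constitutive monomer
#' at a small residual (default 0.05, modelling weak transient interactions
#' between monomers) regardless of UV.
#'
#' @param construct `"NcCg"` (one molecule carrying the acceptor at its
#'   N-terminus and the donor at its C-terminus) or `"TwoInOne"`
#'   (co-expressed donor-only-tagged and acceptor-only-tagged molecules).
#' @param genotype `"WT"`, `"constitutive_monomer"` or `"constitutive_dimer"`.
#' @param uv Logical; whether the tissue was UV-B exposed.
#' @param dimer_fraction Fraction of tagged molecules residing in dimers, in
#'   `[0, 1]`. Defaults by genotype and UV state as described above.
#' @param p_gfp For `"TwoInOne"`, the probability a molecule carries the
#'   donor homotag (default 0.5, a 1:1 co-expression ratio). `p_gfp = 1`
#'   gives the donor-only negative control, `p_gfp = 0` the acceptor-only one.
#' @param residual_monomer Residual dimer fraction of the constitutive
#'   monomer (default 0.05; set 0 for a perfectly monomeric population).
#' @return An object of class `population_state`.
#' @export
population_state <- function(construct = c("NcCg", "TwoInOne"),
                             genotype = c("WT", "constitutive_monomer",
                                          "constitutive_dimer"),
                             uv = FALSE, dimer_fraction = NULL, p_gfp = 0.5,
                             residual_monomer = 0.05) {
  construct <- match.arg(construct)
  genotype <- match.arg(genotype)
  stopifnot(is.logical(uv), length(uv) == 1L,
            is.finite(p_gfp), p_gfp >= 0, p_gfp <= 1,
            is.finite(residual_monomer),
            residual_monomer >= 0, residual_monomer <= 0.2)
  if (is.null(dimer_fraction)) {
    dimer_fraction <- .default_dimer_fraction(genotype, uv, residual_monomer)
  }
  stopifnot(is.finite(dimer_fraction),
            dimer_fraction >= 0, dimer_fraction <= 1)
  if (genotype == "constitutive_monomer" && dimer_fraction > 0.2) {
    stop("a constitutive monomer cannot have dimer_fraction > 0.2.",
         call. = FALSE)
  }
  structure(
    list(construct = construct, genotype = genotype, uv = uv,
         dimer_fraction = dimer_fraction, p_gfp = p_gfp),
    class = "population_state"
  )
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("<population_state> %s / %s / %s UV, dimer fraction %.3g\n",
              x$construct, x$genotype, if (x$uv) "+" else "-",
              x$dimer_fraction))
  invisible(x)
}

#' Species mixture implied by a population state
#'
#' Expands a [population_state()] into the FRET species it contains, one row
#' per assembly type. For the dual-tag (`NcCg`) construct, dimer donors have
#' two transfer pathways (intramolecular and inter-monomer, combined by
#' [combine_acceptors()]) and monomer donors keep only the intramolecular
#' pathway. For the co-expression (`TwoInOne`) construct, dimers assort
#' randomly into GG/GM/MM species and only the mixed GM dimer transfers, via
#' the inter-monomer pathway; monomers and like-tag dimers have per-donor
#' efficiency 0.
#'
#' @param state A [population_state()].
#' @param params A [fret_params()].
#' @param rule Pathway-combination rule passed to [combine_acceptors()].
#' @return A tibble of class `species_mix` with columns `species`, `weight`
#'   (assembly fraction, summing to 1), `n_mol`, `n_donor`, `n_acceptor`
#'   (per assembly), `efficiency` (per donor) and `paths` (list column of
#'   per-pathway single-acceptor efficiencies).
#' @export
species_mixture <- function(state, params, rule = c("rate", "or")) {
  stopifnot(inherits(state, "population_state"), inherits(params, "fret_params"))
  rule <- match.arg(rule)
  f <- state$dimer_fraction
  if (state$construct == "NcCg") {
    mix <- tibble::tibble(
      species    = c("NcCg_dimer", "NcCg_monomer"),
      weight     = c(f / 2, 1 - f),            # assemblies per molecule
      n_mol      = c(2L, 1L),
      n_donor    = c(2L, 1L),
      n_acceptor = c(2L, 1L),
      paths      = list(c(params$E_intra, params$E_inter), params$E_intra)
    )
  } else {
    p <- state$p_gfp
    ass <- assort_2in1_dimers(p)
    mix <- tibble::tibble(
      species    = c("GG_dimer", "GM_dimer", "MM_dimer",
                     "G_monomer", "M_monomer"),
      weight     = c(f / 2 * ass$prob, (1 - f) * p, (1 - f) * (1 - p)),
      n_mol      = c(2L, 2L, 2L, 1L, 1L),
      n_donor    = c(4L, 2L, 0L, 2L, 0L),
      n_acceptor = c(0L, 2L, 4L, 0L, 2L),
      paths      = list(numeric(0), params$E_inter, numeric(0),
                        numeric(0), numeric(0))
    )
  }
  mix <- dplyr::filter(mix, .data$weight > 0)
  mix$weight <- mix$weight / sum(mix$weight)
  mix$efficiency <- purrr::map_dbl(mix$paths, combine_acceptors, rule = rule)
  class(mix) <- c("species_mix", class(mix))
  mix
}

#' Donor-weighted mean transfer efficiency of a mixture
#'
#' The observable donor quenching is the average of per-donor efficiencies
#' over all donors in the population (equal per-donor brightness assumed).
#'
#' @param mix A [species_mixture()] result.
#' @return Mean efficiency in `[0, 1]`; 0 for a donor-free mixture.
#' @export
mean_efficiency <- function(mix) {
  d <- sum(mix$weight * mix$n_donor)
  if (d <= 0) return(0)
  sum(mix$weight * mix$n_donor * mix$efficiency) / d
}

#' Expected channel intensities of a species mixture
#'
#' The measurement model behind the sensitized-emission readout. With mean
#' per-donor efficiency `E`: the donor channel (donor excitation, donor band)
#' is proportional to `g_donor * (1 - E)` per donor — the donor intensity a
#' microscope records is the *post-transfer* value; the FRET channel (donor
#' excitation, acceptor band) collects sensitized emission
#' `g_acceptor * E` per donor plus two artifacts, donor bleed-through
#' `beta_bleed * I_donor` and direct acceptor excitation
#' `alpha_direct * g_acceptor` per acceptor; the acceptor channel (acceptor
#' excitation) is `g_acceptor` per acceptor.
#'
#' @param mix A [species_mixture()] result.
#' @param params A [fret_params()].
#' @param donor_density Tagged molecules per pixel (>= 0). Vectorised, so a
#'   whole expression map can be evaluated in one call.
#' @return A list with elements `donor_488`, `fret_488`, `acceptor_552`
#'   (same shape as `donor_density`) and scalars `mean_eff`, `donors_per_mol`,
#'   `acceptors_per_mol`.
#' @export
expected_channel_intensities <- function(mix, params, donor_density) {
  stopifnot(inherits(params, "fret_params"))
  if (any(donor_density < 0)) {
    stop("`donor_density` must be non-negative.", call. = FALSE)
  }
  mol <- sum(mix$weight * mix$n_mol)
  d_per_mol <- sum(mix$weight * mix$n_donor) / mol
  a_per_mol <- sum(mix$weight * mix$n_acceptor) / mol
  e_bar <- mean_efficiency(mix)
  D <- donor_density * d_per_mol
  A <- donor_density * a_per_mol
  donor <- params$g_donor * D * (1 - e_bar)
  fret <- params$g_acceptor * D * e_bar +
    params$beta_bleed * donor +
    params$alpha_direct * params$g_acceptor * A
  acceptor <- params$g_acceptor * A
  list(donor_488 = donor, fret_488 = fret, acceptor_552 = acceptor,
       mean_eff = e_bar, donors_per_mol = d_per_mol,
       acceptors_per_mol = a_per_mol)
}

#' Expected sensitized-emission ratio of a mixture
#'
#' Closed-form value of the acceptor/donor intensity ratio under donor
#' excitation, artifacts included: the quantity the random-region estimator
#' converges to as noise vanishes.
#'
#' @inheritParams expected_channel_intensities
#' @return Ratio `fret_488 / donor_488` (unitless); `NaN` for a donor-free
#'   mixture.
#' @export
expected_sensitized_ratio <- function(mix, params) {
  ch <- expected_channel_intensities(mix, params, donor_density = 1)
  ch$fret_488 / ch$donor_488
}

# mixture with every transfer pathway's rate scaled by (1 - completeness):
# what remains of the acceptor population after a bleach
.bleach_mix <- function(mix, bleach_completeness, rule = "rate") {
  stopifnot(bleach_completeness >= 0, bleach_completeness <= 1)
  scale_path <- function(e) {
    if (bleach_completeness == 1) return(rep(0, length(e)))
    o <- ifelse(e >= 1, Inf, e / (1 - e)) * (1 - bleach_completeness)
    ifelse(is.infinite(o), 1, o / (1 + o))
  }
  mix$paths <- purrr::map(mix$paths, scale_path)
  mix$efficiency <- purrr::map_dbl(mix$paths, combine_acceptors, rule = rule)
  mix
}

#' Expected donor dequenching after acceptor photobleaching
#'
#' Destroying the acceptor removes the transfer pathways, so the donor
#' intensity rises from `(1 - E)` to `(1 - E')`, where `E'` is the mean
#' efficiency recomputed with every pathway's transfer rate scaled by
#' `1 - bleach_completeness`. The reported statistic is the percent increase
#' `100 * (E - E') / (1 - E)`; at complete bleach this is the classical
#' `100 * E / (1 - E)`.
#'
#' @param mix A [species_mixture()] result.
#' @param params A [fret_params()] (gains cancel; kept for interface symmetry).
#' @param bleach_completeness Fraction of the acceptor population destroyed,
#'   in `[0, 1]`.
#' @param rule Pathway-combination rule, see [combine_acceptors()].
#' @return Expected percent increase of donor intensity (>= 0).
#' @export
expected_bleach_increase <- function(mix, params, bleach_completeness = 1,
                                     rule = c("rate", "or")) {
  rule <- match.arg(rule)
  e_pre <- mean_efficiency(mix)
  if (e_pre >= 1) {
    stop("mean efficiency 1 implies a fully quenched donor: ",
         "recovery is unbounded.", call. = FALSE)
  }
  e_post <- mean_efficiency(.bleach_mix(mix, bleach_completeness, rule))
  100 * (e_pre - e_post) / (1 - e_pre)
}
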