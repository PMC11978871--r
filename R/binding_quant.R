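#' A quantified gel lane
#'
#' One lane of a native gel-shift titration: the protein concentration and
#' the intensities of the free-RNA band (index 0) through the fully shifted
#' band (index \code{n_sites}). Band n corresponds to a duplex with n sites
#' occupied; a 112 bp duplex is treated as carrying 8 protein binding sites.
#'
#' @param protein_conc Protein concentration, nM (>= 0).
#' @param band_intensities Numeric vector of \code{n_sites + 1} non-negative
#'   intensities, band 0 first.
#' @return A \code{gel_lane} object.
#' @export
gel_lane <- function(protein_conc, band_intensities) {
  stopifnot(protein_conc >= 0, length(band_intensities) >= 2,
            all(band_intensities >= 0))
  structure(list(protein_conc = protein_conc,
                 band_intensities = as.numeric(band_intensities),
                 n_sites = length(band_intensities) - 1L),
            class = "gel_lane")
}

#' Bound fraction of a multi-band gel lane
#'
#' Intensity-weighted mean site occupancy divided by the number of sites:
#' \deqn{\mathrm{bound\ fraction} = \frac{\sum_{n=0}^{N} I(n)\, n}{\sum_{n=0}^{N} I(n)\, N}}
#' where I(n) is the intensity of the nth complex band and N the number of
#' binding sites (8 for a 112 bp duplex).
#'
#' @param lane A \code{\link{gel_lane}}.
#' @return Bound fraction in [0, 1].
#' @export
bound_fraction <- function(lane) {
  stopifnot(inherits(lane, "gel_lane"))
  i <- lane$band_intensities
  if (sum(i) <= 0) stop("all band intensities are zero; bound fraction undefined")
  n <- 0:lane$n_sites
  sum(i * n) / (sum(i) * lane$n_sites)
}

#' Fit the Hill equation to a binding curve
#'
#' Least-squares fit of \eqn{f(c) = c^h / (K_d^h + c^h)} to measured bound
#' fractions. By default both the half-saturation concentration Kd and the
#' Hill coefficient h are free; \code{fix_h} constrains h (e.g. to 1 for
#' independent sites). The multi-site structure of the lane enters through
#' the bound-fraction weighting of \code{\link{bound_fraction}}, not through
#' h.
#'
#' @param concentrations Protein concentrations, nM (>= 4 distinct values).
#' @param bound_fractions Matching bound fractions in [0, 1].
#' @param fix_h Optional fixed Hill coefficient.
#' @return A \code{hill_fit}: \code{kd_nM}, \code{hill_coeff}, standard
#'   errors, \code{residual_norm}, \code{converged}.
#' @export
fit_hill <- function(concentrations, bound_fractions, fix_h = NULL) {
  stopifnot(length(concentrations) == length(bound_fractions),
            length(unique(concentrations)) >= 4,
            all(concentrations >= 0),
            all(bound_fractions >= 0 & bound_fractions <= 1))
  c_ <- as.numeric(concentrations)
  f_ <- as.numeric(bound_fractions)
  kd0 <- {
    pos <- c_ > 0
    i <- which.min(abs(f_[pos] - 0.5))
    max(c_[pos][i], min(c_[pos]))
  }
  fit <- tryCatch({
    if (is.null(fix_h)) {
      minpack.lm::nlsLM(f_ ~ c_^h / (kd^h + c_^h),
                        start = list(kd = kd0, h = 1),
                        lower = c(kd = 1e-9, h = 1e-3),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    } else {
      h_fixed <- fix_h
      minpack.lm::nlsLM(f_ ~ c_^h_fixed / (kd^h_fixed + c_^h_fixed),
                        start = list(kd = kd0), lower = c(kd = 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    }
  }, error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(kd_nM = NA_real_, hill_coeff = NA_real_,
                          kd_se = NA_real_, hill_se = NA_real_,
                          residual_norm = NA_real_, converged = FALSE,
                          message = conditionMessage(fit)),
                     class = "hill_fit"))
  }
  co <- summary(fit)$coefficients
  structure(list(kd_nM = co["kd", "Estimate"],
                 hill_coeff = if (is.null(fix_h)) co["h", "Estimate"] else fix_h,
                 kd_se = co["kd", "Std. Error"],
                 hill_se = if (is.null(fix_h)) co["h", "Std. Error"] else 0,
                 residual_norm = sqrt(sum(stats::residuals(fit)^2)),
                 converged = TRUE, message = NULL),
            class = "hill_fit")
}

#' The titration ladder used for quantitative gel shifts
#'
#' The 12-lane titration used for quantitative gel shifts: a zero-protein
#' reference lane followed by two-fold steps from 3.9 to 4000 nM
#' (0, 3.9, 7.8, 15.6, 31.3, 62.5, 125, 250, 500, 1000, 2000, 4000 nM).
#'
#' @return Numeric vector of concentrations in nM.
#' @export
emsa_ladder <- function() {
  c(0, 3.9, 7.8, 15.6, 31.3, 62.5, 125, 250, 500, 1000, 2000, 4000)
}

#' Simulate multi-band gel lanes from a Hill occupancy model
#'
#' Per lane, the per-site occupancy probability is
#' \eqn{p(c) = c^h / (K_d^h + c^h)}; band n receives intensity proportional
#' to the binomial mass \eqn{\binom{N}{n} p^n (1-p)^{N-n}}, optionally
#' perturbed by multiplicative Gaussian noise. Because the binomial mean is
#' \eqn{N p}, the bound fraction of a noiseless lane equals p(c) exactly.
#'
#' @param true_kd True half-saturation concentration, nM.
#' @param h True Hill coefficient.
#' @param n_sites Number of binding sites per duplex (default 8).
#' @param concentrations Ladder of protein concentrations, nM.
#' @param noise_sd SD of the multiplicative intensity noise (0 = noiseless).
#' @param seed Integer seed.
#' @param total_intensity Total lane intensity (arbitrary units).
#' @return List of \code{\link{gel_lane}} objects, one per concentration.
#' @export
simulate_gel <- function(true_kd, h = 1, n_sites = 8,
                         concentrations = emsa_ladder(), noise_sd = 0,
                         seed = 1L, total_intensity = 1000) {
  stopifnot(true_kd > 0, h > 0, n_sites >= 1, noise_sd >= 0)
  set.seed(seed)
  lapply(concentrations, function(cc) {
    p <- if (cc <= 0) 0 else cc^h / (true_kd^h + cc^h)
    ideal <- stats::dbinom(0:n_sites, n_sites, p) * total_intensity
    if (noise_sd > 0) {
      ideal <- pmax(ideal * (1 + stats::rnorm(n_sites + 1, 0, noise_sd)), 0)
    }
    gel_lane(cc, ideal)
  })
}

#' Bound-fraction curve and Hill fit from a set of lanes
#'
#' Applies \code{\link{bound_fraction}} to each lane (replicate lanes at the
#' same concentration are retained as separate points) and fits the Hill
#' equation.
#'
#' @param lanes List of \code{\link{gel_lane}} objects.
#' @param fix_h Optional fixed Hill coefficient (see \code{\link{fit_hill}}).
#' @return A list: \code{curve} (data frame conc_nM, bound_fraction) and
#'   \code{fit} (a \code{hill_fit}).
#' @export
binding_curve <- function(lanes, fix_h = NULL) {
  conc <- vapply(lanes, function(l) l$protein_conc, numeric(1))
  bf <- vapply(lanes, bound_fraction, numeric(1))
  list(curve = data.frame(conc_nM = conc, bound_fraction = bf),
       fit = fit_hill(conc, bf, fix_h = fix_h))
}
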