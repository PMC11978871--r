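#' Kinetic parameters for the scanning-collision activation model
#'
#' Parameter set for the stochastic lattice simulator of kinase activation on
#' dsRNA: molecules bind duplexes with a hard-core footprint, scan by 1D
#' diffusion, and unphosphorylated kinase molecules trans-autophosphorylate
#' when their footprints collide. Obstacle (PACT) molecules co-occupy
#' duplexes, block scanning, and evict the kinase on contact.
#'
#' The defaults are a regime-demonstration set: chosen to reproduce the
#' qualitative behaviors of the system (length dependence, biphasic
#' concentration dependence, obstacle-mediated inhibition), not fitted to any
#' gel quantification.
#'
#' @param pkr_k_on Kinase on-rate per nM of duplex base pairs per s: the
#'   binding propensity of a free molecule is \code{k_on * [duplex] * L}, so
#'   that longer duplexes are proportionally bigger targets and matched mass
#'   doses give matched total binding flux.
#' @param pkr_k_off Kinase off-rate, per s.
#' @param pkr_diffusion Kinase 1D diffusion coefficient, bp^2/s.
#' @param footprint Kinase footprint, bp (default 15).
#' @param phospho_prob_per_contact Probability that a new kinase-kinase
#'   collision phosphorylates both partners (trans only; a lone kinase never
#'   autophosphorylates).
#' @param pact_k_on,pact_k_off,pact_diffusion,pact_footprint Obstacle
#'   kinetics and footprint.
#' @param eviction_prob_on_contact Probability that a new kinase-obstacle
#'   collision evicts the kinase.
#' @param t_end Simulated time, s.
#' @param dt Time step, s; the simulator refuses to run if any per-step
#'   event probability reaches 0.1.
#' @param rng_seed Integer seed.
#' @return A \code{kinetic_params} object.
#' @export
kinetic_params <- function(pkr_k_on = 1e-4, pkr_k_off = 0.3,
                           pkr_diffusion = 1000, footprint = 15,
                           phospho_prob_per_contact = 0.05,
                           pact_k_on = 1e-4, pact_k_off = 1,
                           pact_diffusion = 2000, pact_footprint = 20,
                           eviction_prob_on_contact = 0.5,
                           t_end = 30, dt = 0.002, rng_seed = 1L) {
  stopifnot(pkr_k_on >= 0, pkr_k_off >= 0, pkr_diffusion >= 0, footprint >= 1,
            phospho_prob_per_contact >= 0, phospho_prob_per_contact <= 1,
            pact_k_on >= 0, pact_k_off >= 0, pact_diffusion >= 0,
            pact_footprint >= 1, eviction_prob_on_contact >= 0,
            eviction_prob_on_contact <= 1, t_end > 0, dt > 0)
  structure(list(pkr_k_on = pkr_k_on, pkr_k_off = pkr_k_off,
                 pkr_diffusion = pkr_diffusion, footprint = footprint,
                 phospho_prob_per_contact = phospho_prob_per_contact,
                 pact_k_on = pact_k_on, pact_k_off = pact_k_off,
                 pact_diffusion = pact_diffusion,
                 pact_footprint = pact_footprint,
                 eviction_prob_on_contact = eviction_prob_on_contact,
                 t_end = t_end, dt = dt, rng_seed = as.integer(rng_seed)),
            class = "kinetic_params")
}

#' Convert a dsRNA mass concentration to molarity
#'
#' Uses the standard average of 660 g/mol per base pair:
#' \code{nM = mass_ng_ul * 1e6 / (length_bp * 660)}.
#'
#' @param mass_ng_ul Mass concentration, ng/ul (>= 0).
#' @param length_bp Duplex length, bp (> 0).
#' @return Molar concentration in nM.
#' @export
mass_to_molarity <- function(mass_ng_ul, length_bp) {
  stopifnot(all(mass_ng_ul >= 0), all(length_bp > 0))
  mass_ng_ul * 1e6 / (length_bp * 660)
}

#' Simulate the scanning-collision activation system
#'
#' Fixed-time-step kinetic Monte Carlo over \code{n_pkr} kinase and
#' \code{n_pact} obstacle molecules on \code{n_duplexes} duplexes of the
#' given length. Per step: free molecules bind a random duplex at rate
#' \code{k_on * [duplex]} at a uniformly sampled unoccupied footprint
#' position; bound molecules diffuse with reflection at duplex ends and at
#' neighbors (hard-core); bound molecules dissociate at \code{k_off}; on each
#' new kinase-kinase footprint contact (gap <= 1 bp) both partners become
#' phosphorylated with \code{phospho_prob_per_contact} (trans only); each new
#' kinase-obstacle contact evicts the kinase with
#' \code{eviction_prob_on_contact}. No dephosphorylation is modeled, so the
#' phospho fraction is non-decreasing. Free-pool depletion is implicit in the
#' particle tracking.
#'
#' @param params A \code{\link{kinetic_params}}.
#' @param length Duplex length, bp.
#' @param duplex_conc Duplex molar concentration, nM (use
#'   \code{\link{mass_to_molarity}} for mass doses).
#' @param n_duplexes Number of duplex molecules simulated.
#' @param n_pkr,n_pact Molecule counts (set from concentration ratios by
#'   \code{\link{activation_heatmap}}).
#' @param record_every Record the state every this many steps.
#' @return An \code{activation_result}: \code{time} (s),
#'   \code{phospho_fraction}, \code{co_occupancy} (fraction of duplexes
#'   carrying both species), \code{pact_site_occupancy} (fraction of duplex
#'   bp covered by obstacles), \code{mean_pkr_per_occupied_duplex}, and the
#'   endpoint summaries \code{final_phospho_fraction},
#'   \code{mean_pact_site_occupancy}.
#' @export
simulate_system <- function(params, length, duplex_conc, n_duplexes,
                            n_pkr, n_pact = 0, record_every = 50) {
  stopifnot(inherits(params, "kinetic_params"), length >= 1,
            duplex_conc >= 0, n_duplexes >= 0, n_pkr >= 0, n_pact >= 0)
  dt <- params$dt
  bp_conc <- duplex_conc * length  # nM of duplex base pairs
  p_pkr_bind <- 1 - exp(-params$pkr_k_on * bp_conc * dt)
  p_pkr_off <- 1 - exp(-params$pkr_k_off * dt)
  p_pact_bind <- 1 - exp(-params$pact_k_on * bp_conc * dt)
  p_pact_off <- 1 - exp(-params$pact_k_off * dt)
  probs <- c(p_pkr_bind, p_pkr_off, p_pact_bind, p_pact_off)
  if (any(probs >= 0.1)) {
    stop("dt too coarse: a per-step event probability reaches ",
         signif(max(probs), 3), " (>= 0.1); reduce dt")
  }
  n_steps <- ceiling(params$t_end / dt)
  set.seed(params$rng_seed)
  res <- cpp_simulate_activation(as.integer(n_steps), dt,
                                 as.integer(record_every),
                                 as.integer(n_pkr), as.integer(n_pact),
                                 as.integer(n_duplexes), length,
                                 params$footprint, params$pact_footprint,
                                 params$pkr_diffusion, params$pact_diffusion,
                                 p_pkr_bind, p_pkr_off, p_pact_bind,
                                 p_pact_off, params$phospho_prob_per_contact,
                                 params$eviction_prob_on_contact, 1.0)
  res$final_phospho_fraction <- res$phospho_fraction[length(res$phospho_fraction)]
  res$mean_pact_site_occupancy <- mean(res$pact_site_occupancy)
  class(res) <- "activation_result"
  res
}

#' Grid specification for an activation heatmap
#'
#' @param lengths Duplex lengths, bp.
#' @param ds_ng_ul dsRNA mass concentrations, ng/ul.
#' @param pact_nM Obstacle concentrations, nM (0 = absent).
#' @param replicates Stochastic replicates per cell.
#' @param params Base \code{\link{kinetic_params}}.
#' @param pkr_nM Kinase concentration, nM (default 100, the standard assay
#'   concentration).
#' @param n_pkr Number of kinase molecules simulated (sets the system size;
#'   duplex and obstacle counts follow from the concentration ratios).
#' @return A \code{heatmap_spec} object.
#' @export
heatmap_spec <- function(lengths = c(42, 62, 112),
                         ds_ng_ul = c(0.0625, 0.25, 1, 5, 15),
                         pact_nM = c(0, 50), replicates = 3,
                         params = kinetic_params(), pkr_nM = 100,
                         n_pkr = 200) {
  stopifnot(length(lengths) >= 1, length(ds_ng_ul) >= 1,
            length(pact_nM) >= 1, replicates >= 1,
            inherits(params, "kinetic_params"), pkr_nM > 0, n_pkr >= 1)
  structure(list(lengths = lengths, ds_ng_ul = ds_ng_ul, pact_nM = pact_nM,
                 replicates = as.integer(replicates), params = params,
                 pkr_nM = pkr_nM, n_pkr = as.integer(n_pkr)),
            class = "heatmap_spec")
}

#' Endpoint activation over a length x concentration x obstacle grid
#'
#' Runs \code{\link{simulate_system}} for every grid cell of the spec,
#' averaging the endpoint phospho fraction over replicates. Molecule counts
#' scale from the concentration ratios at fixed \code{n_pkr}: the number of
#' simulated duplexes is \code{round(n_pkr * [duplex] / [kinase])} (minimum
#' 1 when dsRNA is present) and obstacles likewise.
#'
#' @param spec A \code{\link{heatmap_spec}}.
#' @return Data frame with one row per grid cell: \code{length_bp},
#'   \code{ds_ng_ul}, \code{ds_nM}, \code{pact_nM},
#'   \code{mean_activation}, \code{sd_activation},
#'   \code{mean_pact_site_occupancy}, \code{mean_co_occupancy},
#'   \code{mean_pkr_per_occupied_duplex}.
#' @export
activation_heatmap <- function(spec) {
  stopifnot(inherits(spec, "heatmap_spec"))
  grid <- expand.grid(length_bp = spec$lengths, ds_ng_ul = spec$ds_ng_ul,
                      pact_nM = spec$pact_nM, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    L <- grid$length_bp[i]
    ds_nM <- mass_to_molarity(grid$ds_ng_ul[i], L)
    n_dup <- if (ds_nM > 0) max(1L, round(spec$n_pkr * ds_nM / spec$pkr_nM)) else 0L
    n_pact <- round(spec$n_pkr * grid$pact_nM[i] / spec$pkr_nM)
    act <- numeric(spec$replicates)
    occ <- cooc <- multi <- numeric(spec$replicates)
    for (r in seq_len(spec$replicates)) {
      p <- spec$params
      p$rng_seed <- spec$params$rng_seed + 1000L * i + r
      sim <- simulate_system(p, L, ds_nM, n_dup, spec$n_pkr, n_pact)
      act[r] <- sim$final_phospho_fraction
      occ[r] <- sim$mean_pact_site_occupancy
      cooc[r] <- mean(sim$co_occupancy)
      multi[r] <- mean(sim$mean_pkr_per_occupied_duplex)
    }
    data.frame(length_bp = L, ds_ng_ul = grid$ds_ng_ul[i], ds_nM = ds_nM,
               pact_nM = grid$pact_nM[i], mean_activation = mean(act),
               sd_activation = stats::sd(act),
               mean_pact_site_occupancy = mean(occ),
               mean_co_occupancy = mean(cooc),
               mean_pkr_per_occupied_duplex = mean(multi))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
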