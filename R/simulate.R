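#' Configuration for a synthetic genotype-panel trial
#'
#' Builds a validated configuration for [simulate_trial()]. Defaults
#' emulate a greenhouse screen of 89 closely related sorghum genotypes
#' under well-watered (WW) and water-stress (WS) regimes with three pots
#' per genotype and treatment.
#'
#' The generative model (all effects drawn once per trial, fixed order):
#' \deqn{\log g_s = \log(g_{s,base}) + [WS]\log(f_{WS}) + G_i + GT_{it} +
#'   \epsilon_{itr}}
#' with genotype effects \eqn{G_i \sim N(0,\sigma_g^2)}, interaction
#' effects \eqn{GT_{it} \sim N(0,\sigma_{g\times t}^2)} and residuals
#' \eqn{\epsilon \sim N(0,\sigma_e^2)}. Assimilation follows a saturating
#' curve \eqn{A_n = c_{it} A_{max} g_s/(g_s + K_{half}) + \eta} with a
#' lognormal genotypic capacity multiplier \eqn{c_i = e^{PC_i}},
#' optionally rescaled under WS by `capacity_ws_multiplier`. C_i comes
#' from the diffusive supply function \eqn{C_i = C_a - 1.6 A_n/g_s}
#' (floored at 5), keeping A_n, g_s and C_i mutually coherent.
#' Transpiration is \eqn{E = 1000 \, g_s \, VPD / P_{atm}} (mmol m-2 s-1)
#' and water potentials are built to be hydraulically exact:
#' \eqn{\Psi_{md} = \Psi_{pd} - E/K_{plant}} and
#' \eqn{\Psi_{stem} = \Psi_{md} + E/K_{leaf}} with
#' \eqn{K_{leaf} = K_{plant}/f_{leaf}} so the leaf carries fraction
#' `K_leaf_fraction` of total soil-to-leaf resistance.
#'
#' @param n_genotypes Number of genotypes (default 89).
#' @param n_replicates Pots per genotype x treatment (default 3).
#' @param replicate_overrides Optional named integer vector of per-genotype
#'   replicate counts (e.g. 6 for a recurrent parent); names are genotype
#'   ids. Unbalances the design.
#' @param seed Integer seed; mandatory, drives every draw.
#' @param gs_base Median WW stomatal conductance, mol m-2 s-1.
#' @param ws_gs_factor Multiplicative WS effect on median g_s (0, 1].
#' @param sigma_g,sigma_gxt,sigma_e SDs of genotype, genotype x treatment
#'   and residual effects on log g_s.
#' @param A_max Asymptotic assimilation, umol m-2 s-1.
#' @param K_half g_s at half-saturation of A_n, mol m-2 s-1.
#' @param pc_sigma_g SD of the genotypic log capacity multiplier.
#' @param capacity_ws_multiplier Scalar or per-genotype vector (length
#'   `n_genotypes`) multiplying photosynthetic capacity under WS; 1 keeps
#'   capacity, < 1 loses it.
#' @param an_sigma SD of the additive A_n residual, umol m-2 s-1.
#' @param C_a Ambient CO2, umol mol-1.
#' @param vpd_kPa Leaf-to-air vapour pressure deficit, kPa.
#' @param p_atm_kPa Atmospheric pressure, kPa.
#' @param psi_predawn_WW,psi_predawn_WS Pre-dawn water potentials, MPa.
#' @param K_plant_base Median soil-to-leaf conductance, mmol m-2 s-1 MPa-1.
#' @param k_sigma_g SD of genotypic log K_plant variation.
#' @param ws_kplant_factor Multiplicative WS effect on K_plant.
#' @param K_leaf_fraction Fraction of total hydraulic resistance in the
#'   leaf (0, 1).
#' @param haplotype_effect Additive shift on log g_s for the NRP haplotype
#'   group (0 = null).
#' @param nrp_fraction Fraction of genotypes labelled NRP.
#' @param aquaporin_id Label attached to the haplotype assignment.
#' @param measurement_noise Logical; add instrument-level noise to water
#'   potentials and E (off by default so hydraulic identities are exact).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genotypes = 89,
                       n_replicates = 3,
                       replicate_overrides = NULL,
                       seed = 1L,
                       gs_base = 0.20,
                       ws_gs_factor = 0.35,
                       sigma_g = 0.20,
                       sigma_gxt = 0.10,
                       sigma_e = 0.15,
                       A_max = 45,
                       K_half = 0.12,
                       pc_sigma_g = 0.12,
                       capacity_ws_multiplier = 1,
                       an_sigma = 0.5,
                       C_a = 400,
                       vpd_kPa = 1.5,
                       p_atm_kPa = 101.3,
                       psi_predawn_WW = -0.1,
                       psi_predawn_WS = -0.7,
                       K_plant_base = 3.0,
                       k_sigma_g = 0.15,
                       ws_kplant_factor = 0.5,
                       K_leaf_fraction = 0.4,
                       haplotype_effect = 0,
                       nrp_fraction = 0.5,
                       aquaporin_id = "SbPIP1.1",
                       measurement_noise = FALSE) {
  cfg <- as.list(environment())
  if (any(c(cfg$sigma_g, cfg$sigma_gxt, cfg$sigma_e, cfg$pc_sigma_g,
            cfg$an_sigma, cfg$k_sigma_g) < 0)) {
    stop("all SD parameters must be >= 0")
  }
  if (!(cfg$ws_gs_factor > 0 && cfg$ws_gs_factor <= 1)) {
    stop("ws_gs_factor must be in (0, 1]")
  }
  if (!(cfg$K_leaf_fraction > 0 && cfg$K_leaf_fraction < 1)) {
    stop("K_leaf_fraction must be in (0, 1)")
  }
  if (!(length(cfg$capacity_ws_multiplier) %in% c(1L, cfg$n_genotypes))) {
    stop("capacity_ws_multiplier must be scalar or length n_genotypes")
  }
  if (cfg$n_genotypes < 1 || cfg$n_replicates < 1) {
    stop("need at least one genotype and one replicate")
  }
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a replicate-level phenotype trial with known ground truth
#'
#' Draws a full two-treatment trial from the generative model documented
#' in [sim_config()]. The same seed yields bit-identical output. All
#' sampled effect vectors, the per-plant configured conductances and the
#' realized variance components on the log g_s scale are returned in the
#' `truth` element so downstream estimators can be checked against them.
#'
#' @param config A [sim_config()] object.
#' @return List with `records` (plant record data.frame), `truth` (ground
#'   truth list) and `assignments` (haplotype assignment data.frame).
#' @export
simulate_trial <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ng <- config$n_genotypes
  gids <- sprintf("G%03d", seq_len(ng))
  treatments <- c("WW", "WS")

  reps <- rep(config$n_replicates, ng)
  names(reps) <- gids
  if (!is.null(config$replicate_overrides)) {
    ov <- config$replicate_overrides
    reps[names(ov)] <- ov
  }

  cap_ws <- rep(config$capacity_ws_multiplier, length.out = ng)

  # fixed draw order: genotype effects, interaction, capacity, hydraulic,
  # haplotype assignment, then per-observation residuals
  G <- stats::rnorm(ng, 0, config$sigma_g)
  GT <- matrix(stats::rnorm(ng * 2, 0, config$sigma_gxt), ng, 2,
               dimnames = list(gids, treatments))
  PC <- stats::rnorm(ng, 0, config$pc_sigma_g)
  Kg <- exp(stats::rnorm(ng, 0, config$k_sigma_g))
  n_nrp <- round(config$nrp_fraction * ng)
  nrp_idx <- sample.int(ng, n_nrp)
  group <- rep("RP", ng)
  group[nrp_idx] <- "NRP"

  # genotype-level morphology/physiology means
  spad_g <- stats::rnorm(ng, 39.5, 3)
  lma_g <- stats::rnorm(ng, 32, 5)
  lw_g <- stats::rnorm(ng, 4.5, 0.7)
  ll_g <- stats::rnorm(ng, 70, 7)
  lt_g <- stats::rnorm(ng, 0.25, 0.02)
  bio_g <- exp(stats::rnorm(ng, log(28), 0.35))

  rows <- vector("list", ng * 2)
  eps_all <- list()
  eta_all <- list()
  k <- 0L
  for (i in seq_len(ng)) {
    for (t in 1:2) {
      trt <- treatments[t]
      r <- reps[i]
      ws <- trt == "WS"
      eps <- stats::rnorm(r, 0, config$sigma_e)
      eta <- stats::rnorm(r, 0, config$an_sigma)
      hap <- if (group[i] == "NRP") config$haplotype_effect else 0
      log_gs <- log(config$gs_base) + (if (ws) log(config$ws_gs_factor) else 0) +
        G[i] + GT[i, t] + hap + eps
      gs <- exp(log_gs)
      cap <- exp(PC[i]) * (if (ws) cap_ws[i] else 1)
      an <- cap * config$A_max * gs / (gs + config$K_half) + eta
      ci <- pmax(config$C_a - 1.6 * an / gs, 5)
      e_mmol <- 1000 * gs * config$vpd_kPa / config$p_atm_kPa
      kp <- config$K_plant_base * Kg[i] * (if (ws) config$ws_kplant_factor else 1)
      kl <- kp / config$K_leaf_fraction
      psi_pd <- if (ws) config$psi_predawn_WS else config$psi_predawn_WW
      psi_md <- psi_pd - e_mmol / kp
      psi_st <- psi_md + e_mmol / kl
      if (config$measurement_noise) {
        nz <- function(x, s) x + stats::rnorm(length(x), 0, s)
        psi_pd <- nz(rep(psi_pd, r), 0.03)
        psi_md <- nz(psi_md, 0.05)
        psi_st <- nz(psi_st, 0.05)
        e_mmol <- pmax(nz(e_mmol, 0.05), 0)
      } else {
        psi_pd <- rep(psi_pd, r)
      }
      spad <- stats::rnorm(r, spad_g[i] + (if (ws) 4 else 0), 1.5)
      lma <- pmax(stats::rnorm(r, lma_g[i] + (if (ws) 6 else 0), 2), 5)
      rwc <- pmin(pmax(stats::rnorm(r, if (ws) 0.72 else 0.92, 0.03), 0.2),
                  0.995)
      area <- 1.5e-4                      # three 0.5 cm2 discs, m2
      dw <- lma * area
      tw <- dw * 3.5
      fw <- dw + rwc * (tw - dw)
      phips <- pmin(pmax(
        stats::rnorm(r, if (ws) 0.32 else 0.45, 0.04), 0), 1)
      bio <- pmax(stats::rnorm(r, bio_g[i] * (if (ws) 0.45 else 1),
                               2.5), 0.5)
      k <- k + 1L
      rows[[k]] <- data.frame(
        genotype_id = gids[i], treatment = trt, replicate = seq_len(r),
        A_n = an, g_s = gs, C_i = ci, E = e_mmol,
        psi_predawn = psi_pd, psi_stem = psi_st, psi_midday = psi_md,
        SPAD = spad, phi_PSII = phips,
        leaf_width = stats::rnorm(r, lw_g[i], 0.2),
        leaf_length = stats::rnorm(r, ll_g[i], 2),
        leaf_thickness = stats::rnorm(r, lt_g[i], 0.01),
        disc_FW = fw, disc_TW = tw, disc_DW = dw, disc_area = area,
        biomass = bio,
        stringsAsFactors = FALSE)
      eps_all[[k]] <- eps
      eta_all[[k]] <- eta
    }
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL

  eps_vec <- unlist(eps_all, use.names = FALSE)
  truth <- list(
    config = config,
    genotype_id = gids,
    G = stats::setNames(G, gids),
    GT = GT,
    PC = stats::setNames(PC, gids),
    capacity_ws_multiplier = stats::setNames(cap_ws, gids),
    K_plant_genotype = stats::setNames(
      config$K_plant_base * Kg, gids),
    ws_kplant_factor = config$ws_kplant_factor,
    K_leaf_fraction = config$K_leaf_fraction,
    eps = eps_vec,
    an_residual = unlist(eta_all, use.names = FALSE))
  assignments <- data.frame(genotype_id = gids,
                            aquaporin_id = config$aquaporin_id,
                            group = group, stringsAsFactors = FALSE)
  list(records = records, truth = truth, assignments = assignments)
}

#' Realized variance components of a simulated trait
#'
#' Returns the sample variance of each stored effect vector for a trait
#' that was generated with additive structure on its modelling scale.
#' Only `"log_gs"` has such structure (genotype + interaction + residual
#' on log g_s); requesting any other trait is an error, since e.g. C_i is
#' a nonlinear by-product of the model, not an additive trait.
#'
#' @param truth `truth` element of [simulate_trial()] output.
#' @param trait Trait name; only `"log_gs"` is supported.
#' @return List with `sigma2_g`, `sigma2_gxt`, `sigma2_e` (realized sample
#'   variances).
#' @export
truth_variance_components <- function(truth, trait = "log_gs") {
  if (!identical(trait, "log_gs")) {
    stop("trait '", trait, "' has no additive structure on a modelling ",
         "scale; only 'log_gs' is supported")
  }
  v <- function(x) if (length(x) > 1) stats::var(as.vector(x)) else 0
  list(sigma2_g = v(truth$G),
       sigma2_gxt = v(truth$GT),
       sigma2_e = v(truth$eps))
}
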