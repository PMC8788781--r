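# Synthetic single-tubule cohort simulator with full ground truth: tubule
# geometry and cell composition, a marker panel with realistic dynamic range,
# forward-simulated electrophysiology through an equivalent-circuit model,
# intensity-dependent missingness, knockout cohorts with a planted coupled
# module, and PRM transition fixtures.

#' Default marker panel for the collecting-duct simulator
#'
#' Roughly forty named proteins mirroring the main functional families of
#' the cortical collecting duct: Na/K-ATPase subunits, cytoskeletal and
#' ribosomal housekeeping proteins, tight-junction claudins, the principal
#' cell water channels (AQP2/3/4) and ENaC subunits with their regulator
#' NEDD4L, type A intercalated cell vH+-ATPase subunits with AE1, and type B
#' markers around pendrin (SLC26A4) with the basolateral CLCNKB/Barttin
#' chloride-channel complex. Baseline copy numbers span five orders of
#' magnitude, with ENaC far below the aquaporins as in real collecting-duct
#' proteomes.
#'
#' Columns: `protein_id`, `cell_class` (`PC`, `IC-A`, `IC-B`,
#' `housekeeping`), `baseline` (expected copies at reference geometry and
#' composition), `z_load` (loading on the latent water-versus-salt
#' adaptation axis; negative = water-adapted side), `icb_load` (loading on
#' the latent type-B intercalated cell activity factor shared by the
#' pendrin-coupled module), `ko_log2fc` (secondary regulation profile of
#' the pendrin-knockout generator: mild decreases of non-module IC
#' machinery, AE1 unchanged, mild principal-cell increases).
#'
#' @return data.frame with one row per panel protein.
#' @export
default_panel <- function() {
  p <- function(id, cls, base, comp = 1, z = 0, icb = 0, pc = 0, hk = 0,
                ko = 0) {
    data.frame(protein_id = id, cell_class = cls, baseline = base,
               comp_scale = comp, z_load = z, icb_load = icb, pc_load = pc,
               hk_load = hk, ko_log2fc = ko)
  }
  rbind(
    # housekeeping / ubiquitous
    p("Atp1a1", "housekeeping", 5e7, hk = 0.7), p("Atp1b1", "housekeeping", 3e7, hk = 0.7),
    p("Actb", "housekeeping", 2e8, hk = 0.7), p("Gapdh", "housekeeping", 6e7, hk = 0.7),
    p("Tubb5", "housekeeping", 2e7, hk = 0.7), p("Vim", "housekeeping", 1e7, hk = 0.7),
    p("Hspa8", "housekeeping", 1.5e7, hk = 0.7), p("Rpl7", "housekeeping", 8e6, hk = 0.7),
    p("Rps3", "housekeeping", 6e6, hk = 0.7), p("Eef1a1", "housekeeping", 2.5e7, hk = 0.7),
    p("Aldoa", "housekeeping", 1.2e7, hk = 0.7), p("Krt8", "housekeeping", 4e6, hk = 0.7),
    p("Cldn4", "housekeeping", 5e4, hk = 0.7), p("Cldn8", "housekeeping", 3e4, hk = 0.7),
    # principal cells: water side (negative z), salt side (positive z)
    p("Aqp2", "PC", 2e6, comp = 1.5, z = -1.3, ko = 0.3),
    p("Aqp3", "PC", 1.5e6, comp = 2.5, z = -1.2, pc = 0.5, ko = 0.3),
    p("Aqp4", "PC", 6e5, comp = 2.5, z = -0.9, pc = 0.5, ko = 0.3),
    p("Nedd4l", "PC", 1e5, comp = 2.5, z = -0.8, pc = 0.5),
    p("Scnn1a", "PC", 1.2e4, comp = 2.5, z = 0.6, pc = 0.6),
    p("Scnn1b", "PC", 8e3, comp = 2.5, z = 0.6, pc = 0.6),
    p("Scnn1g", "PC", 5e3, comp = 2.5, z = 0.6, pc = 0.6),
    p("Fxyd4", "PC", 3e5, comp = 2.5, pc = 0.6, ko = 0.3),
    p("Wnk1", "PC", 8e4, comp = 2.5, pc = 0.6, ko = 0.3),
    p("Avpr2", "PC", 1e5, comp = 2.5, pc = 0.6, ko = 0.3),
    p("Elf5", "PC", 3e4, comp = 2.5, pc = 0.6, ko = 0.3),
    # type A intercalated cells (vH+-ATPase machinery, AE1, ammonia/carbonic)
    p("Atp6v1b1", "IC-A", 4e6, comp = 1.2, icb = 0.4),
    p("Atp6v1a", "IC-A", 5e6, comp = 2, ko = -1.0),
    p("Atp6v0d2", "IC-A", 1e6, comp = 2, ko = -1.1),
    p("Atp6v1e1", "IC-A", 2e6, comp = 2, ko = -1.0),
    p("Atp6v1c2", "IC-A", 8e5, comp = 2, ko = -1.0),
    p("Atp6v1f", "IC-A", 1.5e6, comp = 2, ko = -1.0),
    p("Atp6v0c", "IC-A", 2.5e6, comp = 2, ko = -0.9),
    p("Atp6v1h", "IC-A", 6e5, comp = 2, ko = -1.0),
    p("Slc4a1", "IC-A", 6e6, comp = 2),               # AE1: unchanged in the KO
    p("Ca2", "IC-A", 3e6, comp = 2, ko = -0.8),
    p("Rhcg", "IC-A", 4e5, comp = 2, ko = -0.8),
    p("Aqp6", "IC-A", 1e5, comp = 2, ko = -0.8),
    # type B intercalated cells (pendrin module)
    p("Slc26a4", "IC-B", 5e6, comp = 2, icb = 0.4),   # anchor
    p("Clcnkb", "IC-B", 2e6, comp = 1.2, icb = 0.5),
    p("Bsnd", "IC-B", 1.5e6, comp = 1.2, icb = 0.5),
    p("Atp6v1g3", "IC-B", 1.5e6, comp = 1.2, icb = 0.5),
    p("Atp6v0a4", "IC-B", 5e5, comp = 2, icb = 0.3, ko = -1.0),
    p("Slc4a9", "IC-B", 2e5, comp = 2, ko = -0.9),
    p("Slc26a7", "IC-B", 1e5, comp = 2, ko = -1.0),
    p("Ca12", "IC-B", 4e5, comp = 2, ko = -1.1),
    p("Insrr", "IC-B", 2e3, comp = 2, ko = -0.5)
  )
}

#' Configuration for the synthetic tubule-cohort generator
#'
#' Bundles and validates all simulator parameters. Defaults describe a
#' wild-type cohort of 12 microperfused collecting ducts: lengths 400-600
#' um, luminal diameters 15-30 um, an intercalated-cell fraction drawn from
#' Beta(2.5, 4.5) and coupled negatively to tubule length, protein
#' abundances from the marker panel with log-normal biological and
#' measurement noise, and phenotypes generated by a two-conductance
#' equivalent circuit (transcellular electromotive force with a paracellular
#' shunt) calibrated so that cohorts fall inside the physiological
#' transepithelial voltage and short-circuit-current ranges of mouse CCD.
#'
#' @param n_tubules number of tubules (>= 3).
#' @param length_range,diameter_range uniform sampling ranges (um).
#' @param ic_shape shape parameters of the Beta distribution of the
#'   intercalated-cell fraction.
#' @param ic_a_share fraction of intercalated cells that are type A.
#' @details The panel's `comp_scale` column sets each protein's
#'   composition-response exponent: marker abundance scales as the class
#'   weight raised to this power. Values above 1 encode the supra-linear
#'   covariation of cell-type transport programs with cell-type mass that
#'   makes same-class markers correlate strongly with each other; ENaC
#'   subunits respond linearly.
#' @param length_ic_slope logit-scale shift of the IC fraction per 100 um of
#'   length above 500 um (negative: longer tubules carry fewer ICs).
#' @param panel marker panel data.frame (see [default_panel()]).
#' @param n_background number of additional uncoupled background proteins
#'   emulating untargeted proteome depth.
#' @param background_range baseline range (copies) of background proteins,
#'   sampled log-uniformly.
#' @param coupling list: `strength` multiplies the panel's `z_load` column
#'   (water-versus-salt axis), `act_z` is the loading of the same axis on
#'   ENaC open-probability ("activity"), `z_comp` couples the axis to the
#'   standardized logit IC fraction (tubules with fewer principal cells run
#'   higher Na-transport activity per cell to sustain reabsorption),
#'   `icb_strength` multiplies `icb_load` (type-B module co-expression).
#' @param noise_sd total log2-scale noise per protein and tubule; split
#'   internally into biological (0.8 x) and measurement (0.6 x) components.
#' @param circuit list: `E` apical electromotive force (mV), `g_t0`
#'   reference transcellular (ENaC) conductance (S/cm^2), `g_p0`
#'   paracellular conductance (S/cm^2), `amil_block` fraction of g_t
#'   blocked by luminal amiloride, `gp_sd` log2 spread of g_p, `act_noise_sd`
#'   log2 noise of ENaC activity, `vte_noise_sd` voltage measurement noise
#'   (mV).
#' @param yield_sd log2 spread of the per-tubule recovery/yield factor: a
#'   common multiplicative offset of all measured intensities of a tubule,
#'   reflecting tubule-to-tubule differences in protein recovery during
#'   single-tubule sample processing.
#' @param deflection_cv relative measurement noise of the cable deflections.
#' @param pnapcl list `meanlog`, `sdlog` of the log-normal paracellular
#'   P_Na/P_Cl distribution.
#' @param vdp_noise_sd dilution-potential measurement noise (mV).
#' @param rho luminal resistivity (Ohm cm); `temperature` (K); `I0` injected
#'   current (nA); `conc_control`, `conc_low` NaCl concentrations (mM).
#' @param missingness list: `target` overall missing fraction of the
#'   untargeted matrix, `b` logistic slope per log2 intensity (> 0).
#' @param seed integer seed; every generator is a pure function of
#'   (config, seed).
#' @return validated config list of class `cohort_config`.
#' @export
cohort_config <- function(n_tubules = 12,
                          length_range = c(400, 600),
                          diameter_range = c(15, 30),
                          ic_shape = c(3.5, 5),
                          ic_a_share = 0.6,
                          length_ic_slope = -0.5,
                          panel = default_panel(),
                          n_background = 362,
                          background_range = c(1e3, 1e8),
                          coupling = list(),
                          noise_sd = 0.3,
                          circuit = list(),
                          yield_sd = 0.4,
                          deflection_cv = 0.005,
                          pnapcl = list(meanlog = log(0.8), sdlog = 0.2),
                          vdp_noise_sd = 0.3,
                          rho = 60, temperature = 310.15, I0 = 13,
                          conc_control = 145, conc_low = 30,
                          missingness = list(target = 0.3, b = 2),
                          seed = 1) {
  coupling <- utils::modifyList(
    list(strength = 1, act_z = 1.8, z_comp = 0.4, icb_strength = 1,
         pc_strength = 1), coupling)
  circuit <- utils::modifyList(
    list(E = -140, g_t0 = 0.9e-3, g_p0 = 5.5e-3, amil_block = 0.98,
         gp_sd = 0.1, act_noise_sd = 0.15, vte_noise_sd = 0.8), circuit)
  cfg <- list(
    n_tubules = n_tubules, length_range = length_range,
    diameter_range = diameter_range, ic_shape = ic_shape,
    ic_a_share = ic_a_share, length_ic_slope = length_ic_slope,
    panel = panel, n_background = n_background,
    background_range = background_range, coupling = coupling,
    noise_sd = noise_sd, circuit = circuit, yield_sd = yield_sd,
    deflection_cv = deflection_cv,
    pnapcl = pnapcl, vdp_noise_sd = vdp_noise_sd, rho = rho,
    temperature = temperature, I0 = I0, conc_control = conc_control,
    conc_low = conc_low, missingness = missingness, seed = seed
  )
  if (n_tubules < 3) stop("n_tubules must be >= 3", call. = FALSE)
  for (rg in c("length_range", "diameter_range", "background_range")) {
    v <- cfg[[rg]]
    if (length(v) != 2 || any(v <= 0) || v[1] > v[2]) {
      stop(sprintf("`%s` must be an ordered positive pair", rg), call. = FALSE)
    }
  }
  if (ic_a_share < 0 || ic_a_share > 1) {
    stop("ic_a_share must lie in [0, 1]", call. = FALSE)
  }
  if (any(ic_shape <= 0)) stop("ic_shape must be positive", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!is.null(cfg$missingness)) {
    tg <- cfg$missingness$target
    if (tg < 0 || tg >= 1) stop("missingness target must lie in [0, 1)",
                                call. = FALSE)
    if (cfg$missingness$b <= 0) stop("missingness slope b must be > 0",
                                     call. = FALSE)
  }
  need <- c("protein_id", "cell_class", "baseline", "comp_scale", "z_load",
            "icb_load", "pc_load", "hk_load", "ko_log2fc")
  if (!all(need %in% names(panel))) {
    stop("panel lacks columns: ",
         paste(setdiff(need, names(panel)), collapse = ", "), call. = FALSE)
  }
  structure(cfg, class = "cohort_config")
}

# class-composition weight of a protein given the IC fraction of a tubule
.class_weight <- function(cell_class, ic, ic_a_share) {
  switch(cell_class,
    "PC" = 1 - ic,
    "IC-A" = ic * ic_a_share,
    "IC-B" = ic * (1 - ic_a_share),
    1  # housekeeping / background: composition-independent
  )
}

# Draw tubule-level latent state: geometry, composition, adaptation axes.
# The salt-water axis z is mildly coupled to the (population-standardized)
# logit IC fraction: tubules with fewer principal cells sustain Na transport
# by running each PC at higher ENaC activity.
.draw_tubules <- function(cfg) {
  n <- cfg$n_tubules
  L <- stats::runif(n, cfg$length_range[1], cfg$length_range[2])
  diameter <- stats::runif(n, cfg$diameter_range[1], cfg$diameter_range[2])
  u <- stats::rbeta(n, cfg$ic_shape[1], cfg$ic_shape[2])
  lg <- stats::qlogis(u) + cfg$length_ic_slope * (L - 500) / 100
  ic <- stats::plogis(lg)
  mu_lg <- digamma(cfg$ic_shape[1]) - digamma(cfg$ic_shape[2])
  sd_lg <- sqrt(trigamma(cfg$ic_shape[1]) + trigamma(cfg$ic_shape[2]) +
                  cfg$length_ic_slope^2 / 3)
  rho <- cfg$coupling$z_comp
  z <- rho * (lg - mu_lg) / sd_lg + sqrt(1 - rho^2) * stats::rnorm(n)
  b <- stats::rnorm(n)   # type-B intercalated cell activity factor
  q <- stats::rnorm(n)   # principal-cell transport-program factor
  h <- stats::rnorm(n)   # cell-density/metabolic state (housekeeping)
  data.frame(
    tubule_id = sprintf("T%02d", seq_len(n)),
    L = L, diameter = diameter, ic_fraction = ic, z = z, b = b, q = q, h = h
  )
}

# Extended panel: markers plus uncoupled log-uniform background proteins.
.full_panel <- function(cfg) {
  panel <- cfg$panel
  if (cfg$n_background > 0) {
    lo <- log10(cfg$background_range[1])
    hi <- log10(cfg$background_range[2])
    bg <- data.frame(
      protein_id = sprintf("BG%04d", seq_len(cfg$n_background)),
      cell_class = "background",
      baseline = 10^stats::runif(cfg$n_background, lo, hi),
      comp_scale = 1, z_load = 0, icb_load = 0, pc_load = 0, hk_load = 0,
      ko_log2fc = 0
    )
    panel <- rbind(panel, bg)
  }
  panel
}

# True log2 abundances (proteins x tubules): baseline x composition weight x
# length factor x structured latent factors x biological noise. Baselines are
# defined at the reference composition (population-mean IC fraction); the
# per-protein comp_scale exponent amplifies composition deviations around
# that reference without shifting the absolute abundance scale.
.true_log2 <- function(cfg, tubules, panel, bio_sd) {
  np <- nrow(panel); nt <- nrow(tubules)
  ref_ic <- cfg$ic_shape[1] / sum(cfg$ic_shape)
  w_ref <- vapply(panel$cell_class, .class_weight, numeric(1),
                  ic = ref_ic, ic_a_share = cfg$ic_a_share)
  w <- vapply(seq_len(nt), function(i) {
    vapply(panel$cell_class, .class_weight, numeric(1),
           ic = tubules$ic_fraction[i], ic_a_share = cfg$ic_a_share)
  }, numeric(np))
  base <- log2(panel$baseline) + log2(w_ref) +
    panel$comp_scale * (log2(w) - log2(w_ref))
  # tubule size: total protein scales with length and luminal circumference
  sizef <- log2(tubules$L / 500) + log2(tubules$diameter / 22.5)
  lenf <- matrix(sizef, np, nt, byrow = TRUE)
  zf <- cfg$coupling$strength * panel$z_load %o% tubules$z
  bf <- cfg$coupling$icb_strength * panel$icb_load %o% tubules$b
  qf <- cfg$coupling$pc_strength * panel$pc_load %o% tubules$q
  hf <- panel$hk_load %o% tubules$h
  noise <- matrix(stats::rnorm(np * nt, sd = bio_sd), np, nt)
  out <- base + lenf + zf + bf + qf + hf + noise
  dimnames(out) <- list(panel$protein_id, tubules$tubule_id)
  out
}

# Equivalent-circuit electrophysiology from the true ENaC membrane density:
# the specific (per-area) transcellular conductance follows ENaC abundance
# per unit of tubule surface, times the latent open-probability factor.
.simulate_ephys <- function(cfg, tubules, log2_true) {
  cc <- cfg$circuit
  n <- nrow(tubules)
  panel <- cfg$panel
  ref_ic <- cfg$ic_shape[1] / sum(cfg$ic_shape)
  scnn1b <- panel[panel$protein_id == "Scnn1b", ]
  a_ref <- log2(scnn1b$baseline) + log2(1 - ref_ic)
  sizef <- log2(tubules$L / 500) + log2(tubules$diameter / 22.5)
  act <- 2^(cfg$coupling$act_z * tubules$z +
              stats::rnorm(n, sd = cc$act_noise_sd))
  g_t <- cc$g_t0 * 2^(log2_true["Scnn1b", ] - sizef - a_ref) * act
  g_p <- cc$g_p0 * 2^stats::rnorm(n, sd = cc$gp_sd)
  vte_model <- cc$E * g_t / (g_t + g_p)
  g_ta <- g_t * (1 - cc$amil_block)
  vte_amil_model <- cc$E * g_ta / (g_ta + g_p)
  Rte <- 1 / (g_t + g_p)
  beta <- stats::rlnorm(n, cfg$pnapcl$meanlog, cfg$pnapcl$sdlog)
  vdp_model <- ghk_dp(beta, cfg$conc_control, cfg$conc_low, cfg$temperature)
  data.frame(
    tubule_id = tubules$tubule_id,
    act = act, g_t = g_t, g_p = g_p, Rte = Rte,
    Vte_model = vte_model, Vte_amil_model = vte_amil_model,
    dVte_amil_model = vte_model - vte_amil_model,
    pna_pcl = beta, Vdp_model = vdp_model
  )
}

#' Apply intensity-dependent missingness to an intensity matrix
#'
#' Each cell is observed with probability
#' \eqn{\mathrm{logit}^{-1}(a + b \log_2 I)} (`b > 0`), the
#' missing-not-at-random dropout typical of nano-scale proteomics, where
#' low-abundance proteins fall below the detection limit first.
#'
#' @param m positive intensity matrix.
#' @param params list with logistic intercept `a` and slope `b` (per log2
#'   intensity); see [calibrate_missingness()].
#' @param seed optional integer seed.
#' @return matrix with unobserved cells set to `NA`.
#' @export
apply_missingness <- function(m, params, seed = NULL) {
  stopifnot(is.matrix(m), is.numeric(m))
  .check_finite(params$a, "a")
  .check_positive(params$b, "b")
  .with_seed(seed, {
    keep_p <- stats::plogis(params$a + params$b * log2(m))
    drop <- matrix(stats::runif(length(m)) > keep_p, nrow(m))
    m[drop] <- NA_real_
    m
  })
}

#' Calibrate the missingness intercept to a target missing fraction
#'
#' Solves for the logistic intercept `a` such that the expected overall
#' missing fraction of `m` under [apply_missingness()] equals `target`,
#' given the slope `b`.
#'
#' @param m positive intensity matrix (typically true intensities).
#' @param target desired overall missing fraction in `[0, 1)`.
#' @param b logistic slope per log2 intensity (> 0).
#' @return list with components `a` and `b`.
#' @export
calibrate_missingness <- function(m, target, b = 0.8) {
  stopifnot(is.matrix(m), all(m > 0, na.rm = TRUE))
  if (target < 0 || target >= 1) stop("target must lie in [0, 1)", call. = FALSE)
  .check_positive(b, "b")
  if (target == 0) return(list(a = Inf, b = b))
  lg <- log2(m[is.finite(m)])
  f <- function(a) mean(stats::plogis(a + b * lg)) - (1 - target)
  a <- stats::uniroot(f, lower = -b * max(lg) - 50, upper = -b * min(lg) + 50,
                      tol = 1e-10)$root
  list(a = a, b = b)
}

#' Generate a synthetic wild-type tubule cohort with ground truth
#'
#' Draws tubule geometry and cell composition, true protein abundances for
#' the marker panel plus background proteome, a complete targeted
#' (PRM-like) intensity matrix, an untargeted (LFQ-like) matrix with
#' intensity-dependent missingness, and forward-simulated perfusion
#' recordings: cable deflections at the configured injected current, basal
#' and amiloride transepithelial voltages from the equivalent circuit, and
#' NaCl dilution potentials from the planted paracellular permeability
#' ratios. Deterministic given `(config, seed)`.
#'
#' @param cfg a [cohort_config()].
#' @return list with elements `recordings` (one row per tubule, ready for
#'   [derive_phenotypes()]), `targeted` (marker intensity matrix, complete),
#'   `untargeted` (full-depth intensity matrix with missing cells),
#'   `marker_map` (protein_id, cell_class for the marker panel), and
#'   `truth` (tubule-level latent state and phenotypes, per-protein panel
#'   with planted couplings, true log2 abundance matrix, missingness
#'   parameters, the config).
#' @examples
#' cohort <- generate_cohort(cohort_config(n_tubules = 6, seed = 42))
#' str(cohort$truth$tubules)
#' @export
generate_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  .with_seed(cfg$seed, {
    bio_sd <- 0.8 * cfg$noise_sd
    meas_sd <- 0.6 * cfg$noise_sd
    tubules <- .draw_tubules(cfg)
    panel <- .full_panel(cfg)
    log2_true <- .true_log2(cfg, tubules, panel, bio_sd)
    marker_ids <- cfg$panel$protein_id
    ephys <- .simulate_ephys(cfg, tubules, log2_true)

    # measurement layer: per-tubule recovery/yield plus per-cell noise
    yield <- stats::rnorm(nrow(tubules), sd = cfg$yield_sd)
    tubules$yield <- yield
    meas <- function(rows) {
      lt <- log2_true[rows, , drop = FALSE]
      lt <- sweep(lt, 2, yield, "+")
      2^(lt + matrix(stats::rnorm(length(lt), sd = meas_sd), nrow(lt)))
    }
    targeted <- meas(marker_ids)
    untargeted <- meas(panel$protein_id)
    mparams <- NULL
    if (!is.null(cfg$missingness) && cfg$missingness$target > 0) {
      mparams <- calibrate_missingness(untargeted, cfg$missingness$target,
                                       cfg$missingness$b)
      untargeted <- apply_missingness(untargeted, mparams)
    }

    # recorded electrophysiology
    defl <- forward_cable(tubules$L, tubules$diameter, ephys$Rte,
                          rho = cfg$rho, I0 = cfg$I0)
    n <- nrow(tubules)
    cc <- cfg$circuit
    recordings <- data.frame(
      tubule_id = tubules$tubule_id,
      L = tubules$L,
      I0 = cfg$I0,
      dV0 = defl$dV0 * (1 + stats::rnorm(n, sd = cfg$deflection_cv)),
      dVL = defl$dVL * (1 + stats::rnorm(n, sd = cfg$deflection_cv)),
      Vte_basal = ephys$Vte_model + stats::rnorm(n, sd = cc$vte_noise_sd),
      Vte_amil = ephys$Vte_amil_model + stats::rnorm(n, sd = cc$vte_noise_sd),
      Vdp = ephys$Vdp_model + stats::rnorm(n, sd = cfg$vdp_noise_sd),
      rho = cfg$rho,
      temperature = cfg$temperature,
      conc_control = cfg$conc_control,
      conc_low = cfg$conc_low
    )

    list(
      recordings = recordings,
      targeted = targeted,
      untargeted = untargeted,
      marker_map = cfg$panel[, c("protein_id", "cell_class")],
      truth = list(
        tubules = cbind(tubules, ephys[, setdiff(names(ephys), "tubule_id")]),
        proteins = panel,
        log2_true = log2_true,
        missingness = mparams,
        config = cfg
      )
    )
  })
}

#' Generate a synthetic knockout-versus-control cohort
#'
#' Simulates tubule pools from knockout mice and wild-type littermates for
#' untargeted differential analysis. The anchor protein (pendrin analogue)
#' is reduced to the noise floor in knockouts; an explicit coupled module is
#' decreased by `module_log2fc`; and, unless overridden via `effects`, the
#' panel's secondary regulation profile (`ko_log2fc` column: mild decreases
#' of non-module intercalated-cell machinery, unchanged AE1, mild
#' principal-cell increases) is applied as well. Module co-expression with
#' the anchor in wild-type tubules arises from the shared type-B latent
#' factor (`icb_load`).
#'
#' @param cfg a [cohort_config()]; `n_tubules` is the number of samples per
#'   genotype here.
#' @param pool_size number of CCDs pooled into each sample (the dissection
#'   protocol pools several tubules per mouse), averaging tubule-to-tubule
#'   composition variance within a sample.
#' @param module character vector of module proteins (must be in the
#'   panel).
#' @param module_log2fc planted log2 fold change of module proteins.
#' @param effects optional named numeric vector of planted log2 fold
#'   changes replacing the default profile entirely (module and secondary);
#'   useful for null simulations (all zeros).
#' @param anchor anchor protein id (default `"Slc26a4"`).
#' @param ic_shift logit-scale shift of the intercalated-cell fraction in
#'   knockout tubules (default -0.5): knockout collecting ducts remodel
#'   toward relatively more principal cells, so IC markers fall and PC
#'   markers rise beyond the direct regulation profile.
#' @param anchor_floor reduce the anchor to the noise floor in knockouts
#'   (default `TRUE`).
#' @param floor_level intensity (copies) of the anchor noise floor.
#' @return list with `wt` and `ko` intensity matrices (missingness
#'   applied), `matrix` (cbind of both), `groups` (`"WT"`/`"KO"` labels),
#'   and `truth` (per-protein planted `ko_log2fc`, `anchor`, per-genotype
#'   tubule tables, config).
#' @examples
#' ko <- generate_ko_cohort(cohort_config(n_tubules = 5, seed = 3))
#' head(ko$truth$proteins)
#' @export
generate_ko_cohort <- function(cfg = cohort_config(n_tubules = 5),
                               pool_size = 5,
                               module = c("Clcnkb", "Bsnd", "Atp6v1g3",
                                          "Atp6v1b1"),
                               module_log2fc = -1.5,
                               effects = NULL,
                               anchor = "Slc26a4",
                               ic_shift = -0.5,
                               anchor_floor = TRUE,
                               floor_level = 500) {
  stopifnot(inherits(cfg, "cohort_config"))
  panel <- .full_panel_static(cfg)
  absent <- setdiff(c(module, anchor), panel$protein_id)
  if (length(absent) > 0) {
    stop("module/anchor proteins absent from panel: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  if (is.null(effects)) {
    effects <- stats::setNames(panel$ko_log2fc, panel$protein_id)
    effects[module] <- module_log2fc
  } else {
    eff0 <- stats::setNames(rep(0, nrow(panel)), panel$protein_id)
    eff0[names(effects)] <- effects
    effects <- eff0
  }
  effects[anchor] <- 0  # the anchor is handled by the floor, not a shift

  .with_seed(cfg$seed, {
    bio_sd <- 0.8 * cfg$noise_sd
    meas_sd <- 0.6 * cfg$noise_sd
    panel <- .full_panel(cfg)  # background baselines drawn inside the stream
    eff <- stats::setNames(rep(0, nrow(panel)), panel$protein_id)
    eff[names(effects)] <- effects

    gen_group <- function(label) {
      # each sample pools `pool_size` dissected tubules from one mouse
      cfg_pool <- cfg
      cfg_pool$n_tubules <- cfg$n_tubules * pool_size
      tubules <- .draw_tubules(cfg_pool)
      if (label == "KO") {
        tubules$ic_fraction <- stats::plogis(
          stats::qlogis(tubules$ic_fraction) + ic_shift)
      }
      sample_of <- rep(seq_len(cfg$n_tubules), each = pool_size)
      lt_tub <- .true_log2(cfg, tubules, panel, bio_sd)
      lt <- log2(t(rowsum(t(2^lt_tub), sample_of) / pool_size))
      colnames(lt) <- sprintf("%sS%02d", label, seq_len(cfg$n_tubules))
      if (label == "KO") {
        lt <- lt + eff[panel$protein_id]
        if (anchor_floor) {
          lt[anchor, ] <- log2(floor_level) +
            stats::rnorm(ncol(lt), sd = bio_sd)
        }
      }
      tubules$sample_id <- sprintf("%sS%02d", label, sample_of)
      list(tubules = tubules, log2_true = lt)
    }
    wt <- gen_group("WT")
    ko <- gen_group("KO")

    meas <- function(lt) {
      lt <- sweep(lt, 2, stats::rnorm(ncol(lt), sd = cfg$yield_sd), "+")
      2^(lt + matrix(stats::rnorm(length(lt), sd = meas_sd), nrow(lt)))
    }
    wt_m <- meas(wt$log2_true)
    ko_m <- meas(ko$log2_true)
    if (!is.null(cfg$missingness) && cfg$missingness$target > 0) {
      mp <- calibrate_missingness(cbind(wt_m, ko_m),
                                  cfg$missingness$target, cfg$missingness$b)
      wt_m <- apply_missingness(wt_m, mp)
      ko_m <- apply_missingness(ko_m, mp)
    }

    truth_proteins <- panel
    truth_proteins$ko_log2fc <- as.numeric(eff[panel$protein_id])
    truth_proteins$is_module <- panel$protein_id %in% module
    truth_proteins$is_anchor <- panel$protein_id == anchor

    list(
      wt = wt_m, ko = ko_m,
      matrix = cbind(wt_m, ko_m),
      groups = rep(c("WT", "KO"), times = c(ncol(wt_m), ncol(ko_m))),
      truth = list(
        proteins = truth_proteins, anchor = anchor, module = module,
        wt_tubules = wt$tubules, ko_tubules = ko$tubules,
        wt_log2_true = wt$log2_true, ko_log2_true = ko$log2_true,
        config = cfg
      )
    )
  })
}

# Panel including background ids but without consuming RNG (for validation).
.full_panel_static <- function(cfg) {
  panel <- cfg$panel
  if (cfg$n_background > 0) {
    panel <- rbind(panel, data.frame(
      protein_id = sprintf("BG%04d", seq_len(cfg$n_background)),
      cell_class = "background", baseline = NA_real_, comp_scale = 1,
      z_load = 0, icb_load = 0, pc_load = 0, hk_load = 0, ko_log2fc = 0
    ))
  }
  panel
}

#' Composition plan for a PRM transition fixture
#'
#' @param clean number of quality-passing transitions (split over
#'   `n_peptides`, at least two per peptide).
#' @param ppm number of mass-error violators (>= the ppm bound).
#' @param window number of transitions eluting outside the scheduled
#'   window.
#' @param coelution number of coelution outliers (in-window, accurate mass,
#'   apex far from the peptide's median).
#' @param singleton number of peptides represented by a single clean
#'   transition (dropped because coelution is undefined).
#' @param n_peptides number of clean peptides.
#' @param sample_id sample identifier written into the fixture.
#' @return plan list consumed by [generate_prm_fixture()].
#' @export
prm_plan <- function(clean = 6, ppm = 2, window = 1, coelution = 1,
                     singleton = 0, n_peptides = 2, sample_id = "T01") {
  stopifnot(clean >= 2 * n_peptides, n_peptides >= 1)
  list(clean = clean, ppm = ppm, window = window, coelution = coelution,
       singleton = singleton, n_peptides = n_peptides, sample_id = sample_id)
}

#' Generate a PRM transition-table fixture with planted defects
#'
#' Emits a transition table with exactly the planned composition: clean
#' transitions coeluting tightly inside their scheduled windows, plus
#' planted mass-error violators, out-of-window eluters, coelution outliers,
#' and singleton peptides. Nuisance values (areas, small apex jitter, small
#' mass errors) are randomised under the seed; the planted defect class of
#' every row is retained in the `planted` column for recovery checks.
#'
#' Planted defects are constructed against the default filter settings of
#' [filter_transitions()] (10 ppm bound, 0.2 min coelution tolerance).
#'
#' @param plan a [prm_plan()].
#' @param seed integer seed.
#' @param ppm_max,coelution_tol the filter settings the defects are planted
#'   against.
#' @return data.frame of transition rows with a `planted` column
#'   (`"clean"`, `"ppm"`, `"window"`, `"coelution"`, `"singleton"`).
#' @examples
#' prm <- generate_prm_fixture(prm_plan(), seed = 1)
#' table(prm$planted)
#' @export
generate_prm_fixture <- function(plan = prm_plan(), seed = 1,
                                 ppm_max = 10, coelution_tol = 0.2) {
  .with_seed(seed, {
    rows <- list()
    add <- function(peptide, protein, fragment, apex, win, ppm, planted) {
      rows[[length(rows) + 1]] <<- data.frame(
        peptide_id = peptide, protein_id = protein, fragment_id = fragment,
        apex_rt = apex, rt_window_start = win[1], rt_window_end = win[2],
        mass_error_ppm = ppm, area = stats::rlnorm(1, log(1e5), 0.5),
        sample_id = plan$sample_id, planted = planted
      )
    }
    clean_ppm <- function() {
      x <- stats::rnorm(1, 0, 2)
      max(min(x, 0.8 * ppm_max), -0.8 * ppm_max)
    }
    # clean peptides, each with its own 4-minute scheduled window
    per_pep <- diff(round(seq(0, plan$clean, length.out = plan$n_peptides + 1)))
    centers <- 10 + 6 * seq_len(plan$n_peptides)
    for (k in seq_len(plan$n_peptides)) {
      pep <- sprintf("PEP%02d_2", k)
      prot <- sprintf("PROT%02d", k)
      win <- centers[k] + c(-2, 2)
      for (j in seq_len(per_pep[k])) {
        add(pep, prot, sprintf("y%d", 3 + j),
            centers[k] + stats::runif(1, -coelution_tol / 4, coelution_tol / 4),
            win, clean_ppm(), "clean")
      }
    }
    # violators are attached to the first clean peptide
    win1 <- centers[1] + c(-2, 2)
    for (j in seq_len(plan$ppm)) {
      add("PEP01_2", "PROT01", sprintf("bP%d", j), centers[1], win1,
          sample(c(-1, 1), 1) * (ppm_max + abs(stats::rnorm(1, 2, 1))), "ppm")
    }
    for (j in seq_len(plan$window)) {
      add("PEP01_2", "PROT01", sprintf("bW%d", j),
          win1[2] + 0.5 + abs(stats::rnorm(1, 0.5, 0.2)), win1,
          clean_ppm(), "window")
    }
    for (j in seq_len(plan$coelution)) {
      add("PEP01_2", "PROT01", sprintf("bC%d", j),
          centers[1] + 3 * coelution_tol + j * coelution_tol, win1,
          clean_ppm(), "coelution")
    }
    for (j in seq_len(plan$singleton)) {
      pep <- sprintf("PEPS%02d_2", j)
      wc <- centers[plan$n_peptides] + 6 * j
      add(pep, sprintf("PROTS%02d", j), "y4", wc, wc + c(-2, 2),
          clean_ppm(), "singleton")
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
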