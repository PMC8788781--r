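# Shared test helpers: independent oracles and small utilities.

# Leaf order of a marker correlation matrix collapsed to the three
# heatmap classes; TRUE when each class forms one contiguous block.
classes_contiguous <- function(order, marker_map) {
  cls <- stats::setNames(marker_map$cell_class, marker_map$protein_id)[order]
  cls3 <- ifelse(cls %in% c("IC-A", "IC-B"), "IC", cls)
  r <- rle(cls3)
  length(r$values) == length(unique(cls3))
}

# Monte-Carlo oracle for the ENaC / amiloride-voltage coupling: simulates
# tubule cohorts directly from the generative equations (written out from
# scratch, no simulator internals) and returns the sample correlations of
# observed marker log2 intensity with the signed amiloride-sensitive
# voltage. Uses the default study conditions.
oracle_coupling <- function(n_rep, n_tub = 12) {
  ref_ic <- 3.5 / 8.5
  mu_lg <- digamma(3.5) - digamma(5)
  sd_lg <- sqrt(trigamma(3.5) + trigamma(5) + 0.5^2 / 3)
  bio <- 0.8 * 0.3
  meas <- 0.6 * 0.3
  r_enac <- numeric(n_rep)
  r_aqp2 <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    L <- runif(n_tub, 400, 600)
    d <- runif(n_tub, 15, 30)
    lg <- qlogis(rbeta(n_tub, 3.5, 5)) - 0.5 * (L - 500) / 100
    ic <- plogis(lg)
    z <- 0.4 * (lg - mu_lg) / sd_lg + sqrt(1 - 0.4^2) * rnorm(n_tub)
    q <- rnorm(n_tub)
    sizef <- log2(L / 500) + log2(d / 22.5)
    comp_dev <- log2(1 - ic) - log2(1 - ref_ic)
    # Scnn1b: baseline 8e3, comp exponent 2.5, z 0.6, pc 0.6
    enac_true <- log2(8e3) + log2(1 - ref_ic) + 2.5 * comp_dev + sizef +
      0.6 * z + 0.6 * q + rnorm(n_tub, sd = bio)
    # Aqp2: baseline 2e6, comp exponent 1.5, z -1.3
    aqp2_true <- log2(2e6) + log2(1 - ref_ic) + 1.5 * comp_dev + sizef -
      1.3 * z + rnorm(n_tub, sd = bio)
    yield <- rnorm(n_tub, sd = 0.4)
    enac_obs <- enac_true + yield + rnorm(n_tub, sd = meas)
    aqp2_obs <- aqp2_true + yield + rnorm(n_tub, sd = meas)
    act <- 2^(1.8 * z + rnorm(n_tub, sd = 0.15))
    g_t <- 0.9e-3 * 2^(enac_true - sizef - log2(8e3) - log2(1 - ref_ic)) * act
    g_p <- 5.5e-3 * 2^rnorm(n_tub, sd = 0.1)
    vte <- -140 * g_t / (g_t + g_p) + rnorm(n_tub, sd = 0.8)
    g_ta <- g_t * 0.02
    vte_a <- -140 * g_ta / (g_ta + g_p) + rnorm(n_tub, sd = 0.8)
    dv <- vte - vte_a
    r_enac[i] <- cor(enac_obs, dv)
    r_aqp2[i] <- cor(aqp2_obs, abs(dv))
  }
  list(enac = r_enac, aqp2 = r_aqp2)
}

# Recovered coupling through the package pipeline for one cohort seed.
recover_coupling <- function(seed) {
  co <- generate_cohort(cohort_config(seed = seed))
  ph <- derive_phenotypes(co$recordings)
  m <- log2(co$targeted)
  c(enac = cor(m["Scnn1b", ], ph$dVte_amil),
    aqp2 = cor(m["Aqp2", ], abs(ph$dVte_amil)))
}

# One knockout-cohort analysis round: differential on the untargeted
# matrix, plus covariation against an independently generated wild-type
# cohort (transport markers only).
run_ko_round <- function(seed, n_perm = 1000) {
  ko <- generate_ko_cohort(cohort_config(n_tubules = 5, seed = seed))
  imp <- impute_downshift(log_center(ko$matrix), seed = seed + 1L)
  dif <- differential(imp, ko$groups)
  tp <- ko$truth$proteins
  mod <- dif$protein_id %in% ko$truth$module
  unplanted <- tp$protein_id[tp$ko_log2fc == 0 & !tp$is_anchor]
  wt <- generate_cohort(cohort_config(seed = seed + 2L))
  cand <- wt$marker_map$protein_id[wt$marker_map$cell_class != "housekeeping"]
  cv <- covariation_vs_regulation(
    double_center(wt$targeted)$values[cand, , drop = FALSE],
    "Slc26a4", dif, n_perm = n_perm, seed = seed + 3L
  )
  c(
    anchor = dif$hit_flag[dif$protein_id == ko$truth$anchor],
    sens = mean(dif$hit_flag[mod] & dif$log2fc[mod] < 0),
    fp = sum(dif$hit_flag[dif$protein_id %in% unplanted]),
    n_unplanted = length(unplanted),
    r = cv$r, p_quad = cv$p_quadrant, p_cor = cv$p_cor
  )
}
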