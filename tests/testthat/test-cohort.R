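# Synthetic cohort generator: determinism, validation, planted structure,
# forward-model consistency, missingness calibration, knockout cohorts.

test_that("configuration is validated", {
  expect_error(cohort_config(n_tubules = 2), "n_tubules")
  expect_error(cohort_config(length_range = c(600, 400)), "ordered")
  expect_error(cohort_config(ic_a_share = 1.5), "ic_a_share")
  expect_error(cohort_config(missingness = list(target = 1.2, b = 1)),
               "target")
  expect_error(cohort_config(panel = data.frame(protein_id = "x")),
               "panel lacks")
})

test_that("generation is a pure function of config and seed", {
  a <- generate_cohort(cohort_config(n_tubules = 5, seed = 77))
  b <- generate_cohort(cohort_config(n_tubules = 5, seed = 77))
  expect_identical(a, b)
  c2 <- generate_cohort(cohort_config(n_tubules = 5, seed = 78))
  expect_false(identical(a$targeted, c2$targeted))
  # generators restore the caller's RNG stream
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(generate_cohort(cohort_config(n_tubules = 4, seed = 3)))
  expect_identical(rnorm(1), before)
})

test_that("true abundances span at least five orders of magnitude", {
  co <- generate_cohort(cohort_config(seed = 2))
  tr <- 2^co$truth$log2_true
  expect_gte(log10(max(tr) / min(tr)), 5)
})

test_that("forward-simulated recordings invert to the true cable parameters", {
  cfg <- cohort_config(n_tubules = 8, seed = 12, noise_sd = 0,
                       deflection_cv = 0,
                       circuit = list(vte_noise_sd = 0, gp_sd = 0,
                                      act_noise_sd = 0),
                       vdp_noise_sd = 0, yield_sd = 0, missingness = NULL)
  co <- generate_cohort(cfg)
  ph <- derive_phenotypes(co$recordings)
  tt <- co$truth$tubules
  expect_equal(ph$Rte, tt$Rte, tolerance = 1e-3)
  expect_equal(ph$diameter, tt$diameter, tolerance = 1e-3)
  expect_equal(ph$pna_pcl, tt$pna_pcl, tolerance = 1e-6)
  expect_equal(ph$dVte_amil, tt$dVte_amil_model, tolerance = 1e-6)
})

test_that("composition truth is perfectly reflected in the noise-free limit", {
  cfg <- cohort_config(n_tubules = 30, seed = 4, noise_sd = 0,
                       length_range = c(500, 500),
                       diameter_range = c(22.5, 22.5),
                       coupling = list(strength = 0, act_z = 0, z_comp = 0,
                                       icb_strength = 0, pc_strength = 0),
                       yield_sd = 0, missingness = NULL)
  co <- generate_cohort(cfg)
  ic <- co$truth$tubules$ic_fraction
  # linear-response IC marker abundance is proportional to the IC fraction
  expect_equal(cor(2^(co$truth$log2_true["Atp6v1a", ] / 2), ic), 1,
               tolerance = 1e-12)
  # deterministic coupling: ENaC rank-orders the amiloride voltage exactly
  cfg2 <- cohort_config(n_tubules = 15, seed = 6, noise_sd = 0,
                        circuit = list(vte_noise_sd = 0, gp_sd = 0,
                                       act_noise_sd = 0),
                        yield_sd = 0, missingness = NULL)
  co2 <- generate_cohort(cfg2)
  ph2 <- derive_phenotypes(co2$recordings)
  enac <- log2(co2$targeted["Scnn1b", ]) -
    (log2(co2$truth$tubules$L / 500) + log2(co2$truth$tubules$diameter / 22.5))
  act <- cfg2$coupling$act_z * co2$truth$tubules$z
  expect_equal(cor(enac + act, ph2$dVte_amil, method = "spearman"), -1)
  # Pearson stays high but below 1: the voltage divider is monotone, not
  # linear, in log conductance
  expect_lt(cor(enac + act, ph2$dVte_amil), -0.9)
})

test_that("missingness is intensity-dependent and calibrated to its target", {
  co <- generate_cohort(cohort_config(seed = 3))
  miss <- rowMeans(is.na(co$untargeted))
  inten <- rowMeans(co$truth$log2_true)
  expect_lt(cor(miss, inten, use = "complete.obs"), -0.5)
  frac <- sapply(1:50, function(s) {
    mean(is.na(generate_cohort(cohort_config(seed = s))$untargeted))
  })
  expect_equal(mean(frac), 0.3, tolerance = 0.02)
  # calibration solves for the requested rate on a known matrix
  set.seed(10)
  m <- matrix(2^runif(5000, 10, 25), 100)
  pars <- calibrate_missingness(m, target = 0.4, b = 1)
  expect_equal(mean(is.na(apply_missingness(m, pars, seed = 1))), 0.4,
               tolerance = 0.03)
  # steep slope splits the panel exactly at the threshold
  hi <- apply_missingness(matrix(2^c(5, 25), 1), list(a = -15 * 1e3, b = 1e3),
                          seed = 1)
  expect_true(is.na(hi[1, 1]) && !is.na(hi[1, 2]))
})

test_that("knockout generator plants the documented regulation profile", {
  ko <- generate_ko_cohort(cohort_config(n_tubules = 4, seed = 9))
  tp <- ko$truth$proteins
  expect_true(all(tp$ko_log2fc[tp$is_module] == -1.5))
  expect_true(tp$ko_log2fc[tp$protein_id == "Slc4a1"] == 0)  # AE1 unchanged
  expect_true(all(tp$ko_log2fc[tp$protein_id %in%
                                 c("Atp6v1a", "Ca12", "Slc26a7")] < 0))
  expect_identical(dim(ko$wt), dim(ko$ko))
  expect_equal(ko$groups, rep(c("WT", "KO"), each = 4))
  # anchor is reduced to the noise floor
  anc_wt <- mean(log2(ko$wt["Slc26a4", ]), na.rm = TRUE)
  anc_ko <- mean(ko$truth$ko_log2_true["Slc26a4", ])
  expect_lt(anc_ko, anc_wt - 5)
  expect_error(generate_ko_cohort(cohort_config(n_tubules = 4),
                                  module = "NotAProtein"), "absent")
})

test_that("null knockout effects leave both genotypes exchangeable", {
  panel <- default_panel()
  eff0 <- stats::setNames(rep(0, nrow(panel)), panel$protein_id)
  ko <- generate_ko_cohort(cohort_config(n_tubules = 6, seed = 15),
                           effects = eff0, anchor_floor = FALSE,
                           ic_shift = 0)
  expect_true(all(ko$truth$proteins$ko_log2fc == 0))
  dif <- differential(impute_downshift(log_center(ko$matrix), seed = 2),
                      ko$groups)
  expect_lt(mean(dif$hit_flag), 0.05)  # chance level on ~400 proteins
})

test_that("PRM fixtures reproduce their plan composition deterministically", {
  plan <- prm_plan(clean = 8, ppm = 3, window = 2, coelution = 1,
                   singleton = 2, n_peptides = 3)
  a <- generate_prm_fixture(plan, seed = 4)
  b <- generate_prm_fixture(plan, seed = 4)
  expect_identical(a, b)
  expect_equal(as.vector(table(factor(a$planted,
    c("clean", "ppm", "window", "coelution", "singleton")))),
    c(8, 3, 2, 1, 2))
  all_clean <- generate_prm_fixture(prm_plan(clean = 6, ppm = 0, window = 0,
                                             coelution = 0), seed = 2)
  f <- filter_transitions(all_clean[, setdiff(names(all_clean), "planted")])
  expect_equal(nrow(f$rejected), 0)
})
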