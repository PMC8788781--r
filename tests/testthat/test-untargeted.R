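# Untargeted normalisation, imputation, differential testing, iBAQ.

test_that("log-centering removes per-sample scale and matches hand example", {
  expect_equal(as.numeric(log_center(matrix(c(2, 8), 2, 1))), c(-1, 1))
  m <- matrix(2^rnorm(20, 8), 5, 4)
  m8 <- m; m8[, 2] <- m8[, 2] * 8
  expect_equal(log_center(m8), log_center(m), tolerance = 1e-12)
  expect_equal(log_center(matrix(rep(4, 3), 3, 1)),
               matrix(0, 3, 1))
  expect_error(log_center(matrix(c(0, 1), 2, 1)), "positive")
})

test_that("downshift imputation draws from the stated distribution", {
  # 1e5 imputed cells in a sample with observed mean 0, sd 1
  set.seed(3)
  m <- matrix(NA_real_, 100001 + 1000, 1)
  m[1:1000, 1] <- scale(rnorm(1000))  # exactly mean 0, sd 1
  imp <- impute_downshift(m, width = 0.3, shift = 1.8, seed = 99)
  drawn <- imp[-(1:1000), 1]
  expect_equal(mean(drawn), -1.8, tolerance = 0.01)
  expect_equal(sd(drawn), 0.3, tolerance = 0.01)
})

test_that("imputation is deterministic under seed and leaves complete data alone", {
  m <- matrix(c(1, 2, 3, NA, 2, 4, 6, 8), 4, 2)
  a <- impute_downshift(m, seed = 5)
  b <- impute_downshift(m, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a, impute_downshift(m, seed = 6)))
  full <- matrix(rnorm(12), 3, 4)
  expect_identical(impute_downshift(full, seed = 1), full)
  # too few observed values in a sample is an error
  bad <- matrix(c(1, NA, NA, NA), 4, 1)
  expect_error(impute_downshift(bad, seed = 1), "fewer than 3")
})

test_that("differential matches stats::t.test and flags hits by both cutoffs", {
  set.seed(11)
  m <- matrix(rnorm(50 * 10), 50, 10,
              dimnames = list(sprintf("P%02d", 1:50), NULL))
  m[1, 6:10] <- m[1, 6:10] - 3
  groups <- rep(c("WT", "KO"), each = 5)
  res <- differential(m, groups)
  # cross-check each statistic against the reference implementation
  for (i in c(1, 2, 25)) {
    tt <- t.test(m[i, 6:10], m[i, 1:5], var.equal = TRUE)
    expect_equal(res$t_stat[i], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(res$p_value[i], tt$p.value, tolerance = 1e-12)
    expect_equal(res$log2fc[i], unname(diff(rev(tt$estimate))),
                 tolerance = 1e-12)
  }
  expect_true(res$hit_flag[1])
  expect_equal(res$hit_flag,
               !is.na(res$p_value) & res$p_value < 0.05 & abs(res$log2fc) >= 1)
  # Welch variant agrees with t.test as well
  resw <- differential(m, groups, var_equal = FALSE)
  ttw <- t.test(m[1, 6:10], m[1, 1:5])
  expect_equal(resw$p_value[1], ttw$p.value, tolerance = 1e-12)
})

test_that("identical groups give zero fold change and p of one", {
  m <- matrix(rep(c(1, 2, 3), 2), 1, 6)
  res <- differential(m, rep(c("WT", "KO"), each = 3))
  expect_equal(res$log2fc, 0)
  expect_equal(res$t_stat, 0)
  expect_equal(res$p_value, 1)
  # degenerate: zero variance in both groups
  res2 <- differential(matrix(1, 1, 6), rep(c("WT", "KO"), each = 3))
  expect_true(res2$degenerate)
  expect_true(is.na(res2$p_value))
})

test_that("hand-evaluated t statistic is reproduced", {
  m <- matrix(c(0, 0, 0, -2, -2.1, -1.9), 1, 6)
  res <- differential(m, rep(c("WT", "KO"), each = 3))
  expect_equal(res$log2fc, -2)
  se <- sqrt(mean(c(var(c(0, 0, 0)), var(c(-2, -2.1, -1.9)))) * (2 / 3))
  expect_equal(res$t_stat, -2 / se, tolerance = 1e-12)
})

test_that("BH q-values are monotone in p-rank", {
  set.seed(2)
  m <- matrix(rnorm(400 * 8), 400, 8)
  res <- differential(m, rep(c("WT", "KO"), each = 4))
  o <- order(res$p_value)
  expect_true(all(diff(res$q_value[o]) >= -1e-12))
  expect_equal(res$q_value, p.adjust(res$p_value, "BH"))
})

test_that("tryptic digestion cleaves after K/R except before P", {
  expect_equal(tryptic_digest("AAAAKRPPPPK"), c("AAAAK", "RPPPPK"))
  expect_equal(tryptic_digest("MNPQST"), "MNPQST")
  expect_equal(tryptic_digest("KKKKKK"), rep("K", 6))
  expect_error(tryptic_digest("ABCZ"), "alphabet")
  expect_error(tryptic_digest(""), "nonempty")
})

test_that("digests concatenate back to the original sequence", {
  set.seed(8)
  aa <- c("A", "C", "D", "E", "G", "K", "R", "P", "S", "T")
  for (i in 1:25) {
    seqs <- paste(sample(aa, sample(10:120, 1), replace = TRUE), collapse = "")
    expect_equal(paste(tryptic_digest(seqs), collapse = ""), seqs)
  }
})

test_that("observable peptide counting respects the length window", {
  expect_equal(observable_peptides("AAAAKRPPPPK"), 1)  # RPPPPK only
  expect_equal(observable_peptides("KKKKKK"), 0)
  expect_equal(observable_peptides("MNPQST", min_len = 6, max_len = 30), 1)
  expect_equal(observable_peptides("MNPQST", min_len = 7), 0)
})

test_that("iBAQ divides summed intensity by observable peptides", {
  expect_equal(ibaq(1000, 10), 100)
  expect_equal(ibaq(0, 5), 0)
  expect_equal(ibaq(7.5e6, 25), 3e5)
  expect_true(is.na(ibaq(1000, 0)))
  # equal intensity: ordering follows inverse observable count
  expect_true(ibaq(1e6, 5) > ibaq(1e6, 50))
  tab <- ibaq_table(c(A = 1000, B = 1000),
                    c(A = "AAAAKRPPPPK", B = "MNPQST"))
  expect_equal(tab$ibaq, c(1000, 1000))
  expect_error(ibaq_table(c(A = 1), c(B = "MNPQST")), "no sequence")
})
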