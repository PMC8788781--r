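# Correlation grids, clustering order, PCA, chord contributions,
# covariation-versus-regulation.

test_that("pairwise Pearson correlations match hand-computed values", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4), c = c(4, 3, 2, 1))
  r <- correlation_matrix(m)
  expect_equal(diag(r), c(a = 1, b = 1, c = 1))
  expect_equal(r["a", "b"], 0.8)
  expect_equal(r["a", "c"], -1)
  expect_equal(r, t(r))
  # invariant to affine rescaling of a series
  m2 <- m; m2["b", ] <- 5 - 2 * m2["b", ]
  r2 <- correlation_matrix(m2)
  expect_equal(abs(r2["a", "b"]), 0.8)
})

test_that("correlation floor and zero-variance series yield missing values", {
  m <- rbind(a = c(1, 2, 3, NA, NA), b = c(2, 1, NA, 4, 5),
             c = c(1, 1, 1, 1, 1), d = c(5, 4, 3, 2, 1))
  r <- correlation_matrix(m, min_obs = 3)
  expect_true(is.na(r["a", "b"]))   # only 2 shared observations
  expect_true(is.na(r["c", "d"]))   # zero variance
  expect_false(is.na(r["a", "d"]))
  expect_error(correlation_matrix(m, min_obs = 2), "at least 3")
})

test_that("protein-phenotype grids align tubules and honour magnitude flags", {
  m <- matrix(rnorm(20), 2, 10,
              dimnames = list(c("A", "B"), sprintf("T%02d", 1:10)))
  ph <- data.frame(tubule_id = sprintf("T%02d", 10:1),
                   dVte_amil = -(1:10), Rte = rnorm(10))
  r <- correlation_matrix(m, phenotypes = ph)
  expect_equal(dim(r), c(2, 2))
  rm_ <- correlation_matrix(m, phenotypes = ph, use_magnitude = "dVte_amil")
  expect_equal(rm_[, "dVte_amil"], -r[, "dVte_amil"])
  expect_error(correlation_matrix(m, phenotypes = ph[1:5, ]), "lacks tubules")
})

test_that("identical correlation profiles merge first in clustering", {
  r <- diag(4)
  dimnames(r) <- list(letters[1:4], letters[1:4])
  r["a", "b"] <- r["b", "a"] <- 0.9
  r["c", "d"] <- r["d", "c"] <- 0.9
  r["a", "c"] <- r["c", "a"] <- r["a", "d"] <- r["d", "a"] <- -0.5
  r["b", "c"] <- r["c", "b"] <- r["b", "d"] <- r["d", "b"] <- -0.5
  hc <- hclust_order(r)
  # a/b and c/d differ only in their self/partner coordinates -> they are
  # the closest pairs and merge first
  expect_equal(hc$hclust$height[1:2], rep(sqrt(2 * 0.1^2), 2))
  first_pairs <- apply(hc$hclust$merge[1:2, ], 1,
                       function(x) paste(sort(rownames(r)[-x]), collapse = ""))
  expect_setequal(first_pairs, c("ab", "cd"))
  expect_error(hclust_order(r[1, 1, drop = FALSE]), "at least 2")
})

test_that("planted marker blocks cluster into contiguous leaves", {
  set.seed(31)
  # three blocks of mutually correlated rows over 40 samples
  block <- function(n, centre) centre + matrix(rnorm(n * 40, sd = 0.4), n)
  f1 <- rnorm(40); f2 <- rnorm(40); f3 <- rnorm(40)
  m <- rbind(t(replicate(5, f1)) + matrix(rnorm(200, sd = .4), 5),
             t(replicate(5, f2)) + matrix(rnorm(200, sd = .4), 5),
             t(replicate(5, f3)) + matrix(rnorm(200, sd = .4), 5))
  rownames(m) <- sprintf("p%02d", 1:15)
  r <- correlation_matrix(m)
  ord <- hclust_order(r)$order
  grp <- rep(c("PC", "IC", "hk"), each = 5)[match(ord, rownames(m))]
  expect_equal(length(rle(grp)$values), 3)
  # permuting input rows preserves the partition into blocks
  perm <- sample(15)
  ord2 <- hclust_order(r[perm, perm])$order
  grp2 <- rep(c("PC", "IC", "hk"), each = 5)[match(ord2, rownames(m))]
  expect_equal(length(rle(grp2)$values), 3)
})

test_that("PCA variance fractions sum to one and detect rank-1 structure", {
  set.seed(5)
  m <- matrix(rnorm(60), 6, 10)
  pc <- pca_matrix(m, axis = "tubules")
  expect_equal(sum(pc$var_fraction), 1)
  rank1 <- outer(1:6, seq(0.1, 1, length.out = 10))
  pc1 <- pca_matrix(rank1, axis = "tubules")
  expect_equal(pc1$var_fraction[1], 1)
  # scores invariant (up to sign) to observation ordering
  perm <- sample(10)
  pc2 <- pca_matrix(m[, perm], axis = "tubules")
  ref <- pc$scores[perm, 1]
  expect_true(min(sum((pc2$scores[, 1] - ref)^2),
                  sum((pc2$scores[, 1] + ref)^2)) < 1e-18)
  expect_error(pca_matrix(matrix(c(1, NA, 2, 3), 2)), "complete")
})

test_that("chord masses and widths follow the hand-computed examples", {
  corr <- matrix(c(0.5, 0.3, -0.2), 3, 1,
                 dimnames = list(c("A", "B", "C"), "Vte"))
  out <- chord_contributions(corr, c(A = "PC", B = "PC", C = "PC"))
  expect_equal(out$mass[out$sign == "pos"], 0.8)
  expect_equal(out$mass[out$sign == "neg"], 0.2)
  # two classes with positive masses 3 and 1 -> widths 0.75 / 0.25
  corr2 <- matrix(c(1, 1, 1, 1), 4, 1,
                  dimnames = list(letters[1:4], "len"))
  mk <- c(a = "PC", b = "PC", c = "PC", d = "IC-A")
  corr2[1:3, 1] <- 1; corr2[4, 1] <- 1 / 3
  out2 <- chord_contributions(corr2 * 3, mk)
  pos <- out2[out2$sign == "pos", ]
  expect_equal(pos$width[pos$cell_class == "PC"], 0.9)
  expect_equal(pos$width[pos$cell_class == "IC-A"], 0.1)
  expect_equal(sum(pos$width), 1)
  # all-zero grid reports zero widths, not NaN
  out3 <- chord_contributions(corr * 0, c(A = "PC", B = "PC", C = "PC"))
  expect_true(all(out3$width == 0))
  expect_error(chord_contributions(corr, c(A = "PC")), "lacks proteins")
})

test_that("chord widths renormalise when a phenotype column is duplicated", {
  corr <- matrix(c(0.7, -0.4, 0.2, -0.8, 0.5, 0.1, -0.3, 0.6), 4, 2,
                 dimnames = list(letters[1:4], c("f1", "f2")))
  mk <- c(a = "PC", b = "PC", c = "IC-A", d = "IC-B")
  base <- chord_contributions(corr, mk)
  dup <- chord_contributions(cbind(corr, f1b = corr[, 1]), mk)
  for (sg in c("pos", "neg")) {
    expect_equal(sum(dup$width[dup$sign == sg]), 1, tolerance = 1e-12)
    b1 <- base[base$sign == sg & base$phenotype == "f1", ]
    d1 <- dup[dup$sign == sg & dup$phenotype == "f1", ]
    expect_equal(d1$mass[order(d1$cell_class)], b1$mass[order(b1$cell_class)])
  }
})

test_that("covariation-regulation comparison pairs anchors correctly", {
  set.seed(13)
  wt <- matrix(rnorm(8 * 12), 8, 12,
               dimnames = list(c("anchor", letters[1:7]), NULL))
  x <- correlation_matrix(wt)[letters[1:7], "anchor"]
  ko <- data.frame(protein_id = c(letters[1:7], "anchor"),
                   log2fc = c(-x, 5))
  cv <- covariation_vs_regulation(wt, "anchor", ko)
  # y = -x exactly -> r = -1; anchor excluded from the table
  expect_equal(cv$r, -1)
  expect_false("anchor" %in% cv$table$protein_id)
  expect_equal(sum(cv$quadrants), 7)
  expect_equal(unname(cv$quadrants["pos_down"] + cv$quadrants["neg_up"]), 7)
  expect_error(covariation_vs_regulation(wt, "absent", ko), "not present")
})

test_that("permutation calibration detects a planted coupled module", {
  set.seed(17)
  latent <- rnorm(12)
  wt <- rbind(
    anchor = latent + rnorm(12, sd = 0.3),
    t(replicate(6, latent + rnorm(12, sd = 0.3))),   # module co-expressed
    matrix(rnorm(20 * 12), 20)
  )
  rownames(wt) <- c("anchor", sprintf("m%d", 1:6), sprintf("n%02d", 1:20))
  ko <- data.frame(protein_id = rownames(wt)[-1],
                   log2fc = c(rnorm(6, -1.5, 0.2), rnorm(20, 0.3, 0.2)))
  cv <- covariation_vs_regulation(wt, "anchor", ko, n_perm = 500, seed = 3)
  expect_lt(cv$r, 0)
  expect_lt(cv$p_cor, 0.05)
  expect_lt(cv$p_quadrant, 0.05)
})
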