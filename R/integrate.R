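# Proteome-phenotype integration: Pearson correlation grids, hierarchical
# clustering of correlation profiles, PCA, chord net-contribution statistics
# per cell class, and the covariation-versus-knockout-regulation comparison.

#' Pearson correlation matrix over pairwise-complete observations
#'
#' Correlates the rows of a protein-by-sample matrix across samples. With
#' `phenotypes` supplied, a rectangular protein-by-phenotype grid is
#' returned instead, matching phenotype rows to sample columns by
#' `tubule_id`. Pairs with fewer than `min_obs` complete observations, and
#' zero-variance series, yield `NA`.
#'
#' @param m numeric matrix (proteins x samples); missing values allowed.
#' @param phenotypes optional data.frame with a `tubule_id` column naming
#'   the samples and numeric phenotype columns (e.g. from
#'   [derive_phenotypes()]).
#' @param min_obs minimum paired observations for a reported coefficient
#'   (default 3).
#' @param use_magnitude optional character vector of phenotype columns to
#'   correlate on absolute values (e.g. `"dVte_amil"` when the
#'   amiloride-sensitive voltage should enter as a magnitude rather than a
#'   signed lumen-minus-bath quantity).
#' @return correlation matrix: square symmetric with unit diagonal when
#'   `phenotypes` is `NULL`, otherwise proteins x phenotypes.
#' @examples
#' m <- matrix(rnorm(30), 3, 10, dimnames = list(c("A", "B", "C"), NULL))
#' correlation_matrix(m)
#' @export
correlation_matrix <- function(m, phenotypes = NULL, min_obs = 3,
                               use_magnitude = NULL) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (min_obs < 3) stop("`min_obs` must be at least 3", call. = FALSE)
  x <- t(m)
  if (is.null(phenotypes)) {
    y <- x
  } else {
    stopifnot(is.data.frame(phenotypes), "tubule_id" %in% names(phenotypes))
    idx <- match(colnames(m), as.character(phenotypes$tubule_id))
    if (anyNA(idx)) {
      stop("phenotype table lacks tubules: ",
           paste(colnames(m)[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    num <- vapply(phenotypes, is.numeric, logical(1))
    num["tubule_id"] <- FALSE
    y <- as.matrix(phenotypes[idx, num, drop = FALSE])
    rownames(y) <- colnames(m)
    for (col in intersect(use_magnitude, colnames(y))) {
      y[, col] <- abs(y[, col])
    }
  }
  r <- suppressWarnings(stats::cor(x, y, use = "pairwise.complete.obs"))
  # enforce the observation floor pair by pair
  nobs <- crossprod(!is.na(x), !is.na(y))
  r[nobs < min_obs] <- NA_real_
  if (is.null(phenotypes)) diag(r)[colSums(!is.na(x)) >= min_obs] <- 1
  r
}

#' Hierarchical clustering order of a correlation matrix
#'
#' Agglomerative clustering (average linkage) on Euclidean distances between
#' the rows of a square correlation matrix, i.e. between correlation
#' profiles, as used for marker heatmaps. Rows/columns that are entirely
#' missing are dropped first; any remaining missing entry is an error.
#' Leaf order is deterministic given the input order.
#'
#' @param corr square numeric correlation matrix with dimnames.
#' @param method linkage criterion passed to [stats::hclust()]; default
#'   `"average"`.
#' @return list with `order` (leaf labels in dendrogram order) and `hclust`
#'   (the [stats::hclust()] object).
#' @examples
#' m <- matrix(rnorm(40), 4, 10, dimnames = list(LETTERS[1:4], NULL))
#' hclust_order(correlation_matrix(m))$order
#' @export
hclust_order <- function(corr, method = "average") {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  all_na <- rowSums(!is.na(corr)) <= 1
  corr <- corr[!all_na, !all_na, drop = FALSE]
  if (nrow(corr) < 2) stop("need at least 2 items to cluster", call. = FALSE)
  if (anyNA(corr)) {
    stop("correlation matrix still has missing entries after dropping empty rows",
         call. = FALSE)
  }
  hc <- stats::hclust(stats::dist(corr, method = "euclidean"), method = method)
  list(order = rownames(corr)[hc$order], hclust = hc)
}

#' Principal component analysis of an intensity matrix
#'
#' Mean-centered PCA (via singular value decomposition) of a complete
#' protein-by-sample matrix. With `axis = "tubules"` the tubules are the
#' observations (scores per tubule, loadings per protein); with
#' `axis = "proteins"` the roles are transposed.
#'
#' @param m complete numeric matrix (proteins x samples), e.g. log2
#'   intensities after imputation.
#' @param axis `"tubules"` or `"proteins"`: which dimension forms the
#'   observations.
#' @return list with `scores`, `loadings`, and `var_fraction` (fractions of
#'   total variance, summing to 1; rank-deficient directions report zero).
#' @examples
#' m <- matrix(rnorm(60), 6, 10)
#' pca_matrix(m, axis = "tubules")$var_fraction
#' @export
pca_matrix <- function(m, axis = c("tubules", "proteins")) {
  axis <- match.arg(axis)
  stopifnot(is.matrix(m), is.numeric(m))
  if (anyNA(m)) stop("PCA needs a complete matrix; impute first", call. = FALSE)
  obs <- if (axis == "tubules") t(m) else m
  if (nrow(obs) < 2 || ncol(obs) < 2) {
    stop("need at least 2 rows and 2 columns", call. = FALSE)
  }
  pc <- stats::prcomp(obs, center = TRUE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, loadings = pc$rotation, var_fraction = vf)
}

#' Chord-diagram contribution statistics per cell class
#'
#' Summarises a protein-by-phenotype correlation grid into the numeric
#' masses behind a chord diagram: for each (cell class, phenotype) pair the
#' positive mass is the sum of positive correlation coefficients of that
#' class's proteins with that phenotype, and the negative mass the sum of
#' `max(-r, 0)`. Widths normalise the masses to sum to one within each sign,
#' i.e. the relative contribution of each class-phenotype link to the total
#' net positive (or negative) correlation. Links are ordered by decreasing
#' width within each sign for presentation parity with circular layouts.
#'
#' @param corr numeric protein-by-phenotype correlation matrix (rows named
#'   by protein).
#' @param markers marker map: data.frame with columns `protein_id` and
#'   `cell_class`, or a named character vector. Every protein in `corr`
#'   must be mapped to exactly one class.
#' @return data.frame with columns `cell_class`, `phenotype`, `sign`
#'   (`"pos"`/`"neg"`), `mass`, `width`; widths within a sign sum to 1 when
#'   the sign's total mass is positive and are 0 otherwise.
#' @examples
#' corr <- matrix(c(0.5, 0.3, -0.2), 3, 1,
#'                dimnames = list(c("A", "B", "C"), "Vte"))
#' chord_contributions(corr, c(A = "PC", B = "PC", C = "IC-A"))
#' @export
chord_contributions <- function(corr, markers) {
  stopifnot(is.matrix(corr), !is.null(rownames(corr)))
  if (is.data.frame(markers)) {
    stopifnot(all(c("protein_id", "cell_class") %in% names(markers)))
    map <- stats::setNames(as.character(markers$cell_class),
                           as.character(markers$protein_id))
  } else {
    map <- markers
  }
  if (anyDuplicated(names(map))) {
    stop("each protein must map to exactly one cell class", call. = FALSE)
  }
  miss <- setdiff(rownames(corr), names(map))
  if (length(miss) > 0) {
    stop("marker map lacks proteins: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  classes <- map[rownames(corr)]
  phen <- colnames(corr)
  if (is.null(phen)) phen <- paste0("phenotype", seq_len(ncol(corr)))
  out <- do.call(rbind, lapply(c("pos", "neg"), function(sg) {
    part <- if (sg == "pos") pmax(corr, 0) else pmax(-corr, 0)
    mass <- rowsum(part, classes, na.rm = TRUE)
    df <- expand.grid(cell_class = rownames(mass), phenotype = phen,
                      stringsAsFactors = FALSE)
    df$sign <- sg
    df$mass <- as.vector(mass)
    total <- sum(df$mass)
    df$width <- if (total > 0) df$mass / total else 0
    df[order(-df$width), , drop = FALSE]
  }))
  rownames(out) <- NULL
  out
}

#' Compare wild-type covariation with knockout regulation
#'
#' For every protein quantified alongside an anchor protein (e.g. pendrin)
#' in wild-type tubules, pairs its tubule-to-tubule Pearson correlation with
#' the anchor (`cor_with_anchor`, x) against its log2 fold change in the
#' knockout (`log2fc`, y, from [differential()]). Proteins co-expressed
#' with the anchor that fall with it in the knockout populate the
#' (x > 0, y < 0) quadrant. An optional permutation test shuffles the fold
#' changes over proteins to calibrate both the overall correlation r(x, y)
#' (one-sided, low) and the (x > 0, y < 0) quadrant count (one-sided, high).
#'
#' @param wt numeric matrix of wild-type log2 intensities (proteins x
#'   tubules) containing the anchor row.
#' @param anchor_protein row name of the anchor protein.
#' @param ko_results data.frame from [differential()] (needs `protein_id`
#'   and `log2fc`).
#' @param min_obs pairwise observation floor for the anchor correlations.
#' @param n_perm number of label permutations (0 disables the test).
#' @param seed optional seed for the permutation draw.
#' @return list with `table` (protein_id, cor_with_anchor, log2fc), `r`
#'   (Pearson correlation of x and y), `quadrants` (named counts
#'   `pos_up`, `pos_down`, `neg_up`, `neg_down`), and, if `n_perm > 0`,
#'   `p_cor` and `p_quadrant`.
#' @export
covariation_vs_regulation <- function(wt, anchor_protein, ko_results,
                                      min_obs = 3, n_perm = 0, seed = NULL) {
  stopifnot(is.matrix(wt), !is.null(rownames(wt)))
  if (!anchor_protein %in% rownames(wt)) {
    stop("anchor protein not present in the wild-type matrix", call. = FALSE)
  }
  stopifnot(is.data.frame(ko_results),
            all(c("protein_id", "log2fc") %in% names(ko_results)))
  others <- setdiff(rownames(wt), anchor_protein)
  rr <- correlation_matrix(wt, min_obs = min_obs)
  x <- rr[others, anchor_protein]
  fc <- stats::setNames(ko_results$log2fc, ko_results$protein_id)
  common <- intersect(others, names(fc))
  if (length(common) < 3) {
    stop("need at least 3 proteins shared between wt matrix and ko results",
         call. = FALSE)
  }
  tab <- data.frame(
    protein_id = common,
    cor_with_anchor = as.numeric(x[common]),
    log2fc = as.numeric(fc[common]),
    row.names = NULL
  )
  ok <- stats::complete.cases(tab)
  xv <- tab$cor_with_anchor[ok]
  yv <- tab$log2fc[ok]
  r <- if (sum(ok) >= 3) stats::cor(xv, yv) else NA_real_
  quad <- c(
    pos_up = sum(xv > 0 & yv > 0),
    pos_down = sum(xv > 0 & yv < 0),
    neg_up = sum(xv < 0 & yv > 0),
    neg_down = sum(xv < 0 & yv < 0)
  )
  out <- list(table = tab, r = r, quadrants = quad)
  if (n_perm > 0) {
    out[c("p_cor", "p_quadrant")] <- .with_seed(seed, {
      n <- length(yv)
      perm_r <- numeric(n_perm)
      perm_q <- integer(n_perm)
      for (b in seq_len(n_perm)) {
        yp <- yv[sample.int(n)]
        perm_r[b] <- stats::cor(xv, yp)
        perm_q[b] <- sum(xv > 0 & yp < 0)
      }
      list(
        (1 + sum(perm_r <= r)) / (n_perm + 1),
        (1 + sum(perm_q >= quad[["pos_down"]])) / (n_perm + 1)
      )
    })
  }
  out
}
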