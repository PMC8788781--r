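# Untargeted (LFQ-like) differential analysis: per-sample log-normalisation,
# downshifted-normal imputation of missing intensities, vectorised two-sample
# t-tests, and iBAQ copy-number estimation via in-silico tryptic digestion.

#' Log2 transform and per-sample mean centering
#'
#' Log2-transforms a protein-by-sample intensity matrix and subtracts each
#' sample's mean over observed entries, removing sample loading differences.
#'
#' @param m numeric matrix of positive intensities (proteins x samples);
#'   missing values allowed.
#' @return numeric matrix on the centered log2 scale.
#' @examples
#' log_center(matrix(c(2, 8), 2, 1))  # -1, 1
#' @export
log_center <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (any(m <= 0, na.rm = TRUE)) {
    stop("intensities must be positive before log transform", call. = FALSE)
  }
  lg <- log2(m)
  sweep(lg, 2, colMeans(lg, na.rm = TRUE), "-")
}

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG stream afterwards so library calls do not perturb analyses.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Impute missing intensities from a downshifted normal distribution
#'
#' Missing values in label-free single-tubule proteomics are dominated by
#' low-abundance dropout, so each missing cell of sample \eqn{s} is drawn
#' from \eqn{N(\mu_s - \mathrm{shift}\cdot\sigma_s,
#' (\mathrm{width}\cdot\sigma_s)^2)}, where \eqn{\mu_s} and \eqn{\sigma_s}
#' are the mean and standard deviation of the observed log2 values of that
#' sample. Defaults `shift = 1.8`, `width = 0.3` are the convention widely
#' used for left-censored proteomics imputation.
#'
#' @param m numeric matrix on the log2 (typically centered) scale.
#' @param width imputation width as a fraction of the per-sample sd.
#' @param shift downshift in per-sample sd units.
#' @param seed optional integer; a fixed seed makes imputation
#'   deterministic without disturbing the caller's RNG stream.
#' @return matrix with missing cells filled in.
#' @examples
#' m <- log_center(matrix(c(2, 4, 8, NA, 4, 16), 3, 2))
#' impute_downshift(m, seed = 7)
#' @export
impute_downshift <- function(m, width = 0.3, shift = 1.8, seed = NULL) {
  stopifnot(is.matrix(m), is.numeric(m))
  .check_positive(width, "width")
  .check_finite(shift, "shift")
  if (!anyNA(m)) return(m)
  .with_seed(seed, {
    for (j in seq_len(ncol(m))) {
      miss <- is.na(m[, j])
      if (!any(miss)) next
      obs <- m[!miss, j]
      if (length(obs) < 3) {
        stop(sprintf("sample %d has fewer than 3 observed values; cannot impute",
                     j), call. = FALSE)
      }
      mu <- mean(obs)
      sd_s <- stats::sd(obs)
      m[miss, j] <- stats::rnorm(sum(miss), mu - shift * sd_s, width * sd_s)
    }
    m
  })
}

# Vectorised two-sample t statistics over matrix rows (equal-variance or
# Welch). Returns t, df, p. Cross-checked against stats::t.test in the tests.
.row_t <- function(x1, x2, var_equal = TRUE) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tt <- (m2 - m1) / se
  p <- 2 * stats::pt(-abs(tt), df)
  list(t = tt, df = df, p = p, diff = m2 - m1)
}

#' Two-group differential analysis of a log2 intensity matrix
#'
#' Per-protein two-tailed two-sample t-test on log2 intensities between a
#' reference group (e.g. wild-type) and a comparison group (e.g. knockout).
#' `log2fc` is the comparison-minus-reference mean difference. Proteins with
#' zero variance in both groups have an undefined test and are flagged
#' `degenerate` with `NA` p-value. Benjamini-Hochberg q-values are added,
#' and `hit_flag` marks proteins passing both the fold-change and p-value
#' cutoffs.
#'
#' @param m numeric matrix of log2 intensities (proteins x samples), complete
#'   (impute first, e.g. with [impute_downshift()]).
#' @param groups character/factor vector of length `ncol(m)` with exactly two
#'   levels.
#' @param ref label of the reference group (default `"WT"`; must occur in
#'   `groups`).
#' @param fc_cut absolute log2 fold-change cutoff for `hit_flag`. Default 1.
#' @param p_cut p-value cutoff for `hit_flag`. Default 0.05.
#' @param var_equal use the pooled-variance Student test (default) or the
#'   Welch test (`FALSE`).
#' @return data.frame with columns `protein_id`, `log2fc`, `t_stat`,
#'   `p_value`, `q_value`, `hit_flag`, `degenerate`.
#' @examples
#' m <- matrix(rnorm(200), 20, 10,
#'             dimnames = list(paste0("P", 1:20), paste0("S", 1:10)))
#' res <- differential(m, rep(c("WT", "KO"), each = 5))
#' @export
differential <- function(m, groups, ref = "WT", fc_cut = 1, p_cut = 0.05,
                         var_equal = TRUE) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (anyNA(m)) stop("matrix contains missing values; impute first", call. = FALSE)
  groups <- as.character(groups)
  if (length(groups) != ncol(m)) {
    stop("`groups` must have one label per sample column", call. = FALSE)
  }
  lv <- unique(groups)
  if (length(lv) != 2 || !(ref %in% lv)) {
    stop("`groups` must contain exactly two levels including `ref`", call. = FALSE)
  }
  other <- setdiff(lv, ref)
  i1 <- which(groups == ref); i2 <- which(groups == other)
  if (length(i1) < 2 || length(i2) < 2) {
    stop("need at least 2 samples per group", call. = FALSE)
  }
  st <- .row_t(m[, i1, drop = FALSE], m[, i2, drop = FALSE], var_equal)
  degenerate <- !is.finite(st$t) & st$diff == 0 | is.nan(st$p)
  p <- st$p
  p[degenerate] <- NA_real_
  q <- stats::p.adjust(p, method = "BH")
  hit <- !is.na(p) & p < p_cut & abs(st$diff) >= fc_cut
  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(m)))
  data.frame(
    protein_id = ids,
    log2fc = st$diff,
    t_stat = st$t,
    p_value = p,
    q_value = q,
    hit_flag = hit,
    degenerate = degenerate,
    row.names = NULL
  )
}

#' In-silico tryptic digestion
#'
#' Cleaves a protein sequence C-terminally to K or R except when the next
#' residue is P, with zero missed cleavages, returning the fully cleaved
#' peptides. The 20 standard amino acids plus U (selenocysteine) and X
#' (unknown) are tolerated.
#'
#' @param sequence amino-acid string.
#' @return character vector of peptides, concatenating back to `sequence`.
#' @examples
#' tryptic_digest("AAAAKRPPPPK")  # "AAAAK", "RPPPPK"
#' @export
tryptic_digest <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1 || nchar(sequence) == 0) {
    stop("`sequence` must be a single nonempty string", call. = FALSE)
  }
  sequence <- toupper(sequence)
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYUX]", sequence)) {
    stop("sequence contains characters outside the amino-acid alphabet",
         call. = FALSE)
  }
  # insert a break after every K/R not followed by P
  marked <- gsub("(?<=[KR])(?!P)", "\n", sequence, perl = TRUE)
  peps <- strsplit(marked, "\n", fixed = TRUE)[[1]]
  peps[nchar(peps) > 0]
}

#' Count theoretically observable tryptic peptides
#'
#' The iBAQ denominator: the number of fully cleaved tryptic peptides (see
#' [tryptic_digest()]) whose length falls in `[min_len, max_len]` residues.
#'
#' @param sequence amino-acid string.
#' @param min_len,max_len inclusive peptide-length bounds; defaults 6 and 30.
#' @return integer count (possibly 0).
#' @examples
#' observable_peptides("AAAAKRPPPPK")  # 1
#' @export
observable_peptides <- function(sequence, min_len = 6, max_len = 30) {
  peps <- tryptic_digest(sequence)
  len <- nchar(peps)
  sum(len >= min_len & len <= max_len)
}

#' Intensity-based absolute quantification (iBAQ)
#'
#' Summed protein intensity divided by the number of theoretically
#' observable tryptic peptides, a copy-number surrogate that makes
#' abundances comparable across proteins of different size.
#'
#' @param summed_intensity numeric vector of summed protein intensities.
#' @param observable_count integer vector of observable-peptide counts; a
#'   count of zero yields a missing value (`NA`), not an error.
#' @return numeric vector of iBAQ values.
#' @examples
#' ibaq(1000, 10)  # 100
#' ibaq(1000, 0)   # NA
#' @export
ibaq <- function(summed_intensity, observable_count) {
  .check_finite(summed_intensity[!is.na(summed_intensity)], "summed_intensity")
  if (any(observable_count < 0, na.rm = TRUE)) {
    stop("`observable_count` must be >= 0", call. = FALSE)
  }
  out <- summed_intensity / observable_count
  out[!is.na(observable_count) & observable_count == 0] <- NA_real_
  out
}

#' iBAQ table for an intensity vector and protein sequences
#'
#' Convenience wrapper joining summed intensities with in-silico digestion
#' counts.
#'
#' @param intensities named numeric vector of summed protein intensities.
#' @param sequences named character vector of protein sequences (names must
#'   cover the intensity names), e.g. from [read_protein_fasta()].
#' @param min_len,max_len observable peptide length bounds.
#' @return data.frame with `protein_id`, `summed_intensity`,
#'   `observable_count`, `ibaq`.
#' @export
ibaq_table <- function(intensities, sequences, min_len = 6, max_len = 30) {
  stopifnot(!is.null(names(intensities)))
  miss <- setdiff(names(intensities), names(sequences))
  if (length(miss) > 0) {
    stop("no sequence for proteins: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  counts <- vapply(names(intensities), function(p) {
    observable_peptides(sequences[[p]], min_len, max_len)
  }, integer(1))
  data.frame(
    protein_id = names(intensities),
    summed_intensity = as.numeric(intensities),
    observable_count = counts,
    ibaq = ibaq(as.numeric(intensities), counts),
    row.names = NULL
  )
}
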