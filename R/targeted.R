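# Targeted (parallel reaction monitoring) quantification: transition-quality
# filtering, MS2-level summation to protein intensities, and log2
# double-centering normalisation.

.TRANSITION_COLS <- c("peptide_id", "protein_id", "fragment_id", "apex_rt",
                      "rt_window_start", "rt_window_end", "mass_error_ppm",
                      "area", "sample_id")

.check_transitions <- function(peaks) {
  stopifnot(is.data.frame(peaks))
  miss <- setdiff(.TRANSITION_COLS, names(peaks))
  if (length(miss) > 0) {
    stop("transition table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(peaks$area < 0, na.rm = TRUE)) {
    stop("transition areas must be >= 0", call. = FALSE)
  }
  if (any(peaks$rt_window_start >= peaks$rt_window_end)) {
    stop("rt_window_start must precede rt_window_end", call. = FALSE)
  }
  invisible(peaks)
}

#' Quality-filter PRM transitions
#'
#' Applies the three transition-level quality requirements for targeted
#' MS2 quantification: (1) mass accuracy, strict `|mass_error_ppm| <
#' ppm_max`; (2) elution inside the scheduled acquisition window; and
#' (3) coelution of the transitions of a peptide within a sample. Coelution
#' is enforced per (peptide, sample) group on the transitions surviving the
#' first two filters by iteratively discarding the transition whose apex is
#' farthest from the group's median apex until the maximum pairwise apex
#' spread is at most `coelution_tol` (ties broken by input order). Groups
#' left with fewer than two transitions are dropped entirely, since
#' coelution is undefined for a singleton.
#'
#' Each rejected transition carries exactly one primary reason code with
#' precedence `ppm` > `window` > `coelution` > `singleton`.
#'
#' @param peaks data.frame of transition peaks with columns `peptide_id`,
#'   `protein_id`, `fragment_id`, `apex_rt`, `rt_window_start`,
#'   `rt_window_end`, `mass_error_ppm`, `area`, `sample_id`.
#' @param ppm_max mass-error bound (ppm, strict inequality). Default 10.
#' @param coelution_tol maximum allowed apex retention-time spread within a
#'   (peptide, sample) group (minutes). Default 0.2.
#' @return list with elements `kept` (data.frame of surviving transitions)
#'   and `rejected` (data.frame with an additional `reason` column, one of
#'   `"ppm"`, `"window"`, `"coelution"`, `"singleton"`).
#' @examples
#' prm <- generate_prm_fixture(plan = prm_plan(), seed = 1)
#' f <- filter_transitions(prm)
#' table(f$rejected$reason)
#' @export
filter_transitions <- function(peaks, ppm_max = 10, coelution_tol = 0.2) {
  .check_positive(ppm_max, "ppm_max")
  .check_positive(coelution_tol, "coelution_tol")
  if (nrow(peaks) == 0) {
    empty <- peaks
    empty$reason <- character(0)
    return(list(kept = peaks, rejected = empty))
  }
  .check_transitions(peaks)

  reason <- rep(NA_character_, nrow(peaks))
  reason[abs(peaks$mass_error_ppm) >= ppm_max] <- "ppm"
  in_window <- peaks$apex_rt >= peaks$rt_window_start &
    peaks$apex_rt <= peaks$rt_window_end
  reason[is.na(reason) & !in_window] <- "window"

  grp <- interaction(peaks$peptide_id, peaks$sample_id, drop = TRUE)
  for (g in levels(grp)) {
    idx <- which(grp == g & is.na(reason))
    # median-anchored iterative trimming to the coelution tolerance
    while (length(idx) >= 2) {
      apex <- peaks$apex_rt[idx]
      if (diff(range(apex)) <= coelution_tol) break
      med <- stats::median(apex)
      drop_i <- which.max(abs(apex - med))
      reason[idx[drop_i]] <- "coelution"
      idx <- idx[-drop_i]
    }
    if (length(idx) == 1) reason[idx] <- "singleton"
  }

  kept <- peaks[is.na(reason), , drop = FALSE]
  rejected <- peaks[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  rownames(kept) <- NULL
  rownames(rejected) <- NULL
  list(kept = kept, rejected = rejected)
}

#' Construct a quantification matrix container
#'
#' Lightweight container for a protein-by-sample intensity grid with a scale
#' tag (`"raw"`, `"log2"`, or `"centered"`) and a provenance record of how
#' many transitions were kept or rejected upstream.
#'
#' @param values numeric matrix, proteins in rows, samples in columns.
#' @param scale one of `"raw"`, `"log2"`, `"centered"`.
#' @param provenance optional named list or table of filter summary counts.
#' @return An object of class `quant_matrix`.
#' @export
quant_matrix <- function(values, scale = c("raw", "log2", "centered"),
                         provenance = NULL) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(values), is.numeric(values))
  structure(list(values = values, scale = scale, provenance = provenance),
            class = "quant_matrix")
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat(sprintf("<quant_matrix> %d proteins x %d samples, scale = %s, %.1f%% missing\n",
              nrow(x$values), ncol(x$values), x$scale,
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Quantify filtered PRM transitions at MS2 level
#'
#' Peptide intensity is the sum of its transition areas per sample; protein
#' intensity is the sum of its peptide intensities per sample. Cells with no
#' surviving transitions are missing (`NA`), never zero: absence of evidence
#' is not evidence of zero abundance.
#'
#' @param kept data.frame of transitions that passed [filter_transitions()].
#' @param provenance optional filter-summary record stored with the result.
#' @return A [quant_matrix()] with `scale = "raw"`.
#' @examples
#' prm <- generate_prm_fixture(plan = prm_plan(), seed = 1)
#' qm <- quantify(filter_transitions(prm)$kept)
#' @export
quantify <- function(kept, provenance = NULL) {
  .check_transitions(kept)
  samples <- unique(kept$sample_id)
  proteins <- unique(kept$protein_id)
  vals <- matrix(NA_real_, nrow = length(proteins), ncol = length(samples),
                 dimnames = list(proteins, samples))
  if (nrow(kept) > 0) {
    agg <- stats::aggregate(area ~ protein_id + sample_id, data = kept, FUN = sum)
    vals[cbind(match(agg$protein_id, proteins),
               match(agg$sample_id, samples))] <- agg$area
  }
  quant_matrix(vals, scale = "raw", provenance = provenance)
}

#' Log2 double-centering normalisation
#'
#' Log2-transforms a raw intensity grid and subtracts first each sample
#' (column) mean and then each protein (row) mean, means taken over observed
#' entries. For a complete matrix one pass of each leaves every row and
#' column mean at zero; sample-wise scale factors (loading differences)
#' and protein-wise offsets (ionisation efficiency) are both removed, so the
#' result expresses relative regulation across tubules.
#'
#' @param m a [quant_matrix()] with `scale = "raw"`, or a bare numeric
#'   matrix of positive raw intensities (missing allowed).
#' @return A [quant_matrix()] with `scale = "centered"`.
#' @examples
#' m <- matrix(c(4, 8, 16, 32), 2, byrow = TRUE)
#' double_center(m)$values   # all zero
#' @export
double_center <- function(m) {
  vals <- if (inherits(m, "quant_matrix")) m$values else m
  prov <- if (inherits(m, "quant_matrix")) m$provenance else NULL
  stopifnot(is.matrix(vals), is.numeric(vals))
  if (any(vals <= 0, na.rm = TRUE)) {
    stop("raw intensities must be positive before log transform", call. = FALSE)
  }
  lg <- log2(vals)
  lg <- sweep(lg, 2, colMeans(lg, na.rm = TRUE), "-")
  lg <- sweep(lg, 1, rowMeans(lg, na.rm = TRUE), "-")
  quant_matrix(lg, scale = "centered", provenance = prov)
}
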