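# Tab-separated and FASTA input/output. All tables are TSV, UTF-8, one
# header row; missing values are empty fields.

#' Read a tab-separated table
#'
#' @param path file path.
#' @return data.frame (strings kept as character, empty fields as `NA`).
#' @export
read_tsv_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, sep = "\t", header = TRUE, na.strings = "",
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write a tab-separated table
#'
#' @param x data.frame.
#' @param path file path.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a protein-by-sample intensity matrix from TSV
#'
#' First column is the protein identifier; remaining columns are samples.
#'
#' @param path file path.
#' @return numeric matrix with protein rownames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv_table(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write a protein-by-sample matrix to TSV
#'
#' @param m matrix with rownames.
#' @param path file path.
#' @param id_col header of the identifier column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "protein_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv_table(df, path)
}

#' Read a perfusion-recording table
#'
#' One row per tubule with the columns used by [derive_phenotypes()].
#'
#' @param path file path.
#' @return data.frame of recordings.
#' @export
read_recordings <- function(path) {
  df <- read_tsv_table(path)
  need <- c("tubule_id", "L", "I0", "dV0", "dVL", "Vte_basal", "Vte_amil",
            "Vdp")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("recording table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Read a marker map (protein to cell class)
#'
#' @param path TSV with columns `protein_id` and `cell_class`.
#' @return data.frame.
#' @export
read_marker_map <- function(path) {
  df <- read_tsv_table(path)
  if (!all(c("protein_id", "cell_class") %in% names(df))) {
    stop("marker map needs columns protein_id and cell_class", call. = FALSE)
  }
  if (anyDuplicated(df$protein_id)) {
    stop("each protein must map to exactly one cell class", call. = FALSE)
  }
  df
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file of amino-acid sequences.
#' @return named character vector of sequences.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
}
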