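#' Abundance matrix constructor
#'
#' A validated features x samples quantitative table. Values are
#' non-negative absolute amounts (SIL-quantified SRM data) or arbitrary
#' intensities; cells that were not quantified are \code{NA}, never 0.
#'
#' @param values numeric matrix, features in rows, samples in columns;
#'   \code{NA} marks missing cells.
#' @param level \code{"protein"} or \code{"peptide"}.
#' @param feature_to_protein named character vector mapping every
#'   peptide id to its protein accession; required when
#'   \code{level = "peptide"}.
#' @return an object of class \code{abundance_matrix}: the numeric
#'   matrix with attributes \code{level} and \code{feature_to_protein}.
#' @export
abundance_matrix <- function(values, level = c("protein", "peptide"),
                             feature_to_protein = NULL) {
  level <- match.arg(level)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry feature (row) and sample (column) names")
  dup_f <- rownames(values)[duplicated(rownames(values))]
  if (length(dup_f))
    stop("duplicate feature ids: ", paste(unique(dup_f), collapse = ", "))
  dup_s <- colnames(values)[duplicated(colnames(values))]
  if (length(dup_s))
    stop("duplicate sample ids: ", paste(unique(dup_s), collapse = ", "))
  neg <- which(!is.na(values) & values < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop("negative value at feature '", rownames(values)[neg[1, 1]],
         "', sample '", colnames(values)[neg[1, 2]], "'")
  if (level == "peptide") {
    if (is.null(feature_to_protein) || length(feature_to_protein) == 0L)
      stop("peptide-level matrix requires a feature_to_protein mapping")
    unmapped <- setdiff(rownames(values), names(feature_to_protein))
    if (length(unmapped))
      stop("peptides without protein mapping: ",
           paste(head(unmapped, 5L), collapse = ", "))
  }
  structure(values, level = level,
            feature_to_protein = feature_to_protein,
            class = c("abundance_matrix", "matrix", "array"))
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d %s(s) x %d sample(s), %.1f%% missing\n",
              nrow(x), attr(x, "level"), ncol(x),
              100 * mean(is.na(x))))
  invisible(x)
}

feature_ids <- function(m) rownames(m)
sample_ids  <- function(m) colnames(m)

#' Read an abundance matrix from a tab-separated file
#'
#' First column holds feature ids, header row holds sample ids; an
#' empty cell or the token \code{NA} denotes a missing (unquantified)
#' value. Missing cells are preserved as missing, never as zero.
#'
#' @param path file path.
#' @inheritParams abundance_matrix
#' @return an \code{\link{abundance_matrix}}.
#' @export
load_abundance_matrix <- function(path, level = c("protein", "peptide"),
                                  feature_to_protein = NULL) {
  level <- match.arg(level)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   na.strings = c("", "NA"), stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("abundance file needs >= 1 sample column")
  ids <- as.character(df[[1L]])
  hdr <- colnames(df)[-1L]
  dup_s <- hdr[duplicated(hdr)]
  if (length(dup_s))
    stop("duplicate sample ids in header: ",
         paste(unique(dup_s), collapse = ", "))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  abundance_matrix(vals, level = level,
                   feature_to_protein = feature_to_protein)
}

#' Write an abundance matrix to a tab-separated file
#'
#' Inverse of \code{\link{load_abundance_matrix}}: missing cells are
#' written as the token \code{NA}.
#'
#' @param m an \code{abundance_matrix}.
#' @param path output file path.
#' @param id_column header name of the feature-id column.
#' @return \code{path}, invisibly.
#' @export
write_abundance_matrix <- function(m, path, id_column = "feature_id") {
  df <- data.frame(rownames(m), unclass(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_column, colnames(m))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Censor values below a signal-intensity quantification limit
#'
#' Values below the limit are unreliable for quantification and are set
#' to missing; values at or above the limit are unchanged. The same
#' mechanism models detection-limit (missing-not-at-random) censoring.
#'
#' @param m an \code{abundance_matrix}.
#' @param limit non-negative threshold; present values strictly below
#'   it become missing.
#' @return the censored matrix, with attribute \code{n_censored}
#'   giving the count of newly censored cells.
#' @export
apply_quantification_limit <- function(m, limit) {
  stopifnot(is.numeric(limit), length(limit) == 1L, limit >= 0)
  idx <- !is.na(m) & m < limit
  m[idx] <- NA_real_
  attr(m, "n_censored") <- sum(idx)
  m
}

#' Roll peptide-level quantities up to protein level
#'
#' Per protein and sample, the value is the mean of the present peptide
#' values; the protein is missing in a sample only when all of its
#' peptides are missing there.
#'
#' @param m a peptide-level \code{abundance_matrix} with a complete
#'   \code{feature_to_protein} mapping.
#' @return a protein-level \code{abundance_matrix}.
#' @export
collapse_peptides_to_proteins <- function(m) {
  if (!identical(attr(m, "level"), "peptide"))
    stop("matrix is not peptide-level")
  map <- attr(m, "feature_to_protein")
  if (is.null(map) || length(map) == 0L)
    stop("empty peptide-to-protein mapping")
  prot <- map[rownames(m)]
  prots <- unique(unname(prot))
  out <- matrix(NA_real_, nrow = length(prots), ncol = ncol(m),
                dimnames = list(prots, colnames(m)))
  for (p in prots) {
    rows <- m[prot == p, , drop = FALSE]
    out[p, ] <- colMeans(rows, na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  abundance_matrix(out, level = "protein")
}
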