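GROUP_LEVELS <- c("HC1", "HC2", "StageI", "StageII", "StageIII", "StageIV")
HC_GROUPS <- c("HC1", "HC2")

#' Validate a per-sample clinical annotation table
#'
#' Columns: \code{sample_id}, \code{cohort} (cohort1/cohort2),
#' \code{group} (HC1, HC2, StageI..StageIV), \code{age}, \code{sex}
#' (M/F), \code{os_time} (days), \code{os_event} (0 censored, 1 death),
#' \code{curative_resection} (yes/no, optional), \code{eligible}
#' (logical). Healthy-control rows never carry survival fields.
#'
#' @param ann a data.frame with the columns above.
#' @return the validated data.frame, class \code{sample_annotation}.
#' @export
sample_annotation <- function(ann) {
  req <- c("sample_id", "cohort", "group")
  miss <- setdiff(req, colnames(ann))
  if (length(miss))
    stop("annotation lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(ann$sample_id))
    stop("duplicate sample ids in annotation")
  bad <- setdiff(unique(ann$group), GROUP_LEVELS)
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  if (!all(ann$cohort %in% c("cohort1", "cohort2")))
    stop("cohort must be 'cohort1' or 'cohort2'")
  for (col in c("age", "os_time", "os_event", "curative_resection",
                "sex", "eligible"))
    if (!col %in% colnames(ann)) ann[[col]] <- NA
  if (!all(is.na(ann$sex) | ann$sex %in% c("M", "F")))
    stop("sex must be M or F")
  surv_rows <- !is.na(ann$os_time)
  if (any(ann$os_time[surv_rows] < 0)) stop("os_time must be >= 0")
  ev <- ann$os_event[!is.na(ann$os_event)]
  if (!all(ev %in% c(0, 1))) stop("os_event must be 0 or 1")
  hc <- ann$group %in% HC_GROUPS
  if (any(hc & (!is.na(ann$os_time) | !is.na(ann$os_event))))
    stop("healthy-control samples must not carry survival fields")
  ann$eligible <- ifelse(is.na(ann$eligible), TRUE, as.logical(ann$eligible))
  class(ann) <- c("sample_annotation", "data.frame")
  ann
}

#' Read a sample annotation table from TSV
#' @param path file path.
#' @return a validated \code{\link{sample_annotation}}.
#' @export
load_annotation <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   na.strings = c("", "NA"), stringsAsFactors = FALSE)
  df$sample_id <- as.character(df$sample_id)
  for (col in c("age", "os_time"))
    if (col %in% colnames(df)) df[[col]] <- as.numeric(df[[col]])
  if ("os_event" %in% colnames(df))
    df$os_event <- as.integer(df$os_event)
  if ("eligible" %in% colnames(df) && !is.logical(df$eligible))
    df$eligible <- df$eligible %in% c("TRUE", "yes", "1", TRUE, 1)
  sample_annotation(df)
}

#' Write a sample annotation table to TSV
#' @param ann a \code{sample_annotation}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_annotation <- function(ann, path) {
  write.table(as.data.frame(ann), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

# align annotation rows to a matrix's sample columns; error on mismatch
align_annotation <- function(m, ann) {
  idx <- match(colnames(m), ann$sample_id)
  if (anyNA(idx))
    stop("samples absent from annotation: ",
         paste(head(colnames(m)[is.na(idx)], 5L), collapse = ", "))
  ann[idx, , drop = FALSE]
}
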