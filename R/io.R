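#' Read a recording from EDF or a plain numeric matrix file
#'
#' `format = "edf"` reads 16-bit EDF with per-channel scaling honored.
#' `format = "matrix"` reads a delimited channels-by-samples numeric matrix
#' (whitespace/tab separated, optionally gzip-compressed) and requires a JSON
#' sidecar `<path>.json` with at least `labels` and `fs`. `format = "auto"`
#' picks by file extension.
#'
#' @param path input file.
#' @param format `"auto"`, `"edf"` or `"matrix"`.
#' @param group optional group label attached to the recording.
#' @return an [recording()].
#' @export
read_recording <- function(path, format = c("auto", "edf", "matrix"),
                           group = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "matrix"
  }
  if (format == "edf") return(read_edf(path, group = group))
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop_invalid("matrix format needs a JSON sidecar with labels and fs: ",
                 sidecar)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$labels) || is.null(meta$fs)) {
    stop_invalid("sidecar must provide 'labels' and 'fs'")
  }
  data <- as.matrix(utils::read.table(path, header = FALSE))
  if (any(!is.finite(data))) stop_invalid("matrix file contains non-finite samples")
  if (nrow(data) != length(meta$labels)) {
    stop_invalid(sprintf("matrix has %d rows but sidecar lists %d labels",
                         nrow(data), length(meta$labels)))
  }
  grp <- if (!is.na(group)) group else if (!is.null(meta$group)) meta$group else NA_character_
  recording(data, meta$fs, meta$labels, group = grp)
}

#' Write a recording to EDF or a matrix file with a JSON sidecar
#'
#' @param rec an [recording()].
#' @param path output file; `"matrix"` format also writes `<path>.json`.
#' @param format `"edf"` or `"matrix"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("edf", "matrix")) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "eeg_recording"))
  if (format == "edf") return(invisible(write_edf(rec, path)))
  utils::write.table(format(rec$data, digits = 10, trim = TRUE,
                            scientific = FALSE),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE, sep = "\t")
  jsonlite::write_json(list(labels = rec$labels, fs = rec$fs,
                            group = rec$group),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a synthetic cohort to disk with its ground-truth sidecar
#'
#' One file per subject (EDF or matrix+sidecar) plus `ground_truth.json`
#' recording the generating parameters per subject and channel.
#'
#' @param recs list of recordings from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @param format `"edf"` or `"matrix"`.
#' @return the directory, invisibly.
#' @export
write_cohort <- function(recs, dir, format = c("edf", "matrix")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- list()
  for (rec in recs) {
    id <- attr(rec, "subject")
    ext <- if (format == "edf") ".edf" else ".tsv"
    write_recording(rec, file.path(dir, paste0(id, ext)), format)
    gt <- attr(rec, "ground_truth")
    truth[[id]] <- c(list(group = rec$group), as.list(gt))
  }
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
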