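#' Multichannel EEG recording container
#'
#' A lightweight S3 container for a channels-by-samples matrix with its
#' sampling rate, 10-20 channel labels, unit-sphere electrode positions and a
#' group label. Positions are looked up from the bundled 10-20 montage table
#' when not supplied, and are renormalized to unit radius.
#'
#' @param data numeric matrix, channels x samples; no NaN/Inf allowed.
#' @param fs sampling rate in Hz.
#' @param labels character vector of unique channel labels (rows of `data`).
#' @param positions optional numeric matrix (channels x 3) of electrode
#'   positions; defaults to the bundled 10-20 unit-sphere montage for known
#'   labels (NA rows for labels absent from the montage).
#' @param group group label (e.g. `"HC"`/`"SZ"` or a synthetic group id).
#' @return An object of class `eeg_recording` with elements `data`, `fs`,
#'   `labels`, `positions`, `group`.
#' @examples
#' rec <- recording(matrix(rnorm(4 * 500), 4), fs = 250,
#'                  labels = c("C3", "C4", "O1", "O2"))
#' rec
#' @export
recording <- function(data, fs, labels, positions = NULL, group = NA_character_) {
  data <- as.matrix(data)
  check_scalar_number(fs, "fs", positive = TRUE)
  if (!is.numeric(data) || any(!is.finite(data))) {
    stop_invalid("recording data must be a numeric matrix without NaN/Inf")
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(data)) {
    stop_invalid("number of labels must equal the number of channels (rows)")
  }
  if (anyDuplicated(labels)) {
    stop_invalid("channel labels must be unique")
  }
  if (is.null(positions)) {
    positions <- montage_positions(labels, strict = FALSE)
  } else {
    positions <- as.matrix(positions)
    if (nrow(positions) != length(labels) || ncol(positions) != 3L) {
      stop_invalid("positions must be a channels x 3 matrix")
    }
    r <- sqrt(rowSums(positions^2))
    ok <- is.finite(r) & r > 0
    positions[ok, ] <- positions[ok, , drop = FALSE] / r[ok]
  }
  rownames(data) <- labels
  rownames(positions) <- labels
  structure(
    list(data = data, fs = fs, labels = labels,
         positions = positions, group = group),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat("  channels:", paste(x$labels, collapse = " "), "\n")
  if (!is.na(x$group)) cat("  group:", x$group, "\n")
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

#' Bundled 10-20 montage (unit-sphere electrode coordinates)
#'
#' Returns the packaged table of idealized unit-sphere coordinates for the 19
#' electrodes of the international 10-20 montage (x toward the right ear,
#' y anterior, z toward the vertex).
#'
#' @return data.frame with columns `label`, `x`, `y`, `z`.
#' @export
montage_1020 <- function() {
  path <- system.file("extdata", "montage_1020.csv", package = "fractalEEG",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# Look up unit-sphere positions for labels; strict = TRUE errors on unknown
# labels, otherwise unknown labels get NA rows.
montage_positions <- function(labels, strict = TRUE) {
  tab <- montage_1020()
  idx <- match(labels, tab$label)
  if (strict && anyNA(idx)) {
    stop_invalid("channel label(s) absent from the 10-20 montage table: ",
                 paste(labels[is.na(idx)], collapse = ", "))
  }
  pos <- as.matrix(tab[idx, c("x", "y", "z")])
  rownames(pos) <- labels
  pos
}

#' The 19 standard 10-20 channel labels
#'
#' @return character vector of the 19 labels in montage-table order.
#' @export
channels_1020 <- function() montage_1020()$label
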