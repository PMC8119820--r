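#' Resting-state-network map for the 19-channel 10-20 montage
#'
#' Reads a channel-to-network partition from CSV (columns `label`,
#' `network`). The bundled default partitions the 19 montage channels into
#' five networks: visual (VN: O1, O2, T5, T6), somatomotor (SM: C3, C4, Cz),
#' dorsal attention (DA: P3, P4, Pz), combined ventral attention and limbic
#' (VAL: F7, F8, T3, T4) and a joint frontal network (FR: F3, F4, Fp1, Fp2,
#' Fz). The map is data, not code, so alternative parcellations are
#' pluggable.
#'
#' @param path CSV path; default is the bundled map.
#' @return data.frame with columns `label`, `network`.
#' @export
rsn_map <- function(path = system.file("extdata", "rsn_map.csv",
                                       package = "fractalEEG",
                                       mustWork = TRUE)) {
  map <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("label", "network") %in% names(map))) {
    stop_invalid("RSN map must have columns 'label' and 'network'")
  }
  if (anyDuplicated(map$label)) {
    stop_invalid("RSN map assigns a channel to more than one network")
  }
  map
}

#' Average per-channel values over resting-state networks
#'
#' Collapses a per-channel table onto networks by the arithmetic mean over
#' the channels belonging to each network, separately within every
#' combination of the remaining key columns (e.g. subject, band, component).
#'
#' @param values data.frame with a `channel` column, a `value` column and any
#'   number of additional key columns.
#' @param map an [rsn_map()] data.frame.
#' @return data.frame like `values` with `channel` replaced by `network`.
#' @export
aggregate_rsn <- function(values, map = rsn_map()) {
  if (!all(c("channel", "value") %in% names(values))) {
    stop_invalid("values must have columns 'channel' and 'value'")
  }
  unknown <- setdiff(unique(values$channel), map$label)
  if (length(unknown)) {
    stop_invalid("channel label(s) not in the RSN map: ",
                 paste(unknown, collapse = ", "))
  }
  missing <- setdiff(map$label, unique(values$channel))
  if (length(missing)) {
    stop_invalid("mapped channel(s) missing from the input: ",
                 paste(missing, collapse = ", "))
  }
  keys <- setdiff(names(values), c("channel", "value"))
  values$network <- map$network[match(values$channel, map$label)]
  agg <- stats::aggregate(
    values["value"],
    by = values[c(keys, "network")],
    FUN = mean
  )
  agg[, c(keys, "network", "value")]
}
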