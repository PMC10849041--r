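#' Read a puncta table from CSV
#'
#' Expected columns: `channel` (M1, S1, or VGLUT1), `x_um`, `y_um`, `z_um`,
#' `diameter_um`; header required, '.' decimal.
#'
#' @param path CSV path.
#' @param min_diameter minimum detection diameter, µm (rows below are an
#'   error, matching the detection convention).
#' @return data.frame.
#' @export
read_puncta <- function(path, min_diameter = 1) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("channel", "x_um", "y_um", "z_um", "diameter_um")
  if (!all(req %in% names(p)))
    stop("puncta CSV must have columns: ", paste(req, collapse = ", "))
  bad <- setdiff(unique(p$channel), c("M1", "S1", "VGLUT1"))
  if (length(bad))
    stop("unknown channel(s): ", paste(bad, collapse = ", "))
  if (any(p$diameter_um < min_diameter))
    stop("puncta below the minimum detection diameter (", min_diameter, " um)")
  p[, req]
}

#' Write a puncta table to CSV
#' @param puncta data.frame with the standard puncta columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_puncta <- function(puncta, path) {
  utils::write.csv(puncta, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a sweep set as tidy CSV plus sidecar metadata
#'
#' @param sweeps list of `sweep_recording`.
#' @param path CSV path for the long table (`sweep`, `time_ms`, `voltage_mV`).
#' @param meta_path CSV path for the metadata (`sweep`, `current_pA`,
#'   `onset_ms`, `offset_ms`).
#' @return `path`, invisibly.
#' @export
write_sweeps <- function(sweeps, path, meta_path) {
  long <- do.call(rbind, lapply(seq_along(sweeps), function(i) {
    s <- sweeps[[i]]
    data.frame(sweep = i, time_ms = s$time_ms, voltage_mV = s$voltage_mV)
  }))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  meta <- do.call(rbind, lapply(seq_along(sweeps), function(i) {
    s <- sweeps[[i]]
    data.frame(sweep = i, current_pA = s$current_pA, onset_ms = s$onset_ms,
               offset_ms = s$offset_ms)
  }))
  utils::write.csv(meta, meta_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sweep set written by [write_sweeps()]
#' @param path,meta_path CSV paths.
#' @return list of `sweep_recording`.
#' @export
read_sweeps <- function(path, meta_path) {
  long <- utils::read.csv(path)
  meta <- utils::read.csv(meta_path)
  lapply(meta$sweep, function(i) {
    s <- long[long$sweep == i, ]
    mi <- meta[meta$sweep == i, ]
    sweep_recording(s$time_ms, s$voltage_mV, mi$current_pA, mi$onset_ms,
                    mi$offset_ms)
  })
}

#' Write assigned inputs to TSV
#' @param inputs table from [filter_inputs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(inputs, path) {
  utils::write.table(inputs, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
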