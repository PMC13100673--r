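# Tabular round-tripping of pulse sets, R^2 maps and convergence traces.
# Every file starts with a '#' comment header declaring the model,
# layer, units and config hash, so artifacts are self-describing.

tmsmap_header <- function(...) {
  kv <- list(...)
  paste0("# tmsmap ",
         paste(sprintf("%s=%s", names(kv), unlist(kv)), collapse = " "))
}

write_csv_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write a pulse set (placements + MEPs) to CSV
#'
#' @param placements list of [coil_placement()] objects.
#' @param meps MEP amplitudes per pulse, mV (optional).
#' @param path output CSV path.
#' @param subject_id tag recorded in the header.
#' @param config_hash config hash recorded in the header.
#' @export
write_pulse_set <- function(placements, meps = NULL, path,
                            subject_id = "S01", config_hash = "none") {
  n <- length(placements)
  g <- function(f) t(vapply(placements, f, numeric(3)))
  pos <- g(function(p) p$position)
  xa <- g(function(p) p$x_axis)
  ya <- g(function(p) p$y_axis)
  za <- g(function(p) p$z_axis)
  df <- data.frame(pulse_id = seq_len(n),
                   pos_x = pos[, 1], pos_y = pos[, 2], pos_z = pos[, 3],
                   xaxis_x = xa[, 1], xaxis_y = xa[, 2], xaxis_z = xa[, 3],
                   yaxis_x = ya[, 1], yaxis_y = ya[, 2], yaxis_z = ya[, 3],
                   zaxis_x = za[, 1], zaxis_y = za[, 2], zaxis_z = za[, 3],
                   intensity = vapply(placements, function(p) p$intensity, 0))
  if (!is.null(meps)) df$mep_mv <- meps
  write_csv_with_header(df, path,
                        tmsmap_header(kind = "pulse_set",
                                      subject = subject_id,
                                      units = "mm;mV",
                                      config = config_hash))
}

#' Read a pulse set from CSV
#' @param path CSV written by [write_pulse_set()].
#' @return list with `placements` and `meps` (NULL if absent).
#' @export
read_pulse_set <- function(path) {
  df <- read.csv(path, comment.char = "#")
  placements <- lapply(seq_len(nrow(df)), function(i)
    coil_placement(c(df$pos_x[i], df$pos_y[i], df$pos_z[i]),
                   c(df$xaxis_x[i], df$xaxis_y[i], df$xaxis_z[i]),
                   c(df$yaxis_x[i], df$yaxis_y[i], df$yaxis_z[i]),
                   c(df$zaxis_x[i], df$zaxis_y[i], df$zaxis_z[i]),
                   df$intensity[i]))
  list(placements = placements, meps = df$mep_mv)
}

#' Write an R^2 map to flat CSV
#'
#' One row per element: fitted sigmoid parameters, R^2 and mask flag;
#' model, layer, pulse count and hotspot element go into the header.
#'
#' @param map an `r2_map` from [localize()].
#' @param path output CSV path.
#' @param layer layer tag for the header.
#' @param config_hash config hash for the header.
#' @export
write_r2_map <- function(map, path, layer = "midlayer",
                         config_hash = "none") {
  df <- data.frame(element_id = seq_along(map$r2),
                   y0 = map$fits[, "y0"], a = map$fits[, "a"],
                   r = map$fits[, "r"], x0 = map$fits[, "x0"],
                   r2 = map$r2, masked = as.integer(map$mask))
  write_csv_with_header(df, path,
                        tmsmap_header(kind = "r2_map", model = map$model,
                                      layer = layer,
                                      n_pulses = map$n_pulses,
                                      hotspot = map$hotspot,
                                      units = "mV;V/m",
                                      config = config_hash))
}

#' Write convergence traces to CSV
#' @param traces a `convergence_traces` object from [sequential_maps()].
#' @param path output CSV path.
#' @param config_hash config hash for the header.
#' @export
write_traces <- function(traces, path, config_hash = "none") {
  write_csv_with_header(traces$traces, path,
                        tmsmap_header(kind = "convergence_traces",
                                      model = traces$model,
                                      units = "unitless;mm",
                                      config = config_hash))
}
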