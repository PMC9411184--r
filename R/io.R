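#' Write drive states to a JSON file
#'
#' Records of the form `{label, amplitudes[], phases[]}`, one per state.
#'
#' @param states A [drive_state()] or list of them.
#' @param path Output file.
#' @export
write_drive_states <- function(states, path) {
  if (inherits(states, "drive_state")) states <- list(states)
  recs <- lapply(states, function(s) {
    list(label = s$label, amplitudes = s$amplitudes, phases = s$phases)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read drive states from a JSON file
#'
#' @param path JSON file written by [write_drive_states()].
#' @return List of [drive_state()] objects.
#' @export
read_drive_states <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(recs)), function(i) {
    drive_state(unlist(recs$amplitudes[i]), unlist(recs$phases[i]),
                label = recs$label[i])
  })
}

#' Read a device configuration from JSON
#'
#' Expects an `array` block (`n_elements`, `chamber_diameter_mm`,
#' `element_width_mm`, `frequency_MHz`), an optional `medium` block
#' (`c0`, `rho0`, `mu0`) and an optional `lambda_override_mm`.
#'
#' @param path JSON configuration file.
#' @return An [build_circular_array()] geometry.
#' @export
read_array_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  med <- do.call(medium, as.list(cfg$medium %||% list()))
  lam <- if (!is.null(cfg$lambda_override_mm)) cfg$lambda_override_mm * 1e-3
         else NULL
  build_circular_array(
    n_elements = cfg$array$n_elements,
    chamber_diameter = cfg$array$chamber_diameter_mm * 1e-3,
    element_width = cfg$array$element_width_mm * 1e-3,
    frequency = cfg$array$frequency_MHz * 1e6,
    med = med,
    wavelength = lam
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a trajectory to CSV
#'
#' Long-format columns t, particle_id, x, y (SI units).
#'
#' @param ensemble A [simulate_switched()] result with a recorded
#'   trajectory.
#' @param path Output CSV file.
#' @export
write_trajectory_csv <- function(ensemble, path) {
  utils::write.csv(trajectory_as_data_frame(ensemble), path,
                   row.names = FALSE)
  invisible(path)
}
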