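#' Read and write trial tables as CSV
#'
#' Plain CSV with the documented columns (`trial`, `block`, `condition`,
#' `direction`, `soa`, `iti`, `response`, `rt`, and, when labelled, `label`
#' and `excluded`).
#'
#' @param trials trial table.
#' @param path file path.
#' @return `read_trial_table` returns the trial `data.frame`.
#' @export
write_trial_table <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read and write study designs as JSON
#'
#' @param design a [study_design()].
#' @param path file path.
#' @return `read_design` returns a `study_design`.
#' @export
write_design <- function(design, path) {
  x <- unclass(design)
  x$soa <- as.list(x$soa)          # keep direction names in JSON
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  study_design(n_blocks = x$n_blocks,
               test_per_block_per_direction = x$test_per_block_per_direction,
               control_per_block_per_direction =
                 x$control_per_block_per_direction,
               soa = unlist(x$soa),
               iti_range = x$iti_range,
               epoch_window = x$epoch_window,
               sampling_rate = x$sampling_rate)
}

#' Read and write sensor layouts as JSON
#'
#' @param layout a `sensor_layout`.
#' @param path file path.
#' @return `read_layout` returns a `sensor_layout`.
#' @export
write_layout <- function(layout, path) {
  jsonlite::write_json(list(
    sensor_ids = layout$sensor_ids,
    positions = layout$positions,
    adjacency = layout$adjacency,
    channel_kind = layout$channel_kind,
    site = layout$site
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  layout <- list(sensor_ids = x$sensor_ids,
                 positions = as.matrix(x$positions),
                 adjacency = matrix(as.integer(as.matrix(x$adjacency)),
                                    ncol = 2L),
                 channel_kind = x$channel_kind,
                 site = as.integer(x$site))
  class(layout) <- "sensor_layout"
  validate_layout(layout)
  layout
}
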