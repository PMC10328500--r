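#' Write / read a disc image as CSV channels plus a JSON sidecar
#'
#' Channels are stored as one plain CSV matrix each (no header), with a JSON
#' sidecar recording the pixel size, channel roles, and file names. Plain
#' text keeps images diffable and portable; TIFF export is intentionally
#' not provided.
#'
#' @param image a [disc_image()].
#' @param dir output directory (created if needed).
#' @param name base name for the sidecar and channel files.
#' @return Path of the JSON sidecar.
#' @export
write_disc_image <- function(image, dir, name = "disc") {
  stopifnot(inherits(image, "disc_image"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  for (ch in names(image$channels)) {
    f <- file.path(dir, sprintf("%s_%s.csv", name, ch))
    utils::write.table(image$channels[[ch]], f, sep = ",",
                       row.names = FALSE, col.names = FALSE)
    files[[ch]] <- basename(f)
  }
  sidecar <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(
    list(pixel_size_um = image$pixel_size_um, roles = image$roles,
         channel_files = files),
    sidecar, auto_unbox = TRUE, digits = NA, null = "null")
  sidecar
}

#' @rdname write_disc_image
#' @param sidecar path to a JSON sidecar written by [write_disc_image()].
#' @export
read_disc_image <- function(sidecar) {
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  dir <- dirname(sidecar)
  channels <- lapply(meta$channel_files, function(f)
    as.matrix(utils::read.table(file.path(dir, f), sep = ",")))
  channels <- lapply(channels, function(m) {
    dimnames(m) <- NULL; m
  })
  disc_image(channels, pixel_size_um = meta$pixel_size_um,
             reference = meta$roles$reference,
             signals = meta$roles$signals,
             marker = meta$roles$marker)
}

#' Write a synthetic disc with its ground-truth sidecar
#'
#' Writes the image channels (CSV + JSON as [write_disc_image()]), the
#' per-pixel compartment map and noiseless junction skeleton as CSV, and a
#' truth sidecar JSON (center, posterior axis, true P/A ratio, generator
#' parameters). Downstream tests read truth from the sidecar, never from
#' the images.
#'
#' @param sd a [generate_disc()] result.
#' @param dir output directory.
#' @param name base name.
#' @return Path of the truth sidecar JSON.
#' @export
write_synth_disc <- function(sd, dir, name = "synthdisc") {
  stopifnot(inherits(sd, "synth_disc"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_disc_image(sd$image, dir, name)
  utils::write.table(sd$compartment_map,
                     file.path(dir, paste0(name, "_compartments.csv")),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(sd$truth$junction_mask * 1L,
                     file.path(dir, paste0(name, "_junctions.csv")),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  truth <- file.path(dir, paste0(name, "_truth.json"))
  jsonlite::write_json(
    list(center_px = sd$center_px, posterior_axis = sd$posterior_axis,
         pa_ratio = sd$truth$pa_ratio,
         params = unclass(sd$truth$params),
         image_sidecar = paste0(name, ".json"),
         compartment_file = paste0(name, "_compartments.csv"),
         junction_file = paste0(name, "_junctions.csv")),
    truth, auto_unbox = TRUE, digits = NA)
  truth
}

#' Write / read a heat map as a CSV matrix plus JSON metadata
#'
#' @param map a `junction_heatmap`.
#' @param path output CSV path; metadata goes to `<path>.json` and counts to
#'   `<path stem>_counts.csv`.
#' @return `path`, invisibly.
#' @export
write_heatmap <- function(map, path) {
  stopifnot(inherits(map, "junction_heatmap"))
  utils::write.table(map$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, na = "NaN")
  counts_f <- sub("\\.csv$", "_counts.csv", path)
  utils::write.table(map$counts, counts_f, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(center_index = map$center_index, block_size_um = map$block_size_um,
         normalization = map$normalization, channel = map$channel,
         row_edges = map$row_edges, col_edges = map$col_edges,
         counts_file = basename(counts_f)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_heatmap
#' @export
read_heatmap <- function(path) {
  v <- as.matrix(utils::read.table(path, sep = ",", na.strings = "NaN"))
  dimnames(v) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  counts_f <- file.path(dirname(path), meta$counts_file)
  counts <- as.matrix(utils::read.table(counts_f, sep = ","))
  dimnames(counts) <- NULL
  new_heatmap(v, counts, center_index = meta$center_index,
              block_size_um = meta$block_size_um,
              normalization = meta$normalization,
              row_edges = meta$row_edges, col_edges = meta$col_edges,
              channel = if (is.null(meta$channel)) NA_character_
                        else meta$channel)
}

#' Read recoil traces from CSV
#'
#' Accepts either columns `t_s, separation_um, side, disc_id`, or vertex
#' coordinates `t_s, x1, y1, x2, y2, side, disc_id` (separation computed
#' by [vertex_separation()]).
#'
#' @param path CSV file.
#' @return List of [recoil_trace()] objects, one per `disc_id`/`side`.
#' @export
read_recoil_traces <- function(path) {
  d <- utils::read.csv(path)
  if (!"separation_um" %in% names(d)) {
    need <- c("x1", "y1", "x2", "y2")
    if (!all(need %in% names(d)))
      stop_bad_arg("CSV needs separation_um or x1,y1,x2,y2 columns")
    d$separation_um <- vertex_separation(d$x1, d$y1, d$x2, d$y2)
  }
  if (!"side" %in% names(d)) d$side <- "anterior"
  if (!"disc_id" %in% names(d)) d$disc_id <- "disc1"
  parts <- split(d, interaction(d$disc_id, d$side, drop = TRUE))
  lapply(unname(parts), function(p)
    recoil_trace(p$t_s, p$separation_um, side = p$side[1L],
                 disc_id = as.character(p$disc_id[1L])))
}

#' Write / read gel lane profiles as long-format CSV
#'
#' Columns: `lane`, `position_px`, `intensity`, and (when windows are set)
#' `window` labeling positions inside the supernatant/pellet windows.
#'
#' @param lanes list of [gel_lane_profile()] objects.
#' @param path CSV file.
#' @return `path` invisibly / list of profiles.
#' @export
write_gel_lanes <- function(lanes, path) {
  rows <- lapply(seq_along(lanes), function(i) {
    p <- lanes[[i]]
    win <- rep("", length(p$position_px))
    if (!is.null(p$band_windows)) {
      for (nm in names(p$band_windows)) {
        wv <- p$band_windows[[nm]]
        win[p$position_px >= wv[1L] & p$position_px <= wv[2L]] <- nm
      }
    }
    data.frame(lane = i, position_px = p$position_px,
               intensity = p$intensity, window = win)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gel_lanes
#' @export
read_gel_lanes <- function(path) {
  d <- utils::read.csv(path)
  lanes <- lapply(split(d, d$lane), function(p) {
    wins <- NULL
    if ("window" %in% names(p) && any(nzchar(p$window))) {
      wins <- lapply(split(p$position_px[nzchar(p$window)],
                           p$window[nzchar(p$window)]), range)
      if (!all(c("supernatant", "pellet") %in% names(wins))) wins <- NULL
    }
    gel_lane_profile(p$position_px, p$intensity, band_windows = wins)
  })
  unname(lanes)
}

#' Write a run manifest for reproducibility
#'
#' JSON record of the command, inputs, configuration and seed of a CLI run,
#' plus package and R versions.
#'
#' @param path output JSON path.
#' @param command subcommand name.
#' @param config named list of options.
#' @param seed RNG seed used (or NULL).
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, command, config = list(), seed = NULL) {
  jsonlite::write_json(
    list(command = command, config = config, seed = seed,
         package_version = as.character(utils::packageVersion("junctension")),
         r_version = R.version.string,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
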