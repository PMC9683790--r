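#' Persist a session to plain-text files
#'
#' Writes the trial table and per-neuron truth as CSV, the fluorescence
#' and behaviour traces as TSV matrices (with the sample rate in a header
#' comment), and the configuration as JSON, into `dir`.
#'
#' @param session A `vip_session`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "vip_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(session$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  truth <- session$truth
  utils::write.csv(data.frame(neuron = seq_along(truth$archetype),
                              archetype = truth$archetype,
                              category = truth$category,
                              responds_cue = truth$responds_cue,
                              soma_diameter = truth$soma_diameter,
                              reward_gain = truth$reward_gain,
                              punish_gain = truth$punish_gain,
                              f0 = truth$f0),
                   file.path(dir, "truth.csv"), row.names = FALSE)
  write_matrix_tsv(session$traces, file.path(dir, "traces.tsv"),
                   session$sample_rate)
  beh <- session$behavior
  write_matrix_tsv(rbind(time = beh$time, pupil = beh$pupil,
                         speed = beh$speed, lick = beh$lick_raster),
                   file.path(dir, "behavior.tsv"), beh$sample_rate)
  cfg <- session$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

write_matrix_tsv <- function(m, path, sample_rate) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# sample_rate_hz\t", sample_rate), con)
  utils::write.table(m, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
}

#' @rdname write_session
#' @return `read_session()` returns a list with `trials`, `traces`,
#'   `truth`, `behavior`, `sample_rate`, `config`.
#' @export
read_session <- function(dir) {
  trials <- utils::read.csv(file.path(dir, "trials.csv"),
                            stringsAsFactors = FALSE)
  truth <- utils::read.csv(file.path(dir, "truth.csv"),
                           stringsAsFactors = FALSE)
  rd <- function(path) {
    hdr <- readLines(path, n = 1)
    fs <- as.numeric(strsplit(hdr, "\t")[[1]][2])
    m <- as.matrix(utils::read.table(path, sep = "\t", skip = 1))
    dimnames(m) <- NULL
    list(m = m, fs = fs)
  }
  tr <- rd(file.path(dir, "traces.tsv"))
  bh <- rd(file.path(dir, "behavior.tsv"))
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  list(trials = trials, traces = tr$m, truth = truth,
       behavior = list(time = bh$m[1, ], pupil = bh$m[2, ],
                       speed = bh$m[3, ], lick_raster = bh$m[4, ],
                       sample_rate = bh$fs),
       sample_rate = tr$fs, config = cfg)
}

#' Read and write tile stacks as multi-page TIFF
#'
#' One TIFF file per tile, frames as pages; intensities are affinely
#' mapped to \[0, 1\] for storage and the mapping recorded in the file
#' name-side JSON so round-trips restore the original scale.
#'
#' @param stack A `vip_tiles` object.
#' @param dir Output directory.
#' @return `dir` invisibly; `read_tile_stack()` returns a list of arrays.
#' @export
write_tile_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "vip_tiles"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scales <- list()
  for (ti in seq_along(stack$tiles)) {
    arr <- stack$tiles[[ti]]
    rng <- range(arr)
    norm <- (arr - rng[1]) / max(diff(rng), 1e-12)
    pages <- lapply(seq_len(dim(arr)[3]), function(f) norm[, , f])
    tiff::writeTIFF(pages, file.path(dir, sprintf("tile%03d.tif", ti)),
                    bits.per.sample = 16)
    scales[[ti]] <- rng
  }
  jsonlite::write_json(list(ranges = scales, pixel_size = stack$pixel_size),
                       file.path(dir, "tiles.json"), digits = NA)
  invisible(dir)
}

#' @rdname write_tile_stack
#' @export
read_tile_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "tiles.json"),
                              simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^tile\\d+\\.tif$",
                           full.names = TRUE))
  tiles <- lapply(seq_along(files), function(ti) {
    pages <- tiff::readTIFF(files[ti], all = TRUE)
    rng <- meta$ranges[ti, ]
    arr <- array(0, c(dim(pages[[1]]), length(pages)))
    for (f in seq_along(pages)) {
      arr[, , f] <- pages[[f]] * (rng[2] - rng[1]) + rng[1]
    }
    arr
  })
  structure(list(tiles = tiles, templates = NULL, shifts = NULL,
                 pixel_size = meta$pixel_size), class = "vip_tiles")
}
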