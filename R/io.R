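#' Write a biplane video as multi-page TIFFs plus a JSON sidecar
#'
#' @param video a [BiplaneVideo-class].
#' @param dir output directory (created if absent).
#' @param prefix file-name prefix.
#' @param truth optional ground-truth list to embed in the sidecar.
#' @return Invisibly, the three file paths written.
#' @export
writeBiplaneVideo <- function(video, dir, prefix = "heart", truth = NULL) {
  fhCheck(is(video, "BiplaneVideo"), "invalidParameterError",
          "video must be a BiplaneVideo")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- nFrames(video)
  asPages <- function(stack) lapply(seq_len(n), function(k) stack[, , k])
  p_long <- file.path(dir, paste0(prefix, "_long.tif"))
  p_short <- file.path(dir, paste0(prefix, "_short.tif"))
  p_meta <- file.path(dir, paste0(prefix, "_meta.json"))
  tiff::writeTIFF(asPages(planeLong(video)), p_long, bits.per.sample = 16)
  tiff::writeTIFF(asPages(planeShort(video)), p_short,
                  bits.per.sample = 16)
  meta <- list(pixel_size = pixelSize(video), frame_rate = frameRate(video),
               n_frames = n)
  if (!is.null(truth))
    meta$truth <- truth[setdiff(names(truth), "params")]
  jsonlite::write_json(meta, p_meta, auto_unbox = TRUE, digits = NA)
  invisible(c(long = p_long, short = p_short, meta = p_meta))
}

#' Read a biplane video from TIFFs plus JSON sidecar
#'
#' @param long_path,short_path multi-page TIFF paths.
#' @param meta_path JSON sidecar with `pixel_size` and `frame_rate`.
#' @return A [BiplaneVideo-class].
#' @export
readBiplaneVideo <- function(long_path, short_path, meta_path) {
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  asStack <- function(path) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  }
  BiplaneVideo(asStack(long_path), asStack(short_path),
               meta$pixel_size, meta$frame_rate)
}

#' Write / read a force trace as CSV plus JSON metadata
#'
#' The CSV holds `time` and `force` columns; marks, CSA, sarcomere length
#' and temperature travel in the JSON sidecar.
#'
#' @param trace a [ForceTrace-class].
#' @param csv_path,meta_path output paths.
#' @return Invisibly, the paths written.
#' @export
writeForceTrace <- function(trace, csv_path, meta_path) {
  fhCheck(is(trace, "ForceTrace"), "invalidParameterError",
          "trace must be a ForceTrace")
  write.csv(data.frame(time = trace@time, force = trace@force),
            csv_path, row.names = FALSE)
  jsonlite::write_json(list(marks = as.list(trace@marks), csa = trace@csa,
                            sarcomere_length = trace@sarcomereLength,
                            temperature = trace@temperature),
                       meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv_path, meta = meta_path))
}

#' @rdname writeForceTrace
#' @export
readForceTrace <- function(csv_path, meta_path) {
  d <- read.csv(csv_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  ForceTrace(d$time, d$force, marks = unlist(meta$marks),
             csa = if (is.null(meta$csa)) NA_real_ else meta$csa,
             sarcomereLength = if (is.null(meta$sarcomere_length))
               NA_real_ else meta$sarcomere_length,
             temperature = if (is.null(meta$temperature))
               NA_real_ else meta$temperature)
}

#' Write / read a Doppler waveform as CSV (plus optional events CSV)
#'
#' @param waveform a [DopplerWaveform-class].
#' @param csv_path path for the `time`,`velocity` CSV.
#' @param events_path optional path for the per-cycle valve-events CSV.
#' @return Invisibly, the paths written.
#' @export
writeDopplerWaveform <- function(waveform, csv_path, events_path = NULL) {
  fhCheck(is(waveform, "DopplerWaveform"), "invalidParameterError",
          "waveform must be a DopplerWaveform")
  write.csv(data.frame(time = waveform@time, velocity = waveform@velocity),
            csv_path, row.names = FALSE)
  if (!is.null(events_path) && nrow(waveform@events))
    write.csv(waveform@events, events_path, row.names = FALSE)
  invisible(c(csv = csv_path, events = events_path))
}

#' @rdname writeDopplerWaveform
#' @export
readDopplerWaveform <- function(csv_path, events_path = NULL) {
  d <- read.csv(csv_path)
  events <- if (!is.null(events_path) && file.exists(events_path))
    read.csv(events_path) else data.frame()
  DopplerWaveform(d$time, d$velocity, events)
}
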