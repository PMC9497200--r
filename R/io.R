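# File formats and pipeline orchestration. Images travel as multi-page
# 16-bit TIFF (pages frame-major, channel-minor) with a small YAML sidecar
# carrying channel order, pixel size and cartridge id; tables travel as
# CSV with a commented provenance header.

.sidecarPath <- function(path) paste0(tools::file_path_sans_ext(path),
                                      ".meta.yaml")

#' Write a cartridge stack as multi-page TIFF
#'
#' Pages are ordered frame-major, channel-minor (frame 1 DAPI, PE, APC,
#' FITC, then frame 2, ...). Intensities are stored as 16-bit samples;
#' the 12-bit range round-trips exactly. Channel order, pixel size and
#' cartridge id are recorded in a YAML sidecar next to the TIFF.
#'
#' @param stack a [CartridgeStack-class].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
writeCartridge <- function(stack, path) {
  stopifnot(is(stack, "CartridgeStack"))
  pages <- list()
  for (f in seq_len(nFrames(stack)))
    for (ci in seq_along(stack@channelNames))
      pages[[length(pages) + 1L]] <- stack@frames[[f]][, , ci] / 65535
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  yaml::write_yaml(list(cartridge_id = stack@cartridgeId,
                        channels = as.list(stack@channelNames),
                        pixel_size_um = stack@pixelSize,
                        frames = nFrames(stack)),
                   .sidecarPath(path))
  invisible(path)
}

#' Read a cartridge stack from multi-page TIFF
#'
#' Accepts the dialect written by [writeCartridge()] (sidecar metadata)
#' or any frame-major/channel-minor multi-page TIFF whose page count is
#' divisible by the declared channel count. Channels are reordered to the
#' canonical DAPI, PE, APC, FITC order on load.
#'
#' @param path TIFF path.
#' @param channelOrder override of the on-disk channel order (character,
#'   e.g. `c("PE", "DAPI", "APC", "FITC")`); defaults to the sidecar's
#'   order, else the canonical order.
#' @param pixelSize override of the pixel size, micrometers.
#' @return a [CartridgeStack-class].
#' @export
readCartridge <- function(path, channelOrder = NULL, pixelSize = NULL) {
  if (!file.exists(path)) stop("cartridge file not found: ", path)
  meta <- if (file.exists(.sidecarPath(path)))
    yaml::read_yaml(.sidecarPath(path)) else list()
  if (is.null(channelOrder))
    channelOrder <- if (!is.null(meta$channels)) unlist(meta$channels)
                    else CHANNELS
  if (is.null(pixelSize))
    pixelSize <- if (!is.null(meta$pixel_size_um)) meta$pixel_size_um else 0.64
  if (!setequal(channelOrder, CHANNELS))
    stop("channelOrder must be a permutation of ",
         paste(CHANNELS, collapse = ", "))
  pages <- tiff::readTIFF(path, all = TRUE)
  nc <- length(channelOrder)
  if (length(pages) %% nc != 0L)
    stop("page count (", length(pages), ") is not divisible by the channel count (",
         nc, ")")
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1L) stop("inconsistent page dimensions in ", path)
  nf <- length(pages) %/% nc
  perm <- match(CHANNELS, channelOrder)
  frames <- vector("list", nf)
  for (f in seq_len(nf)) {
    arr <- array(0, c(dims[[1]], nc))
    for (ci in seq_len(nc))
      arr[, , ci] <- round(pages[[(f - 1L) * nc + perm[ci]]] * 65535)
    frames[[f]] <- arr
  }
  id <- if (!is.null(meta$cartridge_id)) meta$cartridge_id
        else tools::file_path_sans_ext(basename(path))
  CartridgeStack(frames, pixelSize = pixelSize, cartridgeId = id)
}

.writeCsvWithHeader <- function(df, path, hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(hash)) writeLines(paste0("# config_hash: ", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write / read a ground-truth or event table as CSV
#'
#' Plain CSV with an optional commented provenance header
#' (`# config_hash: ...`), skipped transparently on read.
#'
#' @param df data.frame to write.
#' @param path CSV path.
#' @param hash optional provenance hash for the header.
#' @return `path` (write) or the data.frame (read).
#' @export
writeEventTable <- function(df, path, hash = NULL)
  .writeCsvWithHeader(df, path, hash)

#' @rdname writeEventTable
#' @export
readEventTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Render a composite thumbnail of one event
#'
#' Fixed-size crop centered on the event's bounding box with the nuclear
#' DAPI stain mapped to blue and the cytokeratin (PE) stain to green,
#' each min-max scaled over the crop; crops at the frame edge are
#' zero-padded. Deterministic: the same event renders byte-identically.
#'
#' @param obj detected object.
#' @param stack the [CartridgeStack-class].
#' @param path optional PNG output path.
#' @param size thumbnail edge length, pixels (default 48).
#' @return the `size x size x 3` RGB array, invisibly if written.
#' @export
renderThumbnail <- function(obj, stack, path = NULL, size = 48L) {
  fr <- stack@frames[[obj$frame]]
  H <- dim(fr)[1]; W <- dim(fr)[2]
  bb <- obj$bbox
  r0 <- floor((bb[1] + bb[2]) / 2) - size %/% 2L
  c0 <- floor((bb[3] + bb[4]) / 2) - size %/% 2L
  rgb <- array(0, c(size, size, 3L))
  rows <- (r0 + 1L):(r0 + size); cols <- (c0 + 1L):(c0 + size)
  okR <- rows >= 1L & rows <= H; okC <- cols >= 1L & cols <= W
  scale01 <- function(m) {
    rng <- range(m)
    if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1]) else m * 0
  }
  green <- scale01(fr[, , 2]); blue <- scale01(fr[, , 1])
  rgb[okR, okC, 2] <- green[rows[okR], cols[okC]]
  rgb[okR, okC, 3] <- blue[rows[okR], cols[okC]]
  if (!is.null(path)) {
    png::writePNG(rgb, path)
    return(invisible(rgb))
  }
  rgb
}

#' Pipeline configuration
#'
#' @param pixelSize micrometers per pixel.
#' @param channelOrder on-disk channel order of the input stack.
#' @param segmentation see [segmentationParams()].
#' @param gateFile YAML gate file path, or `NULL` for the shipped default
#'   gates.
#' @param subclass see [subclassParams()].
#' @param seed seed recorded in the provenance hash.
#' @return configuration list with a `hash` entry identifying the run.
#' @export
pipelineConfig <- function(pixelSize = 0.64, channelOrder = CHANNELS,
                           segmentation = segmentationParams(),
                           gateFile = NULL, subclass = subclassParams(),
                           seed = NULL) {
  cfg <- list(pixelSize = pixelSize, channelOrder = channelOrder,
              segmentation = segmentation, gateFile = gateFile,
              subclass = subclass, seed = seed)
  tf <- tempfile()
  writeLines(deparse(cfg), tf)
  cfg$hash <- unname(tools::md5sum(tf))
  unlink(tf)
  cfg
}

.stage <- function(name, verbose, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  if (verbose)
    message(sprintf("[%s] %.2fs", name, proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full enumeration pipeline on one cartridge
#'
#' Detection (segment + merge), morphometry, gating, review correction
#' and CTC subclassification, executed in order with per-stage timing on
#' stderr. On a noise-free synthetic cartridge the resulting counts
#' reproduce the planted ground truth exactly.
#'
#' @param input a [CartridgeStack-class] or a TIFF path readable by
#'   [readCartridge()].
#' @param config see [pipelineConfig()].
#' @param annotations optional review annotation data.frame
#'   (`object_id`, `label`).
#' @param out optional output directory for the events/gated/classified
#'   CSVs and a counts YAML.
#' @param verbose log stage timings (default TRUE).
#' @return list with `events` (detected objects), `features`, `gated`,
#'   `classified`, `counts` and `config`.
#' @export
runPipeline <- function(input, config = pipelineConfig(), annotations = NULL,
                        out = NULL, verbose = TRUE) {
  stack <- .stage("read", verbose, {
    if (is(input, "CartridgeStack")) input
    else readCartridge(input, channelOrder = config$channelOrder,
                       pixelSize = config$pixelSize)
  })
  gateset <- .stage("gates", verbose, {
    if (is.null(config$gateFile)) defaultGateSet()
    else readGateSet(config$gateFile)
  })
  events <- .stage("detect", verbose,
                   detectEvents(stack, config$segmentation))
  features <- .stage("measure", verbose, measureEvents(events, stack))
  gated <- .stage("gate", verbose, enumerateEvents(features, gateset))
  gated <- .stage("review", verbose, applyReview(gated, annotations))
  classified <- .stage("classify", verbose,
                       classifyEvents(gated, events, stack, config$subclass))
  res <- list(events = events, features = features, gated = gated,
              classified = classified, counts = gated$counts,
              config = config)
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    writeEventTable(features, file.path(out, "events.csv"), config$hash)
    writeEventTable(gated$events, file.path(out, "gated.csv"), config$hash)
    writeEventTable(classified, file.path(out, "classified.csv"), config$hash)
    yaml::write_yaml(c(as.list(gated$counts), config_hash = config$hash),
                     file.path(out, "counts.yaml"))
  }
  res
}
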