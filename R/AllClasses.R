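#' @import methods
NULL

#' Physical channel names of a cartridge acquisition
#'
#' The CellTracks-style acquisition stores four fluorescence layers per
#' frame: DAPI (nucleus), PE (cytokeratin), APC (CD45) and FITC (free
#' marker channel). This ordering is the on-disk default everywhere in the
#' package.
#'
#' @export
CHANNELS <- c("DAPI", "PE", "APC", "FITC")

#' Logical measurement channels of the feature schema
#'
#' Table-style gates address five logical channels. They are mapped onto
#' the four physical layers as CK <- PE, CD45 <- APC, M2 <- FITC; M1 is a
#' virtual extra-marker channel that defaults to constant zero so that its
#' exclusion predicates pass vacuously.
#'
#' @export
FEATURE_CHANNELS <- c("DAPI", "CK", "CD45", "M1", "M2")

#' Maximum intensity of the 12-bit acquisition, in arbitrary units (AU)
#' @export
BIT_DEPTH_MAX <- 4095

OBJECT_KINDS <- c("CTC_CLUSTER", "CTC_PRETTY", "CTC_HETEROGENEOUS",
                  "CTC_CLEAVED", "CTC_FRAGMENTED", "CTC_CLEAVED_FRAGMENTED",
                  "TDEV", "LEUKOCYTE", "DEBRIS")

SUBCLASS_LEVELS <- c("CLUSTER", "PRETTY", "HETEROGENEOUS_CK", "CLEAVED_CK",
                     "FRAGMENTED", "CLEAVED_CK_FRAGMENTED_DNA")

GATE_LEVELS <- c("CTC", "TDEV", "NEITHER")

#' CartridgeStack: ordered four-channel fluorescence frames
#'
#' A cartridge is an ordered set of co-registered frames; each frame holds
#' the four acquisition channels as an `nrow x ncol x 4` numeric array in
#' the 12-bit intensity range (0--4095 AU). The production instrument scans
#' 175 frames per cartridge; synthetic stacks are typically much smaller.
#'
#' @slot frames list of `H x W x 4` arrays, one per frame.
#' @slot pixelSize numeric(1), micrometers per pixel.
#' @slot channelNames character(4), physical channel order of dim 3.
#' @slot cartridgeId character(1) identifier.
#'
#' @export
setClass("CartridgeStack",
         representation(frames = "list", pixelSize = "numeric",
                        channelNames = "character", cartridgeId = "character"))

setValidity("CartridgeStack", function(object) {
  msg <- character(0)
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  if (length(object@channelNames) != 4L)
    msg <- c(msg, "exactly 4 channel names are required")
  if (length(object@frames)) {
    dims <- vapply(object@frames, function(f) {
      d <- dim(f)
      if (is.null(d) || length(d) != 3L) c(NA_integer_, NA_integer_, NA_integer_) else d
    }, integer(3))
    if (anyNA(dims))
      msg <- c(msg, "every frame must be a 3-d array")
    else {
      if (any(dims[3, ] != 4L))
        msg <- c(msg, "every frame must have exactly 4 channels")
      if (length(unique(dims[1, ])) > 1L || length(unique(dims[2, ])) > 1L)
        msg <- c(msg, "all frames must share the same dimensions")
    }
    rng <- range(vapply(object@frames, function(f) range(f), numeric(2)))
    if (!all(is.finite(rng)) || rng[1] < 0)
      msg <- c(msg, "frame intensities must be finite and nonnegative")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CartridgeStack
#'
#' @param frames list of `H x W x 4` numeric arrays (AU, 0--4095).
#' @param pixelSize micrometers per pixel (default 0.64).
#' @param channelNames physical channel order (default `CHANNELS`).
#' @param cartridgeId identifier string.
#' @return A [CartridgeStack-class] object.
#' @examples
#' fr <- array(2, c(32, 32, 4))
#' cs <- CartridgeStack(list(fr), pixelSize = 0.64)
#' nFrames(cs)
#' @export
CartridgeStack <- function(frames, pixelSize = 0.64, channelNames = CHANNELS,
                           cartridgeId = "cartridge") {
  new("CartridgeStack", frames = frames, pixelSize = pixelSize,
      channelNames = channelNames, cartridgeId = cartridgeId)
}

#' @describeIn CartridgeStack number of frames
#' @param x,object a `CartridgeStack`
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname CartridgeStack
#' @export
setMethod("nFrames", "CartridgeStack", function(x) length(x@frames))

#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' Pixel pitch accessor
#' @param x a `CartridgeStack`
#' @return micrometers per pixel.
#' @rdname pixelSize
#' @export
setMethod("pixelSize", "CartridgeStack", function(x) x@pixelSize)

#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' Channel-name accessor
#' @param x a `CartridgeStack`
#' @rdname channelNames
#' @export
setMethod("channelNames", "CartridgeStack", function(x) x@channelNames)

#' Extract one channel image of one frame
#'
#' @param x a `CartridgeStack`.
#' @param frame frame index (1-based).
#' @param channel channel name (physical, e.g. `"PE"`) or index.
#' @return numeric matrix of intensities.
#' @export
getChannel <- function(x, frame, channel) {
  stopifnot(is(x, "CartridgeStack"), frame >= 1, frame <= nFrames(x))
  if (is.character(channel)) {
    channel <- match(channel, x@channelNames)
    if (is.na(channel)) stop("unknown channel name")
  }
  x@frames[[frame]][, , channel]
}

setMethod("show", "CartridgeStack", function(object) {
  d <- if (nFrames(object)) dim(object@frames[[1]])[1:2] else c(0L, 0L)
  cat("CartridgeStack '", object@cartridgeId, "'\n", sep = "")
  cat("  frames: ", nFrames(object), " (", d[1], " x ", d[2], " px)\n", sep = "")
  cat("  channels: ", paste(object@channelNames, collapse = ", "), "\n", sep = "")
  cat("  pixel size: ", object@pixelSize, " um/px\n", sep = "")
})

#' GateSet: named collections of linear threshold predicates
#'
#' A gate is a conjunction of one-sided threshold predicates on the
#' feature schema; only the two comparison operators `<=` (inclusive) and
#' `>` (strict) are permitted. The default set encodes the printed CTC and
#' tdEV enumeration gates bit-exactly (see [defaultGateSet()]).
#'
#' @slot gates named list; each element a data.frame with columns
#'   `feature`, `channel`, `op` (`"le"` or `"gt"`), `threshold`, `units`.
#'
#' @export
setClass("GateSet", representation(gates = "list"))

GATE_FEATURES <- c("mean", "max", "area", "eccentricity", "perimeter",
                   "perimeter_to_area", "size", "overlay_ck_dapi")

setValidity("GateSet", function(object) {
  msg <- character(0)
  if (is.null(names(object@gates)) || any(!nzchar(names(object@gates))))
    msg <- c(msg, "gates must be named")
  for (nm in names(object@gates)) {
    g <- object@gates[[nm]]
    if (!is.data.frame(g) ||
        !all(c("feature", "channel", "op", "threshold", "units") %in% names(g))) {
      msg <- c(msg, sprintf("gate '%s': malformed predicate table", nm))
      next
    }
    if (!all(g$op %in% c("le", "gt")))
      msg <- c(msg, sprintf("gate '%s': only operators '<=' (le) and '>' (gt) are allowed", nm))
    if (!all(is.finite(g$threshold)))
      msg <- c(msg, sprintf("gate '%s': thresholds must be finite", nm))
    if (!all(g$feature %in% GATE_FEATURES))
      msg <- c(msg, sprintf("gate '%s': unknown feature(s) %s", nm,
                            paste(setdiff(g$feature, GATE_FEATURES), collapse = ", ")))
    bad <- g$feature != "overlay_ck_dapi" & !(g$channel %in% FEATURE_CHANNELS)
    if (any(bad))
      msg <- c(msg, sprintf("gate '%s': unknown channel(s) %s", nm,
                            paste(unique(g$channel[bad]), collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' @export
setGeneric("gateNames", function(x) standardGeneric("gateNames"))

#' Names of the gates in a GateSet
#' @param x a `GateSet`
#' @rdname gateNames
#' @export
setMethod("gateNames", "GateSet", function(x) names(x@gates))

#' @export
setGeneric("predicates", function(x, gate) standardGeneric("predicates"))

#' Predicate table of one gate
#' @param x a `GateSet`
#' @param gate gate name
#' @rdname predicates
#' @export
setMethod("predicates", "GateSet", function(x, gate) {
  if (!gate %in% names(x@gates)) stop("no such gate: ", gate)
  x@gates[[gate]]
})

setMethod("show", "GateSet", function(object) {
  cat("GateSet with", length(object@gates), "gate(s)\n")
  for (nm in names(object@gates)) {
    g <- object@gates[[nm]]
    cat("  ", nm, " (", nrow(g), " predicates)\n", sep = "")
    op <- ifelse(g$op == "le", "<=", ">")
    feat <- ifelse(g$feature == "overlay_ck_dapi", g$feature,
                   paste0(g$feature, "_", g$channel))
    cat(paste0("    ", format(feat, width = 24), op, " ",
               g$threshold, " ", g$units, collapse = "\n"), "\n")
  }
})
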