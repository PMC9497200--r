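# Per-object morphometry: the intensity and shape measurements consumed by
# the enumeration gates.
#
# Conventions (fixed, shared by measured and idealized paths):
#   area      = pixel count of the channel mask * pixelSize^2   [um^2]
#   perimeter = number of mask pixels with at least one 4-neighbour
#               outside the mask (boundary-pixel count)         [pixels]
#   perimeter_to_area = perimeter / mask pixel count
#   eccentricity = sqrt(1 - lambda2/lambda1) of the mask's central
#               second moments (0 = circle)
#   overlay_ck_dapi = |CK mask intersect DAPI mask| / |CK mask|
#   empty masks yield 0 for all features plus an emptiness flag.

.pixCoords <- function(idx, H) {
  cbind(r = (idx - 1L) %% H + 1L, c = (idx - 1L) %/% H + 1L)
}

.maskEccentricity <- function(idx, H) {
  n <- length(idx)
  if (n < 2L) return(0)
  rc <- .pixCoords(idx, H)
  r <- rc[, 1] - mean(rc[, 1]); c <- rc[, 2] - mean(rc[, 2])
  mu20 <- mean(r^2); mu02 <- mean(c^2); mu11 <- mean(r * c)
  disc <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + disc) / 2
  l2 <- (mu20 + mu02 - disc) / 2
  if (l1 <= 0) return(0)
  sqrt(max(0, 1 - l2 / l1))
}

.maskPerimeter <- function(idx, H, W) {
  if (!length(idx)) return(0L)
  inMask <- logical(H * W)
  inMask[idx] <- TRUE
  rc <- .pixCoords(idx, H)
  up    <- rc[, 1] == 1L | !inMask[idx - 1L]
  down  <- rc[, 1] == H  | !inMask[pmin(idx + 1L, H * W)]
  left  <- rc[, 2] == 1L | !inMask[pmax(idx - H, 1L)]
  right <- rc[, 2] == W  | !inMask[pmin(idx + H, H * W)]
  sum(up | down | left | right)
}

.channelFeatures <- function(idx, img, pixelSize) {
  H <- nrow(img); W <- ncol(img)
  if (!length(idx))
    return(list(mean = 0, max = 0, area = 0, eccentricity = 0,
                perimeter = 0, perimeter_to_area = 0, size = 0, empty = TRUE))
  v <- img[idx]
  n <- length(idx)
  per <- .maskPerimeter(idx, H, W)
  area <- n * pixelSize^2
  list(mean = mean(v), max = max(v), area = area,
       eccentricity = .maskEccentricity(idx, H),
       perimeter = per, perimeter_to_area = per / n,
       size = area, empty = FALSE)
}

.featureRow <- function(perChan, overlay) {
  row <- list()
  for (ch in c("DAPI", "CK", "CD45")) {
    f <- perChan[[ch]]
    for (nm in c("mean", "max", "area", "eccentricity", "perimeter",
                 "perimeter_to_area", "size"))
      row[[paste0(nm, "_", ch)]] <- f[[nm]]
    row[[paste0("empty_", ch)]] <- f$empty
  }
  row$mean_M1 <- perChan$M1$mean; row$max_M1 <- perChan$M1$max
  row$mean_M2 <- perChan$M2$mean; row$max_M2 <- perChan$M2$max
  row$overlay_ck_dapi <- overlay
  as.data.frame(row)
}

#' Measure one detected object
#'
#' Computes the full feature vector of a detected event against its
#' cartridge: mean/max intensity, area, eccentricity, perimeter,
#' perimeter-to-area and size per logical channel, plus the CK--DAPI
#' overlay fraction. Logical channels map onto physical layers as
#' CK <- PE, CD45 <- APC, M2 <- FITC; M1 is the virtual constant-zero
#' marker channel. DAPI, CK and CD45 are measured over their own channel
#' masks; M1/M2 are measured over the whole event footprint (the union of
#' all channel masks), reflecting their role as exclusion channels.
#'
#' @param obj a detected object as produced by [mergeEvents()].
#' @param stack the [CartridgeStack-class] the object was detected in.
#' @return one-row data.frame of features.
#' @export
measureObject <- function(obj, stack) {
  fr <- stack@frames[[obj$frame]]
  H <- dim(fr)[1]; W <- dim(fr)[2]
  npx <- H * W
  for (ch in CHANNELS) {
    idx <- obj$pixels[[ch]]
    if (length(idx) && (min(idx) < 1L || max(idx) > npx))
      stop("mask of object '", obj$objectId, "' lies outside the frame")
  }
  ps <- stack@pixelSize
  footprint <- sort(unique(unlist(obj$pixels)))
  perChan <- list(
    DAPI = .channelFeatures(obj$pixels$DAPI, fr[, , 1], ps),
    CK   = .channelFeatures(obj$pixels$PE,   fr[, , 2], ps),
    CD45 = .channelFeatures(obj$pixels$APC,  fr[, , 3], ps),
    M1   = list(mean = 0, max = 0),
    M2   = list(mean = if (length(footprint)) mean(fr[, , 4][footprint]) else 0,
                max  = if (length(footprint)) max(fr[, , 4][footprint]) else 0))
  ck <- obj$pixels$PE
  overlay <- if (length(ck)) length(intersect(ck, obj$pixels$DAPI)) / length(ck) else 0
  cbind(data.frame(object_id = obj$objectId, frame = obj$frame,
                   bbox_r0 = obj$bbox[1], bbox_r1 = obj$bbox[2],
                   bbox_c0 = obj$bbox[3], bbox_c1 = obj$bbox[4]),
        .featureRow(perChan, overlay))
}

#' Measure every detected object of a cartridge
#'
#' @param events list of detected objects from [detectEvents()] /
#'   [mergeEvents()].
#' @param stack the [CartridgeStack-class].
#' @return data.frame, one row per event (the gating input contract).
#' @export
measureEvents <- function(events, stack) {
  if (!length(events)) {
    return(cbind(data.frame(object_id = character(0), frame = integer(0),
                            bbox_r0 = integer(0), bbox_r1 = integer(0),
                            bbox_c0 = integer(0), bbox_c1 = integer(0)),
                 .featureRow(list(DAPI = .channelFeatures(integer(0), matrix(0, 1, 1), 1),
                                  CK = .channelFeatures(integer(0), matrix(0, 1, 1), 1),
                                  CD45 = .channelFeatures(integer(0), matrix(0, 1, 1), 1),
                                  M1 = list(mean = 0, max = 0),
                                  M2 = list(mean = 0, max = 0)), 0)[0, ]))
  }
  do.call(rbind, lapply(events, measureObject, stack = stack))
}

# rasterize the exact footprint discs of an ObjectSpec on a local grid;
# returns list(H, W, idx = list per physical channel)
.rasterFootprint <- function(spec) {
  ext <- ceiling(spec$extentPx) + 2L
  H <- W <- 2L * ext + 1L
  r0 <- c0 <- ext + 1
  idx <- setNames(vector("list", 4), CHANNELS)
  for (ch in CHANNELS) idx[[ch]] <- integer(0)
  rows <- seq_len(H); cols <- seq_len(W)
  for (i in seq_len(nrow(spec$components))) {
    co <- spec$components[i, ]
    d2 <- outer((rows - (r0 + co$dr))^2, (cols - (c0 + co$dc))^2, "+")
    m <- which(d2 <= co$radiusPx^2)
    idx[[co$channel]] <- union(idx[[co$channel]], m)
  }
  list(H = H, W = W, idx = idx)
}

#' Analytic (render-free) feature vector of an object specification
#'
#' Computes the features an ideal measurement of the archetype would
#' produce, without rendering, noise or segmentation: shape features from
#' the exact disc footprints rasterized on the pixel grid, and intensity
#' features from the closed-form means of the blob profiles (clipped
#' Gaussian for DAPI/CD45/FITC, blended smooth disc for CK) over a flat
#' background. Used to label planted ground truth through the same gates
#' as the detection path.
#'
#' @param spec an `ObjectSpec`.
#' @param pixelSize micrometers per pixel (must match the spec's layout).
#' @param background flat background level, AU.
#' @return one-row data.frame with the same feature columns as
#'   [measureObject()].
#' @export
idealizedFeatures <- function(spec, pixelSize = 0.64, background = 2) {
  ras <- .rasterFootprint(spec)
  zero <- matrix(0, ras$H, ras$W)
  w <- if (!is.null(spec$ckBlendW)) spec$ckBlendW else 1
  meanAdd <- c(DAPI = .q1 * spec$peaks[["DAPI"]],
               PE = .profileMean(w) * spec$peaks[["PE"]],
               APC = .q1 * spec$peaks[["APC"]],
               FITC = .q1 * spec$peaks[["FITC"]])
  perChan <- list()
  for (map in list(c("DAPI", "DAPI"), c("CK", "PE"), c("CD45", "APC"))) {
    f <- .channelFeatures(ras$idx[[map[2]]], zero, pixelSize)
    if (!f$empty) {
      f$mean <- meanAdd[[map[2]]] + background
      f$max <- spec$peaks[[map[2]]] + background
    }
    perChan[[map[1]]] <- f
  }
  footprint <- sort(unique(unlist(ras$idx)))
  nfoot <- length(footprint)
  nfitc <- length(ras$idx$FITC)
  m2mean <- if (nfoot) background + meanAdd[["FITC"]] * nfitc / nfoot else 0
  perChan$M1 <- list(mean = 0, max = 0)
  perChan$M2 <- list(mean = m2mean,
                     max = if (nfitc) spec$peaks[["FITC"]] + background
                           else if (nfoot) background else 0)
  ck <- ras$idx$PE
  overlay <- if (length(ck)) length(intersect(ck, ras$idx$DAPI)) / length(ck) else 0
  .featureRow(perChan, overlay)
}
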