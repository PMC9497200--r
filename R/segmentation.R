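# Channel segmentation and channel-merging into candidate events
# ("full detection": every fluorescent object is segmented, measured and
# only later classified by the gates).

#' Triangle threshold of an intensity image
#'
#' Geometric threshold selection for sparse bright objects on a dark
#' background: on the intensity histogram, a line is drawn from the
#' histogram peak to the farthest occupied intensity on the bright side;
#' the threshold is the intensity maximizing the perpendicular distance
#' between histogram and line.
#'
#' @param image numeric matrix of nonnegative intensities.
#' @return threshold intensity (scalar).
#' @export
triangleThreshold <- function(image) {
  v <- as.integer(round(image))
  h <- tabulate(v + 1L)               # bin i+1 = intensity i
  bPeak <- which.max(h)
  bMax <- max(which(h > 0))
  if (bMax <= bPeak) return(bPeak - 1L)   # no bright tail
  ix <- bPeak:bMax
  # distance from (ix, h[ix]) to the line (bPeak, h[bPeak]) -- (bMax, h[bMax])
  dx <- bMax - bPeak; dy <- h[bMax] - h[bPeak]
  d <- abs(dy * (ix - bPeak) - dx * (h[ix] - h[bPeak])) / sqrt(dx^2 + dy^2)
  (ix[which.max(d)]) - 1L
}

#' Default segmentation parameters
#'
#' @param method threshold method, `"triangle"` (default) or `"otsu"`.
#' @param minArea minimum component area in pixels (default 4).
#' @param dilationRadius merge radius in pixels for joining channel
#'   components into events (default 1).
#' @param seedChannels physical channels allowed to seed an event
#'   (default CK/PE and DAPI; APC and FITC components only contribute
#'   measurements).
#' @return parameter list.
#' @export
segmentationParams <- function(method = c("triangle", "otsu"), minArea = 4L,
                               dilationRadius = 1L,
                               seedChannels = c("DAPI", "PE")) {
  list(method = match.arg(method), minArea = as.integer(minArea),
       dilationRadius = as.integer(dilationRadius),
       seedChannels = seedChannels)
}

#' Segment one channel of one frame
#'
#' Thresholds the image adaptively (threshold method with a floor at
#' background + 3 noise SDs, estimated by median and MAD) and labels
#' connected components, discarding those below the minimum area. A
#' constant image yields an empty mask.
#'
#' @param image numeric matrix, nonnegative.
#' @param params see [segmentationParams()].
#' @return integer label matrix; 0 is background, components are numbered
#'   from 1 in raster order.
#' @export
segmentChannel <- function(image, params = segmentationParams()) {
  if (length(dim(image)) != 2L || !is.numeric(image))
    stop("image must be a 2-d numeric matrix")
  if (min(image) < 0) stop("image intensities must be nonnegative")
  if (max(image) == min(image))
    return(matrix(0L, nrow(image), ncol(image)))
  thr <- switch(params$method,
                triangle = triangleThreshold(image),
                otsu = EBImage::otsu(EBImage::Image(image / BIT_DEPTH_MAX),
                                     range = c(0, 1)) * BIT_DEPTH_MAX)
  floorThr <- stats::median(image) + 3 * stats::mad(image)
  thr <- max(thr, floorThr)
  mask <- image > thr
  if (!any(mask)) return(matrix(0L, nrow(image), ncol(image)))
  lab <- EBImage::bwlabel(mask)
  if (params$minArea > 1L) {
    sz <- tabulate(lab[lab > 0])
    keep <- which(sz >= params$minArea)
    lab[!(lab %in% keep)] <- 0L
  }
  # renumber surviving labels consecutively
  u <- sort(unique(lab[lab > 0]))
  relab <- integer(max(u, 0L)); relab[u] <- seq_along(u)
  out <- matrix(0L, nrow(image), ncol(image))
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

# minimum Chebyshev distance between two pixel-index sets <= r ?
.setsTouch <- function(idxA, idxB, H, r) {
  ra <- (idxA - 1L) %% H + 1L; ca <- (idxA - 1L) %/% H + 1L
  rb <- (idxB - 1L) %% H + 1L; cb <- (idxB - 1L) %/% H + 1L
  if (min(rb) - max(ra) > r || min(ra) - max(rb) > r ||
      min(cb) - max(ca) > r || min(ca) - max(cb) > r) return(FALSE)
  if (length(idxA) * length(idxB) <= 40000) {
    d <- pmax(abs(outer(ra, rb, "-")), abs(outer(ca, cb, "-")))
    return(any(d <= r))
  }
  # large components: occupancy grid over the joint bounding box
  r0 <- min(ra, rb); c0 <- min(ca, cb)
  nr <- max(ra, rb) - r0 + 1L + 2L * r
  occ <- matrix(FALSE, nr, max(ca, cb) - c0 + 1L + 2L * r)
  for (dr in -r:r) for (dc in -r:r)
    occ[cbind(ra - r0 + 1L + r + dr, ca - c0 + 1L + r + dc)] <- TRUE
  any(occ[cbind(rb - r0 + 1L + r, cb - c0 + 1L + r)])
}

#' Merge channel components of one frame into candidate events
#'
#' Components from all channels whose footprints overlap or touch within
#' the configured dilation radius are united transitively into one event.
#' Classes containing no seed-channel (CK or DAPI by default) component
#' are dropped: APC and FITC signal never seeds an event on its own.
#' Events are sorted by bounding-box top-left corner for stable
#' identifiers.
#'
#' @param masks named list of label matrices (names = physical channels),
#'   sharing dimensions.
#' @param frame frame index stored on the events.
#' @param params see [segmentationParams()].
#' @return list of detected objects; each holds `objectId` (to be filled
#'   at stack level), `frame`, `bbox` (0-based, half-open
#'   `(r0, r1, c0, c1)`) and `pixels`, a per-channel list of linear pixel
#'   indices.
#' @export
mergeEvents <- function(masks, frame = 1L, params = segmentationParams()) {
  dims <- unique(lapply(masks, dim))
  if (length(dims) != 1L) stop("channel masks must share dimensions")
  H <- dims[[1]][1]
  comps <- list()
  for (ch in names(masks)) {
    lab <- masks[[ch]]
    n <- max(lab)
    if (n > 0) {
      px <- split(which(lab > 0), lab[lab > 0])
      for (k in seq_len(n))
        comps[[length(comps) + 1L]] <- list(channel = ch,
                                            pixels = px[[as.character(k)]])
    }
  }
  n <- length(comps)
  if (n == 0L) return(list())
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  # a component dilated by r touches (is 8-adjacent to) another at
  # Chebyshev distance up to r + 1, bridging an r-pixel background gap
  r <- params$dilationRadius + 1L
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (.setsTouch(comps[[i]]$pixels, comps[[j]]$pixels, H, r)) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  events <- list()
  for (cl in unique(roots)) {
    members <- comps[roots == cl]
    if (!any(vapply(members, function(m) m$channel %in% params$seedChannels,
                    logical(1)))) next
    pixels <- setNames(vector("list", length(CHANNELS)), CHANNELS)
    for (ch in CHANNELS) pixels[[ch]] <- integer(0)
    for (m in members)
      pixels[[m$channel]] <- sort(union(pixels[[m$channel]], m$pixels))
    allIdx <- unlist(pixels)
    rr <- (allIdx - 1L) %% H + 1L; cc <- (allIdx - 1L) %/% H + 1L
    events[[length(events) + 1L]] <-
      list(objectId = NA_character_, frame = as.integer(frame),
           bbox = c(min(rr) - 1L, max(rr), min(cc) - 1L, max(cc)),
           pixels = pixels)
  }
  ord <- order(vapply(events, function(e) e$bbox[1], numeric(1)),
               vapply(events, function(e) e$bbox[3], numeric(1)))
  events[ord]
}

#' Detect all events of a cartridge
#'
#' Segments every channel of every frame and merges channel components
#' into events; assigns stable identifiers `F<frame>_E<index>`.
#'
#' @param stack a [CartridgeStack-class].
#' @param params see [segmentationParams()].
#' @return list of detected objects (see [mergeEvents()]).
#' @export
detectEvents <- function(stack, params = segmentationParams()) {
  stopifnot(is(stack, "CartridgeStack"))
  out <- list()
  for (f in seq_len(nFrames(stack))) {
    masks <- setNames(lapply(seq_along(CHANNELS), function(ci)
      segmentChannel(stack@frames[[f]][, , ci], params)), stack@channelNames)
    ev <- mergeEvents(masks, frame = f, params = params)
    for (k in seq_along(ev))
      ev[[k]]$objectId <- sprintf("F%03d_E%04d", f, k)
    out <- c(out, ev)
  }
  out
}
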