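# Object archetypes and rendering for synthetic cartridges.
#
# Geometry conventions (shared with idealizedFeatures): every blob is a
# disc-shaped footprint of radius R px; DAPI/APC blobs carry a clipped
# Gaussian profile peak * exp(-r^2 / (2 sigma^2)) with R = 2 sigma; CK (PE)
# blobs carry a "smooth disc" profile, a blend of a uniform disc and the
# Gaussian cap, whose blend weight is solved from the requested coefficient
# of variation. Intensities are additive over a flat background, clipped to
# the 12-bit range and rounded to integer counts.

# clipped-Gaussian moments over the 2-sigma footprint
.q1 <- (1 - exp(-2)) / 2      # mean of exp(-r^2/2s^2) over disc r <= 2s
.q2 <- (1 - exp(-4)) / 4      # mean of its square

# CV of the blended profile (1-w) + w * gaussian, as a function of w
.profileCV <- function(w) {
  m <- (1 - w) + w * .q1
  m2 <- (1 - w)^2 + 2 * w * (1 - w) * .q1 + w^2 * .q2
  sqrt(pmax(0, m2 / m^2 - 1))
}

# mean factor of the blended profile (mean intensity = peak * factor)
.profileMean <- function(w) (1 - w) + w * .q1

# solve blend weight (and sinusoidal amplitude for strongly heterogeneous
# targets) from a CV target
.ckProfileParams <- function(cvTarget) {
  cvMaxBlend <- .profileCV(1)
  if (cvTarget <= 0.25) {
    w <- stats::uniroot(function(w) .profileCV(w) - cvTarget,
                        c(0, 1), tol = 1e-8)$root
    list(w = w, modAmp = 0)
  } else {
    # near-uniform base disc plus multiplicative sinusoidal modulation;
    # CV of (1 + a sin sin) is a/2, so a = 2 * sqrt(cv^2 - cv_base^2)
    base <- 0.05
    w <- stats::uniroot(function(w) .profileCV(w) - base, c(0, 1))$root
    a <- min(1, 2 * sqrt(max(0, cvTarget^2 - base^2)))
    list(w = w, modAmp = a)
  }
}

# rejection-sample k points in a disc of radius `rad` (px) with pairwise
# Chebyshev separation >= minSep; returns k x 2 matrix (dr, dc) or NULL
.packPoints <- function(k, rad, minSep, maxTries = 400L) {
  if (k == 1L) {
    th <- stats::runif(1, 0, 2 * pi); r <- rad * sqrt(stats::runif(1))
    return(cbind(r * sin(th), r * cos(th)))
  }
  for (i in seq_len(maxTries)) {
    th <- stats::runif(k, 0, 2 * pi)
    r <- rad * sqrt(stats::runif(k))
    pts <- cbind(r * sin(th), r * cos(th))
    d <- pmax(abs(outer(pts[, 1], pts[, 1], "-")),
              abs(outer(pts[, 2], pts[, 2], "-")))
    if (all(d[upper.tri(d)] >= minSep)) return(pts)
  }
  NULL
}

.newComponents <- function() {
  data.frame(channel = character(0), dr = numeric(0), dc = numeric(0),
             radiusPx = numeric(0), peak = numeric(0),
             stringsAsFactors = FALSE)
}

.addComponent <- function(comp, channel, dr, dc, radiusPx, peak) {
  rbind(comp, data.frame(channel = channel, dr = dr, dc = dc,
                         radiusPx = radiusPx, peak = peak,
                         stringsAsFactors = FALSE))
}

#' Construct an object specification
#'
#' An `ObjectSpec` fully describes one planted object: its archetype kind,
#' center position, per-channel blob layout (component offsets, footprint
#' radii and peak intensities) and CK texture parameters. Specs are usually
#' drawn with [sampleObjectSpec()]; this constructor validates the
#' archetype invariants.
#'
#' @param kind one of the nine archetype kinds (six CTC subclass
#'   archetypes, `TDEV`, `LEUKOCYTE`, `DEBRIS`).
#' @param frame 1-based frame index.
#' @param row,col center pixel coordinates within the frame.
#' @param nucleusCount number of (intact) nuclei.
#' @param ckDiameter,dapiDiameter characteristic diameters, micrometers.
#' @param peaks named numeric vector of peak intensities (AU) per physical
#'   channel, within the 12-bit range.
#' @param speckleCount number of CK speckles (cleaved archetypes).
#' @param ckCvTarget target coefficient of variation of CK pixels.
#' @param components component layout data.frame (`channel`, `dr`, `dc`,
#'   `radiusPx`, `peak`).
#' @param modAmp,modWavelengthPx sinusoidal CK modulation parameters.
#' @return an object of S3 class `ObjectSpec`.
#' @export
objectSpec <- function(kind, frame, row, col, nucleusCount, ckDiameter,
                       dapiDiameter, peaks, speckleCount = 0L,
                       ckCvTarget = 0.05, components,
                       modAmp = 0, modWavelengthPx = 1) {
  kind <- match.arg(kind, OBJECT_KINDS)
  if (any(peaks < 0) || any(peaks > BIT_DEPTH_MAX))
    stop("peak intensities must lie within the 12-bit range 0..4095")
  if (kind == "CTC_CLUSTER" && nucleusCount < 2L)
    stop("CTC_CLUSTER requires nucleusCount >= 2")
  if (kind == "TDEV") {
    if (nucleusCount != 0L) stop("TDEV must have nucleusCount = 0")
    if (ckDiameter < 1 || ckDiameter > 12)
      stop("TDEV ckDiameter must lie in [1, 12] um")
  }
  if (kind == "LEUKOCYTE" && (is.na(peaks["APC"]) || peaks["APC"] <= 0))
    stop("LEUKOCYTE requires a positive CD45 (APC) peak")
  structure(list(kind = kind, frame = as.integer(frame), row = row, col = col,
                 nucleusCount = as.integer(nucleusCount),
                 ckDiameter = ckDiameter, dapiDiameter = dapiDiameter,
                 peaks = peaks, speckleCount = as.integer(speckleCount),
                 ckCvTarget = ckCvTarget, components = components,
                 modAmp = modAmp, modWavelengthPx = modWavelengthPx,
                 extentPx = if (nrow(components))
                   max(pmax(abs(components$dr), abs(components$dc)) +
                         components$radiusPx) else 0),
            class = "ObjectSpec")
}

#' Draw a random object specification of a given archetype
#'
#' Samples diameters, peak intensities and the component layout from the
#' archetype's default parameter ranges, using the current RNG state.
#' Layout constraints (nuclei inside the CK footprint, pairwise component
#' gaps of at least 2 px so that connected components stay separable)
#' are enforced by bounded rejection sampling.
#'
#' @param kind archetype kind.
#' @param pixelSize micrometers per pixel.
#' @param frame,row,col placement (may be updated later by the cartridge
#'   packer).
#' @return an `ObjectSpec`.
#' @export
sampleObjectSpec <- function(kind, pixelSize = 0.64, frame = 1L,
                             row = 0, col = 0) {
  kind <- match.arg(kind, OBJECT_KINDS)
  px <- function(d_um) d_um / (2 * pixelSize)   # radius px from diameter um
  comp <- .newComponents()
  nNuc <- 0L; nSpeck <- 0L; cv <- 0.05
  ckD <- 0; dapiD <- 0
  peaks <- c(DAPI = 0, PE = 0, APC = 0, FITC = 0)
  gap <- 2.5  # px, keeps 4-connectivity components separate

  if (kind %in% c("CTC_PRETTY", "CTC_HETEROGENEOUS")) {
    nNuc <- 1L
    ckD <- stats::runif(1, 8, 14)
    dapiD <- ckD * stats::runif(1, 0.5, 0.65)
    peaks["DAPI"] <- stats::runif(1, 300, 900)
    peaks["PE"] <- stats::runif(1, 180, 600)
    cv <- if (kind == "CTC_PRETTY") stats::runif(1, 0.03, 0.08)
          else stats::runif(1, 0.38, 0.5)
    off <- .packPoints(1L, max(0, px(ckD) - px(dapiD) - 1), 0)
    comp <- .addComponent(comp, "PE", 0, 0, px(ckD), peaks["PE"])
    comp <- .addComponent(comp, "DAPI", off[1], off[2], px(dapiD), peaks["DAPI"])
  } else if (kind == "CTC_CLUSTER") {
    # CK envelope sized from the nuclei so the DAPI/CK overlay stays well
    # above the gate threshold; nuclei may bulge slightly past the rim
    # (centroids remain inside the CK mask)
    nNuc <- sample(2:3, 1L)
    dapiD <- stats::runif(1, 6, 8)
    rn <- px(dapiD)
    Rck <- rn * sqrt(nNuc / stats::runif(1, 0.38, 0.48))
    ckD <- 2 * Rck * pixelSize
    peaks["DAPI"] <- stats::runif(1, 300, 900)
    peaks["PE"] <- stats::runif(1, 180, 600)
    cv <- stats::runif(1, 0.03, 0.08)
    pts <- .packPoints(nNuc, Rck - 0.5 * rn, 2 * rn + gap)
    if (is.null(pts)) { nNuc <- 2L
      pts <- .packPoints(2L, Rck - 0.5 * rn, 2 * rn + gap)
    }
    if (is.null(pts)) stop("infeasible cluster layout")
    comp <- .addComponent(comp, "PE", 0, 0, Rck, peaks["PE"])
    for (i in seq_len(nNuc))
      comp <- .addComponent(comp, "DAPI", pts[i, 1], pts[i, 2],
                            rn, peaks["DAPI"])
  } else if (kind == "CTC_CLEAVED") {
    nNuc <- 1L
    dapiD <- stats::runif(1, 10, 13)
    ckD <- dapiD            # characteristic extent; CK itself is speckles
    nSpeck <- sample(3:5, 1L)
    peaks["DAPI"] <- stats::runif(1, 300, 900)
    peaks["PE"] <- stats::runif(1, 180, 600)
    sd_um <- stats::runif(nSpeck, 3.2, 4.0)
    pts <- NULL
    while (is.null(pts) && nSpeck >= 3L) {
      pts <- .packPoints(nSpeck, 0.9 * px(dapiD), 2 * max(px(sd_um)) + gap)
      if (is.null(pts)) { nSpeck <- nSpeck - 1L; sd_um <- sd_um[seq_len(nSpeck)] }
    }
    if (is.null(pts)) stop("infeasible speckle layout")
    comp <- .addComponent(comp, "DAPI", 0, 0, px(dapiD), peaks["DAPI"])
    for (i in seq_len(nSpeck))
      comp <- .addComponent(comp, "PE", pts[i, 1], pts[i, 2],
                            px(sd_um[i]), peaks["PE"])
  } else if (kind == "CTC_FRAGMENTED") {
    nNuc <- 0L   # nucleus is broken: no intact nucleus remains
    ckD <- stats::runif(1, 10, 11.5)
    fragD <- stats::runif(2, 4.2, 4.5)
    peaks["DAPI"] <- stats::runif(1, 300, 900)
    peaks["PE"] <- stats::runif(1, 180, 600)
    cv <- stats::runif(1, 0.03, 0.08)
    pts <- .packPoints(2L, max(1, px(ckD) - 0.4 * max(px(fragD))),
                       2 * max(px(fragD)) + 2)
    if (is.null(pts)) stop("infeasible fragment layout")
    comp <- .addComponent(comp, "PE", 0, 0, px(ckD), peaks["PE"])
    for (i in 1:2)
      comp <- .addComponent(comp, "DAPI", pts[i, 1], pts[i, 2],
                            px(fragD[i]), peaks["DAPI"])
  } else if (kind == "CTC_CLEAVED_FRAGMENTED") {
    # apoptotic remnant: a chain of 3 nuclear fragments bridged by round
    # CK speckles, so the debris cluster stays one connected event while
    # every component remains separable within its own channel
    nNuc <- 0L
    nFrag <- 3L; nSpeck <- 3L
    fragD <- stats::runif(nFrag, 4.2, 4.5)
    sd_um <- stats::runif(nSpeck, 3.6, 4.0)
    peaks["DAPI"] <- stats::runif(1, 300, 900)
    peaks["PE"] <- stats::runif(1, 180, 600)
    ckD <- 11
    rf <- max(px(fragD)); rs <- max(px(sd_um))
    s <- 2 * rf + 2.2
    th <- stats::runif(1, 0, 2 * pi)
    th1 <- th + stats::runif(1, -0.25, 0.25)
    th2 <- th + pi + stats::runif(1, -0.25, 0.25)
    u1 <- c(sin(th1), cos(th1)); u2 <- c(sin(th2), cos(th2))
    v <- rbind(s * u1, c(0, 0), s * u2)
    for (i in seq_len(nFrag))
      comp <- .addComponent(comp, "DAPI", v[i, 1], v[i, 2],
                            px(fragD[i]), peaks["DAPI"])
    sp <- rbind((v[1, ] + v[2, ]) / 2, (v[2, ] + v[3, ]) / 2,
                v[1, ] + (rf + px(sd_um[3]) - 1.8) * u1)
    for (i in seq_len(nSpeck))
      comp <- .addComponent(comp, "PE", sp[i, 1], sp[i, 2],
                            px(sd_um[i]), peaks["PE"])
  } else if (kind == "TDEV") {
    ckD <- stats::runif(1, 4, 10)
    peaks["PE"] <- stats::runif(1, 180, 600)
    comp <- .addComponent(comp, "PE", 0, 0, px(ckD), peaks["PE"])
  } else if (kind == "LEUKOCYTE") {
    nNuc <- 1L
    dapiD <- stats::runif(1, 6, 9)
    cd45D <- dapiD * stats::runif(1, 1.1, 1.4)
    peaks["DAPI"] <- stats::runif(1, 300, 800)
    peaks["APC"] <- stats::runif(1, 200, 600)
    comp <- .addComponent(comp, "APC", 0, 0, px(cd45D), peaks["APC"])
    comp <- .addComponent(comp, "DAPI", 0, 0, px(dapiD), peaks["DAPI"])
  } else if (kind == "DEBRIS") {
    ckD <- stats::runif(1, 3, 6)
    peaks["PE"] <- stats::runif(1, 40, 90)
    peaks["FITC"] <- stats::runif(1, 120, 300)
    cv <- 0.2
    comp <- .addComponent(comp, "PE", 0, 0, px(ckD), peaks["PE"])
    comp <- .addComponent(comp, "FITC", 0, 0, px(ckD), peaks["FITC"])
  }

  prof <- .ckProfileParams(cv)
  spec <- objectSpec(kind, frame, row, col, nNuc, ckD, dapiD, peaks,
                     speckleCount = nSpeck, ckCvTarget = cv,
                     components = comp, modAmp = prof$modAmp,
                     modWavelengthPx = 0.9 * px(ckD))
  spec$ckBlendW <- prof$w
  spec
}

#' Render one object additively into a four-channel canvas
#'
#' Adds the object's blobs to `canvas` (an `H x W x 4` array in physical
#' channel order). Rendering is additive and does not apply background,
#' noise, clipping or rounding; [generateCartridge()] applies those once
#' per frame.
#'
#' @param spec an `ObjectSpec` (its `row`/`col` are canvas coordinates).
#' @param canvas `H x W x 4` numeric array.
#' @param objectId identifier used in error messages.
#' @return the updated canvas.
#' @export
renderObject <- function(spec, canvas, objectId = "object") {
  H <- dim(canvas)[1]; W <- dim(canvas)[2]
  ext <- ceiling(spec$extentPx)
  if (spec$row - ext < 1 || spec$row + ext > H ||
      spec$col - ext < 1 || spec$col + ext > W)
    stop("object '", objectId, "' extends outside the canvas")
  w <- if (!is.null(spec$ckBlendW)) spec$ckBlendW else 1
  for (i in seq_len(nrow(spec$components))) {
    co <- spec$components[i, ]
    r0 <- spec$row + co$dr; c0 <- spec$col + co$dc
    R <- co$radiusPx; sig <- R / 2
    rows <- max(1, floor(r0 - R)):min(H, ceiling(r0 + R))
    cols <- max(1, floor(c0 - R)):min(W, ceiling(c0 + R))
    d2 <- outer((rows - r0)^2, (cols - c0)^2, "+")
    inside <- d2 <= R^2
    g <- exp(-d2 / (2 * sig^2))
    if (co$channel == "PE") {
      val <- co$peak * ((1 - w) + w * g)
      if (spec$modAmp > 0) {
        mod <- 1 + spec$modAmp *
          outer(sin(2 * pi * (rows - r0) / spec$modWavelengthPx),
                sin(2 * pi * (cols - c0) / spec$modWavelengthPx))
        val <- val * pmax(0, mod)
      }
    } else {
      val <- co$peak * g
    }
    val[!inside] <- 0
    ch <- match(co$channel, CHANNELS)
    canvas[rows, cols, ch] <- canvas[rows, cols, ch] + val
  }
  canvas
}
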