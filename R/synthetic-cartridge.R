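# Whole-cartridge synthesis with planted ground truth.

KIND_TO_SUBCLASS <- c(CTC_CLUSTER = "CLUSTER", CTC_PRETTY = "PRETTY",
                      CTC_HETEROGENEOUS = "HETEROGENEOUS_CK",
                      CTC_CLEAVED = "CLEAVED_CK",
                      CTC_FRAGMENTED = "FRAGMENTED",
                      CTC_CLEAVED_FRAGMENTED = "CLEAVED_CK_FRAGMENTED_DNA")

#' Cartridge generation parameters
#'
#' The production instrument scans 175 frames per cartridge; synthetic
#' defaults are scaled down to a handful of frames of 256 x 256 px.
#'
#' @param frames number of frames.
#' @param dim frame dimensions `c(rows, cols)` in pixels.
#' @param objectMix named integer vector: how many objects of each
#'   archetype kind to plant per cartridge.
#' @param background flat background level, AU (gates compare against
#'   background-inclusive intensities).
#' @param noiseSD additive Gaussian noise SD, AU (0 for oracle tests).
#' @param pixelSize micrometers per pixel.
#' @param spacingMarginPx extra center-to-center spacing beyond the sum of
#'   object extents.
#' @param edgeMarginPx minimum distance of an object's extent from the
#'   frame border.
#' @return configuration list.
#' @export
cartridgeConfig <- function(frames = 4L, dim = c(256L, 256L),
                            objectMix = c(CTC_PRETTY = 5L, TDEV = 50L,
                                          LEUKOCYTE = 100L),
                            background = 2, noiseSD = 0, pixelSize = 0.64,
                            spacingMarginPx = 6, edgeMarginPx = 3) {
  stopifnot(all(names(objectMix) %in% OBJECT_KINDS))
  list(frames = as.integer(frames), dim = as.integer(dim),
       objectMix = objectMix, background = background, noiseSD = noiseSD,
       pixelSize = pixelSize, spacingMarginPx = spacingMarginPx,
       edgeMarginPx = edgeMarginPx)
}

.gateMargin <- function(feature, threshold) {
  m <- switch(feature,
              mean = , max = 10,
              size = , area = 0.15 * threshold,
              overlay_ck_dapi = 0.1,
              eccentricity = 0.1,
              perimeter = 2,
              perimeter_to_area = 0.2,
              0)
  min(m, 0.5 * abs(threshold))   # keep small-threshold predicates satisfiable
}

# does fv pass (resp. fail) the gate with a safety margin on every
# (resp. at least one) predicate?
.gateStatusWithMargin <- function(fv, gate) {
  passM <- TRUE; failM <- FALSE
  for (i in seq_len(nrow(gate))) {
    v <- fv[[.gateColumn(gate$feature[i], gate$channel[i])]]
    m <- .gateMargin(gate$feature[i], gate$threshold[i])
    thr <- gate$threshold[i]
    if (gate$op[i] == "le") {
      passM <- passM && v <= thr - m
      failM <- failM || v > thr + m
    } else {
      passM <- passM && v > thr + m
      failM <- failM || v <= thr - m
    }
  }
  list(pass = passM, fail = failM)
}

# draw an ObjectSpec whose idealized features sit clear of every gate
# threshold, so that noise-free rendering cannot flip its expected label
.sampleSpecWithMargin <- function(kind, pixelSize, background, gateset,
                                  maxTries = 60L) {
  intended <- if (kind %in% names(KIND_TO_SUBCLASS)) "CTC"
              else if (kind == "TDEV") "TDEV" else "NEITHER"
  for (i in seq_len(maxTries)) {
    spec <- try(sampleObjectSpec(kind, pixelSize), silent = TRUE)
    if (inherits(spec, "try-error")) next
    fv <- idealizedFeatures(spec, pixelSize, background)
    sCtc <- .gateStatusWithMargin(fv, predicates(gateset, "CTC"))
    sTdev <- .gateStatusWithMargin(fv, predicates(gateset, "TDEV"))
    ok <- switch(intended,
                 CTC = sCtc$pass && sTdev$fail,
                 TDEV = sTdev$pass && sCtc$fail,
                 NEITHER = sCtc$fail && sTdev$fail)
    if (ok) return(spec)
  }
  stop("could not draw a margin-safe '", kind, "' archetype")
}

#' Generate a synthetic cartridge with planted ground truth
#'
#' Plants the configured object mix at random non-overlapping positions
#' (center-to-center spacing at least the sum of the two objects' extents
#' plus a margin), renders all frames additively over a flat background
#' with optional Gaussian noise, clips to the 12-bit range and rounds to
#' integer counts. The ground truth records, for every planted object,
#' the gate label its idealized feature vector receives under the supplied
#' gate set -- there is no independent labeling path.
#'
#' @param config see [cartridgeConfig()].
#' @param seed integer seed; fixed seeds give bit-identical stacks.
#' @param gateset the [GateSet-class] used for expected labels.
#' @return list with `stack` (a [CartridgeStack-class]), `groundTruth`
#'   (data.frame: `object_id`, `frame`, `row`, `col`, `kind`,
#'   `expected_gate`, `expected_subclass`) and `specs` (the planted
#'   `ObjectSpec`s).
#' @export
generateCartridge <- function(config = cartridgeConfig(), seed = NULL,
                              gateset = defaultGateSet()) {
  if (!is.null(seed)) set.seed(seed)
  H <- config$dim[1]; W <- config$dim[2]
  kinds <- rep(names(config$objectMix), times = config$objectMix)
  nObj <- length(kinds)
  specs <- list()
  placed <- lapply(seq_len(config$frames), function(i)
    data.frame(row = numeric(0), col = numeric(0), ext = numeric(0)))
  gt <- vector("list", nObj)
  for (i in seq_len(nObj)) {
    spec <- .sampleSpecWithMargin(kinds[i], config$pixelSize,
                                  config$background, gateset)
    ext <- spec$extentPx
    lo <- ext + config$edgeMarginPx
    if (2 * lo >= min(H, W))
      stop("frame too small for object kind ", kinds[i])
    ok <- FALSE
    for (try in seq_len(150L)) {
      f <- sample.int(config$frames, 1L)
      r <- stats::runif(1, lo, H - lo); c <- stats::runif(1, lo, W - lo)
      p <- placed[[f]]
      if (!nrow(p) || all(sqrt((p$row - r)^2 + (p$col - c)^2) >=
                            p$ext + ext + config$spacingMarginPx)) {
        ok <- TRUE; break
      }
    }
    if (!ok)
      stop("infeasible packing: could not place object ", i, " (", kinds[i],
           ") after 150 attempts")
    placed[[f]] <- rbind(placed[[f]], data.frame(row = r, col = c, ext = ext))
    spec$frame <- f; spec$row <- r; spec$col <- c
    specs[[i]] <- spec
    fv <- idealizedFeatures(spec, config$pixelSize, config$background)
    label <- if (applyGate(fv, gateset, "CTC")) "CTC"
             else if (applyGate(fv, gateset, "TDEV")) "TDEV" else "NEITHER"
    gt[[i]] <- data.frame(object_id = sprintf("GT%04d", i), frame = f,
                          row = r, col = c, kind = kinds[i],
                          expected_gate = label,
                          expected_subclass = if (label == "CTC")
                            unname(KIND_TO_SUBCLASS[kinds[i]]) else NA_character_,
                          stringsAsFactors = FALSE)
  }
  frames <- vector("list", config$frames)
  for (f in seq_len(config$frames)) {
    canvas <- array(0, c(H, W, 4L))
    for (i in seq_len(nObj))
      if (length(specs) >= i && specs[[i]]$frame == f)
        canvas <- renderObject(specs[[i]], canvas, sprintf("GT%04d", i))
    canvas <- canvas + config$background
    if (config$noiseSD > 0)
      canvas <- canvas + array(stats::rnorm(length(canvas), 0, config$noiseSD),
                               dim(canvas))
    frames[[f]] <- round(pmin(pmax(canvas, 0), BIT_DEPTH_MAX))
  }
  groundTruth <- if (nObj) do.call(rbind, gt) else
    data.frame(object_id = character(0), frame = integer(0), row = numeric(0),
               col = numeric(0), kind = character(0),
               expected_gate = character(0), expected_subclass = character(0))
  list(stack = CartridgeStack(frames, pixelSize = config$pixelSize,
                              cartridgeId = sprintf("synthetic_seed%s",
                                                    ifelse(is.null(seed), "NA", seed))),
       groundTruth = groundTruth, specs = specs)
}
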