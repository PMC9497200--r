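# Rule-based assignment of the six morphological CTC subclasses.
#
# The six classes (clusters; "pretty" intact cells; heterogeneous CK;
# cleaved CK; fragmented DNA/CK; cleaved CK + fragmented DNA) are defined
# in the source material by reviewer-visible morphology; every numeric
# threshold here is an explicit operationalization of those verbal
# criteria and is surfaced in the parameter object.

#' Subclassification thresholds
#'
#' @param tauCv CK coefficient-of-variation threshold separating
#'   homogeneous from heterogeneous CK staining (default 0.25).
#' @param tauShape shape-irregularity (1 - solidity) threshold
#'   (default 0.15).
#' @param speckleAreaUm2 maximum area of a CK speckle, um^2 (default 16).
#' @param speckleEcc maximum eccentricity of a round speckle (default 0.8).
#' @param minSpeckles minimum number of small round CK components for a
#'   "cleaved CK" call (default 3).
#' @param minNucleusAreaUm2 minimum area of an intact nucleus, um^2
#'   (default 20); smaller DAPI components count as fragments only.
#' @return parameter list.
#' @export
subclassParams <- function(tauCv = 0.25, tauShape = 0.15,
                           speckleAreaUm2 = 16, speckleEcc = 0.8,
                           minSpeckles = 3L, minNucleusAreaUm2 = 20) {
  list(tauCv = tauCv, tauShape = tauShape, speckleAreaUm2 = speckleAreaUm2,
       speckleEcc = speckleEcc, minSpeckles = as.integer(minSpeckles),
       minNucleusAreaUm2 = minNucleusAreaUm2)
}

# rebuild a small binary matrix over the event bounding box for one channel
.bboxMask <- function(obj, channel, H) {
  bb <- obj$bbox
  m <- matrix(FALSE, bb[2] - bb[1], bb[4] - bb[3])
  idx <- obj$pixels[[channel]]
  if (length(idx)) {
    r <- (idx - 1L) %% H + 1L - bb[1]
    c <- (idx - 1L) %/% H + 1L - bb[3]
    m[cbind(r, c)] <- TRUE
  }
  m
}

.componentStats <- function(mask, pixelSize) {
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n == 0L)
    return(data.frame(area = numeric(0), ecc = numeric(0),
                      cr = numeric(0), cc = numeric(0)))
  H <- nrow(mask)
  idxAll <- which(lab > 0)
  out <- lapply(split(idxAll, lab[idxAll]), function(idx) {
    rc <- .pixCoords(idx, H)
    data.frame(area = length(idx) * pixelSize^2,
               ecc = .maskEccentricity(idx, H),
               cr = mean(rc[, 1]), cc = mean(rc[, 2]))
  })
  do.call(rbind, out)
}

#' Count intact nuclei within the CK staining of an event
#'
#' A nucleus is a DAPI connected component of at least the minimum
#' nucleus area whose centroid lies inside the CK mask; sub-nuclear DAPI
#' fragments are deliberately not counted (they enter the fragment count
#' instead).
#'
#' @param obj detected object (CTC event).
#' @param stack the [CartridgeStack-class].
#' @param params see [subclassParams()].
#' @return integer nucleus count.
#' @export
countNucleiInCK <- function(obj, stack, params = subclassParams()) {
  if (!length(obj$pixels$PE)) stop("event has an empty CK mask")
  H <- dim(stack@frames[[obj$frame]])[1]
  ck <- .bboxMask(obj, "PE", H)
  comps <- .componentStats(.bboxMask(obj, "DAPI", H), stack@pixelSize)
  if (!nrow(comps)) return(0L)
  inside <- mapply(function(r, c) {
    r <- round(r); c <- round(c)
    r >= 1 && r <= nrow(ck) && c >= 1 && c <= ncol(ck) && ck[r, c]
  }, comps$cr, comps$cc)
  sum(inside & comps$area >= params$minNucleusAreaUm2)
}

#' CK texture and shape irregularity of an event
#'
#' @param obj detected object with non-empty CK mask.
#' @param stack the [CartridgeStack-class].
#' @return list with `ck_cv` (SD/mean of CK intensities within the CK
#'   mask) and `shape_irregularity` (1 - solidity of the CK mask, where
#'   solidity is mask area over convex-hull area).
#' @export
ckTexture <- function(obj, stack) {
  if (!length(obj$pixels$PE)) stop("event has an empty CK mask")
  fr <- stack@frames[[obj$frame]]
  v <- fr[, , 2][obj$pixels$PE]
  cv <- if (mean(v) > 0) stats::sd(v) / mean(v) else 0
  if (is.na(cv)) cv <- 0
  H <- dim(fr)[1]
  rc <- .pixCoords(obj$pixels$PE, H)
  n <- nrow(rc)
  irr <- 0
  if (n >= 3L) {
    hull <- grDevices::chull(rc)
    hx <- rc[hull, 1]; hy <- rc[hull, 2]
    k <- length(hx)
    shoelace <- abs(sum(hx * hy[c(2:k, 1)] - hx[c(2:k, 1)] * hy)) / 2
    # expand the pixel-center polygon to pixel extents (Pick-style)
    hullPerim <- sum(sqrt(diff(c(hx, hx[1]))^2 + diff(c(hy, hy[1]))^2))
    hullArea <- shoelace + hullPerim / 2 + 1
    irr <- max(0, 1 - n / hullArea)
  }
  list(ck_cv = cv, shape_irregularity = irr)
}

#' CK speckling and DNA fragmentation evidence of an event
#'
#' @param obj detected object (CTC event).
#' @param stack the [CartridgeStack-class].
#' @param params see [subclassParams()].
#' @return list with `ck_component_count`, `speckle_flag` (at least
#'   `minSpeckles` CK components that are small and round) and
#'   `dna_fragment_count` (all DAPI components of the event).
#' @export
speckleFragmentation <- function(obj, stack, params = subclassParams()) {
  H <- dim(stack@frames[[obj$frame]])[1]
  ps <- stack@pixelSize
  ckComps <- .componentStats(.bboxMask(obj, "PE", H), ps)
  dapiComps <- .componentStats(.bboxMask(obj, "DAPI", H), ps)
  speckles <- sum(ckComps$area <= params$speckleAreaUm2 &
                    ckComps$ecc <= params$speckleEcc)
  list(ck_component_count = nrow(ckComps),
       speckle_flag = speckles >= params$minSpeckles,
       dna_fragment_count = nrow(dapiComps))
}

#' Assign a morphological subclass from measured evidence
#'
#' First-match cascade (the order is part of the contract):
#' \enumerate{
#'   \item >= 2 intact nuclei in CK and all DAPI components intact
#'     (fragment count equals nucleus count) -> `CLUSTER`;
#'   \item CK speckling and >= 2 DAPI fragments ->
#'     `CLEAVED_CK_FRAGMENTED_DNA`;
#'   \item CK speckling -> `CLEAVED_CK`;
#'   \item >= 2 DAPI fragments or >= 2 (non-speckle) CK components ->
#'     `FRAGMENTED`;
#'   \item CK CV above `tauCv` or shape irregularity above `tauShape` ->
#'     `HETEROGENEOUS_CK`;
#'   \item otherwise -> `PRETTY`.
#' }
#'
#' @param evidence list with `nuclei_in_ck`, `ck_cv`,
#'   `ck_component_count`, `speckle_flag`, `dna_fragment_count`,
#'   `shape_irregularity`.
#' @param params see [subclassParams()].
#' @return character subclass label.
#' @export
classifySubclass <- function(evidence, params = subclassParams()) {
  need <- c("nuclei_in_ck", "ck_cv", "ck_component_count", "speckle_flag",
            "dna_fragment_count", "shape_irregularity")
  miss <- setdiff(need, names(evidence))
  if (length(miss) || any(vapply(evidence[need], function(x)
    is.null(x) || is.na(x), logical(1))))
    stop("incomplete evidence: ", paste(miss, collapse = ", "))
  e <- evidence
  if (e$nuclei_in_ck >= 2L && e$dna_fragment_count == e$nuclei_in_ck)
    return("CLUSTER")
  if (e$speckle_flag && e$dna_fragment_count >= 2L)
    return("CLEAVED_CK_FRAGMENTED_DNA")
  if (e$speckle_flag) return("CLEAVED_CK")
  if (e$dna_fragment_count >= 2L || e$ck_component_count >= 2L)
    return("FRAGMENTED")
  if (e$ck_cv > params$tauCv || e$shape_irregularity > params$tauShape)
    return("HETEROGENEOUS_CK")
  "PRETTY"
}

#' Gather evidence and classify one CTC event
#'
#' @param obj detected object (CTC event).
#' @param stack the [CartridgeStack-class].
#' @param params see [subclassParams()].
#' @return list with `subclass` and the evidence fields.
#' @export
subclassifyObject <- function(obj, stack, params = subclassParams()) {
  ev <- c(list(nuclei_in_ck = countNucleiInCK(obj, stack, params)),
          ckTexture(obj, stack),
          speckleFragmentation(obj, stack, params))
  c(list(subclass = classifySubclass(ev, params)), ev)
}

#' Subclassify every confirmed CTC event of a cartridge
#'
#' Adds `subclass` and evidence columns to the gated event table. tdEV
#' and artifact-excluded events are never subclassified.
#'
#' @param gated result of [enumerateEvents()] or [applyReview()].
#' @param events the detected-object list the feature table was measured
#'   from.
#' @param stack the [CartridgeStack-class].
#' @param params see [subclassParams()].
#' @return the event table with subclass and evidence columns filled in
#'   for confirmed CTCs.
#' @export
classifyEvents <- function(gated, events, stack, params = subclassParams()) {
  tab <- gated$events
  byId <- setNames(events, vapply(events, `[[`, character(1), "objectId"))
  evCols <- c("nuclei_in_ck", "ck_cv", "ck_component_count", "speckle_flag",
              "dna_fragment_count", "shape_irregularity")
  for (col in evCols) tab[[col]] <- NA
  for (i in seq_len(nrow(tab))) {
    if (tab$gate_label[i] != "CTC" ||
        tab$review_status[i] == "EXCLUDED_ARTIFACT") next
    res <- subclassifyObject(byId[[tab$object_id[i]]], stack, params)
    tab$subclass[i] <- res$subclass
    for (col in evCols) tab[[col]][i] <- res[[col]]
  }
  tab
}
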