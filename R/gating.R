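# Linear gating: conjunctions of one-sided threshold predicates applied to
# the morphometry feature table, enumeration of CTC and tdEV events, and
# the review-correction step.

.OP_IN <- c("<=" = "le", ">" = "gt")
.OP_OUT <- c(le = "<=", gt = ">")

.predicate <- function(feature, channel, op, threshold, units) {
  data.frame(feature = feature, channel = channel, op = op,
             threshold = threshold, units = units, stringsAsFactors = FALSE)
}

#' The default CTC and tdEV enumeration gates
#'
#' Returns the shipped gate set with the printed threshold values used for
#' CTC and tdEV enumeration on CellSearch cartridges: a CTC is a
#' CD45-negative (mean <= 5 AU), DAPI-positive (mean > 45 AU), CK-positive
#' (mean > 60 AU) object of CK size in (16, 400] um^2 whose CK footprint
#' overlays DAPI by more than 0.2; a tdEV is a DAPI-negative (mean <= 5 AU)
#' CK-positive particle (mean > 60, max > 90 AU) of CK area/size <= 150
#' um^2, eccentricity <= 0.8, perimeter > 5 px and perimeter-to-area <= 1.
#' Both classes must be negative (mean <= 5 AU) in the two extra marker
#' channels. The same values are shipped as a YAML file under
#' `inst/extdata/gates/table1.yaml`.
#'
#' @return a [GateSet-class] with gates `"CTC"` (8 predicates) and
#'   `"TDEV"` (11 predicates).
#' @export
defaultGateSet <- function() {
  ctc <- rbind(
    .predicate("mean", "CD45", "le", 5, "AU"),
    .predicate("mean", "DAPI", "gt", 45, "AU"),
    .predicate("mean", "CK", "gt", 60, "AU"),
    .predicate("size", "CK", "gt", 16, "um2"),
    .predicate("size", "CK", "le", 400, "um2"),
    .predicate("overlay_ck_dapi", "CK", "gt", 0.2, "AU"),
    .predicate("mean", "M1", "le", 5, "AU"),
    .predicate("mean", "M2", "le", 5, "AU"))
  tdev <- rbind(
    .predicate("mean", "CD45", "le", 5, "AU"),
    .predicate("mean", "DAPI", "le", 5, "AU"),
    .predicate("mean", "CK", "gt", 60, "AU"),
    .predicate("max", "CK", "gt", 90, "AU"),
    .predicate("area", "CK", "le", 150, "um2"),
    .predicate("eccentricity", "CK", "le", 0.8, "AU"),
    .predicate("perimeter_to_area", "CK", "le", 1, "AU"),
    .predicate("perimeter", "CK", "gt", 5, "pixels"),
    .predicate("size", "CK", "le", 150, "um2"),
    .predicate("mean", "M1", "le", 5, "AU"),
    .predicate("mean", "M2", "le", 5, "AU"))
  new("GateSet", gates = list(CTC = ctc, TDEV = tdev))
}

#' Read a gate set from a YAML configuration file
#'
#' The file holds a top-level `gates:` mapping; each gate is a list of
#' predicates with keys `feature`, `channel`, `op` (only `"<="` and `">"`
#' are legal), `threshold` and `units`. Unknown features, channels or
#' operators are rejected with the offending gate and predicate named.
#'
#' @param path YAML file path.
#' @return a [GateSet-class].
#' @seealso [writeGateSet()], [defaultGateSet()]
#' @export
readGateSet <- function(path) {
  if (!file.exists(path)) stop("gate file not found: ", path)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$gates)) stop("gate file has no 'gates' section: ", path)
  gates <- lapply(names(doc$gates), function(nm) {
    preds <- doc$gates[[nm]]
    rows <- lapply(seq_along(preds), function(i) {
      p <- preds[[i]]
      need <- c("feature", "channel", "op", "threshold", "units")
      if (!all(need %in% names(p)))
        stop(sprintf("gate '%s', predicate %d: missing field(s) %s",
                     nm, i, paste(setdiff(need, names(p)), collapse = ", ")))
      if (!p$op %in% names(.OP_IN))
        stop(sprintf("gate '%s', predicate %d: illegal operator '%s' (only '<=' and '>')",
                     nm, i, p$op))
      .predicate(p$feature, p$channel, .OP_IN[[p$op]], as.numeric(p$threshold),
                 p$units)
    })
    do.call(rbind, rows)
  })
  names(gates) <- names(doc$gates)
  new("GateSet", gates = gates)
}

#' Write a gate set to YAML
#'
#' Serialization round-trips bit-exactly with [readGateSet()].
#'
#' @param gateset a [GateSet-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGateSet <- function(gateset, path) {
  stopifnot(is(gateset, "GateSet"))
  doc <- list(gates = lapply(gateset@gates, function(g) {
    lapply(seq_len(nrow(g)), function(i)
      list(feature = g$feature[i], channel = g$channel[i],
           op = unname(.OP_OUT[[g$op[i]]]), threshold = g$threshold[i],
           units = g$units[i]))
  }))
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

.gateColumn <- function(feature, channel) {
  ifelse(feature == "overlay_ck_dapi", "overlay_ck_dapi",
         paste0(feature, "_", channel))
}

#' Apply one gate to feature vectors
#'
#' Evaluates the conjunction of the gate's predicates. Comparisons are
#' exactly as printed: `"<="` inclusive, `">"` strict. Vectorized over the
#' rows of `fv`.
#'
#' @param fv one-row feature vector or multi-row feature table
#'   ([measureEvents()] schema).
#' @param gate a predicate data.frame (one element of a `GateSet`), or a
#'   `GateSet` together with `name`.
#' @param name gate name when `gate` is a `GateSet`.
#' @return logical vector, one element per row of `fv`.
#' @export
applyGate <- function(fv, gate, name = NULL) {
  if (is(gate, "GateSet")) gate <- predicates(gate, name)
  pass <- rep(TRUE, nrow(fv))
  for (i in seq_len(nrow(gate))) {
    col <- .gateColumn(gate$feature[i], gate$channel[i])
    if (!col %in% names(fv))
      stop("feature '", col, "' missing from the feature table")
    v <- fv[[col]]
    pass <- pass & if (gate$op[i] == "le") v <= gate$threshold[i]
                   else v > gate$threshold[i]
  }
  pass
}

#' Enumerate CTC and tdEV events in a feature table
#'
#' Labels each object `CTC` if it passes the CTC gate, else `TDEV` if it
#' passes the tdEV gate, else `NEITHER` (the default gates are mutually
#' exclusive on the DAPI predicate, so the order only matters for custom
#' gate sets), and totals the per-cartridge counts.
#'
#' @param features feature table ([measureEvents()] schema) with unique
#'   `object_id`s.
#' @param gateset a [GateSet-class] containing gates `CTC` and `TDEV`.
#' @return list with `events` (the feature table plus `gate_label`,
#'   `review_status`, `subclass` columns, input order preserved) and
#'   `counts` (named vector `ctc_accept`, `tdev_accept`).
#' @export
enumerateEvents <- function(features, gateset = defaultGateSet()) {
  if (anyDuplicated(features$object_id))
    stop("duplicate object_id in feature table")
  label <- rep("NEITHER", nrow(features))
  if (nrow(features)) {
    isTdev <- applyGate(features, gateset, "TDEV")
    isCtc <- applyGate(features, gateset, "CTC")
    label[isTdev] <- "TDEV"
    label[isCtc] <- "CTC"     # CTC priority over TDEV for custom gates
  }
  events <- features
  events$gate_label <- label
  events$review_status <- rep("UNREVIEWED", nrow(features))
  events$subclass <- rep(NA_character_, nrow(features))
  list(events = events,
       counts = c(ctc_accept = sum(label == "CTC"),
                  tdev_accept = sum(label == "TDEV")))
}

#' Apply review annotations and compute corrected counts
#'
#' Reviewed objects marked as debris or artifacts are excluded from the
#' CTC count, yielding the corrected CTC count; tdEV counts are not
#' subject to review. Unannotated events default to `CONFIRMED`.
#'
#' @param gated result of [enumerateEvents()].
#' @param annotations data.frame with columns `object_id` and `label`
#'   (`"CONFIRMED"` or `"EXCLUDED_ARTIFACT"`), or `NULL` for no review.
#' @return list with updated `events` and `counts` (named vector
#'   `ctc_accept`, `tdev_accept`, `ctc_accept_corrected`).
#' @export
applyReview <- function(gated, annotations = NULL) {
  events <- gated$events
  events$review_status <- ifelse(events$gate_label == "NEITHER",
                                 events$review_status, "CONFIRMED")
  if (!is.null(annotations) && nrow(annotations)) {
    bad <- setdiff(annotations$object_id, events$object_id)
    if (length(bad))
      stop("annotation(s) for unknown object_id: ",
           paste(bad, collapse = ", "))
    if (!all(annotations$label %in% c("CONFIRMED", "EXCLUDED_ARTIFACT")))
      stop("review labels must be CONFIRMED or EXCLUDED_ARTIFACT")
    i <- match(annotations$object_id, events$object_id)
    tdevExcl <- annotations$label == "EXCLUDED_ARTIFACT" &
      events$gate_label[i] == "TDEV"
    if (any(tdevExcl))
      warning("exclusion of tdEV-labeled object(s) ignored for counts: ",
              paste(annotations$object_id[tdevExcl], collapse = ", "))
    events$review_status[i] <- annotations$label
  }
  excluded <- sum(events$gate_label == "CTC" &
                    events$review_status == "EXCLUDED_ARTIFACT")
  ctc <- sum(events$gate_label == "CTC")
  list(events = events,
       counts = c(ctc_accept = ctc,
                  tdev_accept = sum(events$gate_label == "TDEV"),
                  ctc_accept_corrected = ctc - excluded))
}
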