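# Shared fixtures: all built in code at test time.

CTC_KINDS <- c(CTC_CLUSTER = "CLUSTER", CTC_PRETTY = "PRETTY",
               CTC_HETEROGENEOUS = "HETEROGENEOUS_CK",
               CTC_CLEAVED = "CLEAVED_CK", CTC_FRAGMENTED = "FRAGMENTED",
               CTC_CLEAVED_FRAGMENTED = "CLEAVED_CK_FRAGMENTED_DNA")

# a complete feature row passing the CTC gate, with overridable fields
makeFeatureRow <- function(...) {
  row <- list(object_id = "X", frame = 1L,
              bbox_r0 = 0L, bbox_r1 = 10L, bbox_c0 = 0L, bbox_c1 = 10L)
  for (ch in c("DAPI", "CK", "CD45")) {
    row[[paste0("mean_", ch)]] <- 0
    row[[paste0("max_", ch)]] <- 0
    row[[paste0("area_", ch)]] <- 0
    row[[paste0("eccentricity_", ch)]] <- 0
    row[[paste0("perimeter_", ch)]] <- 0
    row[[paste0("perimeter_to_area_", ch)]] <- 0
    row[[paste0("size_", ch)]] <- 0
    row[[paste0("empty_", ch)]] <- TRUE
  }
  row$mean_M1 <- 0; row$max_M1 <- 0; row$mean_M2 <- 2; row$max_M2 <- 2
  row$overlay_ck_dapi <- 0
  row <- utils::modifyList(row, list(
    mean_DAPI = 200, max_DAPI = 400, area_DAPI = 30, size_DAPI = 30,
    empty_DAPI = FALSE,
    mean_CK = 150, max_CK = 300, area_CK = 80, size_CK = 80,
    eccentricity_CK = 0.1, perimeter_CK = 30, perimeter_to_area_CK = 0.3,
    empty_CK = FALSE, overlay_ck_dapi = 0.4))
  row <- utils::modifyList(row, list(...))
  as.data.frame(row)
}

# a feature row passing the tdEV gate
makeTdevRow <- function(...) {
  makeFeatureRow(mean_DAPI = 0, max_DAPI = 0, area_DAPI = 0, size_DAPI = 0,
                 empty_DAPI = TRUE, overlay_ck_dapi = 0,
                 area_CK = 50, size_CK = 50, perimeter_CK = 20,
                 perimeter_to_area_CK = 0.4, ...)
}

# random feature vectors spanning the gate-relevant ranges
randomFeatureTable <- function(n) {
  df <- do.call(rbind, replicate(n, makeFeatureRow(), simplify = FALSE))
  df$object_id <- sprintf("R%05d", seq_len(n))
  df$mean_DAPI <- stats::runif(n, 0, 100)
  df$mean_CK <- stats::runif(n, 0, 150)
  df$max_CK <- stats::runif(n, 0, 300)
  df$mean_CD45 <- stats::runif(n, 0, 15)
  df$mean_M1 <- stats::runif(n, 0, 10)
  df$mean_M2 <- stats::runif(n, 0, 10)
  df$area_CK <- stats::runif(n, 0, 500)
  df$size_CK <- df$area_CK
  df$eccentricity_CK <- stats::runif(n)
  df$perimeter_CK <- stats::runif(n, 0, 60)
  df$perimeter_to_area_CK <- stats::runif(n, 0, 2)
  df$overlay_ck_dapi <- stats::runif(n)
  df
}

# run the full pipeline on a freshly generated cartridge
recoverCartridge <- function(mix, seed, frames = 2L, dim = c(220L, 220L),
                             noiseSD = 0) {
  gen <- generateCartridge(cartridgeConfig(frames = frames, dim = dim,
                                           objectMix = mix,
                                           noiseSD = noiseSD), seed = seed)
  res <- runPipeline(gen$stack, verbose = FALSE)
  list(gen = gen, res = res)
}

# plant one archetype on a small canvas and return its detected object
# and the stack (for morphometry / subclassification unit tests)
singleArchetype <- function(kind, seed, dim = c(96L, 96L)) {
  gen <- generateCartridge(cartridgeConfig(frames = 1L, dim = dim,
                                           objectMix = setNames(1L, kind)),
                           seed = seed)
  events <- detectEvents(gen$stack)
  list(gen = gen, stack = gen$stack, events = events)
}
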