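# Morphological subclassification: evidence extraction and the cascade.

test_that("nuclei are counted only when intact and centered inside CK", {
  arc <- singleArchetype("CTC_CLUSTER", seed = 61)
  expect_length(arc$events, 1L)
  expect_equal(countNucleiInCK(arc$events[[1]], arc$stack),
               arc$gen$specs[[1]]$nucleusCount)
  pretty <- singleArchetype("CTC_PRETTY", seed = 62)
  expect_equal(countNucleiInCK(pretty$events[[1]], pretty$stack), 1L)
  # a fragmented nucleus contributes no intact nuclei
  frag <- singleArchetype("CTC_FRAGMENTED", seed = 63)
  expect_equal(countNucleiInCK(frag$events[[1]], frag$stack), 0L)
  ev <- pretty$events[[1]]
  ev$pixels$PE <- integer(0)
  expect_error(countNucleiInCK(ev, pretty$stack), "empty CK")
})

test_that("a DAPI component centered outside the CK mask is not counted", {
  H <- 50
  ck <- which(outer((1:H - 15)^2, (1:H - 15)^2, "+") <= 49)
  nucIn <- which(outer((1:H - 15)^2, (1:H - 15)^2, "+") <= 16)
  nucOut <- which(outer((1:H - 38)^2, (1:H - 38)^2, "+") <= 16)
  obj <- list(objectId = "X", frame = 1L, bbox = c(0, 50, 0, 50),
              pixels = list(DAPI = c(nucIn, nucOut), PE = ck,
                            APC = integer(0), FITC = integer(0)))
  fr <- array(2, c(H, H, 4))
  stack <- CartridgeStack(list(fr), pixelSize = 1)
  expect_equal(countNucleiInCK(obj, stack,
                               subclassParams(minNucleusAreaUm2 = 10)), 1L)
})

test_that("CK texture separates uniform from modulated staining", {
  pretty <- singleArchetype("CTC_PRETTY", seed = 64)
  tx <- ckTexture(pretty$events[[1]], pretty$stack)
  expect_lt(tx$ck_cv, 0.15)
  expect_lt(tx$shape_irregularity, 0.1)
  het <- singleArchetype("CTC_HETEROGENEOUS", seed = 65)
  txh <- ckTexture(het$events[[1]], het$stack)
  expect_gt(txh$ck_cv, 0.3)
})

test_that("a star-shaped mask is more irregular than a disc", {
  H <- 60
  th <- atan2(outer(1:H - 30, rep(1, H)), outer(rep(1, H), 1:H - 30))
  rr <- sqrt(outer((1:H - 30)^2, (1:H - 30)^2, "+"))
  disc <- which(rr <= 12)
  star <- which(rr <= 7 + 8 * abs(sin(2.5 * th)))
  mkObj <- function(idx) list(objectId = "X", frame = 1L,
                              bbox = c(0, H, 0, H),
                              pixels = list(DAPI = integer(0), PE = idx,
                                            APC = integer(0),
                                            FITC = integer(0)))
  stack <- CartridgeStack(list(array(2, c(H, H, 4))), pixelSize = 1)
  expect_gt(ckTexture(mkObj(star), stack)$shape_irregularity,
            ckTexture(mkObj(disc), stack)$shape_irregularity)
})

test_that("speckle and fragmentation evidence matches planted archetypes", {
  clv <- singleArchetype("CTC_CLEAVED", seed = 66)
  sf <- speckleFragmentation(clv$events[[1]], clv$stack)
  expect_true(sf$speckle_flag)
  expect_equal(sf$ck_component_count, clv$gen$specs[[1]]$speckleCount)
  expect_equal(sf$dna_fragment_count, 1L)
  pretty <- singleArchetype("CTC_PRETTY", seed = 67)
  sfp <- speckleFragmentation(pretty$events[[1]], pretty$stack)
  expect_equal(sfp$ck_component_count, 1L)
  expect_false(sfp$speckle_flag)
  frag <- singleArchetype("CTC_FRAGMENTED", seed = 68)
  sff <- speckleFragmentation(frag$events[[1]], frag$stack)
  expect_equal(sff$dna_fragment_count, 2L)
  expect_false(sff$speckle_flag)
})

test_that("the classification cascade is total and ordered as documented", {
  ev <- list(nuclei_in_ck = 2L, ck_cv = 0.05, ck_component_count = 1L,
             speckle_flag = FALSE, dna_fragment_count = 2L,
             shape_irregularity = 0.01)
  expect_equal(classifySubclass(ev), "CLUSTER")
  ev$nuclei_in_ck <- 0L; ev$speckle_flag <- TRUE; ev$ck_component_count <- 4L
  expect_equal(classifySubclass(ev), "CLEAVED_CK_FRAGMENTED_DNA")
  ev$dna_fragment_count <- 1L
  expect_equal(classifySubclass(ev), "CLEAVED_CK")
  ev$speckle_flag <- FALSE
  expect_equal(classifySubclass(ev), "FRAGMENTED")   # >= 2 CK components
  ev$ck_component_count <- 1L
  ev2 <- list(nuclei_in_ck = 1L, ck_cv = 0.4, ck_component_count = 1L,
              speckle_flag = FALSE, dna_fragment_count = 1L,
              shape_irregularity = 0.01)
  expect_equal(classifySubclass(ev2), "HETEROGENEOUS_CK")
  ev2$ck_cv <- 0.02
  expect_equal(classifySubclass(ev2), "PRETTY")
  # order sensitivity: speckled AND fragmented evidence resolves to the
  # combined class only because rule 2 precedes rules 3-4
  evBoth <- list(nuclei_in_ck = 0L, ck_cv = 0.5, ck_component_count = 4L,
                 speckle_flag = TRUE, dna_fragment_count = 3L,
                 shape_irregularity = 0.3)
  expect_equal(classifySubclass(evBoth), "CLEAVED_CK_FRAGMENTED_DNA")
  expect_error(classifySubclass(list(nuclei_in_ck = 1L)), "incomplete")
})

test_that("every rendered archetype recovers its planted subclass", {
  set.seed(70)
  for (kind in names(CTC_KINDS)) {
    n <- 25L; hits <- 0L
    for (i in seq_len(n)) {
      r <- recoverCartridge(setNames(1L, kind), seed = sample.int(1e6, 1),
                            frames = 1L, dim = c(96L, 96L))
      lab <- r$res$classified$subclass[r$res$classified$gate_label == "CTC"]
      if (length(lab) == 1L && lab == CTC_KINDS[[kind]]) hits <- hits + 1L
    }
    expect_gte(hits / n, 0.95)
  }
})

test_that("tdEV events are never subclassified", {
  r <- recoverCartridge(c(CTC_PRETTY = 1, TDEV = 5), seed = 71, frames = 1L)
  cls <- r$res$classified
  expect_true(all(is.na(cls$subclass[cls$gate_label == "TDEV"])))
  expect_equal(sum(!is.na(cls$subclass)), 1L)
})
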