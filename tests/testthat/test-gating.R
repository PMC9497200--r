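# Gate configuration, predicate semantics, enumeration and review.

test_that("the default gate set encodes the printed predicate counts", {
  gs <- defaultGateSet()
  expect_setequal(gateNames(gs), c("CTC", "TDEV"))
  expect_equal(nrow(predicates(gs, "CTC")), 8L)
  expect_equal(nrow(predicates(gs, "TDEV")), 11L)
  expect_true(all(predicates(gs, "TDEV")$op %in% c("le", "gt")))
})

test_that("the shipped YAML gate file equals the in-code defaults", {
  path <- system.file("extdata", "gates", "table1.yaml", package = "ctcscope")
  expect_true(nzchar(path))
  expect_identical(readGateSet(path)@gates, defaultGateSet()@gates)
})

test_that("gate serialization round-trips bit-exactly", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeGateSet(defaultGateSet(), f)
  g1 <- readGateSet(f)
  f2 <- withr::local_tempfile(fileext = ".yaml")
  writeGateSet(g1, f2)
  expect_identical(readGateSet(f2)@gates, g1@gates)
})

test_that("illegal operators and unknown features are rejected", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("gates:", "  BAD:", "  - feature: mean", "    channel: CK",
               "    op: '<'", "    threshold: 5", "    units: AU"), f)
  expect_error(readGateSet(f), "illegal operator")
  writeLines(c("gates:", "  BAD:", "  - feature: wibble", "    channel: CK",
               "    op: '>'", "    threshold: 5", "    units: AU"), f)
  expect_error(readGateSet(f), "unknown feature")
})

test_that("comparisons are strict for > and inclusive for <= exactly as printed", {
  gs <- defaultGateSet()
  expect_false(applyGate(makeFeatureRow(mean_CK = 60), gs, "CTC"))
  expect_true(applyGate(makeFeatureRow(mean_CK = 60.0001), gs, "CTC"))
  expect_true(applyGate(makeFeatureRow(mean_CD45 = 5), gs, "CTC"))
  expect_false(applyGate(makeFeatureRow(mean_CD45 = 5.0001), gs, "CTC"))
  expect_true(applyGate(makeFeatureRow(size_CK = 400, area_CK = 400), gs, "CTC"))
  expect_false(applyGate(makeFeatureRow(size_CK = 16, area_CK = 16), gs, "CTC"))
  expect_false(applyGate(makeFeatureRow(overlay_ck_dapi = 0.2), gs, "CTC"))
})

test_that("missing features raise an error rather than failing silently", {
  fv <- makeFeatureRow()
  fv$mean_CD45 <- NULL
  expect_error(applyGate(fv, defaultGateSet(), "CTC"), "mean_CD45")
})

test_that("an idealized tdEV passes the tdEV gate and fails the CTC gate", {
  set.seed(14)
  spec <- sampleObjectSpec("TDEV")
  fv <- idealizedFeatures(spec, 0.64, 2)
  gs <- defaultGateSet()
  expect_true(applyGate(fv, gs, "TDEV"))
  expect_false(applyGate(fv, gs, "CTC"))
})

test_that("enumeration labels and counts match planted ground truth", {
  r <- recoverCartridge(c(CTC_PRETTY = 5, TDEV = 20, LEUKOCYTE = 30),
                        seed = 41)
  expect_equal(unname(r$res$counts[c("ctc_accept", "tdev_accept")]), c(5, 20))
})

test_that("empty and leukocyte-only tables enumerate to zero", {
  empty <- randomFeatureTable(3)[0, ]
  expect_equal(unname(enumerateEvents(empty)$counts), c(0, 0))
  set.seed(6)
  leuks <- do.call(rbind, lapply(1:8, function(i) {
    fv <- idealizedFeatures(sampleObjectSpec("LEUKOCYTE"), 0.64, 2)
    cbind(data.frame(object_id = paste0("L", i)), fv)
  }))
  expect_equal(unname(enumerateEvents(leuks)$counts), c(0, 0))
})

test_that("duplicate object ids are rejected", {
  tab <- rbind(makeFeatureRow(), makeFeatureRow())
  expect_error(enumerateEvents(tab), "duplicate")
})

test_that("review exclusions correct only the CTC count", {
  tab <- do.call(rbind, c(lapply(1:10, function(i) makeFeatureRow()),
                          lapply(1:4, function(i) makeTdevRow())))
  tab$object_id <- sprintf("E%02d", 1:14)
  gated <- enumerateEvents(tab)
  expect_equal(unname(gated$counts), c(10, 4))
  noRev <- applyReview(gated, NULL)
  expect_equal(unname(noRev$counts["ctc_accept_corrected"]), 10)
  ann <- data.frame(object_id = c("E01", "E02", "E03"),
                    label = "EXCLUDED_ARTIFACT")
  rev <- applyReview(gated, ann)
  expect_equal(unname(rev$counts["ctc_accept_corrected"]), 7)
  expect_equal(unname(rev$counts["ctc_accept"]), 10)
  expect_equal(unname(rev$counts["tdev_accept"]), 4)
  expect_error(applyReview(gated, data.frame(object_id = "ZZZ",
                                             label = "EXCLUDED_ARTIFACT")),
               "unknown object_id")
  expect_warning(rev2 <- applyReview(gated,
                                     data.frame(object_id = "E11",
                                                label = "EXCLUDED_ARTIFACT")),
                 "tdEV")
  expect_equal(unname(rev2$counts["tdev_accept"]), 4)
})

test_that("the default gates are mutually exclusive on random feature vectors", {
  set.seed(99)
  tab <- randomFeatureTable(2000)
  gs <- defaultGateSet()
  both <- applyGate(tab, gs, "CTC") & applyGate(tab, gs, "TDEV")
  expect_false(any(both))
})

test_that("tightening any threshold never increases the passing count", {
  set.seed(100)
  tab <- randomFeatureTable(1000)
  gs <- defaultGateSet()
  base <- sum(applyGate(tab, gs, "CTC"))
  g <- predicates(gs, "CTC")
  for (i in seq_len(nrow(g))) {
    g2 <- g
    if (g2$op[i] == "gt") g2$threshold[i] <- g2$threshold[i] * 1.3 + 1
    else g2$threshold[i] <- g2$threshold[i] * 0.7
    expect_lte(sum(applyGate(tab, g2)), base)
  }
})
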