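# Channel segmentation and event merging.

blobImage <- function(centers, radius = 4, peak = 200, dim = c(64, 64),
                      bg = 2) {
  img <- matrix(bg, dim[1], dim[2])
  for (k in seq_len(nrow(centers))) {
    for (r in 1:dim[1]) for (c in 1:dim[2]) {
      d2 <- (r - centers[k, 1])^2 + (c - centers[k, 2])^2
      if (d2 <= radius^2)
        img[r, c] <- img[r, c] + peak * exp(-d2 / (2 * (radius / 2)^2))
    }
  }
  round(img)
}

test_that("constant and all-zero frames give empty masks, bad input errors", {
  expect_equal(max(segmentChannel(matrix(0, 32, 32))), 0L)
  expect_equal(max(segmentChannel(matrix(7, 32, 32))), 0L)
  expect_error(segmentChannel(array(0, c(4, 4, 2))), "2-d")
  expect_error(segmentChannel(matrix(-1, 4, 4)), "nonnegative")
})

test_that("isolated blobs segment into the reference component count", {
  one <- blobImage(cbind(30, 30))
  lab1 <- segmentChannel(one)
  # reference: connected components of the thresholded image
  expect_equal(max(lab1), max(EBImage::bwlabel(one > triangleThreshold(one))))
  expect_equal(max(lab1), 1L)
  two <- blobImage(rbind(c(20, 20), c(44, 44)))
  expect_equal(max(segmentChannel(two)), 2L)
})

test_that("components below the minimum area are removed and labels renumbered", {
  img <- blobImage(cbind(30, 30), radius = 5)
  img[5, 5] <- img[5, 6] <- 300      # 2-pixel speck
  lab <- segmentChannel(img, segmentationParams(minArea = 4))
  expect_equal(max(lab), 1L)
  expect_equal(sort(unique(as.vector(lab))), c(0L, 1L))
  lab2 <- segmentChannel(img, segmentationParams(minArea = 1))
  expect_equal(max(lab2), 2L)
})

test_that("raising the minimum area never increases the event count", {
  set.seed(21)
  gen <- generateCartridge(cartridgeConfig(frames = 1, dim = c(200, 200),
                                           objectMix = c(TDEV = 10,
                                                         LEUKOCYTE = 10)),
                           seed = 21)
  counts <- vapply(c(1L, 4L, 9L, 16L, 30L), function(a)
    length(detectEvents(gen$stack, segmentationParams(minArea = a))),
    integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("overlapping and contained channel components merge into one event", {
  m <- matrix(0L, 40, 40)
  ck <- m; ck[10:25, 10:25] <- 1L
  dapi <- m; dapi[14:20, 14:20] <- 1L
  ev <- mergeEvents(list(DAPI = dapi, PE = ck, APC = m, FITC = m))
  expect_length(ev, 1L)
  expect_gt(length(ev[[1]]$pixels$DAPI), 0)
  expect_gt(length(ev[[1]]$pixels$PE), 0)
})

test_that("disjoint far-apart components stay separate events", {
  m <- matrix(0L, 40, 40)
  ck <- m; ck[2:6, 2:6] <- 1L
  dapi <- m; dapi[30:34, 30:34] <- 1L
  ev <- mergeEvents(list(DAPI = dapi, PE = ck, APC = m, FITC = m))
  expect_length(ev, 2L)
})

test_that("pairwise-overlapping chains merge transitively (union-find oracle)", {
  m <- matrix(0L, 30, 60)
  a <- m; a[10:14, 5:20] <- 1L
  b <- m; b[10:14, 19:35] <- 1L      # overlaps a
  c_ <- m; c_[10:14, 34:50] <- 1L    # overlaps b only
  ev <- mergeEvents(list(DAPI = a, PE = b, APC = m, FITC = c_))
  expect_length(ev, 1L)
  # independent oracle: BFS over the pairwise-overlap graph
  comps <- list(which(a > 0), which(b > 0), which(c_ > 0))
  adj <- outer(1:3, 1:3, Vectorize(function(i, j)
    length(intersect(comps[[i]], comps[[j]])) > 0))
  visited <- c(TRUE, FALSE, FALSE); queue <- 1L
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    nb <- which(adj[i, ] & !visited)
    visited[nb] <- TRUE; queue <- c(queue, nb)
  }
  expect_true(all(visited))
})

test_that("gap-2 components stay separate under the default merge radius", {
  m <- matrix(0L, 30, 30)
  a <- m; a[10:14, 5:10] <- 1L
  b <- m; b[10:14, 13:18] <- 1L      # 2 background columns between
  ev <- mergeEvents(list(DAPI = a, PE = b, APC = m, FITC = m))
  expect_length(ev, 2L)
  b1 <- m; b1[10:14, 12:18] <- 1L    # 1 background column: within radius 1
  ev1 <- mergeEvents(list(DAPI = a, PE = b1, APC = m, FITC = m))
  expect_length(ev1, 1L)
})

test_that("APC/FITC components never seed an event on their own", {
  m <- matrix(0L, 30, 30)
  apc <- m; apc[5:12, 5:12] <- 1L
  fitc <- m; fitc[20:26, 20:26] <- 1L
  ev <- mergeEvents(list(DAPI = m, PE = m, APC = apc, FITC = fitc))
  expect_length(ev, 0L)
})

test_that("seed-channel foreground pixels partition into exactly one event", {
  gen <- generateCartridge(cartridgeConfig(frames = 1, dim = c(220, 220),
                                           objectMix = c(CTC_PRETTY = 2,
                                                         TDEV = 8,
                                                         LEUKOCYTE = 10)),
                           seed = 13)
  params <- segmentationParams()
  masks <- setNames(lapply(1:4, function(ci)
    segmentChannel(gen$stack@frames[[1]][, , ci], params)), CHANNELS)
  ev <- mergeEvents(masks, params = params)
  for (ch in c("DAPI", "PE")) {
    fg <- which(masks[[ch]] > 0)
    claimed <- unlist(lapply(ev, function(e) e$pixels[[ch]]))
    expect_equal(sort(claimed), sort(fg))       # every pixel exactly once
    expect_equal(anyDuplicated(claimed), 0L)
  }
})

test_that("noise-free cartridges are recovered object-for-object across seeds", {
  mix <- c(CTC_PRETTY = 2, CTC_CLUSTER = 1, TDEV = 8, LEUKOCYTE = 10,
           DEBRIS = 2)
  for (seed in c(2, 19, 57)) {
    gen <- generateCartridge(cartridgeConfig(frames = 2, dim = c(220, 220),
                                             objectMix = mix), seed = seed)
    ev <- detectEvents(gen$stack)
    expect_length(ev, nrow(gen$groundTruth))
  }
})
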