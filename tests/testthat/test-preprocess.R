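# builds a tiny Visium-style slide fully in code
makeSlide <- function(rows, cols, counts, genes = NULL, inTissue = NULL) {
  n <- length(rows)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(counts)))
  if (is.null(inTissue)) inTissue <- rep(1L, n)
  list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                            "CsparseMatrix"),
       geneIds = genes,
       barcodes = paste0("BC", seq_len(n)),
       positions = data.frame(barcode = paste0("BC", seq_len(n)),
                              in_tissue = inTissue, array_row = rows,
                              array_col = cols))
}

test_that("hex coordinates map onto an injective square grid", {
  pos <- data.frame(barcode = c("a", "b"), in_tissue = 1L,
                    array_row = c(0L, 1L), array_col = c(4L, 5L))
  out <- hexToSquare(pos)
  expect_equal(out$y, c(0L, 1L))
  expect_equal(out$x, c(2L, 2L))
  # a full synthetic slide: every Visium position, mapping stays injective
  grid <- expand.grid(array_row = 0:7, array_col = 0:15)
  grid <- grid[(grid$array_col - grid$array_row %% 2) %% 2 == 0, ]
  grid$barcode <- paste0("s", seq_len(nrow(grid)))
  grid$in_tissue <- 1L
  mapped <- hexToSquare(grid)
  expect_false(anyDuplicated(mapped[, c("y", "x")]) > 0)
  # parity violation is a data error naming the spot
  bad <- data.frame(barcode = "oops", in_tissue = 1L, array_row = 1L,
                    array_col = 4L)
  expect_error(hexToSquare(bad), "oops")
})

test_that("square-grid input passes through unchanged", {
  pos <- data.frame(barcode = c("a", "b"), in_tissue = 1L,
                    array_row = c(1L, 2L), array_col = c(3L, 4L))
  out <- hexToSquare(pos, grid = "square")
  expect_equal(out$y, c(1L, 2L))
  expect_equal(out$x, c(3L, 4L))
})

test_that("tensor assembly places counts and crops empty border rows", {
  slide <- makeSlide(rows = 0L, cols = 0L,
                     counts = matrix(7, 1, 1, dimnames = NULL))
  built <- buildTensor(slide, grid = "square")
  expect_identical(dim(built$tensor), c(1L, 1L, 1L))
  expect_equal(tensorValues(built$tensor)[1, 1, 1], 7)
  # first grid row carries no in-tissue spot -> absent from the tensor
  slide2 <- makeSlide(rows = c(2L, 3L), cols = c(0L, 1L),
                      counts = matrix(c(1, 2, 3, 4), 2, 2))
  built2 <- buildTensor(slide2, grid = "square")
  expect_identical(dim(built2$tensor)[1:2], c(2L, 2L))
  expect_equal(tensorValues(built2$tensor)[1, 1, ], c(1, 2))
  expect_equal(tensorValues(built2$tensor)[2, 2, ], c(3, 4))
  # collision is a data error
  slide3 <- makeSlide(rows = c(0L, 0L), cols = c(0L, 0L),
                      counts = matrix(1, 1, 2))
  expect_error(buildTensor(slide3, grid = "square"), "same grid cell")
})

test_that("a 5x5 slide roundtrips counts through the tensor", {
  set.seed(70)
  grid <- expand.grid(r = 0:4, c = 0:4)
  counts <- matrix(rpois(3 * 25, 4), 3, 25)
  slide <- makeSlide(grid$r, grid$c, counts)
  built <- buildTensor(slide, grid = "square")
  v <- tensorValues(built$tensor)
  for (s in seq_len(25))
    expect_equal(v[grid$r[s] + 1, grid$c[s] + 1, ], counts[, s])
  expect_true(all(built$inTissue))
})

test_that("count filtering applies the entry and gene thresholds in order", {
  # gene 1: entries (2,1,0) -> all below 3 -> zeroed -> total 0 < 4 -> gone
  # gene 2: single entry 4  -> kept
  # gene 3: entries (3,3,0) -> kept (total 6)
  v <- array(0, c(3, 1, 3))
  v[, 1, 1] <- c(2, 1, 0)
  v[, 1, 2] <- c(4, 0, 0)
  v[, 1, 3] <- c(3, 3, 0)
  st <- SpatialTensor(v, geneIds = c("a", "b", "c"))
  f <- filterCounts(st)
  expect_identical(geneIds(f), c("b", "c"))
  expect_equal(tensorValues(f)[, 1, 1], c(4, 0, 0))
  expect_equal(tensorValues(f)[, 1, 2], c(3, 3, 0))
  # boundary behaviour: entry 2 -> 0, entry 3 -> 3
  v2 <- array(c(2, 3, 4), c(3, 1, 1))
  f2 <- filterCounts(SpatialTensor(v2))
  expect_equal(as.numeric(tensorValues(f2)), c(0, 3, 4))
  # all-pass input unchanged, and refiltering is a no-op
  v3 <- array(5, c(2, 2, 2))
  f3 <- filterCounts(SpatialTensor(v3))
  expect_equal(tensorValues(f3), v3)
  expect_equal(tensorValues(filterCounts(f3)), tensorValues(f3))
})

test_that("log transform is log1p, zero-preserving and monotone", {
  v <- array(c(0, exp(1) - 1, 3, 9), c(4, 1, 1))
  lt <- logTransform(SpatialTensor(v))
  expect_equal(as.numeric(tensorValues(lt)), log1p(as.numeric(v)))
  expect_equal(tensorValues(lt)[1, 1, 1], 0)
  expect_equal(tensorValues(lt)[2, 1, 1], 1)
  set.seed(71)
  r <- array(runif(24, 0, 10), c(2, 3, 4))
  expect_identical(order(as.numeric(logTransform(r))), order(as.numeric(r)))
  expect_error(logTransform(array(-1, c(1, 1, 1))), "negative")
})

test_that("mask modes mark nonzero entries or whole in-tissue spots", {
  v <- array(c(0, 2, 0, 5), c(2, 1, 2))
  m <- buildMask(v, "nonzero")
  expect_equal(as.numeric(m), c(0, 1, 0, 1))
  inT <- matrix(c(TRUE, FALSE), 2, 1)
  m2 <- buildMask(v, "in-tissue", inTissue = inT)
  expect_equal(as.numeric(m2), c(1, 0, 1, 0))
  expect_error(buildMask(v, "in-tissue"), "inTissue")
})

test_that("full pipeline runs hex -> tensor -> filter -> log -> mask", {
  set.seed(72)
  # hex slide, 4 rows x 4 columns of spots
  grid <- expand.grid(array_row = 0:3, array_col = 0:7)
  grid <- grid[(grid$array_col - grid$array_row %% 2) %% 2 == 0, ]
  n <- nrow(grid)
  counts <- matrix(rpois(6 * n, 3), 6, n)
  slide <- makeSlide(grid$array_row, grid$array_col, counts)
  prep <- preprocessSpots(slide)
  st <- prep$tensor
  expect_s4_class(st, "SpatialTensor")
  expect_true(all(tensorValues(st) >= 0))
  expect_equal(tensorMask(st), buildMask(st, "nonzero"))
  # values are log1p of thresholded counts: all entries either 0 or >= log1p(3)
  v <- tensorValues(st)
  expect_true(all(v == 0 | v >= log1p(3) - 1e-12))
})

test_that("tensor container files roundtrip values, genes and mask", {
  sim <- simulateSpatialData(shape = c(5, 4, 6), rank = c(2, 2, 2), seed = 73)
  stem <- file.path(withr::local_tempdir(), "t")
  writeSpatialTensor(sim$tensor, stem)
  back <- readSpatialTensor(stem)
  expect_equal(tensorValues(back), tensorValues(sim$tensor),
               tolerance = 1e-12)
  expect_identical(geneIds(back), geneIds(sim$tensor))
  expect_equal(tensorMask(back), tensorMask(sim$tensor))
})

test_that("10x-style files load and align counts to positions by barcode", {
  dir <- withr::local_tempdir()
  counts <- Matrix::Matrix(matrix(c(0, 4, 3, 0, 5, 1), 2, 3), sparse = TRUE)
  Matrix::writeMM(counts, file.path(dir, "m.mtx"))
  writeLines(c("geneA\tGeneA\tExpr", "geneB\tGeneB\tExpr"),
             file.path(dir, "features.tsv"))
  writeLines(c("BC1", "BC2", "BC3"), file.path(dir, "barcodes.tsv"))
  # positions deliberately out of barcode order
  writeLines(c("BC3,1,0,2,10,10", "BC1,1,0,0,0,0", "BC2,1,1,1,5,5"),
             file.path(dir, "positions.csv"))
  spots <- readSpotCounts(file.path(dir, "m.mtx"), file.path(dir, "features.tsv"),
                          file.path(dir, "barcodes.tsv"),
                          file.path(dir, "positions.csv"))
  expect_identical(spots$positions$barcode, c("BC1", "BC2", "BC3"))
  built <- buildTensor(spots, grid = "hex")
  v <- tensorValues(built$tensor)
  expect_equal(v[1, 1, ], c(0, 4))   # BC1 at (0,0)
  expect_equal(v[2, 1, ], c(3, 0))   # BC2 at (1,0)
  expect_equal(v[1, 2, ], c(5, 1))   # BC3 at (0,1)
})
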