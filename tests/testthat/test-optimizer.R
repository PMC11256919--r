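test_that("objective matches the from-definition dense oracle", {
  set.seed(31)
  d <- c(4, 5, 3); r <- c(2, 2, 2)
  T <- randomTensor(d)
  M <- array(rbinom(prod(d), 1, 0.6), d)
  gs <- makeGraphSet(d[1], d[2], randomGeneAdjacency(d[3], p = 0.5, seed = 31))
  m <- randomModel(d, r, seed = 32)
  for (lam in c(0, 0.7)) {
    got <- tuckerObjective(T, M, m, gs, lam)
    expect_equal(unname(got["total"]),
                 objectiveOracle(T, M, m@core, m@Ay, m@Ax, m@Ag, gs, lam),
                 tolerance = 1e-10)
    expect_equal(unname(got["total"]),
                 unname(got["F1"] + lam * got["F2"]), tolerance = 1e-12)
  }
})

test_that("objective edge cases: perfect fit and empty mask", {
  m <- randomModel(c(3, 4, 2), c(2, 2, 2), seed = 33)
  T <- tuckerReconstruct(m)
  gs <- makeGraphSet(3, 4, 2)
  o <- tuckerObjective(T, NULL, m, gs, 0)
  expect_equal(unname(o["F1"]), 0, tolerance = 1e-20)
  expect_equal(unname(o["total"]), 0, tolerance = 1e-20)
  o0 <- tuckerObjective(T + 5, array(0, dim(T)), m, gs, 0)
  expect_equal(unname(o0["F1"]), 0)
})

test_that("analytic gradient split matches central finite differences", {
  set.seed(35)
  d <- c(4, 5, 3); r <- c(2, 2, 2)
  T <- randomTensor(d)
  M <- array(rbinom(prod(d), 1, 0.7), d)
  gadj <- randomGeneAdjacency(d[3], p = 0.6, seed = 36)
  gs <- makeGraphSet(d[1], d[2], gadj)
  split <- lapply(list(gs@Ly, gs@Lx, gs@Lg), SpatialTucker:::.splitLaplacian)
  A <- list(matrix(runif(8), 4, 2), matrix(runif(10), 5, 2),
            matrix(runif(6), 3, 2))
  core <- array(runif(8), r)
  for (lam in c(0, 0.5)) {
    for (mode in 1:4) {
      g <- SpatialTucker:::.gradParts(mode, core, A, M * T, M, split, lam)
      num <- finiteDiffGrad(T, M, core, A, gs, lam, mode)
      expect_lt(max(abs((g$pos - g$neg) - num)) / max(abs(num)), 1e-5)
    }
  }
})

test_that("multiplicative updates keep exact zeros at zero", {
  set.seed(40)
  d <- c(5, 4, 6); r <- c(2, 2, 2)
  sim <- simulateSpatialData(shape = d, rank = r, seed = 40)
  T <- tensorValues(sim$tensor)
  gs <- makeGraphSet(d[1], d[2], d[3])
  split <- lapply(list(gs@Ly, gs@Lx, gs@Lg), SpatialTucker:::.splitLaplacian)
  A <- list(matrix(runif(10), 5, 2), matrix(runif(8), 4, 2),
            matrix(runif(12), 6, 2))
  A[[1]][c(1, 4, 7)] <- 0
  core <- array(runif(8), r)
  core[c(2, 5)] <- 0
  g <- SpatialTucker:::.gradParts(1L, core, A, T, NULL, split, 0.3)
  A1 <- A[[1]] * g$neg / (g$pos + 1e-12)
  expect_identical(A1[c(1, 4, 7)], c(0, 0, 0))
  g4 <- SpatialTucker:::.gradParts(4L, core, A, T, NULL, split, 0.3)
  core2 <- core * g4$neg / (g4$pos + 1e-12)
  expect_identical(core2[c(2, 5)], c(0, 0))
})

test_that("a perfect masked fit is a stationary point of the lambda=0 update", {
  m <- randomModel(c(4, 4, 5), c(2, 2, 2), seed = 41)
  T <- tuckerReconstruct(m)
  gs <- makeGraphSet(4, 4, 5)
  split <- lapply(list(gs@Ly, gs@Lx, gs@Lg), SpatialTucker:::.splitLaplacian)
  A <- list(m@Ay, m@Ax, m@Ag)
  for (mode in 1:3) {
    g <- SpatialTucker:::.gradParts(mode, m@core, A, T, NULL, split, 0)
    ratio <- g$neg / (g$pos + 1e-12)
    expect_equal(ratio, array(1, dim(ratio)), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  g4 <- SpatialTucker:::.gradParts(4L, m@core, A, T, NULL, split, 0)
  expect_equal(g4$neg / (g4$pos + 1e-12), array(1, dim(m@core)),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("normalization preserves the reconstruction and unit column sums", {
  m <- randomModel(c(5, 6, 4), c(2, 3, 2), seed = 42)
  n <- normalizeModel(m)
  expect_lt(max(abs(tuckerReconstruct(m) - tuckerReconstruct(n))), 1e-10)
  for (mode in 1:3)
    expect_equal(colSums(tuckerFactor(n, mode)),
                 rep(1, ncol(tuckerFactor(n, mode))), tolerance = 1e-9,
                 ignore_attr = TRUE)
  # already-normalized model is a fixed point
  n2 <- normalizeModel(n)
  expect_equal(n2@Ay, n@Ay, tolerance = 1e-12)
  expect_equal(n2@core, n@core, tolerance = 1e-12)
})

test_that("normalization absorbs column sums into the core", {
  # single component: factor column (2,2) with core weight 3 -> column
  # (0.5,0.5) and core weight 3*4=12 along that mode
  m <- TuckerModel(array(3, c(1, 1, 1)), matrix(c(2, 2), 2, 1),
                   matrix(1, 2, 1), matrix(1, 2, 1))
  n <- normalizeModel(m)
  expect_equal(as.numeric(n@Ay), c(0.5, 0.5))
  # x and gene columns (1,1) also rescale: total core 3*4*2*2 = 48
  expect_equal(as.numeric(n@core), 48)
  expect_equal(tuckerReconstruct(n), tuckerReconstruct(m), tolerance = 1e-12)
})

test_that("normalization leaves all-zero columns untouched with a warning", {
  m <- randomModel(c(4, 4, 4), c(2, 2, 2), seed = 43)
  m@Ay[, 2] <- 0
  expect_warning(n <- normalizeModel(m), "all-zero")
  expect_identical(n@Ay[, 2], rep(0, 4))
  expect_lt(max(abs(tuckerReconstruct(m) - tuckerReconstruct(n))), 1e-10)
})

test_that("fit is bitwise deterministic given the seed", {
  sim <- simulateSpatialData(shape = c(8, 7, 10), rank = c(2, 2, 2), seed = 50)
  f1 <- fitSpatialTucker(sim$tensor, graphs = sim$network, rank = c(2, 2, 2),
                         lambda = 0.1, maxIter = 40, tol = 0, seed = 9)
  f2 <- fitSpatialTucker(sim$tensor, graphs = sim$network, rank = c(2, 2, 2),
                         lambda = 0.1, maxIter = 40, tol = 0, seed = 9)
  expect_identical(objectiveTrace(f1), objectiveTrace(f2))
  expect_identical(f1@model@core, f2@model@core)
  f3 <- fitSpatialTucker(sim$tensor, graphs = sim$network, rank = c(2, 2, 2),
                         lambda = 0.1, maxIter = 40, tol = 0, seed = 10)
  expect_false(identical(objectiveTrace(f1), objectiveTrace(f3)))
})

test_that("masked entries have zero influence on the fit", {
  sim <- simulateSpatialData(shape = c(8, 7, 10), rank = c(2, 2, 2), seed = 51)
  T <- tensorValues(sim$tensor)
  M <- tensorMask(sim$tensor)
  f1 <- fitSpatialTucker(T, mask = M, rank = c(2, 2, 2), lambda = 0.1,
                         maxIter = 30, tol = 0, seed = 1)
  T2 <- T
  T2[M == 0] <- T2[M == 0] + 99  # arbitrary garbage at unobserved entries
  f2 <- fitSpatialTucker(T2, mask = M, rank = c(2, 2, 2), lambda = 0.1,
                         maxIter = 30, tol = 0, seed = 1)
  expect_identical(f1@model@core, f2@model@core)
  expect_identical(f1@model@Ay, f2@model@Ay)
})

test_that("the lambda=0 path ignores the graphs entirely", {
  sim <- simulateSpatialData(shape = c(8, 7, 10), rank = c(2, 2, 2), seed = 52)
  f1 <- fitSpatialTucker(sim$tensor, graphs = sim$network, rank = c(2, 2, 2),
                         lambda = 0, maxIter = 30, tol = 0, seed = 3)
  f2 <- fitSpatialTucker(sim$tensor, graphs = NULL, rank = c(2, 2, 2),
                         lambda = 0, maxIter = 30, tol = 0, seed = 3)
  expect_identical(f1@model@core, f2@model@core)
  expect_identical(f1@model@Ag, f2@model@Ag)
})

test_that("fit validates rank and records a consistent trace", {
  sim <- simulateSpatialData(shape = c(6, 6, 8), rank = c(2, 2, 2), seed = 53)
  expect_error(fitSpatialTucker(sim$tensor, rank = c(7, 2, 2), maxIter = 5),
               "exceeds")
  expect_error(fitSpatialTucker(sim$tensor, rank = c(0, 2, 2), maxIter = 5),
               "positive")
  f <- fitSpatialTucker(sim$tensor, graphs = sim$network, rank = c(2, 2, 2),
                        lambda = 0.2, maxIter = 25, tol = 0, seed = 2)
  tr <- objectiveTrace(f)
  expect_lte(nrow(tr), 25)
  expect_equal(tr[, "total"], tr[, "F1"] + 0.2 * tr[, "F2"],
               tolerance = 1e-8)
  m <- fittedModel(f)
  expect_true(all(m@core >= 0) && all(m@Ay >= 0) && all(m@Ax >= 0) &&
                all(m@Ag >= 0))
  expect_true(all(imputeExpression(f) >= 0))
})

test_that("convergence tolerance stops the fit early", {
  sim <- simulateSpatialData(shape = c(8, 8, 10), rank = c(2, 2, 2),
                             noise = 0, density = 1, seed = 54)
  f <- fitSpatialTucker(sim$tensor, rank = c(2, 2, 2), lambda = 0,
                        maxIter = 5000, tol = 1e-4, seed = 1)
  expect_true(f@converged)
  expect_lt(f@nIter, 5000)
})
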