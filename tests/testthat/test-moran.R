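test_that("global Moran's I: expectation, checkerboard, path graph and
           brute-force oracle", {
  # expected value is -1/(N-1) for any N
  for (n in c(4, 10, 31)) {
    set.seed(n)
    co <- make_coordinates(n, "grid")
    W <- inverse_distance_weights(co)
    expect_equal(global_moran(rnorm(n), W)$expected, -1 / (n - 1))
  }
  # 2x2 rook checkerboard: perfect negative autocorrelation
  A <- matrix(0, 4, 4)
  A[1, 2] <- A[2, 1] <- A[1, 3] <- A[3, 1] <- 1
  A[2, 4] <- A[4, 2] <- A[3, 4] <- A[4, 3] <- 1
  W <- spatial_weights(A)
  expect_equal(global_moran(c(1, -1, -1, 1), W)$I, -1)
  # path graph 1-2-3-4, x = 1..4, hand-computable double sum
  P <- matrix(0, 4, 4)
  P[1, 2] <- P[2, 1] <- P[2, 3] <- P[3, 2] <- P[3, 4] <- P[4, 3] <- 1
  x <- 1:4
  # deviations (-1.5,-.5,.5,1.5); sum_ij w_ij z_i z_j = 2(.75-.25+.75)=2.5
  # I = (4/6)*2.5/5 = 1/3
  expect_equal(global_moran(x, spatial_weights(P))$I, 1 / 3)
  expect_equal(global_moran(x, spatial_weights(P))$I,
               oracle_moran(x, P))

  set.seed(77)
  for (r in 1:100) {
    n <- sample(4:12, 1)
    M <- matrix(runif(n * n), n, n); diag(M) <- 0
    x <- rnorm(n)
    expect_equal(global_moran(x, spatial_weights(M))$I, oracle_moran(x, M),
                 tolerance = 1e-10)
  }
})

test_that("Moran's I is invariant to affine transformations of x", {
  set.seed(9)
  co <- make_coordinates(10, "random", seed = 10)
  W <- inverse_distance_weights(co, "row")
  x <- rnorm(10)
  I0 <- global_moran(x, W)$I
  expect_equal(global_moran(3.7 * x - 11, W)$I, I0, tolerance = 1e-12)
  expect_equal(global_moran(-2 * x, W)$I, I0, tolerance = 1e-12)
  expect_error(global_moran(rep(1, 10), W), "constant")
})

test_that("inference: closed-form sd positive, permutation detects
           clustering, null z is centred", {
  W <- lattice31()
  set.seed(13)
  x <- rnorm(31)
  for (m in c("randomization", "normality")) {
    mt <- moran_test(x, W, m)
    expect_gt(mt$sd, 0)
    expect_equal(mt$z, (mt$I - mt$expected) / mt$sd)
  }
  # two-block clustered field: strong positive autocorrelation
  co <- make_coordinates(20, "grid")
  W20 <- grid_contiguity_weights(co, "row")
  blocks <- as.data.frame(co)$x <= 2
  set.seed(14)
  xc <- ifelse(blocks, 2, -2) + rnorm(20, 0, 0.3)
  mt <- moran_test(xc, W20, "permutation", nsim = 999, seed = 15)
  expect_lt(mt$p, 0.01)
  expect_error(moran_test(xc, W20, "permutation", nsim = 50), "99")

  # null calibration: z roughly centred over 200 random fields
  set.seed(16)
  zs <- replicate(200, moran_test(rnorm(31), W, "randomization")$z)
  expect_lt(abs(mean(zs)), 0.2)
})

test_that("permutation p-values are approximately super-uniform under the
           null (stochastic)", {
  W <- lattice31()
  set.seed(17)
  ps <- replicate(200, moran_test(rnorm(31), W, "permutation", nsim = 199)$p)
  ks <- suppressWarnings(stats::ks.test(ps, "punif", alternative =
                                          "greater"))
  expect_gt(ks$p.value, 0.01)
})

test_that("local Moran: additivity identity, cluster labels and constructed
           hot block", {
  set.seed(18)
  for (r in 1:20) {
    n <- sample(5:10, 1)
    M <- matrix(runif(n * n), n, n); diag(M) <- 0
    x <- rnorm(n)
    lm_ <- local_moran(x, spatial_weights(M), nsim = 99, seed = r)
    gm <- global_moran(x, M)
    expect_equal(sum(lm_$Ii), gm$I * gm$S0, tolerance = 1e-9)
  }
  # hot block of 5 mutually near high-value units among 20
  co <- make_coordinates(20, "grid")
  W20 <- grid_contiguity_weights(co, "row")
  hot <- c(1, 2, 6, 7, 11)       # contiguous corner cells on the 5x4 grid
  set.seed(19)
  x <- rnorm(20, 0, 0.2); x[hot] <- x[hot] + 3
  lm_ <- local_moran(x, W20, alpha = 0.05, nsim = 499, seed = 20,
                     alternative = "greater")
  # units whose whole neighbourhood lies in the hot block are labelled HH;
  # block-edge cells with mixed neighbourhoods sit near the threshold
  expect_true(all(lm_$cluster[c(1, 6)] == "HH"))
  expect_true(all(lm_$Ii[hot[1:4]] > 0))
  # a low unit surrounded by high neighbours is LH when significant
  x2 <- rep(2, 20); x2[8] <- -3; x2 <- x2 + rnorm(20, 0, 0.05)
  lm2 <- local_moran(x2, W20, alpha = 0.10, nsim = 499, seed = 21)
  expect_true(lm2$cluster[8] %in% c("LH", "NS"))
  sig <- lm2$p < 0.10
  expect_true(all(lm2$cluster[!sig] == "NS"))
})

test_that("quadrant classification crosses mean-centred axes with ties low", {
  ch <- c(a = 2, b = 0.5, c = 0.4, d = 3)
  ef <- c(a = 0.9, b = 0.8, c = 0.2, d = 0.3)
  q <- quadrant_classify(ch, ef)
  expect_equal(as.character(q), c("I", "II", "III", "IV"))
  same <- c(a = 1, b = 1, c = 1)
  expect_true(all(quadrant_classify(same, same) == "III"))
  expect_error(quadrant_classify(ch, ef[1:3]), "differ")
})

test_that("fixture quadrants: 20 provinces in I+III in 2016 and the three
           northeastern provinces in III every year", {
  t2 <- load_fixture("table2_chrdi")
  t4 <- load_fixture("table4_efficiency")
  for (yr in 2016:2020) {
    ch <- with(t2[t2$year == yr, ], setNames(chrdi, unit_id))
    ef <- with(t4[t4$year == yr, ], setNames(corrected, unit_id))
    q <- quadrant_classify(ch, ef)
    if (yr == 2016)
      expect_equal(sum(q %in% c("I", "III")), 20)
    expect_true(all(q[c("Jilin", "Liaoning", "Heilongjiang")] == "III"))
  }
})
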