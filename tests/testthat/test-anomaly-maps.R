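test_that("residual maps keep positive deviations only", {
  a <- array(c(2, 5, 1, 1, 1, 1, 1, 1), c(2, 2, 2))
  b <- array(c(5, 2, 1, 1, 1, 1, 1, 1), c(2, 2, 2))
  m <- residual_map(a, b)
  expect_identical(m$kind, "residual")
  expect_equal(m$scores[1, 1, 1], 0)     # negative residual suppressed
  expect_equal(m$scores[2, 1, 1], 3)
  expect_true(all(residual_map(a, a)$scores == 0))
  expect_error(residual_map(a, array(0, c(2, 2, 3))), "mismatch")
})

test_that("the bandwidth rule matches its formula and floors at h_min", {
  # sigma = 0 always floors
  expect_equal(silverman_bandwidth(0, 10), 0.05)
  # direct evaluation
  expect_equal(silverman_bandwidth(1, 100), (4 / 300)^(1 / 5))
  # analytic inversion: sigma chosen so the formula gives exactly 1
  n <- 12
  expect_equal(silverman_bandwidth((3 * n / 4)^(1 / 5), n), 1, tolerance = 1e-12)
  # 1000 random (sigma, n) against independent log-domain arithmetic
  set.seed(41)
  sig <- runif(1000, 0, 3); ns <- sample(2:500, 1000, TRUE)
  h <- vapply(seq_len(1000), function(i) silverman_bandwidth(sig[i], ns[i]), 0)
  ref <- pmax(exp((log(4) + 5 * log(sig) - log(3 * ns)) / 5), 0.05)
  expect_lt(max(abs(h - ref)), 1e-12)
  expect_true(all(h >= 0.05))
  expect_error(silverman_bandwidth(-1, 5), ">= 0")
})

test_that("kde_log_score matches closed forms and a direct-summation oracle", {
  h <- 0.3
  # single sample at the evaluation point: log of the kernel mode / h
  expect_equal(kde_log_score(1.2, 1.2, h), log(1 / (h * sqrt(2 * pi))))
  # symmetry of a symmetric sample set
  expect_equal(kde_log_score(0.7, c(-2, 2), h), kde_log_score(-0.7, c(-2, 2), h))
  set.seed(11)
  for (i in 1:20) {
    xs <- rnorm(50); x <- rnorm(1); hh <- runif(1, 0.05, 1)
    direct <- log(sum(dnorm((x - xs) / hh)) / (50 * hh))
    expect_equal(kde_log_score(x, xs, hh), direct, tolerance = 1e-10)
  }
  expect_error(kde_log_score(0, 1:3, 0), "> 0")
})

test_that("log-domain evaluation survives far tails where direct summation dies", {
  v <- kde_log_score(60, rnorm(20), 0.05)
  expect_true(is.finite(v))
  expect_lt(v, -1e4)
})

test_that("each voxel's fitted density integrates to one", {
  set.seed(13)
  for (i in 1:5) {
    xs <- rnorm(16, sd = runif(1, 0.01, 0.5))
    hh <- silverman_bandwidth(sqrt(mean((xs - mean(xs))^2)), 16)
    grid <- seq(min(xs) - 8, max(xs) + 8, length.out = 4001)
    f <- exp(vapply(grid, kde_log_score, 0, samples = xs, h = hh))
    expect_equal(sum(f) * diff(grid[1:2]), 1, tolerance = 1e-3)
  }
})

test_that("anomaly scores rise monotonically away from a unimodal sample set", {
  xs <- rnorm(30, 1, 0.2)
  h <- 0.15
  d <- seq(0, 3, by = 0.1)
  sc <- -vapply(mean(xs) + d, kde_log_score, 0, samples = xs, h = h)
  expect_true(all(diff(sc) >= -1e-9))
})

test_that("bimodal reconstruction distributions are honoured", {
  xs <- c(rep(0, 8), rep(1, 8))
  h <- 0.1
  mid <- -kde_log_score(0.5, xs, h)
  at_mode <- -kde_log_score(0, xs, h)
  expect_gt(mid, at_mode)   # a z-score map would invert this
})

test_that("kde_anomaly_map equals the voxel-loop brute force", {
  set.seed(19)
  dims <- c(6, 5, 4)      # bare arrays: the scorer is shape-agnostic
  x <- array(runif(prod(dims)), dims)
  members <- lapply(1:6, function(i) array(runif(prod(dims)), dims))
  m <- kde_anomaly_map(x, members, h_min = 0.05, positive_only = FALSE)
  mp <- kde_anomaly_map(x, members, h_min = 0.05)
  for (v in sample(prod(dims), 40)) {
    xs <- vapply(members, function(mm) mm[v], 0)
    sig <- sqrt(mean((xs - mean(xs))^2))
    hh <- max((4 * sig^5 / (3 * 6))^(1 / 5), 0.05)
    ref <- -log(sum(dnorm((x[v] - xs) / hh)) / (6 * hh))
    expect_equal(m$scores[v], ref, tolerance = 1e-10)
    # default mode clamps the observation at the ensemble mean from below
    refp <- -log(sum(dnorm((max(x[v], mean(xs)) - xs) / hh)) / (6 * hh))
    expect_equal(mp$scores[v], refp, tolerance = 1e-10)
  }
  expect_true(all(m$params$h >= 0.05))
  expect_error(kde_anomaly_map(x, members[1]), "n >= 2")
})

test_that("an observation equal to every member sits at the score minimum", {
  dims <- c(8, 8, 8)
  x <- volume(array(0.4, dims))
  members <- lapply(1:5, function(i) volume(array(0.4, dims)))
  m <- kde_anomaly_map(x, members)
  shifted <- kde_anomaly_map(volume(array(0.55, dims)), members)
  expect_true(all(m$scores < shifted$scores))
})

test_that("lesion voxels score deep in the density tail on fixture phantoms", {
  fit <- fixture_fit()
  ph <- fixture_cases(1, seed_base = 970L)[[1]]
  ens <- generate_ensemble(ph$pet, ph$ct, fit$codec_pet, fit$codec_ct,
                           fit$lm_cond, t = 0.01, n = 8, seed = 3)
  m <- kde_anomaly_map(ph$pet, ens)
  background <- ph$body & !ph$lesion_mask & ph$organ_labels == 0
  expect_gt(mean(m$scores[ph$lesion_mask]), mean(m$scores[background]))
})
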