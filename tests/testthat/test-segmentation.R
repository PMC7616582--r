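test_that("thresholding uses the >= convention", {
  m <- array(c(0, 3, 5, 0, 0, 0, 0, 0), c(2, 2, 2))
  s <- threshold_map(m, 3)
  expect_identical(as.vector(s$mask)[1:3], c(FALSE, TRUE, TRUE))
  expect_true(all(threshold_map(m, -Inf)$mask))
  expect_false(any(threshold_map(m, max(m) + 1)$mask))
})

test_that("connected-component labelling respects the connectivity choice", {
  mask <- array(FALSE, c(4, 4, 1))
  mask[1, 1, 1] <- TRUE; mask[2, 2, 1] <- TRUE   # diagonal contact
  expect_equal(max(label_components(mask, 26)), 1)
  expect_equal(max(label_components(mask, 6)), 2)
  expect_equal(max(label_components(array(FALSE, c(3, 3, 3)))), 0)
})

test_that("growing absorbs plateaus above 40% of the component maximum", {
  pet <- array(3, c(5, 5, 1))
  pet[3, 3, 1] <- 10
  seed <- array(FALSE, c(5, 5, 1)); seed[3, 3, 1] <- TRUE
  # plateau of 3s: 3 < 4, untouched
  g <- grow_to_clinical(seed, pet)
  expect_identical(g$mask, seed)
  pet5 <- array(5, c(5, 5, 1)); pet5[3, 3, 1] <- 10
  g5 <- grow_to_clinical(seed, pet5)
  expect_true(all(g5$mask))              # 5 >= 4: plateau absorbed
})

test_that("separate components grow with their own 40% levels", {
  pet <- array(0, c(9, 3, 1))
  pet[1:3, , 1] <- 4; pet[2, 2, 1] <- 10    # lesion A: level 4
  pet[7:9, , 1] <- 1.5; pet[8, 2, 1] <- 3   # lesion B: level 1.2
  seed <- array(FALSE, dim(pet)); seed[2, 2, 1] <- TRUE; seed[8, 2, 1] <- TRUE
  g <- grow_to_clinical(seed, pet)$mask
  expect_true(all(g[1:3, , 1]))     # A absorbs its 4-plateau (4 >= 4)
  expect_true(all(g[7:9, , 1]))     # B absorbs its 1.5-plateau (1.5 >= 1.2)
  expect_false(any(g[4:6, , 1]))    # the gap stays empty
  # with only lesion A seeded, B's region is untouched: per-component rule
  seedA <- array(FALSE, dim(pet)); seedA[2, 2, 1] <- TRUE
  gA <- grow_to_clinical(seedA, pet)$mask
  expect_false(any(gA[7:9, , 1]))
})

test_that("growing matches the brute-force oracle on random fixtures", {
  for (s in 1:15) {
    cs <- rand_grow_case(s)
    got <- grow_to_clinical(cs$mask, cs$pet)$mask
    expect_identical(got, grow_oracle(cs$mask, cs$pet))
  }
})

test_that("growing is monotone and idempotent", {
  for (s in 16:40) {
    cs <- rand_grow_case(s)
    g1 <- grow_to_clinical(cs$mask, cs$pet)
    expect_true(all(g1$mask[cs$mask]))            # output contains input
    g2 <- grow_to_clinical(g1, cs$pet)
    expect_identical(g2$mask, g1$mask)            # fixed point
  }
  empty <- array(FALSE, c(5, 5, 5))
  expect_identical(grow_to_clinical(empty, array(1, c(5, 5, 5)))$mask, empty)
})

test_that("dice handles agreement, disjointness and the empty-empty case", {
  a <- array(FALSE, c(4, 4, 4)); a[1:2, 1, 1] <- TRUE
  b <- a
  expect_equal(dice(a, b), 1)
  d <- array(FALSE, c(4, 4, 4)); d[4, 4, 4] <- TRUE
  expect_equal(dice(a, d), 0)
  x <- array(FALSE, c(4, 4, 4)); x[1:4, 1, 1] <- TRUE
  y <- array(FALSE, c(4, 4, 4)); y[3:4, 1:2, 1] <- TRUE
  expect_equal(dice(x, y), 0.5)          # |x|=4, |y|=4, overlap 2
  e <- array(FALSE, c(4, 4, 4))
  expect_equal(dice(e, e), 1)
  expect_error(dice(a, array(FALSE, c(4, 4, 5))), "mismatch")
})

test_that("best_dice equals exhaustive search over all distinct values", {
  set.seed(3)
  m <- array(sample(seq(0, 1, by = 0.05), 1000, TRUE), c(10, 10, 10))
  truth <- m >= 0.8
  bd <- best_dice(m, truth, grid_size = 5000)
  vals <- sort(unique(as.vector(m)))
  oracle <- vapply(vals, function(tau) dice(m >= tau, truth), 0)
  expect_equal(bd$dice, max(oracle))
  expect_equal(bd$tau, vals[which.max(oracle)])   # ties -> lowest tau
  expect_true(all(bd$dice >= bd$dices))
  # realisable optimum scores exactly 1
  expect_equal(best_dice(m, m >= vals[7], grid_size = 5000)$dice, 1)
  # constant map: the single achievable dice
  cm <- array(2, c(4, 4, 4))
  expect_equal(best_dice(cm, cm > 1)$dice, 1)
  expect_equal(best_dice(cm, array(FALSE, c(4, 4, 4)) | (cm > 3))$dices,
               dice(cm >= 2, cm > 3))
})

test_that("best_dice_set picks one shared threshold maximising mean dice", {
  set.seed(4)
  maps <- lapply(1:3, function(i) array(runif(512), c(8, 8, 8)))
  truths <- lapply(maps, function(m) m >= 0.9)
  r <- best_dice_set(maps, truths, grid_size = 2000)
  expect_equal(r$dice, 1)                 # tau = 0.9 is realisable for all
  expect_equal(r$per_sample, rep(1, 3))
})

test_that("auprc matches brute force and known limits", {
  # perfect separation
  truth <- array(c(rep(TRUE, 5), rep(FALSE, 195)), c(200, 1, 1))
  sc <- array(c(runif(5, 0.8, 1), runif(195, 0, 0.5)), c(200, 1, 1))
  expect_equal(auprc(sc, truth), 1)
  # brute-force oracle on a 200-voxel instance
  set.seed(6)
  sc2 <- array(sample(seq(0, 1, 0.02), 200, TRUE), c(200, 1, 1))
  truth2 <- array(runif(200) < 0.2, c(200, 1, 1))
  got <- auprc(sc2, truth2)
  vals <- sort(unique(as.vector(sc2)), decreasing = TRUE)
  pr <- t(vapply(vals, function(tau) {
    m <- sc2 >= tau
    c(rec = sum(m & truth2) / sum(truth2), prec = sum(m & truth2) / sum(m))
  }, c(rec = 0, prec = 0)))
  oracle <- sum(diff(c(0, pr[, "rec"])) * pr[, "prec"])
  expect_equal(got, oracle, tolerance = 1e-12)
  # truth-independent scores converge to prevalence
  set.seed(8)
  n <- 40000; prev <- 0.02
  truth3 <- array(runif(n) < prev, c(n, 1, 1))
  sc3 <- array(runif(n), c(n, 1, 1))
  expect_lt(abs(auprc(sc3, truth3) - mean(truth3)), 0.01)
  # invariant under strictly monotone transforms
  expect_equal(auprc(exp(3 * sc2), truth2), got, tolerance = 1e-12)
  expect_error(auprc(sc2, truth2 & FALSE), "no positive")
})

test_that("paired t-test matches the textbook formula and flags degeneracy", {
  a <- c(0.50, 0.61, 0.47, 0.58, 0.66)
  b <- c(0.45, 0.52, 0.50, 0.51, 0.60)
  r <- paired_ttest(a, b)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(r$t, t_hand, tolerance = 1e-12)
  expect_equal(r$p, 2 * pt(-abs(t_hand), df = 4), tolerance = 1e-12)
  expect_false(r$degenerate)
  same <- paired_ttest(a, a)
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  const <- paired_ttest(a, a + 0.1)
  expect_true(const$degenerate)
  expect_true(is.infinite(const$t))
  expect_error(paired_ttest(a, b[1:3]), "equal length")
})
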