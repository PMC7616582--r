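test_that("analytic gradients match numerical differentiation", {
  for (conditional in c(FALSE, TRUE)) {
    cfg <- lm_config(K = 5, layers = 2, heads = 2, width = 8, ffn_mult = 2,
                     conditional = conditional, cond_K = 4, max_len = 7,
                     cond_len = 6, seed = 3)
    P <- with_seed(42, vqheal:::init_lm_params(cfg))
    P$Wout <- matrix(rnorm(length(P$Wout), 0, 0.1), nrow(P$Wout))
    s0 <- c(1L, 4L, 0L, 2L, 3L, 1L)
    c0 <- if (conditional) c(0L, 3L, 1L, 2L, 0L, 1L) else NULL
    r <- vqheal:::lm_step(P, cfg, s0, c0)
    eps <- 1e-6
    set.seed(7)
    for (nm in names(P)) {
      for (rep in 1:3) {
        i <- sample(length(P[[nm]]), 1)
        Pp <- P; Pp[[nm]][i] <- Pp[[nm]][i] + eps
        Pm <- P; Pm[[nm]][i] <- Pm[[nm]][i] - eps
        num <- (vqheal:::lm_step(Pp, cfg, s0, c0, grad = FALSE)$loss -
                  vqheal:::lm_step(Pm, cfg, s0, c0, grad = FALSE)$loss) / (2 * eps)
        expect_lt(abs(num - r$G[[nm]][i]) / max(1e-4, abs(num) + abs(r$G[[nm]][i])),
                  1e-4)
      }
    }
  }
})

test_that("an untrained model predicts near-uniformly and normalises exactly", {
  cfg <- lm_config(K = 9, layers = 1, heads = 2, width = 16, max_len = 20,
                   seed = 13)
  lm0 <- structure(list(params = with_seed(13, vqheal:::init_lm_params(cfg)),
                        config = cfg, history = NA_real_),
                   class = "latent_lm")
  p <- next_token_distribution(c(2L, 5L), NULL, lm0)
  expect_lt(max(p) / min(p), 10)
  set.seed(3)
  for (i in 1:20) {
    pre <- sample(0:8, sample(0:10, 1), replace = TRUE)
    p <- next_token_distribution(as.integer(pre), NULL, lm0)
    expect_equal(sum(p), 1, tolerance = 1e-6)
    expect_true(all(p >= 0))
  }
})

test_that("the model learns a deterministic successor grammar", {
  gr <- toy_grammar()
  expect_lt(tail(gr$lm$history, 1), gr$lm$history[1])
  set.seed(5)
  for (i in 1:10) {
    s0 <- sample(0:(gr$K - 1), 1)
    pre <- (s0 + 0:4) %% gr$K
    p <- next_token_distribution(as.integer(pre), NULL, gr$lm)
    expect_gt(p[((s0 + 5) %% gr$K) + 1], 0.9)
  }
})

test_that("teacher-forced likelihoods equal the per-position oracle", {
  gr <- toy_grammar()
  s <- gr$seqs[[3]]
  lp <- sequence_likelihoods(s, NULL, gr$lm)
  oracle <- vapply(seq_along(s), function(i) {
    next_token_distribution(s[seq_len(i - 1)], NULL, gr$lm)[s[i] + 1]
  }, 0)
  expect_lt(max(abs(lp - oracle)), 1e-5)
  expect_true(all(lp > 0 & lp <= 1))
})

test_that("predictions are causal: future tokens never affect earlier likelihoods", {
  gr <- toy_grammar()
  s <- gr$seqs[[1]]
  lp <- sequence_likelihoods(s, NULL, gr$lm)
  set.seed(9)
  for (cut in c(3, 7, 10)) {
    s2 <- s
    s2[(cut + 1):length(s)] <- sample(0:(gr$K - 1), length(s) - cut, TRUE)
    lp2 <- sequence_likelihoods(s2, NULL, gr$lm)
    expect_equal(lp2[seq_len(cut)], lp[seq_len(cut)], tolerance = 1e-12)
  }
})

test_that("cross-attention conditioning is live and sees ahead of the prefix", {
  ct <- cond_task()
  # reading the conditioning stream beats the unconditional model
  expect_lt(lm_nll(ct$lm_cond, ct$seqs, ct$conds) + 0.05,
            lm_nll(ct$lm_uncond, ct$seqs))
  s <- ct$seqs[[1]]; cond <- ct$conds[[1]]
  lp <- sequence_likelihoods(s, cond, ct$lm_cond)
  # replacing the conditioning content changes the likelihoods
  lp_alt <- sequence_likelihoods(s, (cond + 1L) %% ct$K, ct$lm_cond)
  expect_false(isTRUE(all.equal(lp, lp_alt)))
  # the model has a full view of the conditioning stream: altering only
  # conditioning positions BEYOND i changes likelihoods at positions <= i
  cond2 <- cond
  cond2[(ct$L - 3L):ct$L] <- (cond[(ct$L - 3L):ct$L] + 2L) %% ct$K
  lp2 <- sequence_likelihoods(s, cond2, ct$lm_cond)
  expect_gt(max(abs(lp2[1:(ct$L - 4L)] - lp[1:(ct$L - 4L)])), 1e-8)
})

test_that("model/conditioning mismatches and overflows error clearly", {
  ct <- cond_task()
  gr <- toy_grammar()
  expect_error(sequence_likelihoods(ct$seqs[[1]], NULL, ct$lm_cond),
               "requires a conditioning")
  expect_error(sequence_likelihoods(gr$seqs[[1]], gr$seqs[[1]], gr$lm),
               "unconditional")
  expect_error(sequence_likelihoods(rep(0L, 50), NULL, gr$lm),
               "context window")
  expect_error(lm_config(K = 8, width = 15, heads = 2), "divisible")
  expect_error(lm_config(K = 8, attention = "favor_plus"), "exact")
})

test_that("checkpoints reload with bit-identical likelihoods", {
  gr <- toy_grammar()
  f <- withr::local_tempfile(fileext = ".rds")
  save_lm(gr$lm, f)
  back <- load_lm(f)
  s <- gr$seqs[[2]]
  expect_identical(sequence_likelihoods(s, NULL, back),
                   sequence_likelihoods(s, NULL, gr$lm))
})

test_that("training NLL decreases on phantom-scale sequences", {
  set.seed(77)
  seqs <- lapply(1:12, function(i) {
    base <- rep(c(0L, 1L, 2L, 3L), each = 8)
    idx <- sample(32, 4)
    base[idx] <- sample(0:7, 4, TRUE)
    base
  })
  lm <- train_lm(seqs, NULL, lm_config(K = 8, layers = 1, heads = 2,
                                       width = 16, max_len = 32,
                                       epochs = 8, seed = 1))
  expect_lt(tail(lm$history, 1), lm$history[1])
})
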