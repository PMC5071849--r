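make_ref <- function(n_sims = 2000L, n_loci = 2000L, seed = 42L) {
  draw_prior(n_sims, n_loci, master_seed = seed)
}

test_that("abc_reject retains the tolerance fraction of closest draws", {
  ref <- make_ref()
  obs <- ref$counts[17, ]

  # tolerance 1: everything accepted
  p_all <- abc_reject(obs, ref, tolerance = 1)
  expect_equal(p_all$n_accepted, ref$n_sims)
  expect_setequal(p_all$accepted$index, seq_len(ref$n_sims))

  # exact match + tolerance 1/n: that simulation is the single accepted draw
  p_one <- abc_reject(obs, ref, tolerance = 1 / ref$n_sims)
  expect_equal(p_one$n_accepted, 1L)
  expect_equal(p_one$accepted$index, 17L)
  expect_equal(p_one$accepted$distance, 0)
})

test_that("abc_reject's accepted set matches an exhaustive distance sort", {
  ref <- make_ref(seed = 7)
  obs <- c(BBAA = 900, ABBA = 600, BABA = 500)
  post <- abc_reject(obs, ref, tolerance = 0.05)

  sds <- apply(ref$counts, 2, sd)
  d <- sqrt(colSums((t(ref$counts) / sds - obs / sds)^2))
  naive_idx <- order(d)[seq_len(round(0.05 * ref$n_sims))]
  expect_identical(post$accepted$index, naive_idx)
  expect_equal(post$accepted$distance, sort(d)[seq_along(naive_idx)],
               tolerance = 1e-12)
})

test_that("ridge_adjust leaves draws unchanged when summaries carry no signal, and reproduces exact linear structure", {
  ref <- make_ref(seed = 11)
  # accepted summaries identical to observed: adjusted == raw
  ref0 <- ref
  ref0$counts <- matrix(rep(c(1000L, 600L, 400L), each = ref$n_sims),
                        ref$n_sims)
  colnames(ref0$counts) <- colnames(ref$counts)
  ref0$counts[1:5, 1] <- c(999L, 1001L, 998L, 1002L, 1000L)  # keep sd > 0
  post0 <- suppressWarnings(abc_reject(c(1000, 600, 400), ref0, tolerance = 0.5))
  adj0 <- suppressWarnings(ridge_adjust(post0))
  same <- adj0$accepted$distance == 0
  expect_true(any(same))
  expect_equal(adj0$adjusted$alpha[same], adj0$accepted$alpha[same],
               tolerance = 1e-6)

  # alpha exactly linear in the summaries: adjustment collapses the accepted
  # set onto the true value at the observed summary
  refl <- make_ref(seed = 12)
  refl$params$alpha <- 0.2 + 0.3 * refl$counts[, 1] / 1000 -
    0.1 * refl$counts[, 3] / 1000
  obs <- refl$counts[123, ]
  postl <- abc_reject(obs, refl, tolerance = 0.25)
  adjl <- ridge_adjust(postl, lambda_grid = c(1e-10))
  truth <- refl$params$alpha[123]
  expect_lt(max(abs(adjl$adjusted$alpha - truth)), 1e-4)
})

test_that("ridge coefficients match a naive weighted normal-equations solver", {
  ref <- make_ref(n_sims = 400L, seed = 13)
  obs <- ref$counts[55, ]
  post <- abc_reject(obs, ref, tolerance = 0.05)  # 20 accepted
  lam <- 1e-3
  adj <- ridge_adjust(post, lambda_grid = lam)

  X <- sweep(post$summaries, 2, post$observed_summary)
  d <- post$accepted$distance
  w <- 1 - (d / max(d))^2
  beta_naive <- oracle_ridge_beta(X, post$accepted$alpha, w, lam)
  expect_equal(unname(adj$ridge_beta[, "alpha"]), unname(beta_naive),
               tolerance = 1e-8)
  expect_equal(adj$adjusted$alpha,
               post$accepted$alpha - drop(X %*% beta_naive[-1]),
               tolerance = 1e-8)
})

test_that("posterior probabilities are percentages, certain at threshold zero, and monotone", {
  ref <- make_ref(seed = 15)
  post <- abc_reject(ref$counts[3, ], ref, tolerance = 0.25)
  post$adjusted <- data.frame(alpha = rep(0.5, post$n_accepted),
                              t1 = 1, t2 = 1)
  expect_equal(posterior_probability(post, 0.01), 100)
  expect_equal(posterior_probability(post, 0), 100)

  post2 <- ridge_adjust(abc_reject(ref$counts[3, ], ref, tolerance = 0.25))
  grid <- seq(0, 0.9, by = 0.05)
  probs <- vapply(grid, function(th) posterior_probability(post2, th), 1)
  expect_true(all(diff(probs) <= 1e-12))
  expect_true(all(probs >= 0 & probs <= 100))
})

test_that("cv4abc: near-zero error for perfectly informative summaries, near-one for pure noise", {
  # counts a deterministic invertible function of alpha
  n <- 1500L
  set.seed(31)
  alpha <- runif(n)
  bbaa <- as.integer(round(2500 + 5000 * alpha))
  ref <- draw_prior(n, 10000L, master_seed = 1L)
  ref$params$alpha <- alpha
  ref$counts <- cbind(BBAA = bbaa,
                      ABBA = as.integer(3000 + round(1000 * runif(n))),
                      BABA = 0L)
  ref$counts[, "BABA"] <- 10000L - ref$counts[, 1] - ref$counts[, 2]
  cv_det <- cv4abc(ref, n_cv = 30L, tolerance = 50 / n, seed = 2L)
  expect_lt(cv_det$prediction_error, 0.02)

  # counts independent of alpha: standardized error concentrates near 1
  ref2 <- draw_prior(2000L, 2000L, master_seed = 3L,
                     prior = list(alpha = c(0, 1), t1 = c(1, 1.00001),
                                  t2 = c(1, 1.00001)))
  # t fixed: counts share one multinomial law; alpha never enters the data
  ref2$counts <- ref2$counts[sample.int(2000L), ]
  cv_noise <- cv4abc(ref2, n_cv = 60L, tolerance = 0.25, seed = 4L)
  expect_gt(cv_noise$prediction_error, 0.75)
  expect_lt(cv_noise$prediction_error, 1.3)

  expect_error(cv4abc(ref2, n_cv = 1L, tolerance = 0.1), "n_cv")
})

test_that("adjusted posterior means track the generating alpha on model-consistent data", {
  set.seed(19)
  truth <- runif(30)
  est <- vapply(seq_along(truth), function(i) {
    t1 <- runif(1, 0, 5); t2 <- runif(1, 0, 5)
    obs <- simulate_counts(topology_model("X1", "BBAA", t1),
                           topology_model("X2", "BABA", t2),
                           n_loci = 5000L, alpha = truth[i], seed = 400 + i)
    ref <- draw_prior(3000L, 5000L, master_seed = 800 + i)
    post <- suppressWarnings(ridge_adjust(abc_reject(obs, ref, 0.1)))
    mean(post$adjusted$alpha)
  }, 1)
  expect_gt(stats::cor(truth, est), 0.7)
  expect_lt(mean((est - truth)^2), stats::var(truth))
})
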