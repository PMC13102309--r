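test_that("duration pmf matches the negative-binomial family and normalizes", {
  # n = 1 reduces to a truncated geometric
  d1 <- duration_pmf(1, 0.3, 50)
  geo <- 0.7^(1:50); geo <- geo / sum(geo)
  expect_equal(d1$pmf, geo, tolerance = 1e-12)
  # single support point
  d0 <- duration_pmf(3, 0.5, 1)
  expect_equal(d0$pmf, 1)
  expect_equal(d0$t_bar_rev, 1)
  # matches the standard library pmf, renormalized, across the default grid
  grid <- hsmm_default_grid()
  for (n in grid$n[c(1, 5, 9, 17)]) {
    for (p in grid$p[c(1, 6, 12, 17)]) {
      dd <- duration_pmf(n, p, 70)
      ref <- dnbinom(1:70, size = n, prob = p); ref <- ref / sum(ref)
      expect_equal(dd$pmf, ref, tolerance = 1e-12)
      expect_lt(abs(sum(dd$pmf) - 1), 1e-12)
      expect_equal(dd$t_bar_rev, sum((1:70) * ref), tolerance = 1e-10)
    }
  }
})

test_that("mean duration rises as the tail probability falls", {
  for (n in c(1, 7, 25)) {
    tb <- vapply(seq(0.05, 0.95, by = 0.05),
                 function(p) duration_pmf(n, p, 70)$t_bar_rev, numeric(1))
    expect_true(all(diff(tb) < 0))   # decreasing in p = increasing in 1 - p
  }
})

test_that("emission log-likelihood factorizes over trials", {
  hp <- hsmm_params(1, 0.5, 10, sigma_c = 8)
  expect_identical(emission_loglik(numeric(0), 1, integer(0), hp), 0)
  expect_equal(emission_loglik(60, 1, 1L, hp), dnorm(60, 60, 8, log = TRUE))
  expect_equal(emission_loglik(60, 1, 1L, hp), -log(8 * sqrt(2 * pi)))
  set.seed(3)
  r <- rnorm(7, 50, 10); a <- sample(1:2, 7, replace = TRUE)
  per_trial <- vapply(1:7, function(k) emission_loglik(r[k], 2, a[k], hp),
                      numeric(1))
  expect_equal(emission_loglik(r, 2, a, hp), sum(per_trial))
})

test_that("the forward filter equals brute-force enumeration on small instances", {
  set.seed(11)
  for (D in 2:4) {
    for (pars in list(c(1, 0.5), c(2, 0.3), c(3, 0.7))) {
      hp <- hsmm_params(pars[1], pars[2], D, sigma_c = 8)
      for (rep in 1:2) {
        n <- sample(4:8, 1)
        actions <- sample(1:2, n, replace = TRUE)
        rewards <- rnorm(n, ifelse(actions == 1, 58, 44), 8)
        filt <- hsmm_filter(actions, rewards, hp)
        for (t in seq_len(n)) {
          oracle <- enum_hsmm_posterior(actions, rewards, hp, t)
          expect_equal(filt$p_state1[t], oracle[1], tolerance = 1e-8)
          expect_equal(filt$p_state2[t], oracle[2], tolerance = 1e-8)
        }
      }
    }
  }
})

test_that("the filter starts uniform and sharpens under consistent evidence", {
  # bell-shaped durations (mean 20): an early reversal is improbable, so
  # consistent evidence should drive the predictive posterior above .99
  # before it relaxes as the expected reversal time approaches
  hp <- hsmm_params(20, 0.5, 40, sigma_c = 8)
  actions <- rep(1L, 10); rewards <- rep(60, 10)
  filt <- hsmm_filter(actions, rewards, hp)
  expect_equal(unlist(filt[1, c("p_state1", "p_state2")]),
               c(p_state1 = 0.5, p_state2 = 0.5))
  expect_true(all(diff(filt$p_state1[1:4]) > 0))
  expect_gt(max(filt$p_state1), 0.99)
  # and agrees with the enumeration oracle on this stretched instance
  oracle <- enum_hsmm_posterior(actions, rewards, hp, 6)
  expect_equal(filt$p_state1[6], oracle[1], tolerance = 1e-8)
  # posteriors normalized at every trial
  expect_true(all(abs(filt$p_state1 + filt$p_state2 - 1) < 1e-10))
})

test_that("model-based and mixture policies are the stated maps", {
  expect_equal(mb_policy(c(0.5, 0.5)), c(0.5, 0.5))
  expect_equal(mb_policy(c(1, 0)), c(1, 0))
  expect_error(mb_policy(c(0.5, 0.4)), "normalized")
  expect_equal(mixture_policy(c(0.8, 0.2), c(0.4, 0.6), gamma = 1),
               c(0.8, 0.2))
  expect_equal(mixture_policy(c(0.8, 0.2), c(0.4, 0.6), gamma = 0),
               c(0.4, 0.6))
  expect_equal(mixture_policy(c(0.8, 0.2), c(0.4, 0.6), gamma = 0.5),
               c(0.6, 0.4))
  set.seed(4)
  for (i in 1:20) {
    p1 <- runif(1); mfp <- c(p1, 1 - p1)
    p2 <- runif(1); mbp <- c(p2, 1 - p2)
    g <- runif(1)
    mix <- mixture_policy(mfp, mbp, g)
    expect_equal(sum(mix), 1)
    expect_true(all(mix >= pmin(mfp, mbp) - 1e-12 &
                      mix <= pmax(mfp, mbp) + 1e-12))
  }
})
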