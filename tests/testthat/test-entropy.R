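test_that("log unit-ball volume matches closed forms and stays finite", {
  expect_equal(log_unit_ball_volume(1), log(2), tolerance = 1e-14)
  expect_equal(log_unit_ball_volume(2), log(pi), tolerance = 1e-14)
  expect_equal(log_unit_ball_volume(3), log(4 * pi / 3), tolerance = 1e-14)
  expect_true(is.finite(log_unit_ball_volume(768)))
  expect_true(is.finite(log_unit_ball_volume(10000)))
  expect_error(log_unit_ball_volume(0), class = "embentropy_domain")
  expect_error(log_unit_ball_volume(-2), class = "embentropy_domain")
})

test_that("the two-point hand example reproduces the closed-form value", {
  est <- kl_entropy(matrix(c(0, 1), ncol = 1))
  # rho_1 = rho_2 = 1: H = d log(1) + log V_1 + gamma + log(N - 1)
  expect_equal(est$H, log(2) - digamma(1), tolerance = 1e-12)
  expect_identical(est$N, 2L)
  expect_identical(est$n_clamped, 0L)
})

test_that("estimator is translation invariant and shifts by d log a under scaling", {
  set.seed(21)
  for (d in c(1, 3, 8)) {
    x <- matrix(rnorm(200 * d), ncol = d)
    base <- kl_entropy(x)
    shifted <- kl_entropy(sweep(x, 2, rnorm(d, sd = 50), `+`))
    expect_equal(shifted$H, base$H, tolerance = 1e-9)
    expect_equal(shifted$contributions, base$contributions, tolerance = 1e-9)
    for (a in c(0.25, 3)) {
      scaled <- kl_entropy(a * x)
      expect_equal(scaled$H, base$H + d * log(a), tolerance = 1e-9)
      expect_equal(scaled$contributions, base$contributions + d * log(a),
                   tolerance = 1e-9)
    }
  }
})

test_that("mean of contributions equals the geometric-mean closed form", {
  set.seed(33)
  for (d in c(1, 2, 5)) {
    x <- matrix(rnorm(150 * d), ncol = d)
    est <- kl_entropy(x)
    expect_equal(est$H, mean(est$contributions), tolerance = 1e-12)
    expect_equal(est$H, geometric_mean_form(x), tolerance = 1e-9)
    expect_equal(est$median_contribution, median(est$contributions))
  }
})

test_that("estimator is consistent for Gaussian and uniform clouds", {
  # moderate n here; the n = 10,000 sweep lives in the acceptance suite
  for (d in 1:2) {
    hs <- vapply(1:4, function(seed) {
      set.seed(seed)
      kl_entropy(matrix(rnorm(4000 * d), ncol = d))$H
    }, numeric(1))
    expect_lt(abs(mean(hs) - gaussian_entropy(d, 1)), 0.08)

    hs_u <- vapply(1:4, function(seed) {
      set.seed(seed + 100)
      kl_entropy(matrix(runif(4000 * d), ncol = d))$H
    }, numeric(1))
    expect_lt(abs(mean(hs_u)), 0.08) # uniform on [0,1]^d has entropy 0
  }
})

test_that("the estimator stays finite and scale-consistent at d = 768", {
  set.seed(768)
  x <- matrix(rnorm(60 * 768), ncol = 768)
  est <- kl_entropy(x)
  expect_true(is.finite(est$H))
  expect_identical(est$n_clamped, 0L)
  expect_equal(kl_entropy(2 * x)$H, est$H + 768 * log(2), tolerance = 1e-9)
})

test_that("permuting sample order changes neither H nor the contribution multiset", {
  set.seed(4)
  x <- matrix(rnorm(120 * 3), ncol = 3)
  est <- kl_entropy(x)
  perm <- sample(nrow(x))
  est_p <- kl_entropy(x[perm, ])
  expect_equal(est_p$H, est$H, tolerance = 1e-12)
  expect_equal(sort(est_p$contributions), sort(est$contributions),
               tolerance = 1e-12)
})

test_that("duplicate points are clamped, counted and warned about", {
  x <- matrix(c(0, 0, 3, 7, 12, 20), ncol = 1) # one duplicated pair of 6
  expect_warning(est <- kl_entropy(x), "clamped")
  expect_identical(est$n_clamped, 2L)
  expect_true(is.finite(est$H))

  # a few duplicates below the 10% threshold: counted, no warning
  set.seed(2)
  y <- matrix(rnorm(100), ncol = 1)
  y[2] <- y[1]
  expect_no_warning(est2 <- kl_entropy(y))
  expect_identical(est2$n_clamped, 2L)
})

test_that("k > 1 uses the digamma generalisation consistently", {
  set.seed(12)
  x <- matrix(rnorm(3000 * 2), ncol = 2)
  for (k in c(2, 5)) {
    est <- kl_entropy(x, k = k)
    # still consistent for the Gaussian target
    expect_lt(abs(est$H - gaussian_entropy(2, 1)), 0.1)
    # additive constant is psi(N) - psi(k), checked through a manual rebuild
    dm <- as.matrix(dist(x[1:50, ])); diag(dm) <- Inf
    rho <- apply(dm, 1, function(r) sort(r)[k])
    manual <- mean(2 * log(rho)) + log(pi) + digamma(50) - digamma(k)
    expect_equal(kl_entropy(x[1:50, ], k = k)$H, manual, tolerance = 1e-9)
  }
  expect_error(kl_entropy(x[1:3, ], k = 3), class = "embentropy_sample_size")
  expect_error(kl_entropy(matrix(c(0, 1, NA), ncol = 1)),
               class = "embentropy_domain")
  expect_error(kl_entropy(x, metric = "manhattan"),
               class = "embentropy_config")
})

test_that("class entropies are computed within class and ordered by dispersion", {
  # identical clouds for both classes -> identical estimates
  set.seed(7)
  pts <- matrix(rnorm(60 * 2), ncol = 2)
  es <- embedding_set(rbind(pts, pts + 100), rep(c(1L, 0L), each = 60))
  # translating the negative cloud far away must not affect within-class H
  ce <- class_entropy(es)
  expect_equal(ce$pos$H, ce$neg$H, tolerance = 1e-9)

  # wider positive class -> larger entropy
  set.seed(8)
  wide <- matrix(rnorm(400 * 3, sd = 3), ncol = 3)
  narrow <- matrix(rnorm(400 * 3, sd = 1), ncol = 3)
  es2 <- embedding_set(rbind(wide, narrow), rep(c(1L, 0L), each = 400))
  ce2 <- class_entropy(es2)
  expect_gt(ce2$pos$H, ce2$neg$H)

  # one positive sample: contract violation naming the class
  bad <- embedding_set(matrix(rnorm(10), ncol = 1), c(1L, rep(0L, 9)))
  expect_error(class_entropy(bad), class = "embentropy_sample_size")
  expect_error(class_entropy(bad), "positive")
})

test_that("pooled neighbour search couples the clouds but keeps class means", {
  set.seed(15)
  es <- toy_set(n_pos = 80, n_neg = 80, d = 2, seed = 15)
  pooled <- class_entropy(es, pooled = TRUE)
  whole <- kl_entropy(es$features)
  npos <- sum(es$labels == 1L)
  expect_equal(
    (npos * pooled$pos$H + (nrow(es$features) - npos) * pooled$neg$H) /
      nrow(es$features),
    whole$H, tolerance = 1e-12)
})

test_that("entropy trajectory records per-epoch gaps in input order", {
  es0 <- toy_set(40, 40, d = 2, seed = 1, epoch = 0L)
  traj1 <- entropy_trajectory(list(es0))
  expect_identical(nrow(traj1$records), 1L)

  # identical classes at one epoch: zero gap by symmetry
  set.seed(3)
  pts <- matrix(rnorm(50 * 2), ncol = 2)
  same <- embedding_set(rbind(pts, pts + 1000), rep(c(1L, 0L), each = 50))
  tr <- entropy_trajectory(list(same))
  expect_equal(tr$records$delta_mean, 0, tolerance = 1e-9)
  expect_equal(tr$records$delta_median, 0, tolerance = 1e-9)

  sets <- lapply(0:3, function(e) toy_set(30, 30, seed = e + 1, epoch = e))
  traj <- entropy_trajectory(sets)
  expect_identical(traj$records$epoch, 0:3)
  expect_true(all(traj$records$delta_mean >= 0))
  expect_named(traj$records,
               c("epoch", "pos_mean", "pos_median", "neg_mean", "neg_median",
                 "delta_mean", "delta_median", "n_pos", "n_neg", "n_clamped"))

  dup <- list(sets[[1]], sets[[1]])
  expect_error(entropy_trajectory(dup), class = "embentropy_input")
  expect_error(entropy_trajectory(list()), class = "embentropy_input")
})

test_that("trajectory gaps track a planted dispersion ratio", {
  # class dispersion ratios (1, e, 1) in d dims -> gaps about (0, d, 0)
  d <- 3; n <- 5000
  make_epoch <- function(epoch, ratio, seed) {
    set.seed(seed)
    pos <- matrix(rnorm(n * d, sd = ratio), ncol = d)
    neg <- matrix(rnorm(n * d, sd = 1), ncol = d)
    embedding_set(rbind(pos, neg), rep(c(1L, 0L), each = n), epoch = epoch)
  }
  sets <- list(make_epoch(0L, 1, 41), make_epoch(1L, exp(1), 42),
               make_epoch(2L, 1, 43))
  gaps <- entropy_trajectory(sets)$records$delta_mean
  expect_lt(gaps[1], 0.15)
  expect_lt(abs(gaps[2] - d), 0.15)
  expect_lt(gaps[3], 0.15)
})

test_that("optimal-epoch selection maximises delta_mean with documented tie rules", {
  traj <- data.frame(epoch = 0:2, delta_mean = c(0.1, 0.9, 0.3),
                     delta_median = c(0.1, 0.8, 0.3))
  sel <- select_optimal_epoch(traj)
  expect_identical(sel$optimal_epoch, 1L)
  expect_identical(sel$criterion, "delta_mean")
  expect_true(sel$agreement_with_median)

  # all equal -> smallest epoch
  flat <- data.frame(epoch = 3:6, delta_mean = 1, delta_median = 1)
  expect_identical(select_optimal_epoch(flat)$optimal_epoch, 3L)

  # delta_mean tie broken by larger delta_median
  tie <- data.frame(epoch = 0:2, delta_mean = c(1, 1, 0),
                    delta_median = c(0.2, 0.9, 0))
  expect_identical(select_optimal_epoch(tie)$optimal_epoch, 1L)

  # disagreement between criteria is reported
  dis <- data.frame(epoch = 0:1, delta_mean = c(1, 0.5),
                    delta_median = c(0.1, 0.9))
  expect_false(select_optimal_epoch(dis)$agreement_with_median)

  expect_error(select_optimal_epoch(data.frame()), class = "embentropy_input")
})
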