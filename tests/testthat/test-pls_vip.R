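test_that("PLS fits a perfect univariate relationship exactly", {
  x <- matrix(seq(-2, 2, length.out = 12), ncol = 1)
  m <- fit_pls(x, as.vector(x), 1)
  expect_equal(m$coefficients, 1, tolerance = 1e-10)
  expect_lt(m$ssy[2], 1e-18)
  expect_equal(predict(m, x), as.vector(x), tolerance = 1e-10)
})

test_that("full-rank PLS equals the normal-equations OLS oracle", {
  for (seed in c(12, 77, 301)) {
    dat <- with_seed_local(seed, list(X = matrix(rnorm(48), 12, 4),
                                      y = rnorm(12)))
    m <- fit_pls(dat$X, dat$y, 4)
    Xi <- cbind(1, dat$X)
    ols <- solve(crossprod(Xi), crossprod(Xi, dat$y))
    expect_equal(m$coefficients, as.vector(ols[-1]), tolerance = 1e-6)
  }
})

test_that("destroying the X-y link destroys explained sums of squares", {
  prob <- linear_problem(80, 9, 6, 0.3, r2_target = 0.9, seed = 5)
  m <- fit_pls(prob$X, prob$y, 2)
  yperm <- with_seed_local(6, sample(prob$y))
  mp <- fit_pls(prob$X, yperm, 2)
  expl <- function(m) 1 - m$ssy[length(m$ssy)] / m$ssy[1]
  expect_gt(expl(m), expl(mp))
})

test_that("ssy is non-increasing and predictions honor centering identities", {
  prob <- linear_problem(60, 9, 4, 0.3, r2_target = 0.8, seed = 8)
  m <- fit_pls(prob$X, prob$y, 5)
  expect_true(all(diff(m$ssy) <= 1e-10))
  expect_equal(predict(m, matrix(m$x_center, nrow = 1)), m$y_center)
  # a zero-variance (inert) column gets coefficient 0; rescaling it
  # cannot move predictions
  X <- cbind(prob$X[, 1:6], 3)
  m2 <- fit_pls(X, prob$y, 3)
  expect_equal(m2$coefficients[7], 0, tolerance = 1e-10)
  X2 <- X; X2[, 7] <- 2 * X2[, 7]
  expect_equal(predict(m2, X2), predict(m2, X), tolerance = 1e-8)
})

test_that("degenerate fits are rejected", {
  X <- matrix(rnorm(40), 10, 4)
  expect_error(fit_pls(X, rep(2, 10), 1), "zero variance")
  Xr <- cbind(X[, 1], X[, 1], X[, 2])  # rank 2 after centering
  expect_error(fit_pls(Xr, rnorm(10), 3), "rank")
  expect_error(fit_pls(X, rnorm(10), 0), ">= 1")
})

test_that("factor selection finds planted latent dimensionality", {
  make_latent <- function(n, n_lat, noise, seed) {
    with_seed_local(seed, {
      Tm <- matrix(rnorm(n * n_lat), n, n_lat)
      load <- matrix(rnorm(n_lat * 18), n_lat, 18)
      X <- Tm %*% load + matrix(rnorm(n * 18, 0, 0.05), n, 18)
      y <- Tm %*% seq(2, 1, length.out = n_lat) + rnorm(n, 0, noise)
      list(X = X, y = as.vector(y))
    })
  }
  d2 <- make_latent(150, 2, 1e-4, seed = 31)
  expect_equal(as.integer(select_factors(d2$X, d2$y, max_factors = 5)), 2L)

  noise <- with_seed_local(32, list(X = matrix(rnorm(120 * 10), 120, 10),
                                    y = rnorm(120)))
  expect_equal(as.integer(select_factors(noise$X, noise$y, max_factors = 4)),
               1L)

  d3 <- make_latent(200, 3, 0.05, seed = 33)
  sel <- select_factors(d3$X, d3$y, max_factors = 6)
  expect_equal(as.integer(sel), 3L)
  # oracle: exhaustive PRESS scan with per-A refits on each fold
  n <- nrow(d3$X)
  folds <- as.integer(cut(seq_len(n), 7, labels = FALSE))
  press <- sapply(1:6, function(A) {
    sum(sapply(1:7, function(f) {
      idx <- folds == f
      m <- fit_pls(d3$X[!idx, ], d3$y[!idx], A)
      sum((d3$y[idx] - predict(m, d3$X[idx, , drop = FALSE]))^2)
    }))
  })
  expect_equal(as.integer(sel),
               which(press <= 1.02 * min(press))[1])
  expect_equal(unname(attr(sel, "press")), unname(press), tolerance = 1e-8)
})

test_that("VIP matches the closed form at one dimension and the literal formula at two", {
  prob <- linear_problem(60, 9, 5, 0.3, r2_target = 0.85, seed = 13)
  m1 <- fit_pls(prob$X, prob$y, 1)
  v1 <- compute_vip(m1)
  expect_equal(v1$vip_flat, sqrt(27) * abs(m1$weights[, 1]),
               tolerance = 1e-10)

  # 6-term, 2-factor model: term-by-term evaluation of the formula
  X6 <- prob$X[, 1:6]
  m2 <- fit_pls(X6, prob$y, 2)
  K <- 6
  expl <- c(m2$ssy[1] - m2$ssy[2], m2$ssy[2] - m2$ssy[3])
  total <- m2$ssy[1] - m2$ssy[3]
  by_hand <- sapply(1:K, function(k) {
    sqrt(K * (m2$weights[k, 1]^2 * expl[1] +
                m2$weights[k, 2]^2 * expl[2]) / total)
  })
  v2 <- compute_vip(m2)
  expect_equal(v2$vip_flat, by_hand, tolerance = 1e-10)
})

test_that("squared VIPs always sum to the number of terms", {
  for (seed in 1:8) {
    prob <- linear_problem(50 + 10 * seed, 9, 3 + seed %% 4, 0.4,
                           r2_target = 0.8, seed = 400 + seed)
    A <- 1 + seed %% 3
    v <- compute_vip(fit_pls(prob$X, prob$y, A))
    expect_equal(sum(v$vip_flat^2), 27, tolerance = 1e-6)
    expect_true(all(v$vip_flat >= 0))
  }
})

test_that("VIP is invariant to shifting the response", {
  prob <- linear_problem(70, 15, 6, 0.3, r2_target = 0.85, seed = 19)
  v1 <- compute_vip(fit_pls(prob$X, prob$y, 2))
  v2 <- compute_vip(fit_pls(prob$X, prob$y + 100, 2))
  expect_equal(v1$vip_flat, v2$vip_flat, tolerance = 1e-9)
  expect_equal(dim(v1$values), c(15L, 3L))
  expect_equal(rownames(v1$values), position_labels(15, "II"))
})

test_that("VIP tables round-trip through the supplementary-style TSV", {
  prob <- linear_problem(60, 9, 5, 0.3, r2_target = 0.85, seed = 23)
  m <- fit_pls(prob$X, prob$y, 2, allele = "SYN-A0101")
  v <- compute_vip(m)
  path <- tempfile(fileext = ".tsv")
  write_vip_table(v, path)
  back <- read_vip_table(path)[[1]]
  expect_equal(back$allele, "SYN-A0101")
  expect_equal(back$vip_flat, v$vip_flat, tolerance = 1e-10)
  expect_equal(rownames(back$values), rownames(v$values))
})

test_that("PLS models round-trip through JSON serialization", {
  prob <- linear_problem(50, 9, 4, 0.3, r2_target = 0.85, seed = 29)
  m <- fit_pls(prob$X, prob$y, 2, allele = "SYN-X")
  path <- tempfile(fileext = ".json")
  write_model(m, path)
  back <- read_model(path)
  expect_s3_class(back, "pls_model")
  expect_equal(predict(back, prob$X), predict(m, prob$X))
  expect_equal(compute_vip(back)$vip_flat, compute_vip(m)$vip_flat)
})
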