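# Smaller optimizer caps keep these fits quick; the properties under
# test do not depend on squeezing out the last optimizer iterations.

test_that("perceptron training is a pure function of data and seed", {
  prob <- linear_problem(120, 9, 5, 0.3, r2_target = 0.9, seed = 51)
  m1 <- train_perceptron(prob$X, prob$y, 9, penalty = 0.1, seed = 4,
                         maxit = 300)
  m2 <- train_perceptron(prob$X, prob$y, 9, penalty = 0.1, seed = 4,
                         maxit = 300)
  expect_identical(m1$input_weights, m2$input_weights)
  expect_identical(m1$output_weights, m2$output_weights)
  m3 <- train_perceptron(prob$X, prob$y, 9, penalty = 0.1, seed = 5,
                         maxit = 300)
  expect_false(identical(m1$input_weights, m3$input_weights))
})

test_that("the forward pass reproduces the optimizer's own predictions", {
  prob <- linear_problem(100, 9, 4, 0.3, r2_target = 0.9, seed = 52)
  m <- train_perceptron(prob$X, prob$y, 9, penalty = 0.05, seed = 2,
                        maxit = 300)
  Xs <- scale(prob$X, center = m$x_center, scale = m$x_scale)
  refit <- nnet::nnet(x = Xs, y = (prob$y - m$y_center) / m$y_scale,
                      size = 9, linout = TRUE, decay = 0.05, maxit = 0,
                      Wts = c(as.vector(t(m$input_weights)),
                              m$output_weights),
                      MaxNWts = 1000, trace = FALSE)
  expect_equal(predict(m, prob$X),
               m$y_center + m$y_scale * as.vector(predict(refit, Xs)),
               tolerance = 1e-8)
})

test_that("an overwhelming penalty collapses predictions to the mean", {
  prob <- linear_problem(100, 9, 4, 0.3, r2_target = 0.9, seed = 53)
  m <- train_perceptron(prob$X, prob$y, 9, penalty = 1e6, seed = 1,
                        maxit = 300)
  pred <- predict(m, prob$X)
  expect_lt(max(abs(pred - mean(prob$y))) / abs(mean(prob$y)), 0.01)
  expect_lt(abs(m$train_r2), 0.02)
})

test_that("an unpenalized net represents a linear map almost exactly", {
  prob <- linear_problem(150, 9, 5, 0.4, r2_target = 0.999, seed = 54)
  y <- as.vector(prob$X %*% prob$beta)  # noiseless
  m <- train_perceptron(prob$X, y, 9, penalty = 0, seed = 3,
                        maxit = 1500)
  expect_gte(m$train_r2, 0.99)
})

test_that("training r2 is non-increasing in the penalty", {
  prob <- linear_problem(120, 9, 5, 0.3, r2_target = 0.9, seed = 55)
  lams <- c(0, 0.01, 0.1, 1, 10, 100)
  r2s <- vapply(lams, function(l)
    train_perceptron(prob$X, prob$y, 9, penalty = l, seed = 7,
                     maxit = 400)$train_r2, numeric(1))
  expect_true(all(diff(r2s) <= 0.02))  # monotone up to optimizer jitter
  expect_lt(r2s[length(r2s)], r2s[1])
})

test_that("penalty tuning hits the target band or flags an unattainable one", {
  prob <- linear_problem(150, 9, 5, 0.4, r2_target = 0.98, seed = 56)
  lam <- tune_penalty(prob$X, prob$y, 9, target_r2 = 0.9, seed = 2,
                      maxit = 400)
  expect_true(attr(lam, "attained"))
  expect_gt(as.numeric(lam), 0)
  r2 <- train_perceptron(prob$X, prob$y, 9, penalty = as.numeric(lam),
                         seed = 2, maxit = 400)$train_r2
  expect_gte(r2, 0.88); expect_lte(r2, 0.92)

  # pure noise cannot reach 0.9 with a strong penalty floor: flag path
  noise <- with_seed_local(57, list(X = matrix(rnorm(200 * 3), 200, 3),
                                    y = rnorm(200)))
  lam0 <- tune_penalty(noise$X, noise$y, 2, target_r2 = 0.9, seed = 1,
                       maxit = 300)
  expect_false(attr(lam0, "attained"))
  expect_equal(as.numeric(lam0), 0)
})

test_that("Method 1 selects the tour with the best holdback fit", {
  prob <- linear_problem(300, 9, 5, 0.35, r2_target = 0.9, seed = 58)
  m <- train_method1(prob$X, prob$y, 9, n_tours = 3, penalty = 2,
                     seed = 12, maxit = 400)
  expect_equal(m$tour, which.max(m$tour_r2))
  expect_equal(m$holdback_r2, max(m$tour_r2))
  expect_gte(m$holdback_r2, median(m$tour_r2))
  # direct evaluation on the recorded held-back rows
  hb <- m$holdback_idx
  pred <- predict(m, prob$X[hb, , drop = FALSE])
  r2_direct <- 1 - sum((prob$y[hb] - pred)^2) /
    sum((prob$y[hb] - mean(prob$y[hb]))^2)
  expect_equal(m$holdback_r2, r2_direct, tolerance = 1e-10)
  # a planted linear signal generalizes: holdback within 0.05 of training
  expect_lt(abs(m$holdback_r2 - m$train_r2), 0.05)
})

test_that("Method 2 memberships have the stated combinatorics", {
  ms <- method2_memberships(10, n_subsets = 2, subset_fraction = 0.5,
                            seed = 3)
  expect_length(ms, 2)
  expect_true(all(lengths(ms) == 5))
  expect_true(all(unlist(ms) %in% 1:10))
  # defaults: nine 2/3 subsets -> each row serves ~6 times
  counts <- rowMeans(sapply(1:50, function(s) {
    tabulate(unlist(method2_memberships(200, seed = s)), nbins = 200)
  }))
  expect_equal(mean(counts), 6.0, tolerance = 0.1)
  # determinism
  expect_identical(method2_memberships(50, seed = 9),
                   method2_memberships(50, seed = 9))
})

test_that("ensemble predictions carry mean, SEM and CV% per the definitions", {
  const_member <- function(value) {
    structure(list(n_inputs = 3, n_hidden = 2,
                   input_weights = matrix(0, 2, 4),
                   output_weights = c(0, 0, 0),
                   penalty = 0, seed = 1,
                   x_center = rep(0, 3), x_scale = rep(1, 3),
                   y_center = value, y_scale = 1,
                   converged = TRUE, train_r2 = NA_real_),
              class = "perceptron_model")
  }
  e <- structure(list(members = list(const_member(2), const_member(4)),
                      membership = list(1:3, 1:3),
                      subset_fraction = 0.5, n_subsets = 2, seed = 1),
                 class = "ensemble_model")
  X <- matrix(rnorm(6), 2, 3)
  pr <- predict_ensemble(e, X)
  expect_equal(pr$mean_ln_ic50, c(3, 3))
  expect_equal(pr$sem, c(1, 1))           # sd = sqrt(2), sem = sd/sqrt(2)
  expect_equal(pr$cv_pct, 100 * sqrt(2) / 3 * c(1, 1), tolerance = 1e-10)

  e_same <- structure(list(members = list(const_member(5), const_member(5)),
                           membership = list(1:3, 1:3),
                           subset_fraction = 0.5, n_subsets = 2, seed = 1),
                      class = "ensemble_model")
  pr2 <- predict_ensemble(e_same, X)
  expect_equal(pr2$sem, c(0, 0))
  expect_equal(pr2$cv_pct, c(0, 0))
})

test_that("Method 2 ensembles generalize on planted-network data and beat members", {
  # nonlinear ground truth: 2-hidden-node logistic network
  truth <- with_seed_local(60, list(
    input_weights = matrix(c(0.5, rnorm(27, 0, 0.3),
                             -0.3, rnorm(27, 0, 0.3)),
                           2, 28, byrow = TRUE),
    output_weights = c(7, 3, -3)))
  peps_tr <- random_peptides(400, 9, seed = 61)
  peps_te <- random_peptides(200, 9, seed = 62)
  enc <- function(p) t(vapply(p, encode_peptide, numeric(27)))
  Xtr <- enc(peps_tr); Xte <- enc(peps_te)
  sig <- function(X) {
    act <- cbind(1, X) %*% t(truth$input_weights)
    as.vector(cbind(1, 1 / (1 + exp(-act))) %*% truth$output_weights)
  }
  ytr <- sig(Xtr) + with_seed_local(63, rnorm(400, 0, 0.3))
  yte <- sig(Xte) + with_seed_local(64, rnorm(200, 0, 0.3))
  e <- suppressWarnings(train_method2(Xtr, ytr, 9, penalty = 0.1,
                                      seed = 65, maxit = 400))
  pr <- predict_ensemble(e, Xte)
  r2_oos <- 1 - sum((yte - pr$mean_ln_ic50)^2) /
    sum((yte - mean(yte))^2)
  expect_gte(r2_oos, 0.8)
  # ensemble mean squared error <= average member squared error (Jensen)
  member_mse <- mean(vapply(e$members, function(m)
    mean((yte - predict(m, Xte))^2), numeric(1)))
  expect_lte(mean((yte - pr$mean_ln_ic50)^2), member_mse)
})

test_that("ensembles round-trip through JSON serialization", {
  prob <- linear_problem(90, 9, 4, 0.3, r2_target = 0.9, seed = 66)
  e <- suppressWarnings(train_method2(prob$X, prob$y, 9, n_subsets = 3,
                                      penalty = 0.2, seed = 8,
                                      maxit = 200))
  path <- tempfile(fileext = ".json")
  write_model(e, path)
  back <- read_model(path)
  expect_s3_class(back, "ensemble_model")
  expect_equal(predict_ensemble(back, prob$X[1:10, ]),
               predict_ensemble(e, prob$X[1:10, ]))
  expect_equal(back$membership, e$membership)
})
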