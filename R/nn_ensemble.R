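#' @importFrom nnet nnet
NULL

# Evaluate an expression under a fixed RNG seed without disturbing the
# caller's random-number stream.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

r_squared <- function(obs, pred) {
  1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
}

#' Train a three-layer perceptron regressor
#'
#' Single hidden layer with logistic activation 1/(1+e^-x) and a linear
#' output node (the response, ln ic50, is unbounded). The objective is
#' penalized least squares, sum((y - yhat)^2) + lambda * sum(w^2) over
#' all weights including biases, minimized by quasi-Newton optimization
#' (via \code{nnet}) from small random initial weights drawn uniformly in
#' [-0.1, 0.1] from the seed. Inputs and response are standardized
#' internally for optimizer conditioning and inverse-mapped on output;
#' the penalty applies on the standardized scale. Training is a pure
#' function of (X, y, n_hidden, penalty, seed).
#'
#' By convention the hidden-layer width equals the binding-domain length:
#' 9 nodes for MHC-I 9-mers, 15 for MHC-II 15-mers.
#'
#' @param X n x K descriptor matrix.
#' @param y length-n response.
#' @param n_hidden hidden nodes H.
#' @param penalty L2 penalty lambda >= 0.
#' @param seed integer seed for the weight initialization.
#' @param maxit optimizer iteration cap (default 2000).
#' @return object of class \code{perceptron_model}: weights
#'   (\code{input_weights} H x (K+1) incl. bias, \code{output_weights}
#'   H+1 incl. bias), standardization parameters, \code{train_r2},
#'   \code{converged} flag.
#' @export
train_perceptron <- function(X, y, n_hidden, penalty = 0, seed = 1,
                             maxit = 2000L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); K <- ncol(X)
  if (length(y) != n) stop("X and y dimensions disagree")
  if (anyNA(X) || anyNA(y) || any(!is.finite(X)) || any(!is.finite(y))) {
    stop("non-finite values in X or y")
  }
  if (penalty < 0) stop("penalty must be >= 0")
  if (n < 10 * n_hidden) {
    warning(sprintf("only %d rows for %d hidden nodes (< 10 per node)",
                    n, n_hidden))
  }
  x_center <- colMeans(X)
  x_scale <- apply(X, 2, sd); x_scale[x_scale == 0] <- 1
  y_center <- mean(y)
  y_scale <- sd(y); if (y_scale == 0) y_scale <- 1
  Xs <- scale(X, center = x_center, scale = x_scale)
  ys <- (y - y_center) / y_scale
  nw <- n_hidden * (K + 1L) + (n_hidden + 1L)
  fit <- with_seed(seed, {
    w0 <- runif(nw, -0.1, 0.1)
    nnet::nnet(x = Xs, y = ys, size = n_hidden, linout = TRUE,
               decay = penalty, maxit = maxit, Wts = w0,
               MaxNWts = nw + 1L, trace = FALSE,
               abstol = 1e-8, reltol = 1e-10)
  })
  wts <- fit$wts
  input_weights <- matrix(wts[seq_len(n_hidden * (K + 1L))],
                          nrow = n_hidden, ncol = K + 1L, byrow = TRUE)
  output_weights <- wts[n_hidden * (K + 1L) + seq_len(n_hidden + 1L)]
  m <- structure(list(n_inputs = K, n_hidden = n_hidden,
                      input_weights = input_weights,
                      output_weights = output_weights,
                      penalty = penalty, seed = seed,
                      x_center = x_center, x_scale = x_scale,
                      y_center = y_center, y_scale = y_scale,
                      x_range = apply(X, 2, range),
                      converged = is.null(fit$convergence) ||
                        fit$convergence == 0,
                      train_r2 = NA_real_),
                 class = "perceptron_model")
  m$train_r2 <- r_squared(y, predict(m, X))
  m
}

#' Predict from a perceptron model
#'
#' Forward pass through the stored weights: standardize inputs, logistic
#' hidden layer, linear output, inverse-map to the response scale.
#'
#' @param object a \code{perceptron_model}.
#' @param X matrix with K columns.
#' @param ... unused.
#' @return numeric vector of predicted ln(ic50).
#' @export
predict.perceptron_model <- function(object, X, ...) {
  X <- as.matrix(X)
  if (ncol(X) != object$n_inputs) {
    stop(sprintf("X has %d columns; model expects %d",
                 ncol(X), object$n_inputs))
  }
  Xs <- scale(X, center = object$x_center, scale = object$x_scale)
  act <- cbind(1, Xs) %*% t(object$input_weights)
  hid <- 1 / (1 + exp(-act))
  ys <- as.vector(cbind(1, hid) %*% object$output_weights)
  object$y_center + object$y_scale * ys
}

#' @export
print.perceptron_model <- function(x, ...) {
  cat(sprintf("perceptron: %d-%d-1, lambda = %g, train r2 = %.3f\n",
              x$n_inputs, x$n_hidden, x$penalty, x$train_r2))
  invisible(x)
}

#' Tune the overfitting penalty toward a target training r-squared
#'
#' Training r2 decreases monotonically in the L2 penalty, so a target
#' (default 0.9, matching the share of property variance the three
#' z-scale components carry) is located by bracketing on a log-spaced
#' lambda grid followed by bisection, stopping when the training r2 is
#' within +/-0.02 of the target or the bracket is exhausted. If even the
#' unpenalized fit cannot reach the target, lambda = 0 is returned with
#' attribute \code{attained = FALSE}.
#'
#' @param X,y,n_hidden,seed as in \code{\link{train_perceptron}}.
#' @param target_r2 target training r2, in (0, 1).
#' @param tol acceptance half-width on r2 (default 0.02).
#' @param maxit per-fit optimizer cap.
#' @return lambda (numeric scalar) with attributes \code{r2} (training r2
#'   at the returned lambda) and \code{attained} (logical).
#' @export
tune_penalty <- function(X, y, n_hidden, target_r2 = 0.9, seed = 1,
                         tol = 0.02, maxit = 2000L) {
  if (target_r2 <= 0 || target_r2 >= 1) stop("target_r2 must be in (0,1)")
  r2_at <- function(lam) {
    train_perceptron(X, y, n_hidden, penalty = lam, seed = seed,
                     maxit = maxit)$train_r2
  }
  r0 <- r2_at(0)
  if (r0 < target_r2) {
    return(structure(0, r2 = r0, attained = FALSE))
  }
  lo <- 1e-6; r_lo <- r2_at(lo)
  if (r_lo < target_r2 - tol) {
    # even a vanishing penalty lands below target; accept lambda ~ 0
    return(structure(lo, r2 = r_lo, attained = abs(r_lo - target_r2) <= tol))
  }
  if (abs(r_lo - target_r2) <= tol) {
    return(structure(lo, r2 = r_lo, attained = TRUE))
  }
  hi <- lo; r_hi <- r_lo
  while (r_hi > target_r2 && hi < 1e6) {
    hi <- hi * 10
    r_hi <- r2_at(hi)
  }
  if (r_hi > target_r2) {
    return(structure(hi, r2 = r_hi, attained = FALSE))
  }
  for (i in seq_len(30L)) {
    mid <- sqrt(lo * hi)
    r_mid <- r2_at(mid)
    if (abs(r_mid - target_r2) <= tol) {
      return(structure(mid, r2 = r_mid, attained = TRUE))
    }
    if (r_mid > target_r2) lo <- mid else hi <- mid
  }
  mid <- sqrt(lo * hi)
  r_mid <- r2_at(mid)
  structure(mid, r2 = r_mid, attained = abs(r_mid - target_r2) <= tol)
}

#' Method 1: multi-tour random-holdback training
#'
#' Runs \code{n_tours} independent training tours. Each tour holds back a
#' random fraction of the rows, trains a perceptron on the remainder
#' (penalty tuned once on the full data unless supplied), and scores the
#' tour by r2 on its held-back rows. The tour with the best holdback r2
#' is returned (ties: first tour wins).
#'
#' @param X,y,n_hidden as in \code{\link{train_perceptron}}.
#' @param n_tours number of tours (>= 2, default 5).
#' @param holdback_fraction fraction of rows held back per tour
#'   (default 1/3).
#' @param penalty L2 penalty; \code{NULL} (default) tunes it via
#'   \code{\link{tune_penalty}} on the full data.
#' @param seed master seed; tour splits and member seeds derive from it.
#' @param maxit per-fit optimizer cap.
#' @return the selected \code{perceptron_model}, with extra fields
#'   \code{holdback_r2}, \code{tour} (selected index) and
#'   \code{tour_r2} (all tours' holdback r2).
#' @export
train_method1 <- function(X, y, n_hidden, n_tours = 5,
                          holdback_fraction = 1/3, penalty = NULL,
                          seed = 1, maxit = 2000L) {
  if (n_tours < 2) stop("n_tours must be >= 2")
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (is.null(penalty)) {
    penalty <- as.numeric(tune_penalty(X, y, n_hidden, seed = seed,
                                       maxit = maxit))
  }
  plan <- with_seed(seed, {
    list(holds = lapply(seq_len(n_tours), function(i)
           sort(sample.int(n, round(holdback_fraction * n)))),
         seeds = sample.int(.Machine$integer.max - 1L, n_tours))
  })
  models <- vector("list", n_tours)
  hb_r2 <- numeric(n_tours)
  for (i in seq_len(n_tours)) {
    hold <- plan$holds[[i]]
    m <- train_perceptron(X[-hold, , drop = FALSE], y[-hold], n_hidden,
                          penalty = penalty, seed = plan$seeds[i],
                          maxit = maxit)
    hb_r2[i] <- r_squared(y[hold], predict(m, X[hold, , drop = FALSE]))
    models[[i]] <- m
  }
  best <- which.max(hb_r2)  # first-wins on ties
  m <- models[[best]]
  m$holdback_r2 <- hb_r2[best]
  m$tour <- best
  m$tour_r2 <- hb_r2
  m$holdback_idx <- plan$holds[[best]]
  m
}

#' Draw Method 2 subset memberships
#'
#' The row subsets Method 2 trains on: \code{n_subsets} independent
#' uniform draws of \code{floor(subset_fraction * n)} rows without
#' replacement. At the defaults (nine subsets of 2/3) each row is
#' expected to train about six of the nine members.
#'
#' @param n number of rows.
#' @param n_subsets number of subsets.
#' @param subset_fraction fraction per subset, in (0, 1).
#' @param seed integer seed.
#' @return list of sorted integer index vectors.
#' @export
method2_memberships <- function(n, n_subsets = 9, subset_fraction = 2/3,
                                seed = 1) {
  if (n_subsets < 2) stop("n_subsets must be >= 2")
  if (subset_fraction <= 0 || subset_fraction >= 1) {
    stop("subset_fraction must be in (0, 1)")
  }
  m <- floor(subset_fraction * n)
  with_seed(seed, lapply(seq_len(n_subsets), function(i)
    sort(sample.int(n, m))))
}

#' Method 2: random-subset ensemble training
#'
#' Trains one perceptron per random subset of the rows (nine subsets of
#' 2/3 by default, so each peptide serves in about six training cohorts)
#' and keeps all members; predictions are later averaged with
#' \code{\link{predict_ensemble}} to give a mean estimate, its standard
#' error, and a coefficient of variation.
#'
#' @inheritParams train_method1
#' @param n_subsets number of ensemble members (default 9).
#' @param subset_fraction training fraction per member (default 2/3).
#' @return object of class \code{ensemble_model}: \code{members},
#'   \code{membership} (row indices per member), \code{subset_fraction},
#'   \code{n_subsets}, \code{penalty}, \code{seed}.
#' @export
train_method2 <- function(X, y, n_hidden, n_subsets = 9,
                          subset_fraction = 2/3, penalty = NULL,
                          seed = 1, maxit = 2000L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  membership <- method2_memberships(n, n_subsets, subset_fraction, seed)
  if (floor(subset_fraction * n) < 10 * n_hidden) {
    warning(sprintf("subset size %d below 10 rows per hidden node",
                    floor(subset_fraction * n)))
  }
  if (is.null(penalty)) {
    penalty <- as.numeric(tune_penalty(X, y, n_hidden, seed = seed,
                                       maxit = maxit))
  }
  seeds <- with_seed(seed + 1L,
                     sample.int(.Machine$integer.max - 1L, n_subsets))
  members <- lapply(seq_len(n_subsets), function(i) {
    idx <- membership[[i]]
    train_perceptron(X[idx, , drop = FALSE], y[idx], n_hidden,
                     penalty = penalty, seed = seeds[i], maxit = maxit)
  })
  structure(list(members = members, membership = membership,
                 subset_fraction = subset_fraction, n_subsets = n_subsets,
                 penalty = penalty, seed = seed),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("perceptron ensemble: %d members, %.0f%% subsets, lambda = %g\n",
              x$n_subsets, 100 * x$subset_fraction, x$penalty))
  invisible(x)
}

#' Averaged ensemble predictions with SEM and CV\%
#'
#' Each row is predicted by every ensemble member; the member predictions
#' are summarized as their mean, the standard error of that mean
#' (sd/sqrt(m)) and the coefficient of variation 100*sd/|mean| on the
#' ln(ic50) scale. A mean within 1e-9 of zero leaves cv_pct undefined
#' (NA).
#'
#' @param e an \code{ensemble_model}.
#' @param X descriptor matrix.
#' @return data frame with columns \code{mean_ln_ic50}, \code{sem},
#'   \code{cv_pct}.
#' @export
predict_ensemble <- function(e, X) {
  stopifnot(inherits(e, "ensemble_model"))
  X <- as.matrix(X)
  preds <- vapply(e$members, function(m) predict(m, X),
                  numeric(nrow(X)))
  if (nrow(X) == 1L) preds <- matrix(preds, nrow = 1L)
  mu <- rowMeans(preds)
  sdv <- apply(preds, 1, sd)
  data.frame(mean_ln_ic50 = mu,
             sem = sdv / sqrt(length(e$members)),
             cv_pct = ifelse(abs(mu) < 1e-9, NA_real_,
                             100 * sdv / abs(mu)))
}
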