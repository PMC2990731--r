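#' Fit a PLS regression model by NIPALS
#'
#' Partial least squares regression of a single response on a descriptor
#' matrix, computed dimension-by-dimension with NIPALS deflation.
#' Descriptor columns are centered but not rescaled: z-scale descriptors
#' already carry the eigenvalue weighting of the property PCA, so their
#' relative magnitudes are informative. The response is centered only.
#'
#' Per dimension the weight vector is iterated to convergence (tolerance
#' \code{1e-10} on the change in the unit weight vector, at most 500
#' iterations; with a single response NIPALS converges in one pass) and
#' both blocks are deflated by the extracted score. The residual sum of
#' squares of the centered response after 0..A dimensions is recorded as
#' \code{ssy}, so \code{ssy[a] - ssy[a+1]} is the response SS explained
#' by dimension a+1 — the quantity the VIP formula weights by.
#'
#' @param X n x K descriptor matrix.
#' @param y length-n numeric response (ln ic50).
#' @param n_factors number of latent dimensions A (1 <= A < n, A <=
#'   rank of the centered X).
#' @param allele optional allele tag stored in the model.
#' @param position_labels optional K/3 position labels; inferred from K
#'   when K is 27 or 45.
#' @return an object of class \code{pls_model} with elements
#'   \code{n_factors}, \code{weights} (K x A, unit columns),
#'   \code{x_loadings}, \code{y_loadings}, \code{scores},
#'   \code{coefficients}, \code{x_center}, \code{y_center}, \code{ssy}
#'   (length A+1), \code{position_labels}, \code{low_n} flag.
#' @export
fit_pls <- function(X, y, n_factors, allele = NA_character_,
                    position_labels = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); K <- ncol(X)
  if (length(y) != n) stop("X and y dimensions disagree")
  if (anyNA(X) || anyNA(y)) stop("missing values in X or y")
  if (n_factors < 1) stop("n_factors must be >= 1")
  if (n <= n_factors) stop("need more observations than factors")
  if (var(y) == 0) stop("response has zero variance")
  x_center <- colMeans(X)
  y_center <- mean(y)
  Xc <- sweep(X, 2, x_center)
  rk <- qr(Xc)$rank
  if (n_factors > rk) {
    stop(sprintf("n_factors (%d) exceeds rank of centered X (%d)",
                 n_factors, rk))
  }
  yc <- y - y_center
  A <- n_factors
  W <- matrix(0, K, A); P <- matrix(0, K, A)
  Tm <- matrix(0, n, A); q <- numeric(A)
  ssy <- numeric(A + 1)
  ssy[1] <- sum(yc^2)
  Xa <- Xc; ya <- yc
  for (a in seq_len(A)) {
    w <- crossprod(Xa, ya)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) stop("no covariance left to extract at dimension ", a)
    w <- as.vector(w / nw)
    # NIPALS iteration; immediate for a single response but kept for form
    for (iter in seq_len(500L)) {
      t_ <- as.vector(Xa %*% w)
      qa <- sum(ya * t_) / sum(t_^2)
      u <- ya / qa
      w_new <- crossprod(Xa, u)
      w_new <- as.vector(w_new / sqrt(sum(w_new^2)))
      if (sqrt(sum((w_new - w)^2)) < 1e-10) { w <- w_new; break }
      w <- w_new
    }
    t_ <- as.vector(Xa %*% w)
    tt <- sum(t_^2)
    p <- as.vector(crossprod(Xa, t_)) / tt
    qa <- sum(ya * t_) / tt
    Xa <- Xa - tcrossprod(t_, p)
    ya <- ya - qa * t_
    W[, a] <- w; P[, a] <- p; Tm[, a] <- t_; q[a] <- qa
    ssy[a + 1] <- sum(ya^2)
  }
  coefficients <- as.vector(W %*% solve(crossprod(P, W), q))
  if (is.null(position_labels) && K %% 3 == 0) {
    L <- K %/% 3
    position_labels <- if (L == 9L) position_labels(9L, "I")
                       else if (L == 15L) position_labels(15L, "II")
                       else paste0("pos", seq_len(L))
  }
  structure(list(n_factors = A, weights = W, x_loadings = P,
                 y_loadings = q, scores = Tm,
                 coefficients = coefficients,
                 x_center = x_center, y_center = y_center,
                 x_range = apply(X, 2, range), ssy = ssy,
                 position_labels = position_labels,
                 allele = allele, n = n, low_n = n < 30),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("PLS model%s: %d factors, K = %d descriptors, n = %d%s\n",
              if (is.na(x$allele)) "" else paste0(" [", x$allele, "]"),
              x$n_factors, length(x$coefficients), x$n,
              if (x$low_n) " (flagged: < 30 training peptides)" else ""))
  expl <- 1 - x$ssy[length(x$ssy)] / x$ssy[1]
  cat(sprintf("response SS explained: %.3f\n", expl))
  invisible(x)
}

#' Predict from a PLS model
#'
#' @param object a \code{pls_model}.
#' @param X matrix with the same K columns as the training descriptors.
#' @param ... unused.
#' @return numeric vector of predicted ln(ic50).
#' @export
predict.pls_model <- function(object, X, ...) {
  X <- as.matrix(X)
  if (ncol(X) != length(object$coefficients)) {
    stop(sprintf("X has %d columns; model expects %d",
                 ncol(X), length(object$coefficients)))
  }
  as.vector(object$y_center +
              sweep(X, 2, object$x_center) %*% object$coefficients)
}

# Cumulative coefficient vectors B_a for a = 1..A (K x A matrix), used by
# cross-validated factor selection.
pls_coef_path <- function(m) {
  A <- m$n_factors
  B <- matrix(0, length(m$coefficients), A)
  for (a in seq_len(A)) {
    W <- m$weights[, seq_len(a), drop = FALSE]
    P <- m$x_loadings[, seq_len(a), drop = FALSE]
    q <- m$y_loadings[seq_len(a)]
    B[, a] <- as.vector(W %*% solve(crossprod(P, W), q))
  }
  B
}

#' Choose the number of PLS latent factors by cross-validated PRESS
#'
#' Contiguous-block K-fold cross-validation: the rows are cut into
#' \code{n_folds} consecutive blocks, each block is predicted from a model
#' fitted to the remaining rows, and the predictive residual sum of
#' squares (PRESS) is accumulated for every candidate dimensionality. The
#' returned A is the smallest whose PRESS is within 2\% of the minimum
#' over 1..\code{max_factors} (parsimony rule). Folds are deterministic;
#' the \code{seed} argument is accepted for interface stability but has
#' no effect on contiguous blocks.
#'
#' @param X,y as in \code{\link{fit_pls}}.
#' @param max_factors largest dimensionality scanned.
#' @param n_folds number of CV blocks (default 7).
#' @param seed unused (deterministic folds).
#' @return integer, the selected number of factors; attribute
#'   \code{press} holds the PRESS value per candidate A.
#' @export
select_factors <- function(X, y, max_factors, n_folds = 7, seed = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (max_factors < 1) stop("max_factors must be >= 1")
  folds <- as.integer(cut(seq_len(n), breaks = n_folds, labels = FALSE))
  press <- rep(0, max_factors)
  for (f in seq_len(n_folds)) {
    idx <- folds == f
    Xtr <- X[!idx, , drop = FALSE]; ytr <- y[!idx]
    A_f <- min(max_factors, qr(sweep(Xtr, 2, colMeans(Xtr)))$rank,
               nrow(Xtr) - 1L)
    m <- fit_pls(Xtr, ytr, A_f)
    B <- pls_coef_path(m)
    Xte <- sweep(X[idx, , drop = FALSE], 2, m$x_center)
    for (a in seq_len(max_factors)) {
      aa <- min(a, A_f)
      pred <- m$y_center + as.vector(Xte %*% B[, aa])
      press[a] <- press[a] + sum((y[idx] - pred)^2)
    }
  }
  A <- which(press <= 1.02 * min(press))[1]
  structure(as.integer(A), press = press)
}

#' Variable importance in projection (VIP)
#'
#' For predictor k over a fitted A-dimension PLS model,
#' \deqn{VIP_k = \sqrt{ K \sum_{a=1}^{A} w_{ak}^2 (SSY_{a-1} - SSY_a)
#'   / (SSY_0 - SSY_A) }}
#' where \eqn{w_{ak}} is the unit PLS weight of predictor k on dimension
#' a and \eqn{SSY_{a-1} - SSY_a} the response sum of squares explained by
#' that dimension. The squared VIPs sum to K, so the average VIP is 1 and
#' predictors with VIP > 1 are the ones most relevant to the response.
#'
#' @param m a fitted \code{pls_model} whose descriptors are position x
#'   component z-scales (K divisible by 3).
#' @return an object of class \code{vip_matrix}: list with \code{allele},
#'   \code{values} (L x 3 grid, rows = groove positions, columns =
#'   PC1..PC3) and \code{vip_flat} (length K, descriptor order).
#' @export
compute_vip <- function(m) {
  stopifnot(inherits(m, "pls_model"))
  A <- m$n_factors
  K <- nrow(m$weights)
  expl <- m$ssy[seq_len(A)] - m$ssy[seq_len(A) + 1]
  total <- m$ssy[1] - m$ssy[A + 1]
  if (total <= 0) stop("model explains no response variance; VIP undefined")
  vip2 <- K * as.vector(m$weights^2 %*% expl) / total
  vip <- sqrt(vip2)
  ncomp <- 3L
  if (K %% ncomp != 0) {
    stop("descriptor count is not a multiple of 3; no position grid")
  }
  grid <- matrix(vip, ncol = ncomp, byrow = TRUE)
  rownames(grid) <- m$position_labels
  colnames(grid) <- paste0("PC", seq_len(ncomp))
  structure(list(allele = m$allele, values = grid, vip_flat = vip),
            class = "vip_matrix")
}

#' @export
print.vip_matrix <- function(x, ...) {
  cat(sprintf("VIP matrix%s (%d positions x %d components)\n",
              if (is.na(x$allele)) "" else paste0(" [", x$allele, "]"),
              nrow(x$values), ncol(x$values)))
  print(round(x$values, 3))
  invisible(x)
}

#' Export VIP matrices as a TSV table
#'
#' One row per allele, one column per position x principal component
#' (supplementary-table style layout).
#'
#' @param vips a \code{vip_matrix} or list of them (same geometry).
#' @param path output TSV path.
#' @export
write_vip_table <- function(vips, path) {
  if (inherits(vips, "vip_matrix")) vips <- list(vips)
  labs <- as.vector(t(outer(rownames(vips[[1]]$values),
                            colnames(vips[[1]]$values), paste, sep = ".")))
  rows <- lapply(vips, function(v) v$vip_flat)
  df <- data.frame(allele = vapply(vips, function(v) v$allele, character(1)),
                   do.call(rbind, rows), check.names = FALSE)
  names(df)[-1] <- labs
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a VIP TSV table back into vip_matrix objects
#'
#' @param path TSV written by \code{\link{write_vip_table}}.
#' @return list of \code{vip_matrix} objects.
#' @export
read_vip_table <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  labs <- names(df)[-1]
  pos <- unique(sub("\\.PC[0-9]+$", "", labs))
  lapply(seq_len(nrow(df)), function(i) {
    flat <- as.numeric(df[i, -1])
    grid <- matrix(flat, ncol = 3, byrow = TRUE,
                   dimnames = list(pos, paste0("PC", 1:3)))
    structure(list(allele = df$allele[i], values = grid, vip_flat = flat),
              class = "vip_matrix")
  })
}
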