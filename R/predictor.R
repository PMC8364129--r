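#' Assemble a property dataset
#'
#' Wraps a feature table plus observed property values with the property
#' range \eqn{[\underline{a}, \overline{a}]} used later for target-value
#' admissibility.
#'
#' @param data tibble with `id`, the K descriptor columns of `spec`, and
#'   `value`.
#' @param spec a [descriptor_spec()].
#' @return object of class `property_dataset`.
#' @export
property_dataset <- function(data, spec) {
  stopifnot(all(c("id", "value") %in% names(data)), all(spec$names %in% names(data)))
  structure(list(data = tibble::as_tibble(data), spec = spec,
                 a_lo = min(data$value), a_hi = max(data$value)),
            class = "property_dataset")
}

#' @export
print.property_dataset <- function(x, ...) {
  cat("<property_dataset>", nrow(x$data), "records, value range [",
      signif(x$a_lo, 4), ",", signif(x$a_hi, 4), "]\n")
  invisible(x)
}

#' Train a piecewise-linear (ReLU) regressor
#'
#' A single-hidden-layer network `(K, h, 1)` with ReLU activations fitted by
#' full-batch BFGS on the mean squared error with analytic gradients.
#' Inputs and the response are standardised internally and the scaling is
#' folded back into the exported weights, so the returned weight matrices
#' act on raw descriptor vectors exactly as the forward pass does.
#' A small L2 penalty on the weight matrices (not the biases) gives the
#' underdetermined fit a minimal-norm inductive bias; descriptor sets are
#' highly collinear, and without it held-out predictions wander along
#' directions the training sample does not pin down. Training is
#' deterministic given the seed.
#'
#' @param dataset a [property_dataset()].
#' @param hidden hidden-layer width (default 10, architecture `(K, 10, 1)`).
#' @param seed integer seed for the weight initialisation.
#' @param maxit BFGS iteration budget.
#' @param lambda L2 weight-decay coefficient on the standardised scale.
#' @return object of class `trained_predictor` with fields `W1`, `b1`, `W2`,
#'   `b2`, `spec`, `arch`, `n_A` (node count), `n_B` (ReLU break-points),
#'   `a_lo`, `a_hi`, `seed`.
#' @export
train <- function(dataset, hidden = 10L, seed = 1L, maxit = 400L, lambda = 1e-3) {
  stopifnot(inherits(dataset, "property_dataset"))
  spec <- dataset$spec
  X <- as.matrix(dataset$data[, spec$names])
  y <- dataset$data$value
  if (nrow(X) < 2) stop("need at least two records to train")
  if (stats::sd(y) == 0) warning("constant-target dataset; training proceeds")

  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  ym <- mean(y); ys <- stats::sd(y); if (ys == 0) ys <- 1
  yn <- (y - ym) / ys

  K <- ncol(X); h <- as.integer(hidden)
  n_par <- h * K + h + h + 1L
  unpack <- function(th) {
    W1 <- matrix(th[seq_len(h * K)], h, K)
    b1 <- th[h * K + seq_len(h)]
    W2 <- th[h * K + h + seq_len(h)]
    b2 <- th[n_par]
    list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  }
  fwd <- function(p, X) {
    A <- X %*% t(p$W1)
    A <- sweep(A, 2, p$b1, "+")
    Z <- pmax(A, 0)
    list(A = A, Z = Z, yhat = as.numeric(Z %*% p$W2 + p$b2))
  }
  wmask <- c(rep(1, h * K), rep(0, h), rep(1, h), 0)   # decay weights, not biases
  loss <- function(th) {
    p <- unpack(th)
    f <- fwd(p, Xs)
    mean((f$yhat - yn)^2) + lambda * sum((th * wmask)^2)
  }
  grad <- function(th) {
    p <- unpack(th)
    f <- fwd(p, Xs)
    N <- length(yn)
    r <- 2 * (f$yhat - yn) / N          # N
    gW2 <- as.numeric(t(f$Z) %*% r)     # h
    gb2 <- sum(r)
    D <- (f$A > 0) * 1
    Rh <- (r %o% p$W2) * D              # N x h
    gW1 <- t(Rh) %*% Xs                 # h x K
    gb1 <- colSums(Rh)
    c(as.numeric(gW1), gb1, gW2, gb2) + 2 * lambda * th * wmask
  }
  th0 <- with_local_seed(seed, stats::rnorm(n_par, 0, 0.5 / sqrt(K)))
  fit <- stats::optim(th0, fn = loss, gr = grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-12))
  p <- unpack(fit$par)

  # fold standardisation back into raw-input weights:
  # z = W1 ((x - mu)/sd) + b1  =>  W1' = W1 / sd,  b1' = b1 - W1 (mu/sd)
  W1r <- sweep(p$W1, 2, sdv, "/")
  b1r <- p$b1 - as.numeric(p$W1 %*% (mu / sdv))
  W2r <- p$W2 * ys
  b2r <- p$b2 * ys + ym

  structure(list(W1 = W1r, b1 = b1r, W2 = W2r, b2 = b2r,
                 spec = spec, arch = c(K, h, 1L),
                 n_A = K + h + 1L, n_B = h,
                 a_lo = dataset$a_lo, a_hi = dataset$a_hi,
                 seed = seed, value = fit$value),
            class = "trained_predictor")
}

#' Forward evaluation of a trained predictor
#'
#' Raw piecewise-linear output \eqn{\psi(x)}; no clipping (the clipped
#' variant for reporting is `pmin(pmax(., a_lo), a_hi)` applied by callers).
#'
#' @param object a `trained_predictor`.
#' @param newdata matrix (rows = samples) or numeric vector of length K, in
#'   canonical descriptor order.
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.trained_predictor <- function(object, newdata, ...) {
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  A <- sweep(X %*% t(object$W1), 2, object$b1, "+")
  as.numeric(pmax(A, 0) %*% object$W2 + object$b2)
}

#' @export
print.trained_predictor <- function(x, ...) {
  cat("<trained_predictor> architecture (", paste(x$arch, collapse = ", "),
      "), ReLU; n_A =", x$n_A, " n_B =", x$n_B, "\n")
  invisible(x)
}

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - \sum_j (y_j - \psi_j)^2 / \sum_j (y_j - \bar y)^2}.
#'
#' @param observed,predicted numeric vectors of equal length (N >= 2).
#' @return numeric scalar.
#' @export
r_squared <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  ss <- sum((observed - mean(observed))^2)
  if (ss == 0) stop("observed values have zero variance; R^2 undefined")
  1 - sum((observed - predicted)^2) / ss
}

#' Five-fold cross-validation
#'
#' Random partition into `n_folds` subsets of near-equal size (sizes differ
#' by at most one); each fold is held out once. Reports per-fold test
#' R-squared plus the mean and the best fold.
#'
#' @param dataset a [property_dataset()].
#' @param hidden hidden width.
#' @param n_folds number of folds (default 5).
#' @param seed integer seed controlling both the partition and training inits.
#' @param maxit per-fold BFGS budget.
#' @return object of class `cv_result`: list with `folds` (tibble: fold,
#'   n_test, r2), `mean_r2`, `best_r2`, `models`.
#' @export
cross_validate <- function(dataset, hidden = 10L, n_folds = 5L, seed = 1L, maxit = 300L) {
  N <- nrow(dataset$data)
  stopifnot(N >= n_folds)
  fold_of <- with_local_seed(seed, sample(rep(seq_len(n_folds), length.out = N)))
  rows <- list(); models <- list()
  for (k in seq_len(n_folds)) {
    tr_idx <- which(fold_of != k); te_idx <- which(fold_of == k)
    d_tr <- property_dataset(dataset$data[tr_idx, ], dataset$spec)
    mod <- train(d_tr, hidden = hidden, seed = seed + k, maxit = maxit)
    yhat <- predict(mod, as.matrix(dataset$data[te_idx, dataset$spec$names]))
    rows[[k]] <- tibble::tibble(fold = k, n_test = length(te_idx),
                                r2 = r_squared(dataset$data$value[te_idx], yhat))
    models[[k]] <- mod
  }
  folds <- dplyr::bind_rows(rows)
  structure(list(folds = folds, mean_r2 = mean(folds$r2), best_r2 = max(folds$r2),
                 models = models, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result>", nrow(x$folds), "folds; mean R2 =", signif(x$mean_r2, 4),
      "; best R2 =", signif(x$best_r2, 4), "\n")
  invisible(x)
}

#' @rdname cross_validate
#' @param x a `cv_result`.
#' @param ... unused.
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) x$folds

#' @rdname cross_validate
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(n_folds = nrow(x$folds), mean_r2 = x$mean_r2, best_r2 = x$best_r2)
}

#' Glance at a trained predictor
#' @param x a `trained_predictor`.
#' @param ... unused.
#' @return one-row tibble with architecture and training loss.
#' @method glance trained_predictor
#' @export
glance.trained_predictor <- function(x, ...) {
  tibble::tibble(K = x$arch[1], hidden = x$arch[2], n_A = x$n_A, n_B = x$n_B,
                 train_mse = x$value, seed = x$seed)
}

#' Range-based applicability domain
#'
#' Per-descriptor minimum and maximum over the training records, after
#' applying each descriptor's normalisation rule. By default every element
#' count `ce_a^t` is normalised by n(G); everything else is taken raw.
#'
#' @param dataset a [property_dataset()].
#' @param normalise character vector of descriptor names to divide by `n`;
#'   `NULL` for the default (all `ce_*`).
#' @return object of class `ad_bounds`: tibble with `descriptor`, `rule`,
#'   `lo`, `hi`.
#' @export
ad_bounds <- function(dataset, normalise = NULL) {
  spec <- dataset$spec
  if (is.null(normalise)) normalise <- grep("^ce_", spec$names, value = TRUE)
  X <- as.matrix(dataset$data[, spec$names])
  n <- dataset$data$n
  out <- tibble::tibble(
    descriptor = spec$names,
    rule = ifelse(spec$names %in% normalise, "divide_by_n", "raw")
  )
  vals <- lapply(seq_along(spec$names), function(j) {
    v <- X[, j]
    if (out$rule[j] == "divide_by_n") v <- v / n
    c(min(v), max(v))
  })
  out$lo <- vapply(vals, `[`, numeric(1), 1)
  out$hi <- vapply(vals, `[`, numeric(1), 2)
  class(out) <- c("ad_bounds", class(out))
  out
}

#' Does a feature vector lie in the applicability domain?
#'
#' @param x feature vector (named, canonical order).
#' @param ad an [ad_bounds()].
#' @param tol slack for floating comparisons.
#' @return logical.
#' @export
in_ad <- function(x, ad, tol = 1e-9) {
  n <- x[["n"]]
  all(vapply(seq_len(nrow(ad)), function(j) {
    v <- x[[ad$descriptor[j]]]
    if (ad$rule[j] == "divide_by_n") v <- v / n
    v >= ad$lo[j] - tol && v <= ad$hi[j] + tol
  }, logical(1)))
}

#' Export / import predictor weights as JSON
#'
#' Layer matrices, biases and the activation tag, exactly as used by the
#' forward pass and the MILP encoder.
#'
#' @param model a `trained_predictor`.
#' @param path file path.
#' @return `read_predictor_json()` returns a `trained_predictor` (without
#'   the original descriptor spec attached unless supplied).
#' @param spec optional [descriptor_spec()] to re-attach.
#' @export
write_predictor_json <- function(model, path) {
  jsonlite::write_json(list(
    activation = "relu",
    arch = model$arch,
    W1 = model$W1, b1 = model$b1, W2 = model$W2, b2 = model$b2,
    a_lo = model$a_lo, a_hi = model$a_hi, seed = model$seed,
    descriptor_names = model$spec$names
  ), path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_predictor_json
#' @export
read_predictor_json <- function(path, spec = NULL) {
  x <- jsonlite::fromJSON(path)
  W1 <- x$W1
  if (!is.matrix(W1)) W1 <- matrix(unlist(W1), nrow = x$arch[2], byrow = TRUE)
  stopifnot(nrow(W1) == x$arch[2], ncol(W1) == x$arch[1])
  structure(list(W1 = W1, b1 = as.numeric(x$b1), W2 = as.numeric(x$W2),
                 b2 = as.numeric(x$b2), spec = spec,
                 arch = as.integer(x$arch),
                 n_A = as.integer(x$arch[1] + x$arch[2] + 1L),
                 n_B = as.integer(x$arch[2]),
                 a_lo = x$a_lo, a_hi = x$a_hi, seed = x$seed, value = NA_real_),
            class = "trained_predictor")
}
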