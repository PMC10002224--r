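#' Fit a two-class linear discriminant model
#'
#' Class means and the pooled covariance
#' \deqn{S = \frac{(n_1-1)S_1 + (n_2-1)S_2}{n_1+n_2-2}}
#' define the linear discriminant
#' \deqn{d(x) = (\bar X_1-\bar X_2)' S^{-1}\,(x - \tfrac12(\bar X_1+\bar X_2)),}
#' with `x` assigned to class 1 when d(x) is non-negative (ties to class 1).
#' A singular pooled covariance is regularised by a ridge jitter
#' `lambda = 1e-8 * trace(S)/p` on the diagonal.
#'
#' @param X1,X2 numeric matrices (or vectors for p = 1): samples of class 1
#'   and class 2, one row per sample.
#' @param labels length-2 vector naming the classes (class 1 first).
#' @return Object of class `lda_model` with the means, pooled covariance and
#'   solved discriminant direction.
#' @export
lda_fit <- function(X1, X2, labels = c("1", "2")) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  n1 <- nrow(X1); n2 <- nrow(X2); p <- ncol(X1)
  if (p == 0 || n1 < 2 || n2 < 2)
    stop("lda_fit: need p >= 1 features and at least 2 samples per class")
  stopifnot(ncol(X2) == p)
  m1 <- colMeans(X1); m2 <- colMeans(X2)
  S1 <- stats::cov(X1); S2 <- stats::cov(X2)
  S <- ((n1 - 1) * S1 + (n2 - 1) * S2) / (n1 + n2 - 2)
  w <- tryCatch(solve(S, m1 - m2), error = function(e) NULL)
  if (is.null(w) || rcond(S) < 1e-12) {
    lambda <- 1e-8 * sum(diag(S)) / p
    if (lambda <= 0) lambda <- 1e-8
    message(sprintf("lda_fit: singular pooled covariance, ridge jitter %g",
                    lambda))
    S <- S + diag(lambda, p)
    w <- solve(S, m1 - m2)
  }
  structure(list(mean1 = m1, mean2 = m2, S = S, w = w,
                 labels = as.character(labels), p = p),
            class = "lda_model")
}

#' Discriminant value of a fitted LDA model
#' @param model an `lda_model`.
#' @param X matrix (rows = samples) or single feature vector.
#' @return Numeric vector of discriminant values (positive favours class 1).
#' @export
lda_discriminant <- function(model, X) {
  X <- if (is.null(dim(X))) matrix(X, ncol = model$p) else as.matrix(X)
  if (ncol(X) != model$p) stop("lda_discriminant: feature dimension mismatch")
  if (any(!is.finite(X))) stop("lda_discriminant: non-finite features")
  drop(sweep(X, 2, (model$mean1 + model$mean2) / 2) %*% model$w)
}

#' Predict class labels with a fitted LDA model
#' @inheritParams lda_discriminant
#' @return Character vector of class labels.
#' @export
lda_predict <- function(model, X) {
  d <- lda_discriminant(model, X)
  model$labels[ifelse(d >= 0, 1L, 2L)]
}

## ---------------------------------------------------------------------------
## Feed-forward network: 3 logistic hidden layers, one tanh output unit,
## full-batch bold-driver gradient descent on F = beta*SSE + alpha*||w||^2,
## with evidence-framework (Bayesian regularisation) updates of alpha, beta.
## ---------------------------------------------------------------------------

logistic <- function(z) 1 / (1 + exp(-z))

nn_init <- function(d, hidden, seed) {
  set.seed(seed)
  sizes <- c(d, hidden, 1L)
  W <- b <- list()
  for (l in seq_len(length(sizes) - 1)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l + 1] * sizes[l],
                                  sd = 1 / sqrt(sizes[l])),
                     sizes[l + 1], sizes[l])
    b[[l]] <- stats::rnorm(sizes[l + 1], sd = 0.1)
  }
  list(W = W, b = b, sizes = sizes)
}

## forward pass; returns activations per layer (A[[1]] = input)
nn_forward <- function(net, X) {
  L <- length(net$W)
  A <- vector("list", L + 1)
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z <- A[[l]] %*% t(net$W[[l]]) + matrix(net$b[[l]], nrow(X),
                                           length(net$b[[l]]), byrow = TRUE)
    A[[l + 1]] <- if (l < L) logistic(Z) else tanh(Z)
  }
  A
}

## flatten / unflatten weights (column-major per layer, biases appended)
nn_wvec <- function(net) unlist(lapply(seq_along(net$W), function(l)
  c(as.vector(net$W[[l]]), net$b[[l]])))

nn_unflatten <- function(net, v) {
  pos <- 1L
  for (l in seq_along(net$W)) {
    nw <- length(net$W[[l]])
    net$W[[l]][] <- v[pos:(pos + nw - 1)]
    pos <- pos + nw
    nb <- length(net$b[[l]])
    net$b[[l]] <- v[pos:(pos + nb - 1)]
    pos <- pos + nb
  }
  net
}

## gradient of SSE = sum (o - y)^2 wrt all weights, plus the per-sample
## Jacobian of the output when requested (for the Gauss-Newton Hessian)
nn_grad <- function(net, A, y, jacobian = FALSE) {
  L <- length(net$W)
  n <- nrow(A[[1]])
  o <- drop(A[[L + 1]])
  delta <- matrix((if (jacobian) 1 else 2 * (o - y)) * (1 - o^2), n, 1)
  gW <- gb <- vector("list", L)
  J <- if (jacobian) matrix(0, n, 0) else NULL
  for (l in L:1) {
    gW[[l]] <- t(delta) %*% A[[l]]
    gb[[l]] <- colSums(delta)
    if (jacobian) {
      nk <- ncol(delta); nj <- ncol(A[[l]])
      Jl <- A[[l]][, rep(seq_len(nj), each = nk), drop = FALSE] *
        delta[, rep(seq_len(nk), times = nj), drop = FALSE]
      J <- cbind(Jl, delta, J)
    }
    if (l > 1)
      delta <- (delta %*% net$W[[l]]) * A[[l]] * (1 - A[[l]])
  }
  g <- unlist(lapply(seq_len(L), function(l) c(as.vector(gW[[l]]), gb[[l]])))
  list(g = g, J = J)
}

#' Train the weaning-classification neural network
#'
#' Three logistic hidden layers and a single tanh output unit, trained by
#' full-batch backpropagation with a bold-driver adaptive step (a step that
#' increases the objective is rejected and the step size halved, so the
#' objective is non-increasing). The objective is
#' \eqn{F = \beta\,SSE + \alpha\,\lVert w\rVert^2}; with `reg = "bayes"`,
#' \eqn{\alpha} and \eqn{\beta} are re-estimated every `update_every` epochs by
#' the evidence framework with a Gauss-Newton Hessian approximation
#' (\eqn{\gamma = W - 2\alpha\,\mathrm{tr}\,H^{-1}},
#' \eqn{\alpha = \gamma/2E_w}, \eqn{\beta = (n-\gamma)/2E_d});
#' `reg = "decay"` keeps them fixed (plain weight decay).
#'
#' @param X numeric feature matrix (rows = samples); standardised internally.
#' @param y class labels (two distinct values; at least 2 samples per class).
#'   The first sorted level maps to the +1 target.
#' @param hidden hidden layer widths.
#' @param reg `"bayes"` or `"decay"`.
#' @param alpha,beta initial regularisation / error weights.
#' @param epochs maximum training epochs.
#' @param lr initial step size.
#' @param update_every epochs between evidence updates.
#' @param grad_tol stop when the gradient norm falls below this.
#' @param seed seed for weight initialisation.
#' @return Object of class `nn_model`.
#' @export
nn_fit <- function(X, y, hidden = c(10, 6, 3), reg = c("bayes", "decay"),
                   alpha = 0.01, beta = 1, epochs = 2000, lr = 0.01,
                   update_every = 25, grad_tol = 1e-8, seed = 1) {
  reg <- match.arg(reg)
  X <- as.matrix(X)
  lev <- sort(unique(as.character(y)))
  if (length(lev) != 2) stop("nn_fit: need exactly two classes")
  t_target <- ifelse(as.character(y) == lev[1], 1, -1)
  if (min(table(y)) < 2) stop("nn_fit: need >= 2 samples per class")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  n <- nrow(Xs)

  net <- nn_init(ncol(Xs), hidden, seed)
  w <- nn_wvec(net)
  nw <- length(w)
  objective <- function(w) {
    net2 <- nn_unflatten(net, w)
    A <- nn_forward(net2, Xs)
    ed <- sum((drop(A[[length(A)]]) - t_target)^2)
    list(F = beta * ed + alpha * sum(w^2), ed = ed, A = A, net = net2)
  }
  cur <- objective(w)
  ed0 <- cur$ed
  for (epoch in seq_len(epochs)) {
    gr <- nn_grad(cur$net, cur$A, t_target)
    g <- beta * gr$g + 2 * alpha * w
    if (sqrt(sum(g^2)) < grad_tol) break
    w_new <- w - lr * g
    nxt <- objective(w_new)
    if (!is.finite(nxt$F)) stop("nn_fit: non-finite loss (lr too large?)")
    if (nxt$F <= cur$F) {
      w <- w_new
      cur <- nxt
      lr <- lr * 1.1
    } else {
      lr <- lr / 2
      if (lr < 1e-14) break
    }
    ## evidence update: only meaningful near a minimum of F, so wait until the
    ## data misfit has actually decreased; alpha growth is rate-limited so an
    ## unconverged network is never collapsed by a transient 0/0 estimate
    if (reg == "bayes" && epoch %% update_every == 0 && cur$ed < 0.5 * ed0) {
      gj <- nn_grad(cur$net, cur$A, t_target, jacobian = TRUE)
      H <- 2 * beta * crossprod(gj$J) + diag(2 * alpha, nw)
      tri <- tryCatch(sum(diag(chol2inv(chol(H)))), error = function(e) NA)
      if (is.finite(tri)) {
        gamma <- nw - 2 * alpha * tri
        gamma <- min(max(gamma, 1e-3), nw - 1e-3)
        ew <- sum(w^2)
        if (n > gamma) beta <- (n - gamma) / (2 * max(cur$ed, 1e-12))
        alpha <- min(gamma / (2 * max(ew, 1e-12)), 10 * alpha, 1e3)
        cur <- objective(w)  # objective changed with alpha, beta
      }
    }
  }
  if (any(!is.finite(w))) stop("nn_fit: non-finite weights after training")
  net <- nn_unflatten(net, w)
  structure(list(W = net$W, b = net$b, sizes = net$sizes, labels = lev,
                 center = ctr, scale = scl, alpha = alpha, beta = beta,
                 reg = reg, seed = seed, epochs_run = epoch,
                 schema = "weanwave-nn-1"),
            class = "nn_model")
}

#' Network output (tanh activation) for samples
#' @param model an `nn_model`.
#' @param X feature matrix or single feature vector.
#' @return Numeric vector in (-1, 1).
#' @export
nn_output <- function(model, X) {
  X <- if (is.null(dim(X))) matrix(X, ncol = model$sizes[1]) else as.matrix(X)
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  drop(nn_forward(model, Xs)[[length(model$W) + 1]])
}

#' Predict class labels with a trained network
#'
#' The sign of the tanh output decides; an output of exactly 0 maps to the
#' first (positive-target) class.
#' @inheritParams nn_output
#' @return Character vector of class labels.
#' @export
nn_predict <- function(model, X) {
  o <- nn_output(model, X)
  model$labels[ifelse(o >= 0, 1L, 2L)]
}

#' Equalise two classes by random undersampling
#'
#' The majority class is undersampled (without replacement) to the minority
#' size; seeded and deterministic.
#'
#' @param X feature matrix.
#' @param y class labels (two classes).
#' @param seed integer seed.
#' @return List with `X`, `y` and `idx` (the retained row indices of the
#'   original data, in original order).
#' @export
rebalance <- function(X, y, seed = 1) {
  X <- as.matrix(X)
  tab <- table(y)
  if (length(tab) != 2 || any(tab == 0)) stop("rebalance: need two non-empty classes")
  nmin <- min(tab)
  set.seed(seed)
  idx <- sort(unlist(lapply(names(tab), function(g) {
    i <- which(y == g)
    if (length(i) > nmin) sample(i, nmin) else i
  })))
  list(X = X[idx, , drop = FALSE], y = y[idx], idx = idx)
}

#' Save / load a fitted model as structured text (JSON)
#'
#' @param model an `lda_model` or `nn_model`.
#' @param path file path.
#' @return `load_model` returns the restored model; `save_model` the path,
#'   invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, c("lda_model", "nn_model")))
  obj <- unclass(model)
  obj$.class <- class(model)
  obj$.schema <- "weanwave-model-1"
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- obj$.class
  if (is.null(cls) || !identical(obj$.schema, "weanwave-model-1"))
    stop("load_model: unrecognised model file")
  obj$.class <- NULL
  obj$.schema <- NULL
  if (cls == "lda_model") {
    obj$S <- as.matrix(obj$S)
    obj$mean1 <- stats::setNames(as.numeric(obj$mean1), names(obj$mean1))
    obj$mean2 <- stats::setNames(as.numeric(obj$mean2), names(obj$mean2))
    obj$w <- as.numeric(obj$w)
  } else {
    obj$W <- lapply(obj$W, as.matrix)
    obj$b <- lapply(obj$b, as.numeric)
    obj$sizes <- as.integer(obj$sizes)
  }
  class(obj) <- cls
  obj
}
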