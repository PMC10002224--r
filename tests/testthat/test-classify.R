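test_that("LDA places the boundary midway between symmetric classes", {
  m <- suppressMessages(lda_fit(c(0, 0), c(2, 2), labels = c("lo", "hi")))
  expect_identical(lda_predict(m, 0.5), "lo")
  expect_identical(lda_predict(m, 1.5), "hi")
  expect_identical(lda_predict(m, 1), "lo")  # exact tie goes to class 1
})

test_that("pooled covariance and discriminant match an independent solve", {
  set.seed(20)
  X1 <- matrix(rnorm(90), 30, 3) + 1.5
  X2 <- matrix(rnorm(90), 30, 3) %*% matrix(c(1, .3, 0, .3, 1, 0, 0, 0, 2), 3)
  m <- lda_fit(X1, X2, labels = c("1", "2"))
  S <- (29 * cov(X1) + 29 * cov(X2)) / 58
  expect_equal(m$S, S)
  x <- rnorm(3)
  d_oracle <- drop(t(colMeans(X1) - colMeans(X2)) %*%
                     solve(S, x - (colMeans(X1) + colMeans(X2)) / 2))
  expect_equal(lda_discriminant(m, x), d_oracle, tolerance = 1e-10)
  expect_error(lda_discriminant(m, c(1, NaN, 3)), "finite")
})

test_that("the discriminant rule equals the Mahalanobis-distance rule", {
  set.seed(21)
  X1 <- matrix(rnorm(120), 40, 3) + 1
  X2 <- matrix(rnorm(120), 40, 3)
  m <- lda_fit(X1, X2, labels = c("1", "2"))
  Sm <- m$S
  pts <- matrix(rnorm(3000), 1000, 3)
  mahal <- function(x, mu) drop(t(x - mu) %*% solve(Sm, x - mu))
  lab_mahal <- apply(pts, 1, function(x)
    if (mahal(x, m$mean1) < mahal(x, m$mean2)) "1" else "2")
  expect_identical(lda_predict(m, pts), lab_mahal)
})

test_that("LDA predictions are invariant to affine feature rescaling", {
  toy <- gaussian_toy(n = 40, d = 3, sep = 2, seed = 22)
  X1 <- toy$X[toy$y == "A", ]; X2 <- toy$X[toy$y == "B", ]
  m <- lda_fit(X1, X2)
  scl <- c(3, 0.2, 10); shift <- c(-1, 5, 0)
  tf <- function(X) sweep(sweep(X, 2, scl, "*"), 2, shift, "+")
  m2 <- lda_fit(tf(X1), tf(X2))
  pts <- matrix(rnorm(300), 100, 3)
  expect_identical(lda_predict(m, pts), lda_predict(m2, tf(pts)))
})

test_that("the network separates linear and XOR problems", {
  toy <- gaussian_toy(n = 20, sep = 6, seed = 23)
  m <- nn_fit(toy$X, toy$y, epochs = 500, seed = 1)
  expect_equal(mean(nn_predict(m, toy$X) == toy$y), 1)

  set.seed(24)
  Xx <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2, byrow = TRUE)
  Xx <- Xx[rep(1:4, 10), ] + matrix(rnorm(80, 0, 0.05), 40, 2)
  yy <- rep(c("A", "B", "B", "A"), 10)
  solved <- sum(vapply(1:10, function(s) {
    m <- nn_fit(Xx, yy, epochs = 2000, seed = s)
    mean(nn_predict(m, Xx) == yy) == 1
  }, logical(1)))
  expect_gte(solved, 8)
})

test_that("weight decay shrinks the network monotonically", {
  toy <- gaussian_toy(n = 20, sep = 4, seed = 25)
  nrm <- vapply(c(0.001, 0.1, 10, 1000), function(a) {
    m <- nn_fit(toy$X, toy$y, reg = "decay", alpha = a, epochs = 400, seed = 1)
    sqrt(sum(unlist(m$W)^2) + sum(unlist(m$b)^2))
  }, numeric(1))
  expect_true(all(diff(nrm) < 0))
})

test_that("the forward pass matches a hand-computed network", {
  m <- structure(list(
    W = list(matrix(c(1, -1, 0.5, 0.25), 2, 2), matrix(c(1, 0, 0, 1), 2, 2),
             matrix(c(0.5, -0.5, 1, 2), 2, 2), matrix(c(1, -1), 1, 2)),
    b = list(c(0, 0.5), c(-1, 1), c(0, 0), 0.2),
    sizes = c(2L, 2L, 2L, 2L, 1L), labels = c("p", "n"),
    center = c(0, 0), scale = c(1, 1)), class = "nn_model")
  x <- c(0.3, -0.7)
  sig <- function(z) 1 / (1 + exp(-z))
  a1 <- sig(m$W[[1]] %*% x + m$b[[1]])
  a2 <- sig(m$W[[2]] %*% a1 + m$b[[2]])
  a3 <- sig(m$W[[3]] %*% a2 + m$b[[3]])
  o <- tanh(m$W[[4]] %*% a3 + m$b[[4]])
  expect_equal(nn_output(m, x), drop(o), tolerance = 1e-12)
  ## flipping the output layer flips every label
  toyX <- matrix(rnorm(40), 20, 2)
  m2 <- m
  m2$W[[4]] <- -m2$W[[4]]; m2$b[[4]] <- -m2$b[[4]]
  l1 <- nn_predict(m, toyX); l2 <- nn_predict(m2, toyX)
  expect_true(all(l1 != l2))
})

test_that("both classifiers exceed 95% CV accuracy on a well-separated toy", {
  toy <- gaussian_toy(n = 48, d = 2, sep = 4, seed = 26)
  for (method in c("lda", "nn")) {
    cls <- make_classifier(method, epochs = 400)
    set.seed(1)
    fold <- rep_len(1:4, length(toy$y))[sample(length(toy$y))]
    accs <- vapply(1:4, function(f) {
      m <- cls$fit(toy$X[fold != f, ], toy$y[fold != f])
      mean(cls$predict(m, toy$X[fold == f, , drop = FALSE]) == toy$y[fold == f])
    }, numeric(1))
    expect_gte(mean(accs), 0.95)
  }
})

test_that("rebalancing equalises class counts deterministically", {
  set.seed(27)
  X <- matrix(rnorm(133 * 2), 133, 2)
  y <- rep(c("SG", "FG"), c(94, 39))
  b1 <- rebalance(X, y, seed = 3)
  expect_equal(as.integer(table(b1$y)), c(39L, 39L))
  b2 <- rebalance(X, y, seed = 3)
  expect_identical(b1$idx, b2$idx)
  ## already balanced input is returned intact (order preserved)
  yb <- rep(c("A", "B"), each = 10)
  Xb <- matrix(rnorm(40), 20, 2)
  expect_identical(rebalance(Xb, yb, seed = 1)$X, Xb)
  expect_error(rebalance(X, rep("SG", 133)), "two")
})

test_that("models survive a JSON save/load round trip", {
  dir <- withr::local_tempdir()
  toy <- gaussian_toy(n = 10, sep = 4, seed = 28)
  m_lda <- lda_fit(toy$X[toy$y == "A", ], toy$X[toy$y == "B", ],
                   labels = c("A", "B"))
  m_nn <- nn_fit(toy$X, toy$y, epochs = 100, seed = 1)
  pts <- matrix(rnorm(40), 20, 2)
  for (m in list(m_lda, m_nn)) {
    path <- file.path(dir, "model.json")
    save_model(m, path)
    m2 <- load_model(path)
    expect_identical(class(m2), class(m))
    if (inherits(m, "lda_model")) {
      expect_identical(lda_predict(m2, pts), lda_predict(m, pts))
    } else {
      expect_equal(nn_output(m2, pts), nn_output(m, pts), tolerance = 1e-12)
    }
  }
  bad <- file.path(dir, "bad.json")
  jsonlite::write_json(list(a = 1), bad)
  expect_error(load_model(bad), "unrecognised")
})
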