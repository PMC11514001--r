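## random standardized-scale feature matrix with phi dims in (-pi, pi]
rand_features <- function(n, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * 12), n, 12)
  X[, c(6, 9, 12)] <- runif(3 * n, -pi, pi)
  X
}

rand_hp <- function(seed = 2) {
  set.seed(seed)
  list(l = runif(12, 0.5, 3), sf2 = 2.3, sn2 = 0.01, prior_mean = 0.7)
}

test_that("kernel equals signal variance at zero distance and is symmetric", {
  hp <- rand_hp()
  f <- rand_features(2, seed = 3)
  expect_identical(kernel_value(f[1, ], f[1, ], hp), hp$sf2)
  expect_equal(kernel_value(f[1, ], f[2, ], hp),
               kernel_value(f[2, ], f[1, ], hp))
})

test_that("kernel treats azimuthal dimensions periodically", {
  hp <- rand_hp()
  f <- rand_features(2, seed = 4)
  g <- f
  g[, 6] <- g[, 6] + 2 * pi
  g[, 12] <- g[, 12] - 4 * pi
  expect_equal(kernel_value(f[1, ], f[2, ], hp),
               kernel_value(g[1, ], g[2, ], hp), tolerance = 1e-12)
})

test_that("kernel matches a term-by-term independent evaluation", {
  hp <- rand_hp(5)
  f <- rand_features(2, seed = 6)
  expo <- 0
  for (j in 1:12) {
    d <- f[1, j] - f[2, j]
    expo <- expo + if (j %in% c(6, 9, 12)) 2 * sin(d / 2)^2 / hp$l[j]^2
                   else d^2 / (2 * hp$l[j]^2)
  }
  expect_equal(kernel_value(f[1, ], f[2, ], hp), hp$sf2 * exp(-expo),
               tolerance = 1e-14)
})

test_that("blocked matrix-vector products equal the dense computation", {
  hp <- rand_hp(7)
  X <- rand_features(200, seed = 8)
  v <- rnorm(200)
  Kdense <- outer(seq_len(200), seq_len(200), Vectorize(function(i, j)
    kernel_value(X[i, ], X[j, ], hp)))
  ref <- as.numeric(Kdense %*% v)
  for (bs in c(1L, 7L, 200L)) {
    out <- blocked_kernel_matvec(X, v, hp, block_size = bs)
    expect_lt(max(abs(out - ref)) / max(abs(ref)), 1e-10)
  }
  expect_identical(blocked_kernel_matvec(X, rep(0, 200), hp), rep(0, 200))
})

test_that("kernel matrices are positive semi-definite", {
  hp <- rand_hp(9)
  X <- rand_features(100, seed = 10)
  K <- dimergpr:::.kernel_cross(X, X, hp)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * hp$sf2)
})

test_that("log marginal likelihood matches the closed form at n = 1", {
  hp <- list(l = rep(1.3, 12), sf2 = 2.7, sn2 = 0.4, prior_mean = 5)
  v <- log_marginal_likelihood(matrix(rnorm(12), 1), 5, hp, jitter = 1e-8)
  expect_equal(v, -0.5 * log(2.7 + 0.4 + 1e-8 * 2.7) - 0.5 * log(2 * pi),
               tolerance = 1e-12)
})

test_that("log marginal likelihood is permutation invariant and matches a naive implementation", {
  hp <- rand_hp(11)
  X <- rand_features(50, seed = 12)
  set.seed(13)
  y <- rnorm(50, mean = hp$prior_mean)
  v <- log_marginal_likelihood(X, y, hp, jitter = 1e-8)
  perm <- sample.int(50)
  expect_equal(log_marginal_likelihood(X[perm, ], y[perm], hp, jitter = 1e-8),
               v, tolerance = 1e-9)
  ## naive dense implementation
  K <- dimergpr:::.kernel_cross(X, X, hp) + diag(hp$sn2 + 1e-8 * hp$sf2, 50)
  r <- y - hp$prior_mean
  naive <- -0.5 * as.numeric(r %*% solve(K, r)) -
    0.5 * determinant(K)$modulus[1] - 25 * log(2 * pi)
  expect_equal(v, naive, tolerance = 1e-8)
})

test_that("constant labels are learned as the prior mean", {
  X <- rand_features(20, seed = 14)
  m <- train_atomic_model(X, rep(3.25, 20),
                          train_config(restarts = 1, maxit = 10))
  expect_equal(m$hp$prior_mean, 3.25)
  far <- rand_features(5, seed = 15) + 50
  expect_equal(predict_energy(m, far), rep(3.25, 5), tolerance = 1e-8)
})

test_that("a noiseless linear function of one feature is interpolated", {
  set.seed(1)
  X <- matrix(runif(30 * 12, 1, 3), 30, 12)
  X[, c(6, 9, 12)] <- runif(90, -3, 3)
  y <- X[, 1] - 1
  m <- train_atomic_model(X, y, train_config(restarts = 2, maxit = 100, seed = 2))
  expect_lt(max(abs(predict_energy(m, X) - y)), 1e-4)
})

test_that("training is deterministic given the seed", {
  X <- rand_features(40, seed = 16)
  y <- sin(X[, 1]) + 0.3 * X[, 4]
  cfg <- train_config(restarts = 3, maxit = 40, seed = 5)
  m1 <- train_atomic_model(X, y, cfg)
  m2 <- train_atomic_model(X, y, cfg)
  expect_identical(m1$hp, m2$hp)
  expect_identical(m1$alpha, m2$alpha)
})

test_that("the optimized marginal likelihood is at least the default-start value", {
  X <- rand_features(40, seed = 17)
  y <- cos(X[, 2]) + 0.1 * X[, 7]
  m <- train_atomic_model(X, y, train_config(restarts = 3, maxit = 60, seed = 6))
  vy <- var(y)
  init_hp <- list(l = rep(1, 12), sf2 = vy, sn2 = 1e-4 * vy, prior_mean = mean(y))
  ## model stores standardized features; evaluate both at the same scale
  lml_init <- log_marginal_likelihood(m$X, y, init_hp, jitter = 1e-8)
  expect_gte(m$lml + 1e-9, lml_init)
})

test_that("a near-noiseless model interpolates its training labels", {
  ## dual solve performed directly at tiny fixed noise and jitter
  X <- rand_features(25, seed = 18)
  y <- sin(X[, 1]) + X[, 4]^2
  hp <- list(l = rep(1.5, 12), sf2 = max(var(y), 1), sn2 = 1e-10,
             prior_mean = mean(y))
  K <- dimergpr:::.kernel_cross(X, X, hp) + diag(1e-10, 25)
  alpha <- solve(K, y - hp$prior_mean)
  model <- structure(list(atom = NA_integer_, X = X,
                          center = rep(0, 12), scale = rep(1, 12),
                          hp = hp, alpha = alpha, jitter = 1e-10,
                          n_train = 25, n_hyper = 25, lml = NA_real_),
                     class = "atomic_gpr_model")
  expect_lt(max(abs(predict_energy(model, X) - y)), 1e-6)
})

test_that("a 3-point model matches the hand-expanded sum", {
  X <- rand_features(3, seed = 19)
  y <- c(1.5, -0.3, 0.9)
  m <- train_atomic_model(X, y, train_config(restarts = 1, maxit = 20, seed = 1))
  f <- rand_features(1, seed = 20)[1, ]
  fs <- (f - m$center) / m$scale
  by_hand <- m$hp$prior_mean +
    m$alpha[1] * kernel_value(fs, m$X[1, ], m$hp) +
    m$alpha[2] * kernel_value(fs, m$X[2, ], m$hp) +
    m$alpha[3] * kernel_value(fs, m$X[3, ], m$hp)
  expect_equal(predict_energy(m, f), by_hand, tolerance = 1e-12)
})

test_that("predictions revert to the prior mean far from all data", {
  X <- rand_features(30, seed = 21)
  y <- X[, 1] * 0.5 + sin(X[, 2])
  m <- train_atomic_model(X, y, train_config(restarts = 2, maxit = 60, seed = 3))
  far <- rand_features(1, seed = 22)
  far[, -c(6, 9, 12)] <- far[, -c(6, 9, 12)] + 1e4   # >> 50 lengthscales
  expect_equal(predict_energy(m, far[1, ]), m$hp$prior_mean, tolerance = 1e-8)
  expect_lt(max(abs(predict_gradient(m, far[1, ]))), 1e-8)
})

test_that("predictive-mean gradients match finite differences and are periodic", {
  X <- rand_features(30, seed = 23)
  y <- sin(X[, 1]) + cos(X[, 6]) + 0.2 * X[, 9]
  m <- train_atomic_model(X, y, train_config(restarts = 2, maxit = 60, seed = 4))
  f <- rand_features(1, seed = 24)[1, ]
  g <- predict_gradient(m, f)
  h <- 1e-6
  for (j in 1:12) {
    fp <- f; fp[j] <- fp[j] + h
    fm <- f; fm[j] <- fm[j] - h
    fd <- (predict_energy(m, fp) - predict_energy(m, fm)) / (2 * h)
    expect_lt(abs(g[j] - fd), 1e-6)
  }
  ## continuity of prediction and gradient across the phi branch cut
  eps <- 1e-9
  fA <- f; fA[6] <- pi - eps
  fB <- f; fB[6] <- -pi + eps
  expect_equal(predict_energy(m, fA), predict_energy(m, fB), tolerance = 1e-6)
  expect_equal(predict_gradient(m, fA), predict_gradient(m, fB),
               tolerance = 1e-5)
})

test_that("known lengthscales are recovered from GP-sampled data", {
  set.seed(11)
  n <- 300
  X <- matrix(runif(n * 12, -2, 2), n, 12)
  X[, c(6, 9, 12)] <- runif(3 * n, -pi, pi)
  ltrue <- rep(50, 12)
  signal_dims <- c(1, 4, 7)
  ltrue[signal_dims] <- 0.8
  hp <- list(l = ltrue, sf2 = 4, sn2 = 0, prior_mean = 0)
  K <- dimergpr:::.kernel_cross(X, X, hp) + diag(1e-4, n)
  y <- as.numeric(t(chol(K)) %*% rnorm(n))
  m <- train_atomic_model(X, y, train_config(restarts = 3, maxit = 100, seed = 4))
  for (j in signal_dims) {
    l_std_true <- 0.8 / m$scale[j]
    expect_lt(abs(m$hp$l[j] - l_std_true) / l_std_true, 0.3)
  }
})
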