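test_that("Mann-Whitney exact path equals the enumeration oracle", {
  # canonical fully separated case: U = 0, p = 2/20
  expect_equal(mw_test(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(mw_enum_p(c(1, 2, 3), c(4, 5, 6)), 0.1)

  set.seed(5)
  for (rep in 1:40) {
    nx <- sample(2:6, 1)
    ny <- sample(2:6, 1)
    if (nx + ny > 12) next
    v <- sample(seq(0.01, 0.99, by = 0.01), nx + ny)  # distinct, no ties
    x <- v[seq_len(nx)]; y <- v[-seq_len(nx)]
    expect_equal(mw_test(x, y), mw_enum_p(x, y), tolerance = 1e-12)
  }
})

test_that("Mann-Whitney handles identity, ties and large samples", {
  expect_equal(mw_test(c(2, 2, 2), c(2, 2)), 1)
  expect_equal(mw_test(c(1, 2, 3), c(1, 2, 3)), 1)

  set.seed(6)
  x <- rnorm(200); y <- rnorm(200) + 1
  expect_lt(mw_test(x, y), 0.001)
  # asymptotic path agrees with a permutation oracle
  pooled <- c(x, y)
  r <- rank(pooled)
  obs <- sum(r[1:200])
  perm <- replicate(1e4, sum(sample(r, 200)))
  p_perm <- mean(abs(perm - mean(r) * 200) >= abs(obs - mean(r) * 200))
  expect_lt(p_perm, 0.001)
})

test_that("screening reports group statistics and significance", {
  set.seed(30)
  X <- cbind(a = c(rnorm(10), rnorm(10) + 3), b = rnorm(20))
  g <- rep(c("P", "Q"), each = 10)
  sc <- screen_indices(X, g)
  expect_true(sc$pass[sc$index == "a"])
  expect_false(sc$pass[sc$index == "b"])
  expect_equal(sc$mean_b[sc$index == "a"], mean(X[11:20, "a"]))
  expect_true(all(sc$p >= 0 & sc$p <= 1, na.rm = TRUE))
})

test_that("correlation filter admits independent and rejects collinear", {
  set.seed(8)
  f1 <- rnorm(100)
  X <- cbind(a = f1, b = f1, c = rnorm(100))
  expect_error(correlation_filter(X, c("a", "b")), "no admissible pair")
  pr <- correlation_filter(X, c("a", "b", "c"))
  expect_true(all(apply(pr, 1, function(r) "c" %in% r)))
  # direct rank-correlation oracle
  rho <- cor(rank(X[, "a"]), rank(X[, "c"]))
  expect_lt(abs(rho), 0.3)
  expect_error(correlation_filter(X, "a"), "at least 2")
})

test_that("kernel matrices have their closed-form values and are PSD", {
  x <- matrix(c(0, 0), 1)
  expect_equal(kernel_matrix(x, x, "gaussian", sigma = 1)[1, 1], 1)
  expect_equal(kernel_matrix(x, x, "laplace", sigma = 1)[1, 1], 1)
  expect_equal(kernel_matrix(x, x, "anova", sigma = 1, d = 3)[1, 1], 2^3)

  a <- matrix(c(0, 0), 1); b <- matrix(c(1, 0), 1)  # distance sigma = 1
  expect_equal(kernel_matrix(a, b, "gaussian", sigma = 1)[1, 1],
               exp(-1 / 2))
  expect_equal(kernel_matrix(a, b, "laplace", sigma = 2)[1, 1],
               exp(-1 / 2))

  set.seed(9)
  X <- matrix(rnorm(20), 10, 2)
  for (k in c("gaussian", "laplace", "anova")) {
    K <- kernel_matrix(X, kernel = k, sigma = 1, d = 2)
    expect_true(isSymmetric(K, tol = 1e-12))
    expect_gt(min(eigen(K, symmetric = TRUE)$values), -1e-8)
  }
  expect_error(kernel_matrix(X, kernel = "gaussian", sigma = 0), "sigma")
})

test_that("the SMO solver separates separable and XOR patterns", {
  X <- matrix(c(-2, -1, 1, 2), ncol = 1)
  y <- factor(c("n", "n", "p", "p"))
  K <- kernel_matrix(X, kernel = "gaussian", sigma = 1)
  fit <- train_svm(K, y, C = 10, positive = "p")
  expect_equal(unname(predict(fit, K)), c("n", "n", "p", "p"))

  Xx <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  yx <- factor(c("a", "a", "b", "b"))
  Kx <- kernel_matrix(Xx, kernel = "gaussian", sigma = 0.5)
  fx <- train_svm(Kx, yx, C = 10, positive = "a")
  expect_equal(unname(predict(fx, Kx)), c("a", "a", "b", "b"))

  expect_error(train_svm(K, factor(rep("p", 4)), C = 1), "two classes")
})

test_that("the SMO dual agrees with an independent SVM solver", {
  skip_if_not_installed("kernlab")
  set.seed(10)
  for (rep in 1:5) {
    X <- matrix(rnorm(60), 30, 2)
    y <- factor(rep(c("A", "B"), each = 15))
    X[y == "A", 1] <- X[y == "A", 1] + runif(1, 0.5, 2)
    C <- sample(c(0.5, 1, 5), 1)
    K <- kernel_matrix(X, kernel = "gaussian", sigma = 1)
    fit <- train_svm(K, y, C = C, positive = "A")
    f1 <- predict(fit, K, type = "decision")
    m <- kernlab::ksvm(kernlab::as.kernelMatrix(K), y, type = "C-svc",
                       C = C, scaled = FALSE)
    f2 <- as.numeric(kernlab::predict(
      m, kernlab::as.kernelMatrix(K[, kernlab::SVindex(m), drop = FALSE]),
      type = "decision"))
    # kernlab may flip the sign convention with factor levels
    if (cor(f1, f2) < 0) f2 <- -f2
    expect_lt(max(abs(f1 - f2)), 0.01)
  }
})

test_that("confusion-count metrics satisfy their identities", {
  m <- metrics_from_counts(10, 0, 10, 0)
  expect_equal(unname(m), c(100, 100, 100))
  # an all-positive predictor has full sensitivity, zero specificity
  m2 <- metrics_from_counts(tp = 12, fn = 0, tn = 0, fp = 8)
  expect_equal(unname(m2["sn"]), 100)
  expect_equal(unname(m2["sp"]), 0)
  expect_equal(unname(m2["acc"]), 100 * 12 / 20)
})

test_that("LOOCV keeps standardization inside the training fold", {
  tf <- toy_feature_table(n_per_group = 8, delta = 3)
  ev <- loocv_evaluate(tf$features, tf$groups,
                       pair = c("SBP-dTTm-d", "SBP-dTTsd-u"),
                       kernel = "gaussian", C = 5, sigma = 1,
                       positive = "B")
  expect_equal(length(ev$predictions), 16)
  cnt <- ev$counts
  expect_equal(unname(ev$acc),
               100 * (cnt["tp"] + cnt["tn"]) / sum(cnt),
               ignore_attr = TRUE)
  expect_gt(ev$acc, 75)  # 3-SD separation classifies most subjects

  # vectorized C returns one evaluation per value
  evs <- loocv_evaluate(tf$features, tf$groups,
                        pair = c("SBP-dTTm-d", "SBP-dTTsd-u"),
                        kernel = "gaussian", C = c(0.5, 5), sigma = 1,
                        positive = "B")
  expect_length(evs, 2)
  expect_equal(evs[[1]]$truth, evs[[2]]$truth)
})

test_that("model search finds the separating pair and is deterministic", {
  tf <- toy_feature_table(n_per_group = 15, delta = 2)
  m <- model_search(tf$features, tf$groups, positive = "B",
                    kernels = "gaussian", C_grid = c(1, 5),
                    sigma_grid = c(0.8, 1.5))
  expect_s3_class(m, "baro_model")
  expect_setequal(m$pair, c("SBP-dTTm-d", "SBP-dTTsd-u"))
  expect_gte(m$acc, 90)

  m2 <- model_search(tf$features, tf$groups, positive = "B",
                     kernels = "gaussian", C_grid = c(1, 5),
                     sigma_grid = c(0.8, 1.5))
  expect_identical(m$trace, m2$trace)
  expect_identical(m$pair, m2$pair)

  # single-candidate grid is returned trivially
  m3 <- model_search(tf$features, tf$groups, positive = "B",
                     kernels = "gaussian", C_grid = 1, sigma_grid = 1)
  expect_equal(nrow(m3$trace[m3$trace$kernel == "gaussian" &
                             m3$trace$C == 1 & m3$trace$sigma == 1, ]) > 0,
               TRUE)
  expect_equal(unique(m3$trace$C), 1)

  # predictions on the training table agree with the reported pair model
  pr <- predict(m, tf$features)
  expect_true(all(pr %in% c("A", "B")))
})

test_that("label shuffling keeps searched accuracy near chance", {
  set.seed(77)
  n <- 40
  X <- matrix(rnorm(n * 10), n)
  colnames(X) <- paste0("f", 1:10)
  g0 <- rep(c("A", "B"), each = n / 2)
  accs <- vapply(1:100, function(i) {
    g <- sample(g0)
    m <- tryCatch(
      model_search(X, g, positive = "B", kernels = "gaussian",
                   C_grid = 1, sigma_grid = 1, top_k = 4),
      error = function(e) NULL)
    if (is.null(m)) 50 else m$acc   # no admissible model = chance
  }, numeric(1))
  expect_lt(abs(median(accs) - 50), 15)
})
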