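test_that("initialization is seeded and the architecture has the stated shapes", {
  cfg <- mtl_config(seed = 9)
  m1 <- init_model(50, c("gA", "gB"), cfg)
  m2 <- init_model(50, c("gA", "gB"), cfg)
  expect_identical(m1$tasks, m2$tasks)
  p <- m1$tasks$gA
  expect_equal(dim(p$w_agg), c(3, 50))
  expect_equal(dim(p$W1), c(50, 64))
  expect_equal(dim(p$W2), c(64, 32))
  expect_equal(dim(p$W3), c(32, 16))
  expect_equal(dim(p$W4), c(16, 1))
  # a task's init depends only on (seed, gene), not on its companions
  m3 <- init_model(50, "gA", cfg)
  expect_identical(m3$tasks$gA, m1$tasks$gA)
})

test_that("forward pass matches the aggregation formula", {
  cfg <- mtl_config(seed = 1, activation = "relu")
  model <- init_model(1, "g", cfg)
  p <- model$tasks$g
  p$w_agg <- matrix(c(1, 2, 3), 3, 1)
  model$tasks$g <- p
  # one TF, input (a_sum, a_mean, x) = (0.5, 0.25, 1): neuron value
  # 1*0.5 + 2*0.25 + 3*1 = 4
  cache <- velonet:::forward_task(p, matrix(c(0.5, 0.25, 1), 1), "relu",
                                  keep_cache = TRUE)
  expect_equal(as.numeric(cache$H0), 4)
  neg <- velonet:::forward_task(p, matrix(c(-1, 0, 0), 1), "relu", keep_cache = TRUE)
  expect_equal(as.numeric(neg$H0), 0)

  zero <- lapply(p, function(w) w * 0)
  expect_equal(velonet:::forward_task(zero, matrix(rnorm(3), 1), "relu")$pred, 0)
  expect_error(forward(model, "g", matrix(rnorm(6), 1)), "3 \\* n_tfs|length")
  expect_error(forward(model, "nope", matrix(rnorm(3), 1)), "not a task")
})

test_that("trace norm matches an independent eigenvalue oracle", {
  set.seed(10)
  expect_equal(trace_norm(diag(2)), 2)
  expect_equal(trace_norm(diag(c(3, 4))), 7)
  for (i in 1:100) {
    r <- sample(2:64, 1)
    cc <- sample(2:256, 1)
    w <- matrix(rnorm(r * cc), r, cc)
    # eigenvalues of the Gram matrix: algebraically independent route,
    # numerically good to ~sqrt(machine eps) because it squares the matrix
    oracle <- sum(sqrt(pmax(0, eigen(crossprod(w), symmetric = TRUE,
                                     only.values = TRUE)$values)))
    expect_equal(trace_norm(w), oracle, tolerance = 1e-6)
  }
})

test_that("trace-norm subgradient is U V^T with spectral norm at most 1", {
  expect_equal(trace_norm_subgradient(diag(c(3, 4))), diag(2))
  q <- qr.Q(qr(matrix(rnorm(16), 4)))
  expect_equal(trace_norm_subgradient(q), q)
  set.seed(11)
  for (i in 1:20) {
    w <- matrix(rnorm(20), 5, 4)
    g <- trace_norm_subgradient(w)
    expect_lte(norm(g, "2"), 1 + 1e-8)
    # central differences away from repeated singular values
    if (min(abs(diff(svd(w)$d))) < 1e-2) next
    h <- 1e-6
    idx <- cbind(sample(5, 3, TRUE), sample(4, 3, TRUE))
    for (r in 1:3) {
      wp <- w; wm <- w
      wp[idx[r, 1], idx[r, 2]] <- wp[idx[r, 1], idx[r, 2]] + h
      wm[idx[r, 1], idx[r, 2]] <- wm[idx[r, 1], idx[r, 2]] - h
      fd <- (trace_norm(wp) - trace_norm(wm)) / (2 * h)
      expect_equal(g[idx[r, 1], idx[r, 2]], fd, tolerance = 1e-4)
    }
  }
})

test_that("multitask loss combines MSE, L1 and trace-norm terms", {
  cfg <- mtl_config(lambda_l1 = 0, gamma_trace = 0, repeats = 1, seed = 2)
  model <- init_model(2, "g", cfg)
  model$tasks$g <- lapply(model$tasks$g, function(w) w * 0)
  batch <- list(g = list(features = matrix(0, 1, 6), targets = 1))
  expect_equal(multitask_loss(model, batch, cfg), 1)
  batch0 <- list(g = list(features = matrix(0, 1, 6), targets = 0))
  expect_equal(multitask_loss(model, batch0, cfg), 0)

  # the gamma term adds exactly gamma * nuclear norm of the stacks
  cfg2 <- mtl_config(lambda_l1 = 0, gamma_trace = 0.1, seed = 3)
  m2 <- init_model(4, c("gA", "gB"), cfg2)
  b2 <- list(gA = list(features = matrix(rnorm(24), 2), targets = rnorm(2)),
             gB = list(features = matrix(rnorm(24), 2), targets = rnorm(2)))
  base <- multitask_loss(m2, b2, mtl_config(lambda_l1 = 0, gamma_trace = 0, seed = 3))
  tn <- sum(vapply(c("FC1", "FC2"), function(l) {
    trace_norm(velonet:::shared_stack(m2, l))
  }, numeric(1)))
  expect_equal(multitask_loss(m2, b2, cfg2), base + 0.1 * tn)
  # baseline flag drops the term entirely
  cfg3 <- cfg2; cfg3$sharing_enabled <- FALSE
  expect_equal(multitask_loss(m2, b2, cfg3), base)
})

test_that("ensemble batch plan follows ceiling(C_max / b) and covers all examples", {
  for (cmax in c(1, 7, 100, 1000, 1001)) {
    for (b in c(1, 8, 128)) {
      sizes <- c(big = cmax, small = max(1, cmax %/% 3))
      plan <- sample_epoch_batches(sizes, b, seed = 1)
      expect_equal(plan$batches_per_epoch, ceiling(cmax / b))
      for (g in names(sizes)) {
        expect_setequal(unique(as.integer(plan$index_streams[[g]])),
                        seq_len(sizes[[g]]))
        expect_equal(dim(plan$index_streams[[g]]),
                     c(ceiling(cmax / b), b))
      }
    }
  }
  p1 <- sample_epoch_batches(c(a = 50, b = 20), 16, seed = 7)
  p2 <- sample_epoch_batches(c(a = 50, b = 20), 16, seed = 7)
  expect_identical(p1, p2)
  expect_error(sample_epoch_batches(c(a = 0), 4), "at least one")
})

test_that("training reduces the loss and honors repeats", {
  tasks <- list(gA = mk_task("gA", n_rows = 60, seed = 21),
                gB = mk_task("gB", n_rows = 40, seed = 22))
  cfg <- mtl_config(epochs = 15, batch_size = 16, repeats = 1, seed = 5)
  fit <- train_cluster(tasks, NULL, cfg)
  batches <- lapply(tasks, function(d) list(features = d$features, targets = d$targets))
  init <- init_model(6, names(tasks), mtl_config(seed = derive_seed(5, "run", 1)),
                     tf_ids = tasks$gA$tf_ids)
  expect_lt(multitask_loss(fit$models[[1]], batches, cfg),
            multitask_loss(init, batches, cfg))

  cfg3 <- mtl_config(epochs = 2, batch_size = 16, repeats = 3, seed = 5)
  fit3 <- train_cluster(tasks, tasks, cfg3)
  expect_length(fit3$models, 3)
  expect_equal(nrow(fit3$r2), 6) # 2 genes x 3 repeats
})

test_that("with no sharing, joint training equals training each task alone", {
  tasks <- list(gA = mk_task("gA", n_rows = 40, seed = 31),
                gB = mk_task("gB", n_rows = 30, seed = 32))
  cfg <- mtl_config(epochs = 4, batch_size = 8, repeats = 1,
                    gamma_trace = 0, seed = 8)
  joint <- train_cluster(tasks, NULL, cfg)
  alone <- train_cluster(tasks["gA"], NULL, cfg)
  expect_equal(joint$models[[1]]$tasks$gA, alone$models[[1]]$tasks$gA,
               tolerance = 1e-12)
})

test_that("the compiled engine reproduces the R reference engine", {
  tasks <- list(gA = mk_task("gA", n_rows = 25, seed = 41),
                gB = mk_task("gB", n_rows = 20, seed = 42),
                gC = mk_task("gC", n_rows = 30, seed = 43))
  for (gam in c(0, 0.05)) {
    for (actv in c("leaky_relu", "relu", "tanh")) {
      cfg_r <- mtl_config(epochs = 3, batch_size = 8, repeats = 1,
                          gamma_trace = gam, activation = actv,
                          engine = "r", seed = 6)
      cfg_c <- cfg_r
      cfg_c$engine <- "cpp"
      fr <- train_cluster(tasks, NULL, cfg_r)
      fc <- train_cluster(tasks, NULL, cfg_c)
      for (g in names(tasks)) {
        expect_equal(fr$models[[1]]$tasks[[g]], fc$models[[1]]$tasks[[g]],
                     tolerance = 1e-10)
      }
    }
  }
})
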