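# simulate series from known logistic-quadratic trajectories
simulate_series <- function(n_per_class, coef_list, t = seq(-1, 1,
                                                            length.out = 13)) {
  rows <- purrr::imap(coef_list, function(beta, k) {
    p <- plogis(beta[1] + beta[2] * t + beta[3] * t^2)
    matrix(rbinom(n_per_class[k] * length(t), 1, rep(p, each = n_per_class[k])),
           nrow = n_per_class[k])
  })
  list(y = do.call(rbind, rows),
       class = rep(seq_along(coef_list), n_per_class))
}

test_that("a perfectly separated two-group mixture is recovered exactly", {
  y <- rbind(matrix(1L, 60, 13), matrix(0L, 40, 13))
  fit <- fit_gbtm(y, 2, gbtm_config(seed = 1))
  hi <- which.max(fit$p[1, ])
  expect_equal(unname(fit$assignment[1:60]), rep(hi, 60))
  expect_equal(length(unique(fit$assignment[61:100])), 1)
  expect_true(fit$assignment[61] != hi)
  expect_equal(sort(fit$pi), c(0.4, 0.6), tolerance = 1e-6)
})

test_that("K = 1 reduces to the pooled per-bin logistic regression", {
  set.seed(2)
  y <- matrix(rbinom(50 * 13, 1, 0.6), 50, 13)
  fit <- fit_gbtm(y, 1, gbtm_config(seed = 2))
  t <- seq(-1, 1, length.out = 13)
  dat <- data.frame(y = as.vector(y), t = rep(t, each = 50))
  ref <- glm(y ~ t + I(t^2), data = dat, family = binomial)
  expect_equal(as.vector(fit$beta), unname(coef(ref)), tolerance = 1e-5)
})

test_that("known trajectories are recovered within 0.05 mean absolute error", {
  set.seed(3)
  truth <- list(c(2.5, 0, 0), c(-0.5, -2.5, 0), c(-2.5, 0, 0))
  sim <- simulate_series(c(250, 200, 150), truth)
  fit <- fit_gbtm(sim$y, 3, gbtm_config(seed = 3))
  t <- seq(-1, 1, length.out = 13)
  P_true <- sapply(truth, function(b) plogis(b[1] + b[2] * t + b[3] * t^2))
  # align fitted classes to truth greedily by curve distance
  perm <- apply(sapply(1:3, function(k) {
    colMeans(abs(fit$p - P_true[, k]))
  }), 2, which.min)
  expect_equal(sort(perm), 1:3) # one fitted class per true class
  mae <- mean(abs(fit$p[, perm] - P_true))
  expect_lt(mae, 0.05)
})

test_that("EM is monotone, posteriors normalized, seed reproducible", {
  set.seed(4)
  sim <- simulate_series(c(80, 70), list(c(2, 0, 0), c(-2, 1, 0)))
  f1 <- fit_gbtm(sim$y, 2, gbtm_config(seed = 11))
  f2 <- fit_gbtm(sim$y, 2, gbtm_config(seed = 11))
  expect_true(all(diff(f1$loglik_trace) > -1e-8))
  expect_lt(max(abs(rowSums(f1$posterior) - 1)), 1e-10)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$assignment, f2$assignment)
  expect_equal(f1$bic, -2 * f1$loglik + f1$n_params * log(f1$n))
})

test_that("BIC selects the generating number of classes when separable", {
  set.seed(5)
  y <- rbind(matrix(rbinom(60 * 13, 1, 0.95), 60, 13),
             matrix(rbinom(40 * 13, 1, 0.05), 40, 13))
  sel <- select_k(y, gbtm_config(k_range = 1:4, seed = 5))
  expect_equal(sel$model$K, 2)
  expect_equal(nrow(sel$bic_table), 4)

  noise <- matrix(rbinom(20 * 13, 1, 0.5), 20, 13)
  sel <- select_k(noise, gbtm_config(k_range = 1:3, seed = 6))
  expect_equal(sel$model$K, 1)
})

test_that("K larger than N is fatal and binary input is enforced", {
  y <- matrix(rbinom(5 * 13, 1, 0.5), 5, 13)
  expect_error(fit_gbtm(y, 6), "exceed")
  y_bad <- y; y_bad[1, 1] <- 0.5
  expect_error(fit_gbtm(y_bad, 2), "binary")
})

test_that("labels order classes by mean MPR with documented tie-breaks", {
  set.seed(7)
  y <- rbind(matrix(1L, 30, 13), matrix(0L, 10, 13))
  fit <- fit_gbtm(y, 2, gbtm_config(seed = 7))
  mpr <- c(rep(0.9, 30), rep(0.2, 10))
  lab <- label_clusters(fit, mpr)
  expect_equal(lab$assignment_label[1], "A")
  expect_equal(lab$assignment_label[35], "B")

  # permuting the internal class order leaves the labeled output unchanged
  perm_fit <- fit
  perm <- 2:1
  perm_fit$pi <- fit$pi[perm]
  perm_fit$beta <- fit$beta[, perm]
  perm_fit$p <- fit$p[, perm]
  perm_fit$posterior <- fit$posterior[, perm]
  perm_fit$assignment <- match(fit$assignment, perm)
  lab2 <- label_clusters(perm_fit, mpr)
  expect_identical(lab2$assignment_label, lab$assignment_label)

  # equal mean MPR: the larger class gets the earlier letter
  mpr_tie <- rep(0.5, 40)
  lab3 <- label_clusters(fit, mpr_tie)
  big <- which.max(tabulate(fit$assignment, 2))
  expect_equal(lab3$labels[big], "A")
})

test_that("cluster profiles aggregate member MPRs exactly", {
  set.seed(8)
  y <- rbind(matrix(1L, 60, 13), matrix(0L, 40, 13))
  mpr <- c(runif(60, 0.8, 1), runif(40, 0, 0.3))
  fit <- label_clusters(fit_gbtm(y, 2, gbtm_config(seed = 8)), mpr)
  prof <- cluster_profile(fit, mpr)
  expect_equal(prof$label, c("A", "B"))
  expect_equal(prof$share_pct, c(60, 40))
  expect_equal(prof$mean_mpr_pct[1], 100 * mean(mpr[1:60]))
  expect_equal(sum(prof$share_pct), 100)

  single <- label_clusters(fit_gbtm(matrix(1L, 20, 13), 1,
                                    gbtm_config(seed = 9)), rep(1, 20))
  expect_equal(cluster_profile(single, rep(1, 20))$share_pct, 100)
})

test_that("autoplot returns a trajectory plot and tidiers a tibble", {
  set.seed(10)
  y <- rbind(matrix(1L, 30, 13), matrix(0L, 20, 13))
  fit <- label_clusters(fit_gbtm(y, 2, gbtm_config(seed = 10)),
                        c(rep(1, 30), rep(0, 20)))
  expect_s3_class(autoplot(fit), "ggplot")
  td <- tidy(fit)
  expect_equal(nrow(td), 2 * 3)
  expect_s3_class(glance(fit), "tbl_df")
})
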