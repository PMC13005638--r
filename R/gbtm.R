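# Group-based trajectory modeling of binary adherence series: a K-component
# mixture of Bernoulli responses whose per-bin success probabilities follow
# class-specific polynomial-logit trajectories over standardized bin time,
# fit by EM. Rows with identical series are collapsed to weighted unique
# patterns, which makes the E and M steps cheap at cohort scale.

#' GBTM configuration
#'
#' @param k_range Candidate numbers of classes for [select_k()].
#' @param degree Polynomial degree of the logit trajectories (default 2,
#'   quadratic: the standard GBTM working shape).
#' @param max_iter Maximum EM iterations for the final run.
#' @param tol Absolute log-likelihood convergence tolerance.
#' @param n_restarts Number of starts: the first is k-means on the raw
#'   series, the rest are random perturbations; each start gets a short EM
#'   run and the best continues to convergence.
#' @param short_iter EM iterations per short run.
#' @param min_share Minimum acceptable class share; smaller classes flag the
#'   model as degenerate (not fatal).
#' @param seed Optional seed for restarts; fixed seed implies an identical
#'   fitted model.
#' @return A `gbtm_config` list.
#' @export
gbtm_config <- function(k_range = 2:9, degree = 2, max_iter = 300,
                        tol = 1e-7, n_restarts = 10, short_iter = 25,
                        min_share = 0.02, seed = NULL) {
  stopifnot(degree >= 0, n_restarts >= 1, max_iter >= 1, tol > 0,
            min_share >= 0, min_share < 1)
  structure(list(k_range = k_range, degree = degree, max_iter = max_iter,
                 tol = tol, n_restarts = n_restarts, short_iter = short_iter,
                 min_share = min_share, seed = seed),
            class = "gbtm_config")
}

# log-likelihood of each unique pattern under each class: U x K
pattern_loglik <- function(Y, P) {
  # Y: U x T binary; P: T x K probabilities (clipped)
  Y %*% log(P) + (1 - Y) %*% log(1 - P)
}

logsumexp_rows <- function(M) {
  mx <- apply(M, 1, max)
  mx + log(rowSums(exp(M - mx)))
}

# one M-step: weighted per-class logistic fits on the expanded pattern data
gbtm_mstep <- function(Y, counts, Z, X) {
  U <- nrow(Y); T_ <- ncol(Y); K <- ncol(Z)
  Xbig <- X[rep(seq_len(T_), each = U), , drop = FALSE]
  yvec <- as.vector(Y)
  beta <- matrix(0, ncol(X), K)
  for (k in seq_len(K)) {
    w <- rep(counts * Z[, k], T_)
    keep <- w > 1e-12
    fit <- suppressWarnings(
      stats::glm.fit(Xbig[keep, , drop = FALSE], yvec[keep], weights = w[keep],
                     family = binomial()))
    beta[, k] <- fit$coefficients
  }
  beta
}

gbtm_estep <- function(Y, counts, pi_k, beta, X, clip = 1e-6) {
  P <- plogis(X %*% beta)
  P <- pmin(pmax(P, clip), 1 - clip)
  ll <- sweep(pattern_loglik(Y, P), 2, log(pi_k), "+")
  lse <- logsumexp_rows(ll)
  Z <- exp(ll - lse)
  list(Z = Z, loglik = sum(counts * lse), P = P)
}

run_em <- function(Y, counts, N, pi_k, beta, X, max_iter, tol) {
  trace <- numeric(0)
  e <- gbtm_estep(Y, counts, pi_k, beta, X)
  for (it in seq_len(max_iter)) {
    pi_k <- pmax(colSums(counts * e$Z) / N, 1e-10)
    pi_k <- pi_k / sum(pi_k)
    beta <- gbtm_mstep(Y, counts, e$Z, X)
    e_new <- gbtm_estep(Y, counts, pi_k, beta, X)
    trace <- c(trace, e_new$loglik)
    if (it > 1 && abs(trace[it] - trace[it - 1]) < tol) {
      e <- e_new
      break
    }
    e <- e_new
  }
  list(pi_k = pi_k, beta = beta, e = e, trace = trace)
}

#' Fit a group-based trajectory model
#'
#' Maximizes the mixture likelihood
#' \deqn{L = \prod_i \sum_k \pi_k \prod_t p_{kt}^{y_{it}} (1-p_{kt})^{1-y_{it}},
#'   \quad p_{kt} = \mathrm{logit}^{-1}(\beta_k' x_t)}
#' by EM, where \eqn{x_t} is a polynomial basis in the bin index standardized
#' to \eqn{[-1, 1]}. Class probabilities are clipped to
#' \eqn{[10^{-6}, 1-10^{-6}]} in the E-step. The best of `n_restarts` short
#' runs (by log-likelihood) is run to convergence; the observed-data
#' log-likelihood is non-decreasing across iterations.
#'
#' @param y An N x T binary matrix (no missing entries), e.g. from
#'   [adherence_series_matrix()].
#' @param K Number of latent classes (`K <= N`).
#' @param config A [gbtm_config()].
#' @return A `gbtm` object: class weights `pi`, coefficients `beta`
#'   ((degree+1) x K), fitted per-bin probabilities `p` (T x K),
#'   `loglik`, `n_params`, `bic`, posterior matrix, hard `assignment`,
#'   `loglik_trace`, `degenerate` flag.
#' @export
fit_gbtm <- function(y, K, config = gbtm_config()) {
  y <- as.matrix(y)
  if (anyNA(y)) abort("series matrix must not contain missing values")
  if (!all(y %in% c(0, 1))) abort("series matrix must be binary")
  N <- nrow(y); T_ <- ncol(y)
  if (K > N) abort("K must not exceed the number of series")
  if (!is.null(config$seed)) set.seed(config$seed)

  key <- apply(y, 1, paste, collapse = "")
  uniq <- !duplicated(key)
  Y <- y[uniq, , drop = FALSE]
  counts <- as.vector(table(key)[key[uniq]])
  U <- nrow(Y)
  t_std <- seq(-1, 1, length.out = T_)
  X <- stats::poly(t_std, degree = max(config$degree, 1), raw = TRUE,
                   simple = TRUE)
  X <- cbind(1, X[, seq_len(config$degree), drop = FALSE])
  colnames(X) <- paste0("t", 0:config$degree)

  init_Z <- function(restart) {
    if (restart == 1 && K > 1) {
      km <- suppressWarnings(kmeans(y, centers = K, nstart = 3))
      Z_full <- matrix(1e-3, N, K)
      Z_full[cbind(seq_len(N), km$cluster)] <- 1
    } else if (K > 1) {
      Z_full <- matrix(rgamma(N * K, 0.5), N, K)
    } else {
      Z_full <- matrix(1, N, 1)
    }
    Z_full <- Z_full / rowSums(Z_full)
    # aggregate responsibilities over identical patterns
    agg <- rowsum(Z_full, key)[key[uniq], , drop = FALSE] / counts
    agg / rowSums(agg)
  }

  best <- NULL
  for (restart in seq_len(config$n_restarts)) {
    Z0 <- init_Z(restart)
    pi0 <- pmax(colSums(counts * Z0) / N, 1e-6)
    pi0 <- pi0 / sum(pi0)
    beta0 <- gbtm_mstep(Y, counts, Z0, X)
    run <- run_em(Y, counts, N, pi0, beta0, X,
                  max_iter = config$short_iter, tol = config$tol)
    if (is.null(best) || run$e$loglik > best$e$loglik) best <- run
    if (K == 1) break # deterministic: no restart variability
  }
  run <- run_em(Y, counts, N, best$pi_k, best$beta, X,
                max_iter = config$max_iter, tol = config$tol)
  run$trace <- c(best$trace, run$trace)

  # expand posteriors back to all rows
  post <- run$e$Z[match(key, key[uniq]), , drop = FALSE]
  assignment <- max.col(post, ties.method = "first")
  n_params <- (K - 1) + K * (config$degree + 1)
  loglik <- run$e$loglik
  structure(list(
    K = K, pi = run$pi_k, beta = run$beta, p = run$e$P,
    loglik = loglik, n_params = n_params,
    bic = -2 * loglik + n_params * log(N),
    posterior = post, assignment = assignment,
    loglik_trace = run$trace, n = N, t_std = t_std, degree = config$degree,
    degenerate = any(run$pi_k < config$min_share),
    min_share = config$min_share, labels = NULL, class_mpr = NULL),
    class = "gbtm")
}

#' @export
print.gbtm <- function(x, ...) {
  cat(sprintf("<gbtm> %d classes, N = %d, loglik = %.2f, BIC = %.2f%s\n",
              x$K, x$n, x$loglik, x$bic,
              if (x$degenerate) " (degenerate class present)" else ""))
  shares <- round(100 * x$pi, 1)
  names(shares) <- x$labels %||% paste0("class", seq_len(x$K))
  print(shares)
  invisible(x)
}

#' Select the number of trajectory classes by BIC
#'
#' Fits the model for each candidate K and returns the fit minimizing
#' \eqn{BIC = -2\,\ell + p \log N} among fits whose smallest class share
#' meets `min_share`; if all candidates are degenerate the overall BIC
#' minimizer is returned with a warning.
#'
#' @inheritParams fit_gbtm
#' @param config A [gbtm_config()]; `config$k_range` sets the candidates.
#' @return A list: `model` (best `gbtm`), `bic_table` (tibble of K,
#'   loglik, bic, min_share, degenerate).
#' @export
select_k <- function(y, config = gbtm_config()) {
  if (!length(config$k_range)) abort("empty candidate K range")
  if (!is.null(config$seed)) set.seed(config$seed)
  sub_config <- config
  sub_config$seed <- NULL # one stream across candidates, seeded once above
  fits <- purrr::map(config$k_range, function(k) fit_gbtm(y, k, sub_config))
  bic_table <- purrr::map2(fits, config$k_range, function(f, k) {
    tibble::tibble(K = k, loglik = f$loglik, bic = f$bic,
                   min_class_share = min(f$pi), degenerate = f$degenerate)
  }) |> dplyr::bind_rows()
  ok <- !bic_table$degenerate
  if (!any(ok)) {
    warn("all candidate models have a class below the minimum share")
    ok <- rep(TRUE, nrow(bic_table))
  }
  best_idx <- which(ok)[which.min(bic_table$bic[ok])]
  list(model = fits[[best_idx]], bic_table = bic_table)
}

#' Label trajectory classes A, B, ... by descending mean MPR
#'
#' Classes are renamed alphabetically from highest to lowest adherence based
#' on the mean MPR of their (hard-assigned) members. Ties are broken by
#' larger class size, then by original class index. The labeled output is
#' invariant to permutations of the internal class order.
#'
#' @param model A fitted `gbtm`.
#' @param mpr Per-patient MPR vector aligned with the rows of the series
#'   matrix the model was fit on.
#' @return The model with `labels` (per internal class), `class_mpr`, and
#'   `assignment_label` added.
#' @export
label_clusters <- function(model, mpr) {
  stopifnot(length(mpr) == model$n)
  class_mpr <- purrr::map_dbl(seq_len(model$K), function(k) {
    members <- model$assignment == k
    if (!any(members)) return(NA_real_)
    mean(mpr[members])
  })
  sizes <- tabulate(model$assignment, model$K)
  ord <- order(-class_mpr, -sizes, seq_len(model$K))
  labels <- character(model$K)
  labels[ord] <- LETTERS[seq_len(model$K)]
  model$labels <- labels
  model$class_mpr <- class_mpr
  model$assignment_label <- labels[model$assignment]
  model
}

#' Cluster profile table
#'
#' @param model A labeled `gbtm` (see [label_clusters()]).
#' @param mpr Per-patient MPR vector aligned with the model rows.
#' @return A tibble per class: `label`, `n`, `share_pct`, `mean_mpr_pct`,
#'   ordered A, B, ...
#' @export
cluster_profile <- function(model, mpr) {
  if (is.null(model$labels)) abort("label the model first (label_clusters)")
  stopifnot(length(mpr) == model$n)
  tibble::tibble(label = model$assignment_label, mpr = mpr) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(n = dplyr::n(), mean_mpr_pct = 100 * mean(.data$mpr),
                     .groups = "drop") |>
    dplyr::mutate(share_pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::select("label", "n", "share_pct", "mean_mpr_pct") |>
    dplyr::arrange(.data$label)
}

#' @rdname fit_gbtm
#' @param x A `gbtm` object.
#' @param ... Unused.
#' @export
tidy.gbtm <- function(x, ...) {
  labels <- x$labels %||% paste0("class", seq_len(x$K))
  tidyr::expand_grid(class = labels,
                     term = paste0("t", 0:x$degree)) |>
    dplyr::mutate(estimate = as.vector(x$beta),
                  weight = rep(x$pi, each = x$degree + 1)) |>
    dplyr::arrange(.data$class)
}

#' @rdname fit_gbtm
#' @export
glance.gbtm <- function(x, ...) {
  tibble::tibble(K = x$K, n = x$n, loglik = x$loglik, n_params = x$n_params,
                 bic = x$bic, degenerate = x$degenerate)
}

#' Plot fitted trajectory curves
#'
#' @param object A `gbtm` fit.
#' @param ... Unused.
#' @return A ggplot of the fitted per-bin adherence probabilities by class.
#' @export
autoplot.gbtm <- function(object, ...) {
  labels <- object$labels %||% paste0("class", seq_len(object$K))
  df <- tibble::tibble(
    class = factor(rep(labels, each = length(object$t_std)),
                   levels = sort(labels)),
    bin = rep(seq_along(object$t_std), object$K),
    p = as.vector(object$p),
    share = rep(object$pi, each = length(object$t_std)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$p,
                                   colour = .data$class)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "follow-up bin (4 weeks)",
                  y = "P(bin adherent)", colour = "cluster") +
    ggplot2::theme_minimal()
}
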