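#' Fit a multivariate-t mixture by EM (model-based gating)
#'
#' Automated gating via a `K`-component multivariate-t mixture with fixed
#' degrees of freedom, fitted by expectation-maximization. Each component
#' plays the role of one gated cell population. The degrees of freedom
#' default to `nu = 4`, the heavy-tailed setting typical of cytometry
#' mixture modelling; `nu` is not estimated. There is no component merging,
#' outlier component or model selection over `K` — `K` is supplied by the
#' caller.
#'
#' Initialization runs `n_restarts` k-means++ seedings of `stats::kmeans`
#' on a subsample of at most `init_subsample` events, scores each resulting
#' initialization by one E-step's mixture log-likelihood, and runs full EM
#' from the best. The observed-data log-likelihood is non-decreasing across
#' iterations (recorded in `loglik_trace`). A component whose scatter
#' matrix becomes numerically singular is ridged (small multiple of the
#' average channel variance added to the diagonal) with a warning.
#'
#' @param Y [event_matrix()] or numeric matrix (`n x d`).
#' @param K number of mixture components (populations).
#' @param nu degrees of freedom of every component (fixed, not estimated).
#' @param seed integer seed controlling subsampling and k-means++ draws.
#' @param max_iter EM iteration cap.
#' @param tol relative log-likelihood change declaring convergence.
#' @param n_restarts number of k-means++ initializations scored.
#' @param init_subsample events used for initialization.
#' @return An object of class `t_mixture`: list with `K`, `weights`,
#'   `means` (`K x d`), `covariances` (list of `d x d`), `nu`,
#'   `loglik_trace`, `loglik`, `converged`, `n_iter`, `seed`.
#' @export
#'
#' @examples
#' y <- rbind(matrix(rnorm(300), ncol = 2), matrix(rnorm(300, 8), ncol = 2))
#' m <- fit_t_mixture(y, K = 2, nu = 4, seed = 1)
#' table(assign_events(m, y))
fit_t_mixture <- function(Y, K, nu = 4, seed = 1L, max_iter = 500L,
                          tol = 1e-6, n_restarts = 5L,
                          init_subsample = 5000L) {
  v <- em_values(Y)
  n <- nrow(v); d <- ncol(v)
  stopifnot(K >= 1, nu > 0)
  if (n < K * d) stop("too few events for K components", call. = FALSE)

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))

  sub <- if (n > init_subsample) {
    v[sample.int(n, init_subsample), , drop = FALSE]
  } else v

  best_init <- NULL
  for (r in seq_len(n_restarts)) {
    centers <- kmeanspp_centers(sub, K)
    km <- tryCatch(
      suppressWarnings(stats::kmeans(sub, centers = centers,
                                     iter.max = 30L)),
      error = function(e) NULL)
    if (is.null(km)) next
    init <- init_from_partition(sub, km$cluster, K)
    ll <- estep(v, init, nu)$loglik
    if (is.finite(ll) && (is.null(best_init) || ll > best_init$ll)) {
      best_init <- list(par = init, ll = ll)
    }
  }
  if (is.null(best_init)) stop("mixture initialization failed",
                               call. = FALSE)
  par <- best_init$par

  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    e <- estep(v, par, nu)
    trace <- c(trace, e$loglik)
    if (it > 1 && abs(e$loglik - trace[it - 1]) <
        tol * (abs(trace[it - 1]) + 1e-3)) {
      converged <- TRUE
      break
    }
    par <- mstep(v, e$tau, e$u, par)
  }

  structure(list(K = K, weights = par$weights, means = par$means,
                 covariances = par$covariances, nu = nu,
                 loglik_trace = trace, loglik = trace[length(trace)],
                 converged = converged, n_iter = length(trace),
                 seed = as.integer(seed)),
            class = "t_mixture")
}

#' @export
print.t_mixture <- function(x, ...) {
  cat(sprintf("t_mixture: K = %d, d = %d, nu = %g, loglik = %.4f (%s)\n",
              x$K, ncol(x$means), x$nu, x$loglik,
              if (x$converged) "converged" else "max iterations"))
  invisible(x)
}

# k-means++ seeding (squared-distance weighted center draws)
kmeanspp_centers <- function(v, K) {
  n <- nrow(v)
  idx <- integer(K)
  idx[1] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(v, 2, v[idx[1], ])^2)
  for (k in seq_len(K - 1L) + 1L) {
    prob <- d2 / sum(d2)
    if (!all(is.finite(prob)) || sum(d2) == 0) {
      idx[k] <- sample.int(n, 1L)
    } else {
      idx[k] <- sample.int(n, 1L, prob = prob)
    }
    d2 <- pmin(d2, rowSums(sweep(v, 2, v[idx[k], ])^2))
  }
  v[idx, , drop = FALSE]
}

init_from_partition <- function(v, cluster, K) {
  d <- ncol(v)
  means <- matrix(0, K, d)
  covs <- vector("list", K)
  wts <- numeric(K)
  gv <- stats::var(v) + diag(1e-6 * mean(diag(stats::var(v))) + 1e-12, d)
  for (k in seq_len(K)) {
    rows <- which(cluster == k)
    wts[k] <- max(length(rows), 1) / nrow(v)
    if (length(rows) >= d + 2) {
      means[k, ] <- colMeans(v[rows, , drop = FALSE])
      covs[[k]] <- safe_spd(stats::var(v[rows, , drop = FALSE]), gv)
    } else {
      means[k, ] <- v[sample.int(nrow(v), 1L), ]
      covs[[k]] <- gv
    }
  }
  list(weights = wts / sum(wts), means = means, covariances = covs)
}

safe_spd <- function(sig, fallback) {
  if (any(!is.finite(sig))) return(fallback)
  ok <- tryCatch({chol(sig); TRUE}, error = function(e) FALSE)
  if (ok) sig else {
    ridge_spd(sig)
  }
}

ridge_spd <- function(sig) {
  d <- nrow(sig)
  ridge <- 1e-8 * max(mean(diag(sig)), .Machine$double.eps)
  for (i in 1:30) {
    ok <- tryCatch({chol(sig + diag(ridge, d)); TRUE},
                   error = function(e) FALSE)
    if (ok) break
    ridge <- ridge * 10
  }
  warning("singular component covariance; ridge added", call. = FALSE)
  sig + diag(ridge, d)
}

# log density of the multivariate t, plus squared Mahalanobis distances
t_logdens <- function(v, mu, sig, nu) {
  d <- ncol(v)
  ch <- chol(sig)
  z <- forwardsolve(t(ch), t(sweep(v, 2, mu)))
  delta <- colSums(z^2)
  logdet <- 2 * sum(log(diag(ch)))
  ld <- lgamma((nu + d) / 2) - lgamma(nu / 2) - (d / 2) * log(nu * pi) -
    0.5 * logdet - ((nu + d) / 2) * log1p(delta / nu)
  list(logdens = ld, delta = delta)
}

estep <- function(v, par, nu) {
  n <- nrow(v); d <- ncol(v); K <- length(par$weights)
  logp <- matrix(0, n, K)
  delta <- matrix(0, n, K)
  for (k in seq_len(K)) {
    td <- t_logdens(v, par$means[k, ], par$covariances[[k]], nu)
    logp[, k] <- log(par$weights[k]) + td$logdens
    delta[, k] <- td$delta
  }
  m <- apply(logp, 1, max)
  lse <- m + log(rowSums(exp(logp - m)))
  tau <- exp(logp - lse)
  u <- (nu + d) / (nu + delta)
  list(tau = tau, u = u, loglik = sum(lse))
}

mstep <- function(v, tau, u, par) {
  n <- nrow(v); d <- ncol(v); K <- ncol(tau)
  w <- tau * u
  weights <- colMeans(tau)
  means <- matrix(0, K, d)
  covs <- vector("list", K)
  for (k in seq_len(K)) {
    sw <- sum(w[, k])
    means[k, ] <- colSums(v * w[, k]) / sw
    ctr <- sweep(v, 2, means[k, ])
    sig <- crossprod(ctr * sqrt(w[, k]), ctr * sqrt(w[, k])) /
      max(sum(tau[, k]), .Machine$double.eps)
    sig <- 0.5 * (sig + t(sig))
    ok <- tryCatch({chol(sig); TRUE}, error = function(e) FALSE)
    covs[[k]] <- if (ok) sig else ridge_spd(sig)
  }
  list(weights = weights / sum(weights), means = means, covariances = covs)
}

#' Assign events to mixture components
#'
#' Maximum-a-posteriori component labels under a fitted [fit_t_mixture()]
#' model. Posterior probabilities sum to one per event; exact ties are
#' broken deterministically toward the lower component index.
#'
#' @param model a `t_mixture`.
#' @param Y data of the same dimensionality the model was fitted on.
#' @param posterior if `TRUE`, also return the `n x K` posterior matrix.
#' @return integer vector of component labels in `1..K` (or a list with
#'   `labels` and `posterior`).
#' @export
assign_events <- function(model, Y, posterior = FALSE) {
  stopifnot(inherits(model, "t_mixture"))
  v <- em_values(Y)
  if (ncol(v) != ncol(model$means)) {
    stop("dimension mismatch: model fitted on d = ", ncol(model$means),
         " channels, data has d = ", ncol(v), call. = FALSE)
  }
  e <- estep(v, model[c("weights", "means", "covariances")], model$nu)
  labels <- max.col(e$tau, ties.method = "first")
  if (posterior) list(labels = labels, posterior = e$tau) else labels
}

#' Extract gated population summaries from a fitted mixture
#'
#' Converts each component of a fitted [fit_t_mixture()] model into a
#' population record (the unit of [metacluster()]): location, scatter,
#' degrees of freedom and the number of events assigned by MAP labelling.
#'
#' @inheritParams assign_events
#' @param sample_id sample identifier stored in each population.
#' @return list of `population` objects (lists with `sample_id`,
#'   `pop_index`, `mu`, `sigma`, `nu`, `size`).
#' @export
extract_populations <- function(model, Y, sample_id = NULL) {
  if (is.null(sample_id)) sample_id <- sample_id(Y)
  labels <- assign_events(model, Y)
  lapply(seq_len(model$K), function(k) {
    population(sample_id = sample_id, pop_index = k,
               mu = model$means[k, ], sigma = model$covariances[[k]],
               nu = model$nu, size = max(sum(labels == k), 1L))
  })
}

#' @rdname extract_populations
#' @param pop_index index of the population within its sample.
#' @param mu location vector.
#' @param sigma positive-definite scatter matrix.
#' @param nu degrees of freedom.
#' @param size number of events in the population.
#' @export
population <- function(sample_id, pop_index, mu, sigma, nu = 4,
                       size = 1L) {
  sigma <- as.matrix(sigma)
  stopifnot(length(mu) == nrow(sigma), nrow(sigma) == ncol(sigma),
            size >= 1)
  structure(list(sample_id = as.character(sample_id),
                 pop_index = as.integer(pop_index),
                 mu = as.numeric(mu), sigma = sigma, nu = nu,
                 size = as.integer(size)),
            class = "population")
}
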