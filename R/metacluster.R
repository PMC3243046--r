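#' Mahalanobis distance between gated populations
#'
#' Distance from population `p` to population `q` under `p`'s scatter
#' matrix: `D(p, q) = (mu_p - mu_q)' solve(Sigma_p) (mu_p - mu_q)`. The
#' first argument is the metacluster member; because only its covariance is
#' used the distance is *not* symmetric in general. A numerically singular
#' `Sigma_p` is ridge-regularized with a warning.
#'
#' @param p,q `population` objects (see [population()]) with matching
#'   dimensions.
#' @return non-negative scalar; zero iff the means coincide.
#' @export
#'
#' @examples
#' p <- population("s1", 1, mu = c(0, 0), sigma = diag(c(1, 4)))
#' q <- population("s2", 1, mu = c(1, 2), sigma = diag(2))
#' pop_mahalanobis(p, q)  # 1/1 + 4/4 = 2
pop_mahalanobis <- function(p, q) {
  stopifnot(inherits(p, "population"), inherits(q, "population"))
  if (length(p$mu) != length(q$mu)) {
    stop("population dimensions differ", call. = FALSE)
  }
  diff <- p$mu - q$mu
  sig <- p$sigma
  ch <- tryCatch(chol(sig), error = function(e) NULL)
  if (is.null(ch)) {
    sig <- ridge_spd(sig)
    ch <- chol(sig)
  }
  z <- forwardsolve(t(ch), diff)
  sum(z^2)
}

#' Match gated populations across samples (metaclustering)
#'
#' Groups corresponding cell populations across samples by constrained
#' single-linkage agglomeration. Populations within a sample are assumed
#' distinct, so no metacluster may contain more than one population from
#' the same sample. The algorithm:
#'
#' 1. `K = max_n(pi_n)`, the largest population count over samples.
#' 2. Seed the `K` metaclusters with the populations of a sample attaining
#'    that maximum (ties broken by the highest gating log-likelihood if
#'    `sample_loglik` is given, then by lowest sample position).
#' 3. Repeatedly assign the globally nearest (unassigned population,
#'    feasible metacluster) pair, where the metacluster-to-population
#'    distance is the minimum [pop_mahalanobis()] from any current member
#'    (member's covariance) and is infinite for metaclusters already
#'    holding a population from that sample. Members update immediately,
#'    so clusters grow single-linkage style.
#' 4. Stop when every population is assigned.
#'
#' Ties in step 3 are broken lexicographically on (sample position,
#' population index, metacluster index), making runs deterministic.
#'
#' @param populations_by_sample list (one element per sample) of lists of
#'   [population()] objects; every sample must contribute at least one.
#' @param sample_loglik optional numeric vector (one per sample) used for
#'   the step-2 tie-break, e.g. gating model log-likelihoods.
#' @return An object of class `metaclustering`: list with `K`,
#'   `assignments` (data.frame: sample_id, pop_index, metacluster) and
#'   `metaclusters` (list of member [population()] lists).
#' @export
metacluster <- function(populations_by_sample, sample_loglik = NULL) {
  if (!length(populations_by_sample) ||
      any(!lengths(populations_by_sample))) {
    stop("every sample must contribute at least one population",
         call. = FALSE)
  }
  pops <- populations_by_sample
  n_samples <- length(pops)
  pi_n <- lengths(pops)
  K <- max(pi_n)

  seeds <- which(pi_n == K)
  n0 <- if (length(seeds) > 1 && !is.null(sample_loglik)) {
    seeds[which.max(sample_loglik[seeds])]
  } else {
    seeds[1]
  }

  # flatten to a global index ordered by (sample position, pop index);
  # this order is also the lexicographic tie-break order of step 3
  flat <- do.call(rbind, lapply(seq_len(n_samples), function(n) {
    cbind(sample = n, pop = seq_len(pi_n[n]))
  }))
  P <- nrow(flat)
  all_pops <- lapply(seq_len(P), function(i) {
    pops[[flat[i, 1]]][[flat[i, 2]]]
  })
  # precompute D[i, j] = distance from member i (its covariance) to j
  D <- matrix(0, P, P)
  for (i in seq_len(P)) {
    for (j in seq_len(P)) {
      if (i != j) D[i, j] <- pop_mahalanobis(all_pops[[i]], all_pops[[j]])
    }
  }

  gidx <- function(n, j) which(flat[, 1] == n & flat[, 2] == j)
  label <- rep(NA_integer_, P)
  seed_idx <- vapply(seq_len(K), function(j) gidx(n0, j), 1L)
  label[seed_idx] <- seq_len(K)
  # dmin[k, j]: single-linkage distance from metacluster k to population j
  dmin <- D[seed_idx, , drop = FALSE]
  in_cluster <- matrix(FALSE, n_samples, K)
  in_cluster[n0, ] <- TRUE

  while (anyNA(label)) {
    cand <- dmin
    cand[, !is.na(label)] <- Inf
    cand[t(in_cluster[flat[, 1], , drop = FALSE])] <- Inf
    if (!any(is.finite(cand))) {
      stop("no feasible metacluster assignment remains", call. = FALSE)
    }
    # global minimum; ties broken on (sample, pop) then metacluster index,
    # i.e. column-major order over cand transposed -> iterate columns first
    mval <- min(cand)
    hits <- which(cand <= mval, arr.ind = TRUE)  # (k, j) pairs
    hits <- hits[order(hits[, 2], hits[, 1]), , drop = FALSE]
    k <- hits[1, 1]; j <- hits[1, 2]
    label[j] <- k
    in_cluster[flat[j, 1], k] <- TRUE
    dmin[k, ] <- pmin(dmin[k, ], D[j, ])
  }

  sample_ids <- vapply(pops, function(ps) ps[[1]]$sample_id, "")
  assignments <- data.frame(sample_id = sample_ids[flat[, 1]],
                            pop_index = flat[, 2], metacluster = label,
                            stringsAsFactors = FALSE)
  metaclusters <- lapply(seq_len(K), function(k) {
    all_pops[which(label == k)]
  })
  structure(list(K = K, assignments = assignments,
                 metaclusters = metaclusters, seed_sample = n0),
            class = "metaclustering")
}

#' @export
print.metaclustering <- function(x, ...) {
  cat(sprintf("metaclustering: K = %d, %d populations from %d samples\n",
              x$K, nrow(x$assignments),
              length(unique(x$assignments$sample_id))))
  invisible(x)
}

#' Intra-metacluster variability
#'
#' Total sum of squared deviations of member population centers from their
#' metacluster mean center, summed over metaclusters. Lower values mean
#' more consistent population locations across samples. Computed on
#' whatever scale the populations were gated on.
#'
#' @param mc a [metacluster()] result.
#' @return non-negative scalar; zero iff every metacluster's members share
#'   one center.
#' @export
intra_metacluster_variability <- function(mc) {
  stopifnot(inherits(mc, "metaclustering"))
  total <- 0
  for (k in seq_along(mc$metaclusters)) {
    mus <- do.call(rbind, lapply(mc$metaclusters[[k]], `[[`, "mu"))
    ctr <- colMeans(mus)
    total <- total + sum(sweep(mus, 2, ctr)^2)
  }
  total
}
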