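#' Simulate a benchmark cytometry dataset
#'
#' Generates one synthetic three-channel sample from a nine-component
#' multivariate-t mixture and corrupts it with a random inverse-
#' biexponential map, providing ground truth for evaluating transformation
#' optimization and gating.
#'
#' The generative model: component labels are drawn with fixed proportions
#' `p = (0.0477, 0.0351, 0.0101, 0.0678, 0.0756, 0.0730, 0.1330, 0.0677,
#' 0.490)` (a single Dirichlet(1,...,1,10) realization held fixed so runs
#' are comparable; set `redraw_proportions = TRUE` for a fresh draw).
#' Component `k` emits multivariate-t events with `nu = 4` degrees of
#' freedom and scale `sigma^2 * I` with `sigma^2 = 0.25`; the component
#' locations are the eight corners of the cube `{0, 7}^3` plus its center
#' `(3.5, 3.5, 3.5)`, mimicking well-separated cell populations with one
#' dense central population. The clean events are then pushed through
#' [biexp_function()] with per-dataset random parameters `a, c ~ U(0, 1)`,
#' `b, d ~ U(0, 2)`, `f = 0`, `w = 0` — the "inverse-biexponential"
#' corruption that mimics raw instrument scale. By default the same
#' corruption applies to all three channels (`per_channel_corruption`
#' draws independent parameters per channel instead).
#'
#' @param seed integer seed; the dataset is a deterministic function of it.
#' @param n number of events.
#' @param sigma2 per-component variance scale.
#' @param nu degrees of freedom of the component t distributions.
#' @param cube_max upper corner coordinate (locations span `0..cube_max`).
#' @param redraw_proportions draw fresh Dirichlet proportions instead of
#'   the fixed vector.
#' @param dirichlet_alpha Dirichlet parameter used when redrawing.
#' @param per_channel_corruption independent corruption parameters per
#'   channel.
#' @return An object of class `simulated_dataset`: list with `events`
#'   (corrupted-scale [event_matrix()]), `clean_events` (original scale),
#'   `true_labels` (1..9), `proportions`, `means`, `corruption`
#'   ([transform_spec()] or list of them), `seed`.
#' @export
#'
#' @examples
#' sim <- simulate_dataset(seed = 1, n = 2000)
#' table(sim$true_labels)
simulate_dataset <- function(seed, n = 15000, sigma2 = 0.25, nu = 4,
                             cube_max = 7, redraw_proportions = FALSE,
                             dirichlet_alpha = c(rep(1, 8), 10),
                             per_channel_corruption = FALSE) {
  stopifnot(n >= 1)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))

  p <- c(0.0477, 0.0351, 0.0101, 0.0678, 0.0756, 0.0730, 0.1330, 0.0677,
         0.490)
  if (redraw_proportions) {
    g <- stats::rgamma(length(dirichlet_alpha), shape = dirichlet_alpha)
    p <- g / sum(g)
  }
  corners <- as.matrix(expand.grid(c(0, cube_max), c(0, cube_max),
                                   c(0, cube_max)))
  means <- rbind(corners, rep(cube_max / 2, 3))
  dimnames(means) <- NULL

  labels <- sample.int(9L, n, replace = TRUE, prob = p)
  # multivariate t: Gaussian over sqrt(chi^2_nu / nu), one mixing
  # variable per event shared across the three channels
  z <- matrix(stats::rnorm(n * 3), n, 3)
  wchi <- sqrt(stats::rchisq(n, df = nu) / nu)
  clean <- means[labels, , drop = FALSE] + sqrt(sigma2) * z / wchi
  colnames(clean) <- paste0("ch", 1:3)

  draw_corruption <- function() {
    transform_spec("biexp", a = stats::runif(1, 0, 1),
                   b = stats::runif(1, 0, 2),
                   c = stats::runif(1, 0, 1),
                   d = stats::runif(1, 0, 2), f = 0, w = 0)
  }
  if (per_channel_corruption) {
    corruption <- lapply(1:3, function(j) draw_corruption())
    corrupted <- vapply(1:3, function(j) {
      biexp_function(corruption[[j]], clean[, j])
    }, numeric(n))
    colnames(corrupted) <- colnames(clean)
  } else {
    corruption <- draw_corruption()
    corrupted <- biexp_function(corruption, clean)
  }

  sid <- paste0("sim", seed)
  structure(list(events = event_matrix(corrupted, sample_id = sid),
                 clean_events = event_matrix(clean, sample_id = sid),
                 true_labels = labels, proportions = p, means = means,
                 corruption = corruption, seed = as.integer(seed)),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("simulated_dataset: %d events, 9 components, seed %d\n",
              length(x$true_labels), x$seed))
  invisible(x)
}

#' Per-channel location-scale standardization
#'
#' Puts samples on a common scale by median-centering and MAD-scaling each
#' channel (falling back to the standard deviation for channels with zero
#' MAD). This is deliberately simple plumbing standing in for
#' curve/warping-based inter-sample normalization; it is idempotent up to
#' floating point.
#'
#' @param Y [event_matrix()] or numeric matrix.
#' @return standardized data of the same class and shape.
#' @export
normalize_events <- function(Y) {
  v <- em_values(Y)
  if (any(!is.finite(v))) stop("data must be finite", call. = FALSE)
  out <- apply(v, 2, function(col) {
    ctr <- stats::median(col)
    sc <- stats::mad(col, center = ctr)
    if (sc == 0) sc <- stats::sd(col)
    if (!is.finite(sc) || sc == 0) sc <- 1
    (col - ctr) / sc
  })
  out <- matrix(out, nrow = nrow(v), dimnames = dimnames(v))
  if (inherits(Y, "event_matrix")) {
    event_matrix(out, sample_id = sample_id(Y))
  } else {
    out
  }
}
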