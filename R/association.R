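#' Mutual-information estimator parameters
#'
#' @param k Neighbour count for the k-nearest-neighbour estimator
#'   (default 4).
#' @param noise_amplitude Amplitude of the seeded uniform dither added to
#'   break ties among repeated values (default 1e-8). Expression matrices
#'   contain tied values (zeros in particular) and the estimator requires
#'   distinct distances.
#' @param rng_seed Integer seed for the dither.
#' @return A validated list of class `mi_params`.
#' @export
mi_params <- function(k = 4, noise_amplitude = 1e-8, rng_seed = 1L) {
  if (k < 1) stop("k must be >= 1")
  if (noise_amplitude < 0) stop("noise_amplitude must be >= 0")
  structure(list(k = as.integer(k), noise_amplitude = noise_amplitude,
                 rng_seed = as.integer(rng_seed)), class = "mi_params")
}

#' Pearson correlation with explicit degeneracy handling
#'
#' Standard product-moment correlation; a constant vector (for which the
#' correlation is undefined) is an error so degenerate features can be
#' excluded upstream.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return Correlation in \eqn{[-1, 1]}.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  stats::cor(x, y)
}

#' Kraskov algorithm-2 k-NN mutual information (nats)
#'
#' Estimates the mutual information between two continuous samples with the
#' Kraskov-Stoegbauer-Grassberger algorithm-2 estimator: after a seeded
#' uniform dither of amplitude `noise_amplitude` breaks ties, the k-th
#' nearest neighbour of each point is located under the max-norm in the
#' joint space; per-marginal radii \eqn{\epsilon_x(i)/2, \epsilon_y(i)/2}
#' are the largest marginal distances over those k neighbours, and
#' \eqn{n_x(i), n_y(i)} count the points within the closed marginal balls
#' (self excluded). The estimate is
#' \deqn{\psi(k) - 1/k - \langle\psi(n_x) + \psi(n_y)\rangle + \psi(N)}
#' in nats. The digamma debiasing means estimates near independence can be
#' (slightly) negative; no further bias correction is applied.
#'
#' @param x,y Numeric vectors of equal length N > k, finite values.
#' @param params An [mi_params()] (or arguments via `...`).
#' @param ... Passed to [mi_params()] when `params` is missing.
#' @return Mutual information estimate in nats (may be negative).
#' @export
ksg_mi <- function(x, y, params = mi_params(...), ...) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n <= params$k) stop("need more observations than neighbours (N > k)")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("x and y must be finite")
  if (params$noise_amplitude > 0) {
    set.seed(params$rng_seed)
    x <- x + stats::runif(n, -params$noise_amplitude, params$noise_amplitude)
    y <- y + stats::runif(n, -params$noise_amplitude, params$noise_amplitude)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero-variance input: mutual information undefined")
  cts <- ksg_counts_cpp(x, y, params$k)
  digamma(params$k) - 1 / params$k + digamma(n) -
    mean(digamma(cts[, 1]) + digamma(cts[, 2]))
}

#' Pearson correlation and mutual information for every miR x mRNA pair
#'
#' Both matrices must share an identical ordered sample list. Constant
#' features (zero variance) are dropped with a warning before pairing, as
#' their correlation is undefined. The tie-breaking dither is drawn once
#' per matrix from `params$rng_seed`, so results are deterministic given
#' the seed and invariant to the pairing order.
#'
#' @param mir_m miR [expression_matrix()].
#' @param mrna_m mRNA-probe [expression_matrix()].
#' @param params An [mi_params()].
#' @param verbose Emit progress messages per 1e5 pairs (default FALSE).
#' @return Data frame with one row per (miR, probe) pair: `mir_id`,
#'   `probe_id`, `pearson_r`, `mi` (nats), ordered miR-major.
#' @export
pairwise_associations <- function(mir_m, mrna_m, params = mi_params(),
                                  verbose = FALSE) {
  if (!identical(colnames(mir_m), colnames(mrna_m)))
    stop("matrices must share an identical ordered sample list")
  n <- ncol(mir_m)
  if (n <= params$k) stop("need more samples than neighbours (N > k)")

  drop_constant <- function(m, label) {
    cst <- apply(unclass(m), 1L, function(v) max(v) == min(v))
    if (any(cst)) {
      warning(sum(cst), " constant ", label,
              " feature(s) excluded (correlation undefined)")
      m <- rewrap(unclass(m)[!cst, , drop = FALSE], m)
    }
    m
  }
  mir_m <- drop_constant(mir_m, "miR")
  mrna_m <- drop_constant(mrna_m, "mRNA")

  r_mat <- stats::cor(t(unclass(mir_m)), t(unclass(mrna_m)))

  xm <- unclass(mir_m)
  ym <- unclass(mrna_m)
  if (params$noise_amplitude > 0) {
    set.seed(params$rng_seed)
    xm <- xm + matrix(stats::runif(length(xm), -params$noise_amplitude,
                                   params$noise_amplitude), nrow = nrow(xm))
    ym <- ym + matrix(stats::runif(length(ym), -params$noise_amplitude,
                                   params$noise_amplitude), nrow = nrow(ym))
  }
  if (verbose)
    message(sprintf("computing MI for %d x %d = %d pairs",
                    nrow(xm), nrow(ym), nrow(xm) * nrow(ym)))
  mi_mat <- pairwise_ksg_cpp(xm, ym, params$k)

  data.frame(
    mir_id = rep(rownames(mir_m), each = nrow(mrna_m)),
    probe_id = rep(rownames(mrna_m), times = nrow(mir_m)),
    pearson_r = as.vector(t(r_mat)),
    mi = as.vector(t(mi_mat)),
    stringsAsFactors = FALSE)
}
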