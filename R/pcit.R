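# Evaluation grid shared by curve classification, mean-curve reporting and the
# enumeration oracle. 101 points on [0, 1].
pcit_grid <- function() seq(0, 1, length.out = 101L)

#' Construct a three-segment piecewise-linear plasticity curve
#'
#' A curve is defined by four knots at x-positions \code{0 = x0 < x1 < x2 <
#' x3 = 1} and four y-values in \code{[-1, 1]}, linearly interpolated between
#' knots. This is the curve family over which the nonmonotonic-plasticity
#' posterior is computed.
#'
#' @param x numeric(4), strictly increasing, first 0 and last 1.
#' @param y numeric(4), each within \code{[-1, 1]}.
#' @return An object of class \code{pcit_curve}.
#' @export
pcit_curve <- function(x, y) {
  stopifnot(length(x) == 4L, length(y) == 4L)
  if (x[1] != 0 || x[4] != 1 || any(diff(x) <= 0))
    stop("x-knots must satisfy 0 = x0 < x1 < x2 < x3 = 1")
  if (any(!is.finite(y)) || any(abs(y) > 1))
    stop("y-values must be finite and within [-1, 1]")
  structure(list(x = as.numeric(x), y = as.numeric(y)), class = "pcit_curve")
}

#' Evaluate a plasticity curve
#'
#' Linear interpolation between the curve's knots; exact at knots.
#'
#' @param curve a \code{pcit_curve}.
#' @param x numeric vector of evaluation points in \code{[0, 1]}.
#' @return numeric vector of curve values.
#' @export
curve_value <- function(curve, x) {
  if (any(x < 0 | x > 1)) stop("curve evaluation points must lie in [0, 1]")
  stats::approx(curve$x, curve$y, xout = x, method = "linear")$y
}

# Vectorized evaluation of many curves at shared x points.
# xk, yk: n x 4 matrices of knots; xs: length-m vector. Returns n x m matrix.
# Uses the cumulative-hinge identity
#   f(x) = y0 + sum_s (y_{s+1} - y_s) * clamp((x - x_s)/(x_{s+1} - x_s), 0, 1)
.curve_values_mat <- function(xk, yk, xs) {
  n <- nrow(xk); m <- length(xs)
  out <- matrix(yk[, 1], n, m)
  xs_row <- matrix(xs, n, m, byrow = TRUE)
  for (s in 1:3) {
    frac <- (xs_row - xk[, s]) / (xk[, s + 1] - xk[, s])
    frac[frac < 0] <- 0
    frac[frac > 1] <- 1
    out <- out + (yk[, s + 1] - yk[, s]) * frac
  }
  out
}

# Classify many curves for theory consistency on the standard grid.
# A curve is consistent with nonmonotonic plasticity (U-shape) iff, over the
# grid, the minimum is attained strictly inside (0,1), lies strictly below
# both endpoint values, is negative, and the right endpoint value is positive
# (moderate reactivation weakens, strong reactivation strengthens).
.classify_mat <- function(xk, yk) {
  g <- pcit_grid()
  v <- .curve_values_mat(xk, yk, g)
  im <- max.col(-v, ties.method = "first")
  vmin <- v[cbind(seq_len(nrow(v)), im)]
  im > 1L & im < ncol(v) &
    vmin < v[, 1] & vmin < v[, ncol(v)] &
    vmin < 0 & v[, ncol(v)] > 0
}

#' Theory consistency of a plasticity curve
#'
#' Tests whether the curve is U-shaped in the sense of the nonmonotonic
#' plasticity hypothesis: over the evaluation grid, its minimum is attained
#' strictly inside (0, 1), lies strictly below both endpoint values and below
#' zero, and the right endpoint value is positive.
#'
#' @param curve a \code{pcit_curve}.
#' @return logical scalar.
#' @export
classify_consistency <- function(curve) {
  .classify_mat(matrix(curve$x, 1), matrix(curve$y, 1))[1]
}

#' Draw one random plasticity curve from the raw prior
#'
#' Interior x-knots are two sorted uniform draws on (0, 1); y-values are
#' i.i.d. uniform on \code{[-1, 1]}. Uses the current RNG state.
#'
#' @return a \code{pcit_curve}.
#' @export
sample_curve <- function() {
  xi <- sort(stats::runif(2))
  pcit_curve(c(0, xi, 1), stats::runif(4, -1, 1))
}

# Draw n raw curves as knot matrices (list xk, yk). Uses current RNG state.
.sample_raw <- function(n) {
  xi <- matrix(stats::runif(2L * n), n, 2)
  xi <- cbind(pmin(xi[, 1], xi[, 2]), pmax(xi[, 1], xi[, 2]))
  # degenerate equal draws have probability zero; nudge defensively
  eq <- xi[, 1] == xi[, 2]
  if (any(eq)) xi[eq, 2] <- xi[eq, 2] + 1e-12
  xk <- cbind(0, xi, 1)
  yk <- matrix(stats::runif(4L * n, -1, 1), n, 4)
  list(xk = xk, yk = yk)
}

# Balanced prior: mixture drawing half the sample uniformly from the
# theory-consistent set and half from the inconsistent set (rejection
# sampling), so that the prior probability of consistency is exactly 0.5.
# Uses current RNG state. Returns list(xk, yk, consistent).
.sample_balanced <- function(n_samples, max_batches = 400L) {
  n_half <- n_samples %/% 2L
  if (2L * n_half != n_samples) stop("n_samples must be even for the balanced prior")
  acc <- list(cons = list(xk = NULL, yk = NULL, n = 0L),
              inc  = list(xk = NULL, yk = NULL, n = 0L))
  batch <- min(max(4096L, n_samples), 131072L)
  for (b in seq_len(max_batches)) {
    raw <- .sample_raw(batch)
    cl <- .classify_mat(raw$xk, raw$yk)
    for (grp in c(TRUE, FALSE)) {
      key <- if (grp) "cons" else "inc"
      need <- n_half - acc[[key]]$n
      if (need <= 0L) next
      idx <- which(cl == grp)
      if (length(idx) > need) idx <- idx[seq_len(need)]
      if (length(idx)) {
        acc[[key]]$xk <- rbind(acc[[key]]$xk, raw$xk[idx, , drop = FALSE])
        acc[[key]]$yk <- rbind(acc[[key]]$yk, raw$yk[idx, , drop = FALSE])
        acc[[key]]$n <- acc[[key]]$n + length(idx)
      }
    }
    if (acc$cons$n >= n_half && acc$inc$n >= n_half) break
  }
  if (acc$cons$n < n_half || acc$inc$n < n_half)
    stop("balanced curve sampling failed: one consistency class is too rare")
  list(xk = rbind(acc$cons$xk, acc$inc$xk),
       yk = rbind(acc$cons$yk, acc$inc$yk),
       consistent = rep(c(TRUE, FALSE), each = n_half))
}

#' Importance weight of a curve given data
#'
#' Gaussian residual likelihood: \code{exp(-SSR / (2 * noise_scale^2))} with
#' \code{SSR = sum((y - curve(x))^2)}.
#'
#' @param curve a \code{pcit_curve}.
#' @param xs predictor values in \code{[0, 1]}.
#' @param ys outcome values.
#' @param noise_scale residual scale; defaults to \code{sd(ys)}.
#' @return nonnegative weight.
#' @export
importance_weight <- function(curve, xs, ys, noise_scale = stats::sd(ys)) {
  if (!is.finite(noise_scale) || noise_scale <= 0)
    stop("noise_scale must be positive")
  ssr <- sum((ys - curve_value(curve, xs))^2)
  exp(-ssr / (2 * noise_scale^2))
}

# Log importance weights for a curve sample. pred: n_curves x n_points.
.log_weights <- function(pred, ys, noise_scale) {
  ssr <- rowSums(sweep(pred, 2L, ys)^2)
  -ssr / (2 * noise_scale^2)
}

#' Fit the nonmonotonic-plasticity curve posterior by importance sampling
#'
#' Samples piecewise-linear curves from the balanced prior (half
#' theory-consistent, half inconsistent, so chance level is 0.5), weights each
#' curve by a Gaussian likelihood of the data, and reports the posterior
#' probability of theory consistency, the posterior mean curve on a 101-point
#' grid with a weighted 5th-95th percentile band, and the effective sample
#' size of the importance weights.
#'
#' @param xs predictor values, normalized to \code{[0, 1]}
#'   (see \code{\link{normalize_x}}).
#' @param ys outcome values (e.g. change in competitor evidence).
#' @param n_samples number of curve samples (even; default 10000).
#' @param seed integer seed; the fit is bit-reproducible given
#'   \code{(xs, ys, n_samples, seed)}.
#' @param noise_scale Gaussian residual scale; default \code{sd(ys)}.
#' @param balanced use the balanced prior (default) or the raw uniform prior.
#' @return An object of class \code{pcit_result}: list with elements
#'   \code{p_theory_consistent}, \code{mean_curve} (data.frame x, y, lo, hi),
#'   \code{ess}, \code{n_samples}, \code{noise_scale}, \code{fit_ok},
#'   \code{n_points}. \code{fit_ok} is \code{FALSE} when the effective sample
#'   size falls below 50 (reported, with a warning, rather than an error).
#' @export
pcit_fit <- function(xs, ys, n_samples = 10000L, seed = 1L,
                     noise_scale = NULL, balanced = TRUE) {
  xs <- as.numeric(xs); ys <- as.numeric(ys)
  if (length(xs) != length(ys)) stop("xs and ys must have equal length")
  if (length(xs) < 3L) stop("at least 3 data points are required")
  if (any(!is.finite(xs)) || any(!is.finite(ys))) stop("non-finite data")
  if (any(xs < 0 | xs > 1)) stop("xs must be normalized to [0, 1]")
  if (is.null(noise_scale)) noise_scale <- stats::sd(ys)
  if (!is.finite(noise_scale) || noise_scale <= 0)
    stop("noise_scale must be positive (constant ys need an explicit value)")
  set.seed(seed)
  cs <- if (balanced) .sample_balanced(n_samples) else {
    raw <- .sample_raw(n_samples)
    raw$consistent <- .classify_mat(raw$xk, raw$yk)
    raw
  }
  .pcit_posterior(cs, xs, ys, noise_scale, n_samples)
}

# Posterior summaries given a curve sample. Processes curves in chunks so
# that very large samples stay within memory.
.pcit_posterior <- function(cs, xs, ys, noise_scale, n_samples,
                            chunk = 65536L) {
  n <- nrow(cs$xk)
  idx_chunks <- split(seq_len(n), ceiling(seq_len(n) / chunk))
  lw <- numeric(n)
  for (ii in idx_chunks) {
    pred <- .curve_values_mat(cs$xk[ii, , drop = FALSE],
                              cs$yk[ii, , drop = FALSE], xs)
    lw[ii] <- .log_weights(pred, ys, noise_scale)
  }
  w <- exp(lw - max(lw))
  sw <- sum(w)
  if (!is.finite(sw) || sw <= 0)
    stop("all importance weights underflowed; increase noise_scale")
  p_tc <- sum(w[cs$consistent]) / sw
  ess <- sw^2 / sum(w^2)
  g <- pcit_grid()
  mean_curve <- numeric(length(g))
  # the 5th-95th percentile band is exact for moderate samples and computed
  # from a weight-proportional resample for very large ones
  exact_band <- n <= 131072L
  if (exact_band) {
    gv_all <- matrix(NA_real_, n, length(g))
  } else {
    bi <- sample.int(n, 8192L, replace = TRUE, prob = w)
    gv_all <- matrix(NA_real_, 8192L, length(g))
  }
  for (ii in idx_chunks) {
    gv <- .curve_values_mat(cs$xk[ii, , drop = FALSE],
                            cs$yk[ii, , drop = FALSE], g)
    mean_curve <- mean_curve + colSums(gv * w[ii])
    if (exact_band) {
      gv_all[ii, ] <- gv
    } else {
      hit <- which(bi %in% ii)
      if (length(hit)) gv_all[hit, ] <- gv[match(bi[hit], ii), ]
    }
  }
  mean_curve <- mean_curve / sw
  band <- if (exact_band) {
    apply(gv_all, 2L, .weighted_quantile, w = w, probs = c(0.05, 0.95))
  } else {
    apply(gv_all, 2L, stats::quantile, probs = c(0.05, 0.95), names = FALSE)
  }
  fit_ok <- ess >= 50
  if (!fit_ok)
    warning(sprintf("effective sample size %.1f < 50: model fitting failed", ess))
  structure(list(
    p_theory_consistent = p_tc,
    mean_curve = data.frame(x = g, y = mean_curve,
                            lo = band[1, ], hi = band[2, ]),
    ess = ess, n_samples = n_samples, n_points = length(xs),
    noise_scale = noise_scale, fit_ok = fit_ok
  ), class = "pcit_result")
}

.weighted_quantile <- function(v, w, probs) {
  o <- order(v)
  cw <- cumsum(w[o]) / sum(w)
  sapply(probs, function(p) v[o][which(cw >= p)[1]])
}

#' @export
print.pcit_result <- function(x, ...) {
  cat(sprintf("P-CIT fit: %d curves, %d data points\n", x$n_samples, x$n_points))
  cat(sprintf("  P(theory consistent) = %.3f (chance = 0.5)\n",
              x$p_theory_consistent))
  cat(sprintf("  effective sample size = %.1f (%s)\n", x$ess,
              if (x$fit_ok) "ok" else "model fitting failed"))
  invisible(x)
}

#' Permutation test for the theory-consistency posterior
#'
#' Shuffles \code{ys} against \code{xs} \code{n_perm} times, recomputes the
#' theory-consistency posterior for each shuffle with the same curve sample
#' (weights are recomputed per permutation), and reports
#' \code{p = (1 + #\{permuted >= observed\}) / (n_perm + 1)}.
#'
#' @inheritParams pcit_fit
#' @param n_perm number of permutations (default 1000).
#' @return list with \code{p_value}, \code{observed} (p_theory_consistent),
#'   \code{perm} (vector of permuted posteriors), \code{n_perm}.
#' @export
pcit_permutation_test <- function(xs, ys, n_perm = 1000L, n_samples = 10000L,
                                  seed = 1L, noise_scale = NULL,
                                  balanced = TRUE) {
  if (!is.numeric(n_perm) || n_perm < 1L) stop("n_perm must be >= 1")
  xs <- as.numeric(xs); ys <- as.numeric(ys)
  if (length(xs) < 3L) stop("at least 3 data points are required")
  if (any(xs < 0 | xs > 1)) stop("xs must be normalized to [0, 1]")
  if (is.null(noise_scale)) noise_scale <- stats::sd(ys)
  if (!is.finite(noise_scale) || noise_scale <= 0)
    stop("noise_scale must be positive")
  set.seed(seed)
  cs <- if (balanced) .sample_balanced(n_samples) else {
    raw <- .sample_raw(n_samples); raw$consistent <- .classify_mat(raw$xk, raw$yk); raw
  }
  pred <- .curve_values_mat(cs$xk, cs$yk, xs)
  ptc_of <- function(y) {
    lw <- .log_weights(pred, y, noise_scale)
    w <- exp(lw - max(lw))
    sum(w[cs$consistent]) / sum(w)
  }
  observed <- ptc_of(ys)
  perm <- vapply(seq_len(n_perm), function(i) ptc_of(sample(ys)), numeric(1))
  list(p_value = (1 + sum(perm >= observed)) / (n_perm + 1),
       observed = observed, perm = perm, n_perm = n_perm)
}

#' Min-max normalize reactivation values to [0, 1]
#'
#' @param x numeric vector with at least two distinct finite values.
#' @return rescaled vector with minimum 0 and maximum 1. Invariant under
#'   affine transforms of the input with positive slope.
#' @export
normalize_x <- function(x) {
  if (any(!is.finite(x))) stop("non-finite values in x")
  r <- range(x)
  if (r[1] == r[2]) stop("cannot normalize a constant vector")
  (x - r[1]) / (r[2] - r[1])
}

#' Exhaustive lattice oracle for the theory-consistency posterior
#'
#' Enumerates a dense lattice of piecewise-linear curves (interior knots and
#' y-values on regular grids), computes each curve's Gaussian importance
#' weight, and combines the two consistency classes under the balanced 0.5/0.5
#' prior. This is an independent, sampling-free route to
#' \code{p_theory_consistent}, intended for validating the importance sampler
#' on small instances.
#'
#' @inheritParams pcit_fit
#' @param knot_grid interior-knot lattice (default 10 points on (0, 1)).
#' @param y_grid y-value lattice (default 9 points on [-1, 1]).
#' @return list with \code{p_theory_consistent} and \code{n_curves}.
#' @export
pcit_enumerate <- function(xs, ys, noise_scale = stats::sd(ys),
                           knot_grid = seq(0.025, 0.975, by = 0.05),
                           y_grid = seq(-1, 1, by = 0.1)) {
  if (!is.finite(noise_scale) || noise_scale <= 0)
    stop("noise_scale must be positive")
  kp <- t(utils::combn(knot_grid, 2L))
  yg <- as.matrix(expand.grid(y_grid, y_grid, y_grid, y_grid))
  colnames(yg) <- NULL
  g <- pcit_grid()
  n_y <- nrow(yg)
  sw_cons <- 0; sw_inc <- 0; n_cons <- 0; n_inc <- 0
  for (i in seq_len(nrow(kp))) {
    xk <- c(0, kp[i, 1], kp[i, 2], 1)
    v <- yg %*% .hat_basis(xk, g)        # curve values on the grid
    im <- max.col(-v, ties.method = "first")
    vmin <- v[cbind(seq_len(n_y), im)]
    cl <- im > 1L & im < ncol(v) & vmin < v[, 1] & vmin < v[, ncol(v)] &
      vmin < 0 & v[, ncol(v)] > 0
    pred <- yg %*% .hat_basis(xk, xs)
    w <- exp(-rowSums(sweep(pred, 2L, ys)^2) / (2 * noise_scale^2))
    sw_cons <- sw_cons + sum(w[cl]); n_cons <- n_cons + sum(cl)
    sw_inc <- sw_inc + sum(w[!cl]); n_inc <- n_inc + sum(!cl)
  }
  m_cons <- sw_cons / n_cons; m_inc <- sw_inc / n_inc
  list(p_theory_consistent = 0.5 * m_cons / (0.5 * m_cons + 0.5 * m_inc),
       n_curves = nrow(kp) * n_y,
       prior_consistent = n_cons / (n_cons + n_inc))
}

# Hat-function basis of a fixed knot vector evaluated at points g: 4 x m
# matrix B with curve values = y %*% B.
.hat_basis <- function(xk, g) {
  seg <- pmin(pmax(findInterval(g, xk, rightmost.closed = TRUE), 1L), 3L)
  t <- (g - xk[seg]) / (xk[seg + 1L] - xk[seg])
  B <- matrix(0, 4L, length(g))
  B[cbind(seg, seq_along(g))] <- 1 - t
  B[cbind(seg + 1L, seq_along(g))] <- t
  B
}
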