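#' Fit a 1-D Gaussian mixture to pixel intensities with BIC model selection
#'
#' Fits unequal-variance univariate Gaussian mixtures (EM, via mclust's "V"
#' model) for each candidate component count and selects the count by BIC.
#' The fitted model determines the particle/background threshold through its
#' crossing points (see [compute_threshold()]). For large images the fit runs
#' on a seeded subsample of at most `max_pixels` pixels; assignment and
#' thresholding then apply to all pixels.
#'
#' @param intensities numeric vector of pixel intensities (>= 100 values).
#' @param k_candidates candidate component counts, a subset of 1:6.
#' @param seed seed for the subsample draw.
#' @param max_pixels fit-time subsample cap.
#' @param regularize use a weak conjugate prior on the component parameters
#'   (mclust's `priorControl()`); stabilizes fits on noiseless/degenerate
#'   data where a component would collapse to zero variance.
#' @param channel optional channel name carried into the model.
#' @return object of class `threshold_model`: component count `K`, `weights`,
#'   `means`, `vars` (sorted by mean), `bic` per candidate K (standard
#'   convention, k*ln(n) - 2*ln(L), smaller is better), `crossings`, and
#'   `threshold` (the highest crossing point; `Inf` when K = 1).
#' @export
fit_pixel_gmm <- function(intensities, k_candidates = 1:6, seed = 0,
                          max_pixels = 2e5, regularize = FALSE,
                          channel = NA_character_) {
  x <- as.numeric(intensities)
  if (length(x) < 100) stop("need at least 100 pixels to fit a mixture")
  if (!all(k_candidates %in% 1:6)) stop("k_candidates must be within 1..6")
  if (diff(range(x)) == 0) stop("constant intensities: no mixture to fit")
  if (length(x) > max_pixels) {
    set.seed(seed)
    x <- x[sample.int(length(x), max_pixels)]
  }
  prior <- if (regularize) mclust::priorControl() else NULL
  fit <- mclust::Mclust(x, G = k_candidates, modelNames = "V",
                        prior = prior, verbose = FALSE)
  if (is.null(fit))
    stop("EM failed to fit any candidate mixture (all models degenerate)")
  K <- as.integer(fit$G)
  par <- fit$parameters
  sig2 <- par$variance$sigmasq
  if (length(sig2) == 1) sig2 <- rep(sig2, K)
  ord <- order(par$mean)
  model <- structure(list(
    channel = channel,
    K = K,
    weights = par$pro[ord],
    means = par$mean[ord],
    vars = sig2[ord],
    # mclust maximizes BIC = 2 ln L - k ln n; report the standard
    # minimized form
    bic = -fit$BIC[, "V"],
    n_fit = length(x)
  ), class = "threshold_model")
  model$crossings <- crossing_points(model$weights, model$means, model$vars)
  model$threshold <- compute_threshold(model)
  model
}

#' Crossing points of a 1-D Gaussian mixture
#'
#' Intensities at which the maximum-responsibility component (argmax over k
#' of weight_k * N(x; mean_k, var_k)) switches as x increases. Candidate
#' points are the analytic roots of the pairwise weighted log-density
#' equalities (quadratics in x); actual switches are confirmed by evaluating
#' the argmax on the intervals they delimit. Ties break toward the higher
#' intensity.
#'
#' @param weights,means,vars mixture parameters (equal length K).
#' @return sorted numeric vector of crossing points (possibly empty).
#' @export
crossing_points <- function(weights, means, vars) {
  K <- length(means)
  stopifnot(length(weights) == K, length(vars) == K, all(vars > 0))
  if (K < 2) return(numeric(0))
  roots <- numeric(0)
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    # log(w_i phi_i) = log(w_j phi_j)  <=>  a x^2 + b x + c = 0
    a <- 1 / (2 * vars[j]) - 1 / (2 * vars[i])
    b <- means[i] / vars[i] - means[j] / vars[j]
    c <- means[j]^2 / (2 * vars[j]) - means[i]^2 / (2 * vars[i]) +
      log(weights[i] / weights[j]) + 0.5 * log(vars[j] / vars[i])
    if (abs(a) < 1e-300) {
      if (abs(b) > 0) roots <- c(roots, -c / b)
    } else {
      disc <- b^2 - 4 * a * c
      if (disc >= 0)
        roots <- c(roots, (-b + c(-1, 1) * sqrt(disc)) / (2 * a))
    }
  }
  roots <- sort(unique(roots[is.finite(roots)]))
  if (!length(roots)) return(numeric(0))
  argmax_at <- function(x) {
    vals <- vapply(seq_len(K), function(k)
      log(weights[k]) + stats::dnorm(x, means[k], sqrt(vars[k]), log = TRUE),
      numeric(length(x)))
    if (length(x) == 1) vals <- matrix(vals, nrow = 1)
    max.col(vals, ties.method = "last")
  }
  # evaluate the winning component on each interval delimited by the roots
  lo <- min(means) - 20 * sqrt(max(vars))
  hi <- max(means) + 20 * sqrt(max(vars))
  pts <- c(lo, roots, hi)
  mids <- (pts[-1] + pts[-length(pts)]) / 2
  win <- argmax_at(mids)
  roots[win[-1] != win[-length(win)]]
}

#' Particle/background threshold of a fitted mixture
#'
#' The threshold is the highest crossing point of the mixture: the largest
#' intensity at which the maximum-responsibility component switches. A
#' single-component model carries no foreground/background structure; it
#' yields `Inf` (the channel then contributes nothing to the particle mask)
#' with a warning.
#'
#' @param model a `threshold_model` from [fit_pixel_gmm()].
#' @return threshold intensity (scalar; `Inf` for K = 1).
#' @export
compute_threshold <- function(model) {
  stopifnot(inherits(model, "threshold_model"))
  if (model$K < 2 || !length(model$crossings)) {
    warning("mixture has no crossing point (K = ", model$K,
            "); channel contributes no foreground")
    return(Inf)
  }
  max(model$crossings)
}

#' @export
print.threshold_model <- function(x, ...) {
  cat("<threshold_model>", if (!is.na(x$channel)) x$channel else "",
      " K=", x$K, " threshold=", format(x$threshold), "\n", sep = "")
  invisible(x)
}
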