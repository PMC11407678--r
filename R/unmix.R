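#' Reference emission spectra
#'
#' One row per fluorophore: its emission spectrum over the lambda-scan
#' windows, normalized to unit sum. Shares window metadata with
#' [spectral_stack()].
#'
#' @param matrix numeric matrix (n_fluorophores x n_windows), rows
#'   non-negative and summing to 1 (within 1e-9).
#' @param fluorophores character vector of fluorophore names (row names).
#' @param windows window metadata (one row per column).
#' @return object of class `emission_reference`.
#' @export
emission_reference <- function(matrix, fluorophores,
                               windows = default_spectral_windows()) {
  validate_windows(windows)
  if (!is.matrix(matrix) || nrow(matrix) != length(fluorophores))
    stop("reference matrix must have one row per fluorophore")
  if (ncol(matrix) != nrow(windows))
    stop("reference matrix has ", ncol(matrix), " columns but ",
         nrow(windows), " windows")
  if (any(matrix < 0)) stop("reference spectra must be non-negative")
  if (any(abs(rowSums(matrix) - 1) > 1e-9))
    stop("reference spectra must be normalized to unit sum")
  dimnames(matrix) <- list(fluorophores, NULL)
  structure(list(matrix = matrix, fluorophores = fluorophores,
                 windows = windows),
            class = "emission_reference")
}

#' Unmixed channel images
#'
#' Per-fluorophore abundance images produced by [unmix()], with the
#' per-pixel residual norm of the least-squares fit.
#'
#' @param planes numeric array (H x W x n_fluorophores).
#' @param fluorophores channel names.
#' @param residual H x W matrix of per-pixel residual norms (or NULL).
#' @return object of class `channel_image`.
#' @export
channel_image <- function(planes, fluorophores, residual = NULL) {
  if (!is.array(planes) || length(dim(planes)) != 3)
    stop("planes must be a 3-D array (H x W x n_fluorophores)")
  if (dim(planes)[3] != length(fluorophores))
    stop("one plane per fluorophore required")
  if (any(!is.finite(planes))) stop("channel values must be finite")
  dimnames(planes) <- list(NULL, NULL, fluorophores)
  structure(list(planes = planes, fluorophores = fluorophores,
                 residual = residual),
            class = "channel_image")
}

#' Estimate reference emission spectra from single-fluorophore stacks
#'
#' For each single-color stack, the brightest pixels (top `top_frac` by
#' total counts over windows) define the signal spectrum and the dimmest
#' half defines the background spectrum (per-window median). The reference
#' row is the background-subtracted mean signal spectrum, clamped at zero
#' and normalized to unit sum.
#'
#' @param stacks named list of [spectral_stack()]s, one per fluorophore;
#'   all must share the same window layout.
#' @param top_frac fraction of brightest pixels averaged for the signal
#'   spectrum (default 1%).
#' @param bg_frac fraction of dimmest pixels defining the background
#'   (default 50%).
#' @return an [emission_reference()].
#' @export
estimate_reference_spectra <- function(stacks, top_frac = 0.01,
                                       bg_frac = 0.5) {
  if (is.null(names(stacks)) || any(!nzchar(names(stacks))))
    stop("stacks must be a named list (names = fluorophores)")
  w0 <- stacks[[1]]$windows
  rows <- t(vapply(names(stacks), function(f) {
    st <- stacks[[f]]
    stopifnot(inherits(st, "spectral_stack"))
    if (!isTRUE(all.equal(st$windows, w0, check.attributes = FALSE)))
      stop("window layouts differ between single-color stacks")
    d <- dim(st$planes)
    px <- matrix(st$planes, d[1] * d[2], d[3])
    tot <- rowSums(px)
    if (all(tot == 0)) stop("all-zero stack for fluorophore ", f)
    ord <- order(tot, decreasing = TRUE)
    n_top <- max(1L, ceiling(top_frac * length(tot)))
    n_bg <- max(1L, floor(bg_frac * length(tot)))
    sig <- colMeans(px[ord[seq_len(n_top)], , drop = FALSE])
    bg <- apply(px[rev(ord)[seq_len(n_bg)], , drop = FALSE], 2,
                stats::median)
    s <- pmax(sig - bg, 0)
    if (sum(s) == 0) stop("no signal above background for fluorophore ", f)
    s / sum(s)
  }, numeric(nrow(w0))))
  emission_reference(rows, names(stacks), w0)
}

#' Linear unmixing of a lambda stack into fluorophore channels
#'
#' Per pixel, finds the abundance vector minimizing the squared residual
#' between the measured spectrum and the reference-weighted sum, either
#' unconstrained (ordinary least squares through a QR decomposition shared
#' across pixels) or subject to non-negative abundances (per-pixel NNLS).
#' The per-pixel residual norm is returned alongside the channels.
#'
#' @param stack a [spectral_stack()].
#' @param ref an [emission_reference()] with the same window layout.
#' @param nonneg constrain abundances to be >= 0 (slower; per-pixel
#'   active-set NNLS).
#' @return a [channel_image()].
#' @export
unmix <- function(stack, ref, nonneg = FALSE) {
  stopifnot(inherits(stack, "spectral_stack"),
            inherits(ref, "emission_reference"))
  if (!isTRUE(all.equal(stack$windows, ref$windows,
                        check.attributes = FALSE)))
    stop("stack and reference window layouts differ")
  S <- ref$matrix
  if (nrow(S) > ncol(S))
    stop("need at least as many windows as fluorophores")
  qrS <- qr(t(S))
  if (qrS$rank < nrow(S)) {
    dep <- ref$fluorophores[qrS$pivot[(qrS$rank + 1):nrow(S)]]
    stop("reference spectra are rank deficient; collinear fluorophore(s): ",
         paste(dep, collapse = ", "))
  }
  d <- dim(stack$planes)
  Y <- matrix(stack$planes, d[1] * d[2], d[3])
  if (nonneg) {
    A <- t(apply(Y, 1, function(y) pracma::lsqnonneg(t(S), y)$x))
    if (nrow(S) == 1) A <- t(A)
  } else {
    A <- t(qr.coef(qrS, t(Y)))
  }
  res <- sqrt(rowSums((Y - A %*% S)^2))
  channel_image(array(A, c(d[1], d[2], nrow(S))), ref$fluorophores,
                residual = matrix(res, d[1], d[2]))
}
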