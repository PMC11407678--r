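#' Label connected components of a binary image
#'
#' Two-dimensional connected-component labeling by iterative minimum-label
#' propagation (vectorized over the whole image; converges in a number of
#' sweeps bounded by the largest component's diameter). Components are
#' relabeled 1..P in raster order of their first pixel.
#'
#' @param mask logical (or 0/1) matrix.
#' @param connectivity 8 (default, diagonal neighbors connect) or 4.
#' @return integer matrix of labels, 0 = background.
#' @export
label_components <- function(mask, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  m <- mask != 0
  H <- nrow(m); W <- ncol(m)
  lab <- matrix(0L, H, W)
  lab[m] <- seq_len(sum(m))
  idx <- matrix(seq_len(H * W), H, W)
  lab[m] <- idx[m]                      # initial label = linear index
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (connectivity == 8)
    shifts <- c(shifts, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  shift_mat <- function(x, di, dj, fill) {
    out <- matrix(fill, H, W)
    si <- max(1, 1 + di):min(H, H + di)
    sj <- max(1, 1 + dj):min(W, W + dj)
    out[si, sj] <- x[si - di, sj - dj]
    out
  }
  repeat {
    new <- lab
    for (s in shifts) {
      nb <- shift_mat(lab, s[1], s[2], 0L)
      take <- m & nb > 0L & nb < new
      new[take] <- nb[take]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  u <- unique(lab[lab > 0L])
  lab[lab > 0L] <- match(lab[lab > 0L], sort(u))
  # renumber in raster order of first occurrence
  first <- vapply(seq_along(u), function(k) min(which(lab == k)), integer(1))
  remap <- integer(length(u)); remap[order(first)] <- seq_along(u)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  lab
}

#' Build the particle mask from thresholded channels
#'
#' Binarizes every non-excluded channel at its threshold (pixel >= threshold
#' is foreground), merges the binaries by union, and labels connected
#' components. Excluded channels (e.g. a marker whose diffuse signal would
#' bloat the mask) contribute nothing to the mask support but remain
#' available as intensity columns downstream.
#'
#' @param channels a [channel_image()].
#' @param thresholds named numeric vector, one threshold per non-excluded
#'   channel (extra names are ignored for excluded channels).
#' @param exclude character vector of channels excluded from mask creation.
#' @param connectivity component connectivity, 8 (default) or 4.
#' @param min_area drop components smaller than this many pixels (default 1,
#'   i.e. keep everything; sub-resolution single-pixel specks from noise can
#'   be rejected with `min_area = 2`). Remaining labels stay contiguous.
#' @return object of class `particle_mask`: integer `labels` image,
#'   `binaries` (H x W x channels array of the per-channel masks),
#'   `exclude`, and `n_particles`.
#' @export
binarize_and_merge <- function(channels, thresholds, exclude = character(),
                               connectivity = 8, min_area = 1) {
  stopifnot(inherits(channels, "channel_image"))
  unknown <- setdiff(exclude, channels$fluorophores)
  if (length(unknown))
    stop("unknown channel(s) in exclusion set: ",
         paste(unknown, collapse = ", "))
  use <- setdiff(channels$fluorophores, exclude)
  missing <- setdiff(use, names(thresholds))
  if (length(missing))
    stop("no threshold supplied for channel(s): ",
         paste(missing, collapse = ", "))
  d <- dim(channels$planes)
  binaries <- array(FALSE, d, dimnames = dimnames(channels$planes))
  for (f in use)
    binaries[, , f] <- channels$planes[, , f] >= thresholds[[f]]
  support <- apply(binaries[, , use, drop = FALSE], c(1, 2), any)
  labels <- label_components(support, connectivity)
  if (min_area > 1 && max(labels) > 0) {
    sizes <- tabulate(labels[labels > 0L], nbins = max(labels))
    keep <- which(sizes >= min_area)
    labels[] <- ifelse(labels > 0L & labels %in% keep,
                       match(labels, keep), 0L)
  }
  structure(list(labels = labels, binaries = binaries, exclude = exclude,
                 n_particles = max(labels)),
            class = "particle_mask")
}

#' Measure particles: per-channel summed intensities and areas
#'
#' For every labeled particle, sums the pre-binary (continuous) pixel
#' intensities of every channel — including channels excluded from mask
#' creation — over the particle's pixels, and records the pixel-count area.
#'
#' @param mask a [binarize_and_merge()] result.
#' @param channels the [channel_image()] the mask was built from (same
#'   geometry).
#' @param replicate,condition,timepoint tags stamped onto every row.
#' @return a [particle_table()], one row per particle.
#' @export
extract_particles <- function(mask, channels, replicate = 1L,
                              condition = "none", timepoint = NA_real_) {
  stopifnot(inherits(mask, "particle_mask"),
            inherits(channels, "channel_image"))
  d <- dim(channels$planes)
  if (!identical(dim(mask$labels), d[1:2]))
    stop("mask and channel geometries differ")
  P <- mask$n_particles
  fl <- channels$fluorophores
  inside <- mask$labels > 0L
  lab <- mask$labels[inside]
  if (P == 0) {
    df <- as.data.frame(stats::setNames(
      rep(list(numeric(0)), length(fl)), fl))
    df <- cbind(data.frame(replicate = integer(), condition = character(),
                           timepoint = numeric()), df,
                data.frame(area = integer()))
    return(particle_table(df, markers = fl))
  }
  sums <- vapply(fl, function(f) {
    v <- channels$planes[, , f][inside]
    as.numeric(rowsum(v, lab)[as.character(seq_len(P)), 1])
  }, numeric(P))
  # unconstrained unmixing can dip below zero on noise; intensities are
  # physically non-negative
  sums <- pmax(sums, 0)
  if (P == 1) sums <- matrix(sums, 1, dimnames = list(NULL, fl))
  area <- as.integer(table(factor(lab, levels = seq_len(P))))
  df <- data.frame(replicate = rep(as.integer(replicate), P),
                   condition = rep(condition, P),
                   timepoint = rep(timepoint, P))
  df <- cbind(df, as.data.frame(sums))
  df$area <- area
  particle_table(df, markers = fl)
}
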