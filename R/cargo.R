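#' Cargo positivity thresholds from control (unloaded) particles
#'
#' The threshold for calling a particle positive for a fluorescent cargo is
#' the 99th percentile (linear interpolation between order statistics,
#' quantile type 7) of the cargo-channel intensity on control particles from
#' cells never exposed to the cargo.
#'
#' @param control numeric vector of control intensities, or a named list of
#'   such vectors (one per cargo channel).
#' @param percentile percentile in (0, 100); default 99.
#' @return object of class `cargo_thresholds`: named numeric thresholds with
#'   `percentile` and `n_control` attributes.
#' @export
background_threshold <- function(control, percentile = 99) {
  if (percentile <= 0 || percentile >= 100)
    stop("percentile must lie in (0, 100)")
  if (!is.list(control)) control <- list(cargo = control)
  n <- vapply(control, length, integer(1))
  if (any(n == 0)) stop("empty control sample")
  if (any(n < 100))
    stop("need at least 100 control particles per channel (got ",
         min(n), ")")
  thr <- vapply(control, function(v)
    unname(stats::quantile(v, percentile / 100, type = 7)), numeric(1))
  structure(thr, percentile = percentile, n_control = n,
            class = "cargo_thresholds")
}

#' Filter particles to the cargo-positive endosome population
#'
#' Keeps particles that (a) have strictly positive intensity for every
#' required endosomal marker (points with a zero value in any of them are
#' removed) and (b) are positive for at least one cargo channel, i.e. at or
#' above that cargo's background-derived threshold. Positivity is evaluated
#' on the mean pixel intensity (sum / area) by default, or on the raw sums
#' (`mode = "sum"`); the control sample used for the thresholds must be on
#' the same scale. Per-cargo positivity flags are recorded as
#' `<cargo>_positive` columns. The filter is idempotent.
#'
#' @param table a [particle_table()].
#' @param thresholds a [background_threshold()] result, named by cargo
#'   channel.
#' @param required_nonzero markers that must be > 0 (default RAB5, RAB7,
#'   RAB11).
#' @param mode intensity convention for positivity: "mean" (default) or
#'   "sum".
#' @return the filtered [particle_table()] with positivity flag columns; the
#'   mode used is recorded in the `positivity_mode` attribute.
#' @export
filter_cargo_particles <- function(table, thresholds,
                                   required_nonzero = c("RAB5", "RAB7",
                                                        "RAB11"),
                                   mode = c("mean", "sum")) {
  stopifnot(inherits(table, "particle_table"))
  mode <- match.arg(mode)
  cargo <- names(thresholds)
  missing <- setdiff(c(cargo, required_nonzero), names(table))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  df <- as.data.frame(table)
  keep_req <- rep(TRUE, nrow(df))
  for (m in required_nonzero) keep_req <- keep_req & df[[m]] > 0
  pos <- vapply(cargo, function(ch) {
    v <- if (mode == "mean") df[[ch]] / df$area else df[[ch]]
    v >= thresholds[[ch]]
  }, logical(nrow(df)))
  if (nrow(df) == 1) pos <- matrix(pos, 1, dimnames = list(NULL, cargo))
  keep <- keep_req & rowSums(pos) > 0
  out <- df[keep, , drop = FALSE]
  for (ch in cargo) out[[paste0(ch, "_positive")]] <- pos[keep, ch]
  rownames(out) <- NULL
  res <- particle_table(out, markers = markers(table))
  attr(res, "positivity_mode") <- mode
  res
}

#' Per-cluster cargo proportions over the time course
#'
#' For each combination of condition, timepoint and cargo channel, counts
#' the cargo-positive particles in every cluster and normalizes to
#' proportions (summing to 1 within each group that has at least one
#' positive particle; groups with none get count 0 and proportion NA).
#'
#' @param table a [filter_cargo_particles()] result (must carry
#'   `<cargo>_positive` flags, `condition`, `timepoint`).
#' @param labels per-particle cluster labels (default: the table's
#'   `cluster` column).
#' @param cargo cargo channel names (default: inferred from the
#'   `*_positive` flag columns).
#' @return object of class `cargo_timecourse`: a data.frame with columns
#'   condition, timepoint, cargo, cluster, count, proportion.
#' @export
cluster_proportions <- function(table, labels = table$cluster,
                                cargo = NULL) {
  df <- as.data.frame(table)
  if (is.null(cargo))
    cargo <- sub("_positive$", "",
                 grep("_positive$", names(df), value = TRUE))
  if (!length(cargo)) stop("no cargo positivity flags found")
  if (is.null(labels) || anyNA(labels))
    stop("all particles must carry a cluster label")
  clusters <- sort(unique(labels))
  groups <- unique(df[, c("condition", "timepoint")])
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    in_grp <- df$condition == groups$condition[i] &
      df$timepoint == groups$timepoint[i]
    do.call(rbind, lapply(cargo, function(ch) {
      posrows <- in_grp & df[[paste0(ch, "_positive")]]
      cnt <- tabulate(match(labels[posrows], clusters),
                      nbins = length(clusters))
      data.frame(condition = groups$condition[i],
                 timepoint = groups$timepoint[i],
                 cargo = ch, cluster = clusters, count = cnt,
                 proportion = if (sum(cnt) > 0) cnt / sum(cnt)
                              else rep(NA_real_, length(cnt)))
    }))
  }))
  rownames(out) <- NULL
  class(out) <- c("cargo_timecourse", "data.frame")
  out
}

#' Square-root percent-of-max display scaling
#'
#' Maps non-negative intensities to `sqrt(100 * v / max(v))`, the scale used
#' to display cargo and marker intensities on the landscape: the maximum
#' maps to 10 (sqrt of 100%), zeros stay 0, and the square root compresses
#' the heavy right tail. An all-zero vector is returned as zeros.
#'
#' @param values non-negative numeric vector.
#' @return scaled vector in \[0, 10\].
#' @export
sqrt_percent_max <- function(values) {
  if (any(values < 0, na.rm = TRUE)) stop("values must be non-negative")
  mx <- max(values, na.rm = TRUE)
  if (!is.finite(mx) || mx == 0) return(values * 0)
  sqrt(100 * values / mx)
}
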