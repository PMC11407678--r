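#' Spectral stack container
#'
#' A lambda-scan image stack: one plane per emission window plus the window
#' metadata. Counts are detector counts in the 16-bit range.
#'
#' @param planes numeric array (height x width x n_windows), values in
#'   \[0, 65535\].
#' @param windows window metadata data.frame (see
#'   [default_spectral_windows()]), one row per plane.
#' @return object of class `spectral_stack`.
#' @export
spectral_stack <- function(planes, windows = default_spectral_windows()) {
  if (!is.array(planes) || length(dim(planes)) != 3)
    stop("planes must be a 3-D array (H x W x n_windows)")
  validate_windows(windows)
  if (dim(planes)[3] != nrow(windows))
    stop("stack has ", dim(planes)[3], " planes but ", nrow(windows),
         " window metadata entries")
  if (any(planes < 0) || any(planes > 65535))
    stop("counts must lie within the 16-bit range [0, 65535]")
  structure(list(planes = planes, windows = windows),
            class = "spectral_stack")
}

#' @export
print.spectral_stack <- function(x, ...) {
  d <- dim(x$planes)
  cat("<spectral_stack> ", d[1], "x", d[2], " px, ", d[3], " windows (",
      length(unique(x$windows$spectrometer)), " spectrometer blocks)\n",
      sep = "")
  invisible(x)
}

#' Read / write a spectral stack
#'
#' Stacks are stored as multi-page 16-bit grayscale TIFF with the window
#' metadata in a JSON sidecar (`<stem>.json`) next to the TIFF, since plain
#' TIFF has no standard lambda fields. `write_stack()` rounds counts to
#' integers (they are detector counts) and refuses values outside the 16-bit
#' range; `read_stack()` refuses a stack whose plane count disagrees with its
#' sidecar.
#'
#' @param stack a [spectral_stack()].
#' @param path TIFF file path.
#' @return `read_stack()` returns a [spectral_stack()]; `write_stack()`
#'   returns `path` invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "spectral_stack"))
  pl <- stack$planes
  if (any(pl < 0) || any(pl > 65535))
    stop("counts outside the 16-bit range cannot be written")
  pl <- round(pl)
  pages <- lapply(seq_len(dim(pl)[3]), function(i) pl[, , i] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  jsonlite::write_json(stack$windows, sidecar_path(path),
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop("missing window-metadata sidecar: ", sp)
  windows <- as.data.frame(jsonlite::read_json(sp, simplifyVector = TRUE))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != nrow(windows))
    stop("stack has ", length(pages), " planes but sidecar lists ",
         nrow(windows), " windows")
  planes <- array(0, c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) planes[, , i] <- round(pages[[i]] * 65535)
  spectral_stack(planes, windows)
}

sidecar_path <- function(path) {
  paste0(sub("\\.[Tt][Ii][Ff][Ff]?$", "", path), ".json")
}

# column names that are never treated as marker intensities
.reserved_columns <- c("replicate", "condition", "timepoint", "area",
                       "PCA1", "PCA2", "UMAP1", "UMAP2", "cluster",
                       "id", "true_class", "true_state", "true_cargo",
                       "EGF_positive", "TF_positive")

#' Particle feature table
#'
#' One row per particle: replicate id, optional condition and timepoint
#' tags, per-marker summed intensities (non-negative), the particle area in
#' pixels, and optionally PCA/UMAP coordinates and a cluster label. Extra
#' columns are preserved untouched.
#'
#' @param df data.frame with at least the marker columns and `area`.
#' @param markers character vector naming the marker intensity columns; if
#'   `NULL`, all numeric columns outside the reserved schema
#'   (replicate/condition/timepoint/area/PCA1/PCA2/UMAP1/UMAP2/cluster/...)
#'   are taken as markers.
#' @return the data.frame with class `particle_table` and a `markers`
#'   attribute.
#' @export
particle_table <- function(df, markers = NULL) {
  stopifnot(is.data.frame(df))
  if (is.null(markers)) {
    num <- vapply(df, is.numeric, logical(1))
    markers <- setdiff(names(df)[num], .reserved_columns)
  }
  missing <- setdiff(markers, names(df))
  if (length(missing))
    stop("missing marker columns: ", paste(missing, collapse = ", "))
  if (!"area" %in% names(df)) stop("missing required column: area")
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  for (m in markers)
    if (any(df[[m]] < 0, na.rm = TRUE))
      stop("marker intensities must be non-negative (column ", m, ")")
  if (nrow(df) && any(df$area < 1)) stop("area must be a positive pixel count")
  structure(df, markers = markers,
            class = c("particle_table", "data.frame"))
}

#' Marker columns of a particle table
#' @param table a [particle_table()].
#' @return character vector of marker column names.
#' @export
markers <- function(table) attr(table, "markers")

#' Marker intensity matrix of a particle table
#' @param table a [particle_table()].
#' @return numeric matrix (particles x markers).
#' @export
marker_matrix <- function(table) {
  as.matrix(as.data.frame(table)[, markers(table), drop = FALSE])
}

#' Read / write particle feature tables
#'
#' Comma-separated UTF-8 text with a header row, "." decimal. Numbers are
#' written with full double precision (`%.17g`) so write -> read is an exact
#' round trip, and identical tables produce byte-identical files. Unknown
#' extra columns round-trip unchanged. A truncated final record is rejected
#' rather than silently dropped.
#'
#' @param table a [particle_table()].
#' @param path CSV file path.
#' @param markers optional explicit marker column names for
#'   `read_particles()` (else inferred as in [particle_table()]).
#' @return `read_particles()` returns a [particle_table()];
#'   `write_particles()` returns `path` invisibly.
#' @export
write_particles <- function(table, path) {
  stopifnot(inherits(table, "particle_table"))
  df <- as.data.frame(table)
  for (j in seq_along(df))
    if (is.double(df[[j]]))
      df[[j]] <- ifelse(is.na(df[[j]]), NA, sprintf("%.17g", df[[j]]))
  utils::write.table(df, path, sep = ",", quote = TRUE, row.names = FALSE,
                     fileEncoding = "UTF-8", qmethod = "double", na = "NA")
  invisible(path)
}

#' @rdname write_particles
#' @export
read_particles <- function(path, markers = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (!length(raw)) stop("empty file: ", path)
  # reject silently truncated files: every record must have the header's
  # field count
  nfield <- utils::count.fields(textConnection(raw), sep = ",", quote = "\"")
  if (any(nfield != nfield[1]))
    stop("malformed or truncated CSV: inconsistent field counts in ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  particle_table(df, markers = markers)
}
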