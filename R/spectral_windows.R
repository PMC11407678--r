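#' Default lambda-scan window layout
#'
#' Window metadata for the default acquisition geometry: 52 emission windows
#' of 10 nm bandwidth collected on 4 spectrometer blocks, each block excited
#' by its own laser line (the blocks are acquired sequentially in descending
#' excitation wavelength and appended into a single lambda series).
#'
#' Block definitions (number of steps, first and last window center):
#' spectrometer 1 — 13 steps, 411–481 nm, 405 nm excitation;
#' spectrometer 2 — 11 steps, 494–554 nm, 488 nm excitation;
#' spectrometer 3 — 12 steps, 569–634 nm, 561 nm excitation;
#' spectrometer 4 — 16 steps, 646–731 nm, 640 nm excitation.
#' Within each block the centers are evenly spaced between the first and last
#' window (the nominal 5-nm step does not reproduce the printed block
#' endpoints exactly, so the endpoints and step counts are taken as
#' authoritative).
#'
#' @return A data.frame with one row per window and columns
#'   `center_nm`, `bandwidth_nm`, `spectrometer`, `excitation_nm`.
#' @examples
#' w <- default_spectral_windows()
#' nrow(w)           # 52
#' table(w$spectrometer)
#' @export
default_spectral_windows <- function() {
  blocks <- data.frame(
    spectrometer  = 1:4,
    n_steps       = c(13L, 11L, 12L, 16L),
    first_nm      = c(411, 494, 569, 646),
    last_nm       = c(481, 554, 634, 731),
    excitation_nm = c(405, 488, 561, 640)
  )
  out <- do.call(rbind, lapply(seq_len(nrow(blocks)), function(i) {
    b <- blocks[i, ]
    data.frame(
      center_nm     = seq(b$first_nm, b$last_nm, length.out = b$n_steps),
      bandwidth_nm  = 10,
      spectrometer  = b$spectrometer,
      excitation_nm = b$excitation_nm
    )
  }))
  rownames(out) <- NULL
  out
}

#' Validate a window metadata table
#'
#' @param windows data.frame as returned by [default_spectral_windows()].
#' @return The validated data.frame, invisibly usable.
#' @keywords internal
validate_windows <- function(windows) {
  req <- c("center_nm", "bandwidth_nm", "spectrometer", "excitation_nm")
  if (!is.data.frame(windows) || !all(req %in% names(windows)))
    stop("window metadata must be a data.frame with columns: ",
         paste(req, collapse = ", "))
  # centers must be sorted ascending within each spectrometer block
  for (s in unique(windows$spectrometer)) {
    cc <- windows$center_nm[windows$spectrometer == s]
    if (is.unsorted(cc, strictly = TRUE))
      stop("window centers must be strictly increasing within spectrometer ", s)
  }
  windows
}
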