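#' Marker abundance profiles for seven typical organelle classes
#'
#' Mean log-abundance (natural log of summed photon counts per particle) for
#' each organelle class over the 8-marker roster used throughout the package:
#' SEC61B (ER), GFP.OMP25 and SNAP.OMP25 (mitochondria), GS27 (Golgi),
#' EGF (early endosomes), NHS (plasma membrane), PMP70 (peroxisomes) and
#' LAMP1 (lysosomes). Each class is bright in its cognate marker(s) and dim
#' in the others; mitochondria carry both OMP25 fusions.
#'
#' @param hi,lo mean log-abundance of a class in its own / other markers.
#' @return matrix (7 classes x 8 markers) of mean log-abundances.
#' @export
organelle_class_profiles <- function(hi = log(5000), lo = log(30)) {
  markers <- c("SEC61B", "GFP.OMP25", "SNAP.OMP25", "GS27",
               "EGF", "NHS", "PMP70", "LAMP1")
  classes <- c("ER", "mitochondria", "Golgi", "early_endosome",
               "plasma_membrane", "peroxisome", "lysosome")
  p <- matrix(lo, nrow = length(classes), ncol = length(markers),
              dimnames = list(classes, markers))
  p["ER", "SEC61B"] <- hi
  p["mitochondria", c("GFP.OMP25", "SNAP.OMP25")] <- hi
  p["Golgi", "GS27"] <- hi
  p["early_endosome", "EGF"] <- hi
  p["plasma_membrane", "NHS"] <- hi
  p["peroxisome", "PMP70"] <- hi
  p["lysosome", "LAMP1"] <- hi
  p
}

#' Marker abundance profiles for seven programmed endosome maturation states
#'
#' Four endosomal markers (RAB5, RAB11, RAB7, LAMP1) across seven states
#' covering the endocytic itinerary: early endosomes (high RAB5), two
#' recycling-endosome states (high RAB11, one also RAB5-positive), endosomes
#' undergoing RAB conversion (RAB5 and RAB7 both high), and three
#' late-endosome/lysosome states with increasing LAMP1.
#'
#' @param hi,lo mean log-abundance of a state in its defining / other markers.
#' @return matrix (7 states x 4 markers) of mean log-abundances.
#' @export
endosome_class_profiles <- function(hi = log(3000), lo = log(30)) {
  markers <- c("RAB5", "RAB11", "RAB7", "LAMP1")
  states <- c("early", "recycling_a", "recycling_b", "late",
              "conversion", "late_lysosome", "lysosome")
  p <- matrix(lo, nrow = length(states), ncol = length(markers),
              dimnames = list(states, markers))
  p["early", "RAB5"] <- hi
  p["recycling_a", "RAB11"] <- hi
  p["recycling_b", c("RAB11", "RAB5")] <- hi
  p["late", "RAB7"] <- hi
  p["conversion", c("RAB5", "RAB7")] <- hi
  p["late_lysosome", c("RAB7", "LAMP1")] <- hi
  p["lysosome", "LAMP1"] <- hi
  p
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator: image geometry,
#' particle number, class profiles (mean log-abundance per marker plus a
#' shared log-normal spread), the fraction of dual-class "contact-site"
#' particles, particle radii, background and noise, and the seed that fixes
#' all randomness.
#'
#' @param n_particles number of particles to draw (>= 0).
#' @param class_profiles matrix of mean log-abundances (classes x markers),
#'   e.g. [organelle_class_profiles()].
#' @param weights mixture weights over classes; default uniform. Must sum to 1.
#' @param log_sd log-normal spread of per-particle marker abundances.
#' @param contact_fraction fraction of particles carrying two classes'
#'   markers (membrane contact sites).
#' @param contact_pair length-2 character vector of the two classes forming
#'   contact particles (major, minor).
#' @param contact_asymmetry multiplier on the minor class' profile in a
#'   contact particle (the attached fragment is much smaller than its partner).
#' @param image_size c(height, width) in pixels.
#' @param radius_range inclusive integer range of particle radii in pixels.
#' @param min_separation minimum gap (pixels) between disk boundaries.
#' @param background constant background level (counts per pixel per window).
#' @param poisson apply Poisson shot noise when rendering stacks.
#' @param read_sd Gaussian read-noise standard deviation (counts).
#' @param noise_sd multiplicative log-normal noise sd used by
#'   [make_feature_matrix()].
#' @param n_batches number of simulated independent experiments; replicate
#'   labels are assigned round-robin.
#' @param batch_gains per-batch multiplicative gain (length `n_batches`).
#' @param seed integer seed fixing all randomness.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_particles = 7000,
                       class_profiles = organelle_class_profiles(),
                       weights = NULL,
                       log_sd = 0.6,
                       contact_fraction = 0,
                       contact_pair = c("mitochondria", "ER"),
                       contact_asymmetry = 0.2,
                       image_size = c(128, 128),
                       radius_range = c(2, 5),
                       min_separation = 2,
                       background = 10,
                       poisson = TRUE,
                       read_sd = 2,
                       noise_sd = 0.15,
                       n_batches = 3,
                       batch_gains = NULL,
                       seed = 0) {
  if (n_particles < 0) stop("n_particles must be >= 0")
  if (any(radius_range < 1)) stop("particle radii must be >= 1 pixel")
  if (log_sd < 0 || noise_sd < 0) stop("noise standard deviations must be >= 0")
  if (is.null(weights))
    weights <- rep(1 / nrow(class_profiles), nrow(class_profiles))
  if (length(weights) != nrow(class_profiles))
    stop("weights must have one entry per class")
  if (abs(sum(weights) - 1) > 1e-8)
    stop("class mixture weights must sum to 1")
  if (contact_fraction < 0 || contact_fraction > 1)
    stop("contact_fraction must be in [0, 1]")
  if (contact_fraction > 0 &&
      !all(contact_pair %in% rownames(class_profiles)))
    stop("contact_pair classes not found in class_profiles")
  if (is.null(batch_gains)) batch_gains <- rep(1, n_batches)
  if (length(batch_gains) != n_batches)
    stop("batch_gains must have length n_batches")
  structure(list(
    n_particles = as.integer(n_particles),
    class_profiles = class_profiles,
    weights = weights,
    log_sd = log_sd,
    contact_fraction = contact_fraction,
    contact_pair = contact_pair,
    contact_asymmetry = contact_asymmetry,
    image_size = as.integer(image_size),
    radius_range = as.integer(radius_range),
    min_separation = min_separation,
    background = background,
    poisson = poisson,
    read_sd = read_sd,
    noise_sd = noise_sd,
    n_batches = as.integer(n_batches),
    batch_gains = batch_gains,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# pixel support of a hard disk: integer pixels with centre within radius
disk_pixels <- function(x, y, r, H, W) {
  xs <- max(1L, floor(x - r)):min(H, ceiling(x + r))
  ys <- max(1L, floor(y - r)):min(W, ceiling(y + r))
  g <- expand.grid(i = xs, j = ys)
  g <- g[(g$i - x)^2 + (g$j - y)^2 <= r^2, , drop = FALSE]
  g
}

#' Sample ground-truth particles
#'
#' Draws particle class labels from the configured mixture, per-marker
#' abundances from the class' log-normal profile, and non-overlapping disk
#' geometry within the image. A `contact_fraction` of particles carry the
#' summed profiles of the configured class pair, the minor partner scaled by
#' `contact_asymmetry`; such particles are labeled with the major class in
#' `class` and the minor class in `class2`.
#'
#' @param config a [sim_config()].
#' @param nonoverlap enforce non-overlapping disk placement (required when
#'   the ground truth will be rendered to an image stack; can be disabled
#'   for feature-matrix-only simulations, whose particle counts can exceed
#'   what fits in one frame).
#' @return an object of class `ground_truth`: a list with `particles`
#'   (data.frame: id, class, class2, x, y, radius, area), `abundance`
#'   (n x markers matrix of true summed photon counts) and `markers`.
#' @export
sample_particles <- function(config, nonoverlap = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_particles
  markers <- colnames(config$class_profiles)
  classes <- rownames(config$class_profiles)
  H <- config$image_size[1]; W <- config$image_size[2]

  if (n == 0) {
    return(structure(list(
      particles = data.frame(id = integer(), class = character(),
                             class2 = character(), x = numeric(),
                             y = numeric(), radius = numeric(),
                             area = integer()),
      abundance = matrix(numeric(), 0, length(markers),
                         dimnames = list(NULL, markers)),
      markers = markers), class = "ground_truth"))
  }

  lab <- sample(classes, n, replace = TRUE, prob = config$weights)
  is_contact <- stats::runif(n) < config$contact_fraction
  lab[is_contact] <- config$contact_pair[1]
  lab2 <- rep(NA_character_, n)
  lab2[is_contact] <- config$contact_pair[2]

  mu <- config$class_profiles[lab, , drop = FALSE]
  ab <- exp(mu + matrix(stats::rnorm(n * length(markers), 0, config$log_sd),
                        n, length(markers)))
  if (any(is_contact)) {
    mu2 <- config$class_profiles[lab2[is_contact], , drop = FALSE]
    ab2 <- exp(mu2 + matrix(stats::rnorm(sum(is_contact) * length(markers),
                                         0, config$log_sd),
                            sum(is_contact), length(markers)))
    ab[is_contact, ] <- ab[is_contact, , drop = FALSE] +
      config$contact_asymmetry * ab2
  }
  dimnames(ab) <- list(NULL, markers)

  radius <- sample(seq(config$radius_range[1], config$radius_range[2]),
                   n, replace = TRUE)
  # rejection-sample non-overlapping centroids (disks separated by
  # min_separation); particles stay clear of the image border
  x <- numeric(n); y <- numeric(n)
  if (nonoverlap) {
    for (i in seq_len(n)) {
      for (attempt in 1:2000) {
        xi <- stats::runif(1, radius[i] + 1, H - radius[i])
        yi <- stats::runif(1, radius[i] + 1, W - radius[i])
        if (i == 1 || all(sqrt((x[seq_len(i - 1)] - xi)^2 +
                               (y[seq_len(i - 1)] - yi)^2) >
                          radius[seq_len(i - 1)] + radius[i] +
                          config$min_separation)) {
          x[i] <- xi; y[i] <- yi
          break
        }
        if (attempt == 2000)
          stop("could not place ", n, " non-overlapping particles in a ",
               H, "x", W, " image; enlarge the image or reduce n_particles")
      }
    }
  } else {
    x <- stats::runif(n, max(radius) + 1, H - max(radius))
    y <- stats::runif(n, max(radius) + 1, W - max(radius))
  }
  area <- vapply(seq_len(n), function(i)
    nrow(disk_pixels(x[i], y[i], radius[i], H, W)), integer(1))

  structure(list(
    particles = data.frame(id = seq_len(n), class = lab, class2 = lab2,
                           x = x, y = y, radius = radius, area = area),
    abundance = ab,
    markers = markers), class = "ground_truth")
}

#' Simulate fluorophore emission spectra on a window grid
#'
#' Produces smooth single-peak (log-normal-shaped) emission spectra for a set
#' of fluorophores, gated by the excitation structure of the window layout:
#' a fluorophore only emits in spectrometer blocks whose excitation
#' wavelength is at or below its emission peak. Peaks are spread across the
#' covered range so the resulting reference matrix is well conditioned, with
#' neighbouring spectra still overlapping as real dyes do.
#'
#' @param fluorophores character vector of fluorophore (marker) names.
#' @param windows window metadata, default [default_spectral_windows()].
#' @param peak_nm optional numeric vector of emission peaks (else evenly
#'   spread over the windows' range).
#' @param width_nm spectral width (sd of the Gaussian-shaped emission), in nm.
#' @return an [emission_reference()] object.
#' @export
simulate_emission_spectra <- function(fluorophores,
                                      windows = default_spectral_windows(),
                                      peak_nm = NULL,
                                      width_nm = 18) {
  validate_windows(windows)
  nf <- length(fluorophores)
  rng <- range(windows$center_nm)
  if (is.null(peak_nm))
    peak_nm <- seq(rng[1] + 10, rng[2] - 10, length.out = nf)
  if (length(peak_nm) != nf)
    stop("peak_nm must have one entry per fluorophore")
  S <- t(vapply(seq_len(nf), function(i) {
    s <- exp(-(windows$center_nm - peak_nm[i])^2 / (2 * width_nm^2))
    # a dye is not excited by lasers redder than its emission peak
    s[windows$excitation_nm > peak_nm[i]] <- 0
    s
  }, numeric(nrow(windows))))
  emission_reference(S / rowSums(S), fluorophores, windows)
}

#' Render a lambda-scan stack from ground truth
#'
#' Particles are hard disks of uniform interior intensity: each particle
#' spreads its true abundance evenly over its pixels (density =
#' abundance / area), so the summed, background-subtracted counts over a
#' particle recover its abundance exactly in noiseless mode. A pixel's
#' spectrum is `background + sum_m density_m * spectrum_m`, where each
#' reference spectrum sums to 1 over windows. Noise (when enabled) is Poisson
#' shot noise followed by additive Gaussian read noise, rounded and clamped
#' to the 16-bit range.
#'
#' @param gt a [sample_particles()] result.
#' @param ref an [emission_reference()] covering all markers in `gt`.
#' @param config the [sim_config()] (background, noise switches, image size).
#' @param noise override the config's noise switches (TRUE/FALSE).
#' @return a [spectral_stack()].
#' @export
render_spectral_stack <- function(gt, ref, config, noise = config$poisson) {
  stopifnot(inherits(gt, "ground_truth"), inherits(ref, "emission_reference"))
  missing <- setdiff(gt$markers, ref$fluorophores)
  if (length(missing))
    stop("markers missing from reference spectra: ",
         paste(missing, collapse = ", "))
  H <- config$image_size[1]; W <- config$image_size[2]
  nw <- nrow(ref$windows)
  S <- ref$matrix[gt$markers, , drop = FALSE]

  dens <- matrix(0, H * W, length(gt$markers))
  p <- gt$particles
  for (i in seq_len(nrow(p))) {
    px <- disk_pixels(p$x[i], p$y[i], p$radius[i], H, W)
    idx <- px$i + (px$j - 1L) * H
    dens[idx, ] <- dens[idx, , drop = FALSE] +
      rep(gt$abundance[i, ] / p$area[i], each = nrow(px))
  }
  planes <- dens %*% S + config$background
  if (noise) {
    set.seed(config$seed + 1L)
    planes[] <- stats::rpois(length(planes), planes)
    if (config$read_sd > 0)
      planes[] <- planes + stats::rnorm(length(planes), 0, config$read_sd)
    planes[] <- pmin(pmax(round(planes), 0), 65535)
  }
  spectral_stack(array(planes, c(H, W, nw)), ref$windows)
}

#' Generate a per-particle feature table directly from ground truth
#'
#' Bypasses imaging: per-particle marker sums are the true abundances
#' perturbed by multiplicative log-normal noise and a per-batch gain, with
#' replicate labels assigned round-robin over `config$n_batches` simulated
#' independent experiments. Used to test the landscape and cargo stages in
#' isolation.
#'
#' @param gt a [sample_particles()] result.
#' @param config the [sim_config()] (noise_sd, n_batches, batch_gains, seed).
#' @param noise_sd override of the multiplicative log-normal noise sd.
#' @return a [particle_table()] with marker columns, `area`, `replicate`,
#'   and a `true_class` column carrying the generating label.
#' @export
make_feature_matrix <- function(gt, config, noise_sd = config$noise_sd) {
  stopifnot(inherits(gt, "ground_truth"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  n <- nrow(gt$abundance)
  m <- length(gt$markers)
  rep_id <- if (n) ((seq_len(n) - 1L) %% config$n_batches) + 1L else integer()
  set.seed(config$seed + 2L)
  noise <- if (noise_sd > 0)
    exp(matrix(stats::rnorm(n * m, 0, noise_sd), n, m)) else matrix(1, n, m)
  vals <- gt$abundance * noise * config$batch_gains[rep_id]
  rownames(vals) <- NULL
  df <- data.frame(replicate = rep_id,
                   condition = rep("none", n),
                   timepoint = rep(NA_real_, n))
  df <- cbind(df, as.data.frame(vals))
  df$area <- gt$particles$area
  df$true_class <- ifelse(is.na(gt$particles$class2), gt$particles$class,
                          paste0(gt$particles$class, "+",
                                 gt$particles$class2))
  particle_table(df, markers = gt$markers)
}

#' Simulate an endocytic cargo time course
#'
#' Emulates pulse-chase loading of a degradative cargo (EGF) and a recycling
#' cargo (transferrin) onto endosome particles followed over a chase time
#' course. Each cargo-positive particle's maturation state is drawn from a
#' time-dependent distribution: the degradative route moves
#' early -> conversion -> late -> lysosome, the recycling route moves
#' early -> recycling. Cargo-negative (bystander) endosomes are drawn
#' uniformly over states with background-level cargo signal.
#'
#' @param n_per_timepoint particles per timepoint.
#' @param timepoints chase times in minutes.
#' @param profiles endosome state profiles ([endosome_class_profiles()]).
#' @param log_sd log-normal spread of abundances.
#' @param cargo_mean_log,background_mean_log mean log-intensity of cargo
#'   signal on loaded particles and of the unloaded background.
#' @param frac_egf,frac_tf,frac_none fractions of particles loaded with EGF,
#'   with transferrin, or unloaded; must sum to 1.
#' @param n_batches,condition replicate count and condition tag.
#' @param seed integer seed.
#' @return a [particle_table()] with RAB5/RAB11/RAB7/LAMP1, EGF and TF
#'   columns, `timepoint`, `condition`, `replicate`, `area`, and a
#'   `true_state` column.
#' @export
sample_cargo_timecourse <- function(n_per_timepoint = 600,
                                    timepoints = c(0, 5, 10, 15, 20, 30, 40),
                                    profiles = endosome_class_profiles(),
                                    log_sd = 0.45,
                                    cargo_mean_log = log(4000),
                                    background_mean_log = log(15),
                                    frac_egf = 0.3, frac_tf = 0.3,
                                    frac_none = 0.4,
                                    n_batches = 3,
                                    condition = "untreated",
                                    seed = 0) {
  if (abs(frac_egf + frac_tf + frac_none - 1) > 1e-8)
    stop("cargo fractions must sum to 1")
  set.seed(seed)
  states <- rownames(profiles)
  tmax <- max(timepoints)
  # state occupancy along each route as a function of chase time
  degr_prob <- function(t) {
    u <- t / tmax
    w <- c(early = max(1 - 2 * u, 0), conversion = exp(-8 * (u - 0.25)^2),
           late = exp(-8 * (u - 0.55)^2),
           late_lysosome = exp(-8 * (u - 0.8)^2),
           lysosome = max(2 * u - 1, 0) + 0.05)
    p <- stats::setNames(numeric(length(states)), states)
    p[names(w)] <- w
    p / sum(p)
  }
  recyc_prob <- function(t) {
    u <- t / tmax
    w <- c(early = max(1 - 1.5 * u, 0.05),
           recycling_a = 0.6 * min(1.5 * u, 1) + 0.02,
           recycling_b = 0.4 * min(1.5 * u, 1) + 0.02)
    p <- stats::setNames(numeric(length(states)), states)
    p[names(w)] <- w
    p / sum(p)
  }
  out <- lapply(timepoints, function(t) {
    n <- n_per_timepoint
    cargo <- sample(c("EGF", "TF", "none"), n, replace = TRUE,
                    prob = c(frac_egf, frac_tf, frac_none))
    st <- character(n)
    st[cargo == "EGF"] <- sample(states, sum(cargo == "EGF"), TRUE,
                                 prob = degr_prob(t))
    st[cargo == "TF"] <- sample(states, sum(cargo == "TF"), TRUE,
                                prob = recyc_prob(t))
    st[cargo == "none"] <- sample(states, sum(cargo == "none"), TRUE)
    mu <- profiles[st, , drop = FALSE]
    ab <- exp(mu + matrix(stats::rnorm(n * ncol(profiles), 0, log_sd),
                          n, ncol(profiles)))
    colnames(ab) <- colnames(profiles)
    egf <- exp(stats::rnorm(n, background_mean_log, log_sd))
    tf <- exp(stats::rnorm(n, background_mean_log, log_sd))
    egf[cargo == "EGF"] <- exp(stats::rnorm(sum(cargo == "EGF"),
                                            cargo_mean_log, log_sd))
    tf[cargo == "TF"] <- exp(stats::rnorm(sum(cargo == "TF"),
                                          cargo_mean_log, log_sd))
    df <- data.frame(replicate = ((seq_len(n) - 1L) %% n_batches) + 1L,
                     condition = condition, timepoint = t)
    df <- cbind(df, as.data.frame(ab))
    df$EGF <- egf; df$TF <- tf
    df$area <- sample(10:60, n, replace = TRUE)
    df$true_state <- st
    df$true_cargo <- cargo
    df
  })
  particle_table(do.call(rbind, out),
                 markers = c(colnames(profiles), "EGF", "TF"))
}
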