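#' Synthetic EEG class profiles
#'
#' A class profile describes one labeled population of EEG-like signals:
#' a sum of cosine oscillations, AR(1) Gaussian noise, and Poisson-placed
#' symmetric triangular spikes. The three ingredients map onto the
#' contrasts the geometric features are designed to detect: oscillatory
#' slowing (frequency content), curvature smoothness (AR coefficient) and
#' transient sharpness (spikes — triangles create second-difference
#' discontinuities that CBEFI responds to).
#'
#' @param label Class name (e.g. `"AD"`, `"FTD"`, `"HC"`).
#' @param osc Data.frame with columns `freq` (Hz) and `amp`: cosine
#'   components, all with zero phase.
#' @param ar_coeff AR(1) coefficient in \[0, 1): higher values give
#'   smoother, more slowly wandering noise.
#' @param noise_sd Standard deviation of the AR(1) Gaussian innovations
#'   (>= 0).
#' @param spike_rate Expected transient spikes per second (>= 0).
#' @param spike_amp Spike peak amplitude.
#' @param spike_width Spike half-width in samples.
#' @return An object of class `class_profile`.
#' @export
class_profile <- function(label, osc, ar_coeff = 0, noise_sd = 0,
                          spike_rate = 0, spike_amp = 0, spike_width = 5) {
  osc <- as.data.frame(osc)
  stopifnot(all(c("freq", "amp") %in% names(osc)))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (ar_coeff < 0 || ar_coeff >= 1) stop("ar_coeff must be in [0, 1)")
  if (spike_rate < 0) stop("spike_rate must be >= 0")
  structure(list(label = label, osc = osc, ar_coeff = ar_coeff,
                 noise_sd = noise_sd, spike_rate = spike_rate,
                 spike_amp = spike_amp,
                 spike_width = as.integer(spike_width)),
            class = "class_profile")
}

#' @export
print.class_profile <- function(x, ...) {
  cat(sprintf(
    "class profile '%s': %d oscillation(s), AR(1) %.2f sd %.2f, spikes %g/s\n",
    x$label, nrow(x$osc), x$ar_coeff, x$noise_sd, x$spike_rate))
  invisible(x)
}

#' Shipped synthetic cohorts
#'
#' `easy_profiles()` is the default three-class test cohort: HC is a
#' 10 Hz + 20 Hz mixture over moderately smooth noise; AD is slowed (6 Hz)
#' over very smooth noise (reduced curvature dynamics); FTD keeps the HC
#' oscillation but adds sharp triangular transients. `geometry_profiles()`
#' is the variant in which all classes share the same 10 Hz oscillation and
#' noise level, differing only in the AR coefficient and spike parameters —
#' the curvature/irregularity-only contrast under which WAII and CBEFI are
#' the discriminative features.
#'
#' @return A named list of three [class_profile()] objects (HC, AD, FTD).
#' @export
easy_profiles <- function() {
  list(
    HC = class_profile("HC", data.frame(freq = c(10, 20), amp = c(1, 0.3)),
                       ar_coeff = 0.5, noise_sd = 0.2),
    AD = class_profile("AD", data.frame(freq = 6, amp = 1),
                       ar_coeff = 0.9, noise_sd = 0.2),
    FTD = class_profile("FTD", data.frame(freq = 10, amp = 1),
                        ar_coeff = 0.5, noise_sd = 0.2,
                        spike_rate = 2, spike_amp = 3, spike_width = 5))
}

#' @rdname easy_profiles
#' @export
geometry_profiles <- function() {
  list(
    HC = class_profile("HC", data.frame(freq = 10, amp = 1),
                       ar_coeff = 0.5, noise_sd = 0.2),
    AD = class_profile("AD", data.frame(freq = 10, amp = 1),
                       ar_coeff = 0.95, noise_sd = 0.2),
    FTD = class_profile("FTD", data.frame(freq = 10, amp = 1),
                        ar_coeff = 0.5, noise_sd = 0.2,
                        spike_rate = 2, spike_amp = 3, spike_width = 5))
}

#' Read/write class profiles as plain-text config
#'
#' Serialises a list of [class_profile()]s to a Debian-control-style
#' key/value file (one block per class; oscillation components encoded as
#' `freq:amp` pairs separated by `;`), and back.
#'
#' @param profiles Named or unnamed list of [class_profile()]s.
#' @param path File path.
#' @return `write_profiles()` the path, invisibly; `read_profiles()` a
#'   named list of profiles.
#' @export
write_profiles <- function(profiles, path) {
  blocks <- lapply(profiles, function(p) {
    data.frame(label = p$label,
               osc = paste(sprintf("%g:%g", p$osc$freq, p$osc$amp),
                           collapse = ";"),
               ar_coeff = p$ar_coeff, noise_sd = p$noise_sd,
               spike_rate = p$spike_rate, spike_amp = p$spike_amp,
               spike_width = p$spike_width)
  })
  write.dcf(do.call(rbind, blocks), path)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  d <- as.data.frame(read.dcf(path), stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(d)), function(r) {
    parts <- strsplit(strsplit(d$osc[r], ";")[[1]], ":")
    osc <- data.frame(freq = as.numeric(vapply(parts, `[`, "", 1)),
                      amp = as.numeric(vapply(parts, `[`, "", 2)))
    class_profile(d$label[r], osc,
                  ar_coeff = as.numeric(d$ar_coeff[r]),
                  noise_sd = as.numeric(d$noise_sd[r]),
                  spike_rate = as.numeric(d$spike_rate[r]),
                  spike_amp = as.numeric(d$spike_amp[r]),
                  spike_width = as.integer(d$spike_width[r]))
  })
  stats::setNames(out, d$label)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Counter-based seed derivation so any (subject, channel) cell of a cohort
# is reproducible in isolation. Kept below 2^31 - 1.
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.numeric(master) %% 2147483647
  for (k in idx) s <- (s * 48271 + as.numeric(k) + 1) %% 2147483647
  as.integer(s)
}

#' Generate one synthetic EEG segment
#'
#' Deterministic for fixed `(profile, n, fs, seed)`:
#' signal = sum of cosines + AR(1) Gaussian noise + Poisson-placed
#' symmetric triangular spikes (peak `spike_amp`, half-width `spike_width`
#' samples).
#'
#' @param profile A [class_profile()].
#' @param n Number of samples (>= 2).
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed.
#' @param subject_id,channel,window_index Provenance metadata for the
#'   resulting segment.
#' @return An [eeg_segment()].
#' @examples
#' p <- class_profile("pure", data.frame(freq = 10, amp = 1))
#' seg <- generate_segment(p, n = 500, fs = 500, seed = 1)
#' max(abs(seg$x))  # 1: noiseless cosine
#' @export
generate_segment <- function(profile, n, fs, seed, subject_id = "synth",
                             channel = "ch01", window_index = 0L) {
  stopifnot(inherits(profile, "class_profile"))
  n <- as.integer(n)
  if (n < 2) stop("n must be >= 2")
  t <- seq_len(n) - 1L
  x <- numeric(n)
  for (r in seq_len(nrow(profile$osc)))
    x <- x + profile$osc$amp[r] *
      cos(2 * pi * profile$osc$freq[r] * t / fs)
  with_seed(seed, {
    if (profile$noise_sd > 0) {
      innov <- stats::rnorm(n, sd = profile$noise_sd)
      x <- x + as.numeric(stats::filter(innov, profile$ar_coeff,
                                        method = "recursive"))
    }
    if (profile$spike_rate > 0 && profile$spike_amp != 0) {
      n_spikes <- stats::rpois(1, profile$spike_rate * n / fs)
      if (n_spikes > 0) {
        centers <- sample.int(n, n_spikes, replace = TRUE)
        w <- profile$spike_width
        for (p in centers) {
          d <- seq(-(w - 1L), w - 1L)
          pos <- p + d
          keep <- pos >= 1 & pos <= n
          x[pos[keep]] <- x[pos[keep]] +
            profile$spike_amp * (1 - abs(d[keep]) / w)
        }
      }
    }
  })
  eeg_segment(x, fs = fs, subject_id = subject_id, channel = channel,
              window_index = window_index)
}

#' Generate a labeled synthetic cohort
#'
#' One segment per (subject, channel); per-cell seeds are derived from the
#' master seed by a counter scheme, so cohort generation is a pure function
#' of its arguments and any subset is reproducible in isolation.
#'
#' @param profiles List of [class_profile()] objects (>= 2).
#' @param subjects_per_class Subjects per profile (>= 1).
#' @param channels Channels per subject.
#' @param n Samples per segment.
#' @param fs Sampling rate in Hz.
#' @param seed Master integer seed.
#' @return An object of class `eeg_cohort`: list with `segments` (list of
#'   [eeg_segment()]) and `meta` (data.frame `label`, `subject`,
#'   `channel`).
#' @export
generate_cohort <- function(profiles, subjects_per_class, channels = 2L,
                            n = 2000L, fs = 500, seed = 1L) {
  if (length(profiles) < 2) stop("need at least 2 class profiles")
  if (subjects_per_class < 1) stop("empty dataset: subjects_per_class must be >= 1")
  segments <- list()
  meta <- list()
  idx <- 0L
  for (ci in seq_along(profiles)) {
    prof <- profiles[[ci]]
    for (si in seq_len(subjects_per_class)) {
      subject <- sprintf("%s-%02d", prof$label, si)
      for (ch in seq_len(channels)) {
        idx <- idx + 1L
        chan <- sprintf("ch%02d", ch)
        segments[[idx]] <- generate_segment(
          prof, n = n, fs = fs,
          seed = derive_seed(seed, ci, si, ch),
          subject_id = subject, channel = chan)
        meta[[idx]] <- data.frame(label = prof$label, subject = subject,
                                  channel = chan,
                                  stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(segments = segments, meta = do.call(rbind, meta)),
            class = "eeg_cohort")
}

#' @export
print.eeg_cohort <- function(x, ...) {
  cat(sprintf("synthetic EEG cohort: %d segments, %d classes, %d subjects\n",
              length(x$segments), length(unique(x$meta$label)),
              length(unique(x$meta$subject))))
  invisible(x)
}

#' Extract the feature table of a cohort
#'
#' Builds the ARC network of every segment and computes its 15-entry
#' feature vector, yielding the labeled dataset the selection and
#' classification stages operate on.
#'
#' @param cohort An [generate_cohort()] result, or a list of
#'   [eeg_segment()] with a matching `meta` data.frame.
#' @param params [arc_params()] used for every network.
#' @return Data.frame with columns `feat_01` ... `feat_15`, `label`
#'   (factor), `subject`, `channel` — one row per segment.
#' @export
extract_features <- function(cohort, params = arc_params()) {
  stopifnot(inherits(cohort, "eeg_cohort"))
  rows <- lapply(cohort$segments, function(seg)
    as.data.frame(as.list(feature_vector(build_network(seg, params)))))
  out <- cbind(do.call(rbind, rows), cohort$meta)
  out$label <- factor(out$label)
  rownames(out) <- NULL
  out
}
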