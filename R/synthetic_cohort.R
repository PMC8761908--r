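# Synthetic cohort generator.
#
# Emulates the reference cohort: 52 seizure-free (SF) and 22 not-seizure-free
# (NSF) subjects, 19-channel 10-20 EEG at 256 Hz, and a 15-feature clinical
# table. Each channel is a mixture of four band-limited oscillators (one per
# clinical band, with slowly drifting phase) and white noise; the
# noise-to-oscillation amplitude fraction is drawn per subject from a
# class-dependent distribution whose means differ by `effect_size` (NSF
# higher), which plants the observed NSF > SF complexity ordering.

# Effect size at which the clinical class-conditional distributions reach the
# reference cohort's marginal tables (also the default effect size). Below
# it, clinical class differences shrink proportionally, so that at
# effect_size = 0 the two classes are statistically identical in every
# respect and a classifier can only reach chance level.
.EFFECT_REFERENCE <- 0.3

# Oscillator model constants: band centre frequencies (Hz), relative
# amplitudes (1/f-flavoured), phase-drift knot spacing (samples) and
# per-knot drift standard deviation (radians).
.OSC_FREQS <- c(delta = 2, theta = 6, alpha = 10, beta = 20)
.OSC_AMPS  <- c(delta = 1.0, theta = 0.7, alpha = 0.8, beta = 0.45)
.OSC_KNOT_EVERY <- 64L
.OSC_DRIFT_SD <- 0.3
.SIGNAL_SCALE_UV <- 50
.NOISE_FRACTION_SD <- 0.05

#' Reference contingency tables of the clinical cohort
#'
#' The class-by-level counts of the categorical clinical features in the
#' reference cohort (52 SF vs 22 NSF) that parameterize the synthetic
#' clinical generator: sex, seizure circadian rhythm (2x3), and the nine
#' binary history/imaging features.
#'
#' @return A named list of integer matrices with rows `SF`, `NSF`.
#' @export
clinical_reference_counts <- function() {
  tab <- function(sf, nsf, levels) {
    m <- rbind(SF = sf, NSF = nsf)
    colnames(m) <- levels
    m
  }
  list(
    sex                  = tab(c(33, 19), c(11, 11), c("M", "F")),
    circadian_rhythm     = tab(c(19, 16, 17), c(8, 7, 7), c("day", "night", "both")),
    comorbidity          = tab(c(27, 25), c(16, 6), c("Y", "N")),
    inducement           = tab(c(29, 23), c(17, 5), c("Y", "N")),
    perinatal_injury     = tab(c(12, 40), c(12, 10), c("Y", "N")),
    physical_development = tab(c(9, 43), c(3, 19), c("N", "AN")),
    family_history       = tab(c(2, 50), c(2, 20), c("Y", "N")),
    mri                  = tab(c(17, 35), c(13, 9), c("P", "N")),
    tle                  = tab(c(16, 36), c(8, 14), c("Y", "N")),
    cns_infection        = tab(c(7, 45), c(2, 20), c("Y", "N")),
    head_injury          = tab(c(5, 47), c(2, 20), c("Y", "N")))
}

# Quantitative clinical reference summaries. Skewed, strictly positive
# variables (ages, seizure frequency) are summarized as median +/- IQR and
# modelled log-normal; follow-up time is summarized as mean +/- SD and
# modelled normal (truncated at 1 month).
.clinical_quant_reference <- function() {
  list(
    age = list(dist = "lognormal",
               SF = c(median = 14.5, iqr = 11.50),
               NSF = c(median = 16.5, iqr = 12.00)),
    age_at_onset = list(dist = "lognormal",
                        SF = c(median = 13.5, iqr = 12.25),
                        NSF = c(median = 15.5, iqr = 13.38)),
    follow_up = list(dist = "normal",
                     SF = c(mean = 32.58, sd = 9.83),
                     NSF = c(mean = 36.18, sd = 8.91)),
    seizure_freq_before_oxc = list(dist = "lognormal",
                                   SF = c(median = 0.65, iqr = 0.70),
                                   NSF = c(median = 15.50, iqr = 13.37)))
}

# log-normal parameters matching a target median and interquartile range
.lognorm_params <- function(median, iqr) {
  c(meanlog = log(median),
    sdlog = asinh(iqr / (2 * median)) / qnorm(0.75))
}

#' Specification of a synthetic cohort
#'
#' @param n_sf,n_nsf numbers of seizure-free and not-seizure-free subjects
#'   (defaults 52 and 22, the reference cohort).
#' @param effect_size nonnegative separation of the class-wise broadband
#'   noise fractions: the per-subject noise fraction is centred at
#'   `0.5 - effect_size/2` for SF and `0.5 + effect_size/2` for NSF. At 0 the
#'   two classes are identical in EEG and clinical structure; at the default
#'   (0.3) and above, clinical marginals match the reference cohort tables.
#' @param n_epochs_per_subject number of 15-s epochs per subject (default 15).
#' @param epoch_seconds epoch duration in seconds (default 15).
#' @param sampling_rate sampling frequency in Hz (default 256); must exceed
#'   twice the highest band edge (30 Hz).
#' @param channels ordered channel labels (default the 19-channel 10-20
#'   montage).
#' @param seed integer seed; identical spec and seed give bit-identical
#'   cohorts.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_sf = 52, n_nsf = 22, effect_size = .EFFECT_REFERENCE,
                        n_epochs_per_subject = 15, epoch_seconds = 15,
                        sampling_rate = 256, channels = default_channels(),
                        seed = 1L) {
  if (n_sf < 0 || n_sf != round(n_sf)) stop("invalid `n_sf`: must be a nonnegative integer")
  if (n_nsf < 0 || n_nsf != round(n_nsf)) stop("invalid `n_nsf`: must be a nonnegative integer")
  if (n_sf + n_nsf < 2) stop("invalid `n_sf`/`n_nsf`: cohort must have at least 2 subjects")
  if (effect_size < 0) stop("invalid `effect_size`: must be nonnegative")
  if (sampling_rate <= 60) stop("invalid `sampling_rate`: must exceed 60 Hz (2 x 30 Hz)")
  if (n_epochs_per_subject < 1) stop("invalid `n_epochs_per_subject`")
  if (epoch_seconds <= 0) stop("invalid `epoch_seconds`")
  if (anyDuplicated(channels)) stop("invalid `channels`: labels must be unique")
  structure(list(n_sf = as.integer(n_sf), n_nsf = as.integer(n_nsf),
                 effect_size = effect_size,
                 n_epochs_per_subject = as.integer(n_epochs_per_subject),
                 epoch_seconds = epoch_seconds, sampling_rate = sampling_rate,
                 channels = as.character(channels), seed = as.integer(seed)),
            class = "cohort_spec")
}

# Clinical interpolation weight: 0 = pooled cohort (identical classes),
# 1 = reference class-specific marginals.
.clinical_weight <- function(effect_size) min(1, effect_size / .EFFECT_REFERENCE)

#' Generate the clinical covariate table
#'
#' Samples the 15 clinical features class-conditionally. Categorical levels
#' follow the reference contingency tables and quantitative variables the
#' reference location/scale summaries; class differences are scaled by
#' `effect_size` as described in [cohort_spec()]. Covariates are sampled
#' independently of each other and of the EEG given the class label.
#'
#' @param n_sf,n_nsf class sizes.
#' @param effect_size class-separation control (see [cohort_spec()]).
#' @param seed integer seed.
#' @return A data frame with `subject_id`, `label`, and the 15 clinical
#'   features, SF subjects first.
#' @export
generate_clinical <- function(n_sf, n_nsf, effect_size = .EFFECT_REFERENCE,
                              seed = 1L) {
  g <- .clinical_weight(effect_size)
  counts <- clinical_reference_counts()
  quants <- .clinical_quant_reference()
  n <- n_sf + n_nsf
  labels <- c(rep("SF", n_sf), rep("NSF", n_nsf))
  w_ref <- c(SF = 52, NSF = 22) / 74

  with_seed(seed, {
    out <- data.frame(
      subject_id = sprintf("S%03d", seq_len(n)),
      label = labels, stringsAsFactors = FALSE)
    for (f in names(quants)) {
      q <- quants[[f]]
      if (q$dist == "lognormal") {
        pc <- rbind(SF = .lognorm_params(q$SF["median"], q$SF["iqr"]),
                    NSF = .lognorm_params(q$NSF["median"], q$NSF["iqr"]))
      } else {
        pc <- rbind(SF = q$SF, NSF = q$NSF)
      }
      pooled <- w_ref["SF"] * pc["SF", ] + w_ref["NSF"] * pc["NSF", ]
      vals <- numeric(n)
      for (cl in c("SF", "NSF")) {
        idx <- which(labels == cl)
        if (!length(idx)) next
        p <- pooled + g * (pc[cl, ] - pooled)
        vals[idx] <- if (q$dist == "lognormal")
          exp(rnorm(length(idx), p[1], p[2]))
        else pmax(1, rnorm(length(idx), p[1], p[2]))
      }
      out[[f]] <- vals
    }
    for (f in names(counts)) {
      m <- counts[[f]]
      pooled <- colSums(m) / sum(m)
      vals <- character(n)
      for (cl in c("SF", "NSF")) {
        idx <- which(labels == cl)
        if (!length(idx)) next
        p <- pooled + g * (m[cl, ] / sum(m[cl, ]) - pooled)
        vals[idx] <- sample(colnames(m), length(idx), replace = TRUE, prob = p)
      }
      out[[f]] <- vals
    }
    out[c("subject_id", "label", "sex", "age", "age_at_onset", "follow_up",
          "seizure_freq_before_oxc", "circadian_rhythm", "comorbidity",
          "inducement", "perinatal_injury", "physical_development",
          "family_history", "mri", "tle", "cns_infection", "head_injury")]
  })
}

# Deterministic per-cohort plan: labels, clinical table, per-subject noise
# fractions and per-subject signal seeds. Splitting the signal RNG per
# subject lets callers generate recordings lazily (one at a time) with
# results identical to generate_cohort().
.cohort_plan <- function(spec) {
  labels <- c(rep("SF", spec$n_sf), rep("NSF", spec$n_nsf))
  clinical <- generate_clinical(spec$n_sf, spec$n_nsf, spec$effect_size,
                                seed = derive_seed(spec$seed, 1L))
  mu <- ifelse(labels == "SF", 0.5 - spec$effect_size / 2,
               0.5 + spec$effect_size / 2)
  mu <- pmin(pmax(mu, 0.02), 0.98)
  with_seed(derive_seed(spec$seed, 2L), {
    nf <- pmin(pmax(rnorm(length(labels), mu, .NOISE_FRACTION_SD), 0.02), 0.98)
    subject_seeds <- sample.int(2147483646L, length(labels))
  })
  list(labels = labels, clinical = clinical, noise_fraction = nf,
       subject_seeds = subject_seeds)
}

# One subject's raw multichannel recording for a given noise fraction.
.subject_recording <- function(spec, noise_fraction, seed) {
  n <- spec$n_epochs_per_subject * spec$epoch_seconds * spec$sampling_rate
  if (n != round(n)) stop("epoch grid must give a whole number of samples")
  n <- as.integer(n)
  nseg <- as.integer(ceiling(n / .OSC_KNOT_EVERY))
  nch <- length(spec$channels)
  with_seed(seed, {
    data <- matrix(0, nrow = nch, ncol = n)
    for (ch in seq_len(nch)) {
      phase0 <- runif(length(.OSC_FREQS), 0, 2 * pi)
      drift <- matrix(rnorm(nseg * length(.OSC_FREQS), 0, .OSC_DRIFT_SD),
                      nrow = nseg)
      osc <- .oscillator_cpp(n, spec$sampling_rate, .OSC_FREQS, .OSC_AMPS,
                             phase0, drift, .OSC_KNOT_EVERY)
      osc <- osc / sd(osc)
      noise <- rnorm(n)
      data[ch, ] <- .SIGNAL_SCALE_UV *
        ((1 - noise_fraction) * osc + noise_fraction * noise)
    }
    eeg_recording(data, spec$channels, spec$sampling_rate)
  })
}

#' Generate a labelled synthetic cohort
#'
#' Draws the clinical table, per-subject noise fractions, and one raw
#' 19-channel recording per subject, deterministically under `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return An object of class `synthetic_cohort`: a list of
#'   `synthetic_subject` objects (fields `subject_id`, `label`, `recording`,
#'   `clinical`) with the spec attached as attribute `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  plan <- .cohort_plan(spec)
  subjects <- lapply(seq_along(plan$labels), function(i) {
    structure(list(
      subject_id = plan$clinical$subject_id[i],
      label = plan$labels[i],
      recording = .subject_recording(spec, plan$noise_fraction[i],
                                     plan$subject_seeds[i]),
      clinical = plan$clinical[i, , drop = FALSE]),
      class = "synthetic_subject")
  })
  structure(subjects, class = "synthetic_cohort", spec = spec)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  labs <- vapply(x, `[[`, "", "label")
  cat(sprintf("<synthetic_cohort> %d subjects (%d SF / %d NSF)\n",
              length(x), sum(labs == "SF"), sum(labs == "NSF")))
  invisible(x)
}

#' Write a cohort to disk (EDF + clinical CSV + manifest)
#'
#' Writes one EDF file per subject, a cohort-level clinical CSV, and a JSON
#' manifest echoing the generating spec, the seed, and the file list. Files
#' round-trip through [read_edf()] within EDF 16-bit quantization.
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort()].
#' @param directory output directory (created if absent).
#' @return The manifest, invisibly.
#' @export
write_cohort <- function(cohort, directory) {
  if (!length(cohort)) stop("`cohort` must be nonempty")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  spec <- attr(cohort, "spec")
  edf_files <- vapply(cohort, function(s) {
    f <- file.path(directory, paste0(s$subject_id, ".edf"))
    write_edf(s$recording, f, patient_id = s$subject_id)
    basename(f)
  }, "")
  clinical <- do.call(rbind, lapply(cohort, `[[`, "clinical"))
  clin_file <- file.path(directory, "clinical.csv")
  write.csv(clinical, clin_file, row.names = FALSE)
  manifest <- list(
    spec = unclass(spec),
    seed = spec$seed,
    files = list(edf = unname(edf_files), clinical = basename(clin_file)))
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
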