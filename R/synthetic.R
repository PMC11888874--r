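# Class-dependent signal parameters at full separation (delta = 1).
# Columns: rest baseline and exercise peak per condition.  Values are
# physiologically plausible for an incremental treadmill test: heart-failure
# subjects have blunted peak VO2/HR, metabolic-syndrome subjects are
# intermediate with an elevated resting HR, healthy subjects reach the
# highest peaks.  The generator linearly interpolates between the class mean
# (delta = 0, classes indistinguishable) and these values (delta = 1), and
# extrapolates beyond.
SYNTH_PARAMS <- local({
  p <- rbind(
    #        base_HF base_MS base_H  peak_HF peak_MS peak_H
    HR   = c(  80,     85,     75,     110,    150,    170),
    VO2  = c(  0.35,   0.35,   0.35,   1.2,    2.0,    2.8),
    VCO2 = c(  0.30,   0.30,   0.30,   1.3,    2.2,    3.2),
    VE   = c( 12,     11,     10,      45,     70,    100),
    RR   = c( 16,     15,     14,      32,     38,     45),
    METS = c(  1,      1,      1,       4,      7,     11),
    RER  = c(  0.82,   0.82,   0.80,    1.05,   1.10,   1.15),
    Vtex = c(  0.6,    0.6,    0.6,     1.4,    1.9,    2.4),
    Vtin = c(  0.6,    0.6,    0.6,     1.4,    1.9,    2.4))
  colnames(p) <- c("base_HF", "base_MS", "base_H",
                   "peak_HF", "peak_MS", "peak_H")
  p
})

#' Configuration of the synthetic CPET cohort generator
#'
#' The generator emulates the protocol structure the classifier assumes:
#' per-subject variable-length breath-by-breath series with a rest phase
#' (constant baseline), an incremental-exercise ramp to a class-dependent
#' peak, and an exponential recovery, plus AR(1) breath-to-breath noise and
#' log-normal between-subject variation.  `delta` scales the between-class
#' parameter differences: 0 makes the three conditions indistinguishable in
#' expectation, 1 is the realistic default, larger values exaggerate the
#' separation.
#'
#' @param n_per_class subjects per requested class (>= 1).
#' @param classes subset of `c("HF", "MS", "H")`.
#' @param delta nonnegative class-separation multiplier.
#' @param n_breaths integer range `c(min, max)`; each subject's record length
#'   is drawn uniformly from it.
#' @param phase_fractions named fractions of record length spent in rest,
#'   exercise and recovery; must be positive and sum to 1.
#' @param recovery_tau_frac recovery time constant as a fraction of the
#'   recovery-phase length (smaller = faster return to baseline).
#' @param noise_sd_frac breath-to-breath noise standard deviation as a
#'   fraction of each variable's class-mean dynamic range.
#' @param rho AR(1) autocorrelation of the breath-to-breath noise, in
#'   `[0, 1)`.
#' @param subject_sd log-scale standard deviation of the per-subject
#'   multiplier applied to baselines and peaks (between-subject variation).
#' @param seed integer seed; the full cohort is a deterministic function of
#'   the configuration.
#' @return object of class `cpet_synth_config`.
#' @export
synthetic_config <- function(n_per_class = 15L,
                             classes = c("HF", "MS", "H"),
                             delta = 1,
                             n_breaths = c(120L, 480L),
                             phase_fractions = c(rest = 0.15, exercise = 0.60,
                                                 recovery = 0.25),
                             recovery_tau_frac = 0.25,
                             noise_sd_frac = 0.05,
                             rho = 0.3,
                             subject_sd = 0.08,
                             seed = 1L) {
  n_per_class <- as.integer(n_per_class)
  if (n_per_class < 1L) stop("'n_per_class' must be >= 1", call. = FALSE)
  classes <- match.arg(classes, c("HF", "MS", "H"), several.ok = TRUE)
  if (delta < 0) stop("'delta' must be >= 0", call. = FALSE)
  n_breaths <- as.integer(n_breaths)
  stopifnot(length(n_breaths) == 2L, n_breaths[1] >= 32L,
            n_breaths[2] >= n_breaths[1])
  stopifnot(length(phase_fractions) == 3L, all(phase_fractions > 0),
            abs(sum(phase_fractions) - 1) < 1e-8)
  if (rho < 0 || rho >= 1) stop("'rho' must be in [0, 1)", call. = FALSE)
  stopifnot(noise_sd_frac >= 0, subject_sd >= 0, recovery_tau_frac > 0)
  structure(list(n_per_class = n_per_class, classes = classes, delta = delta,
                 n_breaths = n_breaths,
                 phase_fractions = phase_fractions,
                 recovery_tau_frac = recovery_tau_frac,
                 noise_sd_frac = noise_sd_frac, rho = rho,
                 subject_sd = subject_sd, seed = as.integer(seed)),
            class = "cpet_synth_config")
}

# class-specific (baseline, peak) after applying the separation multiplier
synth_class_params <- function(cls, delta) {
  base_mean <- rowMeans(SYNTH_PARAMS[, 1:3])
  peak_mean <- rowMeans(SYNTH_PARAMS[, 4:6])
  base <- base_mean + delta * (SYNTH_PARAMS[, paste0("base_", cls)] - base_mean)
  peak <- peak_mean + delta * (SYNTH_PARAMS[, paste0("peak_", cls)] - peak_mean)
  list(base = base, peak = peak,
       noise_range = pmax(peak_mean - base_mean, 1e-6))
}

# noise-free phase trajectory of length n for one variable
synth_trajectory <- function(n, base, peak, fr, tau_frac) {
  n_rest <- max(1L, round(fr[["rest"]] * n))
  n_rec <- max(1L, round(fr[["recovery"]] * n))
  n_ex <- n - n_rest - n_rec
  ramp <- base + (peak - base) * seq_len(n_ex) / n_ex
  tau <- tau_frac * n_rec
  rec <- base + (peak - base) * exp(-seq_len(n_rec) / tau)
  c(rep(base, n_rest), ramp, rec)
}

# stationary AR(1): marginal sd constant over the record
ar1_noise <- function(n, sd, rho) {
  if (sd == 0) return(numeric(n))
  innov <- c(stats::rnorm(1, sd = sd),
             stats::rnorm(n - 1, sd = sd * sqrt(1 - rho^2)))
  as.vector(stats::filter(innov, rho, method = "recursive"))
}

#' Generate one synthetic subject
#'
#' Each canonical variable follows the piecewise rest/ramp/recovery
#' trajectory for the subject's class (scaled by `cfg$delta` and a per-subject
#' log-normal multiplier) plus stationary AR(1) Gaussian noise.  By
#' construction, peak VO2 orders HF < MS < H in expectation whenever
#' `delta > 0`.
#'
#' @param cls condition, one of `"HF"`, `"MS"`, `"H"`.
#' @param cfg a [synthetic_config()].
#' @param seed integer seed for this subject's draws.
#' @param subject_id id string; default derives from class and seed.
#' @return a [cpet_record()] including all nine canonical variables and a
#'   time vector (minutes).
#' @export
generate_subject <- function(cls, cfg, seed,
                             subject_id = sprintf("%s_%06d", cls, seed)) {
  stopifnot(inherits(cfg, "cpet_synth_config"))
  cls <- match.arg(cls, c("HF", "MS", "H"))
  set.seed(as.integer(seed))
  lengths <- seq(cfg$n_breaths[1], cfg$n_breaths[2])
  n <- if (length(lengths) == 1L) lengths else sample(lengths, 1L)
  par <- synth_class_params(cls, cfg$delta)
  subj_mult <- exp(stats::rnorm(2L, sd = cfg$subject_sd))  # baseline, peak

  signals <- list()
  for (v in rownames(SYNTH_PARAMS)) {
    base <- par$base[[v]] * subj_mult[1]
    peak <- par$peak[[v]] * subj_mult[2]
    traj <- synth_trajectory(n, base, peak, cfg$phase_fractions,
                             cfg$recovery_tau_frac)
    noise <- ar1_noise(n, cfg$noise_sd_frac * par$noise_range[[v]], cfg$rho)
    signals[[v]] <- traj + noise
  }
  # breath-by-breath timestamps from the respiratory rate (breaths/min)
  time <- cumsum(1 / pmax(signals$RR, 1))
  cpet_record(subject_id, cls, signals, time = time)
}

#' Generate a full cohort, ordered HF block, then MS, then H
#'
#' @param cfg a [synthetic_config()].
#' @return list of `cpet_record`s of length
#'   `n_per_class * length(cfg$classes)`, grouped by class in the canonical
#'   block order.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cpet_synth_config"))
  classes <- intersect(c("HF", "MS", "H"), cfg$classes)
  records <- list()
  idx <- 0L
  for (cls in classes) {
    for (i in seq_len(cfg$n_per_class)) {
      idx <- idx + 1L
      subj_seed <- (cfg$seed %% 2000000L) * 1000L + idx   # < 2^31
      records[[idx]] <- generate_subject(
        cls, cfg, seed = subj_seed,
        subject_id = sprintf("%s_%02d", cls, i))
    }
  }
  records
}

#' Write a synthetic cohort as canonical CSV files plus a manifest
#'
#' Produces one canonical CSV per subject and a `manifest.csv`
#' (`subject_id,condition,filename`, HF/MS/H block order) consumable by
#' [load_cohort()]; the resolved generator configuration is echoed into
#' comment lines of the manifest for provenance.  Regenerating with the same
#' configuration yields byte-identical files.
#'
#' @param cfg a [synthetic_config()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_fixture_cohort <- function(cfg, dir) {
  stopifnot(inherits(cfg, "cpet_synth_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(cfg)
  files <- vapply(cohort, function(rec) {
    fn <- paste0(rec$subject_id, ".csv")
    write_cpet_csv(rec, file.path(dir, fn))
    fn
  }, "")
  cfg_echo <- vapply(names(unclass(cfg)), function(k)
    sprintf("# config: %s=%s", k, paste(cfg[[k]], collapse = ",")), "")
  manifest <- file.path(dir, "manifest.csv")
  writeLines(c(cfg_echo, "subject_id,condition,filename",
               sprintf("%s,%s,%s",
                       vapply(cohort, `[[`, "", "subject_id"),
                       vapply(cohort, `[[`, "", "condition"),
                       files)),
             manifest)
  invisible(manifest)
}
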