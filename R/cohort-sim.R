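#' Synthetic cohort configuration
#'
#' Defaults emulate a four-group valvular-disease study population: aortic
#' stenosis (AS, 69 subjects; severity mix 20.3/53.6/26.1% mild/moderate/
#' severe), moderate-to-severe mitral regurgitation (MR, 24), other
#' structural heart disease (SHD_other, 73) and controls (82). Covariates
#' (age, BMI, BSA) are drawn from skew-normal distributions fitted to each
#' group's quartiles; sex is Bernoulli with the group's female prevalence.
#' Indexed aortic valve area (AVAi, cm^2/m^2) decreases with AS severity;
#' murmur gain increases with severity.
#'
#' @param group_sizes named integer vector for groups `AS`, `MR`,
#'   `SHD_other`, `control`.
#' @param severity_mix named proportions over `mild`, `moderate`, `severe`
#'   for the AS group (must sum to 1).
#' @param covariate_params per-group list with elements `age`, `bmi`, `bsa`
#'   (each `(q25, q50, q75)`) and `sex_female_p`.
#' @param avai_by_severity named list mapping `severe`, `moderate`, `mild`,
#'   `none` to `(mean, sd)` of AVAi in cm^2/m^2.
#' @param murmur_gain_by_severity named vector mapping `none`, `mild`,
#'   `moderate`, `severe` to murmur gain.
#' @param mr_severity_mix proportions over `moderate`, `severe` for MR.
#' @param shd_murmur_gain nonspecific murmur gain for the SHD_other group.
#' @param site_gain per-group murmur attenuation by auscultation site.
#' @param subject_noise_factor extra handling-noise multiplier applied to the
#'   subject-collected recording's `noise_rms`.
#' @param duration_s,rate_hz audio clip length and sampling rate.
#' @param seed integer seed; identical config + seed reproduces the cohort
#'   bitwise.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(
    group_sizes = c(AS = 69, MR = 24, SHD_other = 73, control = 82),
    severity_mix = c(mild = 0.203, moderate = 0.536, severe = 0.261),
    covariate_params = default_covariate_params(),
    avai_by_severity = list(severe = c(0.5, 0.08), moderate = c(0.75, 0.1),
                            mild = c(1.0, 0.12), none = c(1.3, 0.2)),
    murmur_gain_by_severity = c(none = 0, mild = 0.3, moderate = 0.6,
                                severe = 1.0),
    mr_severity_mix = c(moderate = 0.875, severe = 0.125),
    shd_murmur_gain = 0.15,
    site_gain = list(AS = c(aortic = 1, axillary = 0.4),
                     MR = c(aortic = 0.4, axillary = 1),
                     SHD_other = c(aortic = 0.6, axillary = 0.6),
                     control = c(aortic = 1, axillary = 1)),
    subject_noise_factor = 1.2,
    duration_s = 30, rate_hz = 4000, seed = 20260101) {
  need <- c("AS", "MR", "SHD_other", "control")
  if (!all(need %in% names(group_sizes))) {
    stop("group_sizes must name AS, MR, SHD_other, control")
  }
  if (any(group_sizes < 0)) stop("group sizes must be >= 0")
  if (abs(sum(severity_mix) - 1) > 1e-9) stop("severity_mix must sum to 1")
  if (abs(sum(mr_severity_mix) - 1) > 1e-9) stop("mr_severity_mix must sum to 1")
  structure(list(group_sizes = group_sizes[need],
                 severity_mix = severity_mix,
                 covariate_params = covariate_params,
                 avai_by_severity = avai_by_severity,
                 murmur_gain_by_severity = murmur_gain_by_severity,
                 mr_severity_mix = mr_severity_mix,
                 shd_murmur_gain = shd_murmur_gain,
                 site_gain = site_gain,
                 subject_noise_factor = subject_noise_factor,
                 duration_s = duration_s, rate_hz = rate_hz,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_covariate_params <- function() {
  list(
    AS = list(age = c(69, 77, 82), bmi = c(25.6, 29.7, 33.7),
              bsa = c(1.84, 2.00, 2.15), sex_female_p = 0.391),
    MR = list(age = c(69, 77, 81), bmi = c(23.7, 25.6, 28.7),
              bsa = c(1.75, 1.88, 2.00), sex_female_p = 0.417),
    SHD_other = list(age = c(63, 73, 78), bmi = c(25.1, 28.7, 33.2),
                     bsa = c(1.77, 2.04, 2.19), sex_female_p = 0.452),
    control = list(age = c(63, 67, 76), bmi = c(25.1, 27.9, 32.2),
                   bsa = c(1.78, 1.95, 2.14), sex_female_p = 0.463)
  )
}

#' Generate a synthetic cohort
#'
#' Draws subject records for each group and synthesizes three recordings per
#' subject: `(aortic, personnel)`, `(axillary, personnel)` and
#' `(aortic, subject)`. The two aortic recordings are independent
#' realizations of the same subject's generative parameters; the
#' subject-collected one carries extra handling noise. Controls have murmur
#' gain 0; AS murmurs are ejection-type and strongest at the aortic site, MR
#' murmurs holosystolic and strongest at the axilla.
#'
#' @param config a [cohort_config()].
#' @return A `pcg_cohort`: list with `subjects` (data.frame: `id`, `group`,
#'   `severity`, `age`, `sex` (1 = female), `bmi`, `bsa`, `avai`),
#'   `recordings` (list of `pcg_recording`) and the `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  fits <- lapply(config$covariate_params, function(g) {
    list(age = fit_skewnorm_quartiles(g$age),
         bmi = fit_skewnorm_quartiles(g$bmi),
         bsa = fit_skewnorm_quartiles(g$bsa))
  })
  groups <- rep(names(config$group_sizes), times = config$group_sizes)
  n <- length(groups)
  ids <- sprintf("S%03d", seq_len(n))
  subjects <- NULL
  recordings <- vector("list", 3L * n)
  withr::with_seed(config$seed, {
    severity <- vapply(groups, function(g) {
      if (g == "AS") sample(names(config$severity_mix), 1,
                            prob = config$severity_mix)
      else if (g == "MR") sample(names(config$mr_severity_mix), 1,
                                 prob = config$mr_severity_mix)
      else "none"
    }, character(1))
    age <- numeric(n); bmi <- numeric(n); bsa <- numeric(n)
    sex <- integer(n); avai <- numeric(n)
    hr <- pmin(110, pmax(45, rnorm(n, 72, 8)))
    noise <- exp(rnorm(n, log(0.02), 0.2))
    gain_mult <- runif(n, 0.85, 1.15)
    for (i in seq_len(n)) {
      g <- groups[i]
      f <- fits[[g]]
      age[i] <- max(50, rskewnorm(1, f$age))
      bmi[i] <- max(15, rskewnorm(1, f$bmi))
      bsa[i] <- max(1.2, rskewnorm(1, f$bsa))
      sex[i] <- as.integer(runif(1) < config$covariate_params[[g]]$sex_female_p)
      sev_key <- if (g == "AS") severity[i] else "none"
      av <- config$avai_by_severity[[sev_key]]
      avai[i] <- max(0.15, rnorm(1, av[1], av[2]))
    }
    rec_seeds <- sample.int(.Machine$integer.max, 3L * n)
  })
  base_gain <- vapply(seq_len(n), function(i) {
    g <- groups[i]
    if (g == "AS" || g == "MR") {
      unname(config$murmur_gain_by_severity[[severity[i]]])
    } else if (g == "SHD_other") config$shd_murmur_gain else 0
  }, numeric(1)) * gain_mult
  envelope <- c(AS = "crescendo_decrescendo", MR = "holosystolic",
                SHD_other = "crescendo_decrescendo", control = "none")
  slots <- list(c("aortic", "personnel"), c("axillary", "personnel"),
                c("aortic", "subject"))
  k <- 0L
  for (i in seq_len(n)) {
    g <- groups[i]
    for (s in seq_along(slots)) {
      site <- slots[[s]][1]; src <- slots[[s]][2]
      gain <- base_gain[i] * unname(config$site_gain[[g]][[site]])
      env <- if (gain > 0) envelope[[g]] else "none"
      if (env == "none") gain <- 0
      hs <- heart_sound_params(
        heart_rate_bpm = hr[i],
        murmur_gain = gain,
        murmur_envelope = env,
        noise_rms = noise[i] *
          if (src == "subject") config$subject_noise_factor else 1)
      k <- k + 1L
      recordings[[k]] <- synthesize_pcg(
        hs, duration_s = config$duration_s, rate_hz = config$rate_hz,
        seed = rec_seeds[k], subject_id = ids[i], site = site, source = src)
    }
  }
  subjects <- data.frame(id = ids, group = groups, severity = severity,
                         age = age, sex = sex, bmi = bmi, bsa = bsa,
                         avai = avai, stringsAsFactors = FALSE,
                         row.names = NULL)
  structure(list(subjects = subjects, recordings = recordings,
                 config = config),
            class = "pcg_cohort")
}

#' Write / load a cohort as WAV files plus a subjects table
#'
#' One WAV per recording, named `<subject>_<site>_<source>.wav`, and
#' `subjects.csv` with columns id, group, severity, age, sex, bmi, bsa, avai.
#'
#' @param cohort a `pcg_cohort`.
#' @param dir output directory (created if needed).
#' @param bit_depth WAV sample format, see [write_wav()].
#' @return `write_cohort()` the directory, `load_cohort()` a `pcg_cohort`
#'   (without a config), both invisibly/directly.
#' @export
write_cohort <- function(cohort, dir, bit_depth = "float32") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  for (r in cohort$recordings) {
    fname <- sprintf("%s_%s_%s.wav", r$subject_id, r$site, r$source)
    write_wav(r, file.path(dir, fname), bit_depth = bit_depth)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
load_cohort <- function(dir) {
  subjects <- utils::read.csv(file.path(dir, "subjects.csv"),
                              stringsAsFactors = FALSE)
  wavs <- sort(list.files(dir, pattern = "\\.wav$", full.names = TRUE))
  recordings <- lapply(wavs, read_wav)
  structure(list(subjects = subjects, recordings = recordings, config = NULL),
            class = "pcg_cohort")
}

# --- skew-normal helpers -----------------------------------------------

# Owen's T function by 1-D quadrature; accurate enough for quantile fitting.
owen_t <- function(h, a) {
  if (a == 0) return(0)
  s <- sign(a); a <- abs(a)
  f <- function(x) exp(-0.5 * h^2 * (1 + x^2)) / (1 + x^2)
  s * integrate(f, 0, a, rel.tol = 1e-9)$value / (2 * pi)
}

sn_cdf <- function(z, alpha) pnorm(z) - 2 * owen_t(z, alpha)

sn_quantile <- function(p, alpha) {
  uniroot(function(z) sn_cdf(z, alpha) - p, lower = -12, upper = 12,
          tol = 1e-8)$root
}

# Fit (xi, omega, alpha) of a skew-normal to target quartiles by matching
# the quartile-asymmetry ratio, then location/scale. The achievable skew of
# the family is limited; alpha is clamped at +/-12 when the target ratio is
# more extreme.
fit_skewnorm_quartiles <- function(q) {
  stopifnot(length(q) == 3, q[1] < q[2], q[2] < q[3])
  target <- (q[3] - q[2]) / (q[2] - q[1])
  ratio <- function(alpha) {
    z <- vapply(c(0.25, 0.5, 0.75), sn_quantile, numeric(1), alpha = alpha)
    (z[3] - z[2]) / (z[2] - z[1])
  }
  lo <- -12; hi <- 12
  r_lo <- ratio(lo); r_hi <- ratio(hi)
  alpha <- if (target <= r_lo) lo else if (target >= r_hi) hi else {
    uniroot(function(a) ratio(a) - target, lower = lo, upper = hi,
            tol = 1e-4)$root
  }
  z <- vapply(c(0.25, 0.5, 0.75), sn_quantile, numeric(1), alpha = alpha)
  omega <- (q[3] - q[1]) / (z[3] - z[1])
  xi <- q[2] - omega * z[2]
  list(xi = xi, omega = omega, alpha = alpha)
}

rskewnorm <- function(n, fit) {
  delta <- fit$alpha / sqrt(1 + fit$alpha^2)
  u0 <- rnorm(n); u1 <- rnorm(n)
  z <- delta * abs(u0) + sqrt(1 - delta^2) * u1
  fit$xi + fit$omega * z
}
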