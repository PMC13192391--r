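#' Specification of a synthetic cell population
#'
#' Describes the surrogate "experimental" data set: how many cells, how
#' much multiplicative (log-normal) cell-to-cell variability on the two
#' calibrated conductances, the recording-noise level, slow drift, and the
#' RNG seed. The defaults emulate the experimental cohort size (n = 51) and
#' a conductance spread chosen so the plateau-duration coefficient of
#' variation is of the order seen across recorded cells (about 0.5; see the
#' methods vignette).
#'
#' @param n_cells number of cells.
#' @param sigma_g log-normal sigma applied multiplicatively to `gbar_cal`
#'   and `gbar_kca` (log scale).
#' @param noise_sigma Gaussian voltage noise, mV.
#' @param drift_amp slow sinusoidal drift amplitude, mV.
#' @param drift_period drift period, ms.
#' @param seed RNG seed, recorded in every output.
#' @return list of class `population_spec`.
#' @export
population_spec <- function(n_cells = 51, sigma_g = 0.12, noise_sigma = 0.5,
                            drift_amp = 0.5, drift_period = 1000,
                            seed = 1L) {
  stopifnot(n_cells >= 1, sigma_g >= 0, noise_sigma >= 0, drift_amp >= 0,
            drift_period > 0)
  structure(list(n_cells = as.integer(n_cells), sigma_g = sigma_g,
                 noise_sigma = noise_sigma, drift_amp = drift_amp,
                 drift_period = drift_period, seed = as.integer(seed)),
            class = "population_spec")
}

#' Corrupt a clean trace with recording-like noise
#'
#' Adds seeded Gaussian noise and a slow sinusoidal drift to the voltage
#' channel, emulating an experimental recording; all other channels are
#' left clean. The seed and noise parameters are recorded as attributes.
#'
#' @param trace a [simulate()] trace.
#' @param noise_sigma Gaussian noise standard deviation, mV.
#' @param drift_amp drift amplitude, mV.
#' @param drift_period drift period, ms.
#' @param seed RNG seed.
#' @return the corrupted `sim_trace`.
#' @export
corrupt_trace <- function(trace, noise_sigma, drift_amp = 0,
                          drift_period = 1000, seed = 1L) {
  stopifnot(inherits(trace, "sim_trace"))
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (drift_amp < 0) stop("drift_amp must be >= 0")
  out <- trace
  n <- nrow(out$data)
  noise <- withr::with_seed(as.integer(seed), stats::rnorm(n, 0, noise_sigma))
  phase <- withr::with_seed(as.integer(seed) + 1L, stats::runif(1, 0, 2 * pi))
  if (noise_sigma > 0) out$data$V <- out$data$V + noise
  if (drift_amp > 0) {
    out$data$V <- out$data$V +
      drift_amp * sin(2 * pi * out$data$t / drift_period + phase)
  }
  attr(out, "noise") <- list(noise_sigma = noise_sigma,
                             drift_amp = drift_amp,
                             drift_period = drift_period,
                             seed = as.integer(seed))
  out
}

#' Simulate a synthetic cell population
#'
#' Draws `n_cells` parameter sets by jittering the calibrated conductances
#' log-normally, simulates the plateau protocol in each, and tabulates the
#' plateau durations. Cells whose jittered parameters produce no plateau,
#' a nonrepolarizing plateau, or no stable rest are recorded with status
#' labels rather than dropped.
#'
#' @param spec a [population_spec()].
#' @param base calibrated [model_parameters()].
#' @param proto plateau protocol; when `NULL` a just-suprathreshold step
#'   protocol is found per cell.
#' @param cfg a [plateau_config()].
#' @return data.frame of class `population_table`, one row per cell:
#'   `cell`, `gbar_cal`, `gbar_kca`, `status`, `duration`; attributes
#'   `mean_duration`, `se_duration`, `n_plateau`, `spec`.
#' @export
sample_population <- function(spec, base = model_parameters(), proto = NULL,
                              cfg = plateau_config()) {
  stopifnot(inherits(spec, "population_spec"))
  mult <- withr::with_seed(spec$seed, matrix(
    exp(stats::rnorm(2 * spec$n_cells, 0, spec$sigma_g)), ncol = 2))
  rows <- lapply(seq_len(spec$n_cells), function(i) {
    pi_ <- update_parameters(base,
                             gbar_cal = base$gbar_cal * mult[i, 1],
                             gbar_kca = base$gbar_kca * mult[i, 2])
    row <- data.frame(cell = i, gbar_cal = pi_$gbar_cal,
                      gbar_kca = pi_$gbar_kca,
                      status = "plateau", duration = NA_real_)
    r <- tryCatch(initialize_rest(pi_), error = function(e) NULL)
    if (is.null(r) || r$V > pi_$E_pas + 15) { row$status <- "no_rest"; return(row) }
    m <- tryCatch({
      if (is.null(proto)) {
        find_plateau_step(pi_, rest = r, cfg = cfg)$metrics
      } else {
        detect_plateau(simulate(pi_, proto, init = r), cfg)
      }
    }, error = function(e) NULL)
    if (is.null(m) || !m$plateau_present) { row$status <- "no_plateau"; return(row) }
    if (m$nonrepolarizing) { row$status <- "nonrepolarizing"; return(row) }
    row$duration <- m$duration
    row
  })
  res <- do.call(rbind, rows)
  ok <- res$duration[is.finite(res$duration)]
  attr(res, "mean_duration") <- mean(ok)
  attr(res, "se_duration") <- stats::sd(ok) / sqrt(length(ok))
  attr(res, "n_plateau") <- length(ok)
  attr(res, "spec") <- spec
  class(res) <- c("population_table", class(res))
  res
}
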