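#' Grid-search calibration of the unprinted conductances
#'
#' The maximal VGCC scale and SK conductance density have no canonical
#' values; following the empirical approach, every cell of a log-spaced
#' (gbar_cal, gbar_kca) grid (optionally crossed with tau_r and cac) is
#' scored with an identical just-suprathreshold 50 ms step protocol and the
#' plateau duration is measured. Cells whose rest destabilizes (the
#' stimulus-free state settles far above E_pas), that evoke no plateau, or
#' whose plateau never repolarizes are labeled as such. The feasible set is
#' the cells with a repolarizing plateau inside the target duration band;
#' the selected cell is the feasible one closest to the band midpoint.
#'
#' @param base a [model_parameters()] object supplying every non-axis value.
#' @param axes named list of parameter grids; default 20-point log grids
#'   over `[1e-5, 1e-2]` for `gbar_cal` and `gbar_kca`.
#' @param target_band duration band, ms.
#' @param step_onset,step_width calibration step timing, ms.
#' @param duration simulated time per cell, ms.
#' @param cfg a [plateau_config()].
#' @param progress print a dot per grid row.
#' @return list of class `calibration_result`: `grid` (one row per cell:
#'   axis values, `status` in no_rest/no_plateau/nonrepolarizing/plateau,
#'   `duration`, `amplitude`, `rest_V`), `feasible` (subset in band),
#'   `selected` (list `params`, `duration`, `amplitude`), `target_band`.
#' @export
grid_search <- function(base = model_parameters(),
                        axes = list(gbar_cal = 10^seq(-5, -2, length.out = 20),
                                    gbar_kca = 10^seq(-5, -2, length.out = 20)),
                        target_band = c(100, 200),
                        step_onset = 20, step_width = 50, duration = 1500,
                        cfg = plateau_config(), progress = FALSE) {
  stopifnot(length(axes) >= 1, !is.null(names(axes)))
  for (a in axes) if (length(a) < 2 || is.unsorted(a, strictly = TRUE)) {
    stop("each axis must be a strictly increasing grid")
  }
  cells <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  n <- nrow(cells)
  status <- character(n); dur <- amp <- restv <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    p <- do.call(update_parameters, c(list(base), as.list(cells[i, , drop = FALSE])))
    r <- tryCatch(initialize_rest(p), error = function(e) NULL)
    if (is.null(r) || r$V > p$E_pas + 15) { status[i] <- "no_rest"; next }
    restv[i] <- r$V
    res <- tryCatch(
      find_plateau_step(p, rest = r, onset = step_onset, width = step_width,
                        duration = duration, cfg = cfg),
      error = function(e) NULL)
    if (is.null(res)) { status[i] <- "no_plateau"; next }
    amp[i] <- res$amplitude
    if (res$metrics$nonrepolarizing) {
      status[i] <- "nonrepolarizing"
    } else {
      status[i] <- "plateau"
      dur[i] <- res$metrics$duration
    }
    if (progress && i %% length(axes[[1]]) == 0) cat(".")
  }
  if (progress) cat("\n")
  grid <- cbind(cells, data.frame(status = status, duration = dur,
                                  amplitude = amp, rest_V = restv))
  feasible <- grid[grid$status == "plateau" &
                     !is.na(grid$duration) &
                     grid$duration >= target_band[1] &
                     grid$duration <= target_band[2], , drop = FALSE]
  if (nrow(feasible) == 0) {
    warning("empty feasible set: no cell in the ", target_band[1], "-",
            target_band[2], " ms band; inspect the duration landscape")
    selected <- NULL
  } else {
    mid <- mean(target_band)
    best <- feasible[which.min(abs(feasible$duration - mid)), , drop = FALSE]
    sel_par <- do.call(update_parameters,
                       c(list(base), as.list(best[, names(axes), drop = FALSE])))
    selected <- list(params = sel_par, duration = best$duration,
                     amplitude = best$amplitude)
  }
  structure(list(grid = grid, feasible = feasible, selected = selected,
                 target_band = target_band, axes = axes),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> %d cells, %d feasible in [%g, %g] ms\n",
              nrow(x$grid), nrow(x$feasible),
              x$target_band[1], x$target_band[2]))
  if (!is.null(x$selected)) {
    cat(sprintf("  selected: duration %.1f ms\n", x$selected$duration))
  }
  invisible(x)
}

#' Pharmacology analogs on the calibrated model
#'
#' Reruns the plateau protocol under channel-block conditions: the Cd2+
#' analog (gbar_cal = 0) at 1x and 3x the step amplitude, and the apamin
#' analog (gbar_kca = 0). Each condition is re-settled to its own rest; a
#' condition whose stimulus-free state sits more than 15 mV above the
#' baseline rest is reported as depolarized/nonrepolarizing.
#'
#' @param p calibrated [model_parameters()].
#' @param proto plateau protocol (from [find_plateau_step()]); built
#'   automatically when `NULL`.
#' @param cfg a [plateau_config()].
#' @return named list of conditions (`baseline`, `cal0_1x`, `cal0_3x`,
#'   `kca0`), each with `metrics` ([detect_plateau()]) and `trace`.
#' @export
pharmacology_scan <- function(p, proto = NULL, cfg = plateau_config()) {
  rest <- initialize_rest(p)
  if (is.null(proto)) {
    fs <- find_plateau_step(p, rest = rest, cfg = cfg)
    proto <- fs$proto
  }
  amp <- max(proto$steps[, "density"])
  scale_proto <- function(mult) {
    st <- proto$steps
    build_protocol(c(
      lapply(seq_len(nrow(st)), function(i)
        current_step(st[i, 1], st[i, 2], density = st[i, 3] * mult))),
      duration = proto$duration, settle = proto$settle, area = proto$area)
  }
  run <- function(pp, pr) {
    r <- initialize_rest(pp)
    tr <- simulate(pp, pr, init = r)
    m <- detect_plateau(tr, cfg)
    list(metrics = m, trace = tr, rest_V = r$V)
  }
  list(baseline = run(p, proto),
       cal0_1x = run(update_parameters(p, gbar_cal = 0), proto),
       cal0_3x = run(update_parameters(p, gbar_cal = 0), scale_proto(3)),
       kca0 = run(update_parameters(p, gbar_kca = 0), proto))
}
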