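#' Load a run configuration
#'
#' Reads a YAML configuration with up to four blocks -- `parameters`
#' (fields of [model_parameters()]), `protocol` (`events` list plus
#' `duration`/`settle`), `analysis` (fields of [plateau_config()] plus
#' `tau_syn`, `rel_tol`, `seed`) and `output` (directory) -- validates
#' every key, fills defaults, and applies command-line style overrides
#' (file < overrides). Unknown keys are errors that name the key.
#'
#' @param path YAML file path; an empty or missing-block file yields all
#'   defaults.
#' @param overrides named list merged over the file contents, using
#'   dotted keys (`"parameters.gbar_cal"`).
#' @return list of class `run_config` with elements `params`
#'   ([model_parameters()]), `proto` ([build_protocol()] or `NULL` when no
#'   protocol block is given), `analysis` (list), `output` (list), and
#'   `raw` (the resolved key-value tree).
#' @examples
#' cfg <- load_config(system.file("extdata", "example-config.yaml",
#'                                package = "plateaukit"))
#' cfg$params$gbar_kca
#' @export
load_config <- function(path, overrides = list()) {
  raw <- if (file.exists(path)) yaml::read_yaml(path) else
    stop("config file not found: ", path)
  if (is.null(raw)) raw <- list()
  for (key in names(overrides)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("override keys use block.field form: ", key)
    raw[[parts[1]]][[parts[2]]] <- overrides[[key]]
  }
  known_blocks <- c("parameters", "protocol", "analysis", "output")
  unknown <- setdiff(names(raw), known_blocks)
  if (length(unknown)) stop("unknown config block(s): ",
                            paste(unknown, collapse = ", "))

  # YAML 1.1 floats require a dot before the exponent; numbers written as
  # "2e-5" arrive as strings, so coerce numeric-looking scalars
  coerce_num <- function(x) {
    if (is.character(x) && length(x) == 1 &&
        grepl("^[+-]?([0-9]*\\.?[0-9]+)([eE][+-]?[0-9]+)?$", x)) {
      as.numeric(x)
    } else x
  }
  par_fields <- names(formals(model_parameters))
  pb <- lapply(raw$parameters %||% list(), coerce_num)
  bad <- setdiff(names(pb), par_fields)
  if (length(bad)) stop("unknown parameter key(s): ",
                        paste(bad, collapse = ", "))
  params <- do.call(model_parameters, pb)

  proto <- NULL
  if (!is.null(raw$protocol)) {
    prb <- raw$protocol
    bad <- setdiff(names(prb), c("events", "duration", "settle"))
    if (length(bad)) stop("unknown protocol key(s): ",
                          paste(bad, collapse = ", "))
    events <- lapply(prb$events %||% list(), function(ev) {
      kind <- ev$kind %||% stop("protocol event without `kind`")
      ev$kind <- NULL
      ev <- lapply(ev, coerce_num)
      ctor <- switch(kind, step = current_step, ipsp = mock_ipsp,
                     ipsg = ipsg_event, stop("unknown event kind: ", kind))
      bad <- setdiff(names(ev), names(formals(ctor)))
      if (length(bad)) stop("unknown event key(s): ",
                            paste(bad, collapse = ", "))
      do.call(ctor, ev)
    })
    proto <- build_protocol(events,
                            duration = prb$duration %||% 1000,
                            settle = prb$settle %||% 2000,
                            area = params$area)
  }

  an_fields <- c(names(formals(plateau_config)), "tau_syn", "rel_tol", "seed")
  ab <- raw$analysis %||% list()
  bad <- setdiff(names(ab), an_fields)
  if (length(bad)) stop("unknown analysis key(s): ",
                        paste(bad, collapse = ", "))
  cfg <- do.call(plateau_config, ab[intersect(names(ab),
                                              names(formals(plateau_config)))])
  analysis <- list(cfg = cfg, tau_syn = ab$tau_syn %||% 5,
                   rel_tol = ab$rel_tol %||% 0.005,
                   seed = ab$seed %||% 1L)

  ob <- raw$output %||% list()
  bad <- setdiff(names(ob), c("dir"))
  if (length(bad)) stop("unknown output key(s): ", paste(bad, collapse = ", "))

  structure(list(params = params, proto = proto, analysis = analysis,
                 output = list(dir = ob$dir %||% "results"),
                 raw = raw),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the fully resolved configuration back to YAML
#'
#' @param config a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  resolved <- config$raw
  resolved$parameters <- unclass(config$params)[
    setdiff(names(formals(model_parameters)), "ca_drive_clamp")]
  resolved$parameters$ca_drive_clamp <- config$params$ca_drive_clamp
  yaml::write_yaml(resolved, path, precision = 17)
  invisible(path)
}

#' Trace CSV input/output
#'
#' Traces are stored as plain CSV with commented (`#`) header lines echoing
#' the model parameters and protocol, followed by the full sample table at
#' 17 significant digits, so `read_trace(write_trace(x))` reproduces every
#' stored value bit-identically. Columns are keyed by header name, so
#' permuted column order still parses.
#'
#' @param trace a [simulate()] trace.
#' @param path file path.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns a
#'   `sim_trace` (with `params` restored through [model_parameters()] and
#'   an echo of the protocol in `attr(x, "protocol_echo")`).
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "sim_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  p <- trace$params
  par_fields <- setdiff(names(formals(model_parameters)), "ca_drive_clamp")
  kv <- paste(par_fields,
              vapply(par_fields, function(f) sprintf("%.17g", p[[f]]), ""),
              sep = "=", collapse = " ")
  writeLines(c(
    sprintf("# plateaukit trace v1"),
    sprintf("# params %s ca_drive_clamp=%s", kv, p$ca_drive_clamp),
    sprintf("# protocol duration=%.17g settle=%.17g steps=%d ipsps=%d ipsgs=%d",
            trace$protocol$duration, trace$protocol$settle,
            nrow(trace$protocol$steps), nrow(trace$protocol$ipsps),
            nrow(trace$protocol$ipsgs)),
    sprintf("# dt %.17g", trace$dt),
    sprintf("# rest V=%.17g m_cal=%.17g m_kca=%.17g cai=%.17g",
            trace$rest$V, trace$rest$m_cal, trace$rest$m_kca,
            trace$rest$cai)), con)
  d <- trace$data
  writeLines(paste(names(d), collapse = ","), con)
  cols <- lapply(d, function(x) sprintf("%.17g", x))
  writeLines(do.call(paste, c(cols, sep = ",")), con)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  if (!length(hdr) || !grepl("plateaukit trace", lines[1])) {
    stop("not a plateaukit trace file (line 1): ", path)
  }
  body <- lines[-hdr]
  if (!length(body)) stop("no data rows in ", path)
  cols <- strsplit(body[1], ",")[[1]]
  need <- c("t", "V", "m_cal", "m_kca", "cai", "g_syn", "I_pas", "I_VGCC",
            "I_KCa", "I_GABA", "I_inj", "I_sum")
  missing <- setdiff(need, cols)
  if (length(missing)) {
    stop("trace schema error at line ", hdr[length(hdr)] + 1,
         ": missing column(s) ", paste(missing, collapse = ", "))
  }
  mat <- utils::read.csv(textConnection(body), header = TRUE,
                         colClasses = "numeric")
  pl <- sub("^# params ", "", lines[grep("^# params ", lines)[1]])
  kv <- strsplit(strsplit(pl, " ")[[1]], "=")
  vals <- stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
  num <- suppressWarnings(lapply(vals[names(vals) != "ca_drive_clamp"],
                                 as.numeric))
  num$ca_drive_clamp <- identical(vals$ca_drive_clamp, "TRUE")
  params <- do.call(model_parameters,
                    num[intersect(names(num), names(formals(model_parameters)))])
  rl <- lines[grep("^# rest ", lines)[1]]
  rv <- strsplit(strsplit(sub("^# rest ", "", rl), " ")[[1]], "=")
  rest <- stats::setNames(lapply(rv, function(x) as.numeric(x[2])),
                          vapply(rv, `[`, "", 1))
  dt <- as.numeric(sub("^# dt ", "", lines[grep("^# dt ", lines)[1]]))
  out <- structure(list(data = mat, params = params, protocol = NULL,
                        dt = dt,
                        rest = model_state(V = rest$V, m_cal = rest$m_cal,
                                           m_kca = rest$m_kca,
                                           cai = rest$cai)),
                   class = "sim_trace")
  attr(out, "protocol_echo") <- lines[grep("^# protocol ", lines)[1]]
  out
}

#' Write an analysis summary as JSON
#'
#' Fixed, documented key names so downstream consumers are format-stable;
#' scalars are written unboxed.
#'
#' @param x named list of scalars/vectors/data.frames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Write a sweep result as tidy CSV
#'
#' @param sweep a `sweep_result` (or any data.frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  utils::write.csv(as.data.frame(sweep), path, row.names = FALSE)
  invisible(path)
}
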