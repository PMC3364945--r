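## Flat serialized form of a SimulationConfig: exactly the documented
## field names, gating and domain parameters inlined.
.configToList <- function(config) {
  c(as.list(config@gating@rates),
    list(c0 = config@domain@c0, c1 = config@domain@c1,
         c_high = config@domain@c_high, k = config@domain@k,
         n_channels = config@n_channels, ip3 = config@ip3,
         dt = config@dt, record_dt = config@record_dt,
         duration = config@duration, burn_in = config@burn_in,
         seed = config@seed))
}

.configFromList <- function(values) {
  defaults <- .configToList(simulationConfig())
  unknown <- setdiff(names(values), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  bad <- names(values)[!vapply(values, function(v)
    is.numeric(v) && length(v) == 1L && is.finite(v), logical(1L))]
  if (length(bad))
    stop("config key(s) not finite scalars: ", paste(bad, collapse = ", "),
         call. = FALSE)
  v <- modifyList(defaults, values)
  gating <- tryCatch(
    do.call(gatingParameters, v[.GATING_FIELDS]),
    error = function(e) stop("invalid gating parameters: ",
                             conditionMessage(e), call. = FALSE))
  domain <- tryCatch(
    microdomainParameters(c0 = v$c0, c1 = v$c1, c_high = v$c_high, k = v$k),
    error = function(e) stop("invalid microdomain parameters: ",
                             conditionMessage(e), call. = FALSE))
  simulationConfig(n_channels = v$n_channels, ip3 = v$ip3, gating = gating,
                   domain = domain, dt = v$dt, record_dt = v$record_dt,
                   duration = v$duration, burn_in = v$burn_in, seed = v$seed)
}

#' Load and save simulation configurations
#'
#' Configurations are stored as a flat JSON object whose keys are exactly
#' the parameter field names (the ten gating rates, \code{c0}, \code{c1},
#' \code{c_high}, \code{k}, \code{n_channels}, \code{ip3}, \code{dt},
#' \code{record_dt}, \code{duration}, \code{burn_in}, \code{seed}).  Any
#' key may be omitted; missing keys take the package defaults, and an
#' empty file (or empty object) yields the full default configuration
#' (20 channels, ip3 = 0.07 uM, k = 100/s).  Loading validates every
#' invariant -- positivity, the detailed-balance loop, the time-step rule
#' -- and reports the offending key(s) on failure.  The derived
#' dissociation constants are attached as attribute
#' \code{"dissociation_constants"}.
#'
#' @param path file path.
#' @return \code{loadConfig}: a validated [SimulationConfig-class].
#' @examples
#' f <- tempfile(fileext = ".json")
#' saveConfig(simulationConfig(seed = 9), f)
#' cfg <- loadConfig(f)
#' attr(cfg, "dissociation_constants")
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  values <- if (!nzchar(trimws(txt))) list() else
    tryCatch(jsonlite::fromJSON(txt, simplifyVector = TRUE),
             error = function(e) stop("cannot parse config file ", path,
                                      ": ", conditionMessage(e),
                                      call. = FALSE))
  if (!is.list(values) && length(values) == 0L) values <- list()
  config <- .configFromList(as.list(values))
  attr(config, "dissociation_constants") <-
    dissociationConstants(config@gating)
  config
}

#' @rdname loadConfig
#' @param config a [SimulationConfig-class] object.
#' @export
saveConfig <- function(config, path) {
  stopifnot(is(config, "SimulationConfig"))
  jsonlite::write_json(.configToList(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write and read simulation traces
#'
#' Traces are stored as tab-separated text with a commented manifest
#' header: the package version, the RNG seed, and the full configuration
#' (flat JSON on one line), followed by the columns \code{time_s},
#' \code{n_open}, \code{c_uM}, \code{n111}, \code{n011}, \code{n_avail}.
#' The round trip is lossless for both the samples and the configuration,
#' so any trace file can be reproduced exactly from its own header.
#'
#' @param trace a [Trace-class] object.
#' @param path file path.
#' @return \code{readTrace}: the reconstructed [Trace-class].
#' @examples
#' tr <- makeFixtureTrace("two-puffs")
#' f <- tempfile(fileext = ".tsv")
#' writeTrace(tr, f)
#' identical(traceFrame(readTrace(f)), traceFrame(tr))
#' @export
writeTrace <- function(trace, path) {
  stopifnot(is(trace, "Trace"))
  con <- file(path, "w")
  on.exit(close(con))
  cfg_json <- jsonlite::toJSON(.configToList(trace@config),
                               auto_unbox = TRUE, digits = NA)
  writeLines(c(
    sprintf("# ip3rpuff trace v%s",
            as.character(utils::packageVersion("ip3rpuff"))),
    sprintf("# seed=%d", trace@config@seed),
    sprintf("# config=%s", as.character(cfg_json))), con)
  write.table(format(traceFrame(trace), digits = 17, scientific = FALSE,
                     trim = TRUE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrace
#' @export
readTrace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  header <- grep("^#", lines)
  if (length(header) == 0L || !grepl("^# ip3rpuff trace", lines[1L]))
    stop("parse error at line 1: not an ip3rpuff trace file")
  cfg_line <- grep("^# config=", lines, value = TRUE)
  if (length(cfg_line) != 1L)
    stop(sprintf("parse error at line %d: missing '# config=' header",
                 length(header) + 1L))
  config <- .configFromList(as.list(jsonlite::fromJSON(
    sub("^# config=", "", cfg_line), simplifyVector = TRUE)))
  body <- lines[-header]
  expected <- c("time_s", "n_open", "c_uM", "n111", "n011", "n_avail")
  if (length(body) == 0L ||
      !identical(strsplit(body[1L], "\t")[[1L]], expected))
    stop(sprintf("parse error at line %d: expected column header '%s'",
                 length(header) + 1L, paste(expected, collapse = "\t")))
  df <- tryCatch(
    read.table(text = body, header = TRUE, sep = "\t",
               colClasses = c("numeric", "integer", "numeric", "integer",
                              "integer", "integer")),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (anyNA(df))
    stop(sprintf("parse error at line %d: incomplete row",
                 length(header) + 1L + which(rowSums(is.na(df)) > 0)[1L]))
  new("Trace", time = df$time_s, n_open = df$n_open, c = df$c_uM,
      n111 = df$n111, n011 = df$n011, n_avail = df$n_avail,
      config = config)
}

#' Deterministic fixture traces with known event structure
#'
#' Small synthetic open-channel traces for exercising the event detector:
#' \describe{
#'   \item{"silent"}{2 s of zeros: no events.}
#'   \item{"two-puffs"}{activity on [0.1, 0.2] s and [0.8, 0.9] s
#'     separated by a 0.6 s quiet gap (>= the 500 ms window): exactly two
#'     events of lifetime 0.1 s.}
#'   \item{"merged-burst"}{activity on [0.1, 0.2] s and [0.5, 0.6] s
#'     separated by a 0.3 s gap (< 500 ms): exactly one event spanning
#'     0.1--0.6 s.}
#' }
#' All fixtures are sampled at 10 ms and end with at least 1 s of quiet so
#' the final event's termination is certifiable.
#'
#' @param kind one of "two-puffs", "merged-burst", "silent".
#' @return a [Trace-class] object.
#' @export
makeFixtureTrace <- function(kind = c("two-puffs", "merged-burst",
                                      "silent")) {
  kind <- match.arg(kind)
  record_dt <- 0.01
  time <- seq(0, 2, by = record_dt)
  n_open <- integer(length(time))
  window <- function(from, to, level)
    n_open[time >= from & time <= to] <<- level
  if (kind == "two-puffs") {
    window(0.1, 0.2, 3L)
    window(0.8, 0.9, 2L)
  } else if (kind == "merged-burst") {
    window(0.1, 0.2, 5L)
    window(0.5, 0.6, 1L)
  }
  config <- simulationConfig(record_dt = record_dt, duration = 2,
                             burn_in = 0)
  dom <- config@domain
  c_traj <- numeric(length(time))
  c_traj[1L] <- dom@c0
  for (s in 2:length(time)) {
    d <- domainState(c_traj[s - 1L], n_open[s - 1L])
    d <- onOpenCountChange(d, n_open[s], dom)
    c_traj[s] <- advanceConcentration(d, record_dt, dom)$c
  }
  n <- length(time)
  new("Trace", time = time, n_open = n_open, c = c_traj,
      n111 = integer(n), n011 = integer(n),
      n_avail = rep(config@n_channels, n), config = config)
}
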