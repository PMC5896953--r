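#' Write a session to its on-disk layout
#'
#' The layout is a directory holding one `session.json` sidecar plus one
#' tab-separated trace table per channel (`chan1.tsv`, `chan2.tsv`) with the
#' header `time_s<TAB>value`.  Sweeps of a channel are stacked in listing
#' order; the sidecar records per-sweep sample counts, start times, units and
#' epochs so the stack can be split again.  Values are printed with 17
#' significant digits, so a write/read/write cycle is byte identical and
#' sample values round-trip exactly.
#'
#' @param session A [recording_session()].
#' @param path Directory to create (must not be an existing non-directory).
#' @return Invisibly, `path`.
#' @export
write_session <- function(session, path) {
  if (!inherits(session, "gc_session"))
    stop("session must be a gc_session", call. = FALSE)
  if (file.exists(path) && !dir.exists(path))
    stop("path exists and is not a directory: ", path, call. = FALSE)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path))
    stop("could not create session directory: ", path, call. = FALSE)

  chans <- vapply(session$sweeps, function(s) s$channel, 1L)
  uch <- sort(unique(chans))
  # time-critical numerics go into the sidecar as %.17g strings: JSON
  # writers round doubles to ~15 significant digits, which would break the
  # bit-exact round trip of sweep clocks and stimulus times
  g17 <- function(x) sprintf("%.17g", x)
  sweep_index <- lapply(seq_along(session$sweeps), function(i) {
    s <- session$sweeps[[i]]
    list(id = if (is.na(s$id)) sprintf("sw%03d", i) else s$id,
         channel = s$channel, n = length(s$samples),
         t0 = g17(s$t0), sampling_rate = g17(s$sampling_rate),
         signal_kind = s$signal_kind, epoch = s$epoch)
  })
  for (ch in uch) {
    sw <- session$sweeps[chans == ch]
    tim <- unlist(lapply(sw, sweep_times))
    val <- unlist(lapply(sw, `[[`, "samples"))
    con <- file(file.path(path, sprintf("chan%d.tsv", ch)), "wb")
    writeLines(c("time_s\tvalue",
                 paste(sprintf("%.17g", tim), sprintf("%.17g", val),
                       sep = "\t")), con)
    close(con)
  }
  sidecar <- list(
    format = "gcdspike-session", version = 1L,
    channels = uch,
    sites = lapply(session$sites, unclass),
    protocol = list(label = session$protocol$label,
                    pulse_times = g17(session$protocol$pulse_times),
                    params = session$protocol$params),
    sweeps = sweep_index,
    metadata = session$metadata)
  jsonlite::write_json(sidecar, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Read a session written by [write_session()]
#'
#' Validates the layout: a missing sidecar is a format error; a trace table
#' whose time column is not uniformly increasing at the recorded sampling
#' rate, or an unknown signal kind, is a validation error.
#'
#' @param path Session directory.
#' @return A [recording_session()]; sample values equal the written ones.
#' @export
read_session <- function(path) {
  sidecar_path <- file.path(path, "session.json")
  if (!file.exists(sidecar_path))
    stop("not a session directory (missing session.json): ", path,
         call. = FALSE)
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  if (!identical(sc$format, "gcdspike-session"))
    stop("unrecognized session format in ", sidecar_path, call. = FALSE)

  tables <- lapply(sc$channels, function(ch) {
    f <- file.path(path, sprintf("chan%d.tsv", ch))
    if (!file.exists(f))
      stop("missing trace table: ", f, call. = FALSE)
    tab <- utils::read.table(f, header = TRUE, sep = "\t",
                             colClasses = "numeric")
    if (!identical(names(tab), c("time_s", "value")))
      stop("trace table must have columns time_s, value: ", f, call. = FALSE)
    tab
  })
  names(tables) <- as.character(sc$channels)
  offsets <- stats::setNames(rep(0L, length(sc$channels)),
                             as.character(sc$channels))

  sweeps <- lapply(sc$sweeps, function(si) {
    si$t0 <- as.numeric(si$t0)
    si$sampling_rate <- as.numeric(si$sampling_rate)
    kind <- si$signal_kind
    if (!kind %in% c("voltage", "current"))
      stop("unknown signal_kind '", kind, "' in sidecar", call. = FALSE)
    key <- as.character(si$channel)
    tab <- tables[[key]]
    idx <- offsets[[key]] + seq_len(si$n)
    if (max(idx) > nrow(tab))
      stop("trace table for channel ", key,
           " shorter than the sidecar sweep index", call. = FALSE)
    offsets[[key]] <<- offsets[[key]] + si$n
    tt <- tab$time_s[idx]
    dt <- diff(tt)
    if (any(dt <= 0))
      stop("time column must be strictly increasing within a sweep",
           call. = FALSE)
    if (max(abs(dt - 1 / si$sampling_rate)) > 1e-6 / si$sampling_rate +
        1e-9 * abs(tt[length(tt)]))
      stop("non-uniform sampling in channel ", key, " (expected ",
           si$sampling_rate, " Hz)", call. = FALSE)
    new_sweep(tab$value[idx], si$sampling_rate, kind, t0 = si$t0,
              channel = si$channel,
              epoch = if (is.null(si$epoch)) NA_character_ else si$epoch,
              id = si$id, strict = FALSE)
  })
  for (key in names(tables))
    if (offsets[[key]] != nrow(tables[[key]]))
      stop("trace table for channel ", key,
           " longer than the sidecar sweep index", call. = FALSE)

  sites <- lapply(sc$sites, function(s)
    recording_site(s$kind, s$distance_um, strict = FALSE))
  protocol <- stim_protocol(
    as.numeric(unlist(sc$protocol$pulse_times) %||% character(0)),
    sc$protocol$label, params = sc$protocol$params)
  metadata <- sc$metadata %||% list()
  recording_session(sweeps, protocol, sites, metadata)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
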