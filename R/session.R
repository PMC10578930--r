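#' Experimental sessions and their persistence
#'
#' A `session` bundles the named objects of one recording session (epoch
#' sets, event series, signals, frames, event groups) with free-form
#' metadata (strain, experimenter, ...). [save_session()] writes it to a
#' single JSON container file; [load_session()] reads it back bit-exactly.
#'
#' The on-disk contract is a JSON document with top-level keys `format`,
#' `name`, `metadata` and `objects`; each object is tagged with its type
#' and serialized field by field, mirroring an `epochs` / `series` /
#' `groups` grouping. All numbers are written as decimal strings with 17
#' significant digits, which round-trips IEEE doubles exactly — loading a
#' saved session reproduces every time, value, support and metadata entry
#' bit for bit. Built-in loaders assume all streams already share time
#' zero; synchronizing different acquisition clocks is the responsibility
#' of whoever writes a custom loader.
#'
#' @param name Session name.
#' @param objects Named list of package objects.
#' @param metadata Named list of scalar metadata (character or numeric).
#' @return A `session` object.
#' @examples
#' s <- session("demo",
#'              objects = list(wake = epoch_set(0, 600)),
#'              metadata = list(strain = "C57BL/6"))
#' @export
session <- function(name, objects = list(), metadata = list()) {
  if (length(objects)) {
    if (is.null(names(objects)) || anyDuplicated(names(objects)) ||
        any(names(objects) == "")) {
      stop("'objects' must have unique non-empty names")
    }
    for (nm in names(objects)) validate_object(objects[[nm]], nm)
  }
  structure(list(name = name, objects = objects, metadata = metadata),
            class = "session")
}

validate_object <- function(x, name) {
  if (inherits(x, "epoch_set")) {
    validate_epoch_set(x, name)
  } else if (inherits(x, c("ts_events", "ts_signal", "ts_frame"))) {
    validate_series(x, name)
  } else if (inherits(x, "event_group")) {
    validate_epoch_set(x$time_support, name)
    for (u in x$units) validate_series(u, name)
  } else {
    stop("object '", name, "' is not a supported session object")
  }
  invisible(TRUE)
}

#' @export
print.session <- function(x, ...) {
  cat("session '", x$name, "' with ", length(x$objects), " object(s)\n",
      sep = "")
  session_info(x)
  invisible(x)
}

#' One-line inventory of a session's objects
#'
#' @param s A `session`, or a path to a saved session container.
#' @param format Loader to use when `s` is a path.
#' @return The session, invisibly; prints name, type, size, support
#'   duration and (for groups) unit rates.
#' @export
session_info <- function(s, format = "neurotime") {
  if (is.character(s)) s <- load_session(s, format)
  for (nm in names(s$objects)) {
    x <- s$objects[[nm]]
    desc <- if (inherits(x, "epoch_set")) {
      paste0("epoch_set    ", n_intervals(x), " interval(s), ",
             format(total_duration(x)), " s")
    } else if (inherits(x, "event_group")) {
      paste0("event_group  ", length(x), " unit(s), rates [",
             paste(signif(x$metadata$rate, 3), collapse = ", "), "] Hz")
    } else {
      paste0(format(class(x)[1], width = 12), " ", length(x),
             " sample(s) on ", format(total_duration(x$time_support)), " s")
    }
    cat("  ", format(nm, width = 14), desc, "\n")
  }
  invisible(s)
}

# ---- serialization helpers: doubles as %.17g strings (bit-exact) --------

num_out <- function(x) sprintf("%.17g", as.numeric(x))
num_in <- function(x) as.numeric(unlist(x))

ep_out <- function(ep) {
  o <- list(type = "epoch_set", start = num_out(ep$start),
            end = num_out(ep$end))
  if (!is.null(ep$label)) o$label <- as.character(ep$label)
  o
}

ep_in <- function(o) {
  ep <- list(start = num_in(o$start), end = num_in(o$end))
  if (!is.null(o$label)) ep$label <- unlist(o$label)
  class(ep) <- "epoch_set"
  ep
}

serialize_object <- function(x) {
  if (inherits(x, "epoch_set")) return(ep_out(x))
  if (inherits(x, "ts_events")) {
    return(list(type = "ts_events", times = num_out(x$times),
                time_support = ep_out(x$time_support)))
  }
  if (inherits(x, "ts_signal")) {
    return(list(type = "ts_signal", times = num_out(x$times),
                values = num_out(x$values),
                time_support = ep_out(x$time_support)))
  }
  if (inherits(x, "ts_frame")) {
    return(list(type = "ts_frame", times = num_out(x$times),
                columns = colnames(x$values),
                values = num_out(as.numeric(x$values)),
                time_support = ep_out(x$time_support)))
  }
  if (inherits(x, "event_group")) {
    meta <- x$metadata[setdiff(names(x$metadata), c("unit_id", "rate"))]
    return(list(type = "event_group",
                unit_ids = as.integer(unit_ids(x)),
                units = lapply(x$units, function(u) num_out(u$times)),
                time_support = ep_out(x$time_support),
                metadata = lapply(meta, function(v) {
                  if (is.numeric(v)) list(kind = "numeric", data = num_out(v))
                  else list(kind = "character", data = as.character(v))
                })))
  }
  stop("unsupported object type: ", paste(class(x), collapse = "/"))
}

deserialize_object <- function(o, name) {
  x <- switch(
    o$type,
    epoch_set = ep_in(o),
    ts_events = structure(list(times = num_in(o$times),
                               time_support = ep_in(o$time_support)),
                          class = "ts_events"),
    ts_signal = structure(list(times = num_in(o$times),
                               values = num_in(o$values),
                               time_support = ep_in(o$time_support)),
                          class = "ts_signal"),
    ts_frame = {
      tm <- num_in(o$times)
      v <- matrix(num_in(o$values), nrow = length(tm),
                  dimnames = list(NULL, unlist(o$columns)))
      structure(list(times = tm, values = v,
                     time_support = ep_in(o$time_support)),
                class = "ts_frame")
    },
    event_group = {
      sup <- ep_in(o$time_support)
      units <- lapply(o$units, function(tt) {
        structure(list(times = num_in(tt), time_support = sup),
                  class = "ts_events")
      })
      names(units) <- as.character(unlist(o$unit_ids))
      g <- event_group(units, time_support = sup)
      for (nm in names(o$metadata)) {
        mv <- o$metadata[[nm]]
        vals <- if (identical(mv$kind, "numeric")) num_in(mv$data)
                else unlist(mv$data)
        names(vals) <- as.character(unlist(o$unit_ids))
        g <- set_metadata(g, nm, vals)
      }
      g
    },
    stop("unknown object type '", o$type, "'")
  )
  validate_object(x, name)
  x
}

#' Save a session to a JSON container file
#'
#' @param s A [session].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_session <- function(s, path) {
  if (!inherits(s, "session")) stop("'s' must be a session")
  doc <- list(format = "neurotime-session-v1",
              name = s$name,
              metadata = lapply(s$metadata, function(v) {
                if (is.numeric(v)) list(kind = "numeric", data = num_out(v))
                else list(kind = "character", data = as.character(v))
              }),
              objects = lapply(s$objects, serialize_object))
  writeLines(jsonlite::toJSON(doc, auto_unbox = FALSE, null = "null"), path)
  invisible(path)
}

# ---- loader registry ----------------------------------------------------

the_loaders <- new.env(parent = emptyenv())

load_neurotime_session <- function(path) {
  doc <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                            simplifyVector = TRUE, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  if (!identical(unlist(doc$format), "neurotime-session-v1")) {
    stop("not a neurotime session container: ", path)
  }
  objects <- list()
  for (nm in names(doc$objects)) {
    objects[[nm]] <- tryCatch(
      deserialize_object(doc$objects[[nm]], nm),
      error = function(e) stop("corrupt container: object '", nm, "': ",
                               conditionMessage(e), call. = FALSE))
  }
  metadata <- lapply(doc$metadata, function(mv) {
    v <- if (identical(unlist(mv$kind), "numeric")) num_in(unlist(mv$data))
         else unlist(mv$data)
    v
  })
  session(unlist(doc$name), objects, metadata)
}

load_csv_session <- function(path) {
  if (!dir.exists(path)) stop("'", path, "' is not a directory")
  objects <- list()
  for (f in list.files(path, pattern = "^epochs_.*\\.csv$")) {
    nm <- sub("^epochs_(.*)\\.csv$", "\\1", f)
    objects[[nm]] <- read_epochs_csv(file.path(path, f))
  }
  for (f in list.files(path, pattern = "^tracking_.*\\.csv$")) {
    nm <- sub("^tracking_(.*)\\.csv$", "\\1", f)
    objects[[nm]] <- read_tracking_csv(file.path(path, f))
  }
  session(basename(path), objects)
}

#' Register a custom session loader
#'
#' Adds a loader to the registry under `format_name`, after which
#' `load_session(path, format_name)` dispatches to it. The built-in
#' formats are `"neurotime"` (the JSON container written by
#' [save_session()]) and `"csv_session"` (a directory of
#' `epochs_<name>.csv` / `tracking_<name>.csv` files). Re-registering an
#' existing name is rejected.
#'
#' @param name Format name.
#' @param fn Function `path -> session`.
#' @return The format name, invisibly.
#' @export
register_loader <- function(name, fn) {
  if (name %in% loader_names()) {
    stop("a loader named '", name, "' is already registered")
  }
  if (!is.function(fn)) stop("'fn' must be a function(path)")
  assign(name, fn, envir = the_loaders)
  invisible(name)
}

#' @rdname register_loader
#' @export
loader_names <- function() {
  sort(c("neurotime", "csv_session", ls(the_loaders)))
}

#' Load a session through the loader registry
#'
#' @param path Path to a container file or session directory.
#' @param format Registered format name (see [register_loader()]).
#' @return A [session]; every contained object is validated on load.
#' @export
load_session <- function(path, format = "neurotime") {
  fn <- switch(format,
               neurotime = load_neurotime_session,
               csv_session = load_csv_session,
               if (exists(format, envir = the_loaders)) {
                 get(format, envir = the_loaders)
               } else {
                 stop("unknown format '", format, "'; registered formats: ",
                      paste(loader_names(), collapse = ", "))
               })
  s <- fn(path)
  if (!inherits(s, "session")) stop("loader '", format,
                                    "' did not return a session")
  for (nm in names(s$objects)) validate_object(s$objects[[nm]], nm)
  s
}
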