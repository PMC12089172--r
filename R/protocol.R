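#' Content digest of an analysis object
#'
#' Deterministic md5 digest used by the analysis protocol: CAMs and CAM sets
#' digest their canonical JSON; existing file paths digest the file content;
#' everything else digests a canonical JSON serialization of the object.
#' Equal content always yields the same digest within a platform, so digests
#' can be recomputed at replay time.
#'
#' @param x A `cam`, `cam_set`, file path, or any JSON-serializable object.
#' @return A 32-character hex digest string.
#' @export
content_digest <- function(x) {
  txt <- if (inherits(x, "cam")) {
    write_cam(x)
  } else if (inherits(x, "cam_set")) {
    paste(vapply(x$cams, write_cam, character(1)), collapse = "\n")
  } else if (is_string(x) && file.exists(x) && !dir.exists(x)) {
    return(unname(tools::md5sum(x)))
  } else {
    as.character(jsonlite::serializeJSON(x, digits = 15))
  }
  md5_string(txt)
}

md5_string <- function(txt) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(txt, tf, useBytes = TRUE)
  unname(tools::md5sum(tf))
}

#' Open (or resume) an analysis protocol
#'
#' The protocol is the tamper-evident audit trail of an analysis session: an
#' append-only JSON-lines file, one entry per operation, each entry carrying
#' the operation name, a full parameter snapshot (seeds included), input and
#' output content digests, a timestamp, and a rolling hash chaining it to the
#' previous entry. Timestamps are excluded from the hash chain so replay
#' verdicts ignore wall-clock.
#'
#' @param path Path of the `.jsonl` protocol file; created if missing,
#'   resumed (and chain-verified) if present.
#' @return An object of class `cam_protocol`.
#' @export
protocol_open <- function(path) {
  entries <- list()
  if (file.exists(path)) {
    lines <- readLines(path, warn = FALSE)
    entries <- lapply(lines[nzchar(lines)], jsonlite::fromJSON,
                      simplifyVector = TRUE)
    verify_chain(entries)
  }
  structure(list(path = path, entries = entries), class = "cam_protocol")
}

#' Read a protocol file without opening it for appending
#'
#' @param path Protocol `.jsonl` file.
#' @return A `cam_protocol` (chain verified).
#' @export
protocol_read <- function(path) {
  if (!file.exists(path)) stop_camnet(paste("file not found:", path), "camnet_io_error")
  protocol_open(path)
}

# strip S3 classes (but keep data.frames) so parameter snapshots serialize
unclass_deep <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(x))
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  x
}

entry_hash <- function(entry, prev_hash) {
  core <- entry[c("seq", "operation", "params", "inputs", "output")]
  md5_string(paste0(prev_hash, "|",
                    jsonlite::toJSON(core, auto_unbox = TRUE, digits = 15,
                                     null = "null")))
}

verify_chain <- function(entries) {
  prev <- ""
  for (e in entries) {
    h <- entry_hash(e, prev)
    if (!identical(h, e$hash))
      stop_camnet(sprintf("protocol chain broken at entry %d", e$seq),
                  "camnet_protocol_error")
    prev <- h
  }
  invisible(TRUE)
}

#' Record one analysis step in a protocol
#'
#' Appends an entry and flushes it to disk immediately; previous entries are
#' immutable (any later mutation of the file breaks the hash chain and is
#' detected on open/replay).
#'
#' @param proto A `cam_protocol`.
#' @param operation Name of an exported package function that performed the
#'   step.
#' @param params Named list of the non-data parameters (seeds included); must
#'   be JSON-serializable.
#' @param inputs Named list of the data inputs consumed (digested).
#' @param output The object the step produced (digested).
#' @return The updated `cam_protocol`.
#' @export
protocol_record <- function(proto, operation, params = list(), inputs = list(),
                            output = NULL) {
  stopifnot(inherits(proto, "cam_protocol"))
  prev <- if (length(proto$entries))
    proto$entries[[length(proto$entries)]]$hash else ""
  entry <- list(seq = length(proto$entries) + 1L,
                operation = operation,
                params = unclass_deep(params),
                inputs = as.list(vapply(inputs, content_digest, character(1))),
                output = content_digest(output),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z"))
  if (!length(entry$inputs)) entry$inputs <- setNames(list(), character())
  entry$hash <- entry_hash(entry, prev)
  line <- jsonlite::toJSON(entry, auto_unbox = TRUE, digits = 15, null = "null")
  con <- file(proto$path, open = "a")
  writeLines(as.character(line), con)
  flush(con)
  close(con)
  proto$entries[[length(proto$entries) + 1L]] <- jsonlite::fromJSON(
    as.character(line), simplifyVector = TRUE)
  proto
}

#' Run one pipeline step and record it
#'
#' Convenience wrapper: executes `fn(...inputs..., ...params...)`, records the
#' step (operation name, params, input/output digests) in the protocol, and
#' returns both. The recorded stream is replayable with [protocol_replay()].
#'
#' @param proto A `cam_protocol`.
#' @param fn Name of an exported camnet function.
#' @param inputs Named list of data inputs (passed first, digested).
#' @param params Named list of further arguments (recorded verbatim).
#' @return A list: `output` (the step result), `protocol` (updated).
#' @export
protocol_step <- function(proto, fn, inputs = list(), params = list()) {
  f <- get(fn, envir = asNamespace("camnet"))
  output <- do.call(f, c(inputs, params))
  proto <- protocol_record(proto, fn, params = params, inputs = inputs,
                           output = output)
  list(output = output, protocol = proto)
}

#' Replay a protocol against raw inputs
#'
#' Re-executes every recorded operation with its recorded parameters. Objects
#' are matched by content digest: the provided raw inputs seed a store, each
#' step looks its inputs up by digest, runs the recorded function, verifies
#' the output digest, and adds the output to the store. The verdict is PASS
#' iff every step's inputs are found and every recomputed output digest
#' matches the recorded one; otherwise the report names the first diverging
#' step.
#'
#' @param proto A `cam_protocol` (e.g. from [protocol_read()]).
#' @param raw_inputs List of the session's external inputs (CAM sets, maps,
#'   configs ...), in any order.
#' @return A list: `verdict` (`"PASS"`/`"FAIL"`), `failed_at` (seq number or
#'   `NA`), `reason`, `outputs` (list of recomputed outputs by seq).
#' @export
protocol_replay <- function(proto, raw_inputs = list()) {
  stopifnot(inherits(proto, "cam_protocol"))
  verify_chain(proto$entries)
  # store objects by digest; also index CAM-carrying elements of composite
  # results (e.g. the cam_set inside a generator result) so later steps can
  # consume them
  store <- list()
  store_object <- function(x) {
    store[[content_digest(x)]] <<- x
    if (is.list(x) && !is.data.frame(x) && !inherits(x, c("cam", "cam_set")))
      for (el in x) if (inherits(el, c("cam", "cam_set")))
        store[[content_digest(el)]] <<- el
  }
  for (x in raw_inputs) store_object(x)
  outputs <- list()
  for (e in proto$entries) {
    digests <- unlist(e$inputs)
    args <- list()
    ok <- TRUE
    for (nm in names(digests)) {
      d <- digests[[nm]]
      if (is.null(store[[d]])) {
        return(list(verdict = "FAIL", failed_at = e$seq,
                    reason = sprintf("input '%s' of step %d (%s) not found: digest %s",
                                     nm, e$seq, e$operation, d),
                    outputs = outputs))
      }
      args[[nm]] <- store[[d]]
    }
    params <- e$params
    if (is.null(params)) params <- list()
    f <- get(e$operation, envir = asNamespace("camnet"))
    out <- do.call(f, c(args, restore_params(e$operation, params)))
    d_out <- content_digest(out)
    if (!identical(d_out, e$output)) {
      return(list(verdict = "FAIL", failed_at = e$seq,
                  reason = sprintf("output digest of step %d (%s) diverged",
                                   e$seq, e$operation),
                  outputs = outputs))
    }
    store_object(out)
    outputs[[as.character(e$seq)]] <- out
  }
  list(verdict = "PASS", failed_at = NA_integer_, reason = "", outputs = outputs)
}

# JSON round-trips lose R classes; rebuild the structured parameter objects
# the recorded operations expect
restore_params <- function(operation, params) {
  params <- as.list(params)
  if (operation == "generate_cam_set" && !is.null(params$cfg) &&
      !inherits(params$cfg, "gen_config")) {
    params$cfg <- do.call(gen_config, as.list(params$cfg)[
      setdiff(names(params$cfg), character())])
  }
  if (!is.null(params$map) && !inherits(params$map, "summary_map")) {
    m <- params$map
    params$map <- summary_map(tibble::tibble(raw_text = m$entries$raw_text,
                                             category = m$entries$category),
                              split_by_valence = isTRUE(m$split_by_valence))
  }
  if (!is.null(params$spec) && !inherits(params$spec, "slice_spec")) {
    s <- params$spec
    params$spec <- slice_spec(
      edges_to_delete = if (is.null(s$edges_to_delete)) list() else
        lapply(seq_len(NROW(s$edges_to_delete)), function(i)
          unlist(s$edges_to_delete[i, , drop = TRUE])),
      nodes_to_delete = s$nodes_to_delete %||% character(),
      expected_components = s$expected_components,
      anchors = if (is.null(s$anchors)) NULL else unlist(s$anchors),
      min_component_size = s$min_component_size %||% 1L)
  }
  params
}

#' Usage statistics of a protocol
#'
#' @param proto A `cam_protocol`.
#' @return A tibble (`operation`, `n`) of operation usage counts, plus the
#'   total entry count as attribute `n_entries`.
#' @export
protocol_stats <- function(proto) {
  stopifnot(inherits(proto, "cam_protocol"))
  ops <- vapply(proto$entries, `[[`, character(1), "operation")
  tab <- if (length(ops)) table(ops) else table(character())
  out <- tibble::tibble(operation = names(tab), n = as.integer(tab))
  out <- out[order(-out$n, out$operation), ]
  attr(out, "n_entries") <- length(ops)
  out
}
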