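#' Write a force or relaxation trace to CSV with metadata header
#'
#' Traces are stored as RFC-4180 CSV with `#`-prefixed `key: value` metadata
#' lines before the column header. Force traces carry the probe calibration
#' and unstressed reference positions (`time_min,deflection_px,force_uN`);
#' relaxation traces carry area, imposed strain, explant type and stage
#' (`time_s,force_uN[,strain]`). All numeric columns carry unit suffixes.
#'
#' @param trace A [force_trace()] or [relaxation_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  if (inherits(trace, "force_trace")) {
    meta <- c(
      sprintf("# probe_id: %s", trace$calibration$probe_id),
      sprintf("# spring_constant_uN_per_um: %.17g", trace$calibration$spring_constant),
      sprintf("# magnification_um_per_px: %.17g", trace$calibration$magnification),
      sprintf("# pre_unstressed_px: %.17g", trace$pre_unstressed_px),
      sprintf("# post_unstressed_px: %.17g", trace$post_unstressed_px),
      sprintf("# status: %s", trace$status),
      sprintf("# friction_offset_uN: %.17g", trace$friction_offset_uN)
    )
    df <- as.data.frame(trace)
  } else if (inherits(trace, "relaxation_trace")) {
    meta <- c(
      sprintf("# area_mm2: %.17g", trace$area_mm2),
      sprintf("# imposed_strain: %.17g", trace$imposed_strain),
      sprintf("# explant_type: %s", trace$explant_type),
      sprintf("# stage_hr: %.17g", trace$stage_hr)
    )
    df <- as.data.frame(trace)
  } else {
    stop("`trace` must be a force_trace or relaxation_trace")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

parse_meta <- function(lines) {
  kv <- sub("^#\\s*", "", lines)
  keys <- sub(":.*$", "", kv)
  vals <- trimws(sub("^[^:]*:", "", kv))
  stats::setNames(as.list(vals), trimws(keys))
}

#' Read a trace CSV, dispatching on its header
#'
#' Reads a CSV written by [write_trace()] (or hand-built to the same format)
#' and returns a typed trace. Dispatch is on the time column: `time_min`
#' gives a [force_trace()], `time_s` a [relaxation_trace()]. Missing
#' calibration metadata is a hard error listing the missing keys; malformed
#' or unsorted rows are reported with their line numbers.
#'
#' @param path Input file path.
#' @return A `force_trace` or `relaxation_trace`.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  n_meta <- if (any(!is_meta)) which(!is_meta)[1L] - 1L else length(lines)
  meta <- parse_meta(lines[seq_len(n_meta)])
  body <- lines[!is_meta]
  if (length(body) < 3L) stop("fewer than 2 data rows in ", path)
  df <- tryCatch(
    utils::read.csv(text = paste(body, collapse = "\n"),
                    stringsAsFactors = FALSE),
    error = function(e) stop("malformed CSV body in ", path, ": ",
                             conditionMessage(e)))
  header <- names(df)
  nfield <- lengths(strsplit(body, ",", fixed = TRUE))
  bad <- which(nfield != nfield[1L])
  if (length(bad))
    stop("malformed row(s) in ", path, " at line(s): ",
         paste(bad + n_meta, collapse = ", "))

  check_sorted <- function(tv, colname) {
    noninc <- which(diff(tv) <= 0)
    if (length(noninc))
      stop("`", colname, "` not strictly increasing in ", path,
           " at line ", noninc[1L] + 1L + n_meta + 1L)
  }
  need_meta <- function(keys) {
    miss <- setdiff(keys, names(meta))
    if (length(miss))
      stop("missing metadata key(s) in ", path, ": ",
           paste(miss, collapse = ", "))
  }

  if ("time_min" %in% header) {
    need_meta(c("spring_constant_uN_per_um", "magnification_um_per_px"))
    check_sorted(df$time_min, "time_min")
    num_or_na <- function(key, default = NA_real_)
      if (key %in% names(meta)) suppressWarnings(as.numeric(meta[[key]])) else default
    cal <- probe_calibration(
      as.numeric(meta$spring_constant_uN_per_um),
      as.numeric(meta$magnification_um_per_px),
      probe_id = if (!is.null(meta$probe_id)) meta$probe_id else NA_character_)
    tr <- force_trace(df$time_min, df$deflection_px, cal,
                      pre_unstressed_px = num_or_na("pre_unstressed_px"),
                      post_unstressed_px = num_or_na("post_unstressed_px"))
    if (!is.null(meta$status)) tr$status <- meta$status
    if (!is.null(meta$friction_offset_uN))
      tr$friction_offset_uN <- as.numeric(meta$friction_offset_uN)
    if ("force_uN" %in% header && !identical(meta$status, "raw")) {
      # stored forces are authoritative for corrected/compensated traces
      tr$force_uN <- df$force_uN
    }
    tr
  } else if ("time_s" %in% header) {
    need_meta(c("area_mm2", "imposed_strain"))
    check_sorted(df$time_s, "time_s")
    relaxation_trace(
      df$time_s, df$force_uN,
      imposed_strain = as.numeric(meta$imposed_strain),
      area_mm2 = as.numeric(meta$area_mm2),
      strain = if ("strain" %in% header) df$strain else NULL,
      explant_type = if (!is.null(meta$explant_type)) meta$explant_type else NA_character_,
      stage_hr = if (!is.null(meta$stage_hr))
        suppressWarnings(as.numeric(meta$stage_hr)) else NA_real_)
  } else {
    stop("cannot dispatch on header of ", path,
         ": expected a `time_min` or `time_s` column")
  }
}

#' Write / read marker tracks CSV
#'
#' Plain CSV with columns `track_id,time_min,position_um,region`.
#'
#' @param tracks A [marker_tracks()].
#' @param path File path.
#' @return `path` invisibly (write); a `marker_tracks` (read).
#' @export
write_tracks <- function(tracks, path) {
  stopifnot(inherits(tracks, "marker_tracks"))
  utils::write.csv(as.data.frame(tracks), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  marker_tracks(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Run manifest for a pipeline or CLI invocation
#'
#' Every pipeline/CLI run emits one manifest recording the command, a digest
#' of the configuration, digests of the input files, the seed(s), the package
#' version and a timestamp, so that deterministic commands can be re-run and
#' audited. The manifest (not the result files) carries the timestamp, so
#' result files from identical inputs are byte-identical.
#'
#' @param command Command name.
#' @param config The configuration object (list) used for the run.
#' @param inputs Character vector of input file paths (digested with MD5).
#' @param seed Seed(s) used, if any.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(command, config = list(), inputs = character(), seed = NULL) {
  inputs <- as.character(if (is.null(inputs)) character() else inputs)
  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  on.exit(unlink(cfg_file))
  structure(list(
    command = command,
    config_md5 = unname(tools::md5sum(cfg_file)),
    input_md5 = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    seed = seed,
    package_version = as.character(utils::packageVersion("tractorpull")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "run_manifest")
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(path)
}
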