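# File interchange: BrainVision recordings, events sidecars, feature
# tables and TTT series as CSV, and run reports as JSON.

#' Write a recording as a BrainVision triplet
#'
#' Writes `<basename>.vhdr` (header), `<basename>.vmrk` (markers; one
#' "New Segment" marker) and `<basename>.eeg` (multiplexed IEEE float32
#' binary). Amplitudes are stored in microvolts with resolution 1.
#'
#' @param rec An [eeg_recording()].
#' @param basename Path without extension.
#' @return The `.vhdr` path, invisibly.
#' @export
write_brainvision <- function(rec, basename) {
  stopifnot(inherits(rec, "eeg_recording"))
  vhdr <- paste0(basename, ".vhdr")
  vmrk <- paste0(basename, ".vmrk")
  eeg <- paste0(basename, ".eeg")
  nm <- basename(basename)
  hdr <- c(
    "BrainVision Data Exchange Header File Version 1.0",
    "",
    "[Common Infos]",
    paste0("DataFile=", nm, ".eeg"),
    paste0("MarkerFile=", nm, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nrow(rec$data)),
    paste0("SamplingInterval=", format(1e6 / rec$fs, digits = 12)),
    "",
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nrow(rec$data)),
            rec$channel_labels))
  writeLines(hdr, vhdr, useBytes = TRUE)
  writeLines(c(
    "BrainVision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    paste0("DataFile=", nm, ".eeg"),
    "",
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,0"), vmrk)
  con <- file(eeg, "wb")
  on.exit(close(con))
  writeBin(as.numeric(rec$data), con, size = 4, endian = "little")
  invisible(vhdr)
}

#' @noRd
parse_bv_section <- function(lines) {
  out <- list()
  for (ln in lines) {
    if (grepl("^\\s*(;|$)", ln)) next
    if (grepl("^\\[", ln)) next
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) >= 2) {
      out[[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
    }
  }
  out
}

#' Read a BrainVision recording
#'
#' Supports multiplexed binary data in IEEE float32 or signed 16-bit
#' integer format (with per-channel resolution scaling), the formats in
#' common use.
#'
#' @param vhdr_path Path to the `.vhdr` header file.
#' @return An [eeg_recording()].
#' @export
read_brainvision <- function(vhdr_path) {
  lines <- readLines(vhdr_path, warn = FALSE)
  kv <- parse_bv_section(lines)
  fmt <- toupper(kv[["BinaryFormat"]] %||% "IEEE_FLOAT_32")
  orient <- toupper(kv[["DataOrientation"]] %||% "MULTIPLEXED")
  if (orient != "MULTIPLEXED") {
    stop("only MULTIPLEXED BrainVision data is supported", call. = FALSE)
  }
  n_ch <- as.integer(kv[["NumberOfChannels"]])
  fs <- 1e6 / as.numeric(kv[["SamplingInterval"]])
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  ch_info <- strsplit(sub("^Ch[0-9]+=", "", ch_lines), ",")
  labels <- vapply(ch_info, `[[`, "", 1)
  resolution <- vapply(ch_info, function(v) {
    r <- suppressWarnings(as.numeric(v[3]))
    if (is.na(r)) 1 else r
  }, 0)
  eeg_path <- file.path(dirname(vhdr_path), kv[["DataFile"]])
  sz <- file.info(eeg_path)$size
  con <- file(eeg_path, "rb")
  on.exit(close(con))
  if (fmt == "IEEE_FLOAT_32") {
    raw_vals <- readBin(con, "numeric", n = sz / 4, size = 4,
                        endian = "little")
  } else if (fmt == "INT_16") {
    raw_vals <- readBin(con, "integer", n = sz / 2, size = 2,
                        signed = TRUE, endian = "little")
  } else {
    stop("unsupported BinaryFormat: ", fmt, call. = FALSE)
  }
  n_samp <- length(raw_vals) %/% n_ch
  x <- matrix(raw_vals[seq_len(n_samp * n_ch)], nrow = n_ch)
  x <- x * resolution
  eeg_recording(x, fs, channel_labels = labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a trial-events CSV sidecar
#'
#' Plain CSV with 0-based sample indices, one row per trial.
#'
#' @param events A [trial_events()] table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  trial_events(utils::read.csv(path))
}

#' Write / read a feature table as CSV
#'
#' Header comment lines (prefixed `#`) carry the subject id; columns are
#' the (component, band) log-bandpowers, plus the trial index.
#'
#' @param ft A `feature_table` from [build_feature_table()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# subject=%s", attr(ft, "subject")), con)
  df <- data.frame(trial = attr(ft, "trials"), unclass(ft),
                   check.names = FALSE)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  subject <- NA_integer_
  m <- regmatches(meta, regexec("subject=([0-9NA]+)", meta))
  for (mm in m) {
    if (length(mm) == 2) subject <- suppressWarnings(as.integer(mm[2]))
  }
  df <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]),
                        check.names = FALSE)
  vals <- as.matrix(df[, setdiff(names(df), "trial"), drop = FALSE])
  structure(vals, class = c("feature_table", "matrix", "array"),
            subject = subject, trials = df$trial,
            bands = band_definitions())
}

#' Write a run report as JSON (plus CSV side tables)
#'
#' @param report A `vmil_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return The JSON path, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(dir, "report.json")
  payload <- report
  payload$phases <- lapply(report$phases, function(ph) {
    ph$permutation$draws <- NULL        # bulky; distribution summarized by p
    ph$feature_tables <- NULL
    ph$cv <- NULL
    ph
  })
  class(payload) <- NULL
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  for (nm in names(report$phases)) {
    utils::write.csv(report$phases[[nm]]$r2_table,
                     file.path(dir, sprintf("r2_mod_%s.csv", nm)),
                     row.names = FALSE)
  }
  invisible(json_path)
}
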