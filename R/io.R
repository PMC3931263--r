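# Recording I/O: ATF-style tab-separated text (optional two-line header),
# CSV/TSV variants, and an HDF5 container with a documented layout.

#' Text file dialect
#'
#' @param kind `"atf"` (tab separator, ATF 1.0-style two-line header),
#'   `"csv"` or `"tsv"` (headerless except for one column-title line).
#' @param separator Column separator; defaults follow `kind`.
#' @param decimal_digits Digits written after the decimal point.
#' @return A list of class `file_dialect`.
#' @export
file_dialect <- function(kind = c("atf", "csv", "tsv"), separator = NULL,
                         decimal_digits = 6L) {
  kind <- match.arg(kind)
  if (is.null(separator)) separator <- if (kind == "csv") "," else "\t"
  if (decimal_digits < 1L) {
    rlang::abort("`decimal_digits` must be >= 1.", class = "sweepkit_error_argument")
  }
  structure(list(kind = kind, separator = separator,
                 decimal_digits = as.integer(decimal_digits)),
            class = "file_dialect")
}

#' Read a recording from a delimited text file
#'
#' Accepts the two header lines of the ATF 1.0 convention (`ATF\t1.0`, then
#' record/column counts, optional record lines, one column-title line) but
#' tolerates their absence: a leading non-numeric line is treated as column
#' titles, otherwise data start immediately. The first column is time in
#' ms; every further column becomes one channel holding a single sweep. The
#' sampling interval is inferred from the first two time values and time
#' uniformity is verified to 1 part in 1e4.
#'
#' @param path File to read.
#' @param dialect A [file_dialect()].
#' @return A [recording()].
#' @export
read_text_recording <- function(path, dialect = file_dialect("atf")) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("File not found: %s", path), class = "sweepkit_error_io")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  skip <- 0L
  titles <- NULL
  if (length(lines) >= 1L && grepl("^ATF", lines[1])) {
    hdr <- strsplit(lines[2], dialect$separator, fixed = TRUE)[[1]]
    n_rec <- suppressWarnings(as.integer(hdr[1]))
    if (is.na(n_rec)) {
      rlang::abort("Malformed ATF header line 2.", class = "sweepkit_error_format")
    }
    skip <- 2L + n_rec + 1L  # header, counts, records, titles
    titles <- strsplit(lines[skip], dialect$separator, fixed = TRUE)[[1]]
  } else if (length(lines) >= 1L) {
    first <- strsplit(lines[1], dialect$separator, fixed = TRUE)[[1]]
    if (anyNA(suppressWarnings(as.numeric(first)))) {
      skip <- 1L
      titles <- first
    }
  }
  body <- lines[seq.int(skip + 1L, length(lines))]
  if (length(body) < 2L) {
    rlang::abort("Need at least two data rows.", class = "sweepkit_error_format")
  }
  mat <- do.call(rbind, lapply(strsplit(body, dialect$separator, fixed = TRUE),
                               as.numeric))
  if (anyNA(mat)) {
    rlang::abort("Non-numeric values in the data block.", class = "sweepkit_error_format")
  }
  if (ncol(mat) < 2L) {
    rlang::abort("Need a time column plus at least one data column.",
                 class = "sweepkit_error_format")
  }
  tt <- mat[, 1]
  dt <- tt[2] - tt[1]
  if (dt <= 0 || any(abs(diff(tt) - dt) > 1e-4 * dt)) {
    rlang::abort("Time column is not uniformly spaced (tolerance 1e-4).",
                 class = "sweepkit_error_format")
  }
  units <- rep("mV", ncol(mat) - 1L)
  names_ch <- paste0("ch", seq_len(ncol(mat) - 1L) - 1L)
  if (!is.null(titles) && length(titles) == ncol(mat)) {
    lab <- titles[-1]
    u <- sub("^.*\\(([^)]*)\\).*$", "\\1", lab)
    units <- ifelse(u != lab & nzchar(u), u, units)
    nm <- trimws(sub("\\([^)]*\\)", "", lab))
    names_ch <- ifelse(nzchar(nm), nm, names_ch)
  }
  chans <- purrr::map(seq_len(ncol(mat) - 1L), function(j) {
    channel(trace(mat[, j + 1L], dt = dt, y_unit = units[j], t0 = tt[1]),
            name = names_ch[j])
  })
  recording(chans, metadata = list(source = path))
}

#' Write a recording to a delimited text file
#'
#' Every (channel, sweep) pair becomes one data column named
#' `<channel>_sw<j> (<unit>)`; the first column is time in ms. All sweeps
#' must share dt, t0 and length so they can live on one time axis. ATF kind
#' writes the two ATF 1.0 header lines; reading the file back recovers the
#' samples to the written decimal precision and dt exactly (each column as
#' its own single-sweep channel).
#'
#' @param recording A [recording()].
#' @param path Output file.
#' @param dialect A [file_dialect()].
#' @return `path`, invisibly.
#' @export
write_text_recording <- function(recording, path, dialect = file_dialect("atf")) {
  stopifnot(inherits(recording, "sweep_recording"))
  cols <- list(); labels <- character()
  for (ch in recording$channels) {
    for (j in seq_along(ch$sweeps)) {
      sw <- ch$sweeps[[j]]
      cols[[length(cols) + 1L]] <- sw
      # single-sweep channels keep their bare name so that
      # write -> read -> write canonicalizes to a byte-identical file
      lab <- if (length(ch$sweeps) == 1L) ch$name
             else sprintf("%s_sw%d", ch$name, j - 1L)
      labels <- c(labels, sprintf("%s (%s)", lab, sw$y_unit))
    }
  }
  if (length(cols) == 0L) {
    rlang::abort("Recording has no sweeps.", class = "sweepkit_error_argument")
  }
  ns <- vapply(cols, length, integer(1))
  dts <- vapply(cols, function(s) s$dt, numeric(1))
  t0s <- vapply(cols, function(s) s$t0, numeric(1))
  if (length(unique(ns)) > 1L || any(dts != dts[1]) || any(t0s != t0s[1])) {
    rlang::abort("Text export needs equal-length sweeps sharing dt and t0.",
                 class = "sweepkit_error_incompatible")
  }
  sep <- dialect$separator
  dg <- dialect$decimal_digits
  tt <- cols[[1]]$t0 + (seq_len(ns[1]) - 1) * dts[1]
  mat <- cbind(tt, do.call(cbind, lapply(cols, `[[`, "samples")))
  body <- apply(formatC(mat, digits = dg, format = "f"), 1, paste, collapse = sep)
  head_lines <- character()
  if (dialect$kind == "atf") {
    head_lines <- c(paste0("ATF", sep, "1.0"),
                    paste0("0", sep, ncol(mat)))
  }
  title <- paste(c("Time (ms)", labels), collapse = sep)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(head_lines, title, body), con)
  invisible(path)
}

# HDF5 layout:
#   /            attrs: format_version, meta_<key> ...
#   /channels/<i>        attrs: name, y_unit, dt_ms
#   /channels/<i>/sweep_<j>   1-D float64 dataset, attr t0_ms

#' Read / write recordings as HDF5
#'
#' The container layout is `/channels/<i>` groups (0-based), each with
#' attributes `name`, `y_unit` and `dt_ms` and 1-D float64 datasets
#' `sweep_<j>` carrying a `t0_ms` attribute; root attributes hold
#' `format_version` and `meta_*` metadata. Samples round-trip bit-exactly.
#'
#' @param path HDF5 file path.
#' @return `read_h5_recording()` returns a [recording()];
#'   `write_h5_recording()` returns `path` invisibly.
#' @export
read_h5_recording <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("File not found: %s", path), class = "sweepkit_error_io")
  }
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  if (!("channels" %in% rhdf5::h5ls(path, recursive = FALSE)$name)) {
    rlang::abort("Not a sweepkit HDF5 recording (missing /channels).",
                 class = "sweepkit_error_format")
  }
  ls_ch <- rhdf5::h5ls(path)
  ch_names <- sort(ls_ch$name[ls_ch$group == "/channels"])
  chans <- purrr::map(ch_names, function(g) {
    grp <- paste0("/channels/", g)
    at <- rhdf5::h5readAttributes(path, grp)
    if (is.null(at$dt_ms) || is.null(at$y_unit)) {
      rlang::abort(sprintf("Group %s lacks dt_ms/y_unit attributes.", grp),
                   class = "sweepkit_error_format")
    }
    sw_names <- sort(ls_ch$name[ls_ch$group == grp])
    sweeps <- purrr::map(sw_names, function(d) {
      ds <- paste0(grp, "/", d)
      t0 <- rhdf5::h5readAttributes(path, ds)$t0_ms
      trace(as.numeric(rhdf5::h5read(path, ds)), dt = as.numeric(at$dt_ms),
            y_unit = as.character(at$y_unit),
            t0 = if (is.null(t0)) 0 else as.numeric(t0))
    })
    channel(sweeps, name = as.character(at$name))
  })
  root_at <- rhdf5::h5readAttributes(path, "/")
  meta <- root_at[grepl("^meta_", names(root_at))]
  names(meta) <- sub("^meta_", "", names(meta))
  meta <- lapply(meta, function(x) as.character(x)[1])
  recording(chans, metadata = meta)
}

#' @rdname read_h5_recording
#' @param recording A [recording()].
#' @export
write_h5_recording <- function(recording, path) {
  stopifnot(inherits(recording, "sweep_recording"))
  if (file.exists(path)) file.remove(path)
  fid <- rhdf5::H5Fcreate(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5writeAttribute("1.0", fid, "format_version")
  for (key in names(recording$metadata)) {
    rhdf5::h5writeAttribute(as.character(recording$metadata[[key]]), fid,
                            paste0("meta_", key))
  }
  gch <- rhdf5::H5Gcreate(fid, "channels")
  for (i in seq_along(recording$channels)) {
    ch <- recording$channels[[i]]
    gid <- rhdf5::H5Gcreate(gch, sprintf("%03d", i - 1L))
    rhdf5::h5writeAttribute(ch$name, gid, "name")
    rhdf5::h5writeAttribute(ch$sweeps[[1]]$y_unit, gid, "y_unit")
    rhdf5::h5writeAttribute(ch$sweeps[[1]]$dt, gid, "dt_ms")
    for (j in seq_along(ch$sweeps)) {
      ds <- sprintf("sweep_%04d", j - 1L)
      rhdf5::h5writeDataset(ch$sweeps[[j]]$samples, gid, ds)
      did <- rhdf5::H5Dopen(gid, ds)
      rhdf5::h5writeAttribute(ch$sweeps[[j]]$t0, did, "t0_ms")
      rhdf5::H5Dclose(did)
    }
    rhdf5::H5Gclose(gid)
  }
  rhdf5::H5Gclose(gch)
  rhdf5::H5Fclose(fid)
  invisible(path)
}
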