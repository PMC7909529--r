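# Spectrum container and file I/O (two-column CSV and a minimal JCAMP-DX
# dialect with an evenly spaced abscissa).

new_spectrum <- function(ppm, intensity, sample_id = NA_character_,
                         group = NA_character_) {
  stop_if_not(length(ppm) == length(intensity),
              "ppm and intensity must have equal length")
  stop_if_not(length(ppm) >= 2L, "empty or degenerate spectrum")
  ord <- order(ppm)
  ppm <- ppm[ord]
  intensity <- intensity[ord]
  stop_if_not(all(diff(ppm) > 0), "ppm axis must be strictly monotone")
  stop_if_not(all(is.finite(intensity)), "non-finite intensities")
  structure(list(ppm = ppm, intensity = intensity,
                 sample_id = sample_id, group = group),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("1H-NMR spectrum '%s': %d points, %.3f to %.3f ppm\n",
              x$sample_id, length(x$ppm), min(x$ppm), max(x$ppm)))
  invisible(x)
}

#' @export
plot.spectrum <- function(x, ...) {
  graphics::plot(x$ppm, x$intensity, type = "l", xlim = rev(range(x$ppm)),
                 xlab = "chemical shift (ppm)", ylab = "intensity",
                 main = x$sample_id, ...)
  invisible(x)
}

#' Read a spectrum from CSV or JCAMP-DX
#'
#' CSV files hold two numeric columns (ppm, intensity), with or without a
#' header line. The axis is re-sorted ascending on load.
#'
#' @param path input file
#' @param format `"csv"`, `"jcamp"`, or `"auto"` (by file extension)
#' @param sample_id,group metadata; default sample_id is the file stem
#' @return a `spectrum`
#' @export
read_spectrum <- function(path, format = c("auto", "csv", "jcamp"),
                          sample_id = NULL, group = NA_character_) {
  format <- match.arg(format)
  stop_if_not(file.exists(path), "file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.(jdx|dx|jcamp)$", tolower(path))) "jcamp" else "csv"
  }
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  if (format == "csv") read_spectrum_csv(path, sample_id, group)
  else read_spectrum_jcamp(path, sample_id, group)
}

read_spectrum_csv <- function(path, sample_id, group) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  stop_if_not(length(lines) > 0L, "empty spectrum file: %s", path)
  first_vals <- strsplit(lines[1L], ",")[[1L]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first_vals))))
  start <- if (has_header) 2L else 1L
  stop_if_not(length(lines) >= start, "empty spectrum file: %s", path)
  parts <- strsplit(lines[start:length(lines)], ",")
  bad <- which(vapply(parts, function(p) {
    length(p) < 2L || anyNA(suppressWarnings(as.numeric(p[1:2])))
  }, TRUE))
  if (length(bad) > 0L)
    stop(sprintf("non-numeric entry at line %d of %s",
                 bad[1L] + start - 1L, path), call. = FALSE)
  ppm <- vapply(parts, function(p) as.numeric(p[1L]), 0)
  intensity <- vapply(parts, function(p) as.numeric(p[2L]), 0)
  new_spectrum(ppm, intensity, sample_id, group)
}

#' Write a spectrum as two-column CSV
#'
#' @param s a `spectrum`
#' @param path output file
#' @export
write_spectrum_csv <- function(s, path) {
  utils::write.csv(data.frame(ppm = s$ppm, intensity = s$intensity),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a spectrum in JCAMP-DX format
#'
#' Emits an `XYDATA=(X++(Y..Y))` block on the spectrum's (assumed evenly
#' spaced) axis.
#'
#' @param s a `spectrum`
#' @param path output file
#' @export
write_spectrum_jcamp <- function(s, path) {
  n <- length(s$ppm)
  yfac <- max(abs(s$intensity)) / 32767
  if (yfac == 0) yfac <- 1
  yint <- round(s$intensity / yfac)
  header <- c(
    sprintf("##TITLE=%s", s$sample_id),
    "##JCAMP-DX=4.24",
    "##DATA TYPE=NMR SPECTRUM",
    "##XUNITS=PPM",
    "##YUNITS=ARBITRARY",
    sprintf("##XFACTOR=%.12g", 1),
    sprintf("##YFACTOR=%.12g", yfac),
    sprintf("##FIRSTX=%.12g", s$ppm[1L]),
    sprintf("##LASTX=%.12g", s$ppm[n]),
    sprintf("##NPOINTS=%d", n),
    "##XYDATA=(X++(Y..Y))"
  )
  idx <- split(seq_len(n), ceiling(seq_len(n) / 8))
  body <- vapply(idx, function(i) {
    paste(c(sprintf("%.6f", s$ppm[i[1L]]), format(yint[i], trim = TRUE)),
          collapse = " ")
  }, "")
  writeLines(c(header, body, "##END="), path)
  invisible(path)
}

read_spectrum_jcamp <- function(path, sample_id, group) {
  lines <- readLines(path, warn = FALSE)
  field <- function(key) {
    m <- grep(paste0("^##", key, "="), lines, value = TRUE)
    if (length(m) == 0L) return(NA)
    sub(paste0("^##", key, "="), "", m[1L])
  }
  npoints <- as.integer(field("NPOINTS"))
  firstx <- as.numeric(field("FIRSTX"))
  lastx <- as.numeric(field("LASTX"))
  yfac <- as.numeric(field("YFACTOR"))
  if (is.na(yfac)) yfac <- 1
  stop_if_not(is.finite(npoints) && is.finite(firstx) && is.finite(lastx),
              "malformed JCAMP-DX file (missing NPOINTS/FIRSTX/LASTX): %s", path)
  start <- grep("^##XYDATA", lines)
  stop_if_not(length(start) == 1L, "malformed JCAMP-DX file (no XYDATA): %s", path)
  end <- grep("^##END", lines)
  end <- if (length(end) > 0L) min(end[end > start]) else length(lines) + 1L
  body <- lines[(start + 1L):(end - 1L)]
  y <- unlist(lapply(body, function(l) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1L]]))
    stop_if_not(!anyNA(v), "non-numeric JCAMP-DX data line: %s", l)
    v[-1L]   # first token per line is the abscissa
  }))
  stop_if_not(length(y) == npoints,
              "JCAMP-DX NPOINTS (%d) does not match data (%d)", npoints, length(y))
  ppm <- seq(firstx, lastx, length.out = npoints)
  new_spectrum(ppm, y * yfac, sample_id, group)
}
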