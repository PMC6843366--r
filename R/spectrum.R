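#' Spectral trace
#'
#' A `cd_spectrum` holds one intensity trace on a strictly monotone axis
#' (wavenumber in cm^-1 for vibrational spectra, wavelength in nm for
#' UV-Vis), with the acquisition modality and, optionally, the sample
#' temperature.  The axis is always stored ascending; display order is a
#' presentation concern.
#'
#' @param axis numeric axis values (cm^-1 or nm), strictly monotone.
#' @param intensity numeric intensities, same length as `axis`, all finite.
#' @param modality one of `"FTIR-ATR"`, `"NIR"`, `"Raman"`, `"UV-Vis"`.
#' @param temperature sample temperature in K, or `NA`.
#' @return An object of class `cd_spectrum`: a list with elements `axis`,
#'   `intensity`, `modality`, `temperature`.
#' @examples
#' s <- spectrum_trace(seq(3000, 3800, by = 4), dnorm(seq(3000, 3800, by = 4), 3342, 90))
#' print(s)
#' @export
spectrum_trace <- function(axis, intensity, modality = "FTIR-ATR",
                           temperature = NA_real_) {
  axis <- as.numeric(axis)
  intensity <- as.numeric(intensity)
  if (length(axis) != length(intensity))
    stop("axis and intensity must have equal length", call. = FALSE)
  if (length(axis) < 2L)
    stop("a spectrum needs at least 2 points", call. = FALSE)
  if (!all(is.finite(axis)) || !all(is.finite(intensity)))
    stop("axis and intensity must be finite", call. = FALSE)
  modality <- match.arg(modality, c("FTIR-ATR", "NIR", "Raman", "UV-Vis"))
  if (is.unsorted(axis)) {
    o <- order(axis)
    axis <- axis[o]
    intensity <- intensity[o]
  }
  if (any(diff(axis) <= 0))
    stop("axis must be strictly monotone (duplicated axis values)",
         call. = FALSE)
  structure(list(axis = axis, intensity = intensity, modality = modality,
                 temperature = as.numeric(temperature)),
            class = "cd_spectrum")
}

#' @export
print.cd_spectrum <- function(x, ...) {
  unit <- if (x$modality == "UV-Vis") "nm" else "cm^-1"
  cat(sprintf("<cd_spectrum> %s, %d points, axis %.6g-%.6g %s%s\n",
              x$modality, length(x$axis), min(x$axis), max(x$axis), unit,
              if (is.finite(x$temperature))
                sprintf(", T = %g K", x$temperature) else ""))
  invisible(x)
}

#' Read a spectrum from disk
#'
#' Reads a two-column CSV (`axis,intensity`, an optional single header line
#' auto-detected by a non-numeric first token) or a JCAMP-DX file in the
#' `##XYPOINTS=(XY..XY)` or `##XYDATA=(X++(Y..Y))` forms with
#' `##XFACTOR`/`##YFACTOR` applied and `##TEMPERATURE` honoured.
#'
#' @param path file to read.
#' @param format `"csv"` or `"jcamp-dx"`.
#' @param modality passed to [spectrum_trace()]; for JCAMP-DX a stored
#'   modality header wins.
#' @return A [spectrum_trace()] object.
#' @export
read_spectrum <- function(path, format = c("csv", "jcamp-dx"),
                          modality = "FTIR-ATR") {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop(sprintf("format error in %s: file is empty", path), call. = FALSE)
  if (format == "csv") read_spectrum_csv(lines, path, modality)
  else read_spectrum_jdx(lines, path, modality)
}

read_spectrum_csv <- function(lines, path, modality) {
  temperature <- NA_real_
  # comment lines may carry metadata written by write_spectrum()
  meta <- grep("^#", lines, value = TRUE)
  for (m in meta) {
    if (grepl("temperature_K\\s*=", m))
      temperature <- suppressWarnings(as.numeric(sub(".*=", "", m)))
    if (grepl("modality\\s*=", m))
      modality <- trimws(sub(".*=", "", m))
  }
  lines <- grep("^#", lines, value = TRUE, invert = TRUE)
  if (length(lines) == 0L)
    stop(sprintf("format error in %s: no data lines", path), call. = FALSE)
  first_tok <- strsplit(lines[1L], ",")[[1L]][1L]
  if (is.na(suppressWarnings(as.numeric(first_tok))))
    lines <- lines[-1L]                      # header line
  if (length(lines) == 0L)
    stop(sprintf("format error in %s: header but no data", path),
         call. = FALSE)
  parts <- strsplit(lines, ",")
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad))
    stop(sprintf("format error in %s at data line %d: expected two columns",
                 path, bad[1L]), call. = FALSE)
  x <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
  y <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  bad <- which(is.na(x) | is.na(y))
  if (length(bad))
    stop(sprintf("format error in %s at data line %d: non-numeric value",
                 path, bad[1L]), call. = FALSE)
  spectrum_trace(x, y, modality = modality, temperature = temperature)
}

jdx_field <- function(lines, name) {
  rx <- paste0("^##\\s*", name, "\\s*=")
  hit <- grep(rx, lines, value = TRUE)
  if (!length(hit)) return(NA_character_)
  trimws(sub(rx, "", hit[1L]))
}

read_spectrum_jdx <- function(lines, path, modality) {
  stored_mod <- jdx_field(lines, "\\$MODALITY")
  if (!is.na(stored_mod)) modality <- stored_mod
  temperature <- suppressWarnings(as.numeric(jdx_field(lines, "TEMPERATURE")))
  xf <- suppressWarnings(as.numeric(jdx_field(lines, "XFACTOR")))
  yf <- suppressWarnings(as.numeric(jdx_field(lines, "YFACTOR")))
  if (is.na(xf)) xf <- 1
  if (is.na(yf)) yf <- 1
  ixy <- grep("^##\\s*XYPOINTS\\s*=", lines)
  ixd <- grep("^##\\s*XYDATA\\s*=", lines)
  iend <- grep("^##\\s*END\\s*=", lines)
  stop_at <- if (length(iend)) iend[1L] - 1L else length(lines)
  num_split <- function(s) {
    toks <- strsplit(trimws(s), "[,;[:space:]]+")[[1L]]
    suppressWarnings(as.numeric(toks[nzchar(toks)]))
  }
  if (length(ixy)) {
    body <- lines[seq.int(ixy[1L] + 1L, stop_at)]
    body <- body[!grepl("^##", body)]
    vals <- unlist(lapply(body, num_split))
    if (length(vals) < 4L || length(vals) %% 2L != 0L || anyNA(vals))
      stop(sprintf("format error in %s: malformed XYPOINTS block", path),
           call. = FALSE)
    x <- vals[seq(1L, length(vals), 2L)] * xf
    y <- vals[seq(2L, length(vals), 2L)] * yf
  } else if (length(ixd)) {
    body <- lines[seq.int(ixd[1L] + 1L, stop_at)]
    body <- body[!grepl("^##", body)]
    x <- numeric(0); y <- numeric(0)
    for (i in seq_along(body)) {
      vals <- num_split(body[i])
      if (length(vals) < 2L || anyNA(vals))
        stop(sprintf("format error in %s at XYDATA line %d", path, i),
             call. = FALSE)
      x <- c(x, vals[1L] * xf)               # first value is the line's X
      y <- c(y, vals[-1L] * yf)
    }
    # expand X along each line using the global grid step
    npt <- suppressWarnings(as.numeric(jdx_field(lines, "NPOINTS")))
    firstx <- suppressWarnings(as.numeric(jdx_field(lines, "FIRSTX")))
    lastx <- suppressWarnings(as.numeric(jdx_field(lines, "LASTX")))
    if (is.na(npt) || is.na(firstx) || is.na(lastx) || npt != length(y))
      stop(sprintf("format error in %s: XYDATA needs consistent FIRSTX/LASTX/NPOINTS",
                   path), call. = FALSE)
    x <- seq(firstx, lastx, length.out = npt)
  } else {
    stop(sprintf("format error in %s: no XYPOINTS or XYDATA block", path),
         call. = FALSE)
  }
  spectrum_trace(x, y, modality = modality, temperature = temperature)
}

#' Write a spectrum to disk
#'
#' The written file round-trips through [read_spectrum()] to 1 part in 10^6,
#' preserving modality and temperature metadata.
#'
#' @param spectrum a [spectrum_trace()] object.
#' @param path output file.
#' @param format `"csv"` or `"jcamp-dx"`.
#' @export
write_spectrum <- function(spectrum, path, format = c("csv", "jcamp-dx")) {
  format <- match.arg(format)
  stopifnot(inherits(spectrum, "cd_spectrum"))
  lines <- if (format == "csv") {
    c(sprintf("# modality = %s", spectrum$modality),
      if (is.finite(spectrum$temperature))
        sprintf("# temperature_K = %.10g", spectrum$temperature),
      "axis,intensity",
      sprintf("%.10g,%.10g", spectrum$axis, spectrum$intensity))
  } else {
    n <- length(spectrum$axis)
    c("##TITLE=cyclofit spectrum",
      "##JCAMP-DX=4.24",
      "##DATA TYPE=SPECTRUM",
      sprintf("##$MODALITY=%s", spectrum$modality),
      if (is.finite(spectrum$temperature))
        sprintf("##TEMPERATURE=%.10g", spectrum$temperature),
      "##XUNITS=1/CM", "##YUNITS=ABSORBANCE",
      "##XFACTOR=1", "##YFACTOR=1",
      sprintf("##FIRSTX=%.10g", spectrum$axis[1L]),
      sprintf("##LASTX=%.10g", spectrum$axis[n]),
      sprintf("##NPOINTS=%d", n),
      "##XYPOINTS=(XY..XY)",
      sprintf("%.10g, %.10g", spectrum$axis, spectrum$intensity),
      "##END=")
  }
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop(sprintf("cannot write to %s", path), call. = FALSE)
  invisible(NULL)
}

#' Crop a spectrum to an axis window
#'
#' Retains the original intensities at axis points inside `[lo, hi]`; the
#' bounds may be given in either order (spectroscopists quote the O-H window
#' as 3800-3000 cm^-1).
#'
#' @param spectrum a [spectrum_trace()] object.
#' @param lo,hi window bounds on the axis.
#' @return The cropped [spectrum_trace()].
#' @export
crop <- function(spectrum, lo, hi) {
  stopifnot(inherits(spectrum, "cd_spectrum"))
  w <- sort(c(lo, hi))
  keep <- spectrum$axis >= w[1L] & spectrum$axis <= w[2L]
  if (sum(keep) < 2L)
    stop(sprintf("crop window [%g, %g] does not overlap the axis (%g-%g)",
                 w[1L], w[2L], min(spectrum$axis), max(spectrum$axis)),
         call. = FALSE)
  spectrum_trace(spectrum$axis[keep], spectrum$intensity[keep],
                 modality = spectrum$modality,
                 temperature = spectrum$temperature)
}

#' Trapezoidal integral of a trace
#' @param x,y numeric vectors of equal length, `x` ascending.
#' @return The trapezoid-rule integral.
#' @keywords internal
trapz_area <- function(x, y) {
  n <- length(x)
  sum((x[-1L] - x[-n]) * (y[-1L] + y[-n])) / 2
}

#' Normalize a spectrum
#'
#' `"unit-area"` divides by the trapezoidal integral over the axis (the
#' convention used to account for the effective number of absorbers before
#' comparing traces across temperature); `"unit-max"` divides by the maximum.
#'
#' @param spectrum a [spectrum_trace()] object.
#' @param mode `"unit-area"` or `"unit-max"`.
#' @return The normalized [spectrum_trace()].
#' @export
normalize <- function(spectrum, mode = c("unit-area", "unit-max")) {
  mode <- match.arg(mode)
  stopifnot(inherits(spectrum, "cd_spectrum"))
  if (all(spectrum$intensity == 0))
    stop("cannot normalize an all-zero spectrum", call. = FALSE)
  denom <- if (mode == "unit-area") {
    a <- trapz_area(spectrum$axis, spectrum$intensity)
    if (a <= 0) stop("unit-area normalization needs a positive integral",
                     call. = FALSE)
    a
  } else max(spectrum$intensity)
  spectrum_trace(spectrum$axis, spectrum$intensity / denom,
                 modality = spectrum$modality,
                 temperature = spectrum$temperature)
}

#' Ordered series of spectra on a shared grid
#'
#' Bundles spectra measured under a varying condition (temperature in K, or
#' titrant concentration in M) on one common axis grid, sorted by condition.
#'
#' @param spectra list of [spectrum_trace()] objects sharing one axis.
#' @param condition numeric condition per spectrum, unique values.
#' @return An object of class `cd_series`.
#' @export
spectral_series <- function(spectra, condition) {
  if (length(spectra) != length(condition))
    stop("one condition value per spectrum required", call. = FALSE)
  if (anyDuplicated(condition))
    stop("condition values must be unique", call. = FALSE)
  ax <- spectra[[1L]]$axis
  same <- vapply(spectra, function(s)
    length(s$axis) == length(ax) && all(s$axis == ax), TRUE)
  if (!all(same))
    stop("all member spectra must share an identical axis grid",
         call. = FALSE)
  o <- order(condition)
  structure(list(spectra = spectra[o], condition = as.numeric(condition[o]),
                 axis = ax),
            class = "cd_series")
}

#' @export
print.cd_series <- function(x, ...) {
  cat(sprintf("<cd_series> %d spectra, condition %.6g-%.6g, axis %.6g-%.6g\n",
              length(x$spectra), min(x$condition), max(x$condition),
              min(x$axis), max(x$axis)))
  invisible(x)
}
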