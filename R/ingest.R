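#' Construct a spectral cube
#'
#' @param data 3-D reflectance array indexed (row, col, band).
#' @param wavelengths Band centres (nm), strictly increasing, length equal
#'   to the third dimension of `data`.
#' @param meta Free-text acquisition notes.
#' @return A list of class `"spectral_cube"`.
#' @export
spectral_cube <- function(data, wavelengths, meta = "") {
  if (length(dim(data)) != 3L) stopf("data must be a 3-D array")
  if (dim(data)[3] != length(wavelengths))
    stopf("cube has %d bands but %d wavelengths given", dim(data)[3],
          length(wavelengths))
  if (any(diff(wavelengths) <= 0))
    stopf("wavelengths must be strictly increasing")
  structure(list(data = data, wavelengths = as.numeric(wavelengths),
                 meta = meta),
            class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Spectral cube: %d x %d pixels, %d bands (%.1f-%.1f nm)\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Read / write hyperspectral cubes
#'
#' ENVI-style storage: a text header (`<path>.hdr`) holding `samples`,
#' `lines`, `bands`, `interleave`, `data type` and the wavelength list,
#' next to a raw little-endian binary file.  Only 64-bit float (ENVI data
#' type 5) payloads in BSQ or BIL interleave are produced/consumed, which
#' makes write-then-read bit-exact.
#'
#' @param path Path of the binary file (header is `<path>.hdr`).
#' @param format Only `"envi"` is supported.
#' @param cube A `"spectral_cube"`.
#' @param interleave `"bsq"` or `"bil"`.
#' @return `read_cube` returns a `"spectral_cube"`; `write_cube` returns
#'   `path` invisibly.
#' @export
read_cube <- function(path, format = c("envi", "hdf5")) {
  format <- match.arg(format)
  if (format == "hdf5")
    stopf("hdf5 cubes are not supported by this build; use format = 'envi'")
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path)) stopf("missing ENVI header: %s", hdr_path)
  if (!file.exists(path)) stopf("missing ENVI binary: %s", path)
  hdr <- parse_envi_header(hdr_path)
  for (k in c("samples", "lines", "bands"))
    if (is.null(hdr[[k]])) stopf("ENVI header lacks '%s'", k)
  if (is.null(hdr$wavelength))
    stopf("ENVI header lacks wavelengths; refusing to invent an index grid")
  nl <- as.integer(hdr$lines); ns <- as.integer(hdr$samples)
  nb <- as.integer(hdr$bands)
  wl <- as.numeric(hdr$wavelength)
  if (length(wl) != nb)
    stopf("header declares %d bands but %d wavelengths", nb, length(wl))
  if (!is.null(hdr$`data type`) && as.integer(hdr$`data type`) != 5L)
    stopf("only ENVI data type 5 (float64) supported")
  il <- tolower(if (is.null(hdr$interleave)) "bsq" else hdr$interleave)
  raw <- readBin(path, "double", n = nl * ns * nb, size = 8,
                 endian = "little")
  if (length(raw) != nl * ns * nb)
    stopf("binary holds %d values, header implies %d", length(raw),
          nl * ns * nb)
  data <- switch(il,
    bsq = aperm(array(raw, dim = c(ns, nl, nb)), c(2, 1, 3)),
    bil = aperm(array(raw, dim = c(ns, nb, nl)), c(3, 1, 2)),
    stopf("unsupported interleave '%s'", il))
  spectral_cube(data, wl,
                meta = if (is.null(hdr$description)) "" else hdr$description)
}

#' @rdname read_cube
#' @export
write_cube <- function(cube, path, format = c("envi", "hdf5"),
                       interleave = c("bsq", "bil")) {
  format <- match.arg(format)
  interleave <- match.arg(interleave)
  if (format == "hdf5")
    stopf("hdf5 cubes are not supported by this build; use format = 'envi'")
  stopifnot(inherits(cube, "spectral_cube"))
  d <- dim(cube$data)
  vals <- switch(interleave,
    bsq = as.vector(aperm(cube$data, c(2, 1, 3))),
    bil = as.vector(aperm(cube$data, c(2, 3, 1))))
  writeBin(vals, path, size = 8, endian = "little")
  hdr <- c("ENVI",
           sprintf("description = {%s}", cube$meta),
           sprintf("samples = %d", d[2]),
           sprintf("lines = %d", d[1]),
           sprintf("bands = %d", d[3]),
           "header offset = 0",
           "file type = ENVI Standard",
           "data type = 5",
           sprintf("interleave = %s", interleave),
           "byte order = 0",
           sprintf("wavelength units = nm"),
           sprintf("wavelength = {%s}",
                   paste(format(cube$wavelengths, digits = 15, trim = TRUE),
                         collapse = ", ")))
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  out <- list()
  # multi-line brace values first
  m <- gregexpr("([a-zA-Z ]+)=\\s*\\{([^}]*)\\}", txt)[[1]]
  if (m[1] != -1) {
    for (i in seq_along(m)) {
      piece <- substr(txt, m[i], m[i] + attr(m, "match.length")[i] - 1)
      key <- trimws(sub("=.*", "", piece))
      val <- sub(".*\\{", "", sub("\\}.*", "", piece))
      items <- trimws(strsplit(val, ",")[[1]])
      out[[tolower(key)]] <- if (suppressWarnings(!anyNA(as.numeric(items))) &&
                                 length(items) > 0 && nzchar(items[1]))
        as.numeric(items) else paste(items, collapse = ", ")
    }
    txt <- gsub("([a-zA-Z ]+)=\\s*\\{[^}]*\\}", "", txt)
  }
  for (line in strsplit(txt, "\n")[[1]]) {
    if (!grepl("=", line)) next
    key <- tolower(trimws(sub("=.*", "", line)))
    val <- trimws(sub("^[^=]*=", "", line))
    out[[key]] <- val
  }
  out
}

#' Locate the band nearest a target wavelength
#'
#' @param wavelengths Strictly increasing band centres (nm).
#' @param target_nm Target wavelength.
#' @return Integer band position; ties between two equidistant centres go to
#'   the lower wavelength.  Targets more than one grid spacing outside the
#'   grid are rejected.
#' @export
band_index <- function(wavelengths, target_nm) {
  if (length(wavelengths) == 0L) stopf("empty wavelength grid")
  delta <- if (length(wavelengths) > 1L) min(diff(wavelengths)) else Inf
  if (target_nm < min(wavelengths) - delta ||
      target_nm > max(wavelengths) + delta)
    stopf("target %.1f nm outside grid [%.1f, %.1f] +/- %.2f",
          target_nm, min(wavelengths), max(wavelengths), delta)
  d <- abs(wavelengths - target_nm)
  # which.min takes the first (= lower-wavelength) minimiser: the tie rule
  which.min(d)
}

#' Segment leaves from a bright background
#'
#' Thresholds the single band nearest `band_nm`: a pixel is leaf when its
#' reflectance is **below** `threshold` (chlorophyll absorbs strongly near
#' 655 nm while the white board stays bright).  Leaf pixels are grouped by
#' 8-connectivity; components smaller than `min_area` pixels are discarded
#' as noise.  Regions are numbered in reading order of their centroids
#' (top-to-bottom, then left-to-right).
#'
#' @param cube A `"spectral_cube"`.
#' @param band_nm Segmentation band (default 655 nm).
#' @param threshold Reflectance threshold in (0,1), default 0.6.
#' @param min_area Minimum component size in pixels (default 20).
#' @return A list of class `"leaf_mask"`: integer matrix `labels`
#'   (0 = background), `n_regions`, `threshold_used`, `band_used`.
#' @export
segment_leaves <- function(cube, band_nm = 655, threshold = 0.6,
                           min_area = 20) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (threshold <= 0 || threshold >= 1) stopf("threshold must be in (0,1)")
  b <- band_index(cube$wavelengths, band_nm)
  fg <- cube$data[, , b] < threshold
  labels <- label_components(fg, min_area = min_area)
  structure(list(labels = labels, n_regions = max(labels),
                 threshold_used = threshold,
                 band_used = cube$wavelengths[b]),
            class = "leaf_mask")
}

#' @export
print.leaf_mask <- function(x, ...) {
  cat(sprintf("Leaf mask: %d region(s); threshold %.2f at %.1f nm\n",
              x$n_regions, x$threshold_used, x$band_used))
  invisible(x)
}

# 8-connected component labelling by breadth-first flood fill, then
# relabelling in centroid reading order.
label_components <- function(fg, min_area = 1) {
  h <- nrow(fg); w <- ncol(fg)
  lab <- matrix(0L, h, w)
  cur <- 0L
  off_y <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  off_x <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  for (start in which(fg)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      py <- ((p - 1L) %% h) + 1L
      px <- ((p - 1L) %/% h) + 1L
      ny <- py + off_y; nx <- px + off_x
      ok <- ny >= 1L & ny <= h & nx >= 1L & nx <= w
      nb <- (nx[ok] - 1L) * h + ny[ok]
      nb <- nb[fg[nb] & lab[nb] == 0L]
      if (length(nb)) {
        lab[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  if (cur == 0L) return(lab)
  sizes <- tabulate(lab, cur)
  keep <- which(sizes >= min_area)
  # centroid reading order: by centroid row, then centroid column
  cy <- vapply(keep, function(k) mean(row(lab)[lab == k]), 0)
  cx <- vapply(keep, function(k) mean(col(lab)[lab == k]), 0)
  keep <- keep[order(cy, cx)]
  out <- matrix(0L, h, w)
  for (i in seq_along(keep)) out[lab == keep[i]] <- i
  out
}

#' Extract per-leaf mean spectra
#'
#' Row k of the result is the arithmetic mean spectrum over the pixels of
#' mask region k, in region label order.
#'
#' @param cube A `"spectral_cube"`.
#' @param mask A `"leaf_mask"` or an integer label matrix of the cube's
#'   spatial shape.
#' @param labels_metadata Optional data frame with one row per region
#'   (columns `polymer`, `class_mg_l`); defaults to `"unknown"`.
#' @return A `"labeled_spectra"` with one row per region.
#' @export
extract_mean_spectra <- function(cube, mask, labels_metadata = NULL) {
  stopifnot(inherits(cube, "spectral_cube"))
  lab <- if (inherits(mask, "leaf_mask")) mask$labels else mask
  if (!all(dim(lab) == dim(cube$data)[1:2]))
    stopf("mask shape %dx%d does not match cube %dx%d", nrow(lab), ncol(lab),
          dim(cube$data)[1], dim(cube$data)[2])
  n <- max(lab)
  if (n == 0L) stopf("mask contains no regions")
  B <- length(cube$wavelengths)
  if (!is.null(labels_metadata)) {
    if (nrow(labels_metadata) != n)
      stopf("labels_metadata has %d rows for %d regions",
            nrow(labels_metadata), n)
    if (any(is.na(labels_metadata$polymer)) ||
        any(is.na(labels_metadata$class_mg_l)))
      stopf("empty region label in metadata")
  }
  X <- matrix(0, n, B)
  flat <- matrix(cube$data, ncol = B)   # (h*w) x B view
  for (k in seq_len(n)) {
    px <- which(lab == k)
    if (length(px) == 0L) stopf("region %d has no pixels", k)
    X[k, ] <- colMeans(flat[px, , drop = FALSE])
  }
  md <- labels_metadata
  labeled_spectra(X, cube$wavelengths,
                  polymer = if (is.null(md)) rep("unknown", n) else md$polymer,
                  class_mg_l = if (is.null(md)) rep("unknown", n)
                               else md$class_mg_l,
                  sample_id = sprintf("leaf%02d", seq_len(n)))
}

#' Retain bands within a wavelength interval
#'
#' Keeps bands whose centre lies in the closed interval `[lo_nm, hi_nm]`
#' (default 425--965 nm, the low-noise interior of a VNIR acquisition).
#'
#' @param spectra A `"labeled_spectra"`.
#' @param lo_nm,hi_nm Interval bounds (nm), `lo_nm < hi_nm`.
#' @return A `"labeled_spectra"` restricted to the retained bands.
#' @export
crop_bands <- function(spectra, lo_nm = 425, hi_nm = 965) {
  stopifnot(inherits(spectra, "labeled_spectra"))
  if (lo_nm >= hi_nm) stopf("lo_nm must be < hi_nm")
  keep <- spectra$wavelengths >= lo_nm & spectra$wavelengths <= hi_nm
  if (!any(keep))
    stopf("no bands inside [%.1f, %.1f] nm", lo_nm, hi_nm)
  labeled_spectra(spectra$X[, keep, drop = FALSE],
                  spectra$wavelengths[keep],
                  spectra$polymer, spectra$class_mg_l, spectra$sample_id)
}

#' Write / read labelled spectra as CSV
#'
#' Header row: `id, polymer, class_mg_per_L`, then one column per band
#' centre (nm).
#'
#' @param spectra A `"labeled_spectra"`.
#' @param path CSV path.
#' @return `write_spectra_csv` returns `path` invisibly; `read_spectra_csv`
#'   a `"labeled_spectra"`.
#' @export
write_spectra_csv <- function(spectra, path) {
  df <- data.frame(id = spectra$sample_id,
                   polymer = as.character(spectra$polymer),
                   class_mg_per_L = as.character(spectra$class_mg_l),
                   spectra$X, check.names = FALSE)
  names(df)[-(1:3)] <- format(spectra$wavelengths, digits = 10, trim = TRUE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  wl <- as.numeric(names(df)[-(1:3)])
  labeled_spectra(as.matrix(df[, -(1:3), drop = FALSE]), wl,
                  df$polymer, df$class_mg_per_L, df$id)
}
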