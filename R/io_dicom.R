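# Minimal DICOM support: explicit-VR little-endian single-frame grayscale
# files only. The writer emits synthetic series (used by tests and the
# simulator); the reader assembles one 3D volume per series directory,
# sorting slices by position along the slice normal. Sequences (SQ) and
# undefined lengths are not supported.

UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_SC_STORAGE <- "1.2.840.10008.5.1.4.1.1.7"
UID_ROOT <- "1.2.826.0.1.3680043.9.7441"  # arbitrary org root for synthetic UIDs

.dcm_state <- new.env(parent = emptyenv())
.dcm_state$uid_counter <- 0L

dcm_u16 <- function(x) {
  x <- as.integer(x)
  writeBin(ifelse(x > 32767L, x - 65536L, x), raw(), size = 2,
           endian = "little")
}
dcm_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

dcm_pad <- function(val, pad = as.raw(0x20)) {
  if (length(val) %% 2L == 1L) c(val, pad) else val
}

# one explicit-VR element
dcm_element <- function(group, element, vr, value) {
  if (is.character(value))
    value <- charToRaw(value)
  value <- dcm_pad(value, if (vr == "UI") as.raw(0) else as.raw(0x20))
  head <- c(dcm_u16(group), dcm_u16(element), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN"))
    c(head, as.raw(c(0, 0)), dcm_u32(length(value)), value)
  else
    c(head, dcm_u16(length(value)), value)
}

ds_str <- function(...) paste(vapply(list(...), function(x)
  format(x, trim = TRUE, scientific = FALSE), ""), collapse = "\\")

#' Write a 3D volume as a synthetic DICOM series
#'
#' Emits one explicit-VR little-endian single-frame file per slice into a
#' directory: secondary-capture grayscale with 16-bit pixels, rescale
#' slope/intercept chosen so the stored integers reproduce the input values
#' (exactly for non-negative integer data within 16-bit range). Intended
#' for generating synthetic test series and for interchange with DICOM
#' viewers; not a clinical archive writer.
#'
#' @param volume 3D numeric array (x, y, z).
#' @param dir Output directory (created if needed).
#' @param spacing_mm Voxel spacing (mm).
#' @param series_uid Series instance UID; generated when `NULL`.
#' @param time_ms Optional saturation time stored in the inversion-time tag
#'   (0018,0082) of every slice, retrievable via the `time_tag` argument of
#'   [read_dicom_series()].
#' @return Invisibly, the vector of file paths written.
#' @export
write_dicom_series <- function(volume, dir, spacing_mm = c(1, 1, 1),
                               series_uid = NULL, time_ms = NULL) {
  stopifnot(length(dim(volume)) == 3L, all(is.finite(volume)))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(volume)
  if (is.null(series_uid)) {
    .dcm_state$uid_counter <- .dcm_state$uid_counter + 1L  # no RNG use
    series_uid <- paste0(UID_ROOT, ".", Sys.getpid(), ".",
                         .dcm_state$uid_counter)
  }
  study_uid <- paste0(series_uid, ".0")

  lo <- min(volume); hi <- max(volume)
  integral <- all(volume == round(volume)) && lo >= 0 && hi <= 65535
  if (integral) { slope <- 1; intercept <- 0 }
  else {
    slope <- if (hi > lo) (hi - lo) / 65535 else 1
    intercept <- lo
  }

  paths <- character(d[3])
  for (k in seq_len(d[3])) {
    sop_uid <- paste0(series_uid, ".", k)
    stored <- round((as.vector(volume[, , k]) - intercept) / slope)
    px <- dcm_u16(stored)

    meta <- c(
      dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
      dcm_element(0x0002, 0x0002, "UI", UID_SC_STORAGE),
      dcm_element(0x0002, 0x0003, "UI", sop_uid),
      dcm_element(0x0002, 0x0010, "UI", UID_EXPLICIT_LE))
    body <- c(
      dcm_element(0x0008, 0x0016, "UI", UID_SC_STORAGE),
      dcm_element(0x0008, 0x0018, "UI", sop_uid),
      dcm_element(0x0018, 0x0050, "DS", ds_str(spacing_mm[3])),
      if (!is.null(time_ms))
        dcm_element(0x0018, 0x0082, "DS", ds_str(time_ms)),
      dcm_element(0x0020, 0x000D, "UI", study_uid),
      dcm_element(0x0020, 0x000E, "UI", series_uid),
      dcm_element(0x0020, 0x0013, "IS", ds_str(k)),
      dcm_element(0x0020, 0x0032, "DS",
                  ds_str(0, 0, (k - 1) * spacing_mm[3])),
      dcm_element(0x0020, 0x0037, "DS", ds_str(1, 0, 0, 0, 1, 0)),
      dcm_element(0x0028, 0x0002, "US", dcm_u16(1)),
      dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dcm_element(0x0028, 0x0010, "US", dcm_u16(d[2])),  # Rows = y
      dcm_element(0x0028, 0x0011, "US", dcm_u16(d[1])),  # Columns = x
      dcm_element(0x0028, 0x0030, "DS", ds_str(spacing_mm[2], spacing_mm[1])),
      dcm_element(0x0028, 0x0100, "US", dcm_u16(16)),
      dcm_element(0x0028, 0x0101, "US", dcm_u16(16)),
      dcm_element(0x0028, 0x0102, "US", dcm_u16(15)),
      dcm_element(0x0028, 0x0103, "US", dcm_u16(0)),
      dcm_element(0x0028, 0x1052, "DS", ds_str(intercept)),
      dcm_element(0x0028, 0x1053, "DS", ds_str(slope)),
      dcm_element(0x7FE0, 0x0010, "OW", px))
    grouplen <- dcm_element(0x0002, 0x0000, "UL", dcm_u32(length(meta)))
    paths[k] <- file.path(dir, sprintf("slice%04d.dcm", k))
    con <- file(paths[k], "wb")
    writeBin(c(raw(128), charToRaw("DICM"), grouplen, meta, body), con)
    close(con)
  }
  invisible(paths)
}

rd_u16 <- function(r, off) as.integer(r[off]) + 256L * as.integer(r[off + 1L])
rd_u32 <- function(r, off)
  as.integer(r[off]) + 256 * as.integer(r[off + 1L]) +
  65536 * as.integer(r[off + 2L]) + 16777216 * as.integer(r[off + 3L])

# parse one explicit-VR LE file into a named list of elements
dcm_parse <- function(path) {
  r <- readBin(path, "raw", file.size(path))
  if (length(r) < 140L || rawToChar(r[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM marker): ", path)
  off <- 133L
  out <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (off + 7L <= length(r)) {
    group <- rd_u16(r, off); elem <- rd_u16(r, off + 2L)
    vr <- rawToChar(r[(off + 4L):(off + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("unsupported (non explicit-VR little-endian) encoding in ", path)
    if (vr %in% long_vrs) {
      len <- rd_u32(r, off + 8L); voff <- off + 12L
    } else {
      len <- rd_u16(r, off + 6L); voff <- off + 8L
    }
    if (len == 4294967295 || vr == "SQ")
      stop("sequences/undefined lengths are not supported: ", path)
    val <- if (len > 0L) r[voff:(voff + len - 1L)] else raw(0)
    key <- sprintf("%04X,%04X", group, elem)
    out[[key]] <- list(vr = vr, raw = val)
    off <- voff + len
  }
  out
}

dcm_string <- function(el) {
  if (is.null(el)) return(NULL)
  v <- el$raw
  while (length(v) && v[length(v)] %in% as.raw(c(0x00, 0x20)))
    v <- v[-length(v)]
  rawToChar(v)
}
dcm_numbers <- function(el) {
  s <- dcm_string(el)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}
dcm_us <- function(el) rd_u16(el$raw, 1L)

dcm_read_slice <- function(path) {
  els <- dcm_parse(path)
  need <- c("0028,0010", "0028,0011", "7FE0,0010", "0020,0032")
  miss <- setdiff(need, names(els))
  if (length(miss))
    stop("missing required DICOM element(s) ", paste(miss, collapse = ", "),
         " in ", path)
  rows <- dcm_us(els[["0028,0010"]])
  cols <- dcm_us(els[["0028,0011"]])
  bits <- if (!is.null(els[["0028,0100"]])) dcm_us(els[["0028,0100"]]) else 16L
  if (bits != 16L) stop("only 16-bit pixel data is supported: ", path)
  px <- readBin(els[["7FE0,0010"]]$raw, "integer", n = rows * cols,
                size = 2, signed = FALSE, endian = "little")
  slope <- dcm_numbers(els[["0028,1053"]]) %||% 1
  intercept <- dcm_numbers(els[["0028,1052"]]) %||% 0
  ps <- dcm_numbers(els[["0028,0030"]]) %||% c(1, 1)
  orient <- dcm_numbers(els[["0020,0037"]]) %||% c(1, 0, 0, 0, 1, 0)
  list(pixels = matrix(px * slope + intercept, nrow = cols, ncol = rows),
       position = dcm_numbers(els[["0020,0032"]]),
       orientation = orient,
       spacing_rc = ps,  # (row spacing = y, column spacing = x)
       slice_thickness = dcm_numbers(els[["0018,0050"]]) %||% NA_real_,
       series_uid = dcm_string(els[["0020,000E"]]),
       elements = els)
}

cross3 <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

read_dicom_volume <- function(dir, time_tag = NULL) {
  files <- sort(list.files(dir, full.names = TRUE))
  if (!length(files)) stop("empty DICOM directory: ", dir)
  slices <- lapply(files, dcm_read_slice)
  uids <- unique(vapply(slices, function(s) s$series_uid %||% "", ""))
  if (length(uids) > 1L)
    stop("mixed series UIDs in one directory: ", dir, " (",
         paste(uids, collapse = ", "), ")")
  orient <- slices[[1]]$orientation
  normal <- cross3(orient[1:3], orient[4:6])
  pos <- vapply(slices, function(s) sum(s$position * normal), 1.0)
  ord <- order(pos)
  slices <- slices[ord]; pos <- pos[ord]
  nz <- length(slices)
  dz <- NA_real_
  if (nz > 1L) {
    gaps <- diff(pos)
    dz <- stats::median(gaps)
    bad <- which(abs(gaps - dz) > 0.25 * dz)
    if (length(bad))
      stop(sprintf(
        "non-uniform slice spacing in %s: gap of %.3g mm between positions %.3g and %.3g (expected %.3g)",
        dir, gaps[bad[1]], pos[bad[1]], pos[bad[1] + 1L], dz))
  } else dz <- slices[[1]]$slice_thickness
  if (!is.finite(dz) || dz <= 0) dz <- 1
  d <- c(dim(slices[[1]]$pixels), nz)
  vol <- array(0, d)
  for (k in seq_len(nz)) {
    if (!identical(dim(slices[[k]]$pixels), dim(slices[[1]]$pixels)))
      stop("inconsistent slice dimensions in ", dir)
    vol[, , k] <- slices[[k]]$pixels
  }
  time_ms <- NULL
  if (!is.null(time_tag)) {
    el <- slices[[1]]$elements[[toupper(time_tag)]]
    if (is.null(el)) stop("time tag ", time_tag, " absent in ", dir)
    time_ms <- dcm_numbers(el)[1]
    message("using time ", time_ms, " ms from DICOM tag (", time_tag,
            ") for ", dir)
  }
  sp <- c(slices[[1]]$spacing_rc[2], slices[[1]]$spacing_rc[1], dz)
  list(volume = vol, spacing_mm = sp, time_ms = time_ms)
}

#' Assemble a contrast stack from DICOM series directories
#'
#' Each directory holds one contrast's series of single-frame explicit-VR
#' little-endian slices. Slices are sorted by their position projected onto
#' the slice normal (so file discovery order is irrelevant); a missing
#' slice (non-uniform position gaps) and mixed series UIDs are errors.
#' Saturation times are taken from the `times_ms` argument by default:
#' timing tags are vendor-inconsistent and are not trusted silently. Pass
#' `time_tag` (e.g. `"0018,0082"`) to read them from the files instead; the
#' tag used is logged.
#'
#' @param dirs Character vector of series directories, one per contrast, in
#'   schedule order.
#' @param times_ms Saturation times (ms, `Inf` for the unprepared image);
#'   required unless `time_tag` is given.
#' @param time_tag Optional `"GGGG,EEEE"` tag string to read per-series
#'   times from the files.
#' @return A [contrast_stack()].
#' @export
read_dicom_series <- function(dirs, times_ms = NULL, time_tag = NULL) {
  if (!length(dirs)) stop("no series directories given")
  vols <- lapply(dirs, read_dicom_volume, time_tag = time_tag)
  if (is.null(times_ms)) {
    times_ms <- vapply(vols, function(v) v$time_ms %||% NA_real_, 1.0)
    if (any(is.na(times_ms)))
      stop("times_ms not given and no time_tag values found")
  }
  dims <- lapply(vols, function(v) dim(v$volume))
  if (length(unique(dims)) != 1L)
    stop("inconsistent geometry across series: ",
         paste(dirs[vapply(dims, function(d) !identical(d, dims[[1]]), TRUE)],
               collapse = ", "))
  data <- array(unlist(lapply(vols, function(v) v$volume)),
                c(dims[[1]], length(vols)))
  contrast_stack(data, times_ms = times_ms, spacing_mm = vols[[1]]$spacing_mm)
}
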