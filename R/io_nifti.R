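#' Read and write contrast-time sidecar files
#'
#' Plain-text sidecar: one saturation time (ms) per line, with the literal
#' `inf` marking the unprepared (fully recovered) image.
#'
#' @param path File path.
#' @return `read_times` returns a numeric vector with `Inf` for the
#'   sentinel.
#' @export
read_times <- function(path) {
  if (!file.exists(path)) stop("times file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  vals <- suppressWarnings(as.numeric(lines))
  vals[tolower(lines) %in% c("inf", "+inf", "infinity")] <- Inf
  if (any(is.na(vals)))
    stop("unparseable entries in times file: ",
         paste(lines[is.na(vals)], collapse = ", "))
  vals
}

#' @rdname read_times
#' @param times_ms Numeric vector of times, `Inf` allowed.
#' @export
write_times <- function(times_ms, path) {
  writeLines(ifelse(is.finite(times_ms),
                    format(times_ms, trim = TRUE, digits = 15), "inf"),
             path)
  invisible(path)
}

#' Manifest describing a stack on disk
#'
#' Binds together either one 4D NIfTI volume or one 3D NIfTI per contrast,
#' the contrast-times sidecar, and an optional spacing override.
#'
#' @param paths Character vector: one 4D NIfTI path, or `n` 3D NIfTI paths
#'   in contrast order.
#' @param times_file Path of the sidecar written by [write_times()].
#' @param spacing_mm Optional length-3 spacing override (mm); by default
#'   spacing is taken from the NIfTI headers.
#' @return A `stack_manifest` object.
#' @export
stack_manifest <- function(paths, times_file, spacing_mm = NULL) {
  stopifnot(length(paths) >= 1L, length(times_file) == 1L)
  structure(list(paths = paths, times_file = times_file,
                 spacing_mm = spacing_mm),
            class = "stack_manifest")
}

nifti_spacing <- function(img) {
  pd <- attr(img, "pixdim")
  if (is.null(pd)) pd <- RNifti::pixdim(img)
  as.numeric(pd[1:3])
}

#' Read a contrast stack from NIfTI files
#'
#' Loads either a single 4D NIfTI or one 3D NIfTI per contrast, together
#' with the contrast-times sidecar. Volumes are required to share grid
#' shape and spacing exactly; no resampling is performed — inconsistent
#' geometry is an error that names the offending files.
#'
#' @param manifest A [stack_manifest()], or a character vector of paths
#'   (then `times_file` must be given).
#' @param times_file Sidecar path when `manifest` is a plain path vector.
#' @return A [contrast_stack()].
#' @export
read_stack <- function(manifest, times_file = NULL) {
  if (!inherits(manifest, "stack_manifest")) {
    if (is.null(times_file))
      stop("times_file is required when paths are given directly")
    manifest <- stack_manifest(manifest, times_file)
  }
  for (p in manifest$paths)
    if (!file.exists(p)) stop("volume not found: ", p)
  times <- read_times(manifest$times_file)
  if (sum(!is.finite(times)) > 1L)
    stop("at most one unprepared (inf) entry is allowed in the times file")

  imgs <- lapply(manifest$paths, RNifti::readNifti)
  if (length(imgs) == 1L && length(dim(imgs[[1]])) == 4L) {
    data <- array(as.numeric(imgs[[1]]), dim(imgs[[1]]))
    spacing <- nifti_spacing(imgs[[1]])
  } else {
    dims <- lapply(imgs, function(x) as.integer(dim(x)))
    spcs <- lapply(imgs, nifti_spacing)
    bad <- which(vapply(dims, function(d) !identical(d, dims[[1]]), TRUE) |
                   vapply(spcs, function(s) any(abs(s - spcs[[1]]) > 1e-4), TRUE))
    if (length(bad))
      stop("inconsistent geometry across contrasts: ",
           paste(manifest$paths[bad], collapse = ", "))
    data <- array(unlist(lapply(imgs, as.numeric)),
                  c(dims[[1]], length(imgs)))
    spacing <- spcs[[1]]
  }
  if (dim(data)[4] != length(times))
    stop(sprintf("times file has %d entries for %d volumes",
                 length(times), dim(data)[4]))
  spacing <- manifest$spacing_mm %||% spacing
  contrast_stack(data, times_ms = times, spacing_mm = spacing)
}

#' Write a contrast stack as one 4D NIfTI plus a times sidecar
#'
#' @param stack A [contrast_stack()].
#' @param path Output `.nii`/`.nii.gz` path.
#' @param times_file Sidecar path; defaults to `path` with a `.times.txt`
#'   extension.
#' @return Invisibly, the main path.
#' @export
write_stack <- function(stack, path,
                        times_file = sub("\\.nii(\\.gz)?$", ".times.txt", path)) {
  stopifnot(inherits(stack, "contrast_stack"))
  img <- RNifti::asNifti(stack$data)
  RNifti::pixdim(img) <- c(stack$spacing_mm, 1)
  RNifti::writeNifti(img, path)
  write_times(stack$times_ms, times_file)
  invisible(path)
}

#' Write/read a 3D volume (e.g. a T1 map) as NIfTI
#'
#' @param volume 3D numeric array.
#' @param path Output path.
#' @param spacing_mm Voxel spacing (mm).
#' @return Invisibly, the path.
#' @export
write_volume <- function(volume, path, spacing_mm = c(1, 1, 1)) {
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  structure(array(as.numeric(img), dim(img)), spacing_mm = nifti_spacing(img))
}

#' Read/write a phantom specification as YAML or JSON
#'
#' The on-disk representation uses the field names of [phantom_spec()]
#' verbatim; the unprepared contrast time is serialized as the string
#' `"inf"`, never as a fake large number.
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_phantom_spec` returns a [phantom_spec()].
#' @export
read_phantom_spec <- function(path) {
  raw <- if (grepl("\\.json$", path))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  times <- vapply(raw$times_ms, function(t)
    if (is.character(t) && tolower(t) == "inf") Inf else as.numeric(t), 1.0)
  regions <- lapply(raw$regions, function(r) {
    r <- lapply(r, function(x) if (is.list(x)) unlist(x) else x)
    r$label <- as.integer(r$label)
    r
  })
  phantom_spec(grid_shape = unlist(raw$grid_shape),
               spacing_mm = unlist(raw$spacing_mm),
               regions = regions, times_ms = times,
               noise_sigma = raw$noise_sigma %||% 0,
               noise_model = raw$noise_model %||% "gaussian",
               seed = raw$seed %||% 1L)
}

#' @rdname read_phantom_spec
#' @param spec A [phantom_spec()].
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  obj <- unclass(spec)
  obj$times_ms <- lapply(obj$times_ms, function(t)
    if (is.finite(t)) t else "inf")
  if (grepl("\\.json$", path))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(obj, path)
  invisible(path)
}
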