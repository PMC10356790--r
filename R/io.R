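#' Construct a volume
#'
#' A volume is a 3D scalar image with an optional voxel-to-world affine and
#' an optional binary class label. Voxel indexing is 0-based in all crop
#' specifications; axes are ordered (x, y, z) matching the stored array.
#'
#' @param data numeric 3D array.
#' @param affine 4x4 voxel-to-world matrix; identity by default.
#' @param label optional binary label in \{0, 1\}.
#' @return object of class `volume`.
#' @export
volume <- function(data, affine = diag(4), label = NULL) {
  if (length(dim(data)) != 3L) stop("volume data must be a 3D array")
  if (any(dim(data) < 1L)) stop("all spatial extents must be >= 1")
  if (!is.null(label) && !label %in% c(0, 1)) stop("label must be 0 or 1")
  structure(list(data = data, affine = affine, label = label),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  cat("<volume> ", paste(dim(x$data), collapse = " x "),
      if (!is.null(x$label)) sprintf(" | label %d", x$label), "\n", sep = "")
  invisible(x)
}

#' Read a 3D volume from NIfTI
#'
#' Reads a NIfTI-1/2 file; single-frame 4D images are squeezed to 3D,
#' genuinely 4D images are rejected.
#'
#' @param path file path.
#' @return a [volume].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L) {
    if (d[4L] > 1L) stop("expected a 3D image, got ", d[4L], " frames")
    img <- img[, , , 1L]
    d <- dim(img)
  }
  if (length(d) != 3L) stop("expected a 3D image, got ", length(d), " dims")
  aff <- tryCatch(structure(RNifti::xform(img), dimnames = NULL),
                  error = function(e) diag(4))
  volume(array(as.numeric(img), d), affine = aff)
}

#' Write a volume to NIfTI
#'
#' Stores voxel data as float32, the canonical on-disk precision.
#'
#' @param v a [volume] (or plain 3D array).
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  arr <- if (inherits(v, "volume")) v$data else v
  img <- RNifti::asNifti(arr, datatype = "float")
  if (inherits(v, "volume")) img <- RNifti::`sform<-`(img, structure(v$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Standardize a volume to zero mean, unit variance
#'
#' Whole-image standardization: subtracts the sample mean and divides by
#' the sample standard deviation of all voxels. Applied once per image
#' before any cropping, so train/eval statistics do not depend on the
#' sampled crop.
#'
#' @param v a [volume].
#' @return standardized [volume].
#' @export
normalize_volume <- function(v) {
  x <- v$data
  if (any(!is.finite(x))) stop("volume contains non-finite values")
  s <- stats::sd(x)
  if (s == 0) stop("degenerate input: zero-variance volume")
  v$data <- (x - mean(x)) / s
  v
}

#' Crop specification
#'
#' @param origin integer 3-vector, 0-based voxel index of the crop corner.
#' @param size integer 3-vector of crop extents.
#' @return object of class `crop_spec`.
#' @export
crop_spec <- function(origin, size) {
  origin <- as.integer(rep_len(origin, 3L))
  size <- as.integer(rep_len(size, 3L))
  if (any(origin < 0L)) stop("crop origin must be >= 0")
  if (any(size < 1L)) stop("crop size must be >= 1")
  structure(list(origin = origin, size = size), class = "crop_spec")
}

validate_crop <- function(spec, extent) {
  if (!inherits(spec, "crop_spec")) stop("need a crop_spec")
  if (any(spec$origin + spec$size > extent))
    stop("crop out of bounds: origin + size exceeds extent")
  invisible(spec)
}

#' Crop a volume
#'
#' The same [crop_spec] is applicable to a coordinate grid of matching
#' extent via [crop_grid()], so image and coordinates transform together.
#'
#' @param v a [volume].
#' @param spec a [crop_spec].
#' @return cropped [volume].
#' @export
crop_volume <- function(v, spec) {
  validate_crop(spec, dim(v$data))
  o <- spec$origin; s <- spec$size
  v$data <- v$data[o[1] + seq_len(s[1]), o[2] + seq_len(s[2]),
                   o[3] + seq_len(s[3]), drop = FALSE]
  v
}

#' Sample a crop specification
#'
#' `random` mode draws the origin uniformly over all valid origins
#' (reproducibly from `seed` when given); `center` mode returns
#' `floor((extent - size)/2)`.
#'
#' @param extent integer 3-vector of the source extent.
#' @param size integer 3-vector of the crop size.
#' @param mode "random" or "center".
#' @param seed optional integer seed (random mode).
#' @return a [crop_spec].
#' @export
sample_crop <- function(extent, size, mode = c("random", "center"),
                        seed = NULL) {
  mode <- match.arg(mode)
  extent <- as.integer(rep_len(extent, 3L))
  size <- as.integer(rep_len(size, 3L))
  if (any(size > extent)) stop("crop size exceeds source extent")
  slack <- extent - size
  if (mode == "center") return(crop_spec(slack %/% 2L, size))
  if (!is.null(seed)) set.seed(seed)
  origin <- vapply(slack, function(s) sample.int(s + 1L, 1L) - 1L, integer(1))
  crop_spec(origin, size)
}

#' Read a dataset manifest
#'
#' A manifest is a CSV with columns `path`, `label`, `subject_id`, `split`.
#'
#' @param path CSV file path.
#' @return data.frame with the four columns.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("path", "label", "subject_id", "split")
  missing <- setdiff(need, names(m))
  if (length(missing))
    stop("manifest missing columns: ", paste(missing, collapse = ", "))
  m
}

#' Load the volumes of a manifest into memory
#'
#' Reads and standardizes every listed volume.
#'
#' @param manifest data.frame from [read_manifest()].
#' @param dir directory that relative paths are resolved against.
#' @return list with `volumes` (list of normalized [volume]s) and `labels`.
#' @export
load_dataset <- function(manifest, dir = ".") {
  paths <- ifelse(grepl("^/", manifest$path), manifest$path,
                  file.path(dir, manifest$path))
  vols <- lapply(seq_along(paths), function(i) {
    v <- normalize_volume(read_volume(paths[i]))
    v$label <- manifest$label[i]
    v
  })
  out <- list(volumes = vols, labels = as.integer(manifest$label))
  if ("pair_id" %in% names(manifest)) out$pair_ids <- manifest$pair_id
  out
}
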