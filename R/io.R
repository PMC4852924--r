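# k-space archive I/O: a binary float64 sample file plus a JSON sidecar that
# carries the dimensions, sampling mask, full acquisition metadata, and
# provenance. The round trip is lossless for samples and every metadata field.
# (An ISMRMRD-style HDF5 reader would slot in beside this; the archive is the
# package's native format.)

KSPACE_FORMAT <- "lowfieldsim-kspace-v1"
REQUIRED_META <- c("b0", "tr", "te", "flip_angle", "bandwidth",
                   "partial_fourier_fraction", "sequence_family")

sidecar_path <- function(path) paste0(path, ".json")

#' Write k-space data to an array archive
#'
#' `<path>` receives the complex samples as little-endian float64 pairs
#' (Re, Im) in R column-major order (channel fastest, then echo, phase-encode,
#' readout); `<path>.json` receives dimensions, run-length-encoded mask, all
#' acquisition metadata, and provenance.
#'
#' @param data A [kspace_data()] object.
#' @param path Output path ending in `.ksp`.
#' @return `path`, invisibly.
#' @export
write_kspace <- function(data, path) {
  stopifnot(inherits(data, "kspace_data"))
  if (!grepl("\\.ksp$", path)) {
    lfs_io_error(sprintf("unknown extension for '%s': expected .ksp", path))
  }
  v <- as.vector(data$samples)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.vector(rbind(Re(v), Im(v))), con, size = 8, endian = "little")
  rl <- rle(as.vector(data$mask))
  meta <- data$meta
  side <- list(
    format = KSPACE_FORMAT,
    dims = dim(data$samples),
    sample_dtype = "float64 little-endian, interleaved re/im, column-major",
    mask_rle = list(lengths = rl$lengths, values = rl$values),
    meta = list(b0 = meta$b0, tr = meta$tr, te = meta$te, ti = meta$ti,
                flip_angle = meta$flip_angle, bandwidth = meta$bandwidth,
                partial_fourier_fraction = meta$partial_fourier_fraction,
                sequence_family = meta$sequence_family),
    provenance = data$provenance
  )
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read k-space data from an array archive
#'
#' Inverse of [write_kspace()]; errors name the failure distinctly (unknown
#' extension, missing sidecar, missing metadata field, shape mismatch).
#'
#' @param path Path ending in `.ksp`, with its `.json` sidecar present.
#' @return A [kspace_data()] object.
#' @export
read_kspace <- function(path) {
  if (!grepl("\\.ksp$", path)) {
    lfs_io_error(sprintf("unknown extension for '%s': expected .ksp", path))
  }
  if (!file.exists(path)) lfs_io_error(sprintf("file not found: %s", path))
  sp <- sidecar_path(path)
  if (!file.exists(sp)) lfs_io_error(sprintf("missing metadata sidecar: %s", sp))
  side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (!identical(side$format, KSPACE_FORMAT)) {
    lfs_io_error(sprintf("unrecognised archive format: %s", side$format %||% "<absent>"))
  }
  miss <- setdiff(REQUIRED_META, names(side$meta)[!vapply(side$meta, is.null, logical(1))])
  if (length(miss)) {
    lfs_io_error(sprintf("missing required metadata: %s", paste(miss, collapse = ", ")))
  }
  dims <- as.integer(side$dims)
  n <- prod(dims)
  raw <- readBin(path, "double", n = 2L * n + 1L, size = 8, endian = "little")
  if (length(raw) != 2L * n) {
    lfs_io_error(sprintf("shape mismatch: sidecar declares %d complex samples but file holds %g",
                         n, length(raw) / 2))
  }
  samples <- array(complex(real = raw[c(TRUE, FALSE)], imaginary = raw[c(FALSE, TRUE)]), dims)
  mask <- matrix(inverse.rle(list(lengths = as.integer(side$mask_rle$lengths),
                                  values = as.logical(side$mask_rle$values))),
                 dims[3], dims[4])
  m <- side$meta
  meta <- acq_meta(b0 = m$b0, tr = m$tr, te = as.numeric(m$te),
                   flip_angle = m$flip_angle, bandwidth = m$bandwidth,
                   sequence_family = m$sequence_family,
                   ti = m$ti, partial_fourier_fraction = m$partial_fourier_fraction)
  prov <- side$provenance
  kspace_data(samples, mask, meta, provenance = if (is.null(prov)) list() else prov)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a magnitude image
#'
#' Dispatches on extension: `.png` (normalised to the image maximum),
#' `.nii`/`.nii.gz` (via RNifti), or `.csv`.
#'
#' @param image Numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  if (grepl("\\.png$", path)) {
    mx <- max(image)
    png::writePNG(if (mx > 0) image / mx else image, path)
  } else if (grepl("\\.nii(\\.gz)?$", path)) {
    RNifti::writeNifti(RNifti::asNifti(image), path)
  } else if (grepl("\\.csv$", path)) {
    utils::write.table(image, path, sep = ",", row.names = FALSE, col.names = FALSE)
  } else {
    lfs_io_error(sprintf("unknown image extension for '%s' (use .png, .nii, .nii.gz, .csv)", path))
  }
  invisible(path)
}

#' Write / read a binary mask as run-length text
#'
#' Plain-text run-length encoding: a header line with the dimensions, then one
#' `value length` pair per line in column-major order.
#'
#' @param mask Logical matrix.
#' @param path Text path (conventionally `.rle.txt`); `.nii` also accepted for
#'   [write_mask()].
#' @return `path` / the logical matrix.
#' @export
write_mask <- function(mask, path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    RNifti::writeNifti(RNifti::asNifti(mask + 0L), path)
    return(invisible(path))
  }
  rl <- rle(as.vector(mask))
  lines <- c(sprintf("dims %d %d", nrow(mask), ncol(mask)),
             sprintf("%d %d", as.integer(rl$values), rl$lengths))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  lines <- readLines(path)
  hd <- strsplit(lines[1], " ")[[1]]
  if (hd[1] != "dims") lfs_io_error("not a run-length mask file (missing 'dims' header)")
  dims <- as.integer(hd[2:3])
  pairs <- do.call(rbind, lapply(strsplit(lines[-1], " "), as.integer))
  matrix(inverse.rle(list(lengths = pairs[, 2], values = as.logical(pairs[, 1]))),
         dims[1], dims[2])
}
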