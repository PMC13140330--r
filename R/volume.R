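#' Image volume container
#'
#' A `volume_image` is a 3D array of intensities (real, integer or complex)
#' together with its voxel size in mm, a 4x4 voxel-to-world affine (0-based
#' voxel indices, homogeneous coordinates) and a modality tag. It is the unit
#' all mapping and quantification stages operate on.
#'
#' @param data 3D numeric, integer or complex array.
#' @param voxel_size length-3 positive numeric, mm per axis.
#' @param affine 4x4 voxel-to-world matrix; default is a diagonal scaling by
#'   `voxel_size` with the origin at voxel (0,0,0).
#' @param modality_tag one of `"dixon_echo"`, `"mese_echo"`, `"na"`,
#'   `"na_ir"`, `"k"`, or `"label"` for integer mask volumes.
#' @return A `volume_image` object.
#' @export
volume_image <- function(data, voxel_size = c(1, 1, 1), affine = NULL,
                         modality_tag = "mese_echo") {
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  stopifnot(length(dim(data)) == 3L, length(voxel_size) == 3L)
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    abort("voxel_size must be strictly positive on all axes")
  }
  tags <- c("dixon_echo", "mese_echo", "na", "na_ir", "k", "label")
  modality_tag <- match.arg(modality_tag, tags)
  if (is.complex(data) && modality_tag != "dixon_echo") {
    abort("complex data is only valid for modality_tag = 'dixon_echo'")
  }
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  stopifnot(is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  structure(
    list(data = data, voxel_size = as.numeric(voxel_size),
         affine = affine, modality_tag = modality_tag),
    class = "volume_image"
  )
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image> %s  %s  voxel %s mm\n",
              paste(dim(x$data), collapse = "x"), x$modality_tag,
              paste(signif(x$voxel_size, 3), collapse = "x")))
  invisible(x)
}

#' @export
dim.volume_image <- function(x) dim(x$data)

# world coordinates (n x 3) of 0-based voxel indices (n x 3)
voxel_to_world <- function(affine, ijk) {
  ijk <- rbind(t(ijk), 1)
  t(affine %*% ijk)[, 1:3, drop = FALSE]
}

world_to_voxel <- function(affine, xyz) {
  xyz <- rbind(t(xyz), 1)
  t(solve(affine) %*% xyz)[, 1:3, drop = FALSE]
}

# 0-based index grid of all voxels, n x 3, column-major order matching array
voxel_grid <- function(dims) {
  as.matrix(expand.grid(i = seq_len(dims[1]) - 1L,
                        j = seq_len(dims[2]) - 1L,
                        k = seq_len(dims[3]) - 1L))
}

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1/2 file into a [volume_image]. Complex gradient-echo data
#' may arrive as a magnitude/phase or real/imaginary file pair; pass a named
#' character vector of length two (`c(magnitude=, phase=)` or
#' `c(real=, imaginary=)`) and the pair is assembled into one complex volume.
#' Phase images are auto-detected as radians (range within \[-pi, pi\]) or
#' scanner integer units (range within \[-4096, 4096\], rescaled to radians);
#' anything else is a format error.
#'
#' @param path file path, or named length-2 character vector for complex pairs.
#' @param modality_tag modality tag for the resulting volume.
#' @return A [volume_image].
#' @export
read_volume <- function(path, modality_tag = "mese_echo") {
  if (length(path) == 2L) {
    return(read_complex_pair(path, modality_tag))
  }
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) abort(sprintf(
                    "cannot read NIfTI file '%s': %s", path, conditionMessage(e))))
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)  # squeezed singleton
  aff <- structure(RNifti::xform(img), class = NULL)
  attributes(aff) <- list(dim = dim(aff))
  # voxel size from the affine column norms (pixdim is unreliable for
  # squeezed single-slice files)
  vox <- sqrt(colSums(aff[1:3, 1:3]^2))
  if (modality_tag == "label") arr <- array(as.integer(round(arr)), dim(arr))
  volume_image(arr, voxel_size = vox, affine = aff, modality_tag = modality_tag)
}

read_complex_pair <- function(paths, modality_tag) {
  nm <- names(paths)
  a <- read_volume(unname(paths[1]), "mese_echo")
  b <- read_volume(unname(paths[2]), "mese_echo")
  if (setequal(nm, c("magnitude", "phase"))) {
    mag <- a$data
    phs <- b$data
    rng <- range(phs, na.rm = TRUE)
    if (all(abs(rng) <= pi + 1e-6)) {
      # already radians
    } else if (all(abs(rng) <= 4096)) {
      phs <- phs / 4096 * pi
    } else {
      abort(paste("phase volume not in radians [-pi, pi] nor scanner units",
                  "[-4096, 4096]; conventions tried: radians, 4096-integer"))
    }
    dat <- mag * exp(1i * phs)
  } else if (setequal(nm, c("real", "imaginary"))) {
    dat <- a$data + 1i * b$data
  } else {
    abort("complex pair must be named (magnitude, phase) or (real, imaginary)")
  }
  volume_image(dat, voxel_size = a$voxel_size, affine = a$affine,
               modality_tag = modality_tag)
}

#' Write a volume to NIfTI
#'
#' Real volumes are written as one file. Complex volumes are written as a
#' real/imaginary pair with `_real`/`_imag` inserted before the extension;
#' the two paths are returned invisibly.
#'
#' @param vol a [volume_image].
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_image"))
  if (is.complex(vol$data)) {
    p_re <- sub("(\\.nii(\\.gz)?)$", "_real\\1", path)
    p_im <- sub("(\\.nii(\\.gz)?)$", "_imag\\1", path)
    write_nifti_array(Re(vol$data), vol, p_re)
    write_nifti_array(Im(vol$data), vol, p_im)
    return(invisible(c(real = p_re, imaginary = p_im)))
  }
  write_nifti_array(vol$data, vol, path)
  invisible(path)
}

write_nifti_array <- function(arr, vol, path) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vol$voxel_size
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path)
}

#' Multi-echo series
#'
#' An ordered stack of [volume_image]s acquired at strictly increasing echo
#' times, all on one grid.
#'
#' @param volumes list of [volume_image]s sharing grid and affine.
#' @param echo_times numeric vector of echo times in ms, strictly increasing.
#' @return An `echo_series` object.
#' @export
echo_series <- function(volumes, echo_times) {
  stopifnot(length(volumes) == length(echo_times))
  if (length(echo_times) >= 2 && any(diff(echo_times) <= 0)) {
    abort("echo_times must be strictly increasing")
  }
  d0 <- dim(volumes[[1]]$data)
  for (v in volumes) {
    stopifnot(inherits(v, "volume_image"))
    if (!identical(dim(v$data), d0) ||
        max(abs(v$affine - volumes[[1]]$affine)) > 1e-8) {
      abort("all volumes in an echo series must share grid and affine")
    }
  }
  structure(list(volumes = volumes, echo_times = as.numeric(echo_times)),
            class = "echo_series")
}

#' @export
print.echo_series <- function(x, ...) {
  cat(sprintf("<echo_series> %d echoes (%s ms), %s, %s\n",
              length(x$echo_times),
              paste(signif(x$echo_times, 3), collapse = ", "),
              paste(dim(x$volumes[[1]]$data), collapse = "x"),
              x$volumes[[1]]$modality_tag))
  invisible(x)
}

# voxels x echoes signal matrix
series_matrix <- function(series) {
  vapply(series$volumes, function(v) as.vector(v$data),
         if (is.complex(series$volumes[[1]]$data))
           complex(length(series$volumes[[1]]$data))
         else numeric(length(series$volumes[[1]]$data)))
}

#' Write an echo series as numbered NIfTI files
#'
#' @param series an [echo_series].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix; files are `<prefix>_e01.nii.gz`, ...
#' @return Invisibly, a list with the file paths and a TSV of echo times.
#' @export
write_echo_series <- function(series, dir, prefix) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- lapply(seq_along(series$volumes), function(e) {
    write_volume(series$volumes[[e]],
                 file.path(dir, sprintf("%s_e%02d.nii.gz", prefix, e)))
  })
  te_path <- file.path(dir, sprintf("%s_echo_times.tsv", prefix))
  readr::write_tsv(tibble::tibble(echo = seq_along(series$echo_times),
                                  te_ms = series$echo_times), te_path)
  invisible(list(paths = paths, echo_times = te_path))
}

#' Read an echo series written by [write_echo_series()]
#'
#' @param dir directory containing the series.
#' @param prefix file name prefix used at write time.
#' @param modality_tag modality of the series; `"dixon_echo"` expects
#'   real/imaginary pairs.
#' @return An [echo_series].
#' @export
read_echo_series <- function(dir, prefix, modality_tag = "mese_echo") {
  te <- readr::read_tsv(file.path(dir, sprintf("%s_echo_times.tsv", prefix)),
                        show_col_types = FALSE)
  vols <- lapply(te$echo, function(e) {
    if (modality_tag == "dixon_echo") {
      read_volume(c(real = file.path(dir, sprintf("%s_e%02d_real.nii.gz", prefix, e)),
                    imaginary = file.path(dir, sprintf("%s_e%02d_imag.nii.gz", prefix, e))),
                  modality_tag)
    } else {
      read_volume(file.path(dir, sprintf("%s_e%02d.nii.gz", prefix, e)),
                  modality_tag)
    }
  })
  echo_series(vols, te$te_ms)
}
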