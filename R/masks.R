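#' Labelled region mask set
#'
#' Couples an integer label volume with a label table naming each region and
#' assigning it a class (`muscle`, `subcutaneous_fat`, `reference_tube`,
#' `background`, `bone`). Reference tubes additionally carry their nominal
#' Na and K concentrations in mM. Label 0 is implicit background.
#'
#' @param label_map integer [volume_image] (modality `"label"`).
#' @param label_table data frame with columns `label`, `name`, `class` and,
#'   for reference tubes, `na_mM` and `k_mM`.
#' @return A `region_mask_set`.
#' @export
region_mask_set <- function(label_map, label_table) {
  stopifnot(inherits(label_map, "volume_image"))
  label_table <- tibble::as_tibble(label_table)
  stopifnot(all(c("label", "name", "class") %in% names(label_table)))
  if (anyDuplicated(label_table$label) || anyDuplicated(label_table$name)) {
    abort("labels and region names must be unique")
  }
  bad <- setdiff(label_table$class, REGION_CLASSES)
  if (length(bad)) abort(sprintf("unknown region class: %s", paste(bad, collapse = ", ")))
  if (!"na_mM" %in% names(label_table)) label_table$na_mM <- NA_real_
  if (!"k_mM" %in% names(label_table)) label_table$k_mM <- NA_real_
  counts <- tabulate(match(as.vector(label_map$data), label_table$label),
                     nbins = nrow(label_table))
  label_table$n_voxels <- counts
  structure(list(label_map = label_map, label_table = label_table),
            class = "region_mask_set")
}

#' @export
print.region_mask_set <- function(x, ...) {
  cat(sprintf("<region_mask_set> %d regions on a %s grid\n",
              nrow(x$label_table), paste(dim(x$label_map$data), collapse = "x")))
  print(x$label_table)
  invisible(x)
}

#' Write a mask set (NIfTI label map + TSV side-car)
#'
#' @param masks a [region_mask_set].
#' @param label_path output NIfTI path for the label map.
#' @param table_path output TSV path for the label table.
#' @export
write_mask_set <- function(masks, label_path, table_path) {
  write_volume(masks$label_map, label_path)
  readr::write_tsv(masks$label_table, table_path)
  invisible(c(label_path, table_path))
}

#' Read a mask set written by [write_mask_set()]
#'
#' @param label_path NIfTI label map path.
#' @param table_path TSV side-car path.
#' @return A [region_mask_set].
#' @export
read_mask_set <- function(label_path, table_path) {
  region_mask_set(read_volume(label_path, "label"),
                  readr::read_tsv(table_path, show_col_types = FALSE))
}

#' Resample a mask set onto a target grid
#'
#' Nearest-neighbour label assignment in world coordinates: each target voxel
#' centre is mapped through the affines and takes the label of the nearest
#' source voxel (0 outside the source field of view). Regions that end up
#' with zero voxels are kept in the label table with `n_voxels = 0` and a
#' warning, never dropped silently.
#'
#' @param masks a [region_mask_set].
#' @param target a [volume_image] defining the output grid.
#' @return A [region_mask_set] on the target grid.
#' @export
resample_mask <- function(masks, target) {
  src <- masks$label_map
  if (identical(dim(src$data), dim(target$data)) &&
      max(abs(src$affine - target$affine)) < 1e-8) {
    return(masks)
  }
  bb_src <- world_bbox(src)
  bb_tgt <- world_bbox(target)
  if (any(bb_src[2, ] < bb_tgt[1, ]) || any(bb_tgt[2, ] < bb_src[1, ])) {
    abort(sprintf(
      "source and target fields of view are disjoint: source bbox [%s]-[%s], target bbox [%s]-[%s]",
      paste(round(bb_src[1, ], 1), collapse = ","), paste(round(bb_src[2, ], 1), collapse = ","),
      paste(round(bb_tgt[1, ], 1), collapse = ","), paste(round(bb_tgt[2, ], 1), collapse = ",")))
  }
  dims_t <- dim(target$data)
  ijk_t <- voxel_grid(dims_t)
  xyz <- voxel_to_world(target$affine, ijk_t)
  ijk_s <- round(world_to_voxel(src$affine, xyz))
  dims_s <- dim(src$data)
  inside <- ijk_s[, 1] >= 0 & ijk_s[, 1] < dims_s[1] &
    ijk_s[, 2] >= 0 & ijk_s[, 2] < dims_s[2] &
    ijk_s[, 3] >= 0 & ijk_s[, 3] < dims_s[3]
  lab <- integer(nrow(ijk_t))
  idx <- 1L + ijk_s[inside, 1] + dims_s[1] * (ijk_s[inside, 2] + dims_s[2] * ijk_s[inside, 3])
  lab[inside] <- as.vector(src$data)[idx]
  new_map <- volume_image(array(lab, dims_t), voxel_size = target$voxel_size,
                          affine = target$affine, modality_tag = "label")
  out <- region_mask_set(new_map, masks$label_table[setdiff(names(masks$label_table), "n_voxels")])
  lost <- out$label_table$name[out$label_table$n_voxels == 0 &
                                 out$label_table$class != "background"]
  if (length(lost)) {
    warn(sprintf("regions lost during resampling (0 voxels): %s",
                 paste(lost, collapse = ", ")))
  }
  out
}

world_bbox <- function(vol) {
  d <- dim(vol$data)
  corners <- as.matrix(expand.grid(c(0, d[1] - 1), c(0, d[2] - 1), c(0, d[3] - 1)))
  xyz <- voxel_to_world(vol$affine, corners)
  rbind(apply(xyz, 2, min), apply(xyz, 2, max))
}

#' Per-region summary statistics of an image
#'
#' Computes mean, SD and voxel count of an image over each labelled region,
#' using finite voxels only. A region with no finite voxel is returned as an
#' excluded row with reason `"empty_region"`.
#'
#' @param image a [volume_image] on the same grid as `masks`.
#' @param masks a [region_mask_set].
#' @return A tibble with columns `region`, `class`, `value` (mean),
#'   `dispersion` (SD), `voxel_count`, `excluded`, `exclusion_reason`.
#' @export
region_means <- function(image, masks) {
  stopifnot(inherits(image, "volume_image"))
  if (!identical(dim(image$data), dim(masks$label_map$data))) {
    abort("image and masks must share a grid")
  }
  vals <- as.vector(image$data)
  labs <- as.vector(masks$label_map$data)
  tab <- masks$label_table
  purrr::map_dfr(seq_len(nrow(tab)), function(i) {
    v <- vals[labs == tab$label[i]]
    v <- v[is.finite(v)]
    if (length(v) == 0) {
      tibble::tibble(region = tab$name[i], class = tab$class[i],
                     value = NA_real_, dispersion = NA_real_, voxel_count = 0L,
                     excluded = TRUE, exclusion_reason = "empty_region")
    } else {
      tibble::tibble(region = tab$name[i], class = tab$class[i],
                     value = mean(v), dispersion = stats::sd(v),
                     voxel_count = length(v),
                     excluded = FALSE, exclusion_reason = "")
    }
  })
}

# logical mask of one named region
region_indicator <- function(masks, name) {
  lab <- masks$label_table$label[masks$label_table$name == name]
  if (length(lab) != 1) abort(sprintf("unknown region '%s'", name))
  masks$label_map$data == lab
}
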