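#' Export a voxel grid
#'
#' `format = "png_stack"` writes one 8-bit greyscale PNG per z-slice over the
#' padded bounding box, with pixel value 0 for voxels not in the cell and 255
#' for voxels in the cell (the interchange format used to move voxelized
#' geometry into external mesh-based tools; fractional volumes are not
#' representable and are lost). `format = "table"` writes a TSV with one row
#' per stored voxel: `i, j, k, segment, surface, frac, area`.
#'
#' @param grid an `rxd_grid` (non-empty).
#' @param path output directory (png_stack) or file path (table).
#' @param format `"png_stack"` or `"table"`.
#' @return invisibly, the written file paths.
#' @export
export_grid <- function(grid, path, format = c("png_stack", "table")) {
  format <- match.arg(format)
  if (!nrow(grid$keys)) stop("empty grid")
  if (format == "table") {
    df <- as.data.frame(grid$keys)
    df$segment <- grid$seg
    df$surface <- as.integer(grid$surface)
    df$frac <- grid$frac
    df$area <- grid$area
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  rng <- apply(grid$keys, 2, range)
  ni <- rng[2, 1] - rng[1, 1] + 1L
  nj <- rng[2, 2] - rng[1, 2] + 1L
  files <- character()
  for (k in rng[1, 3]:rng[2, 3]) {
    img <- matrix(0, nj, ni)  # rows = y, cols = x
    sel <- grid$keys[, 3] == k
    if (any(sel)) {
      img[cbind(grid$keys[sel, 2] - rng[1, 2] + 1L,
                grid$keys[sel, 1] - rng[1, 1] + 1L)] <- 1
    }
    f <- file.path(path, sprintf("slice_%04d.png", k - rng[1, 3]))
    png::writePNG(img, f)
    files <- c(files, f)
  }
  invisible(files)
}

#' Re-import a PNG z-stack as a voxel key set
#'
#' Reads the slices written by [export_grid()] and returns the `(i, j, k)`
#' keys of in-cell pixels (values >= 0.5), with indices relative to the
#' exported bounding box.
#'
#' @param path directory containing `slice_*.png` files.
#' @return integer matrix of voxel keys.
#' @export
import_png_stack <- function(path) {
  files <- sort(list.files(path, pattern = "^slice_.*\\.png$",
                           full.names = TRUE))
  if (!length(files)) stop("no slice_*.png files in ", path)
  out <- list()
  for (k in seq_along(files)) {
    img <- png::readPNG(files[k])
    w <- which(img >= 0.5, arr.ind = TRUE)
    if (nrow(w)) out[[length(out) + 1L]] <-
        cbind(i = w[, 2] - 1L, j = w[, 1] - 1L, k = k - 1L)
  }
  kk <- do.call(rbind, out)
  kk[order(enc_key(kk[, 1], kk[, 2], kk[, 3])), , drop = FALSE]
}
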