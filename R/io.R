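# image, mask and slice-stack I/O
#
# 2D images are plain numeric matrices (rows x cols) with intensities in
# [0, 1]; slice stacks are 3D arrays H x W x S with the slice (projection)
# axis last.

#' Read a grayscale image
#'
#' Reads an 8/16-bit PNG or a TIFF (including 32-bit float) as a numeric
#' matrix in `[0, 1]`. Integer formats are rescaled by their maximum code
#' value; RGB(A) images are reduced to their first channel.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file
#' @return numeric matrix with values in `[0, 1]`
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext)
  )
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  clamp01(img)
}

#' Write a grayscale image
#'
#' PNG output quantizes to 8 bits; TIFF output stores 32-bit floats so
#' probability maps round-trip without quantization.
#'
#' @param image numeric matrix in `[0, 1]`
#' @param path destination `.png` or `.tif`/`.tiff` path
#' @return the path, invisibly
#' @export
write_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  image <- clamp01(image)
  switch(ext,
    png = png::writePNG(image, path),
    tif = ,
    tiff = tiff::writeTIFF(image, path, bits.per.sample = 32L,
                           compression = "none"),
    stop("unsupported image format: .", ext)
  )
  invisible(path)
}

#' Write a binary mask as an 8-bit PNG (0/255)
#' @param mask logical or 0/1 matrix
#' @param path destination `.png` path
#' @return the path, invisibly
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask > 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read a binary mask (any nonzero pixel is foreground)
#' @param path PNG/TIFF path
#' @return 0/1 integer matrix
#' @export
read_mask <- function(path) {
  m <- read_image(path)
  (m > 0.5) + 0L
}

#' Read a slice stack
#'
#' Accepts a multi-page TIFF, a NIfTI file (`.nii`/`.nii.gz`), or a
#' directory of equally sized PNG slices in lexicographic order. Returns an
#' `H x W x S` array with values in `[0, 1]`; the third axis is the
#' projection axis.
#'
#' @param path file or directory path
#' @return 3D numeric array
#' @export
read_stack <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (length(files) == 0L) stop("no PNG slices found in ", path)
    slices <- lapply(files, read_image)
    dims <- unique(lapply(slices, dim))
    if (length(dims) != 1L) stop("slices in ", path, " differ in shape")
    return(array(unlist(slices), dim = c(dims[[1L]], length(slices))))
  }
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1L] else p)
    dims <- unique(lapply(pages, dim))
    if (length(dims) != 1L) stop("pages in ", path, " differ in shape")
    return(array(unlist(pages), dim = c(dims[[1L]], length(pages))))
  }
  if (ext == "nii") {
    vol <- RNifti::readNifti(path)
    vol <- array(as.numeric(vol), dim = dim(vol))
    if (length(dim(vol)) != 3L) stop("expected a 3D NIfTI volume")
    mx <- max(vol)
    if (mx > 1) vol <- vol / (if (mx <= 255) 255 else if (mx <= 65535) 65535 else mx)
    return(clamp01(vol))
  }
  stop("unsupported stack format: ", path)
}

#' Write a slice stack as a multi-page TIFF
#' @param stack `H x W x S` array in `[0, 1]`
#' @param path destination `.tif`/`.tiff` path
#' @return the path, invisibly
#' @export
write_stack <- function(stack, path) {
  pages <- lapply(seq_len(dim(stack)[3L]), function(s) clamp01(stack[, , s]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  invisible(path)
}

#' Maximum intensity projection
#'
#' Projects a slice stack to a 2D image by taking, for every pixel, the
#' maximum intensity along the slice axis — the standard reduction used to
#' turn an OCT-A retinal slab into the 2D vessel image that segmentation
#' networks consume.
#'
#' @param stack `H x W x S` numeric array
#' @return `H x W` numeric matrix
#' @export
max_intensity_projection <- function(stack) {
  if (length(dim(stack)) != 3L) stop("expected an H x W x S array")
  out <- matrix(stack[, , 1L], dim(stack)[1L], dim(stack)[2L])
  for (s in seq_len(dim(stack)[3L])[-1L])
    out <- pmax(out, matrix(stack[, , s], nrow(out), ncol(out)))
  out
}
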