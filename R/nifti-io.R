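# NIfTI and motion-parameter I/O, delegated to RNifti for the file format.

lr_axis_from_orientation <- function(orient) {
  # RNifti orientation strings like "LAS": one letter per array axis.
  letters3 <- strsplit(orient, "")[[1]]
  ax <- which(letters3 %in% c("L", "R"))
  if (length(ax) != 1L) return(NA_integer_)
  as.integer(ax)
}

#' Read a NIfTI-1 volume
#'
#' Reads `.nii` / `.nii.gz` files into a [volume_image()] (3-D payload) or a
#' [bold_run()] (4-D payload, with TR taken from the time-axis pixdim). The
#' left-right axis is derived from the stored orientation.
#'
#' @param path Path to a NIfTI-1 file.
#' @return A `volume_image` or `bold_run`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("unreadable file: %s", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  nd <- length(dim(img))
  pix <- RNifti::pixdim(img)
  orient <- tryCatch(RNifti::orientation(img), error = function(e) "LAS")
  ax <- lr_axis_from_orientation(orient)
  if (is.na(ax)) ax <- 1L
  if (nd == 3L) {
    volume_image(as.array(img), voxel_dims = pix[1:3], lr_axis = ax)
  } else if (nd == 4L) {
    tr <- pix[4]
    if (!is.finite(tr) || tr <= 0) tr <- 1
    bold_run(as.array(img), tr = tr, voxel_dims = pix[1:3], lr_axis = ax)
  } else {
    stop("unsupported dimensionality: NIfTI payload must be 3-D or 4-D", call. = FALSE)
  }
}

#' Write a volume or BOLD run to NIfTI-1
#'
#' @param obj A `volume_image`, `binary_mask`, `prob_map` or `bold_run`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(obj, path) {
  vd <- voxel_dims(obj)
  arr <- unclass(obj)
  attributes(arr) <- list(dim = dim(arr))
  img <- RNifti::asNifti(arr)
  if (inherits(obj, "bold_run")) {
    RNifti::pixdim(img) <- c(vd, attr(obj, "tr"))
  } else {
    RNifti::pixdim(img) <- vd
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write a 6-column motion-parameter table
#'
#' Whitespace-delimited text, one row per retained volume, columns x/y/z
#' translation then x/y/z rotation (the usual `.par` layout).
#'
#' @param path Text file path.
#' @param n_volumes If given, the row count is checked against it.
#' @return A t x 6 numeric matrix with named columns.
#' @export
read_motion <- function(path, n_volumes = NULL) {
  m <- as.matrix(read.table(path, header = FALSE))
  if (ncol(m) != 6L) stop("motion table must have exactly 6 columns", call. = FALSE)
  if (any(!is.finite(m))) stop("motion table contains non-finite values", call. = FALSE)
  if (!is.null(n_volumes) && nrow(m) != n_volumes) {
    stop(sprintf("motion table has %d rows but the run has %d volumes",
                 nrow(m), n_volumes), call. = FALSE)
  }
  colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  m
}

#' @rdname read_motion
#' @param motion t x 6 numeric matrix.
#' @export
write_motion <- function(motion, path) {
  stopifnot(is.matrix(motion), ncol(motion) == 6L)
  write.table(motion, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a cohort table
#'
#' Tab-separated with a header row; missing cells are `NA`.
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_cohort <- function(path) {
  tibble::as_tibble(read.table(path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE))
}

#' @rdname read_cohort
#' @param x Data frame to write.
#' @export
write_cohort <- function(x, path) {
  write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
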