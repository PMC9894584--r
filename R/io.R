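# Table and NIfTI I/O: BIDS-events-like TSV tables and voxel-by-volume
# series, either delimited or NIfTI (voxels unrolled on a synthetic grid).

#' Write / read a BIDS-events-like table
#'
#' Tab-delimited with a header row; round-trips bit-exactly for numeric
#' columns written with full precision.
#'
#' @param events Data frame (e.g. `design$events`).
#' @param path Output path (.tsv).
#' @return `read_events` returns the data frame.
#' @export
write_events <- function(events, path) {
  utils::write.table(format(events, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  out <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE),
    error = function(e) stop("malformed events table at ", path, ": ",
                             conditionMessage(e))
  )
  out
}

#' Write / read a voxel-by-volume series
#'
#' `format = "tsv"` writes a plain tab-delimited voxel x volume table
#' (bit-exact round trip); `format = "nifti"` unrolls voxels onto a
#' synthetic Vx1x1xT grid (float32, so round trips are exact only to
#' float32 precision).
#'
#' @param values Voxels x volumes matrix.
#' @param path Output path.
#' @param format "tsv" or "nifti".
#' @return `read_series` returns the voxels x volumes matrix.
#' @export
write_series <- function(values, path, format = c("tsv", "nifti")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(format(values, digits = 17, trim = TRUE,
                              scientific = TRUE),
                       path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    arr <- array(values, dim = c(nrow(values), 1, 1, ncol(values)))
    img <- RNifti::asNifti(arr, datatype = "float")
    RNifti::writeNifti(img, path)
  }
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path, format = c("tsv", "nifti")) {
  format <- match.arg(format)
  if (format == "tsv") {
    as.matrix(utils::read.table(path, header = FALSE, sep = "\t"))
  } else {
    arr <- RNifti::readNifti(path)
    matrix(arr, nrow = dim(arr)[1], ncol = dim(arr)[4])
  }
}
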