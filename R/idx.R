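#' Read an IDX image/label pair into a labelled dataset
#'
#' Parses the big-endian IDX container used by the MNIST distribution:
#' images carry magic number 2051 followed by the counts `(n, rows, cols)`
#' and row-major unsigned bytes; labels carry magic 2049 followed by `n`
#' bytes. Both paths may be gzip-compressed (detected transparently). The
#' two files must agree on `n`.
#'
#' @param images_path Path to the image file (magic 2051).
#' @param labels_path Path to the label file (magic 2049).
#' @return A `labeled_dataset` with integer image matrices and labels.
#' @export
read_idx <- function(images_path, labels_path) {
  images <- read_idx_images(images_path)
  labels <- read_idx_labels(labels_path)
  if (length(images) != length(labels))
    stop(sprintf("count mismatch: %d images in '%s' vs %d labels in '%s'",
                 length(images), images_path, length(labels), labels_path),
         call. = FALSE)
  structure(list(images = images, labels = labels,
                 provenance = list(images_path = images_path,
                                   labels_path = labels_path)),
            class = "labeled_dataset")
}

read_idx_images <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  con <- gzfile(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (length(magic) != 1 || magic != 2051L)
    stop(sprintf("'%s': expected image magic 2051 at byte offset 0, got %s",
                 path, if (length(magic)) magic else "EOF"), call. = FALSE)
  dims <- readBin(con, "integer", 3, size = 4, endian = "big")
  if (length(dims) != 3)
    stop(sprintf("'%s': truncated header at byte offset %d", path,
                 4 + 4 * length(dims)), call. = FALSE)
  n <- dims[1]; nr <- dims[2]; nc <- dims[3]
  bytes <- readBin(con, "integer", n * nr * nc, size = 1, signed = FALSE)
  if (length(bytes) != n * nr * nc)
    stop(sprintf("'%s': truncated pixel data at byte offset %d (expected %d bytes)",
                 path, 16 + length(bytes), n * nr * nc), call. = FALSE)
  lapply(seq_len(n), function(i) {
    matrix(bytes[((i - 1) * nr * nc + 1):(i * nr * nc)], nr, nc, byrow = TRUE)
  })
}

read_idx_labels <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  con <- gzfile(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (length(magic) != 1 || magic != 2049L)
    stop(sprintf("'%s': expected label magic 2049 at byte offset 0, got %s",
                 path, if (length(magic)) magic else "EOF"), call. = FALSE)
  n <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (length(n) != 1)
    stop(sprintf("'%s': truncated header at byte offset 4", path), call. = FALSE)
  labels <- readBin(con, "integer", n, size = 1, signed = FALSE)
  if (length(labels) != n)
    stop(sprintf("'%s': truncated label data at byte offset %d (expected %d labels)",
                 path, 8 + length(labels), n), call. = FALSE)
  labels
}

#' Write a labelled dataset as an IDX image/label pair
#'
#' Inverse of [read_idx()]: writes big-endian IDX files (gzip-compressed
#' when the path ends in `.gz`) that round-trip bit-exactly through
#' [read_idx()].
#'
#' @param data A `labeled_dataset` (or list with `images` and `labels`).
#' @param images_path,labels_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_idx <- function(data, images_path, labels_path) {
  images <- data$images
  labels <- as.integer(data$labels)
  stopifnot(length(images) == length(labels), length(images) > 0)
  if (any(labels < 0 | labels > 255)) stop("labels must be bytes in [0, 255]")
  nr <- nrow(images[[1]]); nc <- ncol(images[[1]])

  open_out <- function(path) {
    if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  }
  con <- open_out(images_path)
  writeBin(c(2051L, length(images), nr, nc), con, size = 4, endian = "big")
  writeBin(as.raw(unlist(lapply(images, function(m) as.integer(t(m))))), con)
  close(con)

  con <- open_out(labels_path)
  writeBin(c(2049L, length(labels)), con, size = 4, endian = "big")
  writeBin(as.raw(labels), con)
  close(con)
  invisible(c(images_path, labels_path))
}
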