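# HDF5 + CSV serialization of dataset partitions, mirroring the published
# layout: one HDF file per partition with groups "data" (n x 144 x 256,
# floating point) and "target" (n, integer), plus a sibling CSV metadata
# file with one row per record.

.csv_sibling <- function(path) sub("\\.h5$", ".csv", path)

#' Write a dataset partition to HDF5 + CSV
#'
#' @param partition A `sans_partition` (or a `sans_dataset`).
#' @param path Output HDF5 file path (conventionally `train.h5`, `test.h5`
#'   or `validation.h5`); the CSV metadata sibling replaces the `.h5`
#'   extension with `.csv`.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  stopifnot(inherits(partition, c("sans_partition", "sans_dataset")))
  n <- length(partition$target)
  stopifnot(dim(partition$data)[1] == n, nrow(partition$metadata) == n)
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(partition$data, path, "data")
  rhdf5::h5write(as.integer(partition$target), path, "target")
  rhdf5::H5close()
  write.csv(partition$metadata, .csv_sibling(path), row.names = FALSE)
  invisible(path)
}

#' Read a dataset partition from HDF5 + CSV
#'
#' Inverse of [write_partition()]: `read_partition(write_partition(p, f))`
#' restores `data`, `target` and `metadata` exactly.
#'
#' @param path HDF5 file path written by [write_partition()].
#' @param name Partition name to record (defaults to the file stem).
#' @return A `sans_partition`.
#' @export
read_partition <- function(path, name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  contents <- rhdf5::h5ls(path)
  for (grp in c("data", "target"))
    if (!grp %in% contents$name)
      stop("malformed partition file '", path, "': missing group '", grp, "'")
  data <- rhdf5::h5read(path, "data")
  target <- as.integer(rhdf5::h5read(path, "target"))
  rhdf5::H5close()
  csv <- .csv_sibling(path)
  if (!file.exists(csv)) stop("missing metadata CSV: ", csv)
  metadata <- read.csv(csv, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(metadata) != length(target))
    stop("metadata CSV row count (", nrow(metadata),
         ") does not match HDF record count (", length(target), ")")
  if (any(target < 0 | target > 45))
    stop("malformed partition: target labels outside 0..45")
  structure(list(
    name = if (is.null(name)) sub("\\.h5$", "", basename(path)) else name,
    data = data, target = target, metadata = metadata),
    class = "sans_partition")
}

#' Write all three partitions of a split
#'
#' @param splits Named list from [split_dataset()].
#' @param dir Output directory (created if needed).
#' @return Character vector of HDF5 paths, invisibly.
#' @export
write_splits <- function(splits, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(splits), function(nm) {
    write_partition(splits[[nm]], file.path(dir, paste0(nm, ".h5")))
    file.path(dir, paste0(nm, ".h5"))
  }, character(1))
  invisible(paths)
}
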