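# Tabular point-cloud IO and the SampleCloud container.
#
# Canonical table dialect: comma-separated with a header row and columns
#   sample_id, nucleus_id, x_um, y_um, z_um [, channel_<name> ...]
# Coordinates are real-valued micrometres in a right-handed axis system.

#' Construct a sample cloud
#'
#' A sample cloud holds one specimen's nuclei: identifiers, 3D positions in
#' micrometres, optional per-channel intensities and free-form metadata.
#'
#' @param points numeric n x 3 matrix of nuclear centroids (um).
#' @param sample_id scalar sample identifier.
#' @param nucleus_id vector of per-nucleus identifiers (default `1:n`).
#' @param intensities optional data frame of per-channel intensities, one row
#'   per nucleus, non-negative.
#' @param metadata named list (e.g. `stage_hpf`, `condition`, ground-truth
#'   `population` labels from the synthetic generators).
#' @return object of class `nq_cloud`.
#' @export
nq_cloud <- function(points, sample_id = "sample_1", nucleus_id = NULL,
                     intensities = NULL, metadata = list()) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  colnames(points) <- c("x_um", "y_um", "z_um")
  if (any(!is.finite(points)))
    stop(sprintf("non-finite coordinate in row(s) %s",
                 paste(which(rowSums(!is.finite(points)) > 0), collapse = ", ")))
  if (is.null(nucleus_id)) nucleus_id <- seq_len(nrow(points))
  nucleus_id <- as.character(nucleus_id)
  if (anyDuplicated(nucleus_id))
    stop("duplicate (sample_id, nucleus_id): ",
         paste(utils::head(unique(nucleus_id[duplicated(nucleus_id)]), 5),
               collapse = ", "))
  if (!is.null(intensities)) {
    intensities <- as.data.frame(intensities)
    stopifnot(nrow(intensities) == nrow(points))
  }
  structure(list(sample_id = as.character(sample_id)[1],
                 nucleus_id = nucleus_id, points = points,
                 intensities = intensities, metadata = metadata),
            class = "nq_cloud")
}

#' @export
print.nq_cloud <- function(x, ...) {
  cat(sprintf("Sample cloud '%s': %d nuclei", x$sample_id, nrow(x$points)))
  if (!is.null(x$intensities))
    cat(sprintf(", channels: %s", paste(names(x$intensities), collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' @export
length.nq_cloud <- function(x) nrow(x$points)

#' Read a point-cloud table into sample clouds
#'
#' Reads the canonical comma- (or tab-) separated dialect with columns
#' `sample_id, nucleus_id, x_um, y_um, z_um` and optional `channel_*`
#' intensity columns; plain `x`, `y`, `z` headers are accepted as aliases.
#' Rows are grouped by `sample_id` (order preserved within a sample).
#'
#' @param path file to read.
#' @param sep field separator; default infers `,` or tab from the extension.
#' @return named list of [nq_cloud()] objects, one per distinct `sample_id`.
#' @export
read_point_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  dt <- data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE)
  nm <- names(dt)
  for (ax in c("x", "y", "z")) {
    if (!(paste0(ax, "_um") %in% nm) && ax %in% nm)
      names(dt)[nm == ax] <- paste0(ax, "_um")
  }
  nm <- names(dt)
  miss <- setdiff(c("x_um", "y_um", "z_um"), nm)
  if (length(miss) > 0)
    stop("format error: missing coordinate column(s): ", paste(miss, collapse = ", "))
  if (!"sample_id" %in% nm) dt$sample_id <- "sample_1"
  if (!"nucleus_id" %in% nm) dt$nucleus_id <- seq_len(nrow(dt))
  co <- as.matrix(dt[, c("x_um", "y_um", "z_um")])
  if (any(!is.finite(co)))
    stop(sprintf("validation error: non-finite coordinate in row(s) %s",
                 paste(which(rowSums(!is.finite(co)) > 0), collapse = ", ")))
  key <- paste(dt$sample_id, dt$nucleus_id, sep = "\r")
  if (anyDuplicated(key))
    stop("validation error: duplicate (sample_id, nucleus_id) pairs, e.g. ",
         sub("\r", "/", key[duplicated(key)][1]))
  chan <- grep("^channel_", nm, value = TRUE)
  out <- lapply(split(seq_len(nrow(dt)), factor(dt$sample_id, levels = unique(dt$sample_id))),
                function(rows) {
    d <- dt[rows, , drop = FALSE]
    meta <- list()
    for (extra in setdiff(nm, c("sample_id", "nucleus_id", "x_um", "y_um", "z_um", chan)))
      meta[[extra]] <- d[[extra]]
    nq_cloud(as.matrix(d[, c("x_um", "y_um", "z_um")]),
             sample_id = d$sample_id[1], nucleus_id = d$nucleus_id,
             intensities = if (length(chan)) d[, chan, drop = FALSE] else NULL,
             metadata = meta)
  })
  out
}

#' Write result tables to CSV
#'
#' Values round-trip at full double precision (15 significant digits). When
#' several tables are given they are joined on `(sample_id, nucleus_id)`.
#'
#' @param tables a data frame, or list of data frames sharing the key columns.
#' @param path output file.
#' @export
write_results <- function(tables, path) {
  if (is.data.frame(tables)) tab <- tables
  else {
    tab <- Reduce(function(a, b) merge(a, b, by = c("sample_id", "nucleus_id"),
                                       sort = FALSE), tables)
  }
  ok <- tryCatch({
    data.table::fwrite(tab, path, sep = ",")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("I/O error writing ", path, ": ", conditionMessage(ok))
  invisible(path)
}

#' Convert sample clouds to the canonical table
#'
#' @param clouds an `nq_cloud` or list of them.
#' @param label optional name of a metadata vector to append as a column.
#' @return data frame in the canonical dialect.
#' @export
cloud_table <- function(clouds, label = NULL) {
  if (inherits(clouds, "nq_cloud")) clouds <- list(clouds)
  do.call(rbind, lapply(clouds, function(cl) {
    d <- data.frame(sample_id = cl$sample_id, nucleus_id = cl$nucleus_id,
                    x_um = cl$points[, 1], y_um = cl$points[, 2],
                    z_um = cl$points[, 3])
    if (!is.null(cl$intensities)) d <- cbind(d, cl$intensities)
    if (!is.null(label) && !is.null(cl$metadata[[label]]))
      d[[label]] <- cl$metadata[[label]]
    rownames(d) <- NULL
    d
  }))
}

#' Read a 3D volumetric image
#'
#' Reads a single-channel 3D TIFF stack. The voxel size defaults to 1 um
#' isotropic when no metadata is supplied.
#'
#' @param path TIFF file (one z-slice per page).
#' @param voxel_size length-3 voxel size in um (metadata override).
#' @return object of class `nq_volume`: `data`, a 3D array indexed
#'   `[x, y, z]`, and `voxel_size`.
#' @export
read_volume <- function(path, voxel_size = c(1, 1, 1)) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.(h5|hdf5|ims)$", path, ignore.case = TRUE))
    stop("HDF5 volumes are not supported; convert to 3D TIFF")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(dim(pages[[1]])) != 2L)
    stop("dimensionality error: expected single-channel 2D pages, got array with dim ",
         paste(dim(pages[[1]]), collapse = "x"))
  if (length(pages) < 2L)
    stop("dimensionality error: a 3D volume needs >= 2 z-slices")
  arr <- array(0, dim = c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- t(pages[[k]])
  nq_volume(arr, voxel_size)
}

#' Construct a volume object
#'
#' @param data 3D numeric array indexed `[x, y, z]`; voxel centre `i` is at
#'   coordinate `(i - 0.5) * voxel_size`.
#' @param voxel_size length-3 (or scalar) voxel size in um.
#' @return object of class `nq_volume`.
#' @export
nq_volume <- function(data, voxel_size = c(1, 1, 1)) {
  if (length(dim(data)) != 3L)
    stop("dimensionality error: volume must be a 3D array, got ",
         length(dim(data)), "D")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3)
  structure(list(data = data, voxel_size = as.numeric(voxel_size)),
            class = "nq_volume")
}

#' @export
print.nq_volume <- function(x, ...) {
  cat(sprintf("3D volume %s, voxel size (%s) um\n",
              paste(dim(x$data), collapse = " x "),
              paste(x$voxel_size, collapse = ", ")))
  invisible(x)
}

#' Write a volume as a 3D TIFF stack
#'
#' @param volume an `nq_volume` with values in `[0, 1]` (rescaled if not).
#' @param path output file.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "nq_volume"))
  a <- volume$data
  if (max(a) > 1 || min(a) < 0) a <- (a - min(a)) / max(max(a) - min(a), 1e-12)
  pages <- lapply(seq_len(dim(a)[3]), function(k) t(a[, , k]))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}
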