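#' Preprocess one image
#'
#' Resizes a single-channel image to `target x target` pixels (bilinear)
#' and min-max scales intensities to `[0, 1]`. A constant image (zero
#' dynamic range) maps to all zeros. Resizing is skipped when the image is
#' already at the target size, so preprocessing is idempotent up to float
#' tolerance.
#'
#' @param image numeric matrix (any size).
#' @param target_size output side length in pixels.
#' @return `target_size x target_size` numeric matrix in `[0, 1]`.
#' @export
preprocess <- function(image, target_size = 256L) {
  m <- as.matrix(image)
  if (!length(m)) stop("cannot preprocess an empty image")
  storage.mode(m) <- "double"
  if (!all(dim(m) == target_size))
    m <- EBImage::imageData(EBImage::resize(EBImage::Image(m),
                                            w = target_size, h = target_size,
                                            filter = "bilinear"))
  rng <- range(m)
  if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1])
  else array(0, dim = dim(m))
}

.figshare_classes <- c("meningioma", "glioma", "pituitary")

python_bin <- function() {
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p))
    stop("reading/writing MATLAB v7.3 files needs a `python` with h5py on PATH")
  p
}

figshare_py <- function(args) {
  script <- system.file("python", "figshare_io.py", package = "btcfcnn")
  if (!nzchar(script)) stop("bundled figshare_io.py helper not found")
  status <- system2(python_bin(), c(shQuote(script), args),
                    stdout = TRUE, stderr = TRUE)
  code <- attr(status, "status") %||% 0L
  if (code != 0L)
    stop("HDF5 helper failed: ", paste(status, collapse = "\n"))
  invisible(NULL)
}

new_dataset <- function(x, y, patient_id, path, provenance) {
  counts <- tabulate(y + 1L, nbins = 3L)
  names(counts) <- .figshare_classes
  structure(list(x = x, y = as.integer(y), patient_id = patient_id,
                 path = path, class_names = .figshare_classes,
                 counts = counts, provenance = provenance),
            class = "tumor_dataset")
}

#' @export
print.tumor_dataset <- function(x, ...) {
  cat(sprintf("<tumor_dataset> %d images %dx%d | %s\n", length(x$y),
              dim(x$x)[1L], dim(x$x)[2L],
              paste(sprintf("%s %d", names(x$counts), x$counts),
                    collapse = ", ")))
  invisible(x)
}

#' Load a directory of Figshare-layout tumor slices
#'
#' Reads per-slice MATLAB v7.3 (HDF5-layout) files, each holding a `cjdata`
#' record with fields `image`, `label` (1 meningioma / 2 glioma / 3
#' pituitary), `PID`, `tumorBorder` and `tumorMask`. Labels are mapped to
#' the package convention 0/1/2; images are resized to
#' `target_size x target_size` and min-max normalized via [preprocess()].
#' `tumorBorder`/`tumorMask` are checked for presence but not used
#' (classification only). Files are read in lexicographic order so
#' downstream fold assignments are reproducible.
#'
#' @param dir directory of `.mat` files.
#' @param target_size output image side in pixels.
#' @param skip_bad if `TRUE`, files that fail to parse are dropped with a
#'   warning instead of aborting the load.
#' @return a `"tumor_dataset"`: list with `x` (array `(target_size,
#'   target_size, 1, n)`), `y` (labels 0..2), `patient_id`, `path`,
#'   `class_names`, per-class `counts`, and preprocessing `provenance`.
#' @export
load_figshare <- function(dir, target_size = 256L, skip_bad = FALSE) {
  if (!dir.exists(dir)) stop("no such directory: ", dir)
  meta_path <- tempfile(fileext = ".csv")
  bin_path <- tempfile(fileext = ".bin")
  on.exit(unlink(c(meta_path, bin_path)), add = TRUE)
  figshare_py(c("read", shQuote(dir), shQuote(meta_path), shQuote(bin_path)))
  meta <- read.csv(meta_path, colClasses = c(pid = "character"))
  bad <- meta$status != "ok"
  if (any(bad)) {
    msgs <- sprintf("%s: %s", meta$file[bad], sub("^error:", "", meta$status[bad]))
    if (!skip_bad) stop("failed to load ", sum(bad), " file(s):\n  ",
                        paste(msgs, collapse = "\n  "))
    warning("skipping ", sum(bad), " unreadable file(s)")
  }
  con <- file(bin_path, "rb")
  on.exit(close(con), add = TRUE)
  keep <- which(!bad)
  x <- array(0, dim = c(target_size, target_size, 1L, length(keep)))
  j <- 0L
  for (i in seq_len(nrow(meta))) {
    if (meta$status[i] != "ok") next
    npix <- meta$h[i] * meta$w[i]
    img <- matrix(readBin(con, "double", npix), meta$h[i], meta$w[i])
    j <- j + 1L
    x[, , 1L, j] <- preprocess(img, target_size)
  }
  labels <- as.integer(meta$label[keep])
  if (any(!labels %in% 1:3))
    stop("dataset labels must be 1, 2 or 3 (got ",
         paste(unique(labels), collapse = ", "), ")")
  new_dataset(x, labels - 1L, meta$pid[keep],
              file.path(dir, meta$file[keep]),
              provenance = list(source = "figshare_mat", dir = dir,
                                target_size = target_size,
                                normalization = "minmax",
                                interpolation = "bilinear"))
}

#' Load images from a directory with a CSV manifest
#'
#' Generic entry point for plain image files (PNG/TIFF/JPEG): the manifest
#' CSV must have columns `path`, `label` (0..2) and `patient_id`. Images
#' are read as grayscale (channels averaged if needed) and passed through
#' [preprocess()].
#'
#' @param dir directory the manifest paths are relative to.
#' @param manifest_csv manifest path.
#' @param target_size output image side in pixels.
#' @return a `"tumor_dataset"` (see [load_figshare()]).
#' @export
load_image_dir <- function(dir, manifest_csv, target_size = 256L) {
  man <- read_manifest(manifest_csv)
  if (anyDuplicated(man$path))
    stop("duplicate paths in manifest: ",
         paste(unique(man$path[duplicated(man$path)]), collapse = ", "))
  if (any(!man$label %in% 0:2))
    stop("labels must be in 0..2; offending rows: ",
         paste(which(!man$label %in% 0:2), collapse = ", "))
  paths <- file.path(dir, man$path)
  missing <- !file.exists(paths)
  if (any(missing))
    stop("missing image file(s): ", paste(man$path[missing], collapse = ", "))
  x <- array(0, dim = c(target_size, target_size, 1L, nrow(man)))
  for (i in seq_len(nrow(man))) {
    img <- EBImage::imageData(EBImage::readImage(paths[i]))
    if (length(dim(img)) == 3L) img <- apply(img, c(1L, 2L), mean)
    x[, , 1L, i] <- preprocess(img, target_size)
  }
  new_dataset(x, man$label, man$patient_id, paths,
              provenance = list(source = "image_dir", dir = dir,
                                target_size = target_size,
                                normalization = "minmax",
                                interpolation = "bilinear"))
}

#' Manifest CSV round trip
#'
#' The manifest records sample paths, labels and patient ids plus the
#' preprocessing provenance (serialized as a `# provenance:` JSON header
#' line). `read_manifest` restores both and errors on a missing column.
#'
#' @param dataset a `"tumor_dataset"`, or a data.frame with columns
#'   `path`, `label`, `patient_id`.
#' @param path CSV file path.
#' @return `write_manifest`: `path` invisibly. `read_manifest`: data.frame
#'   with columns `path`, `label`, `patient_id` and attribute
#'   `"provenance"`.
#' @export
write_manifest <- function(dataset, path) {
  if (inherits(dataset, "tumor_dataset")) {
    df <- data.frame(path = dataset$path, label = dataset$y,
                     patient_id = dataset$patient_id,
                     stringsAsFactors = FALSE)
    prov <- dataset$provenance
  } else {
    df <- as.data.frame(dataset)
    prov <- attr(dataset, "provenance") %||% list()
  }
  need <- c("path", "label", "patient_id")
  if (!all(need %in% names(df)))
    stop("manifest needs columns: ", paste(need, collapse = ", "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# provenance: ",
                    jsonlite::toJSON(prov, auto_unbox = TRUE, digits = NA)),
             con)
  write.csv(df[need], con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  lines <- readLines(path)
  prov <- list()
  if (length(lines) && startsWith(lines[1L], "# provenance: ")) {
    prov <- jsonlite::fromJSON(sub("^# provenance: ", "", lines[1L]),
                               simplifyDataFrame = FALSE)
    lines <- lines[-1L]
  }
  df <- read.csv(text = paste(lines, collapse = "\n"),
                 stringsAsFactors = FALSE)
  need <- c("path", "label", "patient_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("manifest schema mismatch; missing column(s): ",
         paste(miss, collapse = ", "))
  df$label <- as.integer(df$label)
  df$patient_id <- as.character(df$patient_id)
  attr(df, "provenance") <- prov
  df
}
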