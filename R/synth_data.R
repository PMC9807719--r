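#' Phantom generator configuration
#'
#' Parameters of the synthetic brain-phantom generator: single-channel
#' square images of an elliptical "head" on a dark background with one
#' class-dependent lesion, plus additive Gaussian noise. The three classes
#' are constructed to be visually separable by lesion position, size and
#' texture, loosely echoing the location tendencies of the three tumor
#' types; they emulate learnable class structure, not anatomy.
#'
#' @param n_samples number of images.
#' @param class_proportions three fractions summing to 1 (deterministic
#'   largest-remainder allocation, so `n = 300` at equal proportions gives
#'   exactly 100 per class).
#' @param image_size image side in pixels (256 matches the reference input
#'   size; 64 is the fast test size).
#' @param noise_sd standard deviation of the additive Gaussian intensity
#'   noise (intensities live in `[0, 1]`).
#' @param tumor_radius_range lesion radius range in pixels; default scales
#'   with the image (5--12% of the side).
#' @param seed integer seed; generation is bit-reproducible given it.
#' @return a `"phantom_config"` list.
#' @export
phantom_config <- function(n_samples = 300L,
                           class_proportions = c(1, 1, 1) / 3,
                           image_size = 256L, noise_sd = 0.05,
                           tumor_radius_range = NULL, seed = 42L) {
  stopifnot(n_samples >= 1, length(class_proportions) == 3L,
            all(class_proportions >= 0), noise_sd >= 0, image_size >= 16L)
  if (abs(sum(class_proportions) - 1) > 1e-8)
    stop("class_proportions must sum to 1")
  if (is.null(tumor_radius_range))
    tumor_radius_range <- pmax(c(2, 3), round(c(0.05, 0.12) * image_size))
  stopifnot(length(tumor_radius_range) == 2L, all(tumor_radius_range >= 1),
            tumor_radius_range[2L] < image_size / 2)
  structure(list(n_samples = as.integer(n_samples),
                 class_proportions = class_proportions,
                 image_size = as.integer(image_size), noise_sd = noise_sd,
                 tumor_radius_range = tumor_radius_range,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# largest-remainder allocation of n into 3 classes
allocate_classes <- function(n, props) {
  base <- floor(n * props)
  rem <- n - sum(base)
  if (rem > 0L) {
    frac <- n * props - base
    extra <- order(-frac, seq_along(props))[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' Generate synthetic tumor phantoms
#'
#' Every image is an elliptical head (moderate intensity ~0.4, light
#' per-image axis jitter) on a dark background, with one lesion whose
#' geometry encodes the class: class 0 ("meningioma-like") a bright smooth
#' disc adjacent to the head boundary; class 1 ("glioma-like") a larger,
#' irregular, mid-intensity blob with textured interior in an off-center
#' lobe; class 2 ("pituitary-like") a small bright disc at the
#' central-inferior position. Gaussian noise at `noise_sd` is added and
#' intensities are clipped to `[0, 1]`.
#'
#' @param config a [phantom_config()].
#' @return a `"tumor_dataset"` (see [load_figshare()]) whose `meta`
#'   element additionally records the lesion center and radius per image.
#' @export
generate_phantoms <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  s <- config$image_size
  n <- config$n_samples
  counts <- allocate_classes(n, config$class_proportions)
  rr <- config$tumor_radius_range
  c0 <- (s + 1) / 2
  row_g <- matrix(seq_len(s), s, s)          # row index grid
  col_g <- matrix(seq_len(s), s, s, byrow = TRUE)

  x <- array(0, dim = c(s, s, 1L, n))
  meta <- data.frame(label = integer(n), lesion_row = numeric(n),
                     lesion_col = numeric(n), lesion_r = numeric(n))
  withr::with_seed(config$seed, {
    y <- sample(rep(0:2, counts))
    for (i in seq_len(n)) {
      a_r <- 0.44 * s * runif(1, 0.97, 1.03)   # head semi-axes (rows, cols)
      a_c <- 0.36 * s * runif(1, 0.97, 1.03)
      img <- matrix(0.02, s, s)
      er <- (row_g - c0) / a_r
      ec <- (col_g - c0) / a_c
      inside <- er * er + ec * ec <= 1
      img[inside] <- 0.40

      cls <- y[i]
      if (cls == 0L) {                         # bright disc at the boundary
        r <- runif(1, rr[1L], rr[2L])
        th <- runif(1, 0, 2 * pi)
        rb <- 1 / sqrt((cos(th) / a_c)^2 + (sin(th) / a_r)^2)
        lr <- c0 + 0.78 * rb * sin(th)
        lc <- c0 + 0.78 * rb * cos(th)
        les <- (row_g - lr)^2 + (col_g - lc)^2 <= r^2
        img[les & inside] <- 0.95
      } else if (cls == 1L) {                  # irregular textured blob
        r <- 1.3 * runif(1, rr[1L], rr[2L])
        th <- runif(1, 0, 2 * pi)
        rb <- 1 / sqrt((cos(th) / a_c)^2 + (sin(th) / a_r)^2)
        lr <- c0 + 0.40 * rb * sin(th)
        lc <- c0 + 0.40 * rb * cos(th)
        p1 <- runif(1, 0, 2 * pi); p2 <- runif(1, 0, 2 * pi)
        phi <- atan2(row_g - lr, col_g - lc)
        rad <- r * (1 + 0.25 * sin(3 * phi + p1) + 0.15 * sin(5 * phi + p2))
        les <- (row_g - lr)^2 + (col_g - lc)^2 <= rad^2
        les <- les & inside
        tex <- matrix(runif(s * s, -0.15, 0.15), s, s)
        img[les] <- 0.60 + tex[les]
      } else {                                 # small central-inferior disc
        r <- runif(1, rr[1L], 0.5 * (rr[1L] + rr[2L]))
        lr <- c0 + 0.18 * s + rnorm(1, 0, 0.015 * s)
        lc <- c0 + rnorm(1, 0, 0.015 * s)
        les <- (row_g - lr)^2 + (col_g - lc)^2 <= r^2
        img[les & inside] <- 0.95
      }

      if (config$noise_sd > 0)
        img <- img + matrix(rnorm(s * s, 0, config$noise_sd), s, s)
      x[, , 1L, i] <- pmin(pmax(img, 0), 1)
      meta$label[i] <- cls
      meta$lesion_row[i] <- lr; meta$lesion_col[i] <- lc; meta$lesion_r[i] <- r
    }
  })
  ds <- new_dataset(x, y, sprintf("SYN%04d", seq_len(n)),
                    sprintf("phantom_%04d", seq_len(n)),
                    provenance = c(list(source = "synthetic_phantom"),
                                   unclass(config)))
  ds$class_names <- c("meningioma_like", "glioma_like", "pituitary_like")
  ds$meta <- meta
  ds
}

#' Write phantoms as Figshare-layout fixture files
#'
#' Generates `n` phantoms and writes them as per-slice MATLAB v7.3-style
#' HDF5 files with the `cjdata` record (image, label 1..3, PID,
#' tumorBorder, tumorMask), i.e. the exact layout [load_figshare()]
#' consumes, so labels and intensities round-trip. Files are synthetic
#' stand-ins for the external dataset, intended for tests and examples.
#'
#' @param dir output directory (created if needed).
#' @param n number of files.
#' @param config a [phantom_config()]; `n_samples` is overridden by `n`.
#' @return character vector of the written file paths, invisibly.
#' @export
fixture_mat <- function(dir, n = 3L,
                        config = phantom_config(image_size = 64L)) {
  config$n_samples <- as.integer(n)
  ds <- generate_phantoms(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- config$image_size
  meta_path <- tempfile(fileext = ".csv")
  bin_path <- tempfile(fileext = ".bin")
  on.exit(unlink(c(meta_path, bin_path)), add = TRUE)
  files <- sprintf("phantom_%04d.mat", seq_len(n))
  meta <- data.frame(file = files, label = ds$y + 1L, pid = ds$patient_id,
                     h = s, w = s, stringsAsFactors = FALSE)
  write.csv(meta, meta_path, row.names = FALSE, quote = FALSE)
  con <- file(bin_path, "wb")
  for (i in seq_len(n))
    writeBin(as.vector(ds$x[, , 1L, i]), con)
  close(con)
  figshare_py(c("write", shQuote(dir), shQuote(meta_path), shQuote(bin_path)))
  invisible(file.path(dir, files))
}
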