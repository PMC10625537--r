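#' Simulate a multi-wavelength two-channel imaging field with known truth
#'
#' Renders a field of labelled somata as soft-edged disks whose green/red
#' intensities at every excitation wavelength come from the forward sensor
#' model ([forward_intensities()]), with per-cell pH drawn from a normal
#' distribution and \[Cl-\]i from a log-normal parameterized by its median
#' (strictly positive and right-skewed, like in vivo chloride distributions).
#' Per-pixel noise is Poisson (photon shot noise, signal-dependent) plus
#' additive Gaussian (read noise). A uniform background offset is added
#' before noise.
#'
#' Defaults emulate a day-time (ZT5-like) field; pass `cl_median = 18.4` for
#' a night-time (ZT17-like) field.
#'
#' @param n_cells Number of somata (>= 0).
#' @param field_size `c(ny, nx)` image size in pixels.
#' @param soma_radius `c(min, max)` soma radius range in px (> 0).
#' @param ph_mean,ph_sd Per-cell pH distribution (dimensionless).
#' @param cl_median Median of the per-cell \[Cl-\]i log-normal (mM, > 0).
#' @param cl_log_sd SD of log(\[Cl-\]i).
#' @param brightness_range `c(min, max)` per-cell brightness (a.u.).
#' @param background Uniform background offset (a.u.).
#' @param noise `list(gaussian_sd =, poisson_gain =)`; both 0 disables noise.
#' @param calib Sensor calibration used by the forward model; the wavelengths
#'   of the stack are the calibration's wavelengths.
#' @param pixel_size_um Pixel size recorded in metadata.
#' @param seed Integer seed (mandatory; a single fixed PRNG stream drives the
#'   whole simulation).
#' @param cells Optional ground-truth table (`cell_id`, `x`, `y`,
#'   `radius_px`, `ph`, `cl_mM`, `brightness`) to render instead of drawing
#'   new cells — e.g. the same neurons before and after a pharmacological
#'   manipulation. Placement and per-cell draws are skipped.
#'
#' @return An object of class `clop_field`: a list with
#'   * `stack`: numeric array `[ny, nx, channel, wavelength]` with
#'     `dimnames` channels `green`/`red` and wavelengths in nm;
#'   * `cells`: ground-truth tibble (`cell_id`, `x`, `y` 0-based px,
#'     `radius_px`, `ph`, `cl_mM`, `brightness`);
#'   * `calib`, `pixel_size_um`, `background`, `noise`, `seed`.
#' @examples
#' fld <- sim_imaging_field(n_cells = 5, field_size = c(96, 96), seed = 1)
#' fld$cells
#' @export
sim_imaging_field <- function(n_cells = 50,
                              field_size = c(256, 256),
                              soma_radius = c(4, 7),
                              ph_mean = 7.15, ph_sd = 0.05,
                              cl_median = 8.9, cl_log_sd = 0.35,
                              brightness_range = c(80, 150),
                              background = 10,
                              noise = list(gaussian_sd = 2, poisson_gain = 1),
                              calib = sensor_calibration(),
                              pixel_size_um = 0.8,
                              seed, cells = NULL) {
  if (missing(seed)) abort("seed is mandatory")
  if (n_cells < 0) abort("n_cells must be >= 0")
  if (any(soma_radius <= 0)) abort("soma radii must be > 0")
  if (cl_median <= 0) abort("cl_median must be > 0")
  ny <- field_size[1]; nx <- field_size[2]
  set.seed(seed)

  if (is.null(cells)) {
    cells <- .place_cells(n_cells, nx, ny, soma_radius)
    cells$ph <- rnorm(n_cells, ph_mean, ph_sd)
    cells$cl_mM <- rlnorm(n_cells, meanlog = log(cl_median), sdlog = cl_log_sd)
    cells$brightness <- runif(n_cells, brightness_range[1], brightness_range[2])
  } else {
    cells <- as_tibble(cells)
    n_cells <- nrow(cells)
  }

  wl <- calib$wavelengths_nm
  stack <- array(0, dim = c(ny, nx, 2, length(wl)),
                 dimnames = list(NULL, NULL, c("green", "red"), wl))
  if (n_cells > 0) {
    for (i in seq_len(n_cells)) {
      w <- forward_intensities(cells$ph[i], cells$cl_mM[i],
                               cells$brightness[i], calib)
      prof <- .soma_profile(cells$x[i], cells$y[i], cells$radius_px[i], nx, ny)
      for (k in seq_along(wl)) {
        stack[prof$rows, prof$cols, "green", k] <-
          stack[prof$rows, prof$cols, "green", k] + w$green[k] * prof$p
        stack[prof$rows, prof$cols, "red", k] <-
          stack[prof$rows, prof$cols, "red", k] + w$red[k] * prof$p
      }
    }
  }
  stack <- stack + background
  g_sd <- noise$gaussian_sd %||% 0
  p_gain <- noise$poisson_gain %||% 0
  if (p_gain > 0) {
    stack[] <- rpois(length(stack), stack / p_gain) * p_gain
  }
  if (g_sd > 0) {
    stack[] <- stack + rnorm(length(stack), 0, g_sd)
  }
  structure(
    list(stack = stack, cells = cells, calib = calib,
         pixel_size_um = pixel_size_um, background = background,
         noise = list(gaussian_sd = g_sd, poisson_gain = p_gain), seed = seed),
    class = "clop_field")
}

# rejection placement with pairwise separation r_i + r_j + 2 px
.place_cells <- function(n_cells, nx, ny, soma_radius, max_tries = 2000) {
  xs <- ys <- rs <- numeric(0)
  for (i in seq_len(n_cells)) {
    r <- runif(1, soma_radius[1], soma_radius[2])
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      x <- runif(1, r + 1, nx - r - 2)
      y <- runif(1, r + 1, ny - r - 2)
      if (length(xs) == 0 ||
          all(sqrt((xs - x)^2 + (ys - y)^2) >= rs + r + 2)) {
        xs <- c(xs, x); ys <- c(ys, y); rs <- c(rs, r)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      abort(sprintf(
        "could not place %d non-overlapping somata of radius %.1f-%.1f px in a %dx%d field (placement failed at cell %d); reduce density",
        n_cells, soma_radius[1], soma_radius[2], ny, nx, i))
    }
  }
  tibble(cell_id = seq_len(n_cells), x = xs, y = ys, radius_px = rs)
}

# soft-edged disk profile on a local patch; 0-based centre (x right, y down)
.soma_profile <- function(x, y, r, nx, ny, edge = 0.7) {
  pad <- ceiling(r + 4 * edge + 1)
  cols <- max(1, floor(x) - pad + 1):min(nx, ceiling(x) + pad + 1)
  rows <- max(1, floor(y) - pad + 1):min(ny, ceiling(y) + pad + 1)
  # pixel (row i, col j) has 0-based coords (j-1, i-1)
  d <- sqrt(outer((rows - 1 - y)^2, (cols - 1 - x)^2, "+"))
  list(rows = rows, cols = cols, p = 1 / (1 + exp((d - r) / edge)))
}

#' @export
print.clop_field <- function(x, ...) {
  d <- dim(x$stack)
  cat(sprintf("<clop_field> %dx%d px, %d wavelengths x 2 channels, %d cells (seed %s)\n",
              d[1], d[2], d[4], nrow(x$cells), format(x$seed)))
  invisible(x)
}

#' Simulate per-cell measurement tables for grouped animals
#'
#' Draws synthetic `CellMeasurementTable` rows directly from the generator's
#' chloride truth model, bypassing image rendering: each animal gets its own
#' median (log-normal between-animal spread around the group median, as seen
#' between mice imaged at the same zeitgeber time), and each cell an
#' independent log-normal draw around the animal median. Used for group-level
#' statistical simulations where rendering thousands of image fields would
#' add nothing.
#'
#' @param n_animals Number of animals in the group.
#' @param cells_per_animal Cells measured per animal (recycled).
#' @param cl_median Group median \[Cl-\]i (mM).
#' @param cl_log_sd Within-animal SD of log(\[Cl-\]i).
#' @param animal_log_sd Between-animal SD of log(median).
#' @param condition Condition label (e.g. `"ZT5"`).
#' @param ph_mean,ph_sd Per-cell pH distribution.
#' @param seed Integer seed (mandatory).
#' @return A tibble with columns `animal_id`, `field_id`, `condition`,
#'   `cell_id`, `ph`, `cl_mM`, `flag`.
#' @export
sim_cell_table <- function(n_animals, cells_per_animal = 70,
                           cl_median = 8.9, cl_log_sd = 0.35,
                           animal_log_sd = 0.18,
                           condition = "ZT5",
                           ph_mean = 7.15, ph_sd = 0.05, seed) {
  if (missing(seed)) abort("seed is mandatory")
  set.seed(seed)
  ncell <- rep_len(cells_per_animal, n_animals)
  purrr::map_dfr(seq_len(n_animals), function(a) {
    med_a <- rlnorm(1, log(cl_median), animal_log_sd)
    n <- ncell[a]
    tibble(animal_id = sprintf("%s_m%02d", condition, a),
           field_id = 1L,
           condition = condition,
           cell_id = seq_len(n),
           ph = rnorm(n, ph_mean, ph_sd),
           cl_mM = rlnorm(n, log(med_a), cl_log_sd),
           flag = NA_character_)
  })
}
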