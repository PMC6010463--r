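# Ground-truthed synthetic fluorescence images: ring-structured microtumor
# cross-sections and 2D monolayer fields with two-state expression.
#
# Images are numeric arrays (rows x cols x channels) holding integer
# intensities on a 16-bit scale (0..65535, arbitrary units).

mt_with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

mt_radius_matrix <- function(size, center) {
  dx <- matrix(rep(seq_len(size[2]) - center[1], each = size[1]),
               nrow = size[1])
  dy <- matrix(rep(seq_len(size[1]) - center[2], times = size[2]),
               nrow = size[1])
  sqrt(dx^2 + dy^2)
}

#' Ground truth for a synthetic microtumor cross-section
#'
#' Bundles the parameters of a ring-structured two-channel image: a disk of
#' `radius` pixels split at radius fractions `boundaries` into core, inner
#' and outer rings (defaults 0.5 and 0.75, mirroring the 300/450/600 um
#' model geometry), with a per-channel mean intensity in each ring, a flat
#' background outside the disk, and additive Gaussian (optionally Poisson)
#' noise. The default channel means emulate the observed mid-plane pattern:
#' a proliferation-marker channel high in both outer and inner shells, and a
#' PHGDH-like channel confined to the outer shell.
#'
#' @param size image side length in pixels (square image).
#' @param center disk center `(x, y)` in pixels; defaults to the image
#'   center.
#' @param radius tumor radius in pixels.
#' @param boundaries radius fractions splitting core|inner and inner|outer;
#'   strictly increasing, in (0, 1).
#' @param channel_means channels x rings matrix (columns `o`, `i`, `c`) of
#'   mean intensities, arbitrary units >= 0.
#' @param background background intensity outside the disk.
#' @param noise_sd per-channel Gaussian noise standard deviation.
#' @param poisson if `TRUE`, pixel intensities are Poisson draws around the
#'   ring mean before Gaussian noise is added.
#' @param seed integer seed; identical truths yield identical images.
#' @return Object of class `mt_ring_truth`.
#' @export
ring_truth <- function(size = 257, center = NULL, radius = 110,
                       boundaries = c(0.5, 0.75),
                       channel_means = rbind(
                         ki67  = c(o = 12000, i = 9000, c = 2000),
                         phgdh = c(o = 12000, i = 3000, c = 1500)),
                       background = 500, noise_sd = c(300, 300),
                       poisson = FALSE, seed = 1L) {
  if (is.null(center)) center <- c((size + 1) / 2, (size + 1) / 2)
  if (length(boundaries) != 2L || any(!is.finite(boundaries)) ||
      boundaries[1] <= 0 || boundaries[2] >= 1 ||
      boundaries[1] >= boundaries[2])
    stop("boundaries must be strictly increasing fractions in (0, 1)",
         call. = FALSE)
  channel_means <- as.matrix(channel_means)
  if (ncol(channel_means) != 3L)
    stop("channel_means must have columns o, i, c", call. = FALSE)
  if (is.null(colnames(channel_means)))
    colnames(channel_means) <- c("o", "i", "c")
  if (any(channel_means < 0) || background < 0)
    stop("mean intensities must be non-negative", call. = FALSE)
  n_ch <- nrow(channel_means)
  noise_sd <- rep_len(noise_sd, n_ch)
  if (any(noise_sd < 0)) stop("noise_sd must be non-negative", call. = FALSE)
  if (radius <= 0 || center[1] - radius < 1 || center[2] - radius < 1 ||
      center[1] + radius > size || center[2] + radius > size)
    stop("tumor disk must lie inside the image", call. = FALSE)
  structure(
    list(size = c(size, size), center = center, radius = radius,
         boundaries = boundaries, channel_means = channel_means,
         background = background, noise_sd = noise_sd, poisson = poisson,
         seed = as.integer(seed)),
    class = "mt_ring_truth"
  )
}

#' Generate a synthetic microtumor cross-section image
#'
#' Renders the ring pattern described by a [ring_truth()]: every pixel takes
#' its ring's mean intensity (background outside the disk), optionally
#' Poisson-resampled, plus Gaussian noise, rounded to the 16-bit integer
#' grid and clamped to `[0, 65535]`. The same truth (same seed) always
#' produces a bit-identical image.
#'
#' @param truth an [`mt_ring_truth`][ring_truth] object.
#' @return List with `image` (rows x cols x channels array) and `truth`.
#' @export
generate_microtumor_image <- function(truth) {
  stopifnot(inherits(truth, "mt_ring_truth"))
  r <- mt_radius_matrix(truth$size, truth$center)
  R <- truth$radius
  b <- truth$boundaries
  n_ch <- nrow(truth$channel_means)
  img <- array(0, dim = c(truth$size, n_ch),
               dimnames = list(NULL, NULL, rownames(truth$channel_means)))
  ring <- matrix(0L, truth$size[1], truth$size[2])  # 0 bg, 1 o, 2 i, 3 c
  ring[r <= R] <- 1L
  ring[r <= b[2] * R] <- 2L
  ring[r <= b[1] * R] <- 3L
  mt_with_seed(truth$seed, {
    for (ch in seq_len(n_ch)) {
      means <- c(truth$background,
                 truth$channel_means[ch, c("o", "i", "c")])
      plane <- matrix(means[ring + 1L], truth$size[1], truth$size[2])
      if (truth$poisson)
        plane <- matrix(stats::rpois(length(plane), plane),
                        truth$size[1], truth$size[2])
      if (truth$noise_sd[ch] > 0)
        plane <- plane + matrix(stats::rnorm(length(plane),
                                             sd = truth$noise_sd[ch]),
                                truth$size[1], truth$size[2])
      img[, , ch] <- pmin(pmax(round(plane), 0), 65535)
    }
  })
  list(image = img, truth = truth)
}

#' Ground truth for a synthetic 2D monolayer field
#'
#' Parameters of a field of disk-shaped cells laid out on a jittered grid,
#' each with a smaller concentric nuclear disk. Per channel (nuclear
#' proliferation marker, cytoplasmic enzyme) every cell is independently ON
#' with probability `p_on`, and its noiseless intensity is lognormal around
#' the state mean: `mean_state * exp(sigma_log * z - sigma_log^2 / 2)`,
#' where the latent pair `(z_nuclear, z_cyto)` is standard bivariate normal
#' with correlation `rho`; noiseless intensities are quantized to the
#' 16-bit integer grid before rendering. Clone-like fields are obtained
#' with `p_on` 0 or 1.
#'
#' @param n_cells number of cells (> 0).
#' @param p_on per-channel ON probability, recycled to length 2
#'   (nuclear, cytoplasmic).
#' @param mean_on,mean_off state mean intensities (arbitrary units).
#' @param sigma_log lognormal dispersion of per-cell intensity.
#' @param rho latent cross-channel correlation, in `[-1, 1]`.
#' @param cell_radius,nucleus_radius disk radii in pixels
#'   (`nucleus_radius < cell_radius`).
#' @param spacing grid pitch in pixels; must allow disjoint cells
#'   (`>= 2 * (cell_radius + jitter) + 1`); default chooses the minimum.
#' @param jitter maximum absolute integer jitter of each cell center.
#' @param noise_sd Gaussian pixel noise standard deviation.
#' @param background background intensity.
#' @param seed integer seed.
#' @return Object of class `mt_cell_truth`.
#' @export
cell_truth <- function(n_cells = 500, p_on = c(0.5, 0.5),
                       mean_on = 9000, mean_off = 1200, sigma_log = 0.15,
                       rho = 0, cell_radius = 9, nucleus_radius = 4,
                       spacing = NULL, jitter = 3, noise_sd = 150,
                       background = 300, seed = 1L) {
  if (!is.numeric(n_cells) || n_cells <= 0)
    stop("n_cells must be positive", call. = FALSE)
  n_cells <- as.integer(n_cells)
  p_on <- rep_len(p_on, 2L)
  if (any(p_on < 0 | p_on > 1)) stop("p_on must be in [0, 1]", call. = FALSE)
  if (abs(rho) > 1) stop("rho must be in [-1, 1]", call. = FALSE)
  if (nucleus_radius >= cell_radius)
    stop("nucleus_radius must be smaller than cell_radius", call. = FALSE)
  min_spacing <- 2 * (cell_radius + jitter) + 1
  if (is.null(spacing)) spacing <- min_spacing
  if (spacing < min_spacing)
    stop("cells would overlap: spacing ", spacing,
         " below packing limit ", min_spacing, call. = FALSE)
  structure(
    list(n_cells = n_cells, p_on = p_on, mean_on = mean_on,
         mean_off = mean_off, sigma_log = sigma_log, rho = rho,
         cell_radius = cell_radius, nucleus_radius = nucleus_radius,
         spacing = spacing, jitter = jitter, noise_sd = noise_sd,
         background = background, seed = as.integer(seed)),
    class = "mt_cell_truth"
  )
}

mt_disk_offsets <- function(radius) {
  d <- expand.grid(dx = -radius:radius, dy = -radius:radius)
  d[d$dx^2 + d$dy^2 <= radius^2, ]
}

#' Generate a synthetic monolayer field with two-state expression
#'
#' Renders the field described by a [cell_truth()]: cells on a jittered grid
#' (disjoint by construction), the nuclear channel drawn over each nucleus
#' disk and the cytoplasmic channel over the whole cell disk at the cell's
#' state-dependent noiseless intensity, plus background and Gaussian pixel
#' noise, rounded to the 16-bit grid. Returns the per-cell truth table and
#' the label masks needed for mask-based quantification.
#'
#' @param truth an [`mt_cell_truth`][cell_truth] object.
#' @return List with `image` (rows x cols x 2 array; channel 1 nuclear,
#'   channel 2 cytoplasmic), `cells` (data frame: `cell`, `x`, `y`,
#'   `state_nuclear`, `state_cyto`, `intensity_nuclear`, `intensity_cyto`),
#'   `masks` (list of `cell` and `nucleus` label matrices) and `truth`.
#' @export
generate_monolayer_field <- function(truth) {
  stopifnot(inherits(truth, "mt_cell_truth"))
  n <- truth$n_cells
  ncol_grid <- ceiling(sqrt(n))
  nrow_grid <- ceiling(n / ncol_grid)
  sp <- truth$spacing
  size <- c(nrow_grid * sp + sp, ncol_grid * sp + sp)
  mt_with_seed(truth$seed, {
    idx <- seq_len(n) - 1L
    gx <- (idx %% ncol_grid) + 1L
    gy <- (idx %/% ncol_grid) + 1L
    jx <- sample(-truth$jitter:truth$jitter, n, replace = TRUE)
    jy <- sample(-truth$jitter:truth$jitter, n, replace = TRUE)
    x <- gx * sp + jx
    y <- gy * sp + jy
    state_nuc <- stats::runif(n) < truth$p_on[1]
    state_cyt <- stats::runif(n) < truth$p_on[2]
    z1 <- stats::rnorm(n)
    z2 <- truth$rho * z1 + sqrt(1 - truth$rho^2) * stats::rnorm(n)
    lognorm <- function(state, z) {
      mu <- ifelse(state, truth$mean_on, truth$mean_off)
      # quantized to the 16-bit grid: the truth table states exactly what
      # is rendered, so zero-noise quantification recovers it exactly
      pmin(round(mu * exp(truth$sigma_log * z - truth$sigma_log^2 / 2)),
           65535)
    }
    int_nuc <- lognorm(state_nuc, z1)
    int_cyt <- lognorm(state_cyt, z2)
    cell_lab <- matrix(0L, size[1], size[2])
    nuc_lab <- matrix(0L, size[1], size[2])
    disk_cell <- mt_disk_offsets(truth$cell_radius)
    disk_nuc <- mt_disk_offsets(truth$nucleus_radius)
    img <- array(truth$background, dim = c(size, 2L),
                 dimnames = list(NULL, NULL, c("nuclear", "cyto")))
    for (k in seq_len(n)) {
      cc <- cbind(y[k] + disk_cell$dy, x[k] + disk_cell$dx)
      nn <- cbind(y[k] + disk_nuc$dy, x[k] + disk_nuc$dx)
      cell_lab[cc] <- k
      nuc_lab[nn] <- k
      img[cbind(cc, 2L)] <- int_cyt[k]
      img[cbind(nn, 1L)] <- int_nuc[k]
    }
    if (truth$noise_sd > 0)
      img <- img + array(stats::rnorm(length(img), sd = truth$noise_sd),
                         dim = dim(img))
    img <- pmin(pmax(round(img), 0), 65535)
    dimnames(img) <- list(NULL, NULL, c("nuclear", "cyto"))
    cells <- data.frame(
      cell = seq_len(n), x = x, y = y,
      state_nuclear = ifelse(state_nuc, "ON", "OFF"),
      state_cyto = ifelse(state_cyt, "ON", "OFF"),
      intensity_nuclear = int_nuc, intensity_cyto = int_cyt,
      stringsAsFactors = FALSE
    )
    list(image = img, cells = cells,
         masks = list(cell = cell_lab, nucleus = nuc_lab), truth = truth)
  })
}

#' Write / read a multichannel image as 16-bit multi-page TIFF
#'
#' Channels are stored as successive TIFF pages at 16-bit depth. Integer
#' intensities on the 0..65535 scale (as produced by the generators)
#' round-trip without loss.
#'
#' @param image rows x cols x channels numeric array, values in 0..65535.
#' @param path file path.
#' @return `write_image()`: `path`, invisibly. `read_image()`: the image
#'   array.
#' @export
write_image <- function(image, path) {
  if (length(dim(image)) == 2L) image <- array(image, dim = c(dim(image), 1))
  stopifnot(length(dim(image)) == 3L)
  if (min(image) < 0 || max(image) > 65535)
    stop("intensities must lie in [0, 65535]", call. = FALSE)
  pages <- lapply(seq_len(dim(image)[3]),
                  function(ch) image[, , ch] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  img <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (ch in seq_along(pages)) img[, , ch] <- round(pages[[ch]] * 65535)
  img
}
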