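# Quantification of ring-structured and monolayer images: radial linescans,
# compartment means, per-cell intensities, and model/image concordance.

mt_as_image <- function(image) {
  if (length(dim(image)) == 2L) image <- array(image, dim = c(dim(image), 1))
  if (length(dim(image)) != 3L)
    stop("image must be a rows x cols x channels array", call. = FALSE)
  image
}

#' Radial linescan profile of a multichannel image
#'
#' Casts `n_lines` rays from the center at equal angular spacing (starting
#' at `start_angle`), samples intensities by nearest-pixel lookup every
#' `step` pixels along each ray, bins samples by radial distance into
#' `n_bins` equal-width bins covering `(0, radius]`, and averages within
#' each bin across all rays.
#'
#' @param image rows x cols x channels array (or a matrix).
#' @param center ray origin `(x, y)` in pixels; must lie inside the image.
#' @param radius maximum sampled radius in pixels; rays must stay inside
#'   the image.
#' @param n_lines number of rays (>= 1; default 9).
#' @param n_bins number of radial bins.
#' @param start_angle angle of the first ray, radians.
#' @param step sampling step along each ray, pixels.
#' @return Object of class `mt_linescan`: list with `profile` (data frame:
#'   `bin`, `r_mid`, one mean-intensity column per channel) and `n_lines`.
#' @export
radial_linescans <- function(image, center = NULL, radius = NULL,
                             n_lines = 9, n_bins = 50, start_angle = 0,
                             step = 0.5) {
  image <- mt_as_image(image)
  h <- dim(image)[1]; w <- dim(image)[2]; n_ch <- dim(image)[3]
  if (is.null(center)) center <- c((w + 1) / 2, (h + 1) / 2)
  if (center[1] < 1 || center[1] > w || center[2] < 1 || center[2] > h)
    stop("center must lie inside the image", call. = FALSE)
  if (is.null(radius))
    radius <- floor(min(center[1] - 1, w - center[1],
                        center[2] - 1, h - center[2]))
  if (n_lines < 1) stop("n_lines must be >= 1", call. = FALSE)
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  angles <- start_angle + 2 * pi * (seq_len(n_lines) - 1) / n_lines
  rs <- seq(step, radius, by = step)
  px <- round(outer(cos(angles), rs) + center[1])   # n_lines x n_r
  py <- round(outer(sin(angles), rs) + center[2])
  if (min(px) < 1 || max(px) > w || min(py) < 1 || max(py) > h)
    stop("rays leave the image; reduce radius", call. = FALSE)
  bin <- matrix(pmin(ceiling(rs / (radius / n_bins)), n_bins),
                nrow = n_lines, ncol = length(rs), byrow = TRUE)
  prof <- data.frame(bin = seq_len(n_bins),
                     r_mid = (seq_len(n_bins) - 0.5) * radius / n_bins)
  ch_names <- dimnames(image)[[3]]
  if (is.null(ch_names)) ch_names <- paste0("ch", seq_len(n_ch))
  for (ch in seq_len(n_ch)) {
    plane <- image[, , ch]
    vals <- plane[cbind(as.vector(py), as.vector(px))]
    means <- tapply(vals, factor(as.vector(bin), levels = seq_len(n_bins)),
                    mean)
    prof[[ch_names[ch]]] <- as.numeric(means)
  }
  structure(list(profile = prof, n_lines = n_lines, radius = radius,
                 center = center),
            class = "mt_linescan")
}

#' Mean intensity per microtumor compartment
#'
#' Splits the tumor disk into core (`r <= b1 * R`), inner annulus
#' (`b1 * R < r <= b2 * R`) and outer annulus (`b2 * R < r <= R`) pixel
#' masks — the same assignment rule the synthetic generator uses — and
#' reports the per-channel mean intensity and pixel count of each
#' compartment.
#'
#' @param image rows x cols x channels array (or a matrix).
#' @param center disk center `(x, y)` in pixels.
#' @param radius tumor radius in pixels; the disk must fit in the image.
#' @param boundaries radius fractions (core|inner, inner|outer), strictly
#'   increasing in (0, 1).
#' @return Object of class `mt_compartment_means`: list with `means`
#'   (channels x compartments matrix, columns `o`, `i`, `c`) and
#'   `pixel_counts`.
#' @export
compartment_means <- function(image, center = NULL, radius = NULL,
                              boundaries = c(0.5, 0.75)) {
  image <- mt_as_image(image)
  h <- dim(image)[1]; w <- dim(image)[2]; n_ch <- dim(image)[3]
  if (is.null(center)) center <- c((w + 1) / 2, (h + 1) / 2)
  if (is.null(radius))
    radius <- floor(min(center[1] - 1, w - center[1],
                        center[2] - 1, h - center[2]))
  if (length(boundaries) != 2L || boundaries[1] <= 0 ||
      boundaries[2] >= 1 || boundaries[1] >= boundaries[2])
    stop("boundaries must be strictly increasing fractions in (0, 1)",
         call. = FALSE)
  if (center[1] - radius < 1 || center[1] + radius > w ||
      center[2] - radius < 1 || center[2] + radius > h)
    stop("tumor disk exceeds image bounds", call. = FALSE)
  r <- mt_radius_matrix(c(h, w), center)
  masks <- list(
    c = r <= boundaries[1] * radius,
    i = r > boundaries[1] * radius & r <= boundaries[2] * radius,
    o = r > boundaries[2] * radius & r <= radius
  )
  counts <- vapply(masks, sum, numeric(1))
  if (any(counts == 0)) stop("empty compartment mask", call. = FALSE)
  ch_names <- dimnames(image)[[3]]
  if (is.null(ch_names)) ch_names <- paste0("ch", seq_len(n_ch))
  means <- matrix(NA_real_, n_ch, 3,
                  dimnames = list(ch_names, c("o", "i", "c")))
  for (ch in seq_len(n_ch)) {
    plane <- image[, , ch]
    for (comp in c("o", "i", "c"))
      means[ch, comp] <- mean(plane[masks[[comp]]])
  }
  structure(list(means = means,
                 pixel_counts = counts[c("o", "i", "c")],
                 center = center, radius = radius,
                 boundaries = boundaries),
            class = "mt_compartment_means")
}

#' @export
print.mt_compartment_means <- function(x, ...) {
  cat("Compartment mean intensities (columns outer / inner / core)\n")
  print(round(x$means, 2))
  cat("pixel counts:", paste(sprintf("%s=%d", names(x$pixel_counts),
                                     x$pixel_counts), collapse = ", "), "\n")
  invisible(x)
}

#' Per-cell two-channel intensities and their correlation
#'
#' Measures, for every labelled cell, the mean nuclear-channel intensity
#' over its nucleus mask and the mean cytoplasmic-channel intensity over its
#' whole-cell mask (masks come from the synthetic truth; no segmentation is
#' performed), and summarises the across-cell linear correlation of the two
#' with a Fisher-z confidence interval. With fewer than 3 cells the
#' correlation is flagged undefined.
#'
#' @param image rows x cols x 2 array (channel 1 nuclear, channel 2
#'   cytoplasmic).
#' @param masks list with `cell` and `nucleus` integer label matrices
#'   (0 = background), as returned by [generate_monolayer_field()].
#' @param conf_level confidence level of the Fisher-z interval.
#' @return List of class `mt_cell_measurements` with `cells` (data frame:
#'   `cell`, `intensity_nuclear`, `intensity_cyto`) and `correlation`
#'   (list `r`, `conf_int`, `conf_level`, `n`, `defined`).
#' @export
per_cell_intensities <- function(image, masks, conf_level = 0.95) {
  image <- mt_as_image(image)
  if (dim(image)[3] < 2L)
    stop("need a nuclear and a cytoplasmic channel", call. = FALSE)
  if (!all(c("cell", "nucleus") %in% names(masks)))
    stop("masks must contain 'cell' and 'nucleus' label matrices",
         call. = FALSE)
  if (!all(dim(masks$cell) == dim(image)[1:2]))
    stop("mask dimensions must match the image", call. = FALSE)
  ids <- sort(unique(masks$cell[masks$cell > 0]))
  nuc_plane <- image[, , 1]
  cyt_plane <- image[, , 2]
  nuc_means <- tapply(nuc_plane[masks$nucleus > 0],
                      masks$nucleus[masks$nucleus > 0], mean)
  cyt_means <- tapply(cyt_plane[masks$cell > 0],
                      masks$cell[masks$cell > 0], mean)
  cells <- data.frame(
    cell = ids,
    intensity_nuclear = as.numeric(nuc_means[as.character(ids)]),
    intensity_cyto = as.numeric(cyt_means[as.character(ids)])
  )
  n <- nrow(cells)
  if (n >= 3L) {
    r <- stats::cor(cells$intensity_nuclear, cells$intensity_cyto)
    z <- atanh(r)
    half <- stats::qnorm(1 - (1 - conf_level) / 2) / sqrt(n - 3)
    correlation <- list(r = r, conf_int = tanh(c(z - half, z + half)),
                        conf_level = conf_level, n = n, defined = TRUE)
  } else {
    correlation <- list(r = NA_real_, conf_int = c(NA_real_, NA_real_),
                        conf_level = conf_level, n = n, defined = FALSE)
  }
  structure(list(cells = cells, correlation = correlation),
            class = "mt_cell_measurements")
}

#' Rank concordance between a model profile and image compartment means
#'
#' Normalizes the image compartment means of one channel to the outer
#' compartment and compares the ordering of the (o, i, c) triplet with a
#' model compartment profile: for each compartment pair the sign of the
#' difference must agree (ties within `tol` count as agreement). Discordant
#' pairs are reported together with the compartments involved.
#'
#' @param profile model prediction ([`mt_profile`][normalize_to_outer] or
#'   named numeric `(o, i, c)`).
#' @param means an [`mt_compartment_means`][compartment_means] object.
#' @param channel channel name or index of `means` to compare against.
#' @param tol relative tolerance under which a difference counts as a tie.
#' @return List with `concordant` (logical), `pairs` (data frame: pair,
#'   model and image signs, agreement) and `flagged` (compartments in
#'   discordant pairs).
#' @export
model_vs_image_check <- function(profile, means, channel = 1, tol = 1e-9) {
  v_model <- mt_profile_values(profile)
  stopifnot(inherits(means, "mt_compartment_means"))
  m <- means$means[channel, ]
  if (!is.finite(m[["o"]]) || m[["o"]] <= 0)
    stop("image outer-compartment mean is not positive; ",
         "normalization undefined", call. = FALSE)
  v_image <- m / m[["o"]]
  pair_sign <- function(v, a, b) {
    d <- v[[a]] - v[[b]]
    if (abs(d) <= tol * max(abs(v))) 0 else sign(d)
  }
  pairs <- data.frame(
    pair = c("o-i", "i-c", "o-c"),
    a = c("o", "i", "o"), b = c("i", "c", "c"),
    stringsAsFactors = FALSE
  )
  pairs$model_sign <- mapply(pair_sign, list(v_model), pairs$a, pairs$b)
  pairs$image_sign <- mapply(pair_sign, list(v_image), pairs$a, pairs$b)
  pairs$agree <- pairs$model_sign == pairs$image_sign
  flagged <- unique(unlist(pairs[!pairs$agree, c("a", "b")]))
  list(concordant = all(pairs$agree),
       pairs = pairs[, c("pair", "model_sign", "image_sign", "agree")],
       flagged = if (length(flagged)) flagged else character(0),
       image_normalized = v_image)
}
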