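# Seeded generators for imaging data: diffraction-limited droplet images
# (shape convolved with a Gaussian point-spread function) and AFM height maps
# (Gaussian grains over a polynomial background). Images carry physical pixel
# sizes; all outputs are in micrometres / nanometres, never pixels.

#' Fluorescence image container
#'
#' @param mat intensity matrix (rows = y, cols = x).
#' @param pixel_size_um micrometres per pixel.
#' @return object of class `bips_image`.
#' @export
bips_image <- function(mat, pixel_size_um) {
  stopifnot(is.matrix(mat), pixel_size_um > 0)
  structure(list(mat = mat, pixel_size_um = pixel_size_um),
            class = "bips_image")
}

#' AFM height map container
#'
#' @param mat heights in nm (rows = y, cols = x).
#' @param pixel_size_nm nm per pixel.
#' @return object of class `afm_heightmap`.
#' @export
afm_heightmap <- function(mat, pixel_size_nm) {
  stopifnot(is.matrix(mat), pixel_size_nm > 0)
  structure(list(mat = mat, pixel_size_nm = pixel_size_nm),
            class = "afm_heightmap")
}

blur_vec <- function(v, k, kr) {
  p <- c(rep(0, kr), v, rep(0, kr))
  f <- stats::filter(p, k, sides = 2)
  as.numeric(f[(kr + 1):(kr + length(v))])
}

# separable Gaussian blur, zero-padded borders
gauss_blur <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  kr <- max(1, ceiling(4 * sigma_px))
  k <- stats::dnorm(seq(-kr, kr), sd = sigma_px)
  k <- k / sum(k)
  m <- apply(m, 2, blur_vec, k = k, kr = kr)
  t(apply(m, 1, blur_vec, k = k, kr = kr))
}

# perimeter of an axis-aligned ellipse with semi-axes a, b (numeric
# elliptic-integral quadrature)
ellipse_perimeter <- function(a, b) {
  4 * stats::integrate(function(th) sqrt(a^2 * sin(th)^2 + b^2 * cos(th)^2),
                       0, pi / 2, rel.tol = 1e-10)$value
}

#' Synthetic diffraction-limited droplet image
#'
#' A filled circle or ellipse of uniform brightness convolved with a Gaussian
#' point-spread function, plus additive Gaussian noise. A radius below half a
#' pixel renders a point source (a pure Gaussian of SD `psf_sd`), whose
#' full width at 20% of maximum is `2 * psf_sd * sqrt(2 * log(5))` -- the
#' diffraction-limited reference spot.
#'
#' @param shape `"circle"` or `"ellipse"`.
#' @param radius_or_axes radius (circle) or semi-axes `c(a, b)` (ellipse), um.
#' @param peak plateau intensity of the unconvolved object, a.u.
#' @param psf_sd point-spread-function standard deviation, um.
#' @param pixel_size um per pixel (must resolve the PSF:
#'   `pixel_size < psf_sd`).
#' @param noise_sd additive Gaussian noise, a.u.
#' @param seed RNG seed.
#' @return list with `image` (a [bips_image()]) and `truth` (shape
#'   parameters, analytic circularity, point-source 20%-width).
#' @export
gen_droplet_image <- function(shape = c("circle", "ellipse"),
                              radius_or_axes = 0.5, peak = 1,
                              psf_sd = 0.159, pixel_size = 0.065,
                              noise_sd = 0, seed = 1) {
  shape <- match.arg(shape)
  stopifnot(pixel_size < psf_sd, peak > 0)
  set.seed(seed)
  axes <- if (shape == "circle") rep(radius_or_axes[1], 2) else {
    stopifnot(length(radius_or_axes) == 2)
    radius_or_axes
  }
  half_um <- max(axes) + 6 * psf_sd
  half_px <- ceiling(half_um / pixel_size)
  n <- 2 * half_px + 1
  centre <- half_px + 1

  if (max(axes) < pixel_size / 2) {
    xx <- (seq_len(n) - centre) * pixel_size
    g <- exp(-outer(xx^2, xx^2, "+") / (2 * psf_sd^2))
    img <- peak * g
    circ <- 1
  } else {
    ss <- 4                                  # supersampling factor
    fine_px <- pixel_size / ss
    nf <- n * ss
    xf <- (seq_len(nf) - (nf + 1) / 2) * fine_px
    ind <- outer(xf^2 / axes[2]^2, xf^2 / axes[1]^2, "+") <= 1  # rows=y uses b
    fine <- gauss_blur(peak * ind, psf_sd / fine_px)
    img <- matrix(0, n, n)
    for (i in seq_len(ss)) for (j in seq_len(ss))
      img <- img + fine[seq(i, nf, by = ss), seq(j, nf, by = ss)]
    img <- img / ss^2
    circ <- 4 * pi * (pi * axes[1] * axes[2]) /
      ellipse_perimeter(axes[1], axes[2])^2
  }
  if (noise_sd > 0) img <- img + matrix(rnorm(n * n, 0, noise_sd), n, n)

  list(
    image = bips_image(img, pixel_size),
    truth = list(shape = shape, axes_um = axes, peak = peak, psf_sd = psf_sd,
                 pixel_size = pixel_size, noise_sd = noise_sd, seed = seed,
                 circularity = circ,
                 point_fw20_um = 2 * psf_sd * sqrt(2 * log(5)))
  )
}

#' Synthetic AFM height map
#'
#' A sum of Gaussian bumps (protein grains) over a low-order polynomial
#' background plus Gaussian height noise. The analytic volume of each grain,
#' \eqn{2\pi h \sigma^2}, is recorded as ground truth.
#'
#' @param grains data.frame with columns `x_nm`, `y_nm`, `height_nm`,
#'   `sd_nm`; all grains must lie inside the field.
#' @param background_poly coefficients of the background over normalized
#'   field coordinates u, v in [0, 1]: `c(const, u, v)` or
#'   `c(const, u, v, u^2, u*v, v^2)`, nm.
#' @param noise_sd height noise SD, nm.
#' @param pixel_size_nm nm per pixel.
#' @param field_px field size in pixels `c(rows, cols)`.
#' @param seed RNG seed.
#' @return list with `map` (an [afm_heightmap()]) and `truth` (per-grain
#'   volumes in nm^3, background coefficients).
#' @export
gen_afm_heightmap <- function(grains = NULL, background_poly = 0,
                              noise_sd = 0.05, pixel_size_nm = 2,
                              field_px = c(256, 256), seed = 1) {
  set.seed(seed)
  nr <- field_px[1]; nc <- field_px[2]
  x <- (seq_len(nc) - 0.5) * pixel_size_nm
  y <- (seq_len(nr) - 0.5) * pixel_size_nm
  if (!is.null(grains) && nrow(grains) > 0) {
    stopifnot(all(c("x_nm", "y_nm", "height_nm", "sd_nm") %in% names(grains)))
    inside <- grains$x_nm > 3 * grains$sd_nm &
      grains$x_nm < max(x) - 3 * grains$sd_nm &
      grains$y_nm > 3 * grains$sd_nm &
      grains$y_nm < max(y) - 3 * grains$sd_nm
    if (!all(inside)) stop("gen_afm_heightmap: grain(s) ",
                           paste(which(!inside), collapse = ", "),
                           " not inside the field")
  }
  m <- matrix(0, nr, nc)
  u <- matrix(rep((x - min(x)) / diff(range(x)), each = nr), nr, nc)
  v <- matrix(rep((y - min(y)) / diff(range(y)), times = nc), nr, nc)
  cf <- c(background_poly, rep(0, 6 - length(background_poly)))
  m <- m + cf[1] + cf[2] * u + cf[3] * v + cf[4] * u^2 + cf[5] * u * v +
    cf[6] * v^2
  if (!is.null(grains)) {
    for (g in seq_len(nrow(grains))) {
      dx2 <- outer(rep(1, nr), (x - grains$x_nm[g])^2)
      dy2 <- outer((y - grains$y_nm[g])^2, rep(1, nc))
      m <- m + grains$height_nm[g] *
        exp(-(dx2 + dy2) / (2 * grains$sd_nm[g]^2))
    }
  }
  if (noise_sd > 0) m <- m + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
  vols <- if (is.null(grains) || nrow(grains) == 0) numeric(0) else
    2 * pi * grains$height_nm * grains$sd_nm^2
  list(
    map = afm_heightmap(m, pixel_size_nm),
    truth = list(grains = grains, grain_volumes_nm3 = vols,
                 background_poly = background_poly, noise_sd = noise_sd,
                 pixel_size_nm = pixel_size_nm, field_px = field_px,
                 seed = seed)
  )
}
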