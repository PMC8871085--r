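#' Specification of a synthetic head phantom
#'
#' Describes a paired non-contrast / contrast head CT phantom: an ellipsoidal
#' skull shell around brain soft tissue, iodine-filled vessel tubes present
#' only in the contrast volume, and metallic clip/coil implants present
#' identically in both volumes (implants are imaged in both scans, which is
#' why plain subtraction removes them). Default HU levels follow the ordering
#' metal > 3500 > bone > vessel > brain > air.
#'
#' @param shape `(slices, rows, cols)`; default `c(64, 128, 128)`.
#' @param spacing voxel spacing in mm; default `c(0.75, 0.5, 0.5)`.
#' @param hu_air,hu_brain,hu_bone,hu_vessel,hu_metal tissue HU levels;
#'   defaults -1000, 35, 1500, 400, 4000.
#' @param skull list: `semi_axes_frac` (ellipsoid semi-axes as fractions of
#'   the half-shape) and `inner_frac` (inner shell boundary as a fraction of
#'   the outer ellipsoid; the band between is bone).
#' @param vessels list of segments `list(from=, to=, radius=)` in voxel
#'   coordinates (slice, row, col); rasterized into brain tissue only.
#' @param implants list of implants: `list(type="clip", center=, size=)`
#'   (axis-aligned box, size in voxels), `list(type="clip_diag", center=,
#'   length=, n_slices=)` (1-voxel-wide oblique blade along the row/col
#'   diagonal) or `list(type="coil", center=, radius=, fill=)` (ball of
#'   scattered voxels).
#' @param noise_sigma_hu SD of i.i.d. Gaussian HU noise added independently
#'   to each volume (two scans, two realizations); default 0.
#' @param misregistration_shift integer voxel shift applied to the contrast
#'   volume (air fill at the trailing edge); default `c(0, 0, 0)`.
#' @param seed RNG seed; all phantom randomness flows from it.
#' @return List of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 128, 128),
                         spacing = c(0.75, 0.5, 0.5),
                         hu_air = -1000, hu_brain = 35, hu_bone = 1500,
                         hu_vessel = 400, hu_metal = 4000,
                         skull = list(semi_axes_frac = c(0.90, 0.84, 0.84),
                                      inner_frac = 0.85),
                         vessels = list(),
                         implants = list(),
                         noise_sigma_hu = 0,
                         misregistration_shift = c(0, 0, 0),
                         seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L))
    stop_input("phantom_spec: shape must be 3 dims, each >= 8")
  if (!(hu_metal > 3500 && 3500 > hu_bone && hu_bone > hu_vessel &&
        hu_vessel > hu_brain && hu_brain > hu_air))
    stop_input("phantom_spec: HU ordering metal > 3500 > bone > vessel > brain > air violated")
  if (noise_sigma_hu < 0) stop_input("phantom_spec: noise_sigma_hu must be >= 0")
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 hu_air = hu_air, hu_brain = hu_brain, hu_bone = hu_bone,
                 hu_vessel = hu_vessel, hu_metal = hu_metal,
                 skull = skull, vessels = vessels, implants = implants,
                 noise_sigma_hu = noise_sigma_hu,
                 misregistration_shift = as.integer(misregistration_shift),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# squared normalized ellipsoid radius for every voxel, as a 3D array
ellipsoid_rho2 <- function(shape, semi_axes) {
  ctr <- (shape + 1) / 2
  d1 <- ((seq_len(shape[1]) - ctr[1]) / semi_axes[1])^2
  d2 <- ((seq_len(shape[2]) - ctr[2]) / semi_axes[2])^2
  d3 <- ((seq_len(shape[3]) - ctr[3]) / semi_axes[3])^2
  outer(outer(d1, d2, `+`), d3, `+`)
}

# rasterize a tube segment: TRUE where distance to the segment <= radius,
# restricted to a padded bounding box for speed
rasterize_tube <- function(shape, from, to, radius) {
  mask <- array(FALSE, dim = shape)
  lo <- pmax(1L, floor(pmin(from, to) - radius))
  hi <- pmin(shape, ceiling(pmax(from, to) + radius))
  gs <- lo[1]:hi[1]; gr <- lo[2]:hi[2]; gc <- lo[3]:hi[3]
  g <- as.matrix(expand.grid(s = gs, r = gr, c = gc))
  v <- to - from
  vv <- sum(v * v)
  w <- sweep(g, 2, from)
  t <- if (vv == 0) rep(0, nrow(g)) else pmin(1, pmax(0, (w %*% v) / vv))
  proj <- outer(as.vector(t), v) # nearest point offset along the segment
  d2 <- rowSums((w - proj)^2)
  inside <- g[d2 <= radius^2, , drop = FALSE]
  if (nrow(inside) > 0L)
    mask[inside] <- TRUE
  mask
}

rasterize_implant <- function(shape, imp) {
  mask <- array(FALSE, dim = shape)
  check <- function(ix) {
    if (any(ix[, 1] < 1 | ix[, 1] > shape[1] |
            ix[, 2] < 1 | ix[, 2] > shape[2] |
            ix[, 3] < 1 | ix[, 3] > shape[3]))
      stop_input("phantom: implant extends outside the frame")
    ix
  }
  if (imp$type == "clip") {
    sz <- as.integer(imp$size); ctr <- as.integer(imp$center)
    rng <- lapply(1:3, function(a) ctr[a] - (sz[a] - 1L) %/% 2L + 0:(sz[a] - 1L))
    ix <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
    mask[check(ix)] <- TRUE
  } else if (imp$type == "clip_diag") {
    ctr <- as.integer(imp$center)
    len <- as.integer(imp$length)
    ns <- as.integer(imp$n_slices %||% 3L)
    off <- seq_len(len) - 1L - (len - 1L) %/% 2L
    sl <- ctr[1] - (ns - 1L) %/% 2L + 0:(ns - 1L)
    ix <- as.matrix(expand.grid(s = sl, i = off))
    ix <- cbind(ix[, 1], ctr[2] + ix[, 2], ctr[3] + ix[, 2])
    mask[check(ix)] <- TRUE
  } else if (imp$type == "coil") {
    ctr <- as.numeric(imp$center)
    rad <- as.numeric(imp$radius)
    fill <- imp$fill %||% 1
    lo <- pmax(1L, as.integer(floor(ctr - rad)))
    hi <- pmin(shape, as.integer(ceiling(ctr + rad)))
    if (any(floor(ctr - rad) < 1) || any(ceiling(ctr + rad) > shape))
      stop_input("phantom: implant extends outside the frame")
    g <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
    d2 <- rowSums(sweep(g, 2, ctr)^2)
    inside <- g[d2 <= rad^2, , drop = FALSE]
    if (fill < 1) # scattered windings: seeded dropout
      inside <- inside[stats::runif(nrow(inside)) < fill, , drop = FALSE]
    mask[inside] <- TRUE
  } else {
    stop_input("phantom: unknown implant type '%s'", imp$type)
  }
  mask
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# integer-voxel roll with fill (positive shift moves content toward higher
# indices; vacated voxels take `fill`)
roll_fill <- function(vox, shift, fill) {
  if (all(shift == 0L)) return(vox)
  d <- dim(vox)
  out <- array(fill, dim = d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    sh <- shift[a]
    if (abs(sh) >= d[a]) return(out)
    if (sh >= 0) { src[[a]] <- 1:(d[a] - sh); dst[[a]] <- (1 + sh):d[a] }
    else { src[[a]] <- (1 - sh):d[a]; dst[[a]] <- 1:(d[a] + sh) }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- vox[src[[1]], src[[2]], src[[3]]]
  out
}

#' Generate a paired non-contrast/contrast phantom with ground truth
#'
#' Deterministic given `spec$seed`. Rasterizes skull shell, brain interior,
#' vessel tubes (added to the contrast volume only: contrast = non-contrast +
#' `hu_vessel` on vessel voxels, before noise), and implants (identical in
#' both volumes). Independent Gaussian noise is then added to each volume,
#' and the configured integer misregistration shift is applied to the
#' contrast volume with air fill.
#'
#' @param spec a [phantom_spec()].
#' @return List of class `phantom_output`: `noncontrast`, `contrast`
#'   ([ct_volume()]s), `metal_truth`, `vessel_truth`, `bone_truth` (3D
#'   logical arrays), and the `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  shape <- spec$shape
  semi <- spec$skull$semi_axes_frac * (shape / 2)
  rho2 <- ellipsoid_rho2(shape, semi)
  inner2 <- spec$skull$inner_frac^2
  bone <- rho2 <= 1 & rho2 > inner2
  brain <- rho2 <= inner2

  metal <- array(FALSE, dim = shape)
  for (imp in spec$implants)
    metal <- metal | rasterize_implant(shape, imp)

  vessel <- array(FALSE, dim = shape)
  for (seg in spec$vessels)
    vessel <- vessel | rasterize_tube(shape, as.numeric(seg$from),
                                      as.numeric(seg$to), seg$radius)
  vessel <- vessel & brain & !metal   # iodine only inside soft tissue
  bone_truth <- bone & !metal         # implants may be requested inside the shell

  nc <- array(spec$hu_air, dim = shape)
  nc[brain] <- spec$hu_brain
  nc[bone_truth] <- spec$hu_bone
  nc[metal] <- spec$hu_metal
  co <- nc
  co[vessel] <- co[vessel] + spec$hu_vessel

  co <- roll_fill(co, spec$misregistration_shift, spec$hu_air)
  if (spec$noise_sigma_hu > 0) {
    nc <- nc + array(stats::rnorm(length(nc), 0, spec$noise_sigma_hu), dim = shape)
    co <- co + array(stats::rnorm(length(co), 0, spec$noise_sigma_hu), dim = shape)
  }
  structure(list(
    noncontrast = ct_volume(nc, spec$spacing, "phantom:noncontrast"),
    contrast = ct_volume(co, spec$spacing, "phantom:contrast"),
    metal_truth = metal, vessel_truth = vessel, bone_truth = bone_truth,
    spec = spec), class = "phantom_output")
}

#' Named phantom presets
#'
#' Fully populated [phantom_spec()]s for the scenarios the method is
#' exercised on:
#' \describe{
#'   \item{single_clip}{one 3x3x9-voxel clip blade deep in brain tissue (the
#'     most common implant pattern).}
#'   \item{two_clips}{two separated clip blades on overlapping slices.}
#'   \item{coil}{a compact ball of scattered high-HU voxels — the strong,
#'     narrow intensity cluster a coil produces.}
#'   \item{clip_near_bone}{a thin oblique blade whose bounding box straddles
#'     the inner skull boundary, so the Otsu region of interest contains a
#'     large bone fraction; running the pipeline segments bone together with
#'     the metal (the method's documented adjacency failure mode).}
#'   \item{misregistered}{the single-clip phantom with a 2-voxel shift of the
#'     contrast volume, leaving bone-edge residuals in the subtraction.}
#' }
#'
#' @param name preset name.
#' @param seed RNG seed forwarded to the spec.
#' @param noise_sigma_hu Gaussian noise SD in HU (default 0).
#' @return A [phantom_spec()].
#' @export
phantom_preset <- function(name = c("single_clip", "two_clips", "coil",
                                    "clip_near_bone", "misregistered"),
                           seed = 1L, noise_sigma_hu = 0) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("single_clip", "two_clips", "coil", "clip_near_bone",
                   "misregistered"))
    stop_input("phantom_preset: unknown preset '%s'",
               paste(as.character(name), collapse = ","))
  vessels <- list(
    list(from = c(8, 64, 64), to = c(56, 64, 64), radius = 2),
    list(from = c(32, 48, 44), to = c(32, 80, 84), radius = 2))
  base <- function(implants, shift = c(0, 0, 0))
    phantom_spec(vessels = vessels, implants = implants,
                 noise_sigma_hu = noise_sigma_hu,
                 misregistration_shift = shift, seed = seed)
  single <- list(list(type = "clip", center = c(32, 56, 70), size = c(3, 3, 9)))
  switch(name,
    single_clip = base(single),
    two_clips = base(list(
      list(type = "clip", center = c(31, 52, 46), size = c(3, 3, 9)),
      list(type = "clip", center = c(31, 84, 64), size = c(3, 3, 9)))),
    coil = base(list(
      list(type = "coil", center = c(32, 60, 58), radius = 4, fill = 0.75))),
    clip_near_bone = base(list(
      # oblique 1-voxel-wide blade whose tip enters the skull shell (inner
      # boundary sits near row 110 at the default shape): the bounding box
      # straddles the bone boundary, the ROI is bone-rich, and Otsu merges
      # bone into the metal class
      list(type = "clip_diag", center = c(32, 108, 64), length = 9,
           n_slices = 3))),
    misregistered = base(single, shift = c(0, 2, 0)))
}

#' Degrade an image or volume with noise or streak artifacts
#'
#' `gaussian_noise` adds seeded i.i.d. HU noise of SD `params$sd`. `streak`
#' adds `params$n_rays` radial lines of amplitude `params$amplitude` HU
#' through `params$center` (row, col) — a parametric stand-in for
#' beam-hardening streaks, not a physics model.
#'
#' @param x matrix (slice) or 3D array / [ct_volume()].
#' @param kind `"gaussian_noise"` or `"streak"`.
#' @param params list of parameters (see above).
#' @param seed RNG seed.
#' @return Degraded copy, same class/shape as the input.
#' @export
degrade <- function(x, kind = c("gaussian_noise", "streak"),
                    params = list(), seed = 1L) {
  kind <- match.arg(kind)
  is_vol <- inherits(x, "ct_volume")
  v <- if (is_vol) x$voxels else x
  if (kind == "gaussian_noise") {
    sd <- params$sd %||% 20
    if (sd < 0) stop_input("degrade: sd must be >= 0")
    if (sd > 0) {
      set.seed(seed)
      v <- v + array(stats::rnorm(length(v), 0, sd), dim = dim(v) %||% length(v))
    }
  } else {
    amp <- params$amplitude %||% 150
    n_rays <- params$n_rays %||% 16
    ctr <- params$center
    if (is.null(ctr)) stop_input("degrade: streak needs params$center (row, col)")
    add_streaks <- function(m) {
      nr <- nrow(m); nc <- ncol(m)
      rmax <- sqrt(nr^2 + nc^2)
      for (th in seq(0, pi, length.out = n_rays + 1L)[-(n_rays + 1L)]) {
        t <- seq(-rmax, rmax, by = 0.5)
        rr <- round(ctr[1] + t * cos(th)); cc <- round(ctr[2] + t * sin(th))
        ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
        ix <- unique(cbind(rr[ok], cc[ok]))
        m[ix] <- m[ix] + amp
      }
      m
    }
    if (length(dim(v)) == 3L) {
      for (i in seq_len(dim(v)[1])) v[i, , ] <- add_streaks(v[i, , ])
    } else v <- add_streaks(v)
  }
  if (is_vol) ct_volume(v, x$spacing, paste0(x$origin_note, "+", kind)) else v
}
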