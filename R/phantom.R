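#' Synthetic walnut phantom specification
#'
#' Parameters of one synthetic nut: a (possibly bumpy) ellipsoidal shell of
#' constant radial thickness around an air cavity containing a two-lobed
#' kernel. Greyscale levels mimic the four-cluster CT histogram (air < foam <
#' kernel < shell); the cavity deliberately shares the exterior air level, so
#' empty space can only be recovered geometrically (by enclosure), exactly as
#' in real scans. Defaults reproduce a typical nut of the reference
#' population: semi-axes 19.2 x 16.1 x 16.6 mm (L 38.4, F 32.3, P 33.3 mm),
#' shell 1.0 mm, kernel filling 30%, noise about 3% of the shell-air
#' contrast.
#'
#' @param outer_radii_mm three semi-axes of the base ellipsoid, mm.
#' @param shell_thickness_mm radial shell thickness, mm
#'   (< min(outer_radii_mm)).
#' @param bump_amplitude_mm amplitude of the band-limited surface
#'   perturbation, mm (0 = smooth ellipsoid).
#' @param bump_frequency angular frequency scale of the perturbation.
#' @param kernel_fill_target kernel volume as a fraction of nut volume, in
#'   (0, 1).
#' @param intensity_levels named greyscale means `c(air, foam, kernel,
#'   shell)`, strictly ascending.
#' @param noise_sigma standard deviation of the additive Gaussian noise.
#' @param seed integer seed driving the bump field and the noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(outer_radii_mm = c(19.2, 16.1, 16.6),
                         shell_thickness_mm = 1.0,
                         bump_amplitude_mm = 0.5,
                         bump_frequency = 4,
                         kernel_fill_target = 0.30,
                         intensity_levels = c(air = 0, foam = 25,
                                              kernel = 90, shell = 160),
                         noise_sigma = 5,
                         seed = 1L) {
  stopifnot(length(outer_radii_mm) == 3, all(outer_radii_mm > 0),
            shell_thickness_mm > 0,
            shell_thickness_mm < min(outer_radii_mm),
            bump_amplitude_mm >= 0, bump_frequency > 0,
            kernel_fill_target > 0, kernel_fill_target < 1,
            length(intensity_levels) == 4, noise_sigma >= 0)
  if (any(diff(intensity_levels) <= 0))
    stop("intensity_levels must be strictly ascending: air < foam < kernel < shell")
  names(intensity_levels) <- c("air", "foam", "kernel", "shell")
  structure(list(outer_radii_mm = as.numeric(outer_radii_mm),
                 shell_thickness_mm = shell_thickness_mm,
                 bump_amplitude_mm = bump_amplitude_mm,
                 bump_frequency = bump_frequency,
                 kernel_fill_target = kernel_fill_target,
                 intensity_levels = intensity_levels,
                 noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# ---- radial geometry --------------------------------------------------------
# A nut is described by a directional outer-radius function
#   R(u) = r_ell(u) + amplitude * B(u)
# where r_ell is the ellipsoid radius along unit direction u and B is a
# smooth band-limited angular field (sum of a few cosine harmonics with
# seed-derived orientations, frequencies and phases, normalised to max 1).
# The shell is the radial band (R - t, R], the cavity everything inside
# R - t. The kernel is the soft-union (log-sum-exp blend) of two ellipsoidal
# lobes scaled by a single factor s, clipped to the cavity with a clearance;
# the whole lobe geometry scales linearly with s, so the kernel fill fraction
# is monotone in s and can be solved by bisection.

make_bump_field <- function(spec) {
  if (spec$bump_amplitude_mm == 0) return(NULL)
  with_seed(spec$seed, {
    J <- 6L
    v <- matrix(stats::rnorm(3 * J), J, 3)
    v <- v / sqrt(rowSums(v^2))
    f <- spec$bump_frequency * stats::runif(J, 0.7, 1.3)
    ph <- stats::runif(J, 0, 2 * pi)
    cf <- stats::runif(J, 0.5, 1)
    field <- list(v = v, f = f, ph = ph, cf = cf, norm = 1)
    u <- fibonacci_sphere(5000L)
    field$norm <- max(abs(eval_bump(field, u)))
    field
  })
}

eval_bump <- function(field, u) {
  acc <- 0
  for (j in seq_along(field$f)) {
    acc <- acc + field$cf[j] *
      cos(field$f[j] * pi * (u %*% field$v[j, ]) + field$ph[j])
  }
  as.vector(acc) / field$norm
}

nut_geometry <- function(spec, kernel = NULL) {
  list(a = spec$outer_radii_mm, t = spec$shell_thickness_mm,
       amp = spec$bump_amplitude_mm, bump = make_bump_field(spec),
       kernel = kernel)
}

# Mean normal thickness of the radial-offset shell. The generator offsets
# the outer surface radially by t, so where the surface is inclined to the
# radial direction the true wall thickness is t * cos(theta), with theta the
# angle between the radial and the surface normal. The ground-truth value
# for the inscribed-sphere thickness measure is therefore the volume-weighted
# mean of t * cos(theta) over the shell: t * sum(R^2) / sum(R^2 / cos(theta)),
# evaluated by quasi-uniform direction sampling with a numerical angular
# gradient of the radius function.
shell_mean_thickness <- function(geom) {
  u <- fibonacci_sphere(20000L)
  R0 <- outer_radius(geom, u)
  a <- ifelse(abs(u[, 1]) < 0.9, 1, 0)
  av <- cbind(a, 1 - a, 0)
  e1 <- av - rowSums(av * u) * u
  e1 <- e1 / sqrt(rowSums(e1^2))
  e2 <- cbind(u[, 2] * e1[, 3] - u[, 3] * e1[, 2],
              u[, 3] * e1[, 1] - u[, 1] * e1[, 3],
              u[, 1] * e1[, 2] - u[, 2] * e1[, 1])
  eps <- 1e-4
  dr <- function(e) {
    up <- u + eps * e; up <- up / sqrt(rowSums(up^2))
    um <- u - eps * e; um <- um / sqrt(rowSums(um^2))
    (outer_radius(geom, up) - outer_radius(geom, um)) / (2 * eps)
  }
  g2 <- dr(e1)^2 + dr(e2)^2
  cost <- 1 / sqrt(1 + g2 / R0^2)
  geom$t * sum(R0^2) / sum(R0^2 / cost)
}

# outer radius along unit directions (n x 3 matrix)
outer_radius <- function(geom, u) {
  w <- (u[, 1] / geom$a[1])^2 + (u[, 2] / geom$a[2])^2 +
       (u[, 3] / geom$a[3])^2
  r <- 1 / sqrt(w)
  if (!is.null(geom$bump)) r <- r + geom$amp * eval_bump(geom$bump, u)
  r
}

# kernel membership for points q (n x 3, nut frame); soft two-lobe union
kernel_inside <- function(kern, q) {
  if (kern$type == "sphere")
    return(rowSums(q^2) <= kern$radius^2)
  s <- kern$s
  la <- s * kern$la
  f <- function(cx) {
    1 - ((q[, 1] - cx) / la[1])^2 - (q[, 2] / la[2])^2 - (q[, 3] / la[3])^2
  }
  f1 <- f(s * kern$off)
  f2 <- f(-s * kern$off)
  hi <- pmax(f1, f2)
  soft <- hi + log1p(exp(-kern$beta * abs(f1 - f2))) / kern$beta
  soft >= 0
}

# classify points q (n x 3, mm, nut frame): 0 bg, 1 shell, 2 kernel, 3 empty
classify_points <- function(geom, q) {
  r <- sqrt(rowSums(q^2))
  u <- q / pmax(r, 1e-12)
  u[r < 1e-12, ] <- rep(c(1, 0, 0), each = sum(r < 1e-12))
  Ro <- outer_radius(geom, u)
  part <- integer(nrow(q))
  solid <- r <= Ro
  shell <- solid & r > Ro - geom$t
  cavity <- solid & !shell
  part[cavity] <- 3L
  part[shell] <- 1L
  if (!is.null(geom$kernel) && any(cavity)) {
    clearance <- geom$kernel$clearance %||% 0
    clear <- r <= Ro - geom$t - clearance
    cand <- cavity & clear
    if (any(cand)) {
      kin <- kernel_inside(geom$kernel, q[cand, , drop = FALSE])
      idx <- which(cand)[kin]
      part[idx] <- 2L
    }
  }
  part
}

# render a nut's part labels on a grid; rot rotates the nut in the lab frame
render_nut <- function(geom, dims, center_vox, voxel_size_mm, rot = NULL) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  part <- array(0L, dims)
  px <- ((0:(nx - 1)) - center_vox[1]) * voxel_size_mm
  py <- ((0:(ny - 1)) - center_vox[2]) * voxel_size_mm
  gx <- rep(px, times = ny)
  gy <- rep(py, each = nx)
  for (k in seq_len(nz)) {
    pz <- (k - 1 - center_vox[3]) * voxel_size_mm
    q <- cbind(gx, gy, pz)
    if (!is.null(rot)) q <- q %*% rot
    part[, , k] <- classify_points(geom, q)
  }
  part
}

# solve the lobe scale s so that kernel fill hits the target (fraction of
# solid voxels); cav_q are cavity-clearance voxel coordinates in the nut frame
solve_kernel_scale <- function(kern, cav_q, n_solid, target, tol = 0.005) {
  fill <- function(s) {
    k <- kern; k$s <- s
    sum(kernel_inside(k, cav_q)) / n_solid
  }
  hi <- 3
  fhi <- fill(hi)
  if (fhi < target - 0.01)
    stop("kernel fill target ", target, " unreachable: lobes would breach ",
         "the shell (max attainable ", round(fhi, 3), ")")
  lo <- 0.05
  if (fill(lo) >= target) return(lo)
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    fm <- fill(mid)
    if (abs(fm - target) <= tol) return(mid)
    if (fm < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

phantom_intensities <- function(part, levels, foam = FALSE) {
  vol <- array(if (foam) levels[["foam"]] else levels[["air"]], dim(part))
  vol[part == 3L] <- levels[["air"]]     # cavity shares the exterior air level
  vol[part == 2L] <- levels[["kernel"]]
  vol[part == 1L] <- levels[["shell"]]
  vol
}

add_noise <- function(vol, sigma, seed) {
  if (sigma <= 0) return(vol)
  vol + with_seed(seed, array(stats::rnorm(length(vol), 0, sigma), dim(vol)))
}

new_phantom_truth <- function(traits, part_map, spec, center_vox) {
  structure(list(traits = traits, part_map = part_map, spec = spec,
                 center_vox = center_vox),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("<phantom_truth>\n")
  tr <- unlist(x$traits)
  cat(paste0("  ", names(tr), " = ", signif(tr, 6), collapse = "\n"), "\n")
  invisible(x)
}

#' Spherical nut phantom with closed-form ground truth
#'
#' The simplest phantom: a spherical shell of outer radius `r`, thickness
#' `t`, and a concentric spherical kernel, digitised at `voxel_size_mm`.
#' Every trait has a closed form (volumes of spheres/annuli, area 4 pi r^2,
#' sphericity = rugosity = VA3D = Feret shape = 1, thickness = t), which
#' makes this the primary fixture for validating the measurement chain.
#'
#' @param outer_radius_mm outer radius, mm.
#' @param shell_thickness_mm shell thickness, mm.
#' @param kernel_radius_mm kernel radius, mm
#'   (< outer_radius_mm - shell_thickness_mm).
#' @param voxel_size_mm grid resolution, mm.
#' @param intensity_levels,noise_sigma,seed see [phantom_spec()].
#' @param margin_mm air margin around the nut.
#' @return A list with `volume` (a [volume3d()]) and `truth` (a
#'   `phantom_truth`: closed-form trait values plus the ground-truth
#'   [part_label_map()]).
#' @export
make_spherical_nut <- function(outer_radius_mm, shell_thickness_mm,
                               kernel_radius_mm, voxel_size_mm = 0.1,
                               intensity_levels = c(air = 0, foam = 25,
                                                    kernel = 90, shell = 160),
                               noise_sigma = 0, seed = 1L, margin_mm = 1.5) {
  r <- outer_radius_mm; t <- shell_thickness_mm; rk <- kernel_radius_mm
  if (rk >= r - t)
    stop("kernel_radius_mm must be smaller than outer radius minus shell thickness")
  if (t >= r) stop("shell thicker than the nut radius")
  spec <- phantom_spec(outer_radii_mm = rep(r, 3), shell_thickness_mm = t,
                       bump_amplitude_mm = 0, kernel_fill_target = 0.5,
                       intensity_levels = intensity_levels,
                       noise_sigma = noise_sigma, seed = seed)
  geom <- nut_geometry(spec, kernel = list(type = "sphere", radius = rk))
  n <- 2L * as.integer(ceiling((r + margin_mm) / voxel_size_mm)) + 1L
  dims <- c(n, n, n)
  ctr <- rep((n - 1) / 2, 3)
  part <- render_nut(geom, dims, ctr, voxel_size_mm)
  vol <- phantom_intensities(part, intensity_levels, foam = FALSE)
  vol <- add_noise(vol, noise_sigma, seed)
  rin <- r - t
  Vn <- 4 / 3 * pi * r^3
  Vs <- 4 / 3 * pi * (r^3 - rin^3)
  Vk <- 4 / 3 * pi * rk^3
  traits <- list(L_mm = 2 * r, F_mm = 2 * r, P_mm = 2 * r, Vn_mm3 = Vn,
                 VA3D = 1, Feret3D = 1, A_mm2 = 4 * pi * r^2, Sphericity = 1,
                 Vs_mm3 = Vs, T_mm = t, Rugosity = 1, Vk_mm3 = Vk,
                 FillingRatio_pct = 100 * Vk / Vn, Ve_mm3 = Vn - Vs - Vk)
  list(volume = volume3d(vol, voxel_size_mm),
       truth = new_phantom_truth(traits,
                                 part_label_map(part, voxel_size_mm),
                                 spec, ctr))
}

#' Bumpy ellipsoidal nut phantom
#'
#' Generates a nut whose outer surface is an ellipsoid modulated by a smooth
#' band-limited angular bump field (deterministic from the seed), with a
#' constant-thickness shell obtained by inward radial offset and a two-lobed
#' kernel scaled to hit `kernel_fill_target` within half a percentage point.
#' Ground-truth traits are computed either by [oracle_traits()] on a grid
#' `oracle_factor` times finer than the working grid (`truth_method =
#' "oracle"`, required for bumpy surfaces) or, for `bump_amplitude_mm = 0`,
#' from the closed-form ellipsoid quantities (`truth_method = "analytic"`:
#' exact volumes, Legendre-elliptic surface area, axis extents, Feret shape
#' a/c). Shell thickness truth is the design thickness in both cases.
#'
#' @param spec a [phantom_spec()].
#' @param voxel_size_mm working grid resolution, mm.
#' @param truth_method "auto" (analytic when the surface is smooth, oracle
#'   otherwise), "oracle", "analytic", or "none" (skip truth traits; the
#'   ground-truth part map is still returned).
#' @param oracle_factor oracle grid refinement factor (>= 2).
#' @param margin_mm air margin around the nut.
#' @return A list with `volume` and `truth` as in [make_spherical_nut()].
#' @export
make_bumpy_nut <- function(spec, voxel_size_mm = 0.1,
                           truth_method = c("auto", "oracle", "analytic",
                                            "none"),
                           oracle_factor = 2L, margin_mm = 1.5) {
  stopifnot(inherits(spec, "phantom_spec"))
  truth_method <- match.arg(truth_method)
  if (truth_method == "auto")
    truth_method <- if (spec$bump_amplitude_mm == 0) "analytic" else "oracle"
  if (truth_method == "analytic" && spec$bump_amplitude_mm > 0)
    stop("analytic truth is only available for bump_amplitude_mm = 0")
  a <- spec$outer_radii_mm
  t <- spec$shell_thickness_mm
  kern <- list(type = "lobes", la = 0.62 * (a - t),
               off = 0.45 * 0.62 * (a[1] - t), s = 1, beta = 8,
               clearance = 0)
  geom <- nut_geometry(spec, kernel = kern)
  half <- a + spec$bump_amplitude_mm + margin_mm
  dims <- 2L * as.integer(ceiling(half / voxel_size_mm)) + 1L
  ctr <- (dims - 1) / 2

  # first pass: shell/cavity labels without the kernel, collecting the
  # cavity-clearance voxel coordinates used to solve the lobe scale
  geom_nok <- geom; geom_nok$kernel <- NULL
  part <- render_nut(geom_nok, dims, ctr, voxel_size_mm)
  n_solid <- sum(part > 0L)
  cav_idx <- which(part == 3L)
  cav_q <- (arrayInd(cav_idx, dims) - 1 -
              matrix(ctr, length(cav_idx), 3, byrow = TRUE)) * voxel_size_mm
  r <- sqrt(rowSums(cav_q^2))
  u <- cav_q / pmax(r, 1e-12)
  clear <- r <= outer_radius(geom, u) - t - kern$clearance
  kern$s <- solve_kernel_scale(kern, cav_q[clear, , drop = FALSE], n_solid,
                               spec$kernel_fill_target)
  geom$kernel <- kern
  kin <- kernel_inside(kern, cav_q[clear, , drop = FALSE])
  part[cav_idx[clear][kin]] <- 2L

  vol <- phantom_intensities(part, spec$intensity_levels, foam = FALSE)
  vol <- add_noise(vol, spec$noise_sigma, spec$seed)
  part_map <- part_label_map(part, voxel_size_mm)

  if (truth_method == "none") {
    traits <- NULL
  } else if (truth_method == "oracle") {
    fine_v <- voxel_size_mm / oracle_factor
    fdims <- 2L * as.integer(ceiling(half / fine_v)) + 1L
    fctr <- (fdims - 1) / 2
    fpart <- render_nut(geom, fdims, fctr, fine_v)
    traits <- oracle_traits(part_label_map(fpart, fine_v),
                            include_thickness = FALSE)
    traits$T_mm <- shell_mean_thickness(geom)
  } else {
    s <- sort(a, decreasing = TRUE)
    Vn <- 4 / 3 * pi * prod(a)
    A <- ellipsoid_surface_area(s[1], s[2], s[3])
    # cavity volume of the radial-offset shell, r <= r_ell(u) - t, by exact
    # radial integration over sampled solid angle (not an ellipsoid itself)
    uu <- fibonacci_sphere(20000L)
    Ru <- outer_radius(geom, uu)
    Vcav <- mean(pmax(Ru - t, 0)^3) * 4 * pi / 3
    vv <- voxel_size_mm^3
    cnt <- tabulate(part, 3L)
    traits <- list(L_mm = 2 * s[1], F_mm = 2 * s[2], P_mm = 2 * s[3],
                   Vn_mm3 = Vn, VA3D = shape_va3d(Vn, A), Feret3D = s[1] / s[3],
                   A_mm2 = A, Sphericity = sphericity(Vn, A),
                   Vs_mm3 = Vn - Vcav,
                   T_mm = shell_mean_thickness(geom),
                   Rugosity = rugosity(Vn, A), Vk_mm3 = cnt[2] * vv,
                   FillingRatio_pct = 100 * cnt[2] / sum(cnt),
                   Ve_mm3 = Vcav - cnt[2] * vv)
  }
  list(volume = volume3d(vol, voxel_size_mm),
       truth = new_phantom_truth(traits, part_map, spec, ctr))
}

#' Brute-force trait oracle on a ground-truth part map
#'
#' Independent reference measurements used to validate the pipeline:
#' volumes by voxel counting; surface area by the coarea integral of a
#' smoothed indicator (a different estimator than the marching-tetrahedra
#' mesh used by [surface_area()]); Feret diameters by exhaustive sampling
#' of 20,000+ directions over support-extracted hull vertices; thickness by
#' the inscribed-sphere transform; derived indices from the oracle (Vn, A).
#'
#' @param partmap a ground-truth [part_label_map()], ideally at >= 2x the
#'   working resolution.
#' @param n_directions Feret direction count (>= 20000 recommended).
#' @param include_thickness compute the (expensive) inscribed-sphere shell
#'   thickness; when `FALSE`, `T_mm` is `NA` and the caller supplies it.
#' @return Named list of the fourteen trait values.
#' @export
oracle_traits <- function(partmap, n_directions = 20000L,
                          include_thickness = TRUE) {
  stopifnot(inherits(partmap, "nut_parts"))
  vs <- partmap$voxel_size_mm
  d <- grid_dims(partmap)
  vols <- part_volumes(partmap)
  solid <- partmap$data > 0L

  pad <- 7L
  arr <- pad_array(solid, pad)
  f <- cpp_gauss3d(as.numeric(arr), dim(arr), 1.5)
  A <- cpp_coarea(f, dim(arr)) * vs^2

  bpts <- voxel_coords_mm(boundary_voxels(solid), vs)
  ev <- eigen(stats::cov(bpts), symmetric = TRUE)
  proj <- bpts %*% ev$vectors
  extents <- apply(proj, 2, function(p) diff(range(p))) + vs

  verts <- bpts[sort(unique(as.vector(
    cpp_support_extremes(bpts, fibonacci_sphere(2562L))))), , drop = FALSE]
  dirs <- fibonacci_hemisphere(as.integer(n_directions))
  w <- cpp_feret_widths(verts, dirs)
  dmin <- min(w)
  u <- dirs[which.min(w), ]
  D <- max(cpp_feret_widths(verts, orthogonal_circle(u, 2880L)))

  T_mm <- NA_real_
  if (include_thickness) {
    shell <- partmap$data == 1L
    if (any(shell)) {
      th <- cpp_local_thickness(as.vector(shell), d)
      T_mm <- mean(th[as.vector(shell)]) * vs
    }
  }
  Vn <- vols[["Vn"]]
  list(L_mm = extents[1], F_mm = extents[2], P_mm = extents[3],
       Vn_mm3 = Vn, VA3D = shape_va3d(Vn, A), Feret3D = D / dmin,
       A_mm2 = A, Sphericity = sphericity(Vn, A), Vs_mm3 = vols[["Vs"]],
       T_mm = T_mm, Rugosity = rugosity(Vn, A), Vk_mm3 = vols[["Vk"]],
       FillingRatio_pct = 100 * vols[["Vk"]] / Vn, Ve_mm3 = vols[["Ve"]])
}

#' Exact surface area of a triaxial ellipsoid
#'
#' Legendre form evaluated with Carlson symmetric elliptic integrals;
#' reduces to 4 pi r^2 for a sphere.
#'
#' @param a,b,c semi-axes with a >= b >= c > 0.
#' @return Surface area.
#' @export
ellipsoid_surface_area <- function(a, b, c) {
  stopifnot(a >= b, b >= c, c > 0)
  if ((a - c) / a < 1e-8) return(4 * pi * ((a * b + a * c + b * c) / 3))
  phi <- acos(c / a)
  k2 <- a^2 * (b^2 - c^2) / (b^2 * (a^2 - c^2))
  sp <- sin(phi); cp <- c / a
  x <- cp^2; y <- 1 - k2 * sp^2
  Fi <- sp * carlson_rf(x, y, 1)
  Ei <- Fi - k2 * sp^3 * carlson_rd(x, y, 1) / 3
  2 * pi * c^2 + (2 * pi * a * b / sp) * (Ei * sp^2 + Fi * cp^2)
}

carlson_rf <- function(x, y, z) {
  for (i in 1:200) {
    lam <- sqrt(x) * sqrt(y) + sqrt(y) * sqrt(z) + sqrt(z) * sqrt(x)
    x <- (x + lam) / 4; y <- (y + lam) / 4; z <- (z + lam) / 4
    mu <- (x + y + z) / 3
    eps <- max(abs(1 - x / mu), abs(1 - y / mu), abs(1 - z / mu))
    if (eps < 1e-12) break
  }
  mu <- (x + y + z) / 3
  X <- 1 - x / mu; Y <- 1 - y / mu; Z <- 1 - z / mu
  E2 <- X * Y - Z^2; E3 <- X * Y * Z
  (1 - E2 / 10 + E3 / 14 + E2^2 / 24 - 3 * E2 * E3 / 44) / sqrt(mu)
}

carlson_rd <- function(x, y, z) {
  s <- 0; fac <- 1
  for (i in 1:200) {
    lam <- sqrt(x) * sqrt(y) + sqrt(y) * sqrt(z) + sqrt(z) * sqrt(x)
    s <- s + fac / (sqrt(z) * (z + lam))
    fac <- fac / 4
    x <- (x + lam) / 4; y <- (y + lam) / 4; z <- (z + lam) / 4
    mu <- (x + y + 3 * z) / 5
    eps <- max(abs(1 - x / mu), abs(1 - y / mu), abs(1 - z / mu))
    if (eps < 1e-12) break
  }
  mu <- (x + y + 3 * z) / 5
  X <- 1 - x / mu; Y <- 1 - y / mu; Z <- 1 - z / mu
  ea <- X * Y; eb <- Z * Z; ec <- ea - eb; ed <- ea - 6 * eb
  ee <- ed + 2 * ec
  3 * s + fac * (1 + ed * (-3 / 14 + 9 * ed / 88 - 4.5 * Z * ee / 26) +
                 Z * (ee / 6 + Z * (-9 * ec / 22 + 3 * Z * ea / 26))) /
    (mu * sqrt(mu))
}

#' Multi-nut scan phantom
#'
#' Emulates a batch scan: several nuts embedded in (optional) floral foam,
#' each with a random rotation, placed on a 3D grid, at random non-overlapping
#' positions, or deliberately as touching pairs (to exercise
#' [split_touching()]). Returns the noisy volume, the per-nut ground truths
#' and a ground-truth label map numbering the nuts' solid material (shell +
#' kernel) 1..n in placement order.
#'
#' @param n_nuts number of nuts.
#' @param specs a single [phantom_spec()] (recycled with per-nut seeds) or a
#'   list of `n_nuts` specs.
#' @param layout "grid", "random" or "touching".
#' @param foam fill the background with foam-level grey (`TRUE`) or air.
#' @param voxel_size_mm grid resolution, mm.
#' @param seed master seed for placement, rotations and noise.
#' @param gap_mm clearance between nut bounding spheres in grid layout.
#' @param max_retries placement retries for the random layout before erroring.
#' @return List with `volume`, `truths` (list of `phantom_truth`, part maps
#'   in local crop coordinates with a `bbox` attribute), and `label_map`.
#' @export
make_scan <- function(n_nuts, specs = NULL,
                      layout = c("grid", "random", "touching"),
                      foam = TRUE, voxel_size_mm = 0.25, seed = 1L,
                      gap_mm = 4, max_retries = 500L) {
  layout <- match.arg(layout)
  if (is.null(specs)) specs <- phantom_spec(seed = seed)
  if (inherits(specs, "phantom_spec")) {
    specs <- lapply(seq_len(n_nuts), function(i) {
      s <- specs; s$seed <- s$seed + i - 1L; s
    })
  }
  stopifnot(length(specs) == n_nuts)
  rb <- vapply(specs, function(s)
    max(s$outer_radii_mm) + s$bump_amplitude_mm, numeric(1))
  rmax <- max(rb)

  placement <- with_seed(seed, {
    rots <- lapply(seq_len(n_nuts), function(i) random_rotation())
    centers <- switch(layout,
      grid = {
        n1 <- ceiling(n_nuts^(1 / 3))
        n2 <- ceiling(sqrt(n_nuts / n1))
        n3 <- ceiling(n_nuts / (n1 * n2))
        cell <- 2 * rmax + gap_mm
        g <- expand.grid(x = seq_len(n1), y = seq_len(n2), z = seq_len(n3))
        as.matrix(g[seq_len(n_nuts), ]) * cell - cell / 2
      },
      random = {
        side <- (2 * rmax + gap_mm) * ceiling(n_nuts^(1 / 3)) * 1.2
        pts <- matrix(NA_real_, n_nuts, 3)
        for (i in seq_len(n_nuts)) {
          ok <- FALSE
          for (try in seq_len(max_retries)) {
            p <- stats::runif(3, rmax + 1, side - rmax - 1)
            if (i == 1 || all(sqrt(colSums((t(pts[seq_len(i - 1), ,
                  drop = FALSE]) - p)^2)) > rb[i] + rb[seq_len(i - 1)] + 1)) {
              pts[i, ] <- p; ok <- TRUE; break
            }
          }
          if (!ok) stop("could not place nut ", i, " without overlap after ",
                        max_retries, " retries")
        }
        pts
      },
      touching = {
        npairs <- ceiling(n_nuts / 2)
        cell <- 4 * rmax + gap_mm
        pts <- matrix(NA_real_, n_nuts, 3)
        for (p in seq_len(npairs)) {
          base <- c((p - 0.5) * 1.1 * cell, cell / 2 + rmax, cell / 2 + rmax)
          i <- 2 * p - 1
          pts[i, ] <- base - c(0.485 * (rb[i] + rb[min(i + 1, n_nuts)]), 0, 0)
          if (i + 1 <= n_nuts)
            pts[i + 1, ] <- base +
              c(0.485 * (rb[i] + rb[i + 1]), 0, 0)
        }
        pts
      })
    list(rots = rots, centers = centers)
  })
  centers <- placement$centers
  margin <- 2
  lo <- apply(centers - rb - margin, 2, min)
  centers <- sweep(centers, 2, lo)
  hi <- apply(centers + rb + margin, 2, max)
  dims <- as.integer(ceiling(hi / voxel_size_mm)) + 1L

  levels <- specs[[1]]$intensity_levels
  vol <- array(if (foam) levels[["foam"]] else levels[["air"]], dims)
  labels <- array(0L, dims)
  truths <- vector("list", n_nuts)
  for (i in seq_len(n_nuts)) {
    sp <- specs[[i]]
    geom <- build_scan_geometry(sp, voxel_size_mm)
    cvox <- centers[i, ] / voxel_size_mm
    half_vox <- ceiling((rb[i] + 1) / voxel_size_mm)
    lo_i <- pmax(1L, as.integer(floor(cvox - half_vox)) + 1L)
    hi_i <- pmin(dims, as.integer(ceiling(cvox + half_vox)) + 1L)
    ld <- hi_i - lo_i + 1L
    lctr <- cvox - (lo_i - 1L)
    part <- render_nut(geom, ld, lctr, voxel_size_mm,
                       rot = placement$rots[[i]])
    sub <- vol[lo_i[1]:hi_i[1], lo_i[2]:hi_i[2], lo_i[3]:hi_i[3], drop = FALSE]
    sub[part == 3L] <- levels[["air"]]
    sub[part == 2L] <- levels[["kernel"]]
    sub[part == 1L] <- levels[["shell"]]
    vol[lo_i[1]:hi_i[1], lo_i[2]:hi_i[2], lo_i[3]:hi_i[3]] <- sub
    lsub <- labels[lo_i[1]:hi_i[1], lo_i[2]:hi_i[2], lo_i[3]:hi_i[3],
                   drop = FALSE]
    lsub[part == 1L | part == 2L] <- i
    labels[lo_i[1]:hi_i[1], lo_i[2]:hi_i[2], lo_i[3]:hi_i[3]] <- lsub
    pm <- part_label_map(part, voxel_size_mm)
    attr(pm, "bbox") <- rbind(lo_i, hi_i)
    truths[[i]] <- new_phantom_truth(
      traits = spherical_truth_or_null(sp), part_map = pm, spec = sp,
      center_vox = cvox)
  }
  vol <- add_noise(vol, specs[[1]]$noise_sigma, seed + 1L)
  list(volume = volume3d(vol, voxel_size_mm),
       truths = truths,
       label_map = label_map(labels, voxel_size_mm, n_labels = n_nuts))
}

# geometry for scan rendering: lobe scale solved analytically-cheaply on a
# coarse standalone grid once per spec (cached by identical parameters would
# be overkill; scans are generated rarely)
build_scan_geometry <- function(spec, voxel_size_mm) {
  a <- spec$outer_radii_mm
  t <- spec$shell_thickness_mm
  kern <- list(type = "lobes", la = 0.62 * (a - t),
               off = 0.45 * 0.62 * (a[1] - t), s = 1, beta = 8,
               clearance = 0)
  geom <- nut_geometry(spec, kernel = NULL)
  # solve fill on a coarse grid (2x working voxel) for speed
  v <- 2 * voxel_size_mm
  half <- a + spec$bump_amplitude_mm + 1
  dims <- 2L * as.integer(ceiling(half / v)) + 1L
  ctr <- (dims - 1) / 2
  part <- render_nut(geom, dims, ctr, v)
  n_solid <- sum(part > 0L)
  cav_idx <- which(part == 3L)
  cav_q <- (arrayInd(cav_idx, dims) - 1 -
              matrix(ctr, length(cav_idx), 3, byrow = TRUE)) * v
  r <- sqrt(rowSums(cav_q^2))
  u <- cav_q / pmax(r, 1e-12)
  clear <- r <= outer_radius(geom, u) - t - kern$clearance
  kern$s <- solve_kernel_scale(kern, cav_q[clear, , drop = FALSE], n_solid,
                               spec$kernel_fill_target)
  geom$kernel <- kern
  geom
}

spherical_truth_or_null <- function(spec) {
  a <- spec$outer_radii_mm
  if (diff(range(a)) > 0 || spec$bump_amplitude_mm > 0) return(NULL)
  r <- a[1]; t <- spec$shell_thickness_mm
  Vn <- 4 / 3 * pi * r^3
  list(L_mm = 2 * r, F_mm = 2 * r, P_mm = 2 * r, Vn_mm3 = Vn,
       VA3D = 1, Feret3D = 1, A_mm2 = 4 * pi * r^2, Sphericity = 1,
       Vs_mm3 = 4 / 3 * pi * (r^3 - (r - t)^3), T_mm = t, Rugosity = 1,
       Vk_mm3 = NA_real_, FillingRatio_pct = NA_real_, Ve_mm3 = NA_real_)
}

#' Pierce a phantom's shell
#'
#' Drills a cylindrical channel of air from inside the cavity out through the
#' shell along `direction`, connecting cavity and exterior -- the geometry of
#' a damaged nut. A voxel is converted to air only when the hole covers it
#' with a full-voxel margin (axis distance <= hole_radius_mm - voxel size),
#' so holes narrower than about one voxel leave the volume unchanged
#' (undetectable at the working resolution, as in a real scan).
#'
#' @param vol the phantom [volume3d()].
#' @param truth the matching `phantom_truth` (provides centre and geometry).
#' @param hole_radius_mm channel radius; pierces the shell when it exceeds
#'   the shell thickness.
#' @param direction drilling direction (default +z).
#' @return The damaged [volume3d()].
#' @export
damage_shell <- function(vol, truth, hole_radius_mm, direction = c(0, 0, 1)) {
  stopifnot(inherits(vol, "nut_volume"), inherits(truth, "phantom_truth"))
  eff <- hole_radius_mm - vol$voxel_size_mm
  if (eff <= 0) return(vol)
  u <- direction / sqrt(sum(direction^2))
  spec <- truth$spec
  geom <- nut_geometry(spec)
  Rdir <- outer_radius(geom, matrix(u, 1, 3))
  start <- Rdir - spec$shell_thickness_mm - 1
  d <- grid_dims(vol)
  idx <- seq_len(prod(d))
  co <- (arrayInd(idx, d) - 1 -
           matrix(truth$center_vox, length(idx), 3, byrow = TRUE)) *
    vol$voxel_size_mm
  ax <- co %*% u
  rad2 <- rowSums(co^2) - ax^2
  carve <- ax >= start & rad2 <= eff^2
  out <- vol$data
  out[array(carve, d)] <- spec$intensity_levels[["air"]]
  volume3d(out, vol$voxel_size_mm)
}
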