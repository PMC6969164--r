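#' AFM force-indentation curve
#'
#' Indentation-force pairs plus tip geometry, the input to the
#' contact-mechanics fitters ([hertz_fit()], [jkr_fit()],
#' [oliver_pharr_fit()]). Indentation is in meters, force in newtons.
#'
#' @param indentation numeric indentation depth (m); negative values are
#'   allowed on adhesive retract branches.
#' @param force numeric force (N), same length.
#' @param segment character/factor of `"approach"`/`"retract"` flags, one
#'   per point (recycled if length 1).
#' @param tip_radius tip (bead) radius (m), > 0.
#' @param poisson sample Poisson ratio, in [0, 0.5); 0.33 is the value used
#'   for silk throughout.
#' @return An object of class `force_curve`.
#' @export
force_curve <- function(indentation, force, segment = "approach",
                        tip_radius, poisson = 0.33) {
  indentation <- as.numeric(indentation)
  force <- as.numeric(force)
  if (length(indentation) != length(force))
    stop_input("indentation and force must have equal length")
  if (length(segment) == 1L) segment <- rep(segment, length(force))
  if (length(segment) != length(force))
    stop_input("segment flags must match the curve length")
  if (!all(segment %in% c("approach", "retract")))
    stop_input("segment must be 'approach' or 'retract'")
  if (tip_radius <= 0) stop_input("tip_radius must be > 0")
  if (poisson < 0 || poisson >= 0.5) stop_input("poisson must be in [0, 0.5)")
  structure(list(indentation = indentation, force = force,
                 segment = segment, tip_radius = tip_radius,
                 poisson = poisson),
            class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("<force_curve> %d points (R = %.3g m, nu = %.2f)\n",
              length(x$force), x$tip_radius, x$poisson))
  invisible(x)
}

#' Write / read a force curve as three-column CSV
#'
#' Columns `indentation_m,force_N,segment` with `# tip_radius_m=` and
#' `# poisson=` header comments.
#'
#' @param x a [force_curve()].
#' @param path file path.
#' @export
write_force_curve_csv <- function(x, path) {
  stopifnot(inherits(x, "force_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tip_radius_m=%.12g", x$tip_radius), con)
  writeLines(sprintf("# poisson=%.12g", x$poisson), con)
  writeLines("indentation_m,force_N,segment", con)
  writeLines(sprintf("%.12g,%.12g,%s", x$indentation, x$force, x$segment), con)
  invisible(path)
}

#' @rdname write_force_curve_csv
#' @export
read_force_curve_csv <- function(path) {
  lines <- readLines(path)
  num <- function(tag) as.numeric(sub(paste0("^# ", tag, "="), "",
                                      grep(paste0("^# ", tag, "="), lines,
                                           value = TRUE)[1]))
  body <- utils::read.csv(text = lines[!grepl("^#", lines)],
                          stringsAsFactors = FALSE)
  force_curve(body$indentation_m, body$force_N, body$segment,
              tip_radius = num("tip_radius_m"), poisson = num("poisson"))
}

# JKR closed forms shared by the generator and fitter.
# Kbar = (4/3) E / (1 - nu^2); contact radius from force:
#   a^3 = (R/Kbar) (F + 3 pi w R + sqrt(6 pi w R F + (3 pi w R)^2))
# indentation from contact radius:
#   delta = a^2 / R - sqrt(2 pi w a / Kbar)
# and the loading branch force from contact radius:
#   F = Kbar a^3 / R - sqrt(6 pi w Kbar a^3).
jkr_a_from_F <- function(F, w, R, Kbar) {
  disc <- 6 * pi * w * R * F + (3 * pi * w * R)^2
  disc[disc < 0] <- NA_real_
  ((R / Kbar) * (F + 3 * pi * w * R + sqrt(disc)))^(1 / 3)
}

jkr_delta_from_a <- function(a, w, R, Kbar) {
  a^2 / R - sqrt(2 * pi * w * a / Kbar)
}

jkr_F_from_a <- function(a, w, R, Kbar) {
  Kbar * a^3 / R - sqrt(6 * pi * w * Kbar * a^3)
}

hertz_force <- function(delta, E, R, nu) {
  (4 / 3) * (E / (1 - nu^2)) * sqrt(R) * delta^1.5
}

#' Synthetic force-indentation curves (Hertz / JKR forward models)
#'
#' Hertz: `F = (4/3) (E / (1 - nu^2)) sqrt(R) delta^(3/2)` on a uniform
#' indentation grid from 0 to `depth_max` (approach segment). JKR: the
#' adhesive contact relations above, parameterized by contact radius from
#' the pull-off point (`F = -(3/2) pi w R`) up to `depth_max` (retract
#' segment). With `work_adhesion = 0` the JKR relations collapse to Hertz
#' and the Hertz grid/output is returned exactly.
#'
#' @param E Young's modulus (Pa), > 0.
#' @param R tip radius (m), > 0.
#' @param nu Poisson ratio, in [0, 0.5).
#' @param depth_max maximum indentation (m), > 0.
#' @param model `"hertz"` or `"jkr"`.
#' @param work_adhesion work of adhesion w (J/m^2); required for JKR.
#' @param noise_sd additive Gaussian force noise sd (N).
#' @param n_points points per curve.
#' @param seed optional RNG seed.
#' @return A [force_curve()].
#' @examples
#' fc <- gen_force_curve(6e6, 0.3e-6, 0.33, 100e-9)
#' hertz_fit(fc)  # recovers 6e6
#' @export
gen_force_curve <- function(E, R, nu = 0.33, depth_max,
                            model = c("hertz", "jkr"),
                            work_adhesion = NULL, noise_sd = 0,
                            n_points = 200, seed = NULL) {
  model <- match.arg(model)
  if (E <= 0 || R <= 0 || depth_max <= 0)
    stop_input("E, R and depth_max must be > 0")
  if (nu < 0 || nu >= 0.5) stop_input("nu must be in [0, 0.5)")
  if (noise_sd < 0) stop_input("noise_sd must be >= 0")
  Kbar <- (4 / 3) * E / (1 - nu^2)

  if (model == "jkr" && is.null(work_adhesion))
    stop_input("JKR curves need work_adhesion")

  if (model == "hertz" || (model == "jkr" && work_adhesion == 0)) {
    delta <- seq(0, depth_max, length.out = n_points)
    f <- hertz_force(delta, E, R, nu)
    seg <- if (model == "hertz") "approach" else "retract"
  } else {
    w <- work_adhesion
    if (w < 0) stop_input("work_adhesion must be >= 0")
    a_pull <- jkr_a_from_F(-1.5 * pi * w * R, w, R, Kbar)
    # contact radius at delta = depth_max
    a_hi <- jkr_a_from_F(hertz_force(depth_max, E, R, nu) + 3 * pi * w * R,
                         w, R, Kbar)
    a_max <- stats::uniroot(function(a) jkr_delta_from_a(a, w, R, Kbar) - depth_max,
                            lower = a_pull, upper = 10 * a_hi,
                            tol = .Machine$double.eps^0.75)$root
    a <- seq(a_pull, a_max, length.out = n_points)
    delta <- jkr_delta_from_a(a, w, R, Kbar)
    f <- jkr_F_from_a(a, w, R, Kbar)
    # order by increasing indentation for a tidy retract branch
    o <- order(delta)
    delta <- delta[o]; f <- f[o]
    seg <- "retract"
  }
  with_seed(seed, {
    if (noise_sd > 0) f <- f + stats::rnorm(length(f), 0, noise_sd)
    force_curve(delta, f, seg, tip_radius = R, poisson = nu)
  })
}
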