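#' Cylindrical sample-holder geometry
#'
#' Describes the sample holder of a hyperthermia calorimetry experiment: a
#' cylindrical cup of wall conductivity `kappa_sh` holding the nanoparticle
#' suspension, open at the top. The wetted/exposed areas can be given
#' explicitly, or derived from the cylinder dimensions and the fill height of
#' the suspension. Explicit areas take precedence over derived ones.
#'
#' In derived mode the areas are the cylinder surfaces:
#' `a_side = 2*pi*r_int*fill_height` (inner lateral wetted wall),
#' `a_bottom = pi*r_int^2` (inner bottom), `a_top = pi*r_int^2` (open
#' sample/air interface) and `a_sh_ext = 2*pi*r_ext*fill_height + pi*r_ext^2`
#' (outer lateral wall plus outer bottom).
#'
#' @param r_int Inner radius (m).
#' @param r_ext Outer radius (m); must exceed `r_int`.
#' @param wall_thickness Bottom-wall thickness `L` (m).
#' @param kappa_sh Wall thermal conductivity (W/(m K)), e.g. 0.2 for acrylic.
#' @param fill_height Height of the suspension column (m); required unless all
#'   four areas are given explicitly.
#' @param a_side,a_bottom,a_sh_ext,a_top Optional explicit areas (m^2):
#'   inner lateral wetted area, inner bottom area, outer holder surface area,
#'   and open sample/air interface area.
#' @return An object of class `holder_geometry`: a list with the radii, wall
#'   thickness, conductivity, the four areas and the total external area
#'   `a_t = a_sh_ext + a_top`.
#' @examples
#' geom <- holder_geometry(r_int = 5e-3, r_ext = 6e-3, wall_thickness = 1e-3,
#'                         kappa_sh = 0.2, fill_height = 7.64e-3)
#' geom$a_t
#' @export
holder_geometry <- function(r_int, r_ext, wall_thickness, kappa_sh,
                            fill_height = NULL,
                            a_side = NULL, a_bottom = NULL,
                            a_sh_ext = NULL, a_top = NULL) {
  stopifnot(is.numeric(r_int), is.numeric(r_ext), is.numeric(wall_thickness),
            is.numeric(kappa_sh))
  if (r_int <= 0) stop("invalid geometry: r_int must be > 0", call. = FALSE)
  if (r_ext <= r_int)
    stop("invalid geometry: r_ext must exceed r_int", call. = FALSE)
  if (wall_thickness <= 0)
    stop("invalid geometry: wall_thickness must be > 0", call. = FALSE)
  if (kappa_sh <= 0)
    stop("invalid geometry: kappa_sh must be > 0", call. = FALSE)

  need_derived <- is.null(a_side) || is.null(a_bottom) ||
    is.null(a_sh_ext) || is.null(a_top)
  if (need_derived) {
    if (is.null(fill_height) || fill_height <= 0)
      stop("fill_height > 0 is required when areas are not all explicit",
           call. = FALSE)
    if (is.null(a_side))   a_side   <- 2 * pi * r_int * fill_height
    if (is.null(a_bottom)) a_bottom <- pi * r_int^2
    if (is.null(a_top))    a_top    <- pi * r_int^2
    if (is.null(a_sh_ext)) a_sh_ext <- 2 * pi * r_ext * fill_height + pi * r_ext^2
  }
  areas <- c(a_side = a_side, a_bottom = a_bottom,
             a_sh_ext = a_sh_ext, a_top = a_top)
  if (any(!is.finite(areas)) || any(areas <= 0))
    stop("invalid geometry: all areas must be finite and > 0", call. = FALSE)

  structure(list(r_int = r_int, r_ext = r_ext,
                 wall_thickness = wall_thickness, kappa_sh = kappa_sh,
                 fill_height = fill_height,
                 a_side = a_side, a_bottom = a_bottom,
                 a_sh_ext = a_sh_ext, a_top = a_top,
                 a_t = a_sh_ext + a_top),
            class = "holder_geometry")
}

#' @export
print.holder_geometry <- function(x, ...) {
  cat("Cylindrical sample holder\n")
  cat(sprintf("  r_int = %g m, r_ext = %g m, wall L = %g m, kappa_sh = %g W/(m K)\n",
              x$r_int, x$r_ext, x$wall_thickness, x$kappa_sh))
  cat(sprintf("  areas (m^2): side %.4g, bottom %.4g, outer %.4g, top %.4g; A_t = %.4g\n",
              x$a_side, x$a_bottom, x$a_sh_ext, x$a_top, x$a_t))
  invisible(x)
}

#' Ambient environment acting as a heat reservoir
#'
#' The surrounding air, assumed to stay at a constant temperature `t_air`
#' over a whole trace (dT_air/dt = 0), with a free-convection heat transfer
#' coefficient `h_air`.
#'
#' @param t_air Ambient temperature (K).
#' @param h_air Air heat-transfer coefficient (W/(m^2 K)); ~8 for still air.
#' @return An object of class `environment_spec`.
#' @export
environment_spec <- function(t_air = 298, h_air = 8) {
  if (!is.numeric(t_air) || t_air <= 0)
    stop("invalid parameter: t_air must be > 0 K", call. = FALSE)
  if (!is.numeric(h_air) || h_air <= 0)
    stop("invalid parameter: h_air must be > 0", call. = FALSE)
  structure(list(t_air = t_air, h_air = h_air), class = "environment_spec")
}

#' Wall-conduction thermal conductance of the sample holder
#'
#' Lumped steady-state solution of Fourier conduction through the cylindrical
#' wall (lateral log-radial term) and the flat bottom (plane-wall term):
#' \deqn{\epsilon_{sh} = \kappa_{sh}\left[\frac{A_{side}}{R_{ext}\ln(R_{ext}/R_{int})}
#'   + \frac{A_{bottom}}{L}\right].}
#'
#' @param geom A [holder_geometry()].
#' @return Conductance in W/K.
#' @export
conduction_conductance <- function(geom) {
  stopifnot(inherits(geom, "holder_geometry"))
  geom$kappa_sh * (geom$a_side / (geom$r_ext * log(geom$r_ext / geom$r_int)) +
                     geom$a_bottom / geom$wall_thickness)
}

#' Air-convection thermal conductances
#'
#' Newton's-law-of-cooling conductances of the two convective paths: the outer
#' holder surface (`h_air * a_sh_ext`) and the open sample/air interface
#' (`h_air * a_top`).
#'
#' @param env An [environment_spec()].
#' @param geom A [holder_geometry()].
#' @return Named numeric vector `c(eps_air_surf =, eps_air_top =)` in W/K.
#' @export
convection_conductances <- function(env, geom) {
  stopifnot(inherits(env, "environment_spec"),
            inherits(geom, "holder_geometry"))
  c(eps_air_surf = env$h_air * geom$a_sh_ext,
    eps_air_top = env$h_air * geom$a_top)
}

#' Effective thermal conductance from the full resistance network
#'
#' Combines the three component conductances as an electrical analogue: the
#' holder-wall resistance `1/eps_sh` in series with the outer-surface air
#' resistance `1/eps_air_surf`, that branch in parallel with the top-interface
#' air resistance `1/eps_air_top`:
#' \deqn{\epsilon = \frac{\epsilon_{sh}\,\epsilon_{air,surf}}
#'   {\epsilon_{sh}+\epsilon_{air,surf}} + \epsilon_{air,top}.}
#'
#' @param eps_sh Holder conduction conductance (W/K).
#' @param eps_air_surf Outer-surface convection conductance (W/K).
#' @param eps_air_top Top-interface convection conductance (W/K); may be 0 to
#'   drop that branch.
#' @return Effective conductance (W/K), always below
#'   `eps_air_surf + eps_air_top` for finite `eps_sh`.
#' @examples
#' effective_conductance_full(0.0910, 0.0048, 0.0024)
#' @export
effective_conductance_full <- function(eps_sh, eps_air_surf, eps_air_top) {
  if (eps_sh <= 0 || eps_air_surf <= 0 || eps_air_top < 0)
    stop("invalid parameter: conductances must be positive", call. = FALSE)
  eps_sh * eps_air_surf / (eps_sh + eps_air_surf) + eps_air_top
}

#' Simplified effective thermal conductance
#'
#' When the holder wall conducts much better than the surrounding air
#' (`eps_sh >> eps_air_surf, eps_air_top`) the series wall resistance drops
#' out and the effective conductance reduces to `h_air * A_t` with
#' `A_t = a_sh_ext + a_top` the total sample/air contact area.
#'
#' @param h_air Air heat-transfer coefficient (W/(m^2 K)).
#' @param a_t Total external contact area (m^2).
#' @return Effective conductance (W/K).
#' @examples
#' effective_conductance_simplified(8, 0.000910)
#' @export
effective_conductance_simplified <- function(h_air, a_t) {
  if (h_air <= 0) stop("invalid parameter: h_air must be > 0", call. = FALSE)
  if (a_t <= 0) stop("invalid parameter: a_t must be > 0", call. = FALSE)
  h_air * a_t
}

#' Heat-transfer coefficient of the air from a fitted conductance
#'
#' Inverts the simplified network, `h_air = eps_eff / A_t`. If standard errors
#' are supplied the uncertainty is propagated to first order assuming
#' independent errors.
#'
#' @param eps_eff Effective thermal conductance (W/K).
#' @param a_t Total external contact area (m^2).
#' @param eps_se,a_t_se Optional standard errors of the two inputs.
#' @return If no errors are given, the coefficient in W/(m^2 K); otherwise a
#'   named vector `c(h_air =, se =)`.
#' @examples
#' derive_h_air(0.00453, 0.000910)
#' @export
derive_h_air <- function(eps_eff, a_t, eps_se = NULL, a_t_se = NULL) {
  if (eps_eff <= 0) stop("invalid parameter: eps_eff must be > 0", call. = FALSE)
  if (a_t <= 0) stop("division error: a_t must be > 0", call. = FALSE)
  h <- eps_eff / a_t
  if (is.null(eps_se) && is.null(a_t_se)) return(h)
  rel2 <- 0
  if (!is.null(eps_se)) rel2 <- rel2 + (eps_se / eps_eff)^2
  if (!is.null(a_t_se)) rel2 <- rel2 + (a_t_se / a_t)^2
  c(h_air = h, se = h * sqrt(rel2))
}

#' All thermal conductances of a holder/environment pair
#'
#' Convenience wrapper computing the three component conductances and both
#' network combinations in one object.
#'
#' @param geom A [holder_geometry()].
#' @param env An [environment_spec()].
#' @return An object of class `conductance_set`: components `eps_sh`,
#'   `eps_air_surf`, `eps_air_top`, the corresponding thermal resistances,
#'   `eps_full` (series/parallel network) and `eps_simplified` (`h_air * A_t`).
#' @export
conductance_set <- function(geom, env) {
  eps_sh <- conduction_conductance(geom)
  conv <- convection_conductances(env, geom)
  eps_full <- effective_conductance_full(eps_sh, conv[["eps_air_surf"]],
                                         conv[["eps_air_top"]])
  eps_simp <- effective_conductance_simplified(env$h_air, geom$a_t)
  structure(list(eps_sh = eps_sh,
                 eps_air_surf = conv[["eps_air_surf"]],
                 eps_air_top = conv[["eps_air_top"]],
                 r_sh = 1 / eps_sh,
                 r_air_surf = 1 / conv[["eps_air_surf"]],
                 r_air_top = 1 / conv[["eps_air_top"]],
                 eps_full = eps_full,
                 eps_simplified = eps_simp,
                 a_t = geom$a_t, h_air = env$h_air),
            class = "conductance_set")
}

#' @export
print.conductance_set <- function(x, ...) {
  cat("Thermal conductances (W/K)\n")
  cat(sprintf("  holder wall   eps_sh       = %.4g\n", x$eps_sh))
  cat(sprintf("  outer surface eps_air,surf = %.4g\n", x$eps_air_surf))
  cat(sprintf("  top interface eps_air,top  = %.4g\n", x$eps_air_top))
  cat(sprintf("  effective (full network)   = %.4g\n", x$eps_full))
  cat(sprintf("  effective (h_air * A_t)    = %.4g\n", x$eps_simplified))
  invisible(x)
}
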