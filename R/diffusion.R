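## Closed-form and quadrature diffusion distributions for single sources.
## Internal units: u, nm, s.  All phi* functions accept a single location
## (length-2 vector) or an n x 2 matrix of locations and return a numeric
## vector of densities in u/nm^2.

.asPoints <- function(r) {
    if (is.matrix(r)) {
        stopifnot(ncol(r) == 2L)
        r
    } else {
        stopifnot(length(r) == 2L)
        matrix(r, nrow = 1L)
    }
}

#' Exponential integral of order one
#'
#' `E1(x) = integral_x^Inf exp(-u)/u du` for `x >= 0`, with `E1(0) = +Inf`.
#' Vectorized; evaluated by power series for `x <= 1` and a continued
#' fraction otherwise.
#'
#' @param x Non-negative numeric vector.
#' @return `E1(x)`.
#' @examples
#' expIntE1(1)  # 0.2193839
#' @export
expIntE1 <- function(x) e1_cpp(as.numeric(x))

.quadForm <- function(pts, r0, Dinv) {
    dx <- pts[, 1] - r0[1]
    dy <- pts[, 2] - r0[2]
    dx * dx * Dinv[1] + dy * dy * Dinv[2]
}

#' Instantaneous point-source distribution
#'
#' Heat-kernel solution for a point source releasing `Q0` species at `r0`,
#' `t0` in a d-dimensional anisotropic medium:
#' `Q0 (4 pi (t - t0))^{-d/2} |D|^{-1/2} exp(-(r-r0)' D^{-1} (r-r0) / (4 (t-t0)))`.
#'
#' @param r Location(s), nm: length-d vector or n x d matrix (d = 2).
#' @param t Evaluation time, s; must exceed `t0`.
#' @param event A [SourceEvent-class] (kind `"instantaneous_point"`; `Q0` is
#'   the total deposited amount in u).
#' @param medium A [DiffusionMedium-class].
#' @return Density in u/nm^d, strictly positive everywhere.
#' @export
phiInstantaneousPoint <- function(r, t, event, medium) {
    stopifnot(is(event, "SourceEvent"), is(medium, "DiffusionMedium"))
    validObject(medium)
    dt <- t - event@t0
    if (dt <= 0)
        stop("instantaneous source not yet active: t must be > t0")
    pts <- .asPoints(r)
    d <- medium@d
    q <- .quadForm(pts, event@r0, 1 / medium@D)
    pref <- event@profile@Q0 / sqrt(prod(4 * pi * medium@D) * dt^d)
    pref * exp(-q / (4 * dt))
}

#' Continuous point-source distribution
#'
#' Exponential-integral solution for a 2-D point source active on
#' `[t0, t0 + tau]`. During the on phase the value at the activation point is
#' `+Inf`; afterwards it follows the logarithmic branch
#' `Q0/(4 pi sqrt(|D|)) log((t - t0)/(t - t0 - tau))`. The singular branch is
#' dispatched on exact coordinate equality with `r0`.
#'
#' @inheritParams phiInstantaneousPoint
#' @param event A [SourceEvent-class]; any kind with a point-like footprint.
#' @return Density in u/nm^2; 0 for `t < t0`.
#' @export
phiContinuousPoint <- function(r, t, event, medium) {
    stopifnot(is(medium, "DiffusionMedium"), medium@d == 2L)
    validObject(medium)
    pts <- .asPoints(r)
    Q0 <- event@profile@Q0
    t0 <- event@t0; tau <- event@tau
    out <- numeric(nrow(pts))
    if (t < t0) return(out)
    pref <- Q0 / (4 * pi * sqrt(prod(medium@D)))
    q <- .quadForm(pts, event@r0, 1 / medium@D)
    at0 <- pts[, 1] == event@r0[1] & pts[, 2] == event@r0[2]
    on <- t <= t0 + tau
    if (on) {
        out[!at0] <- pref * e1_cpp(q[!at0] / (4 * (t - t0)))
        out[at0] <- Inf
    } else {
        out[!at0] <- pref * (e1_cpp(q[!at0] / (4 * (t - t0))) -
                             e1_cpp(q[!at0] / (4 * (t - t0 - tau))))
        out[at0] <- pref * log((t - t0) / (t - t0 - tau))
    }
    out
}

#' Continuous circular-disc source distribution
#'
#' Adaptive double quadrature of the radial disc solution: the inner integral
#' over the disc radius uses the exponentially scaled modified Bessel kernel
#' `I0` (avoiding overflow for large arguments), the outer integral runs over
#' the active emission interval. Isotropic media only.
#'
#' @inheritParams phiInstantaneousPoint
#' @param event A [SourceEvent-class] of kind `"circular_disc"`.
#' @param relTol Relative quadrature tolerance (target; achieved tolerance is
#'   adaptive).
#' @return Density in u/nm^2; 0 for `t < t0`.
#' @export
phiCircularDisc <- function(r, t, event, medium, relTol = 1e-8) {
    stopifnot(is(medium, "DiffusionMedium"), medium@d == 2L)
    if (!isIsotropic(medium))
        stop("circular-disc solution requires an isotropic medium")
    pts <- .asPoints(r)
    Q0 <- event@profile@Q0; rs <- event@profile@rs
    D <- medium@D[1]; t0 <- event@t0; tau <- event@tau
    out <- numeric(nrow(pts))
    if (t < t0 || t == t0) return(out)
    tend <- min(t, t0 + tau)
    for (j in seq_len(nrow(pts))) {
        rho <- sqrt(sum((pts[j, ] - event@r0)^2))
        ## envelope bounds keep the absolute tolerances reachable when the
        ## point lies far outside the disc and the integrals are ~0
        env <- function(dt) exp(-max(0, rho - rs)^2 / (4 * D * dt))
        f <- function(tp) {
            vapply(tp, function(tp1) {
                dt <- t - tp1
                if (dt <= 0)          # limit value as t' -> t
                    return(Q0 / (pi * rs^2) * (rho < rs) +
                           Q0 / (2 * pi * rs^2) * (rho == rs))
                inner <- integrate(function(u) {
                    u * exp(-(rho - u)^2 / (4 * D * dt)) *
                        besselI(u * rho / (2 * D * dt), 0, expon.scaled = TRUE)
                }, 0, rs, rel.tol = relTol,
                   abs.tol = relTol * 1e-2 * rs^2 * env(dt),
                   subdivisions = 200L)$value
                Q0 / (2 * pi * rs^2 * D * dt) * inner
            }, numeric(1))
        }
        out[j] <- integrate(f, t0, tend, rel.tol = relTol,
                            abs.tol = relTol * 1e-2 * Q0 / (pi * rs^2) *
                                (tend - t0) * env(t - t0),
                            subdivisions = 200L)$value
    }
    out
}

#' Continuous square-disc source distribution
#'
#' The spatial convolution of a uniform square source (half-width `side`)
#' with the isotropic heat kernel separates into per-axis error-function
#' differences; the remaining time integral is evaluated adaptively.
#'
#' @inheritParams phiCircularDisc
#' @param event A [SourceEvent-class] of kind `"square_disc"`.
#' @return Density in u/nm^2; 0 for `t < t0`.
#' @export
phiSquareDisc <- function(r, t, event, medium, relTol = 1e-8) {
    stopifnot(is(medium, "DiffusionMedium"), medium@d == 2L)
    if (!isIsotropic(medium))
        stop("square-disc solution requires an isotropic medium")
    pts <- .asPoints(r)
    Q0 <- event@profile@Q0; a <- event@profile@side
    D <- medium@D[1]; t0 <- event@t0; tau <- event@tau
    out <- numeric(nrow(pts))
    if (t <= t0) return(out)
    tend <- min(t, t0 + tau)
    ## (erf((z+a)/s) - erf((z-a)/s)) / (4a), written with upper-tail normal
    ## probabilities to avoid cancellation far outside the source
    axisFactor <- function(dx, dt) {
        z <- abs(dx)
        if (dt <= 0) return((z < a) / (2 * a) + (z == a) / (4 * a))
        s <- sqrt(4 * D * dt)
        (pnorm(-sqrt(2) * (z - a) / s) - pnorm(-sqrt(2) * (z + a) / s)) /
            (2 * a)
    }
    for (j in seq_len(nrow(pts))) {
        dx <- pts[j, 1] - event@r0[1]
        dy <- pts[j, 2] - event@r0[2]
        f <- function(tp) {
            vapply(tp, function(tp1) {
                dt <- t - tp1
                Q0 * axisFactor(dx, dt) * axisFactor(dy, dt)
            }, numeric(1))
        }
        # envelope keeps the absolute tolerance reachable in the far field
        env <- exp(-(max(0, abs(dx) - a)^2 + max(0, abs(dy) - a)^2) /
                       (4 * D * (t - t0)))
        out[j] <- integrate(f, t0, tend, rel.tol = relTol,
                            abs.tol = relTol * 1e-2 * (tend - t0) *
                                Q0 / (4 * a^2) * env,
                            subdivisions = 200L)$value
    }
    out
}

#' Continuous Gaussian source distribution
#'
#' For an isotropic probe (`Ds = diag(Ds, Ds)`) in an isotropic medium the
#' closed exponential-integral/logarithm form is used:
#' on phase, off the activation point,
#' `Q0/(4 pi D) (E1(q / (2 Ds + 4 D (t - t0))) - E1(q / (2 Ds)))` with
#' `q = ||r - r0||^2`; off phase, the second argument becomes
#' `2 Ds + 4 D (t - t0 - tau)`; at the activation point the logarithmic
#' branches apply. Anisotropic probes or media fall back to adaptive time
#' quadrature of the convolved Gaussian with effective covariance
#' `De = Ds + 2 (t - t') D`.
#'
#' @inheritParams phiCircularDisc
#' @param event A [SourceEvent-class] of kind `"gaussian"`.
#' @return Density in u/nm^2; 0 for `t < t0`.
#' @export
phiGaussian <- function(r, t, event, medium, relTol = 1e-8) {
    stopifnot(is(medium, "DiffusionMedium"), medium@d == 2L)
    validObject(medium)
    Ds <- event@profile@Ds
    if (length(Ds) == 1L) Ds <- rep(Ds, 2L)
    if (any(Ds <= 0) || any(medium@D <= 0))
        stop("Ds and D must be strictly positive")
    pts <- .asPoints(r)
    if (t < event@t0) return(numeric(nrow(pts)))
    iso <- isIsotropic(medium) && Ds[1] == Ds[2]
    if (iso) {
        cdd_points_cpp(pts[, 1], pts[, 2], event@r0[1], event@r0[2],
                       event@t0, event@tau, t, event@profile@Q0,
                       medium@D[1], Ds[1])
    } else {
        .phiGaussianAniso(pts, t, event, medium, Ds, relTol)
    }
}

## Eq-type time quadrature for anisotropic Gaussian probe / medium.
.phiGaussianAniso <- function(pts, t, event, medium, Ds, relTol) {
    Q0 <- event@profile@Q0; D <- medium@D
    t0 <- event@t0; tend <- min(t, t0 + event@tau)
    out <- numeric(nrow(pts))
    if (tend <= t0) {
        # on-phase start: nothing deposited yet unless t == t0 (zero measure)
        return(out)
    }
    for (j in seq_len(nrow(pts))) {
        dx <- pts[j, 1] - event@r0[1]
        dy <- pts[j, 2] - event@r0[2]
        f <- function(tp) {
            de1 <- Ds[1] + 2 * (t - tp) * D[1]
            de2 <- Ds[2] + 2 * (t - tp) * D[2]
            Q0 / (2 * pi * sqrt(de1 * de2)) *
                exp(-0.5 * (dx^2 / de1 + dy^2 / de2))
        }
        out[j] <- integrate(f, t0, tend, rel.tol = relTol, abs.tol = 0)$value
    }
    out
}

#' Brute-force superposition oracle
#'
#' Direct numerical evaluation of the space-time superposition integral of
#' the source activation profile against the anisotropic heat kernel. This
#' is deliberately independent of every closed form in the package and is
#' intended as a verification oracle on small cases.
#'
#' @inheritParams phiCircularDisc
#' @param event A [SourceEvent-class] of any kind.
#' @return Density in u/nm^2 at the requested location(s).
#' @export
superpositionOracle <- function(r, t, event, medium, relTol = 1e-8) {
    stopifnot(is(medium, "DiffusionMedium"), medium@d == 2L)
    pts <- .asPoints(r)
    prof <- event@profile
    Q0 <- prof@Q0; D <- medium@D
    t0 <- event@t0; r0 <- event@r0
    if (Q0 == 0) return(numeric(nrow(pts)))
    kern <- function(dx, dy, dt)
        exp(-(dx^2 / D[1] + dy^2 / D[2]) / (4 * dt)) /
            (4 * pi * dt * sqrt(D[1] * D[2]))
    if (prof@kind == "instantaneous_point") {
        dt <- t - t0
        if (dt <= 0) stop("instantaneous source not yet active")
        return(Q0 * kern(pts[, 1] - r0[1], pts[, 2] - r0[2], dt))
    }
    if (t <= t0) return(numeric(nrow(pts)))
    tend <- min(t, t0 + event@tau)
    ## nested 1-D adaptive quadrature throughout: 2-D cubature error
    ## estimators proved unreliable at the 1e-6 level required of this oracle
    tolSp <- relTol * 1e-2
    spatial <- switch(prof@kind,
        continuous_point = function(x, y, dt) kern(x - r0[1], y - r0[2], dt),
        circular_disc = function(x, y, dt) {
            rs <- prof@rs
            k0 <- 1 / (4 * pi * dt * sqrt(D[1] * D[2]))
            fu <- function(us) vapply(us, function(u) {
                u * integrate(function(th)
                        kern(x - (r0[1] + u * cos(th)),
                             y - (r0[2] + u * sin(th)), dt),
                    0, 2 * pi, rel.tol = tolSp,
                    abs.tol = 2 * pi * k0 * 1e-14,
                    subdivisions = 200L)$value
            }, numeric(1))
            integrate(fu, 0, rs, rel.tol = tolSp,
                      abs.tol = rs^2 * k0 * 1e-14,
                      subdivisions = 200L)$value / (pi * rs^2)
        },
        square_disc = function(x, y, dt) {
            a <- prof@side
            axis <- function(z, z0, Dl) {
                s2 <- 4 * Dl * dt
                integrate(function(zp) exp(-(z - zp)^2 / s2),
                          z0 - a, z0 + a, rel.tol = tolSp,
                          abs.tol = 2 * a * 1e-14,
                          subdivisions = 200L)$value
            }
            axis(x, r0[1], D[1]) * axis(y, r0[2], D[2]) /
                ((2 * a)^2 * 4 * pi * dt * sqrt(D[1] * D[2]))
        },
        gaussian = function(x, y, dt) {
            ## integrate in kernel-scaled coordinates w = v / sqrt(4 D dt):
            ## integral hs(r - v) K(v) dv = integral hs(r - s w) e^{-|w|^2}/pi dw,
            ## smooth for all dt (tends to hs(r) as dt -> 0)
            Ds <- prof@Ds
            if (length(Ds) == 1L) Ds <- rep(Ds, 2L)
            hs0 <- 1 / (2 * pi * sqrt(Ds[1] * Ds[2]))
            hs <- function(xp, yp)
                hs0 * exp(-0.5 * ((xp - r0[1])^2 / Ds[1] +
                                  (yp - r0[2])^2 / Ds[2]))
            s1 <- sqrt(4 * D[1] * dt); s2 <- sqrt(4 * D[2] * dt)
            W <- 7.5
            fw <- function(w1s) vapply(w1s, function(w1) {
                integrate(function(w2) hs(x - s1 * w1, y - s2 * w2) *
                              exp(-(w1^2 + w2^2)) / pi,
                          -W, W, rel.tol = tolSp, abs.tol = hs0 * 1e-15,
                          subdivisions = 200L)$value
            }, numeric(1))
            integrate(fw, -W, W, rel.tol = tolSp, abs.tol = hs0 * 1e-15,
                      subdivisions = 200L)$value
        },
        stop("unsupported profile kind"))
    out <- numeric(nrow(pts))
    for (j in seq_len(nrow(pts))) {
        f <- function(tp) vapply(tp, function(tp1) {
            dt <- t - tp1
            # as t' -> t the kernel tends to a delta; use the source density
            if (dt <= 0) dt <- 1e-300
            spatial(pts[j, 1], pts[j, 2], dt)
        }, numeric(1))
        out[j] <- Q0 * integrate(f, t0, tend, rel.tol = relTol,
                                 abs.tol = 0, subdivisions = 500L)$value
    }
    out
}

#' Total deposited species
#'
#' Conservation total `Qtot(t) = Q0 min(t - t0, tau)` for continuous sources
#' (the plane integral of any of the distributions), and `Q0` itself once an
#' instantaneous source has fired.
#'
#' @param event A [SourceEvent-class].
#' @param t Time, s; must be `>= t0`.
#' @return Deposited amount in u.
#' @export
totalSpecies <- function(event, t) {
    stopifnot(t >= event@t0)
    Q0 <- event@profile@Q0
    if (event@profile@kind == "instantaneous_point")
        return(Q0 * as.numeric(t > event@t0))
    Q0 * min(t - event@t0, event@tau)
}

#' Maximum beam diffusion distribution (M-BDD)
#'
#' Peak diffusion distribution produced by a single isotropic Gaussian probe,
#' attained at the activation point at dwell end:
#' `Q0/(4 pi D) log(1 + 2 tau / rho)` with `rho = Ds / D`.
#'
#' @param Q0 Species rate, u/s.
#' @param D Diffusion coefficient, nm^2/s.
#' @param Ds Probe width parameter, nm^2.
#' @param tau Dwell time, s.
#' @return Peak density in u/nm^2.
#' @examples
#' abddMax(Q0 = 63.45e6, D = 10, Ds = 0.01, tau = 10e-6)  # ~1e4
#' @export
abddMax <- function(Q0, D, Ds, tau) {
    rho <- Ds / D
    Q0 / (4 * pi * D) * log(1 + 2 * tau / rho)
}

#' Asymptotic limit distributions of the Gaussian probe
#'
#' For `D -> 0` the distribution keeps the Gaussian probe shape with mass
#' growing linearly during the dwell (`Q0 (t - t0) / (2 pi Ds) exp(-q/(2 Ds))`
#' on phase, `Q0 tau / (2 pi Ds) exp(-q/(2 Ds))` afterwards); for `D -> Inf`
#' it vanishes identically.
#'
#' @inheritParams phiInstantaneousPoint
#' @param event A [SourceEvent-class] of kind `"gaussian"` with isotropic
#'   `Ds`.
#' @param regime `"D_to_zero"` or `"D_to_inf"`.
#' @return Density in u/nm^2.
#' @export
limitDistribution <- function(r, t, event, regime = c("D_to_zero", "D_to_inf")) {
    regime <- match.arg(regime)
    pts <- .asPoints(r)
    if (regime == "D_to_inf") return(numeric(nrow(pts)))
    Ds <- event@profile@Ds[1]
    Q0 <- event@profile@Q0
    t0 <- event@t0; tau <- event@tau
    if (t < t0) return(numeric(nrow(pts)))
    q <- (pts[, 1] - event@r0[1])^2 + (pts[, 2] - event@r0[2])^2
    mass <- if (t <= t0 + tau) Q0 * (t - t0) else Q0 * tau
    mass / (2 * pi * Ds) * exp(-q / (2 * Ds))
}
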