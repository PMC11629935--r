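#' Diffusing medium
#'
#' A homogeneous, infinite, d-dimensional medium with a diagonal matrix of
#' per-axis diffusion coefficients `diag(D1, ..., Dd)` in nm^2/s.
#'
#' @slot d Dimensionality (positive integer; 2 for all STEM work).
#' @slot D Numeric vector of per-axis diffusion coefficients, nm^2/s.
#' @export
setClass("DiffusionMedium",
         representation(d = "integer", D = "numeric"),
         validity = function(object) {
             if (length(object@d) != 1L || object@d < 1L)
                 return("d must be a single positive integer")
             if (length(object@D) != object@d)
                 return("length(D) must equal d")
             if (any(!is.finite(object@D)) || any(object@D <= 0))
                 return("all diffusion coefficients must be strictly positive")
             TRUE
         })

#' Construct a diffusion medium
#'
#' @param D Per-axis diffusion coefficients in nm^2/s. A scalar is recycled
#'   to all `d` axes (isotropic medium).
#' @param d Dimensionality (default 2).
#' @return A [DiffusionMedium-class] object.
#' @examples
#' diffusionMedium(10)                 # isotropic, D = 10 nm^2/s
#' diffusionMedium(c(0.25, 0.5))       # anisotropic 2-D medium
#' @export
diffusionMedium <- function(D = 10, d = 2L) {
    d <- as.integer(d)
    if (length(D) == 1L) D <- rep(as.numeric(D), d)
    new("DiffusionMedium", d = d, D = as.numeric(D))
}

setMethod("show", "DiffusionMedium", function(object) {
    cat(sprintf("DiffusionMedium: d = %d, D = [%s] nm^2/s\n",
                object@d, paste(signif(object@D, 6), collapse = ", ")))
})

#' @describeIn DiffusionMedium-class TRUE if all axis coefficients are equal.
#' @param object A `DiffusionMedium`.
#' @export
isIsotropic <- function(object) {
    stopifnot(is(object, "DiffusionMedium"))
    diff(range(object@D)) == 0
}

.sourceKinds <- c("instantaneous_point", "continuous_point", "circular_disc",
                  "square_disc", "gaussian")

#' Probe source profile
#'
#' Spatial/temporal shape of the diffusing-species source. `Q0` is the rate
#' at which species are released (u/s; for the instantaneous kind it is a
#' total amount in u). The spatial profile integrates to one over the plane,
#' so the deposited total is always `Q0 * min(t - t0, tau)`.
#'
#' @slot kind One of `"instantaneous_point"`, `"continuous_point"`,
#'   `"circular_disc"`, `"square_disc"`, `"gaussian"`.
#' @slot Q0 Species rate, u/s (u for the instantaneous kind).
#' @slot rs Disc radius, nm (circular disc only).
#' @slot side Square half-width, nm (square disc only).
#' @slot Ds Gaussian shape parameters (variance per axis), nm^2.
#' @export
setClass("SourceProfile",
         representation(kind = "character", Q0 = "numeric", rs = "numeric",
                        side = "numeric", Ds = "numeric"),
         validity = function(object) {
             if (!object@kind %in% .sourceKinds)
                 return(sprintf("unknown source kind '%s'", object@kind))
             if (object@Q0 < 0) return("Q0 must be non-negative")
             if (object@kind == "circular_disc" &&
                 (length(object@rs) != 1L || object@rs <= 0))
                 return("circular disc requires rs > 0")
             if (object@kind == "square_disc" &&
                 (length(object@side) != 1L || object@side <= 0))
                 return("square disc requires side > 0")
             if (object@kind == "gaussian" &&
                 (length(object@Ds) < 1L || any(object@Ds <= 0)))
                 return("gaussian source requires positive Ds")
             TRUE
         })

#' Construct a source profile
#'
#' @param kind Source kind; see [SourceProfile-class].
#' @param Q0 Species rate, u/s (u total for `"instantaneous_point"`).
#' @param rs Disc radius, nm (`"circular_disc"`).
#' @param side Square half-width, nm (`"square_disc"`).
#' @param Ds Gaussian shape parameter(s), nm^2; a scalar means an isotropic
#'   probe `diag(Ds, Ds)`.
#' @return A [SourceProfile-class].
#' @examples
#' sourceProfile("gaussian", Q0 = 63.45e6, Ds = 0.01)
#' @export
sourceProfile <- function(kind = "gaussian", Q0 = 1, rs = numeric(),
                          side = numeric(), Ds = numeric()) {
    kind <- match.arg(kind, .sourceKinds)
    if (kind == "gaussian" && length(Ds) == 1L) Ds <- rep(Ds, 2L)
    new("SourceProfile", kind = kind, Q0 = as.numeric(Q0),
        rs = as.numeric(rs), side = as.numeric(side), Ds = as.numeric(Ds))
}

setMethod("show", "SourceProfile", function(object) {
    extra <- switch(object@kind,
        circular_disc = sprintf(", rs = %g nm", object@rs),
        square_disc   = sprintf(", side = %g nm", object@side),
        gaussian      = sprintf(", Ds = [%s] nm^2",
                                paste(object@Ds, collapse = ", ")),
        "")
    cat(sprintf("SourceProfile: %s, Q0 = %g%s\n", object@kind, object@Q0, extra))
})

#' Source activation event
#'
#' A source profile activated at location `r0` from time `t0` for a duration
#' `tau` (ignored for the instantaneous kind).
#'
#' @slot profile A [SourceProfile-class].
#' @slot r0 Activation location, nm (length-d vector).
#' @slot t0 Activation time, s.
#' @slot tau Activation duration, s.
#' @export
setClass("SourceEvent",
         representation(profile = "SourceProfile", r0 = "numeric",
                        t0 = "numeric", tau = "numeric"),
         validity = function(object) {
             if (object@t0 < 0) return("t0 must be >= 0")
             if (object@tau < 0) return("tau must be >= 0")
             TRUE
         })

#' Construct a source event
#'
#' @param profile A [SourceProfile-class].
#' @param r0 Activation location, nm.
#' @param t0 Activation time, s.
#' @param tau Activation duration, s.
#' @return A [SourceEvent-class].
#' @export
sourceEvent <- function(profile, r0 = c(0, 0), t0 = 0, tau = 0) {
    new("SourceEvent", profile = profile, r0 = as.numeric(r0),
        t0 = as.numeric(t0), tau = as.numeric(tau))
}

#' Scan grid of probe positions
#'
#' A rectangular array of probe positions. Probe (row r, col c), 0-based, is
#' located at `origin + (c*step, -r*step)`: columns advance +x, rows advance
#' -y, so field maps render with row 0 on top.
#'
#' @slot nx,ny Probe counts per axis (columns, rows).
#' @slot step Scan step, nm.
#' @slot origin Location of probe (0,0), nm.
#' @export
setClass("ScanGrid",
         representation(nx = "integer", ny = "integer", step = "numeric",
                        origin = "numeric"),
         validity = function(object) {
             if (object@nx < 1L || object@ny < 1L)
                 return("nx and ny must be >= 1")
             if (object@step <= 0) return("step must be > 0")
             if (length(object@origin) != 2L) return("origin must be length 2")
             TRUE
         })

#' Construct a scan grid
#'
#' @param nx,ny Probe counts per axis.
#' @param step Scan step, nm.
#' @param origin Location of probe (0,0), nm.
#' @return A [ScanGrid-class].
#' @examples
#' scanGrid(20, 20, step = 0.05)
#' @export
scanGrid <- function(nx, ny = nx, step = 0.05, origin = c(0, 0)) {
    new("ScanGrid", nx = as.integer(nx), ny = as.integer(ny),
        step = as.numeric(step), origin = as.numeric(origin))
}

setMethod("show", "ScanGrid", function(object) {
    cat(sprintf("ScanGrid: %d x %d probes, step %g nm, origin (%g, %g)\n",
                object@nx, object@ny, object@step,
                object@origin[1], object@origin[2]))
})

#' Scan plan
#'
#' An ordered sequence of probe events on a scan grid with constant dwell
#' time `dwell` and settling/blanking time `settle`: probe i starts at
#' `t_i = (i-1) * (dwell + settle)`.
#'
#' @slot grid A [ScanGrid-class].
#' @slot events `data.frame` with one row per probe in scan order: `index`,
#'   `row`, `col` (0-based), `x`, `y` (nm), `t` (activation time, s), `tau`
#'   (dwell, s), `slot` (0-based slot index).
#' @slot trajectory Trajectory name.
#' @slot kappa Alternating-scan order (1 unless trajectory is "alternating").
#' @slot dwell Dwell time per probe, s.
#' @slot settle Settling/blanking time between probes, s.
#' @export
setClass("ScanPlan",
         representation(grid = "ScanGrid", events = "data.frame",
                        trajectory = "character", kappa = "integer",
                        dwell = "numeric", settle = "numeric"),
         validity = function(object) {
             ev <- object@events
             need <- c("index", "row", "col", "x", "y", "t", "tau", "slot")
             if (!all(need %in% names(ev)))
                 return("events must have columns index,row,col,x,y,t,tau,slot")
             if (object@dwell <= 0) return("dwell must be > 0")
             if (object@settle < 0) return("settle must be >= 0")
             if (nrow(ev) > 1 &&
                 any(diff(ev$t) < ev$tau[-nrow(ev)] * (1 - 1e-9)))
                 return("activation times must satisfy t[i+1] >= t[i] + tau[i]")
             if (anyDuplicated(ev[, c("row", "col")]))
                 return("events must cover each selected node at most once")
             TRUE
         })

#' Subsampling mask
#'
#' Binary selection over the N probes of a scan plan (in scan order), with
#' the hardware timing model used to realise it: a beam blanker keeps the
#' full-scan timing and blanks unselected slots; a scan generator visits only
#' selected positions back-to-back.
#'
#' @slot s Logical vector, length N, in scan order.
#' @slot strategy One of `"UDS"`, `"linehop"`, `"DCS"`, `"full"`, `"custom"`.
#' @slot hardware `"beam_blanker"` or `"scan_generator"`.
#' @slot seed Integer seed the mask was generated from (NA for deterministic
#'   strategies).
#' @export
setClass("SubsamplingMask",
         representation(s = "logical", strategy = "character",
                        hardware = "character", seed = "integer"),
         validity = function(object) {
             if (!object@strategy %in% c("UDS", "linehop", "DCS", "full", "custom"))
                 return("unknown strategy")
             if (!object@hardware %in% c("beam_blanker", "scan_generator"))
                 return("hardware must be beam_blanker or scan_generator")
             TRUE
         })

setMethod("show", "SubsamplingMask", function(object) {
    cat(sprintf("SubsamplingMask: %s/%s, M = %d of N = %d (%.1f%%)\n",
                object@strategy, object@hardware, sum(object@s),
                length(object@s), 100 * mean(object@s)))
})

#' @describeIn SubsamplingMask-class Number of selected probes M.
#' @param object A `SubsamplingMask`.
#' @export
maskSize <- function(object) sum(object@s)

#' Simulation grid settings
#'
#' The spatial/temporal discretisation of field maps. Each scan step is
#' resolved with `subpixels` pixels; `NT` temporal samples are taken per
#' probe interval (NT = 1 evaluates at dwell ends only); the field extent is
#' the probe bounding box padded by `margin` scan steps on every side.
#'
#' @slot subpixels Pixels per scan step (default 10).
#' @slot NT Temporal samples per probe interval (default 1).
#' @slot margin Margin in scan steps around the probe array (default 5).
#' @export
setClass("SimulationGrid",
         representation(subpixels = "integer", NT = "integer",
                        margin = "integer"),
         validity = function(object) {
             if (object@subpixels < 1L) return("subpixels must be >= 1")
             if (object@NT < 1L) return("NT must be >= 1")
             if (object@margin < 0L) return("margin must be >= 0")
             TRUE
         })

#' Construct simulation grid settings
#'
#' @param subpixels Pixels per scan step.
#' @param NT Temporal samples per probe interval.
#' @param margin Margin in scan steps around the probe array.
#' @return A [SimulationGrid-class].
#' @export
simulationGrid <- function(subpixels = 10L, NT = 1L, margin = 5L) {
    new("SimulationGrid", subpixels = as.integer(subpixels),
        NT = as.integer(NT), margin = as.integer(margin))
}

#' Scalar field on a simulation grid
#'
#' A 2-D scalar field (e.g. a diffusion distribution in u/nm^2). `values` is
#' indexed `[row, col]` with row 1 at the top of the field of view; pixel
#' (row i, col j), 1-based, is at `origin + ((j-1)*pixel, -(i-1)*pixel)`.
#'
#' @slot values Numeric matrix, `[ny, nx]`.
#' @slot pixel Pixel size, nm.
#' @slot origin Physical location of pixel (1,1), nm.
#' @slot units Unit string of the values.
#' @slot metadata Free-form list (evaluation times, argmax, settings).
#' @export
setClass("FieldMap",
         representation(values = "matrix", pixel = "numeric",
                        origin = "numeric", units = "character",
                        metadata = "list"),
         validity = function(object) {
             if (object@pixel <= 0) return("pixel size must be > 0")
             if (length(object@origin) != 2L) return("origin must be length 2")
             TRUE
         })

#' Construct a field map
#'
#' @param values Numeric matrix `[ny, nx]`.
#' @param pixel Pixel size, nm.
#' @param origin Location of pixel (1,1), nm.
#' @param units Unit string.
#' @param metadata Optional list.
#' @return A [FieldMap-class].
#' @export
fieldMap <- function(values, pixel, origin = c(0, 0), units = "u/nm^2",
                     metadata = list()) {
    new("FieldMap", values = values, pixel = as.numeric(pixel),
        origin = as.numeric(origin), units = units, metadata = metadata)
}

setMethod("show", "FieldMap", function(object) {
    v <- object@values
    cat(sprintf("FieldMap: %d x %d pixels (%g nm/px), range [%g, %g] %s\n",
                nrow(v), ncol(v), object@pixel, min(v), max(v), object@units))
})

#' @describeIn FieldMap-class Field values matrix `[ny, nx]`.
#' @param object A `FieldMap`.
#' @export
fieldValues <- function(object) object@values

#' @describeIn FieldMap-class Pixel size in nm.
#' @export
pixelSize <- function(object) object@pixel

#' Damage model
#'
#' Threshold model for diffusion-induced damage: damage accrues at rate
#' `p(r,t) * g(psi(r,t) - lambda)` where `g` is the activation (`"sign"` for
#' event frequency, `"relu"` for intensity) and `p` the pupil (`"offline"`:
#' everywhere; `"online"`: only within `rp` of a yet-to-be-scanned probe).
#'
#' @slot lambda DID threshold, u/nm^2.
#' @slot activation `"sign"` or `"relu"`.
#' @slot pupil `"offline"` or `"online"`.
#' @slot rp Online pupil radius, nm.
#' @export
setClass("DamageModel",
         representation(lambda = "numeric", activation = "character",
                        pupil = "character", rp = "numeric"),
         validity = function(object) {
             if (object@lambda < 0) return("lambda must be >= 0")
             if (!object@activation %in% c("sign", "relu"))
                 return("activation must be 'sign' or 'relu'")
             if (!object@pupil %in% c("offline", "online"))
                 return("pupil must be 'offline' or 'online'")
             if (object@pupil == "online" &&
                 (length(object@rp) != 1L || object@rp <= 0))
                 return("online pupil requires rp > 0")
             TRUE
         })

#' Construct a damage model
#'
#' @param lambda DID threshold, u/nm^2.
#' @param activation `"sign"` (damage-event frequency) or `"relu"` (damage
#'   intensity).
#' @param pupil `"offline"` (damage counted everywhere) or `"online"` (only
#'   near yet-to-be-scanned probes).
#' @param rp Online pupil radius, nm (default 3 scan steps at the baseline
#'   step of 0.05 nm).
#' @return A [DamageModel-class].
#' @export
damageModel <- function(lambda, activation = c("sign", "relu"),
                        pupil = c("offline", "online"), rp = 0.15) {
    new("DamageModel", lambda = as.numeric(lambda),
        activation = match.arg(activation), pupil = match.arg(pupil),
        rp = as.numeric(rp))
}

setMethod("show", "DamageModel", function(object) {
    cat(sprintf("DamageModel: lambda = %g u/nm^2, %s activation, %s pupil%s\n",
                object@lambda, object@activation, object@pupil,
                if (object@pupil == "online")
                    sprintf(" (rp = %g nm)", object@rp) else ""))
})

#' Result of diffusion-controlled sampling design
#'
#' @slot mask The designed [SubsamplingMask-class] (in scan order of the base
#'   trajectory).
#' @slot achievedGmcdd GM-CDD of the designed compressive scan, u/nm^2.
#' @slot samplingRatio M/N.
#' @slot lambda Threshold used, u/nm^2.
#' @slot chi End-of-scan PM-CDD [FieldMap-class] of the designed scan.
#' @export
setClass("DCSResult",
         representation(mask = "SubsamplingMask", achievedGmcdd = "numeric",
                        samplingRatio = "numeric", lambda = "numeric",
                        chi = "FieldMap"),
         validity = function(object) {
             if (object@achievedGmcdd >= object@lambda)
                 return("achieved GM-CDD must be strictly below lambda")
             TRUE
         })

setMethod("show", "DCSResult", function(object) {
    cat(sprintf(
        "DCSResult: M = %d (%.1f%%), lambda = %g, achieved GM-CDD = %g u/nm^2\n",
        maskSize(object@mask), 100 * object@samplingRatio, object@lambda,
        object@achievedGmcdd))
})
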