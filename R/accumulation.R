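## Accumulation of per-probe Gaussian distributions into cumulative
## diffusion distribution (CDD) maps and their point-wise / global maxima.

## Lattice geometry shared by all field computations: every pixel and every
## probe lies on the integer sub-pixel lattice, so probe/pixel coordinates
## are generated from one expression and singular-branch dispatch by exact
## coordinate match is reliable.
.lattice <- function(plan, simGrid) {
    g <- plan@grid
    sub <- simGrid@subpixels
    mpx <- simGrid@margin * sub
    pix <- g@step / sub
    nxp <- (g@nx - 1L) * sub + 2L * mpx + 1L
    nyp <- (g@ny - 1L) * sub + 2L * mpx + 1L
    x0 <- g@origin[1] - simGrid@margin * g@step   # pixel (ix = 0)
    y0 <- g@origin[2] + simGrid@margin * g@step   # pixel (iy = 0), top row
    list(sub = sub, mpx = mpx, pix = pix, nxp = nxp, nyp = nyp,
         x0 = x0, y0 = y0,
         xOf = function(ix) x0 + ix * pix,
         yOf = function(iy) y0 - iy * pix)
}

.probePixels <- function(events, lat) {
    list(ix = lat$mpx + events$col * lat$sub,
         iy = lat$mpx + events$row * lat$sub)
}

.checkGaussianIso <- function(probe, medium) {
    stopifnot(is(probe, "SourceProfile"), is(medium, "DiffusionMedium"))
    if (probe@kind != "gaussian")
        stop("scan accumulation assumes a Gaussian probe")
    if (!isIsotropic(medium))
        stop("scan accumulation assumes an isotropic medium")
    Ds <- probe@Ds
    if (length(Ds) > 1L && diff(range(Ds)) != 0)
        stop("scan accumulation assumes an isotropic probe width")
    list(Q0 = probe@Q0, D = medium@D[1], Ds = Ds[1])
}

.fieldFromVec <- function(vec, lat, units = "u/nm^2", metadata = list()) {
    vals <- t(matrix(vec, nrow = lat$nxp, ncol = lat$nyp))
    fieldMap(vals, pixel = lat$pix, origin = c(lat$x0, lat$y0),
             units = units, metadata = metadata)
}

#' Cumulative diffusion distribution (CDD) at a time point
#'
#' Point-wise sum over all selected probe events of the Gaussian-probe
#' distribution, each in its on/off/inactive branch at time `t`.
#'
#' @param plan A [ScanPlan-class].
#' @param probe A Gaussian [SourceProfile-class].
#' @param medium An isotropic [DiffusionMedium-class].
#' @param t Evaluation time, s (non-negative).
#' @param mask Optional [SubsamplingMask-class]; `NULL` = full scan.
#' @param simGrid A [SimulationGrid-class].
#' @return A [FieldMap-class] of the CDD in u/nm^2.
#' @export
cdd <- function(plan, probe, medium, t, mask = NULL,
                simGrid = simulationGrid()) {
    if (t < 0) stop("t must be non-negative")
    par <- .checkGaussianIso(probe, medium)
    lat <- .lattice(plan, simGrid)
    sch <- scheduleEvents(plan, mask)
    pp <- .probePixels(sch, lat)
    ix <- rep(0:(lat$nxp - 1L), times = lat$nyp)
    iy <- rep(0:(lat$nyp - 1L), each = lat$nxp)
    vec <- cdd_points_cpp(lat$xOf(ix), lat$yOf(iy),
                          lat$xOf(pp$ix), lat$yOf(pp$iy),
                          sch$t, sch$tau, t, par$Q0, par$D, par$Ds)
    .fieldFromVec(vec, lat, metadata = list(t = t, kind = "CDD"))
}

.evalSlots <- function(plan, mask, sch) {
    if (is.null(mask) || mask@hardware == "scan_generator" ||
        mask@strategy == "linehop") {   # linehop packs both hardware models
        sch$slot
    } else {
        # blanker: selected dwell ends plus the end of the full scan window
        sort(unique(c(sch$slot, nProbes(plan) - 1L)))
    }
}

#' Point-wise maximum CDD (PM-CDD)
#'
#' For every grid point, the maximum of the CDD over the discrete evaluation
#' times: the dwell ends of all selected probes plus the end of the scan
#' (`NT = 1`), or an `NT`-fold refinement of each probe slot. The default
#' lattice method factorises the constant-slot accumulation into exact
#' per-lag lookup tables on the integer pixel lattice; the generic method
#' evaluates each time point directly and supports `NT > 1`.
#'
#' @inheritParams cdd
#' @param epsRel Per-lag contribution cutoff: increments below `epsRel`
#'   times the single-probe peak are skipped (0 disables the cutoff).
#' @param method `"auto"` (lattice when `NT == 1`), `"lattice"` or
#'   `"generic"`.
#' @return A [FieldMap-class] of the end-of-scan PM-CDD; its `metadata`
#'   carries the GM-CDD, its argmax pixel/time, and the per-time spatial
#'   maxima.
#' @export
pmcdd <- function(plan, probe, medium, mask = NULL,
                  simGrid = simulationGrid(), epsRel = 1e-9,
                  method = c("auto", "lattice", "generic")) {
    method <- match.arg(method)
    if (method == "auto")
        method <- if (simGrid@NT == 1L) "lattice" else "generic"
    par <- .checkGaussianIso(probe, medium)
    lat <- .lattice(plan, simGrid)
    sch <- scheduleEvents(plan, mask)
    pp <- .probePixels(sch, lat)
    slotLen <- plan@dwell + plan@settle

    if (method == "lattice") {
        if (simGrid@NT != 1L)
            stop("lattice method requires NT = 1; use method = 'generic'")
        es <- .evalSlots(plan, mask, sch)
        res <- lag_pmcdd_cpp(pp$ix, pp$iy, sch$slot, es,
                             lat$nxp, lat$nyp, par$Q0, par$D, par$Ds,
                             plan@dwell, slotLen, lat$pix^2, epsRel)
        p0 <- res$argmaxPixel - 1L
        aix <- p0 %% lat$nxp
        aiy <- p0 %/% lat$nxp
        md <- list(kind = "PM-CDD", gmcdd = res$gmcdd,
                   psiMax = as.numeric(res$psiMax),
                   evalSlot = es, evalTime = es * slotLen + plan@dwell,
                   argmaxLocation = c(lat$xOf(aix), lat$yOf(aiy)),
                   argmaxTimeIndex = res$argmaxEval,
                   method = "lattice", epsRel = epsRel)
        return(.fieldFromVec(res$chi, lat, metadata = md))
    }

    ## generic path: direct evaluation at each (refined) time point
    es <- .evalSlots(plan, mask, sch)
    times <- sort(unique(c(
        es * slotLen + plan@dwell,
        if (simGrid@NT > 1L)
            as.numeric(outer(es * slotLen,
                             seq_len(simGrid@NT) * slotLen / simGrid@NT, `+`))
    )))
    ix <- rep(0:(lat$nxp - 1L), times = lat$nyp)
    iy <- rep(0:(lat$nyp - 1L), each = lat$nxp)
    px <- lat$xOf(ix); py <- lat$yOf(iy)
    ex <- lat$xOf(pp$ix); ey <- lat$yOf(pp$iy)
    chi <- rep(0, length(px))
    psiMax <- numeric(length(times))
    for (k in seq_along(times)) {
        v <- cdd_points_cpp(px, py, ex, ey, sch$t, sch$tau, times[k],
                            par$Q0, par$D, par$Ds)
        chi <- pmax(chi, v)
        psiMax[k] <- max(v)
    }
    gm <- max(chi)
    p0 <- which.max(chi) - 1L
    md <- list(kind = "PM-CDD", gmcdd = gm, psiMax = psiMax,
               evalTime = times,
               argmaxLocation = c(lat$xOf(p0 %% lat$nxp),
                                  lat$yOf(p0 %/% lat$nxp)),
               argmaxTimeIndex = which.max(psiMax),
               method = "generic", epsRel = 0)
    .fieldFromVec(chi, lat, metadata = md)
}

#' Global maximum CDD (GM-CDD)
#'
#' The spatial maximum of the PM-CDD: the largest value the CDD attains
#' anywhere at any sampled time during the acquisition.
#'
#' @param x A [FieldMap-class] produced by [pmcdd()], or a [ScanPlan-class]
#'   (in which case the PM-CDD is computed first).
#' @param ... Passed to [pmcdd()] when `x` is a plan.
#' @return A list with `value` (u/nm^2), `location` (nm) and
#'   `timeIndex` of the maximum.
#' @export
setGeneric("gmcdd", function(x, ...) standardGeneric("gmcdd"))

#' @rdname gmcdd
#' @export
setMethod("gmcdd", "FieldMap", function(x, ...) {
    md <- x@metadata
    if (!is.null(md$gmcdd))
        return(list(value = md$gmcdd, location = md$argmaxLocation,
                    timeIndex = md$argmaxTimeIndex))
    v <- x@values
    p <- which.max(v)
    i <- (p - 1) %% nrow(v) + 1
    j <- (p - 1) %/% nrow(v) + 1
    list(value = v[p],
         location = c(x@origin[1] + (j - 1) * x@pixel,
                      x@origin[2] - (i - 1) * x@pixel),
         timeIndex = NA_integer_)
})

#' @rdname gmcdd
#' @param probe,medium,mask,simGrid As in [pmcdd()].
#' @export
setMethod("gmcdd", "ScanPlan", function(x, probe, medium, mask = NULL,
                                        simGrid = simulationGrid(), ...) {
    gmcdd(pmcdd(x, probe, medium, mask = mask, simGrid = simGrid, ...))
})

#' Small-diffusion limit of the CDD
#'
#' For `D -> 0` the CDD is a sum of Gaussian bumps of width `Ds` frozen at
#' the probe positions: the currently active probe contributes mass
#' `Q0 (t - t_j)` and every completed probe `Q0 tau_i`.
#'
#' @inheritParams cdd
#' @return A [FieldMap-class].
#' @export
cddLimitSmallD <- function(plan, probe, t, simGrid = simulationGrid()) {
    stopifnot(probe@kind == "gaussian")
    Ds <- probe@Ds[1]; Q0 <- probe@Q0
    lat <- .lattice(plan, simGrid)
    sch <- scanEvents(plan)
    pp <- .probePixels(sch, lat)
    ix <- rep(0:(lat$nxp - 1L), times = lat$nyp)
    iy <- rep(0:(lat$nyp - 1L), each = lat$nxp)
    px <- lat$xOf(ix); py <- lat$yOf(iy)
    vec <- rep(0, length(px))
    for (i in seq_len(nrow(sch))) {
        el <- t - sch$t[i]
        if (el <= 0) next
        mass <- Q0 * min(el, sch$tau[i])
        q <- (px - lat$xOf(pp$ix[i]))^2 + (py - lat$yOf(pp$iy[i]))^2
        vec <- vec + mass / (2 * pi * Ds) * exp(-q / (2 * Ds))
    }
    .fieldFromVec(vec, lat, metadata = list(t = t, kind = "CDD-smallD"))
}

#' Total deposited species of full and compressive scans
#'
#' `Qstem = Q0 sum(tau_j)` over all probes and `Qcstem = Q0 sum(s_j tau_j)`
#' over the selected ones (`N Q0 tau` and `M Q0 tau` at constant dwell).
#'
#' @inheritParams cdd
#' @return Named numeric `c(Qstem =, Qcstem =)` in u.
#' @export
depositedTotals <- function(plan, probe, mask = NULL) {
    ev <- scanEvents(plan)
    s <- if (is.null(mask)) rep(TRUE, nrow(ev)) else mask@s
    c(Qstem = probe@Q0 * sum(ev$tau),
      Qcstem = probe@Q0 * sum(ev$tau[s]))
}
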