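## Diffusion-induced damage (DID): time integral of an activation function
## of threshold exceedance, gated by a pupil function.

## Latest slot index (0-based) of a selected probe within rp of each pixel;
## -1 where no probe ever comes close. Drives the online pupil.
.lastCover <- function(sch, lat, rp) {
    lastCover <- rep(-1L, lat$nxp * lat$nyp)
    pp <- .probePixels(sch, lat)
    rpix <- rp / lat$pix
    rInt <- floor(rpix)
    for (i in seq_len(nrow(sch))) {
        cx <- pp$ix[i]; cy <- pp$iy[i]
        iys <- max(0L, cy - rInt):min(lat$nyp - 1L, cy + rInt)
        for (iy in iys) {
            span <- sqrt(max(rpix^2 - (iy - cy)^2, 0))
            x0 <- max(0L, as.integer(ceiling(cx - span)))
            x1 <- min(lat$nxp - 1L, as.integer(floor(cx + span)))
            if (x1 < x0) next
            idx <- iy * lat$nxp + (x0:x1) + 1L
            lastCover[idx] <- pmax(lastCover[idx], sch$slot[i])
        }
    }
    lastCover
}

#' Diffusion-induced damage profile
#'
#' Discretised time integral of `p(r, t) g(psi(r, t) - lambda)` from the
#' first activation to the end of the scan, by the rectangle rule over probe
#' slots with the CDD evaluated at each slot's dwell end. Activation
#' `"sign"` counts the time the CDD exceeds the threshold (units s);
#' `"relu"` integrates the exceedance (units u s / nm^2). The offline pupil
#' is identically 1; the online pupil is 1 only within `rp` of a probe that
#' is still to be scanned.
#'
#' @inheritParams pmcdd
#' @param model A [DamageModel-class].
#' @return A [FieldMap-class] of the overall point-wise DID; `units` and
#'   `metadata` record the activation/pupil configuration.
#' @export
didProfile <- function(plan, probe, medium, model, mask = NULL,
                       simGrid = simulationGrid(), epsRel = 1e-9) {
    stopifnot(is(model, "DamageModel"))
    par <- .checkGaussianIso(probe, medium)
    lat <- .lattice(plan, simGrid)
    sch <- scheduleEvents(plan, mask)
    pp <- .probePixels(sch, lat)
    slotLen <- plan@dwell + plan@settle
    nSlots <- if (is.null(mask) || mask@hardware == "scan_generator" ||
                  mask@strategy == "linehop")
        nrow(sch) else nProbes(plan)
    lastCover <- if (model@pupil == "online")
        .lastCover(sch, lat, model@rp) else integer(0)
    act <- if (model@activation == "relu") 1L else 0L

    if (simGrid@NT == 1L) {
        vec <- lag_damage_cpp(pp$ix, pp$iy, sch$slot, nSlots,
                              lat$nxp, lat$nyp, par$Q0, par$D, par$Ds,
                              plan@dwell, slotLen, lat$pix^2, model@lambda,
                              act, lastCover, epsRel)
    } else {
        ## refined time grid: NT rectangles per slot, CDD at sub-slot ends
        ix <- rep(0:(lat$nxp - 1L), times = lat$nyp)
        iy <- rep(0:(lat$nyp - 1L), each = lat$nxp)
        px <- lat$xOf(ix); py <- lat$yOf(iy)
        ex <- lat$xOf(pp$ix); ey <- lat$yOf(pp$iy)
        vec <- rep(0, length(px))
        for (k in seq_len(nSlots) - 1L) {
            width <- if (k == nSlots - 1L) plan@dwell else slotLen
            for (j in seq_len(simGrid@NT)) {
                tEval <- k * slotLen + j * width / simGrid@NT
                v <- cdd_points_cpp(px, py, ex, ey, sch$t, sch$tau, tEval,
                                    par$Q0, par$D, par$Ds) - model@lambda
                g <- if (act == 1L) pmax(v, 0) else as.numeric(v >= 0)
                if (length(lastCover)) g[k >= lastCover] <- 0
                vec <- vec + width / simGrid@NT * g
            }
        }
    }
    units <- if (model@activation == "relu") "u*s/nm^2" else "s"
    .fieldFromVec(vec, lat, units = units,
                  metadata = list(kind = "DID", lambda = model@lambda,
                                  activation = model@activation,
                                  pupil = model@pupil,
                                  rp = if (model@pupil == "online")
                                      model@rp else NA_real_,
                                  NT = simGrid@NT))
}

#' Overall DID
#'
#' Grid quadrature of a damage map: `integral Lambda(r; lambda) dr`.
#'
#' @param map A [FieldMap-class] from [didProfile()].
#' @return Scalar overall DID (damage-map units times nm^2).
#' @export
overallDid <- function(map) {
    stopifnot(is(map, "FieldMap"))
    sum(map@values) * map@pixel^2
}

#' Is a scan DID-free?
#'
#' A scan is DID-free (overall DID exactly zero for every non-negative
#' activation with an everywhere-positive pupil time integral) iff its
#' GM-CDD does not exceed the threshold.
#'
#' @inheritParams didProfile
#' @return A list with `didFree` (logical), `margin` (`lambda - gmcdd`,
#'   u/nm^2) and `gmcdd`.
#' @export
isDidFree <- function(plan, probe, medium, model, mask = NULL,
                      simGrid = simulationGrid(), epsRel = 1e-9) {
    gm <- gmcdd(plan, probe, medium, mask = mask, simGrid = simGrid,
                epsRel = epsRel)$value
    if (model@pupil == "online") {
        lat <- .lattice(plan, simGrid)
        sch <- scheduleEvents(plan, mask)
        if (any(.lastCover(sch, lat, model@rp) < 0L))
            warning(paste("online pupil never opens at some grid points;",
                          "the GM-CDD criterion is sufficient but the",
                          "equivalence with zero DID is not guaranteed there"))
    }
    list(didFree = gm <= model@lambda, margin = model@lambda - gm, gmcdd = gm)
}

#' Single-probe damage condition
#'
#' If the peak distribution of one probe already reaches the threshold
#' (`abddMax >= lambda`), no subsampling strategy can produce a DID-free
#' scan.
#'
#' @inheritParams abddMax
#' @param tauMax Longest dwell time, s.
#' @param lambda DID threshold, u/nm^2.
#' @return `TRUE` if DID is unavoidable under any subsampling.
#' @export
singleProbeCondition <- function(Q0, D, Ds, tauMax, lambda) {
    abddMax(Q0, D, Ds, tauMax) >= lambda
}
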