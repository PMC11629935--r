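## Diffusion-controlled sampling: greedy design of DID-free masks.

#' Design a diffusion-controlled sampling (DCS) mask
#'
#' Traverses the candidate probes in the base trajectory order of `plan` and
#' accepts a candidate only if the would-be CDD at its own dwell end stays
#' strictly below `lambda` at every grid point (which, with the running
#' point-wise maximum maintained over accepted probes, keeps the PM-CDD
#' below the threshold and hence the scan DID-free). Rejected candidates
#' are skipped permanently: under beam-blanker timing their slot still
#' elapses, under scan-generator timing no time elapses.
#'
#' @inheritParams pmcdd
#' @param lambda DID threshold, u/nm^2 (> 0).
#' @param hardware `"beam_blanker"` or `"scan_generator"`.
#' @param minDist Optional minimum distance (nm) between selected probes,
#'   applied as a greedy side constraint during the traversal (0 disables).
#' @return A [DCSResult-class].
#' @export
dcsDesign <- function(plan, probe, medium, lambda,
                      hardware = c("beam_blanker", "scan_generator"),
                      simGrid = simulationGrid(), epsRel = 1e-9,
                      minDist = 0) {
    hardware <- match.arg(hardware)
    if (is.infinite(lambda) && lambda > 0) lambda <- .Machine$double.xmax
    if (lambda <= 0) stop("lambda must be > 0")
    par <- .checkGaussianIso(probe, medium)
    lat <- .lattice(plan, simGrid)
    ev <- scanEvents(plan)
    pp <- .probePixels(ev, lat)
    slotLen <- plan@dwell + plan@settle
    res <- lag_dcs_cpp(pp$ix, pp$iy, lat$nxp, lat$nyp,
                       par$Q0, par$D, par$Ds, plan@dwell, slotLen,
                       lat$pix^2, lambda, hardware == "beam_blanker", epsRel)
    sel <- as.logical(res$selected)
    if (minDist > 0 && any(sel)) {
        keep <- rep(FALSE, length(sel))
        for (j in which(sel)) {
            prior <- which(keep)
            if (!length(prior) ||
                all((ev$x[j] - ev$x[prior])^2 + (ev$y[j] - ev$y[prior])^2 >=
                    minDist^2))
                keep[j] <- TRUE
        }
        if (!identical(keep, sel)) {
            # re-run the greedy check on the distance-filtered candidate set
            return(.dcsOnSubset(plan, probe, medium, lambda, hardware,
                                simGrid, epsRel, keep))
        }
    }
    mask <- new("SubsamplingMask", s = sel, strategy = "DCS",
                hardware = hardware, seed = NA_integer_)
    chi <- .fieldFromVec(res$chi, lat,
                         metadata = list(kind = "PM-CDD", gmcdd = res$gmcdd))
    new("DCSResult", mask = mask, achievedGmcdd = res$gmcdd,
        samplingRatio = sum(sel) / length(sel), lambda = lambda, chi = chi)
}

## Greedy pass restricted to a candidate subset (used by the minimum-distance
## post-filter so the safety guarantee is re-established on the final mask).
.dcsOnSubset <- function(plan, probe, medium, lambda, hardware, simGrid,
                         epsRel, candidates) {
    par <- .checkGaussianIso(probe, medium)
    lat <- .lattice(plan, simGrid)
    ev <- scanEvents(plan)
    keepIdx <- which(candidates)
    sub <- ev[keepIdx, , drop = FALSE]
    pp <- .probePixels(sub, lat)
    slotLen <- plan@dwell + plan@settle
    res <- lag_dcs_cpp(pp$ix, pp$iy, lat$nxp, lat$nyp,
                       par$Q0, par$D, par$Ds, plan@dwell, slotLen,
                       lat$pix^2, lambda, hardware == "beam_blanker", epsRel)
    sel <- rep(FALSE, nrow(ev))
    sel[keepIdx[as.logical(res$selected)]] <- TRUE
    mask <- new("SubsamplingMask", s = sel, strategy = "DCS",
                hardware = hardware, seed = NA_integer_)
    chi <- .fieldFromVec(res$chi, lat,
                         metadata = list(kind = "PM-CDD", gmcdd = res$gmcdd))
    new("DCSResult", mask = mask, achievedGmcdd = res$gmcdd,
        samplingRatio = sum(sel) / length(sel), lambda = lambda, chi = chi)
}

#' DCS efficiency curve
#'
#' Runs [dcsDesign()] across a grid of thresholds and records the sampling
#' ratio and the GM-CDD of each designed mask, normalised by the full-scan
#' GM-CDD, for blanker-vs-generator comparisons.
#'
#' @inheritParams dcsDesign
#' @param lambdaGrid Thresholds, u/nm^2.
#' @param gmcddFull Optional precomputed full-scan GM-CDD (computed if
#'   missing).
#' @return `data.frame(lambda, ratio, m, gmcdd, normGmcdd, hardware)`.
#' @export
dcsEfficiencyCurve <- function(plan, probe, medium, lambdaGrid,
                               hardware = c("beam_blanker", "scan_generator"),
                               simGrid = simulationGrid(), epsRel = 1e-9,
                               gmcddFull = NULL) {
    hardware <- match.arg(hardware)
    if (is.null(gmcddFull))
        gmcddFull <- gmcdd(plan, probe, medium, simGrid = simGrid,
                           epsRel = epsRel)$value
    rows <- lapply(lambdaGrid, function(lam) {
        d <- dcsDesign(plan, probe, medium, lam, hardware = hardware,
                       simGrid = simGrid, epsRel = epsRel)
        data.frame(lambda = lam, ratio = d@samplingRatio,
                   m = maskSize(d@mask), gmcdd = d@achievedGmcdd,
                   normGmcdd = d@achievedGmcdd / gmcddFull,
                   hardware = hardware)
    })
    do.call(rbind, rows)
}
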