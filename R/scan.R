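## Scan trajectories and timing.

#' Generate a scan trajectory
#'
#' Returns the visiting order of all grid nodes as a data.frame with 0-based
#' `row`/`col` indices, one row per probe in scan order.
#'
#' Supported trajectories:
#' * `raster`: row-major, every row left to right.
#' * `snake`: row-major with alternating row direction.
#' * `random`: seeded uniform permutation of all nodes.
#' * `alternating`: order-`kappa` interleave; pass (a, b) of the
#'   `kappa x kappa` offset grid (row-major over offsets) visits nodes
#'   `(a + kappa m, b + kappa n)` in raster order. `kappa = 1` reduces to
#'   raster.
#' * `custom`: caller-supplied `order` (data.frame or matrix of 0-based
#'   row/col), accepted verbatim after a bijection check.
#'
#' @param grid A [ScanGrid-class].
#' @param trajectory Trajectory name.
#' @param kappa Alternating-scan order (>= 1).
#' @param seed Integer seed for `random`.
#' @param order Node order for `custom`.
#' @return `data.frame(row, col)` covering every node exactly once.
#' @examples
#' makeTrajectory(scanGrid(2, 2), "raster")
#' @export
makeTrajectory <- function(grid,
                           trajectory = c("raster", "snake", "random",
                                          "alternating", "custom"),
                           kappa = 1L, seed = 1L, order = NULL) {
    trajectory <- match.arg(trajectory)
    nx <- grid@nx; ny <- grid@ny
    rows <- function(r) data.frame(row = r, col = 0:(nx - 1L))
    out <- switch(trajectory,
        raster = do.call(rbind, lapply(0:(ny - 1L), rows)),
        snake = do.call(rbind, lapply(0:(ny - 1L), function(r) {
            d <- rows(r)
            if (r %% 2L == 1L) d$col <- rev(d$col)
            d
        })),
        random = {
            d <- do.call(rbind, lapply(0:(ny - 1L), rows))
            set.seed(seed)
            d[sample.int(nrow(d)), , drop = FALSE]
        },
        alternating = {
            kappa <- as.integer(kappa)
            if (kappa < 1L || kappa > nx || kappa > ny)
                stop("kappa must be in [1, min(nx, ny)]")
            blocks <- list()
            for (a in 0:(kappa - 1L)) {          # row offset
                for (b in 0:(kappa - 1L)) {      # col offset
                    rr <- seq(a, ny - 1L, by = kappa)
                    cc <- seq(b, nx - 1L, by = kappa)
                    blocks[[length(blocks) + 1L]] <-
                        data.frame(row = rep(rr, each = length(cc)),
                                   col = rep(cc, times = length(rr)))
                }
            }
            do.call(rbind, blocks)
        },
        custom = {
            if (is.null(order)) stop("custom trajectory requires 'order'")
            d <- as.data.frame(order)
            names(d)[1:2] <- c("row", "col")
            d[, c("row", "col")]
        })
    rownames(out) <- NULL
    if (nrow(out) != nx * ny ||
        anyDuplicated(out) ||
        any(out$row < 0 | out$row >= ny | out$col < 0 | out$col >= nx))
        stop("trajectory must be a bijection onto the grid nodes")
    out
}

#' Construct a scan plan
#'
#' Builds the ordered probe-event table for a trajectory over `grid` with
#' constant dwell and settling time: probe i is activated at
#' `t_i = (i - 1) (dwell + settle)` for dwell `tau_i = dwell`.
#'
#' @inheritParams makeTrajectory
#' @param dwell Dwell time per probe, s.
#' @param settle Settling/blanking time between probes, s.
#' @return A [ScanPlan-class].
#' @examples
#' scanPlan(scanGrid(3, 3), dwell = 1e-5)
#' @export
scanPlan <- function(grid, trajectory = "raster", dwell = 10e-6, settle = 0,
                     kappa = 1L, seed = 1L, order = NULL) {
    traj <- makeTrajectory(grid, trajectory, kappa = kappa, seed = seed,
                           order = order)
    n <- nrow(traj)
    slotLen <- dwell + settle
    ev <- data.frame(index = seq_len(n),
                     row = traj$row, col = traj$col,
                     x = grid@origin[1] + traj$col * grid@step,
                     y = grid@origin[2] - traj$row * grid@step,
                     t = (seq_len(n) - 1) * slotLen,
                     tau = dwell,
                     slot = seq_len(n) - 1L)
    new("ScanPlan", grid = grid, events = ev, trajectory = trajectory,
        kappa = as.integer(kappa), dwell = dwell, settle = settle)
}

setMethod("show", "ScanPlan", function(object) {
    cat(sprintf(
        "ScanPlan: %s scan of %d probes (%d x %d), dwell %g s, settle %g s\n",
        object@trajectory, nrow(object@events), object@grid@nx,
        object@grid@ny, object@dwell, object@settle))
})

#' @describeIn ScanPlan-class Number of probe positions N.
#' @param object A `ScanPlan`.
#' @export
nProbes <- function(object) nrow(object@events)

#' @describeIn ScanPlan-class The probe-event table.
#' @export
scanEvents <- function(object) object@events

#' Full (all-ones) mask
#'
#' @param plan A [ScanPlan-class].
#' @return A [SubsamplingMask-class] selecting every probe.
#' @export
fullMask <- function(plan) {
    new("SubsamplingMask", s = rep(TRUE, nProbes(plan)), strategy = "full",
        hardware = "beam_blanker", seed = NA_integer_)
}

#' Uniform density sampling (UDS) mask
#'
#' Selects exactly `round(ratio * N)` probes uniformly at random without
#' replacement, reproducibly from `seed`.
#'
#' @param plan A [ScanPlan-class].
#' @param ratio Sampling ratio in (0, 1].
#' @param seed Integer seed.
#' @param hardware Timing model the mask will be realised with.
#' @return A [SubsamplingMask-class].
#' @export
makeUdsMask <- function(plan, ratio, seed = 1L,
                        hardware = c("beam_blanker", "scan_generator")) {
    hardware <- match.arg(hardware)
    stopifnot(ratio > 0, ratio <= 1)
    n <- nProbes(plan)
    m <- round(ratio * n)
    if (m < 1L) stop("ratio selects no probes")
    set.seed(seed)
    s <- rep(FALSE, n)
    s[sample.int(n, m)] <- TRUE
    new("SubsamplingMask", s = s, strategy = "UDS", hardware = hardware,
        seed = as.integer(seed))
}

#' Linehop mask
#'
#' `L = round(ratio * ny)` lanes each sample exactly one pixel per column;
#' lanes start at equally spaced rows and move by a seeded -1/0/+1 row step
#' between consecutive columns, clamped to the grid. Collisions between
#' lanes within a column are resampled (bounded retries, then shifted
#' deterministically to the nearest free row).
#'
#' @inheritParams makeUdsMask
#' @return A [SubsamplingMask-class] (in the scan order of `plan`, which must
#'   be a raster plan for the column structure to be meaningful).
#' @export
makeLinehopMask <- function(plan, ratio, seed = 1L,
                            hardware = c("scan_generator", "beam_blanker")) {
    hardware <- match.arg(hardware)
    stopifnot(ratio > 0, ratio <= 1)
    nx <- plan@grid@nx; ny <- plan@grid@ny
    L <- round(ratio * ny)
    if (L < 1L) stop("ratio yields no lanes")
    set.seed(seed)
    sel <- matrix(FALSE, nrow = ny, ncol = nx)   # [row, col]
    prev <- as.integer(floor((seq_len(L) - 1L) * ny / L))
    for (cc in seq_len(nx)) {
        taken <- rep(FALSE, ny)
        cur <- integer(L)
        for (l in seq_len(L)) {
            ok <- FALSE
            for (try in 1:20) {
                cand <- prev[l] + sample(c(-1L, 0L, 1L), 1L)
                cand <- min(max(cand, 0L), ny - 1L)
                if (!taken[cand + 1L]) { ok <- TRUE; break }
            }
            if (!ok) {  # deterministic shift to nearest free row within +/-1
                for (cand in unique(pmin(pmax(prev[l] + c(0L, -1L, 1L), 0L),
                                         ny - 1L))) {
                    if (!taken[cand + 1L]) { ok <- TRUE; break }
                }
            }
            if (!ok) {  # fall back to any free row (degenerate ratio ~ 1)
                cand <- which(!taken)[1L] - 1L
            }
            taken[cand + 1L] <- TRUE
            cur[l] <- cand
        }
        sel[cur + 1L, cc] <- TRUE
        prev <- cur
    }
    ev <- scanEvents(plan)
    s <- sel[cbind(ev$row + 1L, ev$col + 1L)]
    new("SubsamplingMask", s = s, strategy = "linehop", hardware = hardware,
        seed = as.integer(seed))
}

#' Resolve the activation schedule of a (possibly subsampled) scan
#'
#' Applies the mask's hardware timing model to the plan. Under a beam
#' blanker every slot, selected or not, advances time by `dwell + settle`
#' and unselected slots deposit nothing; under a scan generator only
#' selected slots exist, consecutive with spacing `dwell + settle`. With
#' `settle = 0` the total acquisition times are `N tau` and `M tau`
#' respectively.
#'
#' Linehop masks are realised as their own connected scan path (all lanes
#' advance column by column, lanes ordered by row within a column), so the
#' probe sequence contains no unselected slots and the blanker and generator
#' timings coincide; in particular the two hardware models yield identical
#' CDD fields at zero settling time.
#'
#' @param plan A [ScanPlan-class].
#' @param mask A [SubsamplingMask-class] (default: full mask).
#' @return `data.frame` of the selected probe events with resolved `t` and
#'   `slot` columns, in activation order.
#' @export
scheduleEvents <- function(plan, mask = NULL) {
    ev <- scanEvents(plan)
    if (is.null(mask)) return(ev)
    stopifnot(length(mask@s) == nrow(ev))
    out <- ev[mask@s, , drop = FALSE]
    slotLen <- plan@dwell + plan@settle
    if (mask@strategy == "linehop") {
        out <- out[order(out$col, out$row), , drop = FALSE]
        out$slot <- seq_len(nrow(out)) - 1L
        out$t <- out$slot * slotLen
    } else if (mask@hardware == "scan_generator") {
        out$slot <- seq_len(nrow(out)) - 1L
        out$t <- out$slot * slotLen
    }
    rownames(out) <- NULL
    out
}

#' Total acquisition time of a (possibly subsampled) scan
#'
#' @inheritParams scheduleEvents
#' @return Time in s from first activation to the end of the last dwell,
#'   including trailing settle time of earlier slots.
#' @export
acquisitionTime <- function(plan, mask = NULL) {
    sch <- scheduleEvents(plan, mask)
    if (!is.null(mask) && mask@hardware == "beam_blanker") {
        n <- nProbes(plan)
        (n - 1L) * (plan@dwell + plan@settle) + plan@dwell
    } else {
        max(sch$t) + plan@dwell
    }
}
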