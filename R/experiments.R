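## Pre-canned simulation campaigns: baseline, parameter sweeps, compressive
## Monte-Carlo runs and deterministic test fixtures.

.writeSummary <- function(summary, config, outDir, name) {
    if (is.null(outDir)) return(invisible(NULL))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    payload <- list(summary = summary,
                    config = configAsList(config),
                    units = list(density = "u/nm^2", amount = "u",
                                 length = "nm", time = "s"),
                    package = as.character(packageVersion("stemdiff")))
    jsonlite::write_json(payload, file.path(outDir, paste0(name, ".json")),
                         auto_unbox = TRUE, digits = NA)
    invisible(NULL)
}

#' Run the baseline acquisition
#'
#' Computes the end-of-scan PM-CDD of the configured scan, its global
#' maximum, the single-probe peak (M-BDD), the deposited total and the
#' GM-CDD / M-BDD ratio. With `outDir` set, writes the PM-CDD map (CSV and
#' 32-bit float TIFF) and a JSON summary with a provenance header.
#'
#' @param config An [ExperimentConfig-class].
#' @param outDir Optional output directory.
#' @param mask Optional [SubsamplingMask-class].
#' @return A list with `summary` (named numerics) and `chi` (the PM-CDD
#'   [FieldMap-class]).
#' @examples
#' \donttest{
#' res <- runBaseline(experimentConfig(nx = 6, ny = 6, margin = 2))
#' res$summary
#' }
#' @export
runBaseline <- function(config, outDir = NULL, mask = NULL) {
    plan <- configPlan(config)
    chi <- pmcdd(plan, config@probe, config@medium, mask = mask,
                 simGrid = config@simGrid)
    gm <- gmcdd(chi)
    ab <- abddMax(config@probe@Q0, config@medium@D[1], config@probe@Ds[1],
                  config@dwell)
    tot <- depositedTotals(plan, config@probe, mask)
    summary <- list(gmcdd = gm$value, abddMax = ab,
                    ratioGmcddAbdd = gm$value / ab,
                    Qstem = tot[["Qstem"]], Qcstem = tot[["Qcstem"]],
                    acquisitionTime = acquisitionTime(plan, mask),
                    nProbes = nProbes(plan),
                    gridPixels = dim(chi@values))
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        writeFieldMap(chi, file.path(outDir, "pmcdd.csv"))
        writeFieldMap(chi, file.path(outDir, "pmcdd.tif"))
        .writeSummary(summary, config, outDir, "baseline")
    }
    list(summary = summary, chi = chi)
}

#' Parameter sweeps of the PM-CDD
#'
#' Re-runs the configured scan with one parameter varied, mirroring the
#' canonical campaign grids (diffusion coefficient, probe width, scan step,
#' dwell time, blanking ratio, trajectory, alternating order).
#'
#' @inheritParams runBaseline
#' @param parameter One of `"D"`, `"Ds"`, `"step"`, `"dwell"`,
#'   `"settleRatio"` (settle/dwell), `"trajectory"`, `"kappa"`.
#' @param values Values to sweep; defaults to the canonical grid for the
#'   chosen parameter.
#' @return `data.frame` with one row per value: `parameter`, `value`,
#'   `gmcdd`, `abddMax`, `Qstem`.
#' @export
runSweep <- function(config, parameter, values = NULL, outDir = NULL) {
    canonical <- list(
        D = c(0.1, 1, 10, 100),
        Ds = c(1e-4, 1e-3, 1e-2, 1e-1),
        step = c(5e-4, 5e-3, 5e-2, 5e-1),
        dwell = c(0.1, 1, 10, 100) * 1e-6,
        settleRatio = c(0, 0.1, 1, 10),
        trajectory = c("raster", "snake", "random", "alternating"),
        kappa = c(1, 2, 4, 6, 8, 10, 12, 14))
    if (!parameter %in% names(canonical))
        stop("unknown sweep parameter: ", parameter)
    if (is.null(values)) values <- canonical[[parameter]]
    rows <- lapply(seq_along(values), function(i) {
        v <- values[[i]]
        cfg <- config
        switch(parameter,
            D = { cfg@medium <- diffusionMedium(v) },
            Ds = { cfg@probe <- sourceProfile("gaussian",
                                              Q0 = config@probe@Q0, Ds = v) },
            step = { cfg@grid <- scanGrid(config@grid@nx, config@grid@ny,
                                          step = v) },
            dwell = { cfg@dwell <- v },
            settleRatio = { cfg@settle <- v * config@dwell },
            trajectory = { cfg@trajectory <- v },
            kappa = { cfg@trajectory <- "alternating"
                      cfg@kappa <- as.integer(v) })
        res <- runBaseline(cfg,
                           outDir = if (is.null(outDir)) NULL
                                    else file.path(outDir,
                                                   paste0(parameter, "_", i)))
        data.frame(parameter = parameter, value = as.character(v),
                   gmcdd = res$summary$gmcdd, abddMax = res$summary$abddMax,
                   Qstem = res$summary$Qstem)
    })
    do.call(rbind, rows)
}

#' Compressive-scan Monte-Carlo campaign
#'
#' Draws `trials` seeded masks per sampling ratio, computes the GM-CDD of
#' each compressive scan and reports it normalised by the full-scan GM-CDD.
#'
#' @inheritParams runBaseline
#' @param strategy `"UDS"` or `"linehop"`.
#' @param hardware Timing model for the masks.
#' @param ratios Sampling ratios (fractions; canonical grids by strategy).
#' @param trials Monte-Carlo trials per ratio.
#' @return `data.frame(strategy, hardware, ratio, trial, maskSeed, m, gmcdd,
#'   normGmcdd)`; the full-scan GM-CDD is attached as
#'   `attr(, "gmcddFull")`.
#' @export
runCompressive <- function(config, strategy = c("UDS", "linehop"),
                           hardware = c("beam_blanker", "scan_generator"),
                           ratios = NULL, trials = 10L, outDir = NULL) {
    strategy <- match.arg(strategy)
    hardware <- match.arg(hardware)
    if (is.null(ratios))
        ratios <- if (strategy == "UDS")
            c(0.05, 0.10, 0.20, 0.30, 0.40, 0.50)
        else c(0.05, 0.10, 0.20, 0.25, 1/3, 0.50)
    plan <- configPlan(config)
    gmFull <- gmcdd(plan, config@probe, config@medium,
                    simGrid = config@simGrid)$value
    set.seed(config@seed)
    maskSeeds <- sample.int(1e6, trials)
    rows <- list()
    for (r in ratios) {
        for (k in seq_len(trials)) {
            mask <- if (strategy == "UDS")
                makeUdsMask(plan, r, seed = maskSeeds[k], hardware = hardware)
            else
                makeLinehopMask(plan, r, seed = maskSeeds[k],
                                hardware = hardware)
            gm <- gmcdd(plan, config@probe, config@medium, mask = mask,
                        simGrid = config@simGrid)$value
            rows[[length(rows) + 1L]] <-
                data.frame(strategy = strategy, hardware = hardware,
                           ratio = r, trial = k, maskSeed = maskSeeds[k],
                           m = maskSize(mask), gmcdd = gm,
                           normGmcdd = gm / gmFull)
        }
    }
    out <- do.call(rbind, rows)
    attr(out, "gmcddFull") <- gmFull
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        write.csv(out, file.path(outDir,
                                 paste0("compressive_", strategy, "_",
                                        hardware, ".csv")),
                  row.names = FALSE)
        .writeSummary(list(gmcddFull = gmFull), config, outDir,
                      paste0("compressive_", strategy, "_", hardware))
    }
    out
}

#' Deterministic test fixtures
#'
#' Small fully specified configurations for fast deterministic runs:
#' `single_probe` (one probe, baseline physics), `two_probe` (1 x 2),
#' `tiny_3x3` (3 x 3 at reduced spatial resolution) and `baseline_mini`
#' (10 x 10, otherwise baseline).
#'
#' @param name Fixture name.
#' @return An [ExperimentConfig-class].
#' @export
generateFixture <- function(name = c("single_probe", "two_probe", "tiny_3x3",
                                     "baseline_mini")) {
    name <- match.arg(name)
    switch(name,
        single_probe = experimentConfig(nx = 1L, ny = 1L, margin = 5L),
        two_probe = experimentConfig(nx = 2L, ny = 1L, margin = 5L),
        tiny_3x3 = experimentConfig(nx = 3L, ny = 3L, subpixels = 4L,
                                    margin = 2L),
        baseline_mini = experimentConfig(nx = 10L, ny = 10L))
}
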