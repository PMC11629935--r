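## Experiment configuration: bundles scan, probe, medium and grid settings.
## Defaults are the baseline acquisition: 20 x 20 raster, 0.05 nm step,
## 10 us dwell, zero settling, Ds = 0.01 nm^2, D = 10 nm^2/s,
## Q0 = 63.45 Mu/s.

#' Experiment configuration
#'
#' @slot grid A [ScanGrid-class].
#' @slot trajectory Trajectory name.
#' @slot kappa Alternating order.
#' @slot dwell Dwell time, s.
#' @slot settle Settling/blanking time, s.
#' @slot probe A Gaussian [SourceProfile-class].
#' @slot medium A [DiffusionMedium-class].
#' @slot simGrid A [SimulationGrid-class].
#' @slot seed Integer seed for stochastic components.
#' @export
setClass("ExperimentConfig",
         representation(grid = "ScanGrid", trajectory = "character",
                        kappa = "integer", dwell = "numeric",
                        settle = "numeric", probe = "SourceProfile",
                        medium = "DiffusionMedium",
                        simGrid = "SimulationGrid", seed = "integer"))

#' Construct an experiment configuration
#'
#' All arguments default to the baseline acquisition.
#'
#' @param nx,ny Probe grid size.
#' @param step Scan step, nm.
#' @param trajectory,kappa Trajectory and alternating order.
#' @param dwell Dwell time, s.
#' @param settle Settling/blanking time, s.
#' @param Ds Probe width parameter, nm^2.
#' @param Q0 Species rate, u/s.
#' @param D Diffusion coefficient, nm^2/s.
#' @param subpixels,NT,margin Simulation grid settings.
#' @param seed Integer seed.
#' @return An [ExperimentConfig-class].
#' @examples
#' experimentConfig()          # baseline
#' experimentConfig(nx = 10, ny = 10, dwell = 1e-6)
#' @export
experimentConfig <- function(nx = 20L, ny = 20L, step = 0.05,
                             trajectory = "raster", kappa = 1L,
                             dwell = 10e-6, settle = 0,
                             Ds = 0.01, Q0 = 63.45e6, D = 10,
                             subpixels = 10L, NT = 1L, margin = 5L,
                             seed = 1L) {
    new("ExperimentConfig",
        grid = scanGrid(nx, ny, step = step),
        trajectory = trajectory, kappa = as.integer(kappa),
        dwell = dwell, settle = settle,
        probe = sourceProfile("gaussian", Q0 = Q0, Ds = Ds),
        medium = diffusionMedium(D),
        simGrid = simulationGrid(subpixels, NT, margin),
        seed = as.integer(seed))
}

setMethod("show", "ExperimentConfig", function(object) {
    cat(sprintf(
        "ExperimentConfig: %dx%d %s scan, step %g nm, dwell %g us, settle %g us\n",
        object@grid@nx, object@grid@ny, object@trajectory, object@grid@step,
        object@dwell * 1e6, object@settle * 1e6))
    cat(sprintf("  Ds = %g nm^2, D = %g nm^2/s, Q0 = %g u/s, seed = %d\n",
                object@probe@Ds[1], object@medium@D[1], object@probe@Q0,
                object@seed))
})

#' @describeIn ExperimentConfig-class Build the [ScanPlan-class] of a
#'   configuration.
#' @param config An `ExperimentConfig`.
#' @export
configPlan <- function(config) {
    scanPlan(config@grid, config@trajectory, dwell = config@dwell,
             settle = config@settle, kappa = config@kappa,
             seed = config@seed)
}

#' @describeIn ExperimentConfig-class Plain-list view (used for provenance
#'   headers in serialized outputs).
#' @export
configAsList <- function(config) {
    list(grid = list(nx = config@grid@nx, ny = config@grid@ny,
                     step_nm = config@grid@step,
                     origin_nm = config@grid@origin),
         trajectory = config@trajectory, kappa = config@kappa,
         dwell_us = config@dwell * 1e6, settle_us = config@settle * 1e6,
         probe = list(Ds_nm2 = config@probe@Ds[1],
                      Q0_Mu_s = config@probe@Q0 / 1e6),
         medium = list(D_nm2_s = config@medium@D[1]),
         sim = list(subpixels = config@simGrid@subpixels,
                    NT = config@simGrid@NT,
                    margin_steps = config@simGrid@margin),
         seed = config@seed)
}

#' Read an experiment configuration from YAML
#'
#' Keys carry explicit unit suffixes and are converted to the internal
#' u/nm/s units at the boundary. Recognised keys (all optional, defaults =
#' baseline): `grid: {nx, ny, step_nm}`, `trajectory`, `kappa`, `dwell_us`,
#' `settle_us`, `probe: {Ds_nm2, Q0_Mu_s}`, `medium: {D_nm2_s}`,
#' `sim: {subpixels, NT, margin_steps}`, `seed`.
#'
#' @param path YAML file.
#' @return An [ExperimentConfig-class].
#' @export
readExperimentConfig <- function(path) {
    y <- yaml::read_yaml(path)
    num <- function(x, field) {
        if (is.null(x)) return(NULL)
        if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
            stop("config field '", field, "' must be a single finite number")
        x
    }
    args <- list()
    args$nx <- num(y$grid$nx, "grid.nx")
    args$ny <- num(y$grid$ny, "grid.ny")
    args$step <- num(y$grid$step_nm, "grid.step_nm")
    args$trajectory <- y$trajectory
    args$kappa <- num(y$kappa, "kappa")
    if (!is.null(y$dwell_us)) args$dwell <- num(y$dwell_us, "dwell_us") * 1e-6
    if (!is.null(y$settle_us)) args$settle <- num(y$settle_us, "settle_us") * 1e-6
    args$Ds <- num(y$probe$Ds_nm2, "probe.Ds_nm2")
    if (!is.null(y$probe$Q0_Mu_s))
        args$Q0 <- num(y$probe$Q0_Mu_s, "probe.Q0_Mu_s") * 1e6
    args$D <- num(y$medium$D_nm2_s, "medium.D_nm2_s")
    args$subpixels <- num(y$sim$subpixels, "sim.subpixels")
    args$NT <- num(y$sim$NT, "sim.NT")
    args$margin <- num(y$sim$margin_steps, "sim.margin_steps")
    args$seed <- num(y$seed, "seed")
    do.call(experimentConfig, args[!vapply(args, is.null, logical(1))])
}
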