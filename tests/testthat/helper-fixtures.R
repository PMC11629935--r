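# Shared fixtures and slow-result cache for the suite.

# Baseline acquisition parameters (20x20 raster, 0.05 nm step, 10 us dwell,
# Ds = 0.01 nm^2, D = 10 nm^2/s, Q0 = 63.45 Mu/s).
table1 <- list(Q0 = 63.45e6, D = 10, Ds = 0.01, tau = 10e-6, step = 0.05,
               n = 20L)

baselineProbe <- function() sourceProfile("gaussian", Q0 = table1$Q0,
                                          Ds = table1$Ds)
baselineMedium <- function() diffusionMedium(table1$D)
baselinePlan <- function(trajectory = "raster", settle = 0, seed = 1L)
    scanPlan(scanGrid(table1$n, table1$n, step = table1$step),
             trajectory, dwell = table1$tau, settle = settle, seed = seed)

gaussEvent <- function(Q0 = 1, Ds = 0.1, r0 = c(0, 0), t0 = 0, tau = 1)
    sourceEvent(sourceProfile("gaussian", Q0 = Q0, Ds = Ds), r0, t0, tau)

# Tiny plan on lattice-friendly geometry for fast end-to-end runs.
tinyPlan <- function(n = 3L, dwell = 1e-5, settle = 0, trajectory = "raster")
    scanPlan(scanGrid(n, n, step = 0.05), trajectory, dwell = dwell,
             settle = settle)
tinyGrid <- function(sub = 4L, margin = 2L) simulationGrid(sub, 1L, margin)

# Radial plane integral 2*pi * int r f(r) dr for radially symmetric fields.
planeIntegralRadial <- function(f, upper, relTol = 1e-7)
    2 * pi * integrate(function(r) r * vapply(r, f, numeric(1)), 0, upper,
                       rel.tol = relTol, abs.tol = 0,
                       subdivisions = 400L)$value

# Fixed Gauss-Legendre panels: cheap and accurate when f is expensive and
# smooth except for a kink at r = edge (a source boundary).
glSum <- function(f, a, b, n) {
    gl <- pracma::gaussLegendre(n, a, b)
    sum(gl$w * vapply(gl$x, f, numeric(1)))
}

planeIntegralRadialGL <- function(f, edge, upper) {
    g <- function(r) r * f(r)
    2 * pi * (glSum(g, 0, edge, 48L) + glSum(g, edge, upper, 200L))
}

# Quadrant tensor Gauss-Legendre integral of a symmetric 2-D field with an
# axis kink at x,y = edge; fEval takes an n x 2 matrix of points.
quadrantIntegralGL <- function(fEval, edge, upper) {
    g1 <- pracma::gaussLegendre(24L, 0, edge)
    g2 <- pracma::gaussLegendre(96L, edge, upper)
    x <- c(g1$x, g2$x); w <- c(g1$w, g2$w)
    pts <- as.matrix(expand.grid(x = x, y = x))
    wts <- as.numeric(outer(w, w))
    4 * sum(wts * fEval(pts))
}

# Cache for results shared between expensive tests (full baseline runs).
.testCache <- new.env(parent = emptyenv())

cachedBaselineChi <- function() {
    if (is.null(.testCache$chi))
        .testCache$chi <- pmcdd(baselinePlan(), baselineProbe(),
                                baselineMedium())
    .testCache$chi
}

cachedBaselineGm <- function() gmcdd(cachedBaselineChi())$value
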