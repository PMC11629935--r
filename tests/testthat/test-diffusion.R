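test_that("instantaneous point source follows the anisotropic heat kernel", {
    md <- diffusionMedium(1)
    ev <- sourceEvent(sourceProfile("instantaneous_point", Q0 = 4 * pi),
                      r0 = c(0, 0), t0 = 0)
    # unit constants: Q0/(4 pi D t) e^0 = 1 at the source
    expect_equal(phiInstantaneousPoint(c(0, 0), 1, ev, md), 1.0)
    # conservation: radial plane integral returns Q0 at several times
    for (t in c(0.2, 1, 3)) {
        got <- planeIntegralRadial(
            function(r) phiInstantaneousPoint(c(r, 0), t, ev, md),
            sqrt(4 * t) * 8)
        expect_equal(got, 4 * pi, tolerance = 1e-7)
    }
    # anisotropy D = diag(0.25, 0.5): (1,0) and (0, sqrt(2)) give equal
    # quadratic forms 1/0.25 = 2/0.5
    mda <- diffusionMedium(c(0.25, 0.5))
    for (t in c(0.5, 2))
        expect_equal(phiInstantaneousPoint(c(1, 0), t, ev, mda),
                     phiInstantaneousPoint(c(0, sqrt(2)), t, ev, mda))
    # not yet active
    expect_error(phiInstantaneousPoint(c(0, 0), 0, ev, md), "not yet active")
    expect_error(diffusionMedium(c(1, -1)), "positive")
})

test_that("continuous point source: log branch, continuity, isotropy", {
    md <- diffusionMedium(1)
    ev <- sourceEvent(sourceProfile("continuous_point", Q0 = 4 * pi),
                      r0 = c(0, 0), t0 = 0, tau = 1)
    # off-phase value at the source with unit constants: log((t-t0)/(t-t0-tau))
    expect_equal(phiContinuousPoint(c(0, 0), 2, ev, md), log(2))
    # on-phase at the source is +Inf; before activation it is 0
    expect_identical(phiContinuousPoint(c(0, 0), 0.5, ev, md), Inf)
    expect_identical(phiContinuousPoint(c(0.3, 0), -0.1, ev, md), 0)
    # branch continuity at t = t0 + tau for off-source points
    for (r in c(0.05, 0.4, 1.5)) {
        lo <- phiContinuousPoint(c(r, 0), 1 - 1e-12, ev, md)
        hi <- phiContinuousPoint(c(r, 0), 1 + 1e-12, ev, md)
        expect_equal(lo, hi, tolerance = 1e-6)
    }
    # isotropic scalar equals anisotropic representation with equal entries
    mdI <- diffusionMedium(0.25)
    mdA <- diffusionMedium(c(0.25, 0.25))
    pts <- rbind(c(0.2, 0.1), c(-1, 0.5), c(0, 2))
    expect_identical(phiContinuousPoint(pts, 1.4, ev, mdI),
                     phiContinuousPoint(pts, 1.4, ev, mdA))
})

test_that("circular disc source: conservation, point limit, symmetry", {
    md <- diffusionMedium(0.25)
    ev <- sourceEvent(sourceProfile("circular_disc", Q0 = 2, rs = 0.2),
                      r0 = c(0, 0), t0 = 0, tau = 1)
    # conservation at dwell end: plane integral = Q0 * tau
    got <- planeIntegralRadialGL(
        function(r) phiCircularDisc(c(r, 0), 1, ev, md, relTol = 1e-7),
        edge = 0.2, upper = 0.2 + 8 * sqrt(4 * 0.25))
    expect_equal(got, 2 * 1, tolerance = 1e-4)
    # rs -> 0 converges to the continuous point source off the centre
    evP <- sourceEvent(sourceProfile("continuous_point", Q0 = 2),
                       r0 = c(0, 0), t0 = 0, tau = 1)
    target <- phiContinuousPoint(c(0.5, 0), 1.3, evP, md)
    err <- vapply(c(0.2, 0.1, 0.05), function(rs) {
        evR <- sourceEvent(sourceProfile("circular_disc", Q0 = 2, rs = rs),
                           r0 = c(0, 0), t0 = 0, tau = 1)
        abs(phiCircularDisc(c(0.5, 0), 1.3, evR, md) - target) / target
    }, numeric(1))
    expect_true(all(diff(err) < 0))          # monotone convergence
    expect_lt(err[3], 1e-2)
    # rotational symmetry at equal radius
    r <- 0.37
    ang <- c(0.3, 1.2, 2.5, 4.4)
    vals <- phiCircularDisc(cbind(r * cos(ang), r * sin(ang)), 0.8, ev, md)
    expect_equal(max(vals) - min(vals), 0, tolerance = 1e-7 * max(vals))
    # anisotropic medium rejected
    expect_error(phiCircularDisc(c(0, 0), 1, ev, diffusionMedium(c(1, 2))),
                 "isotropic")
})

test_that("square disc source: conservation, reflection symmetry", {
    md <- diffusionMedium(0.25)
    ev <- sourceEvent(sourceProfile("square_disc", Q0 = 2, side = 0.2),
                      r0 = c(0, 0), t0 = 0, tau = 1)
    # conservation at dwell end via one-quadrant tensor quadrature
    L <- 0.2 + 7 * sqrt(4 * 0.25)
    got <- quadrantIntegralGL(
        function(pts) phiSquareDisc(pts, 1, ev, md, relTol = 1e-7),
        edge = 0.2, upper = L)
    expect_equal(got, 2, tolerance = 1e-4)
    # 4-fold reflection symmetry about the centre
    p <- c(0.31, 0.17)
    vals <- phiSquareDisc(rbind(p, c(-p[1], p[2]), c(p[1], -p[2]), -p),
                          0.6, ev, md)
    expect_equal(max(vals) - min(vals), 0, tolerance = 1e-8 * max(vals))
})

test_that("gaussian source: closed forms, branches, point limit", {
    Ds <- 0.1; D <- 0.25
    md <- diffusionMedium(D)
    ev <- gaussEvent(Q0 = 4 * pi * D, Ds = Ds, tau = 1)
    # at the source, on phase, t - t0 = Ds/(2D) forces a log(2)
    expect_equal(phiGaussian(c(0, 0), Ds / (2 * D), ev, md), log(2))
    # branch continuity at dwell end, on and off the source
    for (p in list(c(0, 0), c(0.2, -0.1), c(1.5, 0.3))) {
        lo <- phiGaussian(p, 1 - 1e-12, ev, md)
        hi <- phiGaussian(p, 1 + 1e-12, ev, md)
        expect_equal(lo, hi, tolerance = 1e-6)
    }
    # Ds -> 0 converges to the continuous point source off the centre
    evP <- sourceEvent(sourceProfile("continuous_point", Q0 = 1),
                       c(0, 0), 0, 1)
    target <- phiContinuousPoint(c(0.4, 0), 1.5, evP, md)
    err <- vapply(c(1e-2, 1e-3, 1e-4), function(ds)
        abs(phiGaussian(c(0.4, 0), 1.5, gaussEvent(Q0 = 1, Ds = ds), md) -
            target) / target, numeric(1))
    expect_true(all(diff(err) < 0))
    expect_lt(err[3], 1e-3)
    # conservation mid-dwell: plane integral = Q0 * t
    ev1 <- gaussEvent(Q0 = 3, Ds = 0.1, tau = 1)
    got <- planeIntegralRadial(function(r) phiGaussian(c(r, 0), 0.5, ev1, md),
                               sqrt(2 * 0.1 + 4 * D * 0.5) * 10)
    expect_equal(got, 3 * 0.5, tolerance = 1e-6)
    # linearity in Q0 is exact
    expect_identical(phiGaussian(c(0.3, 0.2), 0.7,
                                 gaussEvent(Q0 = 2, Ds = 0.1), md),
                     2 * phiGaussian(c(0.3, 0.2), 0.7,
                                     gaussEvent(Q0 = 1, Ds = 0.1), md))
    expect_error(gaussEvent(Ds = -1), "positive")
})

test_that("anisotropic gaussian quadrature agrees with the isotropic closed form", {
    md <- diffusionMedium(0.3)
    ev <- gaussEvent(Q0 = 1.7, Ds = 0.08, tau = 1)
    # force the anisotropic path with an epsilon-different medium
    mdA <- diffusionMedium(c(0.3, 0.3 * (1 + 1e-13)))
    pts <- rbind(c(0.25, -0.4), c(1, 0.2))
    for (t in c(0.6, 1.9))
        expect_equal(phiGaussian(pts, t, ev, mdA),
                     phiGaussian(pts, t, ev, md), tolerance = 1e-7)
})

test_that("M-BDD closed form and Corollary-1 maximality", {
    # unit constants: Q0 = 4 pi D and 2 tau / rho = 1 give log(2)
    expect_equal(abddMax(Q0 = 4 * pi, D = 1, Ds = 2, tau = 1), log(2))
    expect_identical(abddMax(1, 1, 1, 0), 0)
    # the bound dominates the field and is attained at (r0, t0 + tau)
    Q0 <- 2; D <- 0.25; Ds <- 0.05; tau <- 1
    md <- diffusionMedium(D)
    ev <- gaussEvent(Q0 = Q0, Ds = Ds, tau = tau)
    ab <- abddMax(Q0, D, Ds, tau)
    expect_equal(phiGaussian(c(0, 0), tau, ev, md), ab)
    rr <- seq(0, 1.5, by = 0.1)
    for (t in c(0.2, 0.7, 1.0, 1.4, 3)) {
        vals <- phiGaussian(cbind(rr, 0), t, ev, md)
        expect_true(all(vals <= vals[1] + 1e-12))   # max at the source
        expect_lte(vals[1], ab + 1e-12)
    }
})

test_that("monotone behaviour in space and time (single probe)", {
    md <- diffusionMedium(0.25)
    ev <- gaussEvent(Q0 = 1, Ds = 0.05, tau = 1)
    # non-increasing in distance at a fixed on-phase time
    rr <- seq(0, 2, by = 0.05)
    vals <- phiGaussian(cbind(rr, 0), 0.6, ev, md)
    expect_true(all(diff(vals) <= 1e-15))
    # at the source: strictly increasing on phase, strictly decreasing off
    tOn <- seq(0.1, 1, by = 0.1)
    vOn <- vapply(tOn, function(t) phiGaussian(c(0, 0), t, ev, md),
                  numeric(1))
    expect_true(all(diff(vOn) > 0))
    tOff <- seq(1.1, 3, by = 0.2)
    vOff <- vapply(tOff, function(t) phiGaussian(c(0, 0), t, ev, md),
                   numeric(1))
    expect_true(all(diff(vOff) < 0))
})

test_that("asymptotic limit distributions", {
    ev <- gaussEvent(Q0 = 2, Ds = 0.1, tau = 1)
    # D -> 0: closed Gaussian forms match the full solution at tiny D
    mdSmall <- diffusionMedium(1e-6 * 0.1 / 1)
    pts <- cbind(seq(0, 1, by = 0.1), 0)
    for (t in c(0.5, 2)) {
        full <- phiGaussian(pts, t, ev, mdSmall)
        lim <- limitDistribution(pts, t, ev, regime = "D_to_zero")
        expect_equal(full, lim, tolerance = 1e-3)
    }
    # D -> Inf: identically zero
    expect_identical(limitDistribution(pts, 0.5, ev, regime = "D_to_inf"),
                     rep(0, nrow(pts)))
    # off-phase D -> 0 bump integrates to Q0 * tau
    got <- planeIntegralRadial(
        function(r) limitDistribution(c(r, 0), 2, ev, regime = "D_to_zero"),
        sqrt(0.1) * 12)
    expect_equal(got, 2, tolerance = 1e-8)
})

test_that("total deposited species follows Q0 * min(t - t0, tau)", {
    ev <- gaussEvent(Q0 = 3, Ds = 0.1, t0 = 0.5, tau = 2)
    expect_identical(totalSpecies(ev, 0.5), 0)
    expect_equal(totalSpecies(ev, 1.5), 3)
    expect_equal(totalSpecies(ev, 10), 6)
    evI <- sourceEvent(sourceProfile("instantaneous_point", Q0 = 5),
                       c(0, 0), t0 = 1)
    expect_identical(totalSpecies(evI, 1), 0)
    expect_identical(totalSpecies(evI, 2), 5)
})

test_that("superposition oracle: zero source and spot equivalences", {
    md <- diffusionMedium(0.3)
    ev0 <- gaussEvent(Q0 = 0, Ds = 0.1, tau = 1)
    expect_identical(superpositionOracle(rbind(c(0, 0), c(1, 1)), 0.7, ev0, md),
                     c(0, 0))
    # continuous point closed form vs time quadrature of the kernel, 3 radii
    evP <- sourceEvent(sourceProfile("continuous_point", Q0 = 1.3),
                       c(0, 0), 0, 1)
    for (r in c(0.1, 0.5, 1.2)) {
        a <- phiContinuousPoint(c(r, 0), 0.8, evP, md)
        b <- superpositionOracle(c(r, 0), 0.8, evP, md)
        expect_equal(a, b, tolerance = 1e-6)
    }
    # gaussian closed form vs full space-time quadrature on a small case
    evG <- gaussEvent(Q0 = 1.3, Ds = 0.1, tau = 1)
    for (t in c(0.8, 1.6)) {
        a <- phiGaussian(c(0.4, -0.2), t, evG, md)
        b <- superpositionOracle(c(0.4, -0.2), t, evG, md)
        expect_equal(a, b, tolerance = 1e-6)
    }
})

test_that("the compiled exponential integral matches an independent implementation", {
    x <- c(1e-8, 1e-4, 0.05, 0.5, 1, 1.5, 4, 20, 120, 650)
    expect_equal(expIntE1(x), pracma::expint_E1(x), tolerance = 1e-13)
    expect_identical(expIntE1(0), Inf)
    expect_identical(expIntE1(800), 0)
})
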