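test_that("ramp splitting reproduces the cool-heat-cool instrument protocol", {
    p <- paramsForTm(-336.4, 58.8)
    tr <- simulateMeltTrace(p)  # default 90-10-90-10 pattern
    curves <- splitRamps(tr)
    expect_identical(length(curves), 3L)
    expect_identical(vapply(curves, function(c) c@direction, ""),
                     c("cooling", "heating", "cooling"))
    single <- splitRamps(data.frame(temperature = seq(10, 90, 0.25),
                                    signal = 0))
    expect_identical(length(single), 1L)
    expect_identical(single[[1]]@direction, "heating")
    expect_error(splitRamps(data.frame(temperature = rep(25, 50), signal = 0)),
                 "never changes")
    # short trailing segment is discarded with a warning
    tr2 <- data.frame(temperature = c(seq(50, 10, -0.5), seq(10.5, 15, 0.5)),
                      signal = 0)
    expect_warning(cs <- splitRamps(tr2), "discarded")
    expect_identical(length(cs), 1L)
})

test_that("baseline fitting recovers exact linear plateaus and generator baselines", {
    tC <- seq(10, 90, 0.25)
    lower <- function(t) 0.001 * t + 0.5
    upper <- function(t) 0.002 * t + 0.8
    sv <- ifelse(tC <= 45, lower(tC), upper(tC))
    bl <- fitBaselines(MeltCurve(tC, sv))
    expect_equal(unname(bl@folded), c(0.001, 0.5), tolerance = 1e-9)
    expect_equal(unname(bl@unfolded), c(0.002, 0.8), tolerance = 1e-9)
    # round trip against generator baselines (noise-free, transition
    # centred so both plateaus lie inside the fitting windows)
    p <- paramsForTm(-380, 50)
    bl2 <- fitBaselines(simulateCurve(p, folded = c(2e-3, 0.55),
                                      unfolded = c(1.5e-3, 0.75)))
    expect_lt(abs(bl2@folded[1] - 2e-3) / 2e-3, 0.02)
    expect_lt(abs(bl2@unfolded[1] - 1.5e-3) / 1.5e-3, 0.02)
    # constant signal gives two flat lines
    bl3 <- fitBaselines(MeltCurve(tC, rep(1, length(tC))))
    expect_equal(unname(bl3@folded[1]), 0, tolerance = 1e-12)
    expect_equal(unname(bl3@unfolded[1]), 0, tolerance = 1e-12)
    expect_error(fitBaselines(MeltCurve(tC, sv), foldedWindow = c(10, 10.3)),
                 "degenerate")
    expect_error(fitBaselines(MeltCurve(tC, sv), windowFrac = 0.5),
                 "windowFrac")
})

test_that("folded fraction hits the limiting identities and is affine-invariant", {
    tC <- seq(10, 90, 0.25)
    bl <- new("BaselineFit", folded = c(0.001, 0.5), unfolded = c(0.002, 0.8),
              foldedWindow = c(10, 22), unfoldedWindow = c(78, 90))
    lowLine <- 0.001 * tC + 0.5
    upLine <- 0.002 * tC + 0.8
    expect_true(all(thetaValues(fractionFolded(MeltCurve(tC, lowLine), bl)) == 1))
    expect_true(all(thetaValues(fractionFolded(MeltCurve(tC, upLine), bl)) == 0))
    mid <- (lowLine + upLine) / 2
    expect_equal(thetaValues(fractionFolded(MeltCurve(tC, mid), bl)),
                 rep(0.5, length(tC)))
    # gain/offset on the signal leaves theta unchanged (baselines refitted)
    p <- paramsForTm(-300, 50)
    cv <- simulateCurve(p)
    th1 <- thetaValues(fractionFolded(cv, fitBaselines(cv)))
    cv2 <- MeltCurve(tempC(cv), 3.7 * signalValues(cv) - 1.2)
    th2 <- thetaValues(fractionFolded(cv2, fitBaselines(cv2)))
    expect_equal(th1, th2, tolerance = 1e-9)
    # coinciding baselines are rejected
    expect_error(fractionFolded(MeltCurve(tC, rep(1, length(tC))),
                                new("BaselineFit", folded = c(0, 1),
                                    unfolded = c(0, 1),
                                    foldedWindow = c(10, 22),
                                    unfoldedWindow = c(78, 90))),
                 "degenerate")
})

test_that("melting temperature interpolation is exact for symmetric and model profiles", {
    tC <- seq(10, 90, 0.25)
    sym <- ThetaProfile(tC, 1 / (1 + exp((tC - 45) / 2)))
    expect_equal(meltingTemperature(sym), 45, tolerance = 1e-6)
    expect_equal(meltingTemperature(sym, method = "derivative"), 45,
                 tolerance = 0.05)
    p <- ThermoParams(-336.4, -902.0, "bimolecular", CT = 6e-6)
    prof <- ThetaProfile(tC, thetaFromParams(p, celsiusToKelvin(tC)))
    expect_lt(abs(meltingTemperature(prof) - predictedTm(p, celsius = TRUE)),
              0.1)
    expect_error(meltingTemperature(ThetaProfile(tC, rep(0.95, length(tC)))),
                 "cross")
    wiggly <- ThetaProfile(seq(1, 30), 0.5 + 0.2 * sin(seq(1, 30)))
    expect_warning(meltingTemperature(wiggly, smoothWindow = 0), "multiple")
})

test_that("van't Hoff regression recovers generating parameters from noise-free profiles", {
    p <- ThermoParams(-336.4, -902.0, "bimolecular", CT = 6e-6)
    cv <- simulateCurve(p)
    fit <- analyzeCurve(cv, "bimolecular", CT = 6e-6, refine = FALSE)
    expect_lt(abs(deltaH(fit) + 336.4) / 336.4, 0.01)
    expect_lt(abs(stdFreeEnergy(fit) + 67.5), 0.5)
    expect_gt(rSquared(fit), 0.999)
    # exactly linear ln K: r^2 = 1
    tC <- seq(10, 90, 0.25)
    prof <- ThetaProfile(tC, thetaFromParams(p, celsiusToKelvin(tC)))
    direct <- vantHoffFit(prof, "bimolecular", CT = 6e-6)
    expect_gt(rSquared(direct), 1 - 1e-9)
    expect_equal(deltaH(direct), -336.4, tolerance = 1e-6)
    expect_equal(deltaS(direct), -902.0, tolerance = 1e-6)
    # window pre-condition
    flat <- ThetaProfile(tC, rep(0.95, length(tC)))
    expect_error(vantHoffFit(flat, "bimolecular", CT = 6e-6), "fewer than 5")
})

test_that("unimolecular fits give concentration-independent quadruplex-like Tm", {
    pq <- ThermoParams(-200, -565, "unimolecular")
    expect_equal(predictedTm(pq), 353.98, tolerance = 1e-4)
    cv <- simulateCurve(pq, Trange = c(40, 120))
    fit <- analyzeCurve(cv, "unimolecular")
    expect_lt(abs(celsiusToKelvin(tmObserved(fit)) - 353.98), 0.3)
    expect_lt(abs(deltaH(fit) + 200) / 200, 0.01)
})

test_that("direct two-state refinement removes residual baseline bias", {
    set.seed(211)
    for (i in 1:5) {
        p <- drawScreenedParams()
        cv <- simulateCurve(p)
        plain <- analyzeCurve(cv, "bimolecular", CT = 6e-6, refine = FALSE)
        refined <- analyzeCurve(cv, "bimolecular", CT = 6e-6)
        errPlain <- abs(deltaH(plain) - deltaH(p))
        errRef <- abs(deltaH(refined) - deltaH(p))
        expect_lt(errRef, errPlain + 1e-9)
        expect_lt(errRef / abs(deltaH(p)), 1e-6)
    }
})

test_that("hysteresis diagnostic flags shifted heating/cooling pairs", {
    p <- paramsForTm(-336.4, 58.8)
    tr0 <- simulateMeltTrace(p, pattern = c("cooling", "heating"))
    cs0 <- splitRamps(tr0)
    fits0 <- lapply(cs0, analyzeCurve, molecularity = "bimolecular", CT = 6e-6)
    h0 <- hysteresis(fits0[[2]], fits0[[1]])
    expect_lt(h0$deltaTm, 0.1)
    expect_false(h0$nonEquilibrium)
    tr2 <- simulateMeltTrace(p, pattern = c("cooling", "heating"),
                             hysteresisShift = 2)
    cs2 <- splitRamps(tr2)
    fits2 <- lapply(cs2, analyzeCurve, molecularity = "bimolecular", CT = 6e-6)
    h2 <- hysteresis(fits2[[2]], fits2[[1]])
    expect_equal(h2$deltaTm, 2, tolerance = 0.1)
    expect_true(h2$nonEquilibrium)
})

test_that("transition separation applies the 25-degree acceptance rule", {
    r1 <- transitionSeparation(58.6, 80)
    expect_equal(r1$separation, 21.4)
    expect_false(r1$pass)
    r2 <- transitionSeparation(51.4, 80)
    expect_equal(r2$separation, 28.6)
    expect_true(r2$pass)
    expect_false(transitionSeparation(60, 60)$pass)
})

test_that("molecularity test classifies concentration series by the R/deltaH slope", {
    p <- ThermoParams(-336.4, -902.0, "bimolecular", CT = 6e-6)
    cts <- c(1.5e-6, 3e-6, 6e-6, 1.2e-5)
    ser <- simulateConcentrationSeries(p, cts)
    tms <- vapply(ser, function(e)
        celsiusToKelvin(tmObserved(analyzeCurve(e$curve, "bimolecular",
                                                CT = e$CT))), numeric(1))
    mt <- molecularityTest(cts, tms, deltaH = -336.4)
    expect_identical(mt$classification, "bimolecular")
    expect_equal(mt$slope, 8.314 / -336400, tolerance = 0.02)
    flat <- molecularityTest(cts, rep(331.9, 4), deltaH = -336.4)
    expect_identical(flat$classification, "unimolecular")
    expect_equal(flat$slope, 0, tolerance = 1e-12)
    expect_error(molecularityTest(c(3e-6, 6e-6), c(330, 331), -336.4),
                 "3 distinct")
})
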