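# GP internals: closed-form single-point posterior as an independent oracle
test_that("GP posterior matches direct 1x1 matrix algebra at frozen hyperparameters", {
    theta <- log(c(1.3, 0.9, 1.1, 2.0, 0.4, 0.25))
    X <- matrix(c(0.3, -0.2, 0.5), nrow = 1)
    y <- 0.8
    D2 <- NeoVolNorm:::.sqDistList(X)
    K <- NeoVolNorm:::.gpKernel(theta, D2, tcrossprod(X))
    L <- chol(K)
    alpha <- backsolve(L, forwardsolve(t(L), y))
    xs <- matrix(c(0.1, 0.4, -0.3), nrow = 1)
    p <- NeoVolNorm:::.gpPredict(theta, X, y, L, alpha, xs)

    # oracle: hand-rolled scalar kernel evaluations
    s2f <- 1.3; ls <- c(0.9, 1.1, 2.0); s2l <- 0.4; s2n <- 0.25
    kf <- function(a, b) s2f * exp(-0.5 * sum((a - b)^2 / ls^2)) + s2l * sum(a * b)
    x1 <- c(0.3, -0.2, 0.5); x2 <- c(0.1, 0.4, -0.3)
    k11 <- kf(x1, x1) + s2n + 1e-8
    k21 <- kf(x2, x1)
    k22 <- kf(x2, x2) + 1e-8
    muOracle <- k21 / k11 * y
    varOracle <- k22 - k21^2 / k11 + s2n
    expect_equal(p$mean, muOracle, tolerance = 1e-10)
    expect_equal(p$var, varOracle, tolerance = 1e-10)
})

test_that("analytic marginal-likelihood gradient matches finite differences", {
    set.seed(42)
    X <- matrix(rnorm(30), ncol = 3)
    y <- rnorm(10)
    D2 <- NeoVolNorm:::.sqDistList(X)
    XXt <- tcrossprod(X)
    theta <- log(c(0.8, 1.2, 0.7, 1.5, 0.3, 0.2))
    g <- NeoVolNorm:::.gpNlml(theta, y, D2, XXt)$grad
    fd <- vapply(seq_along(theta), function(j) {
        h <- 1e-6; tp <- theta; tm <- theta
        tp[j] <- tp[j] + h; tm[j] <- tm[j] - h
        (NeoVolNorm:::.gpNlml(tp, y, D2, XXt)$value -
         NeoVolNorm:::.gpNlml(tm, y, D2, XXt)$value) / (2 * h)
    }, numeric(1))
    expect_equal(g, fd, tolerance = 1e-5)
})

test_that("fitting errors on degenerate inputs and small cohorts", {
    ve <- fixtureControls(40, 3)
    subjects <- as.data.frame(SummarizedExperiment::colData(ve))
    expect_error(fitNormative(subjects, rep(2.5, 40), measure = "const"),
                 "zero variance")
    expect_error(fitNormative(subjects[1:10, ], rnorm(10), measure = "m"),
                 "at least 30")
    expect_error(fitNormative(subjects, c(rnorm(39), NA), measure = "m"),
                 "finite")
})

test_that("a near-constant target is recovered everywhere in range", {
    ve <- fixtureControls(60, 4)
    subjects <- as.data.frame(SummarizedExperiment::colData(ve))
    set.seed(1)
    cval <- 7.3
    y <- cval + rnorm(60, sd = 1e-4)
    m <- fitNormative(subjects, y, measure = "nearconst", seed = 1,
                      restarts = 2)
    grid <- data.frame(sex = rep(c("female", "male"), 5),
                       pma_scan = seq(36, 45, length.out = 10),
                       age_from_birth = seq(0.5, 6, length.out = 10))
    p <- predictNormative(m, grid)
    expect_true(all(abs(p$predicted_mean - cval) < 1e-3 * cval + 1e-6))
})

test_that("synthetic-cohort predictive means track the generator truth", {
    spec <- cohortSpec(n = 220, seed = 101)
    ve <- fixtureControls(220, 101)
    m <- fixtureModel("cerebellum")
    g <- spec$growth
    i <- which(g$segment == "cerebellum")
    grid <- expand.grid(sex = c("female", "male"),
                        pma_scan = seq(34, 45, by = 1))
    grid$age_from_birth <- pmax(grid$pma_scan - 39, 0.5)
    p <- predictNormative(m, grid)
    mult <- ifelse(grid$sex == "male", 1 + g$sex_offset[i] / 2,
                   1 - g$sex_offset[i] / 2)
    truth <- g$vmax[i] / (1 + exp(-g$rate[i] * (grid$pma_scan - g$t0[i]))) * mult
    sigma <- g$cv[i] * truth
    expect_lt(mean(abs(p$predicted_mean - truth)), 0.5 * median(sigma))
})

test_that("prediction is deterministic, warns out of range, refuses unfitted models", {
    m <- fixtureModel("cerebellum")
    s <- data.frame(sex = "female", pma_scan = 40, age_from_birth = 2)
    expect_identical(predictNormative(m, s), predictNormative(m, s))
    far <- data.frame(sex = "male", pma_scan = 49.5, age_from_birth = 10)
    expect_warning(predictNormative(m, far), "outside the training range")
    expect_error(predictNormative(new("NormativeModel", measure = "x"), s),
                 "not fitted")
})

test_that("z-scores follow the definition and the inclusive extreme rule", {
    m <- fixtureModel("cerebellum")
    s <- data.frame(sex = "female", pma_scan = 40, age_from_birth = 2)
    p <- predictNormative(m, s)
    z0 <- zscore(m, s, p$predicted_mean)
    expect_equal(z0$z, 0)
    expect_false(z0$extreme)
    zhi <- zscore(m, s, p$predicted_mean + 2.6 * p$predicted_sd)
    expect_equal(zhi$z, 2.6, tolerance = 1e-12)
    expect_true(zhi$extreme)
    zlo <- zscore(m, s, p$predicted_mean - 1.0 * p$predicted_sd)
    expect_equal(zlo$z, -1, tolerance = 1e-12)
    expect_false(zlo$extreme)
    zb <- zscore(m, s, p$predicted_mean - 2.6 * p$predicted_sd)
    expect_true(zb$extreme)
})

test_that("scaling all targets scales predictions and leaves z-scores unchanged", {
    ve <- fixtureControls(80, 6)
    subjects <- as.data.frame(SummarizedExperiment::colData(ve))
    y <- measureMatrix(ve, "absolute")["thalamus", ]
    a <- 3.7
    m1 <- fitNormative(subjects, y, measure = "thalamus", seed = 5,
                       restarts = 2)
    m2 <- fitNormative(subjects, a * y, measure = "thalamus", seed = 5,
                       restarts = 2)
    s <- data.frame(sex = c("female", "male"), pma_scan = c(38, 43),
                    age_from_birth = c(1, 4))
    p1 <- predictNormative(m1, s); p2 <- predictNormative(m2, s)
    expect_equal(p2$predicted_mean, a * p1$predicted_mean, tolerance = 1e-6)
    expect_equal(p2$predicted_sd, a * p1$predicted_sd, tolerance = 1e-6)
    obs <- p1$predicted_mean + c(1.3, -0.4) * p1$predicted_sd
    z1 <- zscore(m1, s, obs)$z
    z2 <- zscore(m2, s, a * obs)$z
    expect_equal(z1, z2, tolerance = 1e-6)
})

test_that("refits with identical inputs and seed are bit-identical", {
    ve <- fixtureControls(60, 4)
    m1 <- fitNormative(ve, measure = "brainstem", seed = 17, restarts = 3)
    m2 <- fitNormative(ve, measure = "brainstem", seed = 17, restarts = 3)
    expect_identical(m1@hyperparams, m2@hyperparams)
    s <- data.frame(sex = "male", pma_scan = 41, age_from_birth = 3)
    expect_identical(zscore(m1, s, 8)$z, zscore(m2, s, 8)$z)
})

test_that("held-out controls are calibrated near standard normal", {
    spec <- cohortSpec(n = 220, seed = 101)
    m <- fixtureModel("cerebellum")
    held <- generateControls(spec, streamOffset = 900000L)[, 1:100]
    cal <- calibrationReport(m, held,
                             measureMatrix(held, "absolute")["cerebellum", 1:100])
    expect_gt(cal$mean_z, -0.3)  # n = 100 band
    expect_lt(cal$mean_z, 0.3)
    expect_gt(cal$sd_z, 0.8)
    expect_lt(cal$sd_z, 1.2)
    expect_lt(cal$frac_extreme, 0.05)
    expect_error(calibrationReport(m, held[, 0],
                                   numeric(0)), "empty")
})

test_that("noise-free interpolation reproduces training targets", {
    # smooth noise-free function of the covariates; the optimized fit should
    # interpolate almost exactly (tiny fitted noise)
    ve <- fixtureControls(50, 8)
    subjects <- as.data.frame(SummarizedExperiment::colData(ve))
    y <- 5 + 0.3 * subjects$pma_scan +
        0.5 * sin(subjects$pma_scan / 2) +
        0.2 * (subjects$sex == "male")
    m <- fitNormative(subjects, y, measure = "smooth", seed = 3, restarts = 3)
    p <- predictNormative(m, subjects)
    expect_lt(max(abs(p$predicted_mean - y) / abs(y)), 1e-3)
    cal <- calibrationReport(m, subjects, y)
    expect_true(all(abs(cal$z) < 0.5))
})

test_that("models round-trip through JSON serialization", {
    m <- fixtureModel("cerebellum")
    f <- tempfile(fileext = ".json")
    writeNormativeModel(m, f)
    m2 <- readNormativeModel(f)
    s <- data.frame(sex = c("female", "male"), pma_scan = c(39, 42),
                    age_from_birth = c(2, 5))
    expect_equal(predictNormative(m2, s), predictNormative(m, s),
                 tolerance = 1e-10)
    expect_equal(m2@hyperparams, m@hyperparams, tolerance = 1e-12)
})

test_that("predictive SD does not shrink toward the design edges", {
    m <- fixtureModel("cerebellum")
    center <- data.frame(sex = "female", pma_scan = 41, age_from_birth = 2)
    edge <- data.frame(sex = "female", pma_scan = 45.5, age_from_birth = 2)
    expect_lte(predictNormative(m, center)$predicted_sd,
               predictNormative(m, edge)$predicted_sd * 1.05)
})
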