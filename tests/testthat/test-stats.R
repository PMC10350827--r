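test_that("Cliff's delta matches hand enumeration and bands correctly", {
    expect_equal(cliffsDelta(c(1, 2, 3), c(1, 2, 3))$d, 0)
    expect_equal(cliffsDelta(c(1, 2, 3), c(1, 2, 3))$category, "negligible")
    expect_equal(cliffsDelta(c(4, 5), c(1, 2))$d, 1)
    expect_equal(cliffsDelta(c(4, 5), c(1, 2))$category, "large")
    expect_equal(cliffsDelta(c(1, 2, 3), c(2, 3, 4))$d, -5 / 9)
})

test_that("Cliff's delta equals the all-pairs oracle on random instances", {
    set.seed(11)
    for (i in 1:200) {
        n <- sample(2:10, 1); m <- sample(2:10, 1)
        x <- sample(-5:5, n, replace = TRUE) + round(runif(n), 2)
        y <- sample(-5:5, m, replace = TRUE) + round(runif(m), 2)
        expect_equal(cliffsDelta(x, y)$d, bruteCliffs(x, y), tolerance = 1e-12)
        expect_equal(cliffsDelta(x, y)$d, -cliffsDelta(y, x)$d,
                     tolerance = 1e-12)
    }
})

test_that("effect-size banding is total and resolves gap values downward", {
    # every |d| maps to exactly one category; printed-gap values (0.335,
    # 0.4745) fall in the lower band
    for (d in seq(0, 1, by = 0.001))
        expect_length(effectSizeCategory(d), 1)
    expect_equal(effectSizeCategory(0.147), "negligible")
    expect_equal(effectSizeCategory(0.148), "small")
    expect_equal(effectSizeCategory(0.335), "small")
    expect_equal(effectSizeCategory(0.34), "medium")
    expect_equal(effectSizeCategory(0.4745), "medium")
    expect_equal(effectSizeCategory(0.475), "large")
    expect_equal(effectSizeCategory(-0.6), "large")
})

test_that("Mann-Whitney exact branch reproduces permutation enumeration", {
    # complete separation at n = m = 3: p = 2/choose(6,3)
    mw <- mannWhitney(c(1, 2, 3), c(4, 5, 6))
    expect_equal(mw$U, 0)
    expect_true(mw$exact)
    expect_equal(mw$p, 0.1)
    # identical samples: U = nm/2
    expect_equal(mannWhitney(c(5, 7, 9), c(5, 7, 9))$U, 4.5)

    # full enumeration oracle for tie-free n = m = 4
    enumP <- function(x, y) {
        pooled <- c(x, y)
        uStat <- function(xs, ys) {
            r <- rank(c(xs, ys))
            sum(r[seq_along(xs)]) - length(xs) * (length(xs) + 1) / 2
        }
        obs <- uStat(x, y)
        combs <- utils::combn(8, 4)
        us <- apply(combs, 2, function(idx)
            uStat(pooled[idx], pooled[-idx]))
        dev <- abs(us - 8)          # distance from the null mean nm/2
        mean(dev >= abs(obs - 8))
    }
    set.seed(21)
    for (i in 1:20) {
        v <- sample(1:100, 8)
        x <- v[1:4]; y <- v[5:8]
        mw <- mannWhitney(x, y)
        expect_true(mw$exact)
        expect_equal(mw$p, enumP(x, y), tolerance = 1e-12)
    }
})

test_that("Mann-Whitney U links to Cliff's delta for tie-free data", {
    set.seed(5)
    for (i in 1:50) {
        x <- rnorm(sample(3:12, 1)); y <- rnorm(sample(3:12, 1))
        mw <- mannWhitney(x, y)
        d <- cliffsDelta(x, y)$d
        expect_equal(2 * mw$U / (length(x) * length(y)) - 1, d,
                     tolerance = 1e-12)
    }
})

test_that("Mann-Whitney warns and returns p = 1 on constant pooled samples", {
    expect_warning(mw <- mannWhitney(c(2, 2), c(2, 2, 2)), "constant")
    expect_equal(mw$p, 1)
})

test_that("Kruskal-Wallis agrees with the two-group rank test and nulls out", {
    set.seed(3)
    x <- rnorm(30); y <- rnorm(30) + 0.5
    kw <- kruskalWallis(list(x, y))
    mw <- mannWhitney(x, y)
    expect_lt(abs(kw$p - mw$p), 0.02)
    expect_warning(kw0 <- kruskalWallis(list(c(1, 1), c(1, 1), c(1, 1))))
    expect_equal(kw0$H, 0)
    expect_equal(kruskalWallis(list(c(1, 2), c(1, 2), c(1, 2)))$H, 0)
})

test_that("BH adjustment equals an independent step-up implementation", {
    # hand-stepped oracle
    bhOracle <- function(p) {
        m <- length(p)
        o <- order(p)
        adj <- numeric(m)
        prev <- 1
        for (k in m:1) {
            val <- min(prev, p[o[k]] * m / k)
            adj[o[k]] <- val
            prev <- val
        }
        pmin(adj, 1)
    }
    expect_equal(bhAdjust(0.03), 0.03)
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    set.seed(13)
    for (i in 1:200) {
        p <- runif(sample(1:30, 1))^sample(1:3, 1)
        a <- bhAdjust(p)
        expect_equal(a, bhOracle(p), tolerance = 1e-12)
        expect_true(all(a >= p - 1e-15))
        o <- order(p)
        expect_true(all(diff(a[o]) >= -1e-15))
    }
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Spearman rho, p and strength bands behave as specified", {
    expect_equal(spearmanCor(1:5, (1:5)^2)$rho, 1)
    expect_equal(spearmanCor(1:5, (1:5)^2)$band, "very strong")
    expect_equal(spearmanCor(1:5, -(1:5))$rho, -1)
    expect_equal(spearmanCor(1:5, -(1:5))$band, "very strong")
    expect_equal(spearmanCor(1:4, c(1, 3, 2, 4))$rho, 0.8)
    expect_error(spearmanCor(rep(1, 5), 1:5), "constant")
    # midpoint cut-points make the banding total
    expect_equal(spearmanBand(0.19), "very weak")
    expect_equal(spearmanBand(0.20), "weak")
    expect_equal(spearmanBand(0.392), "weak")
    expect_equal(spearmanBand(0.398), "moderate")
    expect_equal(spearmanBand(0.80), "very strong")
})

test_that("LMS z-scores follow the formula and its log-limit", {
    ref <- new("LMSReference", table = data.frame(
        sex = rep(c("female", "male"), each = 3),
        age_weeks = rep(c(30, 40, 50), 2),
        L = c(1, 1, 1, 0.5, 0.5, 0.5),
        M = c(3, 3.5, 4, 3.2, 3.7, 4.2),
        S = rep(0.12, 6)))
    expect_equal(lmsZscore(3.5, ref, "female", 40), 0)
    expect_equal(lmsZscore(3.5 * 1.12, ref, "female", 40), 1)
    # interpolation is linear in age
    expect_equal(lmsZscore(3.25, ref, "female", 35), 0)
    expect_error(lmsZscore(3.5, ref, "female", 55), "outside")
    # L -> 0 converges to the log form
    refL <- function(L) new("LMSReference", table = data.frame(
        sex = "female", age_weeks = c(30, 50), L = L, M = 3.5, S = 0.12))
    zLog <- log(4 / 3.5) / 0.12
    expect_equal(lmsZscore(4, refL(1e-8), "female", 40), zLog,
                 tolerance = 1e-6)
    expect_equal(lmsZscore(4, refL(0), "female", 40), zLog)
})

test_that("the bundled synthetic LMS reference loads and validates", {
    f <- system.file("extdata", "lms_reference_synthetic.csv",
                     package = "NeoVolNorm")
    ref <- readLMSReference(f)
    expect_s4_class(ref, "LMSReference")
    expect_equal(lmsZscore(ref@table$M[1], ref, ref@table$sex[1],
                           ref@table$age_weeks[1]), 0)
})

test_that("significance stars map FDR thresholds", {
    expect_equal(significanceStars(c(0.0005, 0.005, 0.04, 0.2)),
                 c("***", "**", "*", "ns"))
})
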