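# Gaussian-process regression internals: RBF-ARD + linear + noise kernel,
# analytic-gradient marginal-likelihood optimisation, posterior prediction.
# Everything operates on standardized covariates/targets; standardization
# lives in the NormativeModel wrapper.

.GP_JITTER <- 1e-8

# squared-distance arrays per input dimension, computed once per fit
.sqDistList <- function(X, X2 = NULL) {
    if (is.null(X2)) X2 <- X
    lapply(seq_len(ncol(X)), function(d)
        outer(X[, d], X2[, d], "-")^2)
}

# kernel from log-hyperparameters
# theta = log(sigma2_f, ls_1..ls_d, sigma2_lin, sigma2_n)
.gpKernel <- function(theta, D2, XXt, withNoise = TRUE) {
    d <- length(D2)
    s2f <- exp(theta[1]); ls2 <- exp(2 * theta[2:(d + 1)])
    s2l <- exp(theta[d + 2]); s2n <- exp(theta[d + 3])
    M <- 0
    for (j in seq_len(d)) M <- M + D2[[j]] / ls2[j]
    K <- s2f * exp(-0.5 * M) + s2l * XXt
    if (withNoise) {
        n <- nrow(K)
        K[seq.int(1L, n * n, n + 1L)] <-
            K[seq.int(1L, n * n, n + 1L)] + s2n + .GP_JITTER
    }
    K
}

# negative log marginal likelihood and its gradient in theta
.gpNlml <- function(theta, y, D2, XXt) {
    n <- length(y)
    K <- .gpKernel(theta, D2, XXt)
    L <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(L)) return(list(value = 1e10, grad = rep(0, length(theta))))
    alpha <- backsolve(L, backsolve(L, y, transpose = TRUE))
    nlml <- 0.5 * sum(y * alpha) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)

    d <- length(D2)
    s2f <- exp(theta[1]); ls2 <- exp(2 * theta[2:(d + 1)])
    s2n <- exp(theta[d + 3])
    M <- 0
    for (j in seq_len(d)) M <- M + D2[[j]] / ls2[j]
    E <- s2f * exp(-0.5 * M)
    W <- chol2inv(L) - tcrossprod(alpha)  # grad_j = 0.5 * sum(W * dK_j)
    WE <- W * E
    grad <- numeric(length(theta))
    grad[1] <- 0.5 * sum(WE)
    for (j in seq_len(d))
        grad[j + 1] <- 0.5 * sum(WE * D2[[j]]) / ls2[j]
    grad[d + 2] <- 0.5 * exp(theta[d + 2]) * sum(W * XXt)
    grad[d + 3] <- 0.5 * sum(diag(W)) * s2n
    list(value = nlml, grad = grad)
}

# multi-restart L-BFGS-B maximization of the marginal likelihood;
# deterministic given (y, X, seed). Returns theta, nlml, restart index.
.gpOptimize <- function(y, X, seed, restarts = 5L, maxit = 150L) {
    D2 <- .sqDistList(X)
    XXt <- tcrossprod(X)
    d <- ncol(X)
    starts <- list(c(0, rep(0, d), log(0.1), log(0.1)))
    if (restarts > 1L) {
        draws <- .withSeed(seed, {
            lapply(seq_len(restarts - 1L), function(i)
                c(log(runif(1, 0.1, 2)),
                  log(runif(d, 0.3, 10)),
                  log(runif(1, 0.01, 2)),
                  log(runif(1, 0.01, 1))))
        })
        starts <- c(starts, draws)
    }
    # optim evaluates fn and gr at the same point; cache the last evaluation
    cache <- new.env(parent = emptyenv())
    evalAt <- function(th) {
        if (is.null(cache$th) || !identical(th, cache$th)) {
            cache$res <- .gpNlml(th, y, D2, XXt)
            cache$th <- th
        }
        cache$res
    }
    fn <- function(th) evalAt(th)$value
    gr <- function(th) evalAt(th)$grad
    best <- NULL
    for (i in seq_along(starts)) {
        fit <- tryCatch(
            optim(starts[[i]], fn, gr, method = "L-BFGS-B",
                  lower = rep(-12, d + 3), upper = rep(8, d + 3),
                  control = list(maxit = maxit, factr = 1e9)),
            error = function(e) NULL)
        if (is.null(fit)) next
        if (is.null(best) || fit$value < best$value - 1e-9)
            best <- list(value = fit$value, par = fit$par, restart = i)
    }
    if (is.null(best)) stop("GP hyperparameter optimization failed")
    best
}

# posterior mean / predictive variance (noise included) at new inputs
.gpPredict <- function(theta, X, y, L, alpha, Xnew, includeNoise = TRUE) {
    d <- ncol(X)
    D2s <- .sqDistList(Xnew, X)
    s2f <- exp(theta[1]); ls2 <- exp(2 * theta[2:(d + 1)])
    s2l <- exp(theta[d + 2]); s2n <- exp(theta[d + 3])
    M <- 0
    for (j in seq_len(d)) M <- M + D2s[[j]] / ls2[j]
    Ks <- s2f * exp(-0.5 * M) + s2l * (Xnew %*% t(X))
    mu <- as.numeric(Ks %*% alpha)
    V <- backsolve(L, t(Ks), transpose = TRUE)
    kss <- s2f + s2l * rowSums(Xnew^2) + .GP_JITTER
    var <- pmax(kss - colSums(V^2), .GP_JITTER)
    if (includeNoise) var <- var + s2n
    list(mean = mu, var = var)
}

# evaluate an expression under a temporary RNG state
.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

# deterministic per-stream sub-seed derivation (stays below 2^31)
.subSeed <- function(seed, index) {
    as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483647)
}
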