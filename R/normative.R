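#' Fit a Gaussian-process normative model for one measure
#'
#' Models a volumetric measure in the control cohort as a Gaussian process
#' over three covariates: sex (coded female = 0, male = 1), postmenstrual
#' age at scan (weeks) and age from birth (weeks). The kernel is an
#' anisotropic RBF (one length scale per standardized covariate) plus a
#' linear kernel plus independent Gaussian noise; hyperparameters maximize
#' the marginal likelihood by gradient ascent from multiple seeded
#' restarts. Covariates and targets are standardized internally; the
#' predictive SD returned by \code{\link{predictNormative}} includes the
#' noise variance so that control z-scores are approximately standard
#' normal.
#'
#' @param subjects data.frame of control subject records (columns
#'   \code{sex}, \code{pma_scan}, \code{age_from_birth}), or a
#'   \linkS4class{VolumetricExperiment} whose colData carries them.
#' @param values numeric vector of the measure for those subjects; omitted
#'   when \code{subjects} is a \linkS4class{VolumetricExperiment}, in which
#'   case \code{measure} is looked up with \code{\link{measureMatrix}}.
#' @param measure measure name.
#' @param type \code{"absolute"} or \code{"relative"} (lookup only).
#' @param seed integer seed for the restart draws.
#' @param restarts number of optimisation restarts (default 5).
#' @param minN minimum number of controls (default 30).
#' @return a \linkS4class{NormativeModel}.
#' @examples
#' ve <- generateControls(cohortSpec(n = 60, seed = 5))
#' m <- fitNormative(ve, measure = "cerebellum", seed = 5)
#' m
#' @export
fitNormative <- function(subjects, values = NULL, measure,
                         type = c("absolute", "relative"),
                         seed = 1L, restarts = 5L, minN = 30L) {
    type <- match.arg(type)
    if (is(subjects, "SummarizedExperiment")) {
        if (is.null(values))
            values <- measureMatrix(subjects, type)[measure, ]
        subjects <- as.data.frame(SummarizedExperiment::colData(subjects))
    }
    n <- nrow(subjects)
    if (length(values) != n)
        stop("values length does not match subject count")
    if (n < minN)
        stop("need at least ", minN, " controls to fit a normative model, got ", n)
    if (any(!is.finite(values)))
        stop("non-finite measure values")
    need <- c("sex", "pma_scan", "age_from_birth")
    if (any(!need %in% colnames(subjects)) ||
        anyNA(subjects[, need]))
        stop("missing covariates among: ", paste(need, collapse = ", "))
    if (var(values) == 0)
        stop("degenerate measure '", measure, "': zero variance")

    Xraw <- .covariateMatrix(subjects)
    xCenter <- colMeans(Xraw)
    xScale <- apply(Xraw, 2, sd)
    xScale[xScale == 0] <- 1
    X <- sweep(sweep(Xraw, 2, xCenter), 2, xScale, "/")
    yCenter <- mean(values); yScale <- sd(values)
    y <- (values - yCenter) / yScale

    opt <- .gpOptimize(y, X, seed = seed, restarts = restarts)
    theta <- opt$par
    K <- .gpKernel(theta, .sqDistList(X), tcrossprod(X))
    L <- chol(K)
    alpha <- backsolve(L, backsolve(L, y, transpose = TRUE))
    hp <- exp(theta)
    names(hp) <- c("sigma2_f", "ls_sex", "ls_pma", "ls_age",
                   "sigma2_lin", "sigma2_n")
    new("NormativeModel", measure = measure, hyperparams = hp,
        xCenter = xCenter, xScale = xScale,
        yCenter = yCenter, yScale = yScale,
        X = X, y = y, alpha = alpha, L = L,
        trainingRange = list(pma_scan = range(subjects$pma_scan),
                             age_from_birth = range(subjects$age_from_birth)),
        logLik = -opt$value, seed = as.integer(seed), fitted = TRUE)
}

.covariateMatrix <- function(subjects) {
    sex01 <- ifelse(subjects$sex == "male", 1, 0)
    cbind(sex = sex01, pma_scan = subjects$pma_scan,
          age_from_birth = subjects$age_from_birth)
}

.modelTheta <- function(model) {
    log(unname(model@hyperparams))
}

#' Predictive mean and SD from a normative model
#'
#' Returns the posterior mean and the predictive standard deviation
#' (including observation noise) of the modelled measure at each subject's
#' covariates. Covariates more than 2 weeks outside the training range
#' trigger a warning but still yield a prediction.
#'
#' @param model a fitted \linkS4class{NormativeModel}.
#' @param subjects data.frame of subject records (or a
#'   \linkS4class{VolumetricExperiment}).
#' @return data.frame with columns \code{predicted_mean},
#'   \code{predicted_sd}.
#' @export
predictNormative <- function(model, subjects) {
    if (!model@fitted) stop("model is not fitted")
    if (is(subjects, "SummarizedExperiment"))
        subjects <- as.data.frame(SummarizedExperiment::colData(subjects))
    Xraw <- .covariateMatrix(subjects)
    for (v in c("pma_scan", "age_from_birth")) {
        r <- model@trainingRange[[v]]
        out <- Xraw[, v] < r[1] - 2 | Xraw[, v] > r[2] + 2
        if (any(out))
            warning(sum(out), " subject(s) with ", v,
                    " > 2 weeks outside the training range [",
                    round(r[1], 2), ", ", round(r[2], 2), "]")
    }
    Xnew <- sweep(sweep(Xraw, 2, model@xCenter), 2, model@xScale, "/")
    p <- .gpPredict(.modelTheta(model), model@X, model@y, model@L,
                    model@alpha, Xnew, includeNoise = TRUE)
    data.frame(predicted_mean = p$mean * model@yScale + model@yCenter,
               predicted_sd = sqrt(p$var) * model@yScale,
               row.names = rownames(subjects))
}

#' Deviation z-scores against a normative model
#'
#' z = (observed - predicted mean) / predictive SD; a deviation is flagged
#' extreme when z <= -threshold or z >= +threshold (inclusive), threshold
#' 2.6 SD by default, i.e. roughly the top and bottom half-percent of the
#' reference population.
#'
#' @param model a fitted \linkS4class{NormativeModel}.
#' @param subjects subject records (data.frame or
#'   \linkS4class{VolumetricExperiment}).
#' @param observed numeric vector of observed values; omitted when
#'   \code{subjects} is a \linkS4class{VolumetricExperiment} (looked up by
#'   the model's measure).
#' @param type measure lookup type for VolumetricExperiment input.
#' @param threshold extreme-deviation threshold in SD units.
#' @return data.frame: \code{subject_id}, \code{measure}, \code{observed},
#'   \code{predicted_mean}, \code{predicted_sd}, \code{z}, \code{extreme}.
#' @export
zscore <- function(model, subjects, observed = NULL,
                   type = c("absolute", "relative"), threshold = 2.6) {
    type <- match.arg(type)
    if (is(subjects, "SummarizedExperiment")) {
        if (is.null(observed))
            observed <- measureMatrix(subjects, type)[model@measure, ]
        ids <- colnames(subjects)
        subjects <- as.data.frame(SummarizedExperiment::colData(subjects))
    } else {
        ids <- if ("subject_id" %in% colnames(subjects))
            subjects$subject_id else rownames(subjects)
    }
    p <- predictNormative(model, subjects)
    z <- (observed - p$predicted_mean) / p$predicted_sd
    data.frame(subject_id = ids, measure = model@measure,
               observed = observed,
               predicted_mean = p$predicted_mean,
               predicted_sd = p$predicted_sd,
               z = z, extreme = z <= -threshold | z >= threshold,
               row.names = NULL)
}

#' Held-out calibration summary of a normative model
#'
#' On held-out controls the deviation z-scores should be approximately
#' standard normal: mean near 0, SD near 1, and a small fraction beyond the
#' extreme threshold. Reports those summaries plus the Kolmogorov-Smirnov
#' statistic against N(0,1) and the per-subject z list.
#'
#' @param model fitted \linkS4class{NormativeModel}.
#' @param subjects held-out subject records (disjoint from training).
#' @param observed held-out observed values (optional for
#'   \linkS4class{VolumetricExperiment} input).
#' @param type,threshold as in \code{\link{zscore}}.
#' @return list: \code{mean_z}, \code{sd_z}, \code{frac_extreme},
#'   \code{ks_stat}, \code{n}, \code{z}.
#' @export
calibrationReport <- function(model, subjects, observed = NULL,
                              type = c("absolute", "relative"),
                              threshold = 2.6) {
    nHeld <- if (is(subjects, "SummarizedExperiment")) ncol(subjects)
             else nrow(subjects)
    if (nHeld == 0) stop("empty held-out set")
    sc <- zscore(model, subjects, observed, type, threshold)
    if (nrow(sc) == 0) stop("empty held-out set")
    ks <- suppressWarnings(ks.test(sc$z, "pnorm"))
    list(mean_z = mean(sc$z), sd_z = sd(sc$z),
         frac_extreme = mean(sc$extreme),
         ks_stat = unname(ks$statistic), n = nrow(sc), z = sc$z)
}

#' Serialize a normative model to JSON
#'
#' The JSON file stores the kernel hyperparameters, standardization
#' constants, the training design and targets (needed for posterior
#' prediction) and a training digest; \code{readNormativeModel}
#' reconstructs the Cholesky prediction state from them.
#'
#' @param model fitted \linkS4class{NormativeModel}.
#' @param file path to write.
#' @export
writeNormativeModel <- function(model, file) {
    if (!model@fitted) stop("model is not fitted")
    obj <- list(
        measure = model@measure,
        hyperparams = as.list(model@hyperparams),
        x_center = as.list(model@xCenter),
        x_scale = as.list(model@xScale),
        y_center = model@yCenter, y_scale = model@yScale,
        X_sex = model@X[, "sex"],
        X_pma = model@X[, "pma_scan"],
        X_age = model@X[, "age_from_birth"],
        y = model@y,
        training_range = model@trainingRange,
        log_lik = model@logLik, seed = model@seed,
        n = length(model@y))
    jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
    invisible(file)
}

#' @rdname writeNormativeModel
#' @export
readNormativeModel <- function(file) {
    obj <- jsonlite::read_json(file, simplifyVector = TRUE)
    X <- cbind(sex = as.numeric(obj$X_sex),
               pma_scan = as.numeric(obj$X_pma),
               age_from_birth = as.numeric(obj$X_age))
    hp <- unlist(obj$hyperparams)
    theta <- log(unname(hp))
    K <- .gpKernel(theta, .sqDistList(X), tcrossprod(X))
    L <- chol(K)
    alpha <- backsolve(L, backsolve(L, obj$y, transpose = TRUE))
    new("NormativeModel", measure = obj$measure, hyperparams = hp,
        xCenter = unlist(obj$x_center), xScale = unlist(obj$x_scale),
        yCenter = obj$y_center, yScale = obj$y_scale,
        X = X, y = obj$y, alpha = alpha, L = L,
        trainingRange = lapply(obj$training_range, as.numeric),
        logLik = obj$log_lik, seed = as.integer(obj$seed), fitted = TRUE)
}
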