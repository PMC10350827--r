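#' @import methods
#' @importFrom stats approx cor dnorm ks.test kruskal.test lm median optim
#'   p.adjust pchisq pf pnorm predict pt qnorm quantile rbinom rexp rnorm
#'   runif sd setNames var wilcox.test anova coef resid .lm.fit
#' @importFrom utils read.csv write.csv modifyList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' VolumetricExperiment: cohort container for neonatal segment volumes
#'
#' A \linkS4class{SummarizedExperiment} whose single \code{"volumes"} assay
#' holds absolute segment volumes in cm\eqn{^3} (rows = segments, columns =
#' subjects) and whose \code{colData} carries the subject records (sex,
#' gestational age at birth, postmenstrual age at scan, age from birth,
#' group label and optional CHD flag). Validity enforces the full segment
#' key set, non-negative volumes and the demographic invariants
#' (\code{20 <= ga_birth <= pma_scan <= 50},
#' \code{age_from_birth == pma_scan - ga_birth}).
#'
#' @slot .. see \linkS4class{SummarizedExperiment}.
#' @seealso \code{\link{VolumetricExperiment}} (constructor),
#'   \code{\link{computeAggregates}}, \code{\link{computeRelative}}
#' @export
setClass("VolumetricExperiment", contains = "SummarizedExperiment")

.REQUIRED_SUBJECT_COLS <- c("sex", "ga_birth", "pma_scan",
                            "age_from_birth", "group")

setValidity("VolumetricExperiment", function(object) {
    msg <- character(0)
    if (!"volumes" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'volumes' is required")
    else {
        v <- SummarizedExperiment::assay(object, "volumes")
        missing <- setdiff(requiredSegmentNames(), rownames(v))
        if (length(missing))
            msg <- c(msg, paste0("missing segment key(s): ",
                                 paste(missing, collapse = ", ")))
        if (any(!is.finite(v)))
            msg <- c(msg, "non-finite volume values")
        else if (any(v < 0))
            msg <- c(msg, "negative volume values")
    }
    cd <- SummarizedExperiment::colData(object)
    miss <- setdiff(.REQUIRED_SUBJECT_COLS, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste0("missing subject column(s): ",
                             paste(miss, collapse = ", ")))
    if (!length(miss) && ncol(object) > 0) {
        if (!all(cd$sex %in% c("female", "male")))
            msg <- c(msg, "sex must be 'female' or 'male'")
        bad <- cd$ga_birth < 20 | cd$ga_birth > cd$pma_scan | cd$pma_scan > 50
        if (any(bad))
            msg <- c(msg, "require 20 <= ga_birth <= pma_scan <= 50")
        if (any(abs(cd$age_from_birth - (cd$pma_scan - cd$ga_birth)) > 1e-8))
            msg <- c(msg, "age_from_birth must equal pma_scan - ga_birth")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a VolumetricExperiment
#'
#' @param volumes numeric matrix of absolute volumes (cm\eqn{^3}), rows
#'   named by segment (all of \code{requiredSegmentNames()};
#'   \code{unlabeled_intracranial} optional and added as zero when absent),
#'   columns named by subject id.
#' @param subjects \code{data.frame} or \code{DataFrame} of subject records
#'   with columns \code{sex} (\code{"female"}/\code{"male"}),
#'   \code{ga_birth}, \code{pma_scan}, \code{age_from_birth} (weeks, decimal;
#'   filled in as \code{pma_scan - ga_birth} when absent), \code{group} and
#'   optionally \code{chd} plus weight/head-circumference columns. Row order
#'   must match the columns of \code{volumes}.
#' @return a \linkS4class{VolumetricExperiment}.
#' @examples
#' ve <- .exampleVolumetricExperiment()
#' ve
#' @export
VolumetricExperiment <- function(volumes, subjects) {
    volumes <- as.matrix(volumes)
    if (is.null(rownames(volumes)))
        stop("volumes must have segment row names")
    if (!.UNLABELED %in% rownames(volumes)) {
        volumes <- rbind(volumes,
                         matrix(0, 1, ncol(volumes),
                                dimnames = list(.UNLABELED, colnames(volumes))))
    }
    subjects <- as.data.frame(subjects)
    if (!"age_from_birth" %in% colnames(subjects) &&
        all(c("ga_birth", "pma_scan") %in% colnames(subjects)))
        subjects$age_from_birth <- subjects$pma_scan - subjects$ga_birth
    if (!"subject_id" %in% colnames(subjects))
        subjects$subject_id <- colnames(volumes)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(volumes = volumes),
        colData = S4Vectors::DataFrame(subjects, row.names = colnames(volumes)))
    new("VolumetricExperiment", se)
}

#' @export
setMethod("show", "VolumetricExperiment", function(object) {
    cat("VolumetricExperiment with", ncol(object), "subjects and",
        nrow(object), "segments\n")
    grp <- table(SummarizedExperiment::colData(object)$group)
    if (length(grp))
        cat("groups:", paste(names(grp), grp, sep = "=", collapse = ", "), "\n")
    if (ncol(object)) {
        pma <- SummarizedExperiment::colData(object)$pma_scan
        cat(sprintf("PMA at scan: %.2f-%.2f weeks (median %.2f)\n",
                    min(pma), max(pma), median(pma)))
    }
})

#' NormativeModel: per-measure Gaussian-process normative regression
#'
#' Holds the fitted state of one Gaussian-process regression of a volumetric
#' measure on standardized covariates (sex, PMA at scan, age from birth):
#' kernel hyperparameters (RBF signal variance and per-dimension length
#' scales, linear-kernel variance, noise variance), the covariate and target
#' standardization constants, the training design and the Cholesky-derived
#' prediction state. Predictions return a posterior mean and a predictive SD
#' that includes the observation-noise variance, so control deviation
#' z-scores have unit variance.
#'
#' @slot measure measure name.
#' @slot hyperparams named numeric: \code{sigma2_f}, \code{ls_sex},
#'   \code{ls_pma}, \code{ls_age}, \code{sigma2_lin}, \code{sigma2_n}.
#' @slot xCenter,xScale covariate standardization constants.
#' @slot yCenter,yScale target standardization constants.
#' @slot X standardized training covariates (n x 3).
#' @slot y standardized training targets.
#' @slot alpha,L prediction state (\eqn{K^{-1}y} and Cholesky factor).
#' @slot trainingRange range of raw PMA and age-from-birth seen in training.
#' @slot logLik maximized log marginal likelihood.
#' @slot seed seed used for restart draws.
#' @slot fitted logical.
#' @export
setClass("NormativeModel",
    representation(measure = "character", hyperparams = "numeric",
                   xCenter = "numeric", xScale = "numeric",
                   yCenter = "numeric", yScale = "numeric",
                   X = "matrix", y = "numeric",
                   alpha = "numeric", L = "matrix",
                   trainingRange = "list", logLik = "numeric",
                   seed = "integer", fitted = "logical"),
    prototype(fitted = FALSE, seed = NA_integer_))

setValidity("NormativeModel", function(object) {
    if (!object@fitted) return(TRUE)
    hp <- object@hyperparams
    need <- c("sigma2_f", "ls_sex", "ls_pma", "ls_age",
              "sigma2_lin", "sigma2_n")
    if (!all(need %in% names(hp)))
        return("incomplete hyperparameter set")
    if (any(hp <= 0)) return("hyperparameters must be positive")
    if (any(object@yScale <= 0)) return("target scale must be positive")
    TRUE
})

#' @export
setMethod("show", "NormativeModel", function(object) {
    cat("NormativeModel for measure:", object@measure, "\n")
    if (!object@fitted) { cat("  <unfitted>\n"); return(invisible(NULL)) }
    cat(sprintf("  n = %d controls, log marginal likelihood = %.3f\n",
                length(object@y), object@logLik))
    hp <- object@hyperparams
    cat(sprintf("  kernel: RBF(s2=%.3g, ls=[%.2f, %.2f, %.2f]) + lin(%.3g) + noise(%.3g)\n",
                hp["sigma2_f"], hp["ls_sex"], hp["ls_pma"], hp["ls_age"],
                hp["sigma2_lin"], hp["sigma2_n"]))
})

#' LMSReference: growth-chart reference in LMS form
#'
#' Per-sex grids of the LMS parameters (skewness power L, median M,
#' coefficient of variation S) over age, as used by growth-chart z-scoring.
#' Interpolation between grid ages is linear; ages outside the grid are an
#' error (no extrapolation).
#'
#' @slot table data.frame with columns \code{sex}, \code{age_weeks},
#'   \code{L}, \code{M}, \code{S}.
#' @export
setClass("LMSReference", representation(table = "data.frame"))

setValidity("LMSReference", function(object) {
    tb <- object@table
    need <- c("sex", "age_weeks", "L", "M", "S")
    if (!all(need %in% colnames(tb)))
        return(paste("LMS table needs columns:", paste(need, collapse = ", ")))
    if (any(tb$M <= 0) || any(tb$S <= 0))
        return("M and S must be positive")
    for (s in unique(tb$sex)) {
        a <- tb$age_weeks[tb$sex == s]
        if (any(diff(a) <= 0))
            return("age grid must be strictly increasing within sex")
    }
    TRUE
})

#' @export
setMethod("show", "LMSReference", function(object) {
    tb <- object@table
    cat("LMSReference:", nrow(tb), "grid rows,",
        "ages", min(tb$age_weeks), "-", max(tb$age_weeks), "weeks,",
        "sexes:", paste(unique(tb$sex), collapse = ", "), "\n")
})

# small fixture used in documentation examples
#' @keywords internal
#' @export
.exampleVolumetricExperiment <- function(n = 6) {
    spec <- cohortSpec(n = n, seed = 11L)
    generateControls(spec)
}
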