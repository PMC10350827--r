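#' Whole-brain and composite volume aggregates
#'
#' Computes the derived volumes from a validated segment table: the three
#' whole-brain denominators (TTV = 19 tissue segments + unlabelled
#' intracranial remainder; TBV = TTV + lateral ventricles; ICV = TBV +
#' extra-cerebral CSF), total cortical grey matter, total white matter,
#' total deep grey matter (caudate + lentiform + thalamus + unlabelled
#' remainder), the six lobar/regional composites, posterior fossa
#' (cerebellum + brainstem) and basal ganglia (caudate + lentiform). Sums
#' are exact.
#'
#' @param ve a \linkS4class{VolumetricExperiment}, or a named numeric vector
#'   of one subject's segment volumes.
#' @return a numeric matrix (aggregates x subjects), or a named vector when
#'   a single subject's vector was given.
#' @examples
#' v <- setNames(rep(1, 19), segmentNames())
#' v <- c(v, ecsf = 3, lateral_ventricles = 2)
#' computeAggregates(v)[c("TTV", "TBV", "ICV")]
#' @export
computeAggregates <- function(ve) {
    if (is.numeric(ve) && !is.matrix(ve)) {
        m <- .segmentMatrix(ve)
        return(computeAggregates(m)[, 1])
    }
    v <- if (is(ve, "SummarizedExperiment"))
        SummarizedExperiment::assay(ve, "volumes") else as.matrix(ve)
    .validateSegments(v)
    if (!.UNLABELED %in% rownames(v))
        v <- rbind(v, matrix(0, 1, ncol(v),
                             dimnames = list(.UNLABELED, colnames(v))))
    members <- aggregateMembers()
    out <- vapply(members, function(m) {
        if (ncol(v) == 0) return(numeric(0))
        colSums(v[m, , drop = FALSE])
    }, numeric(ncol(v)))
    out <- matrix(out, nrow = ncol(v),
                  dimnames = list(colnames(v), names(members)))
    t(out)
}

.segmentMatrix <- function(x) {
    matrix(x, ncol = 1, dimnames = list(names(x), "subject"))
}

.validateSegments <- function(v) {
    missing <- setdiff(requiredSegmentNames(), rownames(v))
    if (length(missing))
        stop("missing segment key(s): ", paste(missing, collapse = ", "))
    if (any(!is.finite(v)))
        stop("non-finite volume values")
    if (any(v < 0)) {
        bad <- which(v < 0, arr.ind = TRUE)
        stop("negative volume for segment '", rownames(v)[bad[1, 1]], "'")
    }
    invisible(TRUE)
}

#' Relative volumes with the segmentation's denominators
#'
#' Expresses every tissue segment and tissue composite as a proportion of
#' total tissue volume, the lateral ventricles as a proportion of total
#' brain volume and the extra-cerebral CSF as a proportion of intracranial
#' volume.
#'
#' @param ve a \linkS4class{VolumetricExperiment} or a named numeric vector
#'   of one subject's segment volumes.
#' @param measures which measures to return; defaults to all segments and
#'   composites with a relative form.
#' @return numeric matrix (measures x subjects) of unitless proportions, or
#'   a named vector for single-subject input.
#' @examples
#' ve <- .exampleVolumetricExperiment()
#' rel <- computeRelative(ve)
#' colSums(rel[segmentNames(), ]) # tissue shares of TTV, close to 1
#' @export
computeRelative <- function(ve, measures = NULL) {
    if (is.numeric(ve) && !is.matrix(ve) && !is(ve, "SummarizedExperiment"))
        return(computeRelative(.segmentMatrix(ve), measures)[, 1])
    v <- if (is(ve, "SummarizedExperiment"))
        SummarizedExperiment::assay(ve, "volumes") else as.matrix(ve)
    .validateSegments(v)
    agg <- computeAggregates(v)
    full <- rbind(v[setdiff(rownames(v), rownames(agg)), , drop = FALSE], agg)
    if (is.null(measures))
        measures <- names(which(!is.na(relativeDenominator(rownames(full)))))
    den <- relativeDenominator(measures)
    if (any(is.na(den)))
        stop("no relative form for measure(s): ",
             paste(measures[is.na(den)], collapse = ", "))
    if (ncol(v) > 0) {
        dn <- agg[c("TTV", "TBV", "ICV"), , drop = FALSE]
        if (any(dn <= 0))
            stop("degenerate input: zero whole-brain denominator for subject(s) ",
                 paste(colnames(v)[colSums(dn <= 0) > 0], collapse = ", "))
    }
    out <- full[measures, , drop = FALSE] / agg[den, , drop = FALSE]
    rownames(out) <- measures
    out
}

#' Measure matrix for modelling
#'
#' Returns the matrix of volumetric measures used by the normative models:
#' either absolute volumes (segments plus aggregates, cm\eqn{^3}) or
#' relative volumes (proportions of their whole-brain denominators).
#'
#' @param ve a \linkS4class{VolumetricExperiment}.
#' @param type \code{"absolute"} or \code{"relative"}.
#' @return numeric matrix, measures x subjects.
#' @export
measureMatrix <- function(ve, type = c("absolute", "relative")) {
    type <- match.arg(type)
    v <- SummarizedExperiment::assay(ve, "volumes")
    if (type == "absolute") rbind(v, computeAggregates(ve)) else computeRelative(ve)
}

#' Read and write segment-volume and demographics tables
#'
#' CSV conventions: comma-delimited, decimal point, UTF-8, one row per
#' subject. The volume table has a \code{subject_id} column plus one column
#' per segment (all of \code{requiredSegmentNames()};
#' \code{unlabeled_intracranial} optional). The demographics table has
#' \code{subject_id}, \code{sex}, \code{ga_birth}, \code{pma_scan},
#' \code{group} and optional \code{chd} and growth columns.
#'
#' @param volumesFile,demographicsFile CSV paths.
#' @return a \linkS4class{VolumetricExperiment}.
#' @export
readVolumetricExperiment <- function(volumesFile, demographicsFile) {
    vol <- read.csv(volumesFile, stringsAsFactors = FALSE)
    dem <- read.csv(demographicsFile, stringsAsFactors = FALSE)
    if (!"subject_id" %in% colnames(vol))
        stop("volume table needs a subject_id column")
    if (!"subject_id" %in% colnames(dem))
        stop("demographics table needs a subject_id column")
    ids <- vol$subject_id
    if (!setequal(ids, dem$subject_id))
        stop("subject_id sets differ between the two tables")
    dem <- dem[match(ids, dem$subject_id), , drop = FALSE]
    m <- t(as.matrix(vol[, setdiff(colnames(vol), "subject_id"), drop = FALSE]))
    colnames(m) <- ids
    VolumetricExperiment(m, dem)
}

#' @rdname readVolumetricExperiment
#' @param ve a \linkS4class{VolumetricExperiment}.
#' @param file output CSV path.
#' @export
writeVolumeTable <- function(ve, file) {
    v <- SummarizedExperiment::assay(ve, "volumes")
    df <- data.frame(subject_id = colnames(v), t(v), check.names = FALSE)
    write.csv(df, file, row.names = FALSE)
    invisible(file)
}

#' @rdname readVolumetricExperiment
#' @export
writeDemographicsTable <- function(ve, file) {
    cd <- as.data.frame(SummarizedExperiment::colData(ve))
    write.csv(cd, file, row.names = FALSE)
    invisible(file)
}

#' Demographic cohort summary
#'
#' Counts and percentages of the categorical cohort descriptors (female sex,
#' preterm birth below 37 weeks gestation, non-singleton pregnancy, CHD,
#' gastrointestinal malformation where recorded), plus medians and ranges of
#' the age variables. Percentages are reported to one decimal place, as in
#' cohort demographics tables.
#'
#' @param subjects data.frame of subject records (or a
#'   \linkS4class{VolumetricExperiment}).
#' @return data.frame with columns \code{variable}, \code{count}, \code{n},
#'   \code{percent}.
#' @examples
#' ve <- .exampleVolumetricExperiment(20)
#' demographicSummary(ve)
#' @export
demographicSummary <- function(subjects) {
    if (is(subjects, "SummarizedExperiment"))
        subjects <- as.data.frame(SummarizedExperiment::colData(subjects))
    n <- nrow(subjects)
    row <- function(variable, count)
        data.frame(variable = variable, count = count, n = n,
                   percent = round(100 * count / n, 1))
    out <- rbind(
        row("female", sum(subjects$sex == "female")),
        row("preterm_lt_37", sum(subjects$ga_birth < 37)))
    if ("singleton" %in% colnames(subjects))
        out <- rbind(out, row("non_singleton", sum(!subjects$singleton)))
    if ("chd" %in% colnames(subjects) && !all(is.na(subjects$chd)))
        out <- rbind(out, row("chd", sum(subjects$chd, na.rm = TRUE)))
    if ("gi_malformation" %in% colnames(subjects))
        out <- rbind(out, row("gi_malformation",
                              sum(subjects$gi_malformation, na.rm = TRUE)))
    out
}

#' Standard-normal mass beyond a deviation threshold
#'
#' The per-tail probability that a standard-normal deviate exceeds the
#' extreme-deviation threshold, as a percentage. At the default threshold of
#' 2.6 SD each tail holds about half a percent of the reference population.
#'
#' @param threshold positive z threshold (default 2.6).
#' @return percentage (one tail).
#' @examples
#' extremeTailPercent() # ~0.47, i.e. "top and bottom 0.5%"
#' @export
extremeTailPercent <- function(threshold = 2.6) {
    stopifnot(threshold > 0)
    100 * pnorm(-threshold)
}
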