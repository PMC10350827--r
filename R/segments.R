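#' Neonatal brain segmentation taxonomy
#'
#' The volumetric pipeline works on a fixed segmentation of the neonatal
#' brain into 19 specific tissue segments (six cortical grey-matter and six
#' white-matter lobar segments, cerebellum, brainstem, caudate, lentiform,
#' thalamus, hippocampus and amygdala), two CSF-filled compartments
#' (extra-cerebral CSF and the lateral ventricles) and an optional
#' unlabelled intracranial remainder. Whole-brain denominators are derived
#' from these: total tissue volume (TTV) sums the tissue segments plus the
#' unlabelled remainder, total brain volume (TBV) adds the lateral
#' ventricles, and intracranial volume (ICV) adds the extra-cerebral CSF.
#'
#' @return \code{segmentNames()} returns the character vector of the 19
#'   tissue segment names; \code{csfSegmentNames()} the two CSF compartment
#'   names; \code{requiredSegmentNames()} their union (the 21 keys every
#'   volume table must carry); \code{aggregateNames()} the names of the
#'   derived aggregates; \code{aggregateMembers()} a named list mapping each
#'   aggregate to its member segments.
#'
#' @examples
#' segmentNames()
#' aggregateMembers()$posterior_fossa
#' @export
segmentNames <- function() {
    c("frontal_gm", "frontal_wm", "temporal_gm", "temporal_wm",
      "parietal_gm", "parietal_wm", "occipital_gm", "occipital_wm",
      "insula_gm", "insula_wm", "cingulate_gm", "cingulate_wm",
      "cerebellum", "brainstem", "caudate", "lentiform", "thalamus",
      "hippocampus", "amygdala")
}

#' @rdname segmentNames
#' @export
csfSegmentNames <- function() {
    c("ecsf", "lateral_ventricles")
}

#' @rdname segmentNames
#' @export
requiredSegmentNames <- function() {
    c(segmentNames(), csfSegmentNames())
}

.UNLABELED <- "unlabeled_intracranial"

.GM_SEGMENTS <- c("frontal_gm", "temporal_gm", "parietal_gm",
                  "occipital_gm", "insula_gm", "cingulate_gm")
.WM_SEGMENTS <- c("frontal_wm", "temporal_wm", "parietal_wm",
                  "occipital_wm", "insula_wm", "cingulate_wm")

#' @rdname segmentNames
#' @export
aggregateMembers <- function() {
    list(
        total_cortical_gm  = .GM_SEGMENTS,
        total_wm           = .WM_SEGMENTS,
        # the unlabelled intracranial remainder is counted with the deep
        # grey matter; hippocampus and amygdala are kept outside it
        total_deep_gm      = c("caudate", "lentiform", "thalamus", .UNLABELED),
        total_frontal_lobe   = c("frontal_gm", "frontal_wm"),
        total_temporal_lobe  = c("temporal_gm", "temporal_wm"),
        total_parietal_lobe  = c("parietal_gm", "parietal_wm"),
        total_occipital_lobe = c("occipital_gm", "occipital_wm"),
        total_insula         = c("insula_gm", "insula_wm"),
        total_cingulate      = c("cingulate_gm", "cingulate_wm"),
        posterior_fossa    = c("cerebellum", "brainstem"),
        basal_ganglia      = c("caudate", "lentiform"),
        TTV = c(segmentNames(), .UNLABELED),
        TBV = c(segmentNames(), .UNLABELED, "lateral_ventricles"),
        ICV = c(segmentNames(), .UNLABELED, "lateral_ventricles", "ecsf")
    )
}

#' @rdname segmentNames
#' @export
aggregateNames <- function() {
    names(aggregateMembers())
}

#' Relative-volume denominator for a measure
#'
#' Tissue segments and tissue composites are expressed as a proportion of
#' total tissue volume (TTV); the lateral ventricles as a proportion of
#' total brain volume (TBV); extra-cerebral CSF as a proportion of
#' intracranial volume (ICV). The whole-brain volumes themselves have no
#' relative form.
#'
#' @param measure character vector of segment or aggregate names.
#' @return character vector of denominator names (\code{"TTV"},
#'   \code{"TBV"} or \code{"ICV"}), \code{NA} for measures with no relative
#'   form.
#' @examples
#' relativeDenominator(c("cerebellum", "lateral_ventricles", "ecsf", "TTV"))
#' @export
relativeDenominator <- function(measure) {
    vapply(measure, function(m) {
        if (m %in% c("TTV", "TBV", "ICV")) return(NA_character_)
        if (m == "lateral_ventricles") return("TBV")
        if (m == "ecsf") return("ICV")
        if (m %in% c(segmentNames(), .UNLABELED) ||
            m %in% setdiff(aggregateNames(), c("TTV", "TBV", "ICV")))
            return("TTV")
        NA_character_
    }, character(1))
}
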