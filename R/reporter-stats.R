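# Dual-reporter readthrough quantification: background-corrected
# FLuc/RLuc ratios, readthrough efficiency against a sense-codon control,
# relative readthrough levels, and the imaging GFP/mCD8 ratio.

#' Background-corrected relative luminescence (FLuc/RLuc)
#'
#' @param fluc,rluc raw luminescence counts.
#' @param flucBg,rlucBg background counts.
#' @return dimensionless ratio (corrected FLuc over corrected RLuc).
#'   A negative corrected FLuc is kept (flagged by a warning); a
#'   non-positive corrected RLuc is an invalid transfection control and an
#'   error.
#' @examples
#' relativeLuminescence(1100, 600, 100, 100)  # 2.0
#' @export
relativeLuminescence <- function(fluc, rluc, flucBg = 0, rlucBg = 0) {
    stopifnot(all(fluc >= 0), all(rluc >= 0))
    cf <- fluc - flucBg
    cr <- rluc - rlucBg
    if (any(cr <= 0))
        stop("invalid transfection control: corrected RLuc <= 0")
    if (any(cf < 0))
        warning("negative corrected FLuc value(s)")
    cf / cr
}

#' Readthrough efficiency relative to a sense-codon control
#'
#' The FLuc/RLuc ratio of a readthrough reporter expressed as a percentage
#' of the matched sense-codon control (stop codon mutated to a sense
#' codon, defining 100\% readthrough).
#'
#' @param testMean mean corrected ratio of the readthrough construct.
#' @param senseControlMean mean corrected ratio of the sense-codon
#'   control; must be positive.
#' @return percentage.
#' @examples
#' readthroughEfficiency(4.1, 22)  # about 18.6
#' @export
readthroughEfficiency <- function(testMean, senseControlMean) {
    if (any(senseControlMean <= 0))
        stop("sense-codon control mean must be > 0")
    100 * testMean / senseControlMean
}

#' Readthrough levels relative to a reference construct
#'
#' Rescales per-construct readthrough efficiencies so the reference
#' construct maps to exactly 1.
#'
#' @param efficiencies named numeric vector of efficiencies (percent).
#' @param reference name of the reference construct; must be present with
#'   a positive efficiency.
#' @return named numeric vector of ratios.
#' @export
relativeReadthroughLevel <- function(efficiencies, reference) {
    if (!reference %in% names(efficiencies))
        stop("reference construct '", reference, "' missing")
    ref <- efficiencies[[reference]]
    if (ref <= 0) stop("reference efficiency must be > 0")
    out <- efficiencies / ref
    out[[reference]] <- 1
    out
}

#' Per-construct efficiencies from a plate-reader table
#'
#' Computes background-corrected FLuc/RLuc ratios, averages them per
#' construct (mean of ratios across replicates by default, or ratio of
#' means with \code{perReplicate = FALSE}... the two orders of averaging
#' differ under noise and both are in use; the default averages
#' per-replicate ratios), and expresses each construct relative to the
#' sense-codon control.
#'
#' @param plate data.frame with columns \code{construct_id}, \code{fluc},
#'   \code{rluc}, \code{fluc_bg}, \code{rluc_bg}.
#' @param senseControl construct id of the sense-codon control.
#' @param perReplicate average per-replicate ratios (TRUE, default) or
#'   compute one ratio of summed corrected signals per construct (FALSE).
#' @return data.frame with \code{construct_id}, \code{mean_ratio},
#'   \code{n}, \code{efficiency_percent}, sorted by construct id.
#' @export
plateEfficiencies <- function(plate, senseControl, perReplicate = TRUE) {
    need <- c("construct_id", "fluc", "rluc", "fluc_bg", "rluc_bg")
    missing <- setdiff(need, names(plate))
    if (length(missing))
        stop("plate table lacks column(s): ", paste(missing, collapse = ", "))
    if (!senseControl %in% plate$construct_id)
        stop("sense-codon control '", senseControl, "' not in plate table")
    ids <- sort(unique(plate$construct_id), method = "radix")
    meanRatio <- vapply(ids, function(id) {
        sub <- plate[plate$construct_id == id, , drop = FALSE]
        if (perReplicate)
            mean(relativeLuminescence(sub$fluc, sub$rluc, sub$fluc_bg,
                                      sub$rluc_bg))
        else
            sum(sub$fluc - sub$fluc_bg) / sum(sub$rluc - sub$rluc_bg)
    }, numeric(1))
    ctrl <- meanRatio[[senseControl]]
    data.frame(construct_id = ids,
               mean_ratio = unname(meanRatio),
               n = as.integer(table(plate$construct_id)[ids]),
               efficiency_percent =
                   unname(readthroughEfficiency(meanRatio, ctrl)),
               row.names = NULL)
}

#' In-vivo readthrough ratio from imaging intensities
#'
#' Background-corrected GFP over background-corrected mCD8 intensity (per
#' unit area), with an optional adjustment of the mCD8 normalizer towards
#' a reference construct's mean mCD8 level:
#' \code{adjust = "multiply"} multiplies the raw ratio by
#' (corrected sample mCD8) / (reference mean), compensating constructs
#' whose membrane-marker expression deviates from the reference;
#' \code{"divide"} applies the reciprocal orientation; \code{"none"}
#' returns the raw ratio.
#'
#' @param gfp,gfpBg,mcd8,mcd8Bg intensities per unit area.
#' @param referenceMcd8Mean reference mean corrected mCD8 intensity.
#' @param adjust \code{"multiply"} (default), \code{"divide"} or
#'   \code{"none"}.
#' @return dimensionless ratio.
#' @export
invivoReadthroughRatio <- function(gfp, gfpBg, mcd8, mcd8Bg,
                                   referenceMcd8Mean = NULL,
                                   adjust = c("multiply", "divide", "none")) {
    adjust <- match.arg(adjust)
    cm <- mcd8 - mcd8Bg
    if (any(cm <= 0))
        stop("non-positive corrected mCD8 denominator")
    ratio <- (gfp - gfpBg) / cm
    if (adjust == "none") return(ratio)
    if (is.null(referenceMcd8Mean) || any(referenceMcd8Mean <= 0))
        stop("referenceMcd8Mean must be a positive value")
    if (adjust == "multiply") ratio * cm / referenceMcd8Mean
    else ratio * referenceMcd8Mean / cm
}
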