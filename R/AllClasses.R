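#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData rowData<- colData<- assays<-
NULL

#' SexExperiment: counts with feature lengths and sample sex
#'
#' A thin extension of \linkS4class{SummarizedExperiment} for gene- or
#' isoform-level count data from a two-sex cohort. The first assay is
#' \code{"counts"} (non-negative integers); \code{rowData} carries a
#' \code{length} column (feature length in bp, used for TPM) and
#' \code{colData} carries \code{sex} (\code{"male"}/\code{"female"}) and an
#' optional \code{batch} column (e.g. collection week).
#'
#' @slot .. see \linkS4class{SummarizedExperiment}.
#' @export
setClass("SexExperiment", contains = "SummarizedExperiment")

setValidity("SexExperiment", function(object) {
    msg <- character()
    if (!"counts" %in% names(assays(object)))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cnt <- assay(object, "counts")
        if (any(cnt < 0, na.rm = TRUE))
            msg <- c(msg, "counts must be non-negative")
    }
    if (!"length" %in% names(rowData(object)))
        msg <- c(msg, "rowData must contain a 'length' column")
    else if (any(rowData(object)$length <= 0, na.rm = TRUE))
        msg <- c(msg, "feature lengths must be > 0")
    if (!"sex" %in% names(colData(object)))
        msg <- c(msg, "colData must contain a 'sex' column")
    else if (!all(colData(object)$sex %in% c("male", "female")))
        msg <- c(msg, "sex labels must be 'male' or 'female'")
    if (length(msg)) msg else TRUE
})

#' Construct a SexExperiment
#'
#' @param counts integer matrix, features x samples; rownames are feature ids.
#' @param lengths numeric vector of feature lengths (bp), one per row.
#' @param sex character vector of sample sexes ("male"/"female").
#' @param batch optional character/factor of batch labels (collection week).
#' @param rowData optional extra per-feature annotation (a DataFrame).
#' @return A \linkS4class{SexExperiment}.
#' @examples
#' m <- matrix(rpois(20, 10), 5, 4,
#'             dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
#' se <- SexExperiment(m, lengths = rep(1000, 5),
#'                     sex = c("male", "male", "female", "female"))
#' @export
SexExperiment <- function(counts, lengths, sex, batch = NULL, rowData = NULL) {
    counts <- as.matrix(counts)
    if (length(lengths) != nrow(counts))
        stop("'lengths' must have one entry per feature")
    if (length(sex) != ncol(counts))
        stop("'sex' must have one entry per sample")
    rd <- DataFrame(length = as.numeric(lengths), row.names = rownames(counts))
    if (!is.null(rowData)) {
        extra <- as(rowData, "DataFrame")
        rd <- cbind(rd, extra[, setdiff(colnames(extra), "length"),
                              drop = FALSE])
    }
    cd <- DataFrame(sex = as.character(sex), row.names = colnames(counts))
    if (!is.null(batch)) cd$batch <- as.character(batch)
    new("SexExperiment",
        SummarizedExperiment(assays = list(counts = counts),
                             rowData = rd, colData = cd))
}

#' SEEventSet: skipped-exon events with junction counts
#'
#' Container for skipped-exon (SE) alternative-splicing events. Each event has
#' per-sample inclusion (I) and skipping (S) junction counts and effective
#' lengths for the inclusion and skipping forms; event coordinates locate the
#' skipped exon and its flanking exons on the genome.
#'
#' @slot events a \code{DataFrame} with one row per event: \code{event_id},
#'   \code{gene_id}, \code{chrom}, \code{strand}, \code{exon_start},
#'   \code{exon_end} (the skipped exon, 1-based inclusive),
#'   \code{upstream_end}, \code{downstream_start} (flanking exon boundaries),
#'   \code{inc_len}, \code{skip_len} (effective lengths, default 2 and 1).
#' @slot inclusion,skipping integer matrices, events x samples.
#' @slot sampleSex character, one of "male"/"female" per sample.
#' @export
setClass("SEEventSet",
    representation(events = "DataFrame",
                   inclusion = "matrix",
                   skipping = "matrix",
                   sampleSex = "character"))

setValidity("SEEventSet", function(object) {
    msg <- character()
    ev <- object@events
    need <- c("event_id", "gene_id", "chrom", "strand",
              "exon_start", "exon_end", "inc_len", "skip_len")
    miss <- setdiff(need, colnames(ev))
    if (length(miss))
        msg <- c(msg, paste("events is missing columns:",
                            paste(miss, collapse = ", ")))
    if (!identical(dim(object@inclusion), dim(object@skipping)))
        msg <- c(msg, "inclusion and skipping matrices must match in shape")
    if (nrow(object@inclusion) != nrow(ev))
        msg <- c(msg, "one matrix row per event is required")
    if (ncol(object@inclusion) != length(object@sampleSex))
        msg <- c(msg, "one sex label per sample column is required")
    if (any(object@inclusion < 0) || any(object@skipping < 0))
        msg <- c(msg, "junction counts must be non-negative")
    if (!length(miss) && nrow(ev) &&
        (any(ev$inc_len < 1) || any(ev$skip_len < 1)))
        msg <- c(msg, "effective lengths must be >= 1")
    if (!all(object@sampleSex %in% c("male", "female")))
        msg <- c(msg, "sampleSex must be 'male' or 'female'")
    if (length(msg)) msg else TRUE
})

#' Construct an SEEventSet
#'
#' @param events DataFrame/data.frame of event descriptions (see
#'   \linkS4class{SEEventSet}). Missing \code{inc_len}/\code{skip_len} default
#'   to 2 and 1 (two inclusion junctions vs one skipping junction).
#' @param inclusion,skipping integer matrices of junction counts
#'   (events x samples).
#' @param sampleSex character vector of per-sample sexes.
#' @return An \linkS4class{SEEventSet}.
#' @export
SEEventSet <- function(events, inclusion, skipping, sampleSex) {
    events <- as(events, "DataFrame")
    if (is.null(events$inc_len)) events$inc_len <- 2
    if (is.null(events$skip_len)) events$skip_len <- 1
    inclusion <- as.matrix(inclusion)
    skipping <- as.matrix(skipping)
    if (is.null(rownames(inclusion))) rownames(inclusion) <- events$event_id
    if (is.null(rownames(skipping))) rownames(skipping) <- events$event_id
    new("SEEventSet", events = events, inclusion = inclusion,
        skipping = skipping, sampleSex = as.character(sampleSex))
}

setMethod("show", "SexExperiment", function(object) {
    callNextMethod()
    tab <- table(colData(object)$sex)
    cat("sex: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n",
        sep = "")
})

setMethod("show", "SEEventSet", function(object) {
    cat("SEEventSet with", nrow(object@events), "skipped-exon events and",
        ncol(object@inclusion), "samples\n")
    tab <- table(object@sampleSex)
    cat("sex: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n",
        sep = "")
})

#' @rdname SEEventSet
#' @param object an SEEventSet.
#' @export
eventInfo <- function(object) object@events

#' @rdname SEEventSet
#' @export
inclusionCounts <- function(object) object@inclusion

#' @rdname SEEventSet
#' @export
skippingCounts <- function(object) object@skipping

#' @rdname SEEventSet
#' @export
sampleSex <- function(object) {
    if (is(object, "SEEventSet")) object@sampleSex
    else as.character(colData(object)$sex)
}

#' Feature lengths of a SexExperiment
#' @param object a SexExperiment.
#' @export
featureLengths <- function(object) {
    stats::setNames(rowData(object)$length, rownames(object))
}
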