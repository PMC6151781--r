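#' Accessors for iseScreen classes
#'
#' \code{moleculeIds} and \code{descriptorNames} return the row and column
#' identities of a \linkS4class{DescriptorTable}; \code{descriptorValues} its
#' numeric matrix. \code{filters} and \code{nFilters} access the member
#' filters of a \linkS4class{FilterEnsemble}; \code{descriptorPool} its
#' descriptor universe and \code{trainingMeta} its metadata.
#' \code{conditions} returns a \linkS4class{RangeFilter}'s condition table
#' and \code{efficiency} its \linkS4class{FilterEfficiency} (or NULL).
#' \code{efficiencyRates} flattens a FilterEfficiency to a named vector
#' (PA, PNA, NA, NNA, MCC). \code{mbiScores} extracts the ranked score table
#' of a \linkS4class{ScreenResult}; \code{fpScheme} the scheme label of a
#' \linkS4class{FingerprintSet}.
#'
#' @param x the object.
#' @return See each description above.
#' @name accessors
#' @examples
#' tab <- DescriptorTable(matrix(1:4, 2, 2,
#'     dimnames = list(c("a", "b"), c("MW", "logP"))))
#' moleculeIds(tab)
#' descriptorNames(tab)
NULL

#' @rdname accessors
#' @export
setGeneric("moleculeIds", function(x) standardGeneric("moleculeIds"))
#' @rdname accessors
#' @export
setGeneric("descriptorNames", function(x) standardGeneric("descriptorNames"))
#' @rdname accessors
#' @export
setGeneric("descriptorValues", function(x) standardGeneric("descriptorValues"))
#' @rdname accessors
#' @export
setGeneric("filters", function(x) standardGeneric("filters"))
#' @rdname accessors
#' @export
setGeneric("nFilters", function(x) standardGeneric("nFilters"))
#' @rdname accessors
#' @export
setGeneric("descriptorPool", function(x) standardGeneric("descriptorPool"))
#' @rdname accessors
#' @export
setGeneric("trainingMeta", function(x) standardGeneric("trainingMeta"))
#' @rdname accessors
#' @export
setGeneric("conditions", function(x) standardGeneric("conditions"))
#' @rdname accessors
#' @export
setGeneric("efficiency", function(x) standardGeneric("efficiency"))
#' @rdname accessors
#' @export
setGeneric("efficiencyRates", function(x) standardGeneric("efficiencyRates"))
#' @rdname accessors
#' @export
setGeneric("mbiScores", function(x) standardGeneric("mbiScores"))
#' @rdname accessors
#' @export
setGeneric("fpScheme", function(x) standardGeneric("fpScheme"))

#' @rdname accessors
setMethod("moleculeIds", "DescriptorTable", function(x) rownames(x@values))
#' @rdname accessors
setMethod("descriptorNames", "DescriptorTable", function(x) colnames(x@values))
#' @rdname accessors
setMethod("descriptorValues", "DescriptorTable", function(x) x@values)
#' @rdname accessors
setMethod("filters", "FilterEnsemble", function(x) x@filters)
#' @rdname accessors
setMethod("nFilters", "FilterEnsemble", function(x) length(x@filters))
#' @rdname accessors
setMethod("descriptorPool", "FilterEnsemble", function(x) x@descriptorPool)
#' @rdname accessors
setMethod("trainingMeta", "FilterEnsemble", function(x) x@trainingMeta)
#' @rdname accessors
setMethod("conditions", "RangeFilter", function(x) x@conditions)
#' @rdname accessors
setMethod("efficiency", "RangeFilter", function(x) x@efficiency)
#' @rdname accessors
setMethod("efficiencyRates", "FilterEfficiency", function(x)
    c(PA = x@pa, PNA = x@pna, "NA" = x@na, NNA = x@nna, MCC = x@mcc))
#' @rdname accessors
setMethod("mbiScores", "ScreenResult", function(x)
    data.frame(id = x@ids, mbi = x@mbi,
               n_passed = as.integer(rowSums(x@passMatrix)),
               row.names = NULL, stringsAsFactors = FALSE))
#' @rdname accessors
setMethod("fpScheme", "FingerprintSet", function(x) x@scheme)
#' @rdname accessors
setMethod("moleculeIds", "FingerprintSet", function(x) rownames(x@bits))
#' @rdname accessors
setMethod("moleculeIds", "ScreenResult", function(x) x@ids)

#' Subset a DescriptorTable
#'
#' Standard two-index subsetting by molecule and descriptor; always keeps
#' matrix structure (no dimension dropping).
#'
#' @param x a \linkS4class{DescriptorTable}.
#' @param i,j row (molecule) and column (descriptor) indices.
#' @param ... ignored.
#' @param drop ignored; dimensions are never dropped.
#' @return A \linkS4class{DescriptorTable}.
#' @export
setMethod("[", "DescriptorTable", function(x, i, j, ..., drop = FALSE) {
    v <- x@values
    if (!missing(i)) v <- v[i, , drop = FALSE]
    if (!missing(j)) v <- v[, j, drop = FALSE]
    new("DescriptorTable", values = v)
})

#' @describeIn DescriptorTable-class number of molecules and descriptors
#' @param x a DescriptorTable.
#' @export
setMethod("dim", "DescriptorTable", function(x) dim(x@values))

#' Subset a FingerprintSet by molecule
#'
#' @param x a \linkS4class{FingerprintSet}.
#' @param i molecule indices or ids.
#' @param j,...,drop ignored.
#' @return A \linkS4class{FingerprintSet}.
#' @export
setMethod("[", "FingerprintSet", function(x, i, j, ..., drop = FALSE)
    new("FingerprintSet", bits = x@bits[i, , drop = FALSE],
        scheme = x@scheme))

setMethod("show", "DescriptorTable", function(object) {
    d <- dim(object@values)
    cat("DescriptorTable:", d[1], "molecules x", d[2], "descriptors\n")
    if (d[2]) {
        nm <- colnames(object@values)
        cat("  descriptors:", paste(utils::head(nm, 5), collapse = ", "),
            if (d[2] > 5) "..." else "", "\n")
    }
})

setMethod("show", "FilterEfficiency", function(object) {
    cat(sprintf(
        "FilterEfficiency: PA %.2f%%  PNA %.2f%%  NA %.2f%%  NNA %.2f%%  MCC %.3f\n",
        object@pa, object@pna, object@na, object@nna, object@mcc))
})

setMethod("show", "RangeFilter", function(object) {
    cn <- object@conditions
    cat("RangeFilter with", nrow(cn), "condition(s):\n")
    for (k in seq_len(nrow(cn)))
        cat(sprintf("  %s (%.2f-%.2f)\n", cn$descriptor[k], cn$low[k],
                    cn$high[k]))
    if (!is.null(object@efficiency)) show(object@efficiency)
})

setMethod("show", "FilterEnsemble", function(object) {
    mccs <- vapply(object@filters, function(f) f@efficiency@mcc, numeric(1))
    cat("FilterEnsemble:", length(object@filters), "unique filters over a",
        length(object@descriptorPool), "descriptor pool\n")
    cat(sprintf("  training MCC: %.3f-%.3f (median %.3f)\n",
                min(mccs), max(mccs), stats::median(mccs)))
})

setMethod("show", "ScreenResult", function(object) {
    cat("ScreenResult:", length(object@ids), "molecules x",
        ncol(object@passMatrix), "filters\n")
    if (length(object@ids))
        cat(sprintf("  MBI range: %.3f to %.3f\n", min(object@mbi),
                    max(object@mbi)))
})

setMethod("show", "FingerprintSet", function(object) {
    cat("FingerprintSet:", nrow(object@bits), "molecules,",
        ncol(object@bits), "bits, scheme", object@scheme, "\n")
})

setMethod("show", "IseConfig", function(object) {
    cat(sprintf(
        "IseConfig: k=%d, M=%d, elim %.0f%%/top %.0f%%, limit %g, restarts %d, floor %.2f, seed %d\n",
        object@filterSize, object@sampleSize, 100 * object@elimFraction,
        100 * object@topFraction, object@exhaustiveLimit, object@restarts,
        object@mccFloor, object@seed))
})

setMethod("show", "BenchmarkSpec", function(object) {
    cat(sprintf(
        "BenchmarkSpec: %d actives vs %d inactives, %d descriptors (%d informative), box width %.2f, noise %.2f, seed %d\n",
        object@nActive, object@nInactive, object@nDescriptors,
        object@nInformative, object@boxWidth, object@noiseRate, object@seed))
})

#' @describeIn ScreenResult-class ranked data.frame (id, mbi, n_passed,
#'   pass vector as a bitstring)
#' @param x a ScreenResult.
#' @param row.names,optional,... passed through conventions of the generic,
#'   ignored.
#' @export
as.data.frame.ScreenResult <- function(x, row.names = NULL, optional = FALSE,
                                       ...) {
    df <- mbiScores(x)
    df$pass_vector <- apply(x@passMatrix, 1L, function(b)
        paste(as.integer(b), collapse = ""))
    df
}
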