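MODEL_SCHEMA_VERSION <- "1.0"

# Syntactic SMILES validation. OpenBabel silently repairs many malformed
# strings (e.g. unbalanced parentheses), so structural errors are caught
# here before parsing: balanced () and [], paired ring-closure digits,
# legal atom/bond symbols outside brackets.
.validSmilesSyntax <- function(s) {
    if (is.na(s) || !nzchar(s)) return(FALSE)
    chars <- strsplit(s, "")[[1]]
    n <- length(chars)
    depth <- 0L; inBracket <- FALSE; bracketLen <- 0L
    rings <- integer(0)
    twoChar <- c(Cl = "l", Br = "r")
    organic <- c("B", "C", "N", "O", "P", "S", "F", "I",
                 "b", "c", "n", "o", "p", "s", "*")
    bonds <- c("-", "=", "#", "$", ":", "/", "\\", ".")
    i <- 1L
    while (i <= n) {
        ch <- chars[i]
        if (inBracket) {
            bracketLen <- bracketLen + 1L
            if (ch == "[") return(FALSE)
            if (ch == "]") {
                if (bracketLen <= 1L) return(FALSE)
                inBracket <- FALSE
            }
            i <- i + 1L
            next
        }
        if (ch == "[") { inBracket <- TRUE; bracketLen <- 0L }
        else if (ch == "]") return(FALSE)
        else if (ch == "(") depth <- depth + 1L
        else if (ch == ")") {
            depth <- depth - 1L
            if (depth < 0L) return(FALSE)
        } else if (ch == "%") {
            if (i + 2L > n || !all(grepl("[0-9]", chars[i + 1:2])))
                return(FALSE)
            id <- as.integer(paste(chars[i + 1:2], collapse = ""))
            rings <- .toggleRing(rings, id)
            i <- i + 2L
        } else if (grepl("[0-9]", ch)) {
            rings <- .toggleRing(rings, as.integer(ch))
        } else if (ch %in% names(twoChar) && i < n &&
                   chars[i + 1L] == twoChar[[ch]]) {
            i <- i + 1L
        } else if (!(ch %in% c(organic, bonds))) {
            return(FALSE)
        }
        i <- i + 1L
    }
    depth == 0L && !inBracket && length(rings) == 0L
}

.toggleRing <- function(open, id) {
    if (id %in% open) setdiff(open, id) else c(open, id)
}

#' Read molecules from a SMILES file
#'
#' Reads a whitespace-separated SMILES file: each non-empty line is either
#' "SMILES id" or a bare SMILES (the id is then auto-assigned
#' \code{m<line number>}). Lines failing SMILES validation are counted and
#' reported in the \code{rejected} attribute, never silently dropped.
#' Records whose SMILES canonicalize to an already-seen molecule are kept
#' but flagged in the \code{duplicates} attribute. Reading is deterministic
#' and order-preserving.
#'
#' @param path path to the SMILES file.
#' @param expectedLabel class label attached to every record:
#'   \code{"active"}, \code{"inactive"} or \code{"unknown"}.
#' @return A data.frame with columns \code{id}, \code{smiles} (the input
#'   string, verbatim), \code{canonical} (canonical SMILES), \code{label};
#'   attributes \code{rejected} (data.frame of line/smiles/reason) and
#'   \code{duplicates} (character ids flagged as duplicate structures).
#' @export
readMolecules <- function(path, expectedLabel = c("unknown", "active",
                                                  "inactive")) {
    expectedLabel <- match.arg(expectedLabel)
    if (!file.exists(path))
        stop("input error: file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    keep <- which(nzchar(trimws(lines)))
    rejected <- data.frame(line = integer(0), smiles = character(0),
                           reason = character(0), stringsAsFactors = FALSE)
    ids <- character(0); smis <- character(0); lns <- integer(0)
    for (ln in keep) {
        tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
        smi <- tok[1]
        id <- if (length(tok) >= 2L) tok[2] else sprintf("m%d", ln)
        if (!.validSmilesSyntax(smi)) {
            rejected <- rbind(rejected, data.frame(
                line = ln, smiles = smi, reason = "invalid SMILES syntax",
                stringsAsFactors = FALSE))
            next
        }
        ids <- c(ids, id); smis <- c(smis, smi); lns <- c(lns, ln)
    }
    if (!length(ids))
        stop("empty-dataset error: no valid molecule records in ", path)
    if (anyDuplicated(ids))
        stop("format error: duplicate molecule ids: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    canon <- .canonicalSmiles(smis, ids)
    bad <- which(is.na(canon))
    if (length(bad)) {
        rejected <- rbind(rejected, data.frame(
            line = lns[bad], smiles = smis[bad],
            reason = "unparseable SMILES", stringsAsFactors = FALSE))
        ids <- ids[-bad]; smis <- smis[-bad]; canon <- canon[-bad]
    }
    if (!length(ids))
        stop("empty-dataset error: no valid molecule records in ", path)
    dup <- ids[duplicated(canon)]
    out <- data.frame(id = ids, smiles = smis, canonical = canon,
                      label = expectedLabel, stringsAsFactors = FALSE)
    attr(out, "rejected") <- rejected
    attr(out, "duplicates") <- dup
    out
}

.canonicalSmiles <- function(smiles, ids) {
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(
        stats::setNames(smiles, ids)))
    valid <- ChemmineR::validSDF(sdf)
    canon <- rep(NA_character_, length(smiles))
    if (any(valid)) {
        p <- suppressWarnings(ChemmineR::propOB(sdf[valid]))
        canon[valid] <- trimws(p$cansmi)
    }
    canon[canon == ""] <- NA_character_
    canon
}

#' Read a descriptor table from CSV
#'
#' Expects a header \code{id,<name1>,<name2>,...} with numeric cells.
#' Descriptor names are preserved verbatim (no syntactic-name munging, so
#' MOE-style names like \code{PEOE_VSA+4} survive). Rows containing a
#' non-numeric or missing cell are excluded and reported via the
#' \code{rejected} attribute.
#'
#' @param path CSV path.
#' @return A \linkS4class{DescriptorTable} with attribute \code{rejected}
#'   (character vector of excluded ids).
#' @export
readDescriptorTable <- function(path) {
    if (!file.exists(path))
        stop("input error: file not found: ", path)
    df <- utils::read.csv(path, check.names = FALSE,
                          colClasses = "character", comment.char = "#")
    if (ncol(df) < 2L)
        stop("format error: no descriptor columns in ", path)
    if (colnames(df)[1] != "id")
        stop("format error: first column must be 'id'")
    if (anyDuplicated(df$id))
        stop("format error: duplicate ids: ",
             paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
    vals <- suppressWarnings(
        vapply(df[-1], as.numeric, numeric(nrow(df))))
    vals <- matrix(vals, nrow = nrow(df),
                   dimnames = list(df$id, colnames(df)[-1]))
    badRow <- !stats::complete.cases(vals) | !apply(is.finite(vals), 1, all)
    rejected <- df$id[badRow]
    vals <- vals[!badRow, , drop = FALSE]
    if (!nrow(vals))
        stop("empty-dataset error: no numeric rows in ", path)
    out <- DescriptorTable(vals)
    attr(out, "rejected") <- rejected
    out
}

#' Write a descriptor table to CSV
#'
#' Full-precision (17 significant digits) CSV in the dialect read back by
#' \code{\link{readDescriptorTable}}. Written atomically (temp file +
#' rename).
#'
#' @param table a \linkS4class{DescriptorTable}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeDescriptorTable <- function(table, path) {
    stopifnot(is(table, "DescriptorTable"))
    v <- descriptorValues(table)
    df <- data.frame(id = rownames(v), stringsAsFactors = FALSE,
                     check.names = FALSE)
    for (j in colnames(v)) df[[j]] <- sprintf("%.17g", v[, j])
    tmp <- paste0(path, ".tmp")
    utils::write.csv(df, tmp, row.names = FALSE, quote = TRUE)
    file.rename(tmp, path)
    invisible(path)
}

#' Write / read a trained model as JSON
#'
#' The model file is human-inspectable JSON with an explicit
#' \code{schema_version}: the descriptor pool, every filter's conditions
#' (\code{\{"descriptor", "low", "high"\}}) and efficiency rates at full
#' precision, and the training metadata. \code{readModel} refuses files
#' whose schema version does not match and fails cleanly (no partial model)
#' on corrupted JSON. Writing is atomic. Round-trips are lossless:
#' \code{readModel(writeModel(m))} reproduces every filter bound and rate
#' bit for bit.
#'
#' @param ensemble a \linkS4class{FilterEnsemble}.
#' @param path JSON file path.
#' @return \code{writeModel}: \code{path}, invisibly. \code{readModel}: a
#'   \linkS4class{FilterEnsemble}.
#' @export
writeModel <- function(ensemble, path) {
    stopifnot(is(ensemble, "FilterEnsemble"))
    validObject(ensemble)
    obj <- list(
        schema_version = MODEL_SCHEMA_VERSION,
        descriptor_pool = ensemble@descriptorPool,
        filters = lapply(ensemble@filters, function(f) {
            e <- f@efficiency
            list(conditions = lapply(seq_len(nrow(f@conditions)),
                     function(k) list(
                         descriptor = f@conditions$descriptor[k],
                         low = f@conditions$low[k],
                         high = f@conditions$high[k])),
                 efficiency = list(pa = e@pa, pna = e@pna, na = e@na,
                                   nna = e@nna, mcc = e@mcc))
        }),
        training_meta = ensemble@trainingMeta)
    tmp <- paste0(path, ".tmp")
    # digits = I(17): significant digits, enough for exact double round-trip
    jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = I(17),
                         null = "null")
    file.rename(tmp, path)
    invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
    if (!file.exists(path))
        stop("input error: file not found: ", path)
    obj <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (is.null(obj$schema_version) ||
        !identical(obj$schema_version, MODEL_SCHEMA_VERSION))
        stop("versioned-format error: expected schema_version ",
             MODEL_SCHEMA_VERSION, ", found ",
             if (is.null(obj$schema_version)) "none"
             else obj$schema_version)
    fl <- lapply(obj$filters, function(f) {
        cn <- f$conditions
        rangeFilter(
            vapply(cn, `[[`, character(1), "descriptor"),
            vapply(cn, function(c) as.numeric(c$low), numeric(1)),
            vapply(cn, function(c) as.numeric(c$high), numeric(1)),
            efficiency = new("FilterEfficiency",
                pa = as.numeric(f$efficiency$pa),
                pna = as.numeric(f$efficiency$pna),
                na = as.numeric(f$efficiency$na),
                nna = as.numeric(f$efficiency$nna),
                mcc = as.numeric(f$efficiency$mcc)))
    })
    meta <- .simplifyMeta(obj$training_meta)
    FilterEnsemble(fl,
                   descriptorPool = unlist(obj$descriptor_pool),
                   trainingMeta = meta)
}

# collapse scalar JSON lists back to vectors, recursively, so metadata
# round-trips to its natural R shape
.simplifyMeta <- function(x) {
    if (!is.list(x)) return(x)
    if (is.null(names(x)) && length(x) &&
        all(vapply(x, function(e) is.atomic(e) && length(e) == 1L,
                   logical(1))))
        return(unlist(x))
    lapply(x, .simplifyMeta)
}
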