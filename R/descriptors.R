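# SMARTS patterns used by the count descriptors
.SMARTS <- list(
    rotatable = "[!$(*#*)&!D1]-&!@[!$(*#*)&!D1]",
    donor = "[#7,#8;!H0]")

.REACTIVE_SMARTS <- c(
    acyl_halide = "[CX3](=O)[F,Cl,Br,I]",
    aldehyde = "[CX3H1]=O",
    peroxide = "[OX2][OX2]",
    azide = "[N-]=[N+]=N",
    diazonium = "[N+]#N",
    iso_cyanate = "N=C=[O,S]",
    sulfonyl_halide = "S(=O)(=O)[F,Cl,Br,I]",
    anhydride = "C(=O)OC(=O)")

.SLOGP_EDGES <- c(-Inf, -0.4, -0.2, 0, 0.1, 0.15, 0.2, 0.25, 0.3, 0.4, Inf)
.SMR_EDGES <- c(-Inf, 1.29, 1.82, 2.24, 2.45, 2.75, 3.05, 3.63, Inf)

.registryRows <- function() {
    row <- function(name, description, analog_of = name)
        data.frame(name = name, description = description,
                   analog_of = analog_of, stringsAsFactors = FALSE)
    els <- c("H", "B", "C", "N", "O", "S", "P", "F", "Cl", "Br", "I")
    rbind(
        row("MW", "molecular weight (OpenBabel, average masses)", "Weight"),
        row("logP", "octanol/water partition coefficient (OpenBabel additive model)", "logP(o/w)"),
        row("SMR", "molar refractivity (OpenBabel additive model)"),
        row("TPSA", "topological polar surface area (OpenBabel)"),
        row("logS", "aqueous solubility, ESOL-style linear estimate: 0.16 - 0.63 logP - 0.0062 MW + 0.066 RB - 0.74 AP"),
        row("a_count", "atom count including implicit hydrogens"),
        row("a_heavy", "heavy atom count"),
        row("a_aro", "aromatic atom count"),
        do.call(rbind, lapply(els, function(e)
            row(paste0("a_n", e), paste(e, "atom count (implicit H counted for H)")))),
        row("a_don", "N/O atoms bearing at least one hydrogen (donor atoms)"),
        row("a_acc", "hydrogen-bond acceptor count (OpenBabel HBA2 definition)"),
        row("a_hyd", "hydrophobic atoms: carbons with no N/O neighbor plus halogens"),
        row("a_ICM", "atom information content: entropy (bits) of the element distribution"),
        row("lip_don", "Lipinski donor count (OpenBabel HBD)"),
        row("lip_acc", "Lipinski acceptor count (OpenBabel HBA1)"),
        row("lip_violation", "number of Lipinski rule-of-five violations (MW>500, logP>5, HBD>5, HBA>10)"),
        row("lip_druglike", "1 if at most one Lipinski violation, else 0"),
        row("opr_violation", "number of Oprea lead-likeness violations (MW>450, logP outside [-3.5,4.5], rings>4, rot>10, HBD>5, HBA>8)"),
        row("opr_leadlike", "1 if no Oprea violation, else 0"),
        row("b_count", "bond count including bonds to implicit hydrogens"),
        row("b_heavy", "heavy-heavy bond count"),
        row("b_single", "single heavy bonds (non-aromatic)"),
        row("b_double", "double bonds"),
        row("b_triple", "triple bonds"),
        row("b_ar", "bonds between two aromatic atoms"),
        row("b_rotN", "rotatable bond count (acyclic single bonds between non-terminal heavy atoms)"),
        row("b_rotR", "rotatable bond fraction: b_rotN / b_heavy"),
        row("b_rigid", "rigid bond count: b_heavy - b_rotN"),
        row("rings", "smallest-set ring count (cyclomatic number)"),
        row("Nmol", "number of connected fragments"),
        row("Chiral", "potential tetrahedral stereocenters (carbon with four distinct one-bond substituent signatures)"),
        row("Chiral_u", "potential stereocenters without stereo annotation in the input SMILES"),
        row("Reactive", "matches of a small registry of reactive-group patterns (acyl halide, aldehyde, peroxide, azide, diazonium, iso(thio)cyanate, sulfonyl halide, anhydride)"),
        do.call(rbind, lapply(c("Chi0", "Chi1", "Chi0_C", "Chi1_C"), function(n)
            row(n, "Kier-Hall connectivity index (\"_C\" = carbon-restricted)"))),
        row("VSA", "total approximate van der Waals surface area (Labute-style per-atom approximation)"),
        row("Q_VSA_POS", "VSA over atoms with positive Gasteiger charge"),
        row("Q_VSA_NEG", "VSA over atoms with negative Gasteiger charge"),
        row("Q_VSA_FPOS", "fraction of VSA on positively charged atoms"),
        row("Q_VSA_FNEG", "fraction of VSA on negatively charged atoms"),
        do.call(rbind, lapply(0:6, function(k)
            row(sprintf("PEOE_VSA+%d", k),
                sprintf("VSA of atoms with Gasteiger charge in [%.2f, %s)",
                        0.05 * k, if (k == 6) "Inf" else sprintf("%.2f", 0.05 * (k + 1)))))),
        do.call(rbind, lapply(0:6, function(k)
            row(sprintf("PEOE_VSA-%d", k),
                sprintf("VSA of atoms with Gasteiger charge in (%s, %.2f)",
                        if (k == 6) "-Inf" else sprintf("%.2f", -0.05 * (k + 1)), -0.05 * k)))),
        do.call(rbind, lapply(0:9, function(k)
            row(sprintf("SlogP_VSA%d", k),
                "VSA binned by coarse atomic logP contribution"))),
        do.call(rbind, lapply(0:7, function(k)
            row(sprintf("SMR_VSA%d", k),
                "VSA binned by coarse atomic molar-refractivity contribution"))),
        do.call(rbind, lapply(c("PEOE", "SLOGP", "SMR"), function(p)
            do.call(rbind, lapply(0:3, function(k)
                row(sprintf("BCUT_%s_%d", p, k),
                    sprintf("Burden-matrix eigenvalue quartile %d with %s atomic property on the diagonal", k, p)))))),
        do.call(rbind, lapply(c("PEOE", "SLOGP", "SMR"), function(p)
            do.call(rbind, lapply(0:3, function(k)
                row(sprintf("GCUT_%s_%d", p, k),
                    sprintf("inverse-square graph-distance matrix eigenvalue quartile %d with %s atomic property on the diagonal", k, p)))))))
}

#' The descriptor registry
#'
#' Lists every 2D descriptor the package can compute: the name used in
#' descriptor tables and filters, a description of the formula, and the
#' MOE-style descriptor the entry is an analog of (\code{analog_of}). The
#' registry holds over 100 descriptors spanning the families that dominate
#' range-filter models: partial-charge surface-area bins (PEOE_VSA),
#' refractivity bins (SMR_VSA), logP bins (SlogP_VSA), Burden/graph
#' eigenvalue descriptors (BCUT/GCUT over charge, logP and refractivity),
#' atom/bond/chirality counts, connectivity indices, rule-of-thumb
#' drug-likeness indicators and bulk properties (MW, logP, logS, TPSA).
#' These are documented analogs: exact numerical parity with MOE is not a
#' goal, and externally computed tables can be imported unchanged via
#' \code{\link{readDescriptorTable}}.
#'
#' @return data.frame with columns \code{name}, \code{description},
#'   \code{analog_of}.
#' @examples
#' reg <- listDescriptors()
#' nrow(reg)
#' subset(reg, analog_of == "GCUT_SLOGP_0")
#' @export
listDescriptors <- function() .registryRows()

#' Compute 2D descriptors for a molecule set
#'
#' Parses each molecule's SMILES and computes the requested registry
#' descriptors. Deterministic and permutation-equivariant: the same
#' molecules in a different order give the same rows in that order.
#' Molecules that cannot be parsed (or yield a non-finite value) are
#' excluded from the result and reported via the \code{rejected}
#' attribute; single-atom (bond-less) records are likewise rejected.
#'
#' @param mols a data.frame from \code{\link{readMolecules}} (columns
#'   \code{id}, \code{smiles}) or a named character vector of SMILES.
#' @param names descriptor names to compute (\code{"all"} for the full
#'   registry). Unknown names raise an error listing them.
#' @return A \linkS4class{DescriptorTable} (attribute \code{rejected}:
#'   excluded ids).
#' @examples
#' tab <- computeDescriptors(c(ethanol = "CCO", benzene = "c1ccccc1"),
#'                           names = c("MW", "a_don", "a_aro"))
#' descriptorValues(tab)
#' @export
computeDescriptors <- function(mols, names = "all") {
    reg <- listDescriptors()
    if (identical(names, "all")) names <- reg$name
    unknown <- setdiff(names, reg$name)
    if (length(unknown))
        stop("registry error: unknown descriptor name(s): ",
             paste(unknown, collapse = ", "))
    if (is.data.frame(mols)) {
        smiles <- stats::setNames(mols$smiles, mols$id)
    } else {
        smiles <- mols
        if (is.null(base::names(smiles)))
            base::names(smiles) <- sprintf("m%d", seq_along(smiles))
    }
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
    valid <- ChemmineR::validSDF(sdf)
    rejected <- base::names(smiles)[!valid]
    if (!any(valid))
        stop("empty-dataset error: no parseable molecules")
    sdf <- sdf[valid]
    smiles <- smiles[valid]
    ids <- base::names(smiles)

    props <- suppressWarnings(ChemmineR::propOB(sdf))
    rot <- ChemmineR::smartsSearchOB(sdf, .SMARTS$rotatable,
                                     uniqueMatches = TRUE)
    don <- ChemmineR::smartsSearchOB(sdf, .SMARTS$donor,
                                     uniqueMatches = TRUE)
    reactive <- rep(0, length(sdf))
    for (p in .REACTIVE_SMARTS)
        reactive <- reactive +
            ChemmineR::smartsSearchOB(sdf, p, uniqueMatches = TRUE)

    full <- matrix(NA_real_, length(ids), nrow(reg),
                   dimnames = list(ids, reg$name))
    for (i in seq_along(ids)) {
        full[i, ] <- .descriptorRow(
            ctx = .molContext(sdf[[i]], smiles[[i]]),
            props = props[i, , drop = FALSE],
            rot = rot[i], don = don[i], reactive = reactive[i],
            regNames = reg$name)
    }
    badRow <- !apply(is.finite(full), 1, all)
    rejected <- c(rejected, ids[badRow])
    full <- full[!badRow, names, drop = FALSE]
    if (!nrow(full))
        stop("empty-dataset error: no molecule yielded finite descriptors")
    out <- DescriptorTable(full)
    attr(out, "rejected") <- rejected
    out
}

.descriptorRow <- function(ctx, props, rot, don, reactive, regNames) {
    out <- stats::setNames(numeric(length(regNames)), regNames)
    sym <- ctx$symbols
    mw <- props$MW; logp <- props$logP
    hbd <- props$HBD; hba <- props$HBA1

    out["MW"] <- mw; out["logP"] <- logp
    out["SMR"] <- props$MR; out["TPSA"] <- props$TPSA

    out["a_heavy"] <- ctx$nAtoms
    out["a_count"] <- ctx$nAtoms + sum(ctx$nH)
    out["a_aro"] <- sum(ctx$aromatic)
    for (e in c("B", "C", "N", "O", "S", "P", "F", "Cl", "Br", "I"))
        out[paste0("a_n", e)] <- sum(sym == e)
    out["a_nH"] <- sum(ctx$nH)
    out["a_don"] <- don
    out["a_acc"] <- props$HBA2
    halogens <- sym %in% c("F", "Cl", "Br", "I")
    hydC <- vapply(seq_len(ctx$nAtoms), function(i)
        sym[i] == "C" && !any(sym[ctx$neighbors[[i]]] %in% c("N", "O")),
        logical(1))
    out["a_hyd"] <- sum(hydC) + sum(halogens)
    out["a_ICM"] <- .atomInfoContent(ctx)

    b <- ctx$bonds
    nBheavy <- nrow(b)
    out["b_heavy"] <- nBheavy
    out["b_count"] <- nBheavy + sum(ctx$nH)
    aromBond <- ctx$aromatic[b$a1] & ctx$aromatic[b$a2]
    out["b_ar"] <- sum(aromBond)
    out["b_single"] <- sum(b$order == 1L & !aromBond)
    out["b_double"] <- sum(b$order == 2L & !aromBond)
    out["b_triple"] <- sum(b$order == 3L)
    out["b_rotN"] <- rot
    out["b_rotR"] <- if (nBheavy) rot / nBheavy else 0
    out["b_rigid"] <- nBheavy - rot

    nmol <- .nComponents(ctx)
    nRings <- nBheavy - ctx$nAtoms + nmol
    out["rings"] <- nRings
    out["Nmol"] <- nmol
    chir <- .chiralCount(ctx)
    out["Chiral"] <- chir
    nStereo <- length(gregexpr("@{1,2}", ctx$smiles)[[1]])
    if (!grepl("@", ctx$smiles)) nStereo <- 0L
    out["Chiral_u"] <- max(0L, chir - nStereo)
    out["Reactive"] <- reactive

    out[c("Chi0", "Chi1", "Chi0_C", "Chi1_C")] <- .chiIndices(ctx)

    out["logS"] <- 0.16 - 0.63 * logp - 0.0062 * mw + 0.066 * rot -
        0.74 * (out["a_aro"] / ctx$nAtoms)

    out["lip_don"] <- hbd
    out["lip_acc"] <- hba
    lipv <- sum(mw > 500, logp > 5, hbd > 5, hba > 10)
    out["lip_violation"] <- lipv
    out["lip_druglike"] <- as.numeric(lipv <= 1)
    oprv <- sum(mw > 450, logp < -3.5 || logp > 4.5, nRings > 4,
                rot > 10, hbd > 5, hba > 8)
    out["opr_violation"] <- oprv
    out["opr_leadlike"] <- as.numeric(oprv == 0)

    q <- .gasteigerCharges(ctx)
    vsa <- .atomVSA(ctx)
    out["VSA"] <- sum(vsa)
    out["Q_VSA_POS"] <- sum(vsa[q > 0])
    out["Q_VSA_NEG"] <- sum(vsa[q < 0])
    tot <- max(sum(vsa), .Machine$double.eps)
    out["Q_VSA_FPOS"] <- out["Q_VSA_POS"] / tot
    out["Q_VSA_FNEG"] <- out["Q_VSA_NEG"] / tot
    for (k in 0:6) {
        hi <- if (k == 6) Inf else 0.05 * (k + 1)
        out[sprintf("PEOE_VSA+%d", k)] <- sum(vsa[q >= 0.05 * k & q < hi])
        lo <- if (k == 6) -Inf else -0.05 * (k + 1)
        out[sprintf("PEOE_VSA-%d", k)] <- sum(vsa[q > lo & q <= -0.05 * k &
                                                  q < 0])
    }
    lp <- .atomLogP(ctx)
    binL <- cut(lp, .SLOGP_EDGES, labels = FALSE, right = FALSE)
    for (k in 0:9)
        out[sprintf("SlogP_VSA%d", k)] <- sum(vsa[binL == k + 1L])
    mr <- .atomMR(ctx)
    binM <- cut(mr, .SMR_EDGES, labels = FALSE, right = FALSE)
    for (k in 0:7)
        out[sprintf("SMR_VSA%d", k)] <- sum(vsa[binM == k + 1L])

    for (spec in list(c("PEOE", "q"), c("SLOGP", "lp"), c("SMR", "mr"))) {
        prop <- switch(spec[2], q = q, lp = lp, mr = mr)
        bv <- .bcutValues(ctx, prop)
        gv <- .gcutValues(ctx, prop)
        for (k in 0:3) {
            out[sprintf("BCUT_%s_%d", spec[1], k)] <- bv[k + 1L]
            out[sprintf("GCUT_%s_%d", spec[1], k)] <- gv[k + 1L]
        }
    }
    out
}

#' Prune a descriptor pool
#'
#' Drops constant columns (variance at or below \code{varFloor}) and exact
#' duplicate columns (maximum absolute difference to an earlier retained
#' column at or below \code{dupTol}), keeping the original column order of
#' the survivors. Keeps the ISE search space free of dead dimensions.
#'
#' @param table a \linkS4class{DescriptorTable}.
#' @param varFloor variance threshold (default 0: only exactly constant
#'   columns are dropped).
#' @param dupTol duplicate tolerance (default 0: only exact duplicates).
#' @return Character vector of retained descriptor names.
#' @export
prunePool <- function(table, varFloor = 0, dupTol = 0) {
    v <- descriptorValues(table)
    keep <- character(0)
    for (nm in colnames(v)) {
        x <- v[, nm]
        if (stats::var(x) <= varFloor) next
        dup <- FALSE
        for (k in keep) {
            if (max(abs(x - v[, k])) <= dupTol) { dup <- TRUE; break }
        }
        if (!dup) keep <- c(keep, nm)
    }
    if (!length(keep))
        stop("empty-pool error: every descriptor column was pruned")
    keep
}
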