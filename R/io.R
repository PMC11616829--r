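#' @include contrasts.R
NULL

#' Write a simulated trio dataset to standard formats
#'
#' Emits a phased VCF (GT `a|b`, 1-based positions, one sample per trio
#' member, region carried in the INFO field as `RG=`), a PED-style trio map
#' (family, individual, father, mother, sex, phenotype), a two-column
#' region map, and the generating-truth table.
#'
#' @param sim output of [simulateTrios()] with `keepHaplotypes = TRUE`.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix (default `"trios"`).
#' @return Invisibly, the named vector of file paths written (`vcf`, `ped`,
#'   `regions`, `truth`).
#' @export
writeTrioData <- function(sim, dir, prefix = "trios") {
    if (is.null(sim$haplotypes))
        stop("simulateTrios() must be run with keepHaplotypes = TRUE")
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    h <- sim$haplotypes
    truth <- sim$truth
    n <- nrow(h$mh1)
    fam <- sprintf("fam%04d", seq_len(n))
    mo <- paste0(fam, "_mo"); fa <- paste0(fam, "_fa")
    ch <- paste0(fam, "_ch")
    gtCol <- function(h1, h2) paste0(t(h1), "|", t(h2))  # variant-major
    mT <- h$mh1; mT[!h$tm, ] <- h$mh2[!h$tm, ]
    fT <- h$fh1; fT[!h$tf, ] <- h$fh2[!h$tf, ]
    p <- nrow(truth)
    gt <- matrix("", p, 3L * n)
    gt[, seq(1L, 3L * n, by = 3L)] <- gtCol(h$mh1, h$mh2)
    gt[, seq(2L, 3L * n, by = 3L)] <- gtCol(h$fh1, h$fh2)
    gt[, seq(3L, 3L * n, by = 3L)] <- gtCol(mT, fT)
    samples <- character(3L * n)
    samples[seq(1L, 3L * n, by = 3L)] <- mo
    samples[seq(2L, 3L * n, by = 3L)] <- fa
    samples[seq(3L, 3L * n, by = 3L)] <- ch
    colnames(gt) <- samples
    gt <- cbind(FORMAT = rep("GT", p), gt)
    fix <- cbind(CHROM = "1", POS = as.character(truth$position),
                 ID = truth$id, REF = "A", ALT = "T", QUAL = ".",
                 FILTER = "PASS", INFO = paste0("RG=", truth$region))
    meta <- c("##fileformat=VCFv4.2",
              "##source=trioEMVS",
              paste0("##INFO=<ID=RG,Number=1,Type=Integer,",
                     "Description=\"Gene region index\">"),
              paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                     "Description=\"Phased genotype\">"),
              "##contig=<ID=1>")
    vcf <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
    paths <- c(vcf = file.path(dir, paste0(prefix, ".vcf.gz")),
               ped = file.path(dir, paste0(prefix, ".ped")),
               regions = file.path(dir, paste0(prefix, "_regions.tsv")),
               truth = file.path(dir, paste0(prefix, "_truth.tsv")))
    vcfR::write.vcf(vcf, paths["vcf"])
    ped <- rbind(
        data.frame(family = fam, individual = mo, father = "0",
                   mother = "0", sex = 2L, phenotype = 1L),
        data.frame(family = fam, individual = fa, father = "0",
                   mother = "0", sex = 1L, phenotype = 1L),
        data.frame(family = fam, individual = ch, father = fa,
                   mother = mo, sex = 0L, phenotype = 2L))
    ped <- ped[order(ped$family), ]
    utils::write.table(ped, paths["ped"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(truth[, c("id", "region")], paths["regions"],
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = c("variant_id", "region_id"))
    utils::write.table(truth, paths["truth"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(paths)
}

#' Read a variant-to-region map
#'
#' Accepts either a two-column TSV (`variant_id`, `region_id`) or a
#' BED-style file (chromosome, 0-based half-open start/end, region id in
#' the fourth column) that is mapped onto 1-based variant positions.
#'
#' @param path file path.
#' @param variants data.frame with `id` and `position` columns used to
#'   resolve BED intervals.
#' @return Integer region ids named by variant id.
#' @export
readRegionMap <- function(path, variants = NULL) {
    head1 <- readLines(path, n = 1L)
    tab <- utils::read.table(path, sep = "\t", header = grepl("[A-Za-z_]",
                             strsplit(head1, "\t")[[1]][2]),
                             stringsAsFactors = FALSE)
    if (ncol(tab) >= 4L && is.numeric(tab[[2]]) && is.numeric(tab[[3]])) {
        if (is.null(variants))
            stop("BED-style region maps need the variant table to resolve",
                 " positions")
        region <- rep(NA_integer_, nrow(variants))
        for (k in seq_len(nrow(tab))) {
            hit <- variants$position > tab[[2]][k] &
                   variants$position <= tab[[3]][k]
            region[hit] <- as.integer(tab[[4]][k])
        }
        names(region) <- variants$id
        return(region)
    }
    region <- as.integer(tab[[2]])
    names(region) <- as.character(tab[[1]])
    region
}

#' Read phased trios from VCF and PED
#'
#' Loads a fully phased VCF and a PED trio map, builds the pseudo-sibling
#' contrasts for every complete trio, recodes each variant to its minor
#' allele in the parental pool (ties at 0.5 keep the VCF ALT coding), and
#' classifies common versus rare variants by the sample MAF computed from
#' the parental haplotypes (four independent haplotypes per family).
#' Families with unphased genotypes or Mendelian inconsistencies are
#' dropped with a warning naming the family (and offending variants).
#'
#' @param vcfPath phased VCF (`.vcf` or `.vcf.gz`); GT must use `|`.
#' @param pedPath PED file; children are rows with non-zero father and
#'   mother columns.
#' @param regionMap optional path to a region map (see [readRegionMap()]);
#'   when absent, regions are taken from the `RG` INFO key if present,
#'   otherwise every variant falls in region 1.
#' @param mafThreshold rare/common cutoff on sample MAF (default 0.05).
#' @param minMAC exclude variants whose minor-allele count in the parental
#'   haplotype pool is at most this value (default 0: drop only
#'   monomorphic sites; 3 omits singletons, doubletons and tripletons).
#' @return A [TrioContrasts-class] object.
#' @export
readTrios <- function(vcfPath, pedPath, regionMap = NULL,
                      mafThreshold = 0.05, minMAC = 0L) {
    vcf <- vcfR::read.vcfR(vcfPath, verbose = FALSE)
    fix <- vcf@fix
    gt <- vcfR::extract.gt(vcf, element = "GT")
    ids <- fix[, "ID"]
    ids[is.na(ids) | ids == "."] <- paste0("var", which(is.na(ids) |
                                                        ids == "."))
    rownames(gt) <- ids
    ped <- utils::read.table(pedPath, header = TRUE,
                             stringsAsFactors = FALSE)
    names(ped)[1:4] <- c("family", "individual", "father", "mother")
    kids <- ped[ped$father != "0" & ped$mother != "0", ]
    p <- nrow(gt)
    info <- fix[, "INFO"]
    info[is.na(info)] <- ""
    region <- rep(1L, p)
    rg <- regmatches(info, regexpr("RG=[0-9]+", info))
    if (length(rg) == p && all(nzchar(rg)))
        region <- as.integer(sub("RG=", "", rg))
    if (!is.null(regionMap)) {
        vtab <- data.frame(id = ids, position = as.integer(fix[, "POS"]))
        rm <- readRegionMap(regionMap, vtab)
        hit <- match(ids, names(rm))
        region[!is.na(hit)] <- rm[hit[!is.na(hit)]]
    }
    splitGT <- function(col) {
        if (any(!grepl("|", col, fixed = TRUE))) return(NULL)
        a <- matrix(as.integer(unlist(strsplit(col, "|", fixed = TRUE))),
                    nrow = 2L)
        list(h1 = a[1, ], h2 = a[2, ])
    }
    families <- list()
    famIDs <- character(0)
    parentHaps <- list()
    for (k in seq_len(nrow(kids))) {
        fid <- kids$family[k]
        need <- c(kids$mother[k], kids$father[k], kids$individual[k])
        if (!all(need %in% colnames(gt))) {
            warning("family ", fid, ": missing sample(s) in VCF; skipped")
            next
        }
        mo <- splitGT(gt[, need[1]])
        fa <- splitGT(gt[, need[2]])
        ch <- splitGT(gt[, need[3]])
        if (is.null(mo) || is.null(fa) || is.null(ch)) {
            warning("family ", fid, ": unphased genotype; dropped")
            next
        }
        trio <- tryCatch(enumeratePseudoSiblings(mo, fa,
                             list(h1 = ch$h1, h2 = ch$h2)),
                         error = function(e) e)
        if (inherits(trio, "error")) {
            warning("family ", fid, ": ", conditionMessage(trio),
                    "; dropped")
            next
        }
        families[[length(families) + 1L]] <- trio
        famIDs <- c(famIDs, fid)
        parentHaps[[length(parentHaps) + 1L]] <-
            rbind(mo$h1, mo$h2, fa$h1, fa$h2)
    }
    if (!length(families))
        stop("no usable trio found")
    H <- do.call(rbind, parentHaps)
    freq <- colMeans(H)
    flip <- freq > 0.5
    if (any(flip)) {
        for (k in seq_along(families)) {
            families[[k]]$case[flip] <- 2L - families[[k]]$case[flip]
            families[[k]]$pseudo[, flip] <- 2L - families[[k]]$pseudo[, flip]
        }
    }
    maf <- ifelse(flip, 1 - freq, freq)
    variants <- data.frame(id = ids, position = as.integer(fix[, "POS"]),
                           region = region, maf = maf,
                           isCommon = maf >= mafThreshold)
    obj <- buildContrasts(families, variants, famIDs)
    v <- obj@variants
    keepIdx <- v$maf * nrow(H) > minMAC & !v$monomorphic
    TrioContrasts(obj@contrasts[, keepIdx, drop = FALSE], famIDs,
                  v[keepIdx, setdiff(names(v), "monomorphic")])
}

#' Write fit results as TSV files
#'
#' @param fit a [TrioFit-class] object.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @param threshold selection threshold (see [selectVariants()]).
#' @return Invisibly, the paths written (`variants`, `regions`).
#' @export
writeFitResults <- function(fit, dir, prefix = "fit", threshold = 0.5) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(variants = file.path(dir, paste0(prefix, "_variants.tsv")),
               regions = file.path(dir, paste0(prefix, "_regions.tsv")))
    utils::write.table(selectVariants(fit, threshold), paths["variants"],
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(selectedRegions(fit, threshold), paths["regions"],
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(paths)
}

#' Evaluate a directory of replicate results against their truths
#'
#' Pairs per-replicate selection tables (`<prefix>_variants.tsv`, written
#' by [writeFitResults()]) with truth tables (`<prefix>_truth.tsv`, written
#' by [writeTrioData()]) and computes the region-level weighted average
#' correct association percentage, variant-level average true/false
#' positive rates, and the MAF-stratified report.
#'
#' @param resultsDir directory of `*_variants.tsv` files.
#' @param truthDir directory of `*_truth.tsv` files (default: same).
#' @param restrict denominator convention for [atprAfpr()].
#' @return list with `wacap`, `rates` (ATPR/AFPR), `byMAF`, and the number
#'   of replicates.
#' @export
evaluateReplicates <- function(resultsDir, truthDir = resultsDir,
                               restrict = "perDataset") {
    resFiles <- sort(list.files(resultsDir, "_variants\\.tsv$",
                                full.names = TRUE))
    truFiles <- sort(list.files(truthDir, "_truth\\.tsv$",
                                full.names = TRUE))
    if (!length(resFiles)) stop("no *_variants.tsv files in ", resultsDir)
    if (length(resFiles) != length(truFiles))
        stop("found ", length(resFiles), " result file(s) but ",
             length(truFiles), " truth file(s)")
    truth0 <- utils::read.table(truFiles[1], header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
    ids <- truth0$id
    D <- length(resFiles)
    selected <- matrix(FALSE, D, length(ids), dimnames = list(NULL, ids))
    polymorphic <- matrix(FALSE, D, length(ids))
    mafs <- matrix(NA_real_, D, length(ids))
    regions <- sort(unique(truth0$region))
    selReg <- matrix(FALSE, D, length(regions))
    for (d in seq_len(D)) {
        tru <- utils::read.table(truFiles[d], header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
        if (!identical(tru$id, ids))
            stop("replicate ", d, ": truth variant panel differs")
        res <- utils::read.table(resFiles[d], header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
        hit <- match(res$id, ids)
        if (anyNA(hit))
            stop("replicate ", d, ": selection table has unknown variants")
        selected[d, hit] <- res$selected
        polymorphic[d, ] <- tru$polymorphic
        mafs[d, ] <- tru$sampleMAF
        regFile <- sub("_variants\\.tsv$", "_regions.tsv", resFiles[d])
        if (file.exists(regFile)) {
            reg <- utils::read.table(regFile, header = TRUE, sep = "\t")
            selReg[d, match(reg$region, regions)] <- reg$selected
        } else {
            selReg[d, ] <- vapply(regions, function(r)
                any(selected[d, tru$region == r]), logical(1))
        }
    }
    associated <- vapply(regions, function(r)
        any(truth0$causal[truth0$region == r]), logical(1))
    medMAF <- apply(mafs, 2L, stats::median)
    list(wacap = wacap(selReg, associated),
         rates = atprAfpr(selected, truth0$causal, polymorphic, restrict),
         byMAF = mafStratifiedReport(selected, truth0$causal, medMAF,
                                     polymorphic, restrict = restrict),
         nReplicates = D)
}
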