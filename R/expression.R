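# Chemokine ligand-receptor pairing from islet expression counts:
# median-of-ratios normalization, expressed-chemokine calling in CD11c
# samples, and top-ligand ranking paired with receptor expression in T-cell
# samples.

#' Curated murine chemokine ligand-receptor pairing map
#'
#' Shipped as an editable TSV resource
#' (\code{extdata/chemokine_pairing.tsv}): one row per ligand-receptor pair,
#' following standard murine chemokine nomenclature (many-to-many; e.g.
#' Cxcl16-Cxcr6, Cxcl9/Cxcl10/Cxcl11-Cxcr3, Ccl19/Ccl21-Ccr7).
#'
#' @param file alternative pairing TSV with columns \code{ligand},
#'   \code{receptor}.
#' @return data.frame with columns \code{ligand}, \code{receptor}.
#' @export
chemokinePairingMap <- function(file = NULL) {
    if (is.null(file))
        file <- system.file("extdata", "chemokine_pairing.tsv",
                            package = "isletTraffic", mustWork = TRUE)
    map <- utils::read.delim(file, stringsAsFactors = FALSE)
    stopifnot(all(c("ligand", "receptor") %in% names(map)))
    map
}

# gene class annotation relative to the pairing map
annotateGeneClass <- function(genes, pairing = chemokinePairingMap()) {
    ifelse(genes %in% pairing$ligand, "chemokine_ligand",
        ifelse(genes %in% pairing$receptor, "chemokine_receptor", "other"))
}

#' Simulate an islet CD11c / T-cell expression count matrix
#'
#' Draws gene x sample integer counts from a negative binomial with
#' preset per-population means scaled by a per-sample library depth factor,
#' and packages them as a SummarizedExperiment with population labels in
#' \code{colData} and gene classes (chemokine ligand / receptor / other) in
#' \code{rowData}.
#'
#' @param preset an [expressionPreset()] bundle.
#' @return a \linkS4class{SummarizedExperiment} with assay \code{counts}.
#' @export
generateExpressionCounts <- function(preset) {
    stopifnot(inherits(preset, "ExpressionPreset"))
    withr::with_seed(preset$seed, {
        genes <- rownames(preset$mean_counts)
        pops <- colnames(preset$mean_counts)
        ns <- preset$n_samples_per_population
        samples <- paste0(rep(pops, each = ns), "_", rep(seq_len(ns),
                          length(pops)))
        population <- rep(pops, each = ns)
        depth <- stats::runif(length(samples), preset$library_size_range[1L],
                              preset$library_size_range[2L])
        counts <- matrix(0L, length(genes), length(samples),
                         dimnames = list(genes, samples))
        for (j in seq_along(samples)) {
            mu <- preset$mean_counts[, population[j]] * depth[j]
            disp <- preset$dispersion[genes]
            det <- disp < 1e-8            # noise-free limit: rounded means
            cj <- integer(length(mu))
            cj[det] <- as.integer(round(mu[det]))
            cj[!det] <- as.integer(stats::rnbinom(sum(!det), mu = mu[!det],
                                                  size = 1 / disp[!det]))
            counts[, j] <- cj
        }
        SummarizedExperiment::SummarizedExperiment(
            assays = list(counts = counts),
            colData = S4Vectors::DataFrame(population = population,
                                           depth_factor = depth,
                                           row.names = samples),
            rowData = S4Vectors::DataFrame(
                gene_class = annotateGeneClass(genes), row.names = genes))
    })
}

#' Median-of-ratios size factors
#'
#' Per-sample size factor: the median, over genes with strictly positive
#' counts in every sample, of the gene's count divided by its geometric mean
#' across samples. This is the classical median-of-ratios normalization for
#' count matrices.
#'
#' @param counts integer matrix (genes x samples) or a SummarizedExperiment
#'   with a \code{counts} assay.
#' @param pseudo_reference use all genes with positive geometric mean
#'   (computed over positive entries) instead of the all-positive gene set -
#'   a fallback for sparse matrices.
#' @return named numeric vector of positive per-sample factors.
#' @export
computeSizeFactors <- function(counts, pseudo_reference = FALSE) {
    counts <- .assayCounts(counts)
    if (ncol(counts) == 1L)
        return(stats::setNames(1, colnames(counts)))
    if (pseudo_reference) {
        lg <- log(counts)
        lg[!is.finite(lg)] <- NA
        ref <- exp(rowMeans(lg, na.rm = TRUE))
        use <- is.finite(ref) & ref > 0
    } else {
        use <- rowSums(counts > 0) == ncol(counts)
        if (!any(use))
            stop("no gene has nonzero counts in all samples; ",
                 "consider pseudo_reference = TRUE")
        ref <- exp(rowMeans(log(counts[use, , drop = FALSE])))
    }
    mat <- counts[use, , drop = FALSE] / if (pseudo_reference) ref[use] else ref
    sf <- apply(mat, 2L, stats::median, na.rm = TRUE)
    if (any(!is.finite(sf) | sf <= 0))
        stop("non-positive size factor; matrix too sparse for median-of-ratios")
    sf
}

.assayCounts <- function(x) {
    if (is(x, "SummarizedExperiment"))
        x <- SummarizedExperiment::assay(x, "counts")
    as.matrix(x)
}

#' Normalize a count matrix by size factors
#'
#' @param counts matrix or SummarizedExperiment (assay \code{counts}); for a
#'   SummarizedExperiment the result is returned as a new assay
#'   \code{normalized}.
#' @param factors per-sample positive factors from [computeSizeFactors()]
#'   (computed if missing).
#' @return normalized matrix, or the SummarizedExperiment with a
#'   \code{normalized} assay.
#' @export
normalizeCounts <- function(counts, factors = NULL) {
    mat <- .assayCounts(counts)
    if (is.null(factors)) factors <- computeSizeFactors(mat)
    stopifnot(all(factors > 0), length(factors) == ncol(mat))
    norm <- sweep(mat, 2L, factors, "/")
    if (is(counts, "SummarizedExperiment")) {
        SummarizedExperiment::assay(counts, "normalized") <- norm
        counts
    } else norm
}

.populationMeans <- function(se, population, assay = "normalized") {
    stopifnot(is(se, "SummarizedExperiment"))
    sel <- SummarizedExperiment::colData(se)$population == population
    if (!any(sel)) stop("no samples for population ", population)
    rowMeans(SummarizedExperiment::assay(se, assay)[, sel, drop = FALSE])
}

#' Expressed chemokine ligands in a population
#'
#' Ligand genes whose mean normalized count in the population reaches the
#' threshold.
#'
#' @param se SummarizedExperiment with a \code{normalized} assay and
#'   \code{gene_class} rowData (see [generateExpressionCounts()]).
#' @param population population label (default \code{"CD11c"}).
#' @param threshold mean normalized count cutoff (default 10).
#' @return list: \code{genes} (sorted by decreasing mean), \code{count},
#'   \code{means} (all ligand means).
#' @export
expressedChemokines <- function(se, population = "CD11c", threshold = 10) {
    means <- .populationMeans(se, population)
    lig <- rownames(se)[SummarizedExperiment::rowData(se)$gene_class ==
                        "chemokine_ligand"]
    m <- sort(means[lig], decreasing = TRUE)
    expressed <- m[m >= threshold]
    list(genes = names(expressed), count = length(expressed), means = m)
}

#' Top expressed ligands paired with receptor expression
#'
#' Ranks chemokine ligands by mean normalized expression in the CD11c
#' population (ties broken lexicographically) and pairs each of the top k
#' with its receptor(s) and their mean normalized expression in the T-cell
#' population.
#'
#' @param se SummarizedExperiment with \code{normalized} assay.
#' @param pairing pairing map data.frame (default the shipped resource); an
#'   error names any ranked ligand missing from the map.
#' @param k number of top ligands (default 10).
#' @param ligandPopulation,receptorPopulation population labels.
#' @return list: \code{ranking} (data.frame rank, ligand, ligand_mean),
#'   \code{pairs} (data.frame rank, ligand, receptor, receptor_mean),
#'   \code{top_receptor} (highest-mean receptor in the receptor population).
#' @export
topLigandsWithReceptors <- function(se, pairing = chemokinePairingMap(),
                                    k = 10L, ligandPopulation = "CD11c",
                                    receptorPopulation = "Tcell") {
    ligMeans <- .populationMeans(se, ligandPopulation)
    recMeans <- .populationMeans(se, receptorPopulation)
    cls <- SummarizedExperiment::rowData(se)$gene_class
    lig <- rownames(se)[cls == "chemokine_ligand"]
    rec <- rownames(se)[cls == "chemokine_receptor"]
    ord <- order(-ligMeans[lig], lig)      # ties: lexicographic
    top <- lig[ord][seq_len(min(k, length(lig)))]
    if (k == 0L || !length(top))
        return(list(ranking = data.frame(rank = integer(),
                        ligand = character(), ligand_mean = numeric()),
                    pairs = data.frame(rank = integer(), ligand = character(),
                        receptor = character(), receptor_mean = numeric()),
                    top_receptor = NA_character_))
    missing <- setdiff(top, pairing$ligand)
    if (length(missing))
        stop("ligand(s) not in pairing map: ", paste(missing, collapse = ", "))
    ranking <- data.frame(rank = seq_along(top), ligand = top,
                          ligand_mean = unname(ligMeans[top]))
    pairs <- do.call(rbind, lapply(seq_along(top), function(i) {
        rr <- pairing$receptor[pairing$ligand == top[i]]
        data.frame(rank = i, ligand = top[i], receptor = rr,
                   receptor_mean = unname(recMeans[rr]))
    }))
    topRec <- if (length(rec)) rec[which.max(recMeans[rec])] else NA_character_
    list(ranking = ranking, pairs = pairs, top_receptor = topRec)
}
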