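# File interfaces: OME-TIFF label volumes (one channel per label class,
# uint16, physical spacing in the OME-XML ImageDescription), track / count
# tables as CSV, expression matrices as TSV or MatrixMarket with sidecars,
# and JSON summaries.

.CHANNELS <- c("islet", "lumen", "cd11c", "tcell")

omeXmlDescription <- function(d, spacing) {
    paste0(
        '<?xml version="1.0" encoding="UTF-8"?>',
        '<OME xmlns="http://www.openmicroscopy.org/Schemas/OME/2016-06">',
        '<Image ID="Image:0" Name="islet_phantom">',
        sprintf(paste0(
            '<Pixels ID="Pixels:0" DimensionOrder="XYCZT" Type="uint16" ',
            'SizeX="%d" SizeY="%d" SizeZ="%d" SizeC="4" SizeT="1" ',
            'PhysicalSizeX="%.6g" PhysicalSizeY="%.6g" PhysicalSizeZ="%.6g" ',
            'PhysicalSizeXUnit="µm" PhysicalSizeYUnit="µm" ',
            'PhysicalSizeZUnit="µm">'),
            d[1], d[2], d[3], spacing[1], spacing[2], spacing[3]),
        paste0(sprintf('<Channel ID="Channel:0:%d" Name="%s" SamplesPerPixel="1"/>',
                       seq_along(.CHANNELS) - 1L, .CHANNELS), collapse = ""),
        '<TiffData/></Pixels></Image></OME>')
}

#' Write an islet phantom as OME-TIFF with companion OME-XML
#'
#' One uint16 plane per channel and z slice (plane order XYCZT: channel
#' fastest), channels islet / lumen / cd11c / tcell, instance labels
#' preserved. The OME-XML metadata block (dimensions, channel names,
#' physical spacing) goes to a companion file \code{<path>.companion.xml},
#' the OME companion-file convention. The round trip through
#' [readIsletPhantom()] is bit-exact.
#'
#' @param phantom an [IsletPhantom-class].
#' @param path output file path (.ome.tiff).
#' @return the path, invisibly.
#' @export
writeIsletPhantom <- function(phantom, path) {
    stopifnot(is(phantom, "IsletPhantom"))
    d <- dim(phantom@isletMask)
    vols <- list(islet = phantom@isletMask * 1L,
                 lumen = phantom@lumenMask * 1L,
                 cd11c = phantom@cd11cLabels,
                 tcell = phantom@tcellLabels)
    if (max(vapply(vols, max, numeric(1))) > 65535)
        stop("instance labels exceed uint16 range")
    planes <- vector("list", 4L * d[3])
    k <- 1L
    for (z in seq_len(d[3])) {
        for (ch in seq_along(vols)) {
            # tiff wants row-major [y, x] matrices in [0, 1]
            planes[[k]] <- t(vols[[ch]][, , z]) / 65535
            k <- k + 1L
        }
    }
    tiff::writeTIFF(planes, path, bits.per.sample = 16L,
                    compression = "LZW")
    writeLines(omeXmlDescription(d, phantom@spacing),
               paste0(path, ".companion.xml"))
    invisible(path)
}

#' Read an islet phantom from OME-TIFF
#'
#' @param path file written by [writeIsletPhantom()].
#' @return an [IsletPhantom-class].
#' @export
readIsletPhantom <- function(path) {
    planes <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    companion <- paste0(path, ".companion.xml")
    if (!file.exists(companion))
        stop("missing companion OME-XML metadata file: ", companion)
    xml <- xml2::read_xml(companion)
    px <- xml2::xml_find_first(xml, ".//*[local-name()='Pixels']")
    d <- as.integer(c(xml2::xml_attr(px, "SizeX"),
                      xml2::xml_attr(px, "SizeY"),
                      xml2::xml_attr(px, "SizeZ")))
    spacing <- as.numeric(c(xml2::xml_attr(px, "PhysicalSizeX"),
                            xml2::xml_attr(px, "PhysicalSizeY"),
                            xml2::xml_attr(px, "PhysicalSizeZ")))
    if (length(planes) != 4L * d[3]) stop("plane count does not match SizeZ*SizeC")
    vols <- lapply(seq_along(.CHANNELS), function(ch) {
        a <- array(0L, d)
        for (z in seq_len(d[3]))
            a[, , z] <- t(planes[[(z - 1L) * 4L + ch]])
        a
    })
    new("IsletPhantom",
        isletMask = vols[[1L]] > 0L, lumenMask = vols[[2L]] > 0L,
        cd11cLabels = vols[[3L]], tcellLabels = vols[[4L]],
        spacing = spacing)
}

#' Write / read a track table as CSV
#'
#' Columns: track_id, frame, t_seconds, x_um, y_um, z_um plus any metadata
#' columns (islet_id, infiltration).
#'
#' @param tracks data.frame of tracks.
#' @param path CSV path.
#' @return the path ([writeTracks()]) or the data.frame ([readTracks()]).
#' @export
writeTracks <- function(tracks, path) {
    utils::write.csv(tracks, path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeTracks
#' @export
readTracks <- function(path) {
    utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a trafficking count table as CSV
#'
#' @param counts TraffickingCounts data.frame.
#' @param path CSV path.
#' @return the path, or the TraffickingCounts on read.
#' @export
writeTraffickingCounts <- function(counts, path) {
    utils::write.csv(counts, path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeTraffickingCounts
#' @export
readTraffickingCounts <- function(path) {
    out <- utils::read.csv(path, stringsAsFactors = FALSE)
    class(out) <- c("TraffickingCounts", "data.frame")
    out
}

#' Write an expression experiment as TSV or MatrixMarket
#'
#' \code{format = "tsv"} writes a gene x sample table; \code{format = "mtx"}
#' writes MatrixMarket plus \code{*_genes.tsv} and \code{*_samples.tsv}
#' sidecars (sample sidecar carries the population labels).
#'
#' @param se SummarizedExperiment with a \code{counts} assay.
#' @param path output path (for mtx, the \code{.mtx} path; sidecars are
#'   derived from it).
#' @param format "tsv" or "mtx".
#' @return the main path, invisibly.
#' @export
writeExpression <- function(se, path, format = c("tsv", "mtx")) {
    format <- match.arg(format)
    counts <- .assayCounts(se)
    pop <- SummarizedExperiment::colData(se)$population
    if (format == "tsv") {
        df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        utils::write.table(
            data.frame(sample = colnames(counts), population = pop),
            sub("\\.tsv$", "_samples.tsv", path), sep = "\t", quote = FALSE,
            row.names = FALSE)
    } else {
        Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), path)
        base <- sub("\\.mtx$", "", path)
        utils::write.table(
            data.frame(gene = rownames(counts),
                gene_class = SummarizedExperiment::rowData(se)$gene_class),
            paste0(base, "_genes.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
        utils::write.table(
            data.frame(sample = colnames(counts), population = pop),
            paste0(base, "_samples.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
    }
    invisible(path)
}

#' Read an expression experiment written by [writeExpression()]
#'
#' @param path the TSV or MTX path.
#' @param format "tsv" or "mtx".
#' @return a SummarizedExperiment with assay \code{counts}, population
#'   colData and gene_class rowData.
#' @export
readExpression <- function(path, format = c("tsv", "mtx")) {
    format <- match.arg(format)
    if (format == "tsv") {
        df <- utils::read.delim(path, check.names = FALSE)
        counts <- as.matrix(df[, -1L, drop = FALSE])
        rownames(counts) <- df$gene
        smp <- utils::read.delim(sub("\\.tsv$", "_samples.tsv", path))
    } else {
        counts <- as.matrix(Matrix::readMM(path))
        base <- sub("\\.mtx$", "", path)
        genes <- utils::read.delim(paste0(base, "_genes.tsv"))
        smp <- utils::read.delim(paste0(base, "_samples.tsv"))
        dimnames(counts) <- list(genes$gene, smp$sample)
    }
    storage.mode(counts) <- "integer"
    SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(population = smp$population,
                                       row.names = colnames(counts)),
        rowData = S4Vectors::DataFrame(
            gene_class = annotateGeneClass(rownames(counts)),
            row.names = rownames(counts)))
}

#' Write a ground-truth record (or any summary list) as JSON
#'
#' @param x a list (data.frame members are kept as records).
#' @param path JSON path.
#' @return the path, invisibly.
#' @export
writeGroundTruth <- function(x, path) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
    invisible(path)
}
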