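## plain-text table dialects: TSV with header, gene ids in column 1,
## UTF-8, '.' decimal separator; GMT per the standard (see enrichment.R)

.checkNumericCells <- function(df, path, skipCols = character(0)) {
    for (j in setdiff(colnames(df), skipCols)) {
        v <- df[[j]]
        if (is.character(v)) {
            suppress <- suppressWarnings(as.numeric(v))
            bad <- which(is.na(suppress) & !is.na(v))
            if (length(bad))
                stop("malformed numeric cell in '", path, "' at row ",
                     bad[1], ", column '", j, "': '", v[bad[1]], "'")
            df[[j]] <- suppress
        }
    }
    df
}

#' Read and write gene-level count tables
#'
#' Count TSV dialect: header row, gene identifiers in the first column
#' (\code{gene_id}), one column per sample. Duplicate gene ids and
#' malformed numeric cells are errors.
#'
#' @param path file path.
#' @return \code{readCounts}: integer matrix, genes x samples.
#' @export
readCounts <- function(path) {
    df <- read.delim(path, check.names = FALSE, colClasses = "character")
    if (ncol(df) < 2L) stop("count table needs a gene column and >= 1 sample")
    ids <- df[[1]]
    if (anyDuplicated(ids))
        stop("duplicate gene id(s) in '", path, "': ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    df <- .checkNumericCells(df[-1], path)
    m <- as.matrix(df)
    rownames(m) <- ids
    storage.mode(m) <- "integer"
    m
}

#' @rdname readCounts
#' @param counts matrix or \linkS4class{SummarizedExperiment}.
#' @export
writeCounts <- function(counts, path) {
    m <- .countsMatrix(counts)
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a sample sheet
#'
#' CSV with required columns \code{sample_id}, \code{cell_line},
#' \code{condition}, \code{r_protein}, \code{replicate}.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readSampleSheet <- function(path) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    required <- c("sample_id", "cell_line", "condition", "r_protein",
                  "replicate")
    missing <- setdiff(required, colnames(df))
    if (length(missing))
        stop("sample sheet is missing column(s): ",
             paste(missing, collapse = ", "))
    bad <- setdiff(unique(df$condition), c("producer", "control"))
    if (length(bad))
        stop("unknown condition value(s): ", paste(bad, collapse = ", "))
    df
}

#' Read a titer table
#'
#' CSV with columns \code{r_protein}, \code{cell_line},
#' \code{titer_ug_ml} (and optionally \code{detected}); titers must be
#' non-negative, undetected r-proteins are recorded as 0.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readTiters <- function(path) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    required <- c("r_protein", "cell_line", "titer_ug_ml")
    missing <- setdiff(required, colnames(df))
    if (length(missing))
        stop("titer table is missing column(s): ",
             paste(missing, collapse = ", "))
    if (any(df$titer_ug_ml < 0)) stop("titers must be >= 0")
    if (is.null(df$detected)) df$detected <- df$titer_ug_ml > 0
    df
}

#' Read a PTM annotation table
#'
#' CSV with columns \code{r_protein}, \code{length_aa},
#' \code{n_glyc_sites}, \code{o_glyc_sites}, \code{disulfide_bonds},
#' \code{gpi_anchor}.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readPTMTable <- function(path) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    required <- c("r_protein", "length_aa", "n_glyc_sites",
                  "o_glyc_sites", "disulfide_bonds", "gpi_anchor")
    missing <- setdiff(required, colnames(df))
    if (length(missing))
        stop("PTM table is missing column(s): ",
             paste(missing, collapse = ", "))
    if (any(df$length_aa <= 0)) stop("'length_aa' must be positive")
    counts <- df[, c("n_glyc_sites", "o_glyc_sites", "disulfide_bonds",
                     "gpi_anchor")]
    if (any(counts < 0)) stop("PTM site counts must be >= 0")
    df
}

#' Read an ortholog conversion table
#'
#' Two-column TSV \code{cho_gene_id <TAB> human_gene_id} (header
#' optional; detected from the first line).
#'
#' @param path file path.
#' @return data.frame with columns \code{cho_gene_id},
#'   \code{human_gene_id}.
#' @export
readOrthologMap <- function(path) {
    first <- readLines(path, n = 1)
    hasHeader <- grepl("gene_id", first, fixed = TRUE)
    df <- read.delim(path, header = hasHeader, stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("ortholog map needs two columns")
    df <- df[, 1:2]
    colnames(df) <- c("cho_gene_id", "human_gene_id")
    unique(df)
}

#' Write all bundle inputs to a directory
#'
#' Materializes a [SyntheticBundle-class] as the plain-text files the
#' pipeline reads: per-host count TSVs, a sample sheet CSV, the GMT
#' gene-set collection, the ortholog map TSV, the titer CSV and the PTM
#' CSV.
#'
#' @param bundle a [SyntheticBundle-class].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths.
#' @export
writeBundle <- function(bundle, dir) {
    stopifnot(is(bundle, "SyntheticBundle"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(dir, f)
    writeCounts(choCounts(bundle), p("counts_cho.tsv"))
    writeCounts(hekCounts(bundle), p("counts_hek293.tsv"))
    st <- rbind(as.data.frame(colData(choCounts(bundle))),
                as.data.frame(colData(hekCounts(bundle))))
    write.csv(st, p("samples.csv"), row.names = FALSE, quote = FALSE)
    writeGMT(geneSets(bundle), p("gene_sets.gmt"))
    write.table(orthologMap(bundle), p("orthologs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.csv(titerTable(bundle), p("titers.csv"), row.names = FALSE,
              quote = FALSE)
    write.csv(ptmTable(bundle), p("ptm.csv"), row.names = FALSE,
              quote = FALSE)
    write.table(functionalAnnotation(bundle), p("annotation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    c(counts_cho = p("counts_cho.tsv"),
      counts_hek293 = p("counts_hek293.tsv"),
      samples = p("samples.csv"),
      gene_sets = p("gene_sets.gmt"),
      orthologs = p("orthologs.tsv"),
      titers = p("titers.csv"),
      ptm = p("ptm.csv"),
      annotation = p("annotation.tsv"))
}
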