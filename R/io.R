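#' Read an OTU count table
#'
#' Reads a tab-separated count table with a header row and a first column of
#' identifiers, and normalizes it to the samples-by-taxa orientation. Files
#' ending in `.biom` are read through the biomformat package (taxa are rows
#' in BIOM, so `orientation` is ignored).
#'
#' @param path path to a TSV file (or `.biom` file).
#' @param orientation `"samples_as_rows"` (default) or `"taxa_as_rows"`,
#'   describing the file layout.
#' @return an [OtuTable-class].
#' @export
readOtuTable <- function(path,
                         orientation = c("samples_as_rows", "taxa_as_rows")) {
    orientation <- match.arg(orientation)
    if (!file.exists(path)) stop("file not found: ", path)
    if (grepl("\\.biom$", path)) {
        if (!requireNamespace("biomformat", quietly = TRUE))
            stop("reading BIOM files requires the biomformat package")
        m <- as.matrix(biomformat::biom_data(biomformat::read_biom(path)))
        return(otuTable(t(m)))   # biom stores taxa as rows
    }
    df <- read.delim(path, header = TRUE, row.names = NULL, sep = "\t",
                     check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(df[[1L]])
    body <- df[, -1L, drop = FALSE]
    bad <- which(!vapply(body, is.numeric, logical(1)))
    if (length(bad))
        stop("non-numeric values in column '", names(body)[bad[1L]], "'")
    m <- as.matrix(body)
    rownames(m) <- ids
    if (orientation == "taxa_as_rows") m <- t(m)
    otuTable(m)
}

#' Construct an OTU table from a matrix
#'
#' @param counts samples-by-taxa non-negative numeric matrix. Missing
#'   dimnames are filled in (`sample1..n`, `taxon1..p`).
#' @return an [OtuTable-class].
#' @export
otuTable <- function(counts) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)))
        rownames(counts) <- paste0("sample", seq_len(nrow(counts)))
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("taxon", seq_len(ncol(counts)))
    new("OtuTable", counts = counts)
}

#' Write an OTU table as TSV
#'
#' @param table an [OtuTable-class].
#' @param path output path; the parent directory must exist.
#' @export
writeOtuTable <- function(table, path) {
    stopifnot(is(table, "OtuTable"))
    m <- otuCounts(table)
    df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Filter taxa by prevalence
#'
#' Removes taxa that are present (count > 0) in strictly fewer than
#' `minPrevalence * n` samples; a taxon present in exactly that many
#' samples is retained. Applied before pseudo-count addition. With the
#' conventional 10% threshold this drops rarely observed taxa whose
#' covariances are dominated by zeros.
#'
#' @param table an [OtuTable-class].
#' @param minPrevalence fraction in \[0, 1\]; default 0.1.
#' @return the filtered [OtuTable-class]; sample set and taxa order are
#'   preserved.
#' @export
prevalenceFilter <- function(table, minPrevalence = 0.1) {
    stopifnot(is(table, "OtuTable"))
    if (!is.numeric(minPrevalence) || length(minPrevalence) != 1L ||
        minPrevalence < 0 || minPrevalence > 1)
        stop("minPrevalence must be a fraction in [0, 1]")
    m <- otuCounts(table)
    present <- colSums(m > 0)
    keep <- present >= minPrevalence * nrow(m)   # strictly-less-than removal
    if (sum(keep) < 2L)
        stop("prevalence filter would leave fewer than 2 taxa")
    otuTable(m[, keep, drop = FALSE])
}

cooccurrenceColumns <- c("taxon_i", "taxon_j", "n_i", "n_j", "n_ij", "M")

#' Read literature co-occurrence abstract counts
#'
#' One row per unordered taxon pair with the four abstract counts of its
#' 2-by-2 contingency table: `n_i` (abstracts naming only taxon i), `n_j`
#' (only taxon j), `n_ij` (both) and `M` (neither).
#'
#' @param path TSV with columns `taxon_i`, `taxon_j`, `n_i`, `n_j`, `n_ij`,
#'   `M`.
#' @return data.frame with those columns.
#' @export
readCooccurrenceCounts <- function(path) {
    df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                     check.names = FALSE)
    missing <- setdiff(cooccurrenceColumns, names(df))
    if (length(missing))
        stop("co-occurrence file is missing column(s): ",
             paste(missing, collapse = ", "))
    df <- df[cooccurrenceColumns]
    num <- df[c("n_i", "n_j", "n_ij", "M")]
    if (any(!vapply(num, is.numeric, logical(1))) ||
        any(unlist(num) < 0) || any(unlist(num) != round(unlist(num))))
        stop("abstract counts must be non-negative integers")
    if (anyDuplicated(pairKey(df$taxon_i, df$taxon_j)))
        stop("duplicate taxon pairs in co-occurrence file")
    df
}

interactionLabelValues <- c("interacting", "non_interacting", "unknown")

#' Read curated interaction labels
#'
#' @param path TSV with columns `taxon_i`, `taxon_j`, `label`; labels must
#'   be one of `interacting`, `non_interacting`, `unknown`.
#' @return data.frame with those columns.
#' @export
readInteractionLabels <- function(path) {
    df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                     check.names = FALSE)
    missing <- setdiff(c("taxon_i", "taxon_j", "label"), names(df))
    if (length(missing))
        stop("label file is missing column(s): ",
             paste(missing, collapse = ", "))
    bad <- setdiff(unique(df$label), interactionLabelValues)
    if (length(bad))
        stop("unknown label value(s): ", paste(bad, collapse = ", "),
             " (expected ", paste(interactionLabelValues, collapse = "/"), ")")
    if (anyDuplicated(pairKey(df$taxon_i, df$taxon_j)))
        stop("duplicate taxon pairs in label file")
    df[c("taxon_i", "taxon_j", "label")]
}

#' Construct an association network from an edge list
#'
#' @param edges data.frame with columns `taxon_i`, `taxon_j`, `sign`,
#'   `weight` (unordered pairs; reordered so `taxon_i < taxon_j`).
#' @param taxaIds all node ids; defaults to the ids seen in `edges`.
#' @return an [AssociationNetwork-class].
#' @export
associationNetwork <- function(edges, taxaIds = NULL) {
    if (is.null(taxaIds))
        taxaIds <- sort(unique(c(edges$taxon_i, edges$taxon_j)))
    if (nrow(edges)) {
        swap <- edges$taxon_i > edges$taxon_j
        tmp <- edges$taxon_i[swap]
        edges$taxon_i[swap] <- edges$taxon_j[swap]
        edges$taxon_j[swap] <- tmp
        edges <- edges[order(edges$taxon_i, edges$taxon_j), , drop = FALSE]
        rownames(edges) <- NULL
    }
    new("AssociationNetwork", edges = edges, taxaIds = taxaIds)
}

#' Write a network to disk
#'
#' `edge_list_tsv` writes columns `taxon_i`, `taxon_j`, `sign`, `weight`
#' (lexicographically ordered, lossless round trip via [readNetwork()]);
#' `graphml` writes GraphML through igraph with `sign` and `weight` edge
#' attributes.
#'
#' @param net an [AssociationNetwork-class].
#' @param path output path.
#' @param format `"edge_list_tsv"` (default) or `"graphml"`.
#' @export
writeNetwork <- function(net, path, format = c("edge_list_tsv", "graphml")) {
    stopifnot(is(net, "AssociationNetwork"))
    format <- tryCatch(match.arg(format), error = function(e)
        stop("unknown format '", format[1L],
             "'; supported: edge_list_tsv, graphml", call. = FALSE))
    if (format == "edge_list_tsv") {
        write.table(networkEdges(net), path, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    } else {
        g <- igraph::make_empty_graph(n = length(taxaIds(net)),
                                      directed = FALSE)
        g <- igraph::set_vertex_attr(g, "name", value = taxaIds(net))
        e <- networkEdges(net)
        if (nrow(e)) {
            g <- igraph::add_edges(g, rbind(e$taxon_i, e$taxon_j))
            g <- igraph::set_edge_attr(g, "sign", value = e$sign)
            g <- igraph::set_edge_attr(g, "weight", value = e$weight)
        }
        igraph::write_graph(g, path, format = "graphml")
    }
    invisible(path)
}

#' Read an edge-list TSV network
#'
#' @param path file written by [writeNetwork()] with
#'   `format = "edge_list_tsv"`.
#' @param taxaIds optional full node set (isolated nodes are not stored in
#'   the edge list).
#' @return an [AssociationNetwork-class].
#' @export
readNetwork <- function(path, taxaIds = NULL) {
    df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                     check.names = FALSE)
    missing <- setdiff(c("taxon_i", "taxon_j", "sign", "weight"), names(df))
    if (length(missing))
        stop("network file is missing column(s): ",
             paste(missing, collapse = ", "))
    df$taxon_i <- as.character(df$taxon_i)
    df$taxon_j <- as.character(df$taxon_j)
    associationNetwork(df, taxaIds)
}
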