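# Readers for the external file formats: multi-omics TSV matrices,
# STRING-style interaction tables, system-level gene property tables and
# plain-text driver gene lists. All symbol matching downstream is
# uppercase-exact; readers fold gene symbols to upper case on entry.

read_omics_tsv <- function(path, what) {
  if (!file.exists(path)) dg_stop(what, " file not found: ", path)
  df <- tryCatch(
    read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
               stringsAsFactors = FALSE, quote = ""),
    error = function(e) dg_stop("malformed TSV in ", what, " file ", path, ": ",
                                conditionMessage(e))
  )
  if (ncol(df) < 2L) dg_stop("malformed TSV in ", what, " file ", path,
                             ": need a sample-ID column plus gene columns")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) dg_stop("duplicate sample IDs in ", path, ": ",
                                  paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- colnames(m)[!apply(m, 2L, function(col) all(!is.na(suppressWarnings(as.numeric(col)))))]
    dg_stop("non-numeric values in ", what, " file ", path,
            if (length(bad)) paste0(" (columns: ", paste(head(bad, 5L), collapse = ", "), ")"))
  }
  storage.mode(m) <- "double"
  rownames(m) <- ids
  colnames(m) <- toupper(colnames(m))
  if (anyDuplicated(colnames(m))) dg_stop("duplicate gene symbols in ", path)
  if (anyNA(m)) {
    n_na <- sum(is.na(m))
    dg_stop("missing values (NA) are not allowed in omics matrices: ",
            n_na, " found in ", path)
  }
  m
}

check_domain <- function(m, what) {
  offenders <- switch(what,
    mutation = which(!(m %in% c(0, 1))),
    methylation = which(m < 0 | m > 1),
    cnv = which(!(m %in% c(-2, -1, 0, 1, 2))),
    integer(0))
  if (length(offenders)) {
    idx <- arrayInd(offenders[seq_len(min(5L, length(offenders)))], dim(m))
    desc <- apply(idx, 1L, function(ij)
      sprintf("%s/%s=%g", rownames(m)[ij[1L]], colnames(m)[ij[2L]], m[ij[1L], ij[2L]]))
    dg_stop("out-of-range values in ", what, " matrix (",
            length(offenders), " offenders, e.g. ", paste(desc, collapse = ", "), ")")
  }
  invisible(m)
}

#' Load an aligned multi-omics cohort
#'
#' Reads four tumor matrices (binary somatic mutation, log2 expression,
#' methylation beta values, GISTIC2-style copy-number categories) and an
#' optional control expression matrix, all as TSV with samples in rows and
#' gene symbols in the header. Tumor matrices are aligned to the samples
#' present in every omics layer and to the genes shared by all files
#' (including controls when supplied); both orderings are lexicographic so
#' loading is independent of input row order.
#'
#' @param mutation,expression,methylation,cnv paths to the tumor matrices.
#' @param control_expression optional path to a control-samples expression
#'   matrix used for DEG calling.
#' @return an object of class `cohort_data`: list with `sample_ids`,
#'   `gene_ids`, the four matrices, and `control_expression` (or NULL).
#' @export
load_cohort <- function(mutation, expression, methylation, cnv,
                        control_expression = NULL) {
  mats <- list(
    mutation = read_omics_tsv(mutation, "mutation"),
    expression = read_omics_tsv(expression, "expression"),
    methylation = read_omics_tsv(methylation, "methylation"),
    cnv = read_omics_tsv(cnv, "cnv")
  )
  check_domain(mats$mutation, "mutation")
  check_domain(mats$methylation, "methylation")
  check_domain(mats$cnv, "cnv")
  ctrl <- if (!is.null(control_expression))
    read_omics_tsv(control_expression, "control expression") else NULL

  samples <- Reduce(intersect, lapply(mats, rownames))
  gene_sets <- c(lapply(mats, colnames), if (!is.null(ctrl)) list(colnames(ctrl)))
  genes <- Reduce(intersect, gene_sets)
  if (length(samples) == 0L) dg_stop("no common samples across omics files")
  if (length(genes) == 0L) dg_stop("no common genes across omics files")
  samples <- sort(samples)
  genes <- sort(genes)

  mats <- lapply(mats, function(m) m[samples, genes, drop = FALSE])
  if (!is.null(ctrl)) ctrl <- ctrl[sort(rownames(ctrl)), genes, drop = FALSE]
  dg_log("cohort loaded: ", length(samples), " samples x ", length(genes),
         " genes", if (!is.null(ctrl)) paste0(", ", nrow(ctrl), " controls"))
  structure(list(sample_ids = samples,
                 gene_ids = genes,
                 mutation = mats$mutation,
                 expression = mats$expression,
                 methylation = mats$methylation,
                 cnv = mats$cnv,
                 control_expression = ctrl),
            class = "cohort_data")
}

#' @export
print.cohort_data <- function(x, ...) {
  cat("multi-omics cohort:", length(x$sample_ids), "samples x",
      length(x$gene_ids), "genes\n")
  cat("  layers: mutation, expression, methylation, cnv",
      if (!is.null(x$control_expression))
        sprintf("(+ %d control expression samples)", nrow(x$control_expression)),
      "\n")
  invisible(x)
}

#' Load a protein-protein interaction table
#'
#' Expects a 3-column TSV (geneA, geneB, score) in the style of a STRING
#' flat export. Edges below the score threshold are dropped, self-edges
#' removed, and undirected duplicates collapsed (the highest score is
#' kept).
#'
#' @param path TSV file.
#' @param score_threshold minimum score kept (edges with score >= threshold
#'   are retained); STRING's high-confidence convention is 700.
#' @return object of class `ppi_table`: data.frame with columns `gene_a`,
#'   `gene_b`, `score` (gene_a < gene_b lexicographically) plus the
#'   threshold as attribute.
#' @export
load_ppi <- function(path, score_threshold = 700) {
  if (!file.exists(path)) dg_stop("PPI file not found: ", path)
  df <- tryCatch(
    read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE, quote = ""),
    error = function(e) dg_stop("malformed PPI TSV ", path, ": ", conditionMessage(e))
  )
  if (nrow(df) == 0L) {
    dg_log("PPI file ", path, " contains no edges")
    warning("PPI table is empty", call. = FALSE)
    out <- data.frame(gene_a = character(0), gene_b = character(0),
                      score = numeric(0), stringsAsFactors = FALSE)
    attr(out, "score_threshold") <- score_threshold
    class(out) <- c("ppi_table", "data.frame")
    return(out)
  }
  if (ncol(df) < 3L) dg_stop("PPI file must have 3 columns (geneA, geneB, score)")
  score <- suppressWarnings(as.numeric(df[[3L]]))
  if (anyNA(score)) dg_stop("non-numeric interaction score in ", path,
                            " (first bad row: ", which(is.na(score))[1L], ")")
  a <- toupper(as.character(df[[1L]]))
  b <- toupper(as.character(df[[2L]]))
  keep <- score >= score_threshold & a != b
  a <- a[keep]; b <- b[keep]; score <- score[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  ord <- order(key, -score)
  lo <- lo[ord]; hi <- hi[ord]; score <- score[ord]; key <- key[ord]
  first <- !duplicated(key)
  out <- data.frame(gene_a = lo[first], gene_b = hi[first], score = score[first],
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "score_threshold") <- score_threshold
  class(out) <- c("ppi_table", "data.frame")
  dg_log("PPI loaded: ", nrow(out), " undirected edges at threshold ", score_threshold)
  out
}

#' Load driver-gene label lists
#'
#' Each file holds one gene symbol per line (case-insensitive); the
#' catalogue is the uppercased, deduplicated union of all lists.
#'
#' @param paths character vector of gene-list files.
#' @return object of class `label_catalogue`: sorted character vector of
#'   positive gene symbols.
#' @export
load_labels <- function(paths) {
  symbols <- character(0)
  for (p in paths) {
    if (!file.exists(p)) dg_stop("gene list not found: ", p)
    lines <- trimws(readLines(p, warn = FALSE))
    symbols <- c(symbols, lines[nzchar(lines)])
  }
  symbols <- sort(unique(toupper(symbols)))
  if (length(symbols) == 0L) dg_stop("all gene-list files are empty")
  structure(symbols, class = "label_catalogue")
}

#' Load the system-level gene property table
#'
#' A TSV with a gene-symbol column followed by exactly 18 numeric columns
#' of global gene properties (gene length, domain count, gene age,
#' essentiality, ...), one row per gene.
#'
#' @param path TSV file.
#' @return object of class `system_features`: numeric genes x 18 matrix
#'   with uppercased gene symbols as rownames.
#' @export
load_system_features <- function(path) {
  if (!file.exists(path)) dg_stop("system feature table not found: ", path)
  df <- tryCatch(
    read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE, quote = ""),
    error = function(e) dg_stop("malformed system feature table ", path, ": ",
                                conditionMessage(e))
  )
  if (ncol(df) != 19L)
    dg_stop("system feature table must have 1 gene column + 18 feature columns, got ",
            ncol(df), " in ", path)
  genes <- toupper(as.character(df[[1L]]))
  if (anyDuplicated(genes)) dg_stop("duplicate genes in system feature table: ",
                                    paste(unique(genes[duplicated(genes)]), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) dg_stop("missing values in system feature table ", path)
  rownames(m) <- genes
  structure(m, class = c("system_features", class(m)))
}

write_matrix_tsv <- function(m, path, id_col = "sample_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
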