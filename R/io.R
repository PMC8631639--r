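# TSV readers/writers. Tables travel as tab-separated text: samples as rows,
# first column `sample_id`, remaining columns gene IDs, full round-trip float
# precision ("%.17g", '.' decimal separator, LF newlines), with an optional
# gene-metadata sidecar (`gene_id`, `chromosome`, `index`).

#' Read a sample-by-gene table from TSV
#'
#' @param path TSV with a header row; first column holds IDs, remaining
#'   columns numeric values. Cells equal to `missingToken` become `NA`; any
#'   other non-numeric cell is an error naming its location.
#' @param metaPath optional gene-metadata sidecar TSV with columns
#'   `gene_id`, `chromosome`, `index`. Without it genes are placed on one
#'   unknown chromosome in file order (digit work is unaffected; adjacency
#'   diagnostics need real metadata).
#' @param orientation `"samples_by_genes"` (default) or `"genes_by_samples"`
#'   (the table is transposed on read).
#' @param missingToken string marking missing values (default `"NA"`).
#' @param label per-sample label to assign (default `"real"`).
#' @return a [CNACohort-class].
#' @export
readGeneTable <- function(path, metaPath = NULL,
                          orientation = c("samples_by_genes",
                                          "genes_by_samples"),
                          missingToken = "NA", label = "real") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1L),
                          na.strings = missingToken, data.table = FALSE,
                          showProgress = FALSE)
  if (nrow(dt) == 0L || ncol(dt) < 2L) stop("empty table: ", path,
                                            call. = FALSE)
  ids <- dt[[1]]
  if (anyDuplicated(ids))
    stop("duplicate row IDs in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(dt)[-1]))
    stop("duplicate column IDs in ", path, call. = FALSE)
  body <- dt[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    if (!is.numeric(body[[j]])) {
      v <- body[[j]]
      bad <- which(!is.na(v) & is.na(suppressWarnings(as.numeric(v))))
      if (length(bad))
        stop(sprintf("non-numeric cell in %s at line %d, column '%s': '%s'",
                     path, bad[1] + 1L, colnames(body)[j], v[bad[1]]),
             call. = FALSE)
      body[[j]] <- as.numeric(v)
    }
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  if (orientation == "genes_by_samples") m <- t(m)

  chromosome <- index <- NULL
  if (!is.null(metaPath)) {
    meta <- data.table::fread(metaPath, sep = "\t", header = TRUE,
                              data.table = FALSE, showProgress = FALSE)
    need <- c("gene_id", "chromosome", "index")
    if (!all(need %in% colnames(meta)))
      stop("gene metadata must have columns gene_id, chromosome, index",
           call. = FALSE)
    at <- match(colnames(m), meta$gene_id)
    if (anyNA(at))
      stop("gene metadata is missing genes: ",
           paste(colnames(m)[is.na(at)][1:min(3, sum(is.na(at)))],
                 collapse = ", "), call. = FALSE)
    chromosome <- as.character(meta$chromosome[at])
    index <- as.integer(meta$index[at])
  } else {
    chromosome <- rep(NA_character_, ncol(m))
    index <- seq_len(ncol(m))
  }
  cnaCohort(m, chromosome = chromosome, index = index, label = label)
}

#' Write a cohort as TSV (plus gene-metadata sidecar)
#'
#' Values are rendered with `%.17g` so a write-read round trip reproduces
#' every double bit for bit; delimiters are tabs, newlines LF, decimal
#' separator always `'.'`.
#'
#' @param table a [CNACohort-class].
#' @param prefix output prefix; writes `<prefix>.tsv` and
#'   `<prefix>.genes.tsv`.
#' @return invisibly, the two paths written.
#' @export
writeGeneTable <- function(table, prefix) {
  stopIfNotCohort(table)
  X <- cnaMatrix(table)
  chr <- matrix(sprintf("%.17g", X), nrow(X))
  chr[is.na(X)] <- "NA"
  out <- data.table::data.table(sample_id = rownames(X))
  for (j in seq_len(ncol(X))) out[[colnames(X)[j]]] <- chr[, j]
  mainPath <- paste0(prefix, ".tsv")
  data.table::fwrite(out, mainPath, sep = "\t", quote = FALSE, eol = "\n")
  metaPath <- paste0(prefix, ".genes.tsv")
  data.table::fwrite(geneMeta(table), metaPath, sep = "\t", quote = FALSE,
                     eol = "\n")
  invisible(c(mainPath, metaPath))
}

#' Write a results table as TSV
#'
#' Deterministic column order (as given), tabs, LF newlines, `'.'` decimal
#' separator, full float precision.
#'
#' @param results a data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeResults <- function(results, path) {
  if (!is.data.frame(results)) stop("'results' must be a data.frame",
                                    call. = FALSE)
  out <- results
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, eol = "\n")
  invisible(path)
}
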