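#' OTU count table
#'
#' Container for a taxa-by-samples matrix of sequence counts, the working
#' object of every downstream step. Rows are OTUs, columns are samples
#' (classic QIIME orientation). Taxonomy (semicolon-delimited lineages) and
#' per-sample metadata are optional and validated against the ids.
#'
#' @param counts integer matrix (OTUs x samples) with non-negative entries.
#'   Row and column names are used as OTU and sample ids; if absent they are
#'   generated (`OTU_1`, ..., `S1`, ...).
#' @param taxonomy optional named character vector, `otu_id -> lineage`
#'   (e.g. `"k__Bacteria;p__Proteobacteria;..."`). Names must be OTU ids.
#' @param metadata optional data.frame of per-sample covariates with
#'   `rownames` equal to sample ids (or a `sample_id` column).
#' @return an object of class `otu_table`: a list with elements `counts`,
#'   `taxonomy`, `metadata`.
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 2L, 1L, 0L), nrow = 3,
#'             dimnames = list(paste0("OTU_", 1:3), c("S1", "S2")))
#' tab <- otu_table(m)
#' n_otus(tab)
#' @export
otu_table <- function(counts, taxonomy = NULL, metadata = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (length(counts) == 0 || nrow(counts) == 0 || ncol(counts) == 0)
    stop("empty OTU table: need at least one OTU and one sample")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("OTU_", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("S", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts))) {
    dup <- unique(rownames(counts)[duplicated(rownames(counts))])
    stop("duplicate OTU id(s): ", paste(dup, collapse = ", "))
  }
  if (anyDuplicated(colnames(counts))) {
    dup <- unique(colnames(counts)[duplicated(colnames(counts))])
    stop("duplicate sample id(s): ", paste(dup, collapse = ", "))
  }
  if (any(!is.finite(counts)))
    stop("counts contain missing or non-finite values")
  if (any(counts < 0))
    stop("counts must be non-negative; first offence at row ",
         which(rowSums(counts < 0) > 0)[1])
  if (any(counts != round(counts)))
    stop("counts must be integers; first offence at row ",
         which(rowSums(counts != round(counts)) > 0)[1])
  storage.mode(counts) <- "integer"

  if (!is.null(taxonomy)) {
    taxonomy <- unlist(taxonomy)
    if (is.null(names(taxonomy)))
      stop("taxonomy must be named by OTU id")
    unknown <- setdiff(names(taxonomy), rownames(counts))
    if (length(unknown))
      stop("taxonomy refers to unknown OTU id(s): ",
           paste(unknown, collapse = ", "))
  }
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    if ("sample_id" %in% names(metadata)) {
      rownames(metadata) <- metadata$sample_id
      metadata$sample_id <- NULL
    }
    unknown <- setdiff(rownames(metadata), colnames(counts))
    if (length(unknown))
      stop("metadata refers to unknown sample id(s): ",
           paste(unknown, collapse = ", "))
  }
  structure(list(counts = counts, taxonomy = taxonomy, metadata = metadata),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat("OTU table:", nrow(x$counts), "OTUs x", ncol(x$counts), "samples\n")
  cat("total reads:", sum(x$counts),
      "| per-sample range:", paste(range(colSums(x$counts)), collapse = "-"),
      "\n")
  if (!is.null(x$taxonomy)) cat("taxonomy for", length(x$taxonomy), "OTUs\n")
  if (!is.null(x$metadata))
    cat("metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname otu_table
#' @param x an `otu_table`.
#' @export
n_otus <- function(x) nrow(x$counts)

#' @rdname otu_table
#' @export
n_samples <- function(x) ncol(x$counts)

#' @rdname otu_table
#' @export
otu_ids <- function(x) rownames(x$counts)

#' @rdname otu_table
#' @export
sample_ids <- function(x) colnames(x$counts)

#' Read an OTU table from disk
#'
#' Accepts the classic tab-separated layout (`#OTU ID` header, sample
#' columns, optional trailing `taxonomy` column with semicolon lineages) or
#' dense BIOM JSON (read via the biomformat package).
#'
#' @param path file path.
#' @param format `"tsv"` (default) or `"biom-json"`.
#' @return an [otu_table].
#' @export
read_otu_table <- function(path, format = c("tsv", "biom-json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "biom-json") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM requires the 'biomformat' package")
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    return(otu_table(m))
  }
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("OTU table needs an id column and >= 1 sample")
  ids <- as.character(df[[1]])
  df <- df[, -1, drop = FALSE]
  taxonomy <- NULL
  if (tolower(names(df)[ncol(df)]) == "taxonomy") {
    taxonomy <- stats::setNames(as.character(df[[ncol(df)]]), ids)
    df <- df[, -ncol(df), drop = FALSE]
  }
  m <- as.matrix(df)
  if (!is.numeric(m))
    stop("non-numeric count encountered in ", path)
  bad <- which(m != floor(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("non-integer or negative count at row ", ids[bad[1, 1]],
         ", column ", colnames(m)[bad[1, 2]])
  rownames(m) <- ids
  otu_table(m, taxonomy = taxonomy)
}

#' Write an OTU table as classic TSV
#'
#' @param x an [otu_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(x, path) {
  df <- data.frame(`#OTU ID` = otu_ids(x), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(x$taxonomy)) {
    tax <- x$taxonomy[otu_ids(x)]
    tax[is.na(tax)] <- ""
    df$taxonomy <- unname(tax)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' First column is the sample id; remaining columns are covariates.
#'
#' @param path file path.
#' @return data.frame with sample ids as rownames.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (anyDuplicated(df[[1]]))
    stop("duplicate sample id(s) in metadata: ",
         paste(unique(df[[1]][duplicated(df[[1]])]), collapse = ", "))
  rownames(df) <- as.character(df[[1]])
  df[, -1, drop = FALSE]
}

#' Restrict an OTU table to a subset of OTUs
#'
#' Rows are kept in their original table order regardless of the order of
#' `otus`; sample columns are untouched. Used to carve out one ecological
#' group before computing its beta-null deviation.
#'
#' @param x an [otu_table].
#' @param otus character vector of OTU ids, a subset of `otu_ids(x)`.
#' @return an [otu_table] with the selected rows.
#' @export
subset_otus <- function(x, otus) {
  unknown <- setdiff(otus, otu_ids(x))
  if (length(unknown))
    stop("unknown OTU id(s): ", paste(unknown, collapse = ", "))
  keep <- otu_ids(x)[otu_ids(x) %in% otus]
  otu_table(x$counts[keep, , drop = FALSE],
            taxonomy = if (!is.null(x$taxonomy))
              x$taxonomy[intersect(names(x$taxonomy), keep)],
            metadata = x$metadata)
}
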