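#' Rarefy an OTU table to even depth
#'
#' Subsamples each sample's reads to a common depth WITHOUT replacement
#' (a multivariate hypergeometric draw per sample, via [vegan::rrarefy]),
#' the normalization applied to amplicon count tables before partitioning
#' and ordination. Samples whose total is below `depth` are dropped with a
#' warning: subsampling cannot create reads.
#'
#' @param x an [otu_table].
#' @param depth target reads per sample (positive integer; 7000 and 12000
#'   are typical choices for bacterial and archaeal 16S tables).
#' @param seed integer seed; the draw is deterministic given
#'   `(x, depth, seed)`.
#' @param drop_empty drop OTU rows that end up all-zero? Default `FALSE`
#'   so group labels computed on the parent table remain addressable.
#' @return a rarefied [otu_table]; every column sums exactly to `depth`.
#' @export
rarefy_table <- function(x, depth, seed = 1L, drop_empty = FALSE) {
  if (length(depth) != 1 || depth < 1 || depth != round(depth))
    stop("depth must be a positive integer")
  totals <- colSums(x$counts)
  low <- totals < depth
  if (all(low))
    stop("no samples at requested depth ", depth,
         " (max sample total is ", max(totals), ")")
  if (any(low))
    warning("dropping ", sum(low), " sample(s) below depth ", depth, ": ",
            paste(colnames(x$counts)[low], collapse = ", "))
  m <- x$counts[, !low, drop = FALSE]
  # rrarefy's input heuristics re-warn on validated data; counts and depth
  # are checked above
  r <- with_seed_local(seed, suppressWarnings(vegan::rrarefy(t(m), depth)))
  out <- t(r)
  if (drop_empty) out <- out[rowSums(out) > 0, , drop = FALSE]
  meta <- x$metadata
  if (!is.null(meta)) meta <- meta[colnames(out), , drop = FALSE]
  tax <- x$taxonomy
  if (!is.null(tax) && drop_empty)
    tax <- tax[intersect(names(tax), rownames(out))]
  otu_table(out, taxonomy = tax, metadata = meta)
}

#' Relative abundance matrix
#'
#' @param x an [otu_table] or count matrix (OTUs x samples).
#' @return numeric matrix of per-sample proportions (all-zero samples map
#'   to zeros), with attribute `transform = "relative"`.
#' @export
relative_abundance <- function(x) {
  m <- if (inherits(x, "otu_table")) x$counts else as.matrix(x)
  totals <- colSums(m)
  p <- sweep(m, 2, pmax(totals, 1), "/")
  p[, totals == 0] <- 0
  structure(p, transform = "relative")
}

#' Hellinger transformation
#'
#' Square root of relative abundance: `sqrt(count / sample total)`. Makes
#' Euclidean-embedding methods (PCoA, RDA) appropriate for count data by
#' damping the influence of dominant taxa. Squared entries of every
#' non-empty sample column sum to 1.
#'
#' @param x an [otu_table] or count matrix (OTUs x samples).
#' @return numeric matrix with attribute `transform = "hellinger"`.
#' @export
hellinger_transform <- function(x) {
  p <- relative_abundance(x)
  structure(sqrt(p), transform = "hellinger")
}
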