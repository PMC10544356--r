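#' Coerce input to a validated count matrix
#'
#' Accepts an integer-valued matrix with gene row names and sample column
#' names, or a data frame whose first column holds gene identifiers
#' (remaining columns one per sample). Checks non-negativity, integrality,
#' uniqueness of gene and sample identifiers, and absence of missing
#' values.
#'
#' @param x matrix or data frame of counts, genes as rows.
#' @return an integer-mode matrix with unique dimnames.
#' @export
as_count_matrix <- function(x) {
  if (is.data.frame(x)) {
    ids <- as.character(x[[1]])
    m <- as.matrix(x[-1])
    rownames(m) <- ids
    x <- m
  }
  if (!is.matrix(x)) stop("counts must be a matrix or data frame",
                          call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("counts need gene row names and sample column names",
         call. = FALSE)
  }
  if (anyNA(x)) stop("counts must not contain missing values",
                     call. = FALSE)
  if (!is.numeric(x)) stop("counts must be numeric", call. = FALSE)
  if (any(x < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(x != round(x))) stop("counts must be integers", call. = FALSE)
  dup <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup)) {
    stop("duplicate gene identifiers: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    stop("duplicate sample identifiers", call. = FALSE)
  }
  storage.mode(x) <- "double"
  x
}

#' Counts per million
#'
#' Scales each sample (column) by its library size, times 1e6. Used only
#' for gene filtering; no between-sample normalization is applied anywhere
#' in the pipeline.
#'
#' @param counts count matrix (genes by samples), see [as_count_matrix()].
#' @return a numeric matrix of the same shape whose columns each sum to
#'   1e6.
#' @examples
#' m <- matrix(c(1, 3), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
#' compute_cpm(m)
#' @export
compute_cpm <- function(counts) {
  counts <- as_count_matrix(counts)
  libsize <- colSums(counts)
  if (any(libsize == 0)) {
    stop("sample(s) with zero library size: ",
         paste(colnames(counts)[libsize == 0], collapse = ", "),
         call. = FALSE)
  }
  sweep(counts, 2, libsize, "/") * 1e6
}

#' Filter lowly and sparsely expressed genes
#'
#' A gene is removed when its mean CPM across all samples (both groups
#' pooled, library sizes from the unfiltered matrix) is strictly below
#' \code{cpm_threshold}, or when the proportion of samples with a zero
#' count is at least \code{zero_proportion}. Defaults follow the standard
#' rule mean CPM < 0.5 or zeros in at least 85\% of samples. Filtering is
#' idempotent: removing genes can only shrink library sizes, so the mean
#' CPM of every retained gene does not decrease and a second pass removes
#' nothing.
#'
#' @param counts count matrix (genes by samples).
#' @param cpm_threshold keep genes with mean CPM at or above this value.
#' @param zero_proportion remove genes with at least this proportion of
#'   zero counts.
#' @return a list with \code{counts} (the retained submatrix) and
#'   \code{report}, a tibble with columns \code{gene_id}, \code{removed}
#'   and \code{reason} (\code{"low_cpm"}, \code{"high_zero_proportion"},
#'   \code{"both"}, or \code{NA} for kept genes).
#' @export
filter_genes <- function(counts, cpm_threshold = 0.5,
                         zero_proportion = 0.85) {
  stopifnot(cpm_threshold >= 0, zero_proportion > 0, zero_proportion <= 1)
  counts <- as_count_matrix(counts)
  cpm <- compute_cpm(counts)
  low <- rowMeans(cpm) < cpm_threshold
  sparse <- rowMeans(counts == 0) >= zero_proportion
  removed <- low | sparse
  reason <- dplyr::case_when(
    low & sparse ~ "both",
    low ~ "low_cpm",
    sparse ~ "high_zero_proportion",
    .default = NA_character_
  )
  if (sum(!removed) < 2) {
    stop("fewer than 2 genes pass filtering; CLR is undefined",
         call. = FALSE)
  }
  list(
    counts = counts[!removed, , drop = FALSE],
    report = tibble::tibble(
      gene_id = rownames(counts),
      removed = unname(removed),
      reason = reason
    )
  )
}

#' Centered log-ratio transformation
#'
#' Per sample, \eqn{\mathrm{CLR}(x_{gi}) = \log x_{gi} -
#' \frac{1}{G}\sum_{g'} \log x_{g'i}} over the \eqn{G} retained genes,
#' using the natural logarithm. Zero cells are first replaced by
#' \code{pseudo_value} (0.5 by default); nonzero counts are untouched.
#' Each output column sums to zero, and the transform is invariant to
#' rescaling a zero-free sample.
#'
#' @param counts filtered count matrix (genes by samples), at least two
#'   genes.
#' @param pseudo_value positive replacement for zero counts.
#' @return numeric matrix of CLR values, same dimnames as the input.
#' @examples
#' m <- matrix(c(1, 2, 4), 3, 1, dimnames = list(paste0("g", 1:3), "s1"))
#' clr_transform(m)  # (-log 2, 0, log 2)
#' @export
clr_transform <- function(counts, pseudo_value = 0.5) {
  stopifnot(pseudo_value > 0)
  counts <- as_count_matrix(counts)
  if (nrow(counts) < 2) {
    stop("CLR needs at least two genes", call. = FALSE)
  }
  counts[counts == 0] <- pseudo_value
  lg <- log(counts)
  sweep(lg, 2, colMeans(lg), "-")
}
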