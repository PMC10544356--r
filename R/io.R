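.delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a count matrix from TSV or CSV
#'
#' Expects gene identifiers in the first column and one column per
#' sample with a header row of sample identifiers. Cells must be
#' non-negative integers; duplicate identifiers, missing values and
#' ragged rows are rejected with informative errors.
#'
#' @param path file path; comma-separated when the extension is
#'   \code{.csv}, tab-separated otherwise.
#' @return an integer count matrix with gene row names and sample column
#'   names.
#' @export
read_counts <- function(path) {
  d <- readr::read_delim(path, delim = .delim_for(path),
                         show_col_types = FALSE, progress = FALSE)
  prob <- readr::problems(d)
  if (nrow(prob) > 0) {
    stop("malformed counts file ", path, " at line ", prob$row[1], ": ",
         prob$expected[1], call. = FALSE)
  }
  if (ncol(d) < 2) stop("counts file needs gene IDs plus >= 1 sample",
                        call. = FALSE)
  as_count_matrix(as.data.frame(d))
}

#' Write a count matrix to TSV or CSV
#'
#' @param counts count matrix, genes as rows.
#' @param path output path; delimiter chosen by extension as in
#'   [read_counts()].
#' @return the path, invisibly.
#' @export
write_counts <- function(counts, path) {
  counts <- as_count_matrix(counts)
  d <- tibble::as_tibble(counts, rownames = "gene_id")
  readr::write_delim(d, path, delim = .delim_for(path))
  invisible(path)
}

#' Read sample group labels
#'
#' Two-column delimited file: sample identifier, group label.
#'
#' @param path file path (TSV, or CSV by extension).
#' @return a tibble with columns \code{sample_id} and \code{group}.
#' @export
read_groups <- function(path) {
  d <- readr::read_delim(path, delim = .delim_for(path),
                         show_col_types = FALSE, progress = FALSE)
  if (ncol(d) < 2) stop("group file needs two columns", call. = FALSE)
  out <- tibble::tibble(sample_id = as.character(d[[1]]),
                        group = as.character(d[[2]]))
  if (anyDuplicated(out$sample_id)) {
    stop("duplicate sample identifiers in group file", call. = FALSE)
  }
  out
}

#' Write a differential-variability result table
#'
#' Emits the fixed column schema \code{gene_id, sigma_control,
#' sigma_treatment, se_control, se_treatment, z, p_value, q_value,
#' sd_ratio, log2_sd_ratio, status} as a delimited file.
#'
#' @param result a \code{clrdv_dv} object or compatible data frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_dv_results <- function(result, path) {
  d <- if (inherits(result, "clrdv_dv")) tidy(result) else
    tibble::as_tibble(result)
  stopifnot(all(.clrdv_result_cols %in% names(d)))
  readr::write_delim(d[.clrdv_result_cols], path, delim = .delim_for(path))
  invisible(path)
}

#' Generate a plain-text simulation fixture on disk
#'
#' Writes \code{counts.tsv}, \code{groups.tsv} and \code{truth.tsv} for a
#' small simulated two-group experiment. \code{"tiny"} is 50 genes with
#' 40 samples per group and no DV spiking; \code{"null"} is 300 genes,
#' 50 per group, no spiking; \code{"spiked"} is 300 genes, 100 per
#' group, 10\% DV genes. Byte-identical for a given kind and seed.
#'
#' @param kind one of \code{"tiny"}, \code{"null"}, \code{"spiked"}.
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @return named character vector of the files written, invisibly.
#' @export
make_fixture <- function(kind = c("tiny", "null", "spiked"), dir,
                         seed = 1) {
  kind <- match.arg(kind)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- switch(kind,
    tiny = list(G = 50, n = 40, prop_dv = 0),
    null = list(G = 300, n = 50, prop_dv = 0),
    spiked = list(G = 300, n = 100, prop_dv = 0.1)
  )
  sim <- simulate_two_groups(synth_nb2_params(cfg$G, seed), cfg$n,
                             prop_dv = cfg$prop_dv, seed = seed + 1)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    groups = file.path(dir, "groups.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_counts(sim$counts, paths[["counts"]])
  readr::write_tsv(sim$groups, paths[["groups"]])
  readr::write_tsv(sim$truth, paths[["truth"]])
  invisible(paths)
}
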