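#' Kolmogorov-Smirnov statistic against a fitted skew-normal
#'
#' One-sample KS test of \code{values} against the skew-normal CDF with
#' the estimated centered parameters plugged in, with the p-value taken
#' from the asymptotic Kolmogorov distribution. Because the parameters
#' are estimated from the same sample, the test is a plug-in diagnostic:
#' its null distribution is conservative, which is acceptable for the
#' model-adequacy screening it is used for here.
#'
#' @param values numeric vector (at least 20 observations).
#' @param cp centered parameters at the fitted optimum — a list with
#'   \code{mu}, \code{sigma}, \code{gamma}, or an \code{sn_fit} object.
#' @return a list with \code{D} (the supremum distance between the
#'   empirical CDF and the fitted CDF) and \code{p}.
#' @export
ks_stat <- function(values, cp) {
  if (inherits(cp, "sn_fit")) cp <- cp$cp
  stopifnot(length(values) >= 20)
  dp <- cp_to_dp(cp$mu, cp$sigma, cp$gamma)
  kt <- suppressWarnings(
    stats::ks.test(values, function(q) psn(q, dp$xi, dp$omega, dp$alpha),
                   exact = FALSE)
  )
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Per-gene goodness-of-fit screening of the skew-normal model
#'
#' Filters and CLR-transforms a count matrix, fits the skew-normal model
#' to every gene's CLR values across all samples, and computes the
#' plug-in KS statistic for each fit.
#'
#' @param counts genes-by-samples count matrix or data frame.
#' @param cpm_threshold,zero_proportion,pseudo_value see [run_clrdv()].
#' @return a tibble with columns \code{gene_id}, \code{ks_D},
#'   \code{ks_p}, \code{fit_ok}.
#' @export
clrdv_gof <- function(counts, cpm_threshold = 0.5, zero_proportion = 0.85,
                      pseudo_value = 0.5) {
  counts <- as_count_matrix(counts)
  flt <- filter_genes(counts, cpm_threshold, zero_proportion)
  clr <- clr_transform(flt$counts, pseudo_value)
  purrr::map_dfr(rownames(clr), function(g) {
    fit <- tryCatch(fit_sn_cp(clr[g, ], warn_small = FALSE),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      return(tibble::tibble(gene_id = g, ks_D = NA_real_,
                            ks_p = NA_real_, fit_ok = FALSE))
    }
    ks <- ks_stat(clr[g, ], fit)
    tibble::tibble(gene_id = g, ks_D = ks$D, ks_p = ks$p, fit_ok = TRUE)
  })
}

#' Proportion of genes the skew-normal model fits well
#'
#' @param records goodness-of-fit table from [clrdv_gof()].
#' @param threshold KS p-value above which a fit counts as adequate.
#' @return the proportion of successfully fitted genes with
#'   \code{ks_p > threshold}.
#' @export
gof_summary <- function(records, threshold = 0.05) {
  if (nrow(records) == 0) stop("empty goodness-of-fit table",
                               call. = FALSE)
  ok <- records$fit_ok & !is.na(records$ks_p)
  if (!any(ok)) stop("no successful fits to summarize", call. = FALSE)
  mean(records$ks_p[ok] > threshold)
}

#' Histogram of goodness-of-fit p-values
#'
#' Plots the per-gene KS p-values on the \eqn{\sqrt{-\log_{10} p}} scale
#' for compactness, with a dashed line at the adequacy threshold.
#'
#' @param records table from [clrdv_gof()].
#' @param threshold adequacy threshold on the p-value.
#' @return a ggplot object.
#' @export
plot_gof_pvalues <- function(records, threshold = 0.05) {
  d <- records[records$fit_ok & !is.na(records$ks_p), ]
  d$tp <- sqrt(-log10(pmax(d$ks_p, 1e-300)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$tp)) +
    ggplot2::geom_histogram(bins = 60, fill = "steelblue",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = sqrt(-log10(threshold)),
                        linetype = 2, colour = "red") +
    ggplot2::labs(
      x = expression(sqrt(-log[10] ~ "KS p-value")),
      y = "genes"
    ) +
    ggplot2::theme_minimal()
}
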