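#' Wald statistic for equality of skew-normal standard deviations
#'
#' \eqn{Z = (\hat\sigma_2 - \hat\sigma_1) /
#' \sqrt{\mathrm{Var}(\hat\sigma_2) + \mathrm{Var}(\hat\sigma_1)}}, where
#' the variances are the \eqn{\sigma} diagonal elements of the inverse
#' observed information in centered parameters. Asymptotically standard
#' normal under \eqn{\sigma_1 = \sigma_2}; the two-sided p-value is
#' \eqn{2(1 - \Phi(|Z|))}.
#'
#' @param fit1,fit2 converged [fit_sn_cp()] objects for the reference and
#'   test group respectively.
#' @return the Wald Z statistic (test minus reference orientation).
#' @export
wald_z <- function(fit1, fit2) {
  if (!isTRUE(fit1$converged) || !isTRUE(fit2$converged) ||
      !is.finite(fit1$var_sigma) || !is.finite(fit2$var_sigma)) {
    stop("both fits must be converged with finite var_sigma",
         call. = FALSE)
  }
  (fit2$cp$sigma - fit1$cp$sigma) / sqrt(fit1$var_sigma + fit2$var_sigma)
}

#' Benjamini-Yekutieli adjusted p-values
#'
#' Step-up adjustment \eqn{q_{(i)} = \min_{j \ge i}
#' \min\{1, m\,c(m)\,p_{(j)}/j\}} with the harmonic factor
#' \eqn{c(m) = \sum_{k=1}^m 1/k}, valid under arbitrary dependence between
#' the tests. Missing entries are excluded from the family size \eqn{m}
#' and returned as \code{NA}.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @return adjusted values in the input order.
#' @export
by_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BY")
  q
}

.clrdv_result_cols <- c(
  "gene_id", "sigma_control", "sigma_treatment", "se_control",
  "se_treatment", "z", "p_value", "q_value", "sd_ratio",
  "log2_sd_ratio", "status"
)

.resolve_design <- function(groups, sample_ids, reference = NULL) {
  if (is.data.frame(groups)) {
    if (ncol(groups) < 2) {
      stop("group table needs columns sample_id and group", call. = FALSE)
    }
    idx <- match(sample_ids, as.character(groups[[1]]))
    if (anyNA(idx)) {
      stop("samples missing from group table: ",
           paste(sample_ids[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    groups <- as.character(groups[[2]])[idx]
  }
  groups <- as.character(groups)
  if (length(groups) != length(sample_ids)) {
    stop("group labels must align with the samples", call. = FALSE)
  }
  lev <- unique(groups)
  if (length(lev) != 2) {
    stop("exactly two groups are required, got ", length(lev),
         call. = FALSE)
  }
  if (is.null(reference)) reference <- lev[1]
  if (!reference %in% lev) {
    stop("reference group '", reference, "' not found", call. = FALSE)
  }
  test <- setdiff(lev, reference)
  n1 <- sum(groups == reference)
  n2 <- sum(groups == test)
  if (min(n1, n2) < 20) {
    stop("each group needs at least 20 samples (", reference, ": ", n1,
         ", ", test, ": ", n2, ")", call. = FALSE)
  }
  if (min(n1, n2) < 50) {
    warning("group sizes below 50 (", reference, ": ", n1, ", ", test,
            ": ", n2, "): sigma estimates may be unreliable",
            call. = FALSE)
  }
  list(labels = groups, reference = reference, test = test)
}

#' Test genes for differential variability
#'
#' The full pipeline: filter genes on the pooled samples, CLR-transform
#' the pooled filtered matrix, split columns by group, fit a skew-normal
#' distribution in centered parameters to each gene within each group,
#' form the Wald statistic on \eqn{\sigma}, and adjust the two-sided
#' p-values with the Benjamini-Yekutieli procedure over the genes whose
#' fits succeeded in both groups. Genes with a failed fit are reported
#' with \code{status = "fit_failed"} and excluded from the adjustment
#' family, never silently dropped. Effect sizes are reported as the SD
#' ratio \eqn{\hat\sigma_{treatment}/\hat\sigma_{control}} and its log2.
#'
#' @param counts genes-by-samples count matrix or data frame (first column
#'   gene identifiers).
#' @param groups group label per sample — a vector aligned with the
#'   columns, or a two-column data frame (sample_id, group).
#' @param reference label of the reference (control) group; defaults to
#'   the first label encountered.
#' @param alpha significance threshold on the BY-adjusted p-value.
#' @param cpm_threshold,zero_proportion gene-filter settings, see
#'   [filter_genes()].
#' @param pseudo_value zero replacement for the CLR, see
#'   [clr_transform()].
#' @return an object of class \code{clrdv_dv}: a tibble with columns
#'   \code{gene_id}, \code{sigma_control}, \code{sigma_treatment},
#'   \code{se_control}, \code{se_treatment}, \code{z}, \code{p_value},
#'   \code{q_value}, \code{sd_ratio}, \code{log2_sd_ratio},
#'   \code{status}, one row per tested gene, plus run metadata in
#'   attributes (see [glance.clrdv_dv()]).
#' @examples
#' sim <- simulate_two_groups(synth_nb2_params(60, seed = 1),
#'                            n_per_group = 50, prop_dv = 0, seed = 1)
#' res <- suppressWarnings(
#'   run_clrdv(sim$counts, sim$groups, reference = "control")
#' )
#' glance(res)
#' @export
run_clrdv <- function(counts, groups, reference = NULL, alpha = 0.05,
                      cpm_threshold = 0.5, zero_proportion = 0.85,
                      pseudo_value = 0.5) {
  counts <- as_count_matrix(counts)
  design <- .resolve_design(groups, colnames(counts), reference)

  flt <- filter_genes(counts, cpm_threshold, zero_proportion)
  clr <- clr_transform(flt$counts, pseudo_value)
  in1 <- design$labels == design$reference
  in2 <- design$labels == design$test

  fits <- purrr::map(rownames(clr), function(g) {
    f1 <- tryCatch(fit_sn_cp(clr[g, in1], warn_small = FALSE),
                   error = function(e) NULL)
    f2 <- tryCatch(fit_sn_cp(clr[g, in2], warn_small = FALSE),
                   error = function(e) NULL)
    ok <- !is.null(f1) && !is.null(f2) && f1$converged && f2$converged &&
      is.finite(f1$var_sigma) && is.finite(f2$var_sigma)
    if (!ok) {
      return(tibble::tibble(
        gene_id = g, sigma_control = NA_real_, sigma_treatment = NA_real_,
        se_control = NA_real_, se_treatment = NA_real_, z = NA_real_,
        p_value = NA_real_, sd_ratio = NA_real_,
        log2_sd_ratio = NA_real_, status = "fit_failed"
      ))
    }
    z <- wald_z(f1, f2)
    tibble::tibble(
      gene_id = g,
      sigma_control = f1$cp$sigma, sigma_treatment = f2$cp$sigma,
      se_control = f1$se[["sigma"]], se_treatment = f2$se[["sigma"]],
      z = z, p_value = 2 * stats::pnorm(-abs(z)),
      sd_ratio = f2$cp$sigma / f1$cp$sigma,
      log2_sd_ratio = log2(f2$cp$sigma / f1$cp$sigma),
      status = "ok"
    )
  })
  res <- dplyr::bind_rows(fits)
  res$q_value <- by_adjust(res$p_value)
  res <- res[, .clrdv_result_cols]

  structure(
    res,
    class = c("clrdv_dv", class(res)),
    alpha = alpha,
    reference = design$reference,
    test = design$test,
    n_input_genes = nrow(counts),
    n_filtered = sum(flt$report$removed),
    n_tested = sum(res$status == "ok"),
    n_failed = sum(res$status == "fit_failed"),
    n_flagged = sum(res$q_value < alpha, na.rm = TRUE),
    filter_report = flt$report
  )
}

#' @export
print.clrdv_dv <- function(x, ...) {
  cat("Differential-variability test (", attr(x, "reference"), " vs ",
      attr(x, "test"), ")\n", sep = "")
  cat("genes: ", attr(x, "n_input_genes"), " input, ",
      attr(x, "n_filtered"), " filtered out, ",
      attr(x, "n_tested"), " tested, ",
      attr(x, "n_failed"), " fit failures, ",
      attr(x, "n_flagged"), " flagged at q < ", attr(x, "alpha"),
      "\n\n", sep = "")
  NextMethod()
}

#' Tidy a differential-variability result
#'
#' @param x a \code{clrdv_dv} object from [run_clrdv()].
#' @param ... unused.
#' @return the per-gene result as a plain tibble.
#' @export
tidy.clrdv_dv <- function(x, ...) {
  tibble::as_tibble(unclass(x)[.clrdv_result_cols])
}

#' One-row summary of a differential-variability run
#'
#' @param x a \code{clrdv_dv} object.
#' @param ... unused.
#' @return a one-row tibble with gene counts at each pipeline stage and
#'   the number of genes flagged at the run's alpha.
#' @export
glance.clrdv_dv <- function(x, ...) {
  tibble::tibble(
    reference = attr(x, "reference"),
    test = attr(x, "test"),
    n_input_genes = attr(x, "n_input_genes"),
    n_filtered = attr(x, "n_filtered"),
    n_tested = attr(x, "n_tested"),
    n_failed = attr(x, "n_failed"),
    n_flagged = attr(x, "n_flagged"),
    alpha = attr(x, "alpha")
  )
}

#' Volcano plot of differential variability
#'
#' log2 SD ratio (treatment over control) against \eqn{-\log_{10}} of the
#' BY-adjusted p-value, with flagged genes highlighted.
#'
#' @param object a \code{clrdv_dv} object.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.clrdv_dv <- function(object, ...) {
  alpha <- attr(object, "alpha")
  d <- tidy(object)
  d <- d[d$status == "ok", ]
  d$flagged <- d$q_value < alpha
  ggplot2::ggplot(
    d,
    ggplot2::aes(x = .data$log2_sd_ratio,
                 y = -log10(pmax(.data$q_value, 1e-300)),
                 colour = .data$flagged)
  ) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey55", `TRUE` = "firebrick"),
      name = paste0("q < ", alpha)
    ) +
    ggplot2::labs(
      x = expression(log[2] ~ "SD ratio (treatment / control)"),
      y = expression(-log[10] ~ "BY-adjusted p")
    ) +
    ggplot2::theme_minimal()
}
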