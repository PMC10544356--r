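#' Estimate NB2 parameters for one gene
#'
#' Maximum likelihood fit of the NB2 negative-binomial model with
#' variance \eqn{\mu + \phi\mu^2} (size \eqn{= 1/\phi}), via
#' \code{MASS::fitdistr}; if the likelihood fit fails (e.g. the data are
#' under-dispersed), falls back to method of moments
#' \eqn{\hat\phi = \max(0, (s^2 - \bar x)/\bar x^2)}. The dispersion is
#' floored at 1e-8 so the size parameter stays finite.
#'
#' @param gene_counts integer vector of counts, length at least 10, not
#'   all zero.
#' @return a list with \code{mu}, \code{phi} and \code{method}
#'   (\code{"mle"} or \code{"moments"}).
#' @export
estimate_nb2 <- function(gene_counts) {
  x <- as.numeric(gene_counts)
  if (length(x) < 10) stop("need at least 10 observations", call. = FALSE)
  if (all(x == 0)) stop("all counts are zero", call. = FALSE)
  if (any(x < 0) || any(x != round(x))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  xbar <- mean(x)
  s2 <- stats::var(x)
  mle <- tryCatch(
    suppressWarnings(MASS::fitdistr(x, "negative binomial")),
    error = function(e) NULL
  )
  if (!is.null(mle) && all(is.finite(mle$estimate)) &&
      mle$estimate[["size"]] > 0) {
    return(list(mu = unname(mle$estimate[["mu"]]),
                phi = max(1e-8, 1 / mle$estimate[["size"]]),
                method = "mle"))
  }
  list(mu = xbar, phi = max(1e-8, (s2 - xbar) / xbar^2),
       method = "moments")
}

#' Synthetic NB2 parameter generator
#'
#' Emits reproducible, realistic bulk-RNA-seq-like per-gene NB2
#' parameters for simulation when no seed dataset is at hand. Gene means
#' are log-normal (median 150 counts, log-sd 1.3, truncated to
#' \[2, 5e4\]), spanning roughly CPM 1-1,000 at the implied library size;
#' dispersion follows the usual decreasing mean-dispersion trend
#' \eqn{0.1 + 4/\mu} with log-normal noise (log-sd 0.35), capped at 5 and
#' floored at 1e-8. Genes drawn from these parameters pass the default
#' expression filter at typical sample sizes.
#'
#' @param G number of genes.
#' @param seed integer seed; the same \code{(G, seed)} pair always yields
#'   the same table.
#' @return a tibble with columns \code{gene_id}, \code{mu}, \code{phi}.
#' @export
synth_nb2_params <- function(G, seed) {
  stopifnot(G >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  mu <- stats::rlnorm(G, meanlog = log(150), sdlog = 1.3)
  # truncate by resampling out-of-range draws
  bad <- mu < 2 | mu > 5e4
  while (any(bad)) {
    mu[bad] <- stats::rlnorm(sum(bad), meanlog = log(150), sdlog = 1.3)
    bad <- mu < 2 | mu > 5e4
  }
  phi <- (0.1 + 4 / mu) * stats::rlnorm(G, 0, 0.35)
  phi <- pmax(1e-8, pmin(5, phi))
  tibble::tibble(
    gene_id = sprintf("gene_%05d", seq_len(G)),
    mu = mu, phi = phi
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Draw differential-variability fold factors
#'
#' Each draw picks one of the two support intervals — (0.25, 0.5) and
#' (2, 4) by default — with probability 1/2, then samples uniformly
#' within it. The fold multiplies the NB2 size parameter \eqn{1/\phi} of
#' the spiked group, i.e. \eqn{\phi' = \phi/x}: folds above 1 reduce
#' dispersion (tighter counts), folds below 1 inflate it.
#'
#' @param n number of draws.
#' @param fold_support list of two positive intervals, each excluding 1.
#' @return numeric vector of folds.
#' @export
sample_dv_fold <- function(n = 1,
                           fold_support = list(c(0.25, 0.5), c(2, 4))) {
  stopifnot(length(fold_support) == 2,
            all(vapply(fold_support, length, 1L) == 2),
            all(unlist(fold_support) > 0),
            !any(vapply(fold_support, function(iv) {
              iv[1] <= 1 && 1 <= iv[2]
            }, logical(1))))
  pick <- sample.int(2, n, replace = TRUE)
  lo <- vapply(fold_support, `[`, 0, 1)[pick]
  hi <- vapply(fold_support, `[`, 0, 2)[pick]
  stats::runif(n, lo, hi)
}

#' Simulate a two-group NB2 count experiment with DV spiking
#'
#' Both groups share per-gene NB2 parameters except for a random subset
#' of \code{floor(prop_dv * G)} genes, whose size parameter \eqn{1/\phi}
#' in the spiked group is multiplied by a fold drawn with
#' [sample_dv_fold()] — group means stay identical, so any signal is pure
#' variability. Counts are drawn independently per gene and sample.
#'
#' @param params NB2 parameter table (\code{gene_id}, \code{mu},
#'   \code{phi}), e.g. from [synth_nb2_params()].
#' @param n_per_group samples per group.
#' @param prop_dv proportion of genes spiked as differentially variable.
#' @param spiked_group which group (1 or 2) receives the spike; group 1
#'   is labeled \code{"control"}, group 2 \code{"treatment"}.
#' @param fold_support see [sample_dv_fold()].
#' @param seed optional integer seed for reproducibility.
#' @return a list with \code{counts} (genes-by-samples matrix),
#'   \code{truth} (tibble \code{gene_id}, \code{is_dv}, \code{fold},
#'   \code{spiked_group}), and \code{groups} (tibble \code{sample_id},
#'   \code{group}).
#' @export
simulate_two_groups <- function(params, n_per_group, prop_dv = 0.1,
                                spiked_group = 2,
                                fold_support = list(c(0.25, 0.5), c(2, 4)),
                                seed = NULL) {
  stopifnot(all(c("gene_id", "mu", "phi") %in% names(params)),
            n_per_group >= 1, prop_dv >= 0, prop_dv <= 1,
            spiked_group %in% 1:2)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  G <- nrow(params)
  n_dv <- floor(prop_dv * G)
  dv_idx <- sort(sample.int(G, n_dv))
  fold <- rep(1, G)
  if (n_dv > 0) fold[dv_idx] <- sample_dv_fold(n_dv, fold_support)

  phi1 <- params$phi
  phi2 <- params$phi
  if (spiked_group == 1) phi1 <- phi1 / fold else phi2 <- phi2 / fold

  draw <- function(phi) {
    matrix(
      stats::rnbinom(G * n_per_group, mu = rep(params$mu, n_per_group),
                     size = rep(1 / phi, n_per_group)),
      nrow = G
    )
  }
  counts <- cbind(draw(phi1), draw(phi2))
  rownames(counts) <- params$gene_id
  colnames(counts) <- c(sprintf("control_%03d", seq_len(n_per_group)),
                        sprintf("treatment_%03d", seq_len(n_per_group)))
  list(
    counts = counts,
    truth = tibble::tibble(
      gene_id = params$gene_id,
      is_dv = fold != 1,
      fold = fold,
      spiked_group = ifelse(fold != 1, spiked_group, NA_integer_)
    ),
    groups = tibble::tibble(
      sample_id = colnames(counts),
      group = rep(c("control", "treatment"), each = n_per_group)
    )
  )
}

#' Score DV calls against simulation truth
#'
#' @param truth truth tibble from [simulate_two_groups()] (or any table
#'   with \code{is_dv}), aligned with \code{called}.
#' @param called logical vector of DV calls, one per truth row.
#' @return a one-row tibble with \code{tp}, \code{fp}, \code{tn},
#'   \code{fn}, \code{fdr} (\code{FP/(FP+TP)}, 0 when nothing is called)
#'   and \code{type2} (\code{FN} over the number of true DV genes).
#' @export
score_calls <- function(truth, called) {
  if (nrow(truth) != length(called)) {
    stop("truth and calls have different lengths", call. = FALSE)
  }
  is_dv <- truth$is_dv
  tp <- sum(called & is_dv)
  fp <- sum(called & !is_dv)
  tn <- sum(!called & !is_dv)
  fn <- sum(!called & is_dv)
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    fdr = if (tp + fp == 0) 0 else fp / (fp + tp),
    type2 = if (tp + fn == 0) 0 else fn / (tp + fn)
  )
}

#' Benchmark the DV test on simulated NB2 data
#'
#' Chains [synth_nb2_params()] (or a supplied parameter table),
#' [simulate_two_groups()], [run_clrdv()] and [score_calls()] over
#' repeated simulation instances, re-applying the standard expression
#' filter before testing. Scoring is restricted to genes actually tested
#' (passing the filter with successful fits in both groups).
#'
#' @param G number of genes (ignored when \code{params} is given).
#' @param n_per_group samples per group.
#' @param prop_dv proportion of DV genes.
#' @param n_instances number of independent simulation instances.
#' @param seed integer seed controlling parameters and all instances.
#' @param alpha BY-adjusted significance threshold for calling a gene.
#' @param params optional NB2 parameter table replacing the synthetic
#'   generator.
#' @param fold_support see [sample_dv_fold()].
#' @return a tibble with one row per instance: \code{instance},
#'   \code{n_tested}, \code{n_called}, \code{fdr}, \code{type2}.
#' @export
clrdv_benchmark <- function(G = 2000, n_per_group = 100, prop_dv = 0.1,
                            n_instances = 5, seed = 1, alpha = 0.05,
                            params = NULL,
                            fold_support = list(c(0.25, 0.5), c(2, 4))) {
  if (is.null(params)) params <- synth_nb2_params(G, seed)
  purrr::map_dfr(seq_len(n_instances), function(i) {
    sim <- simulate_two_groups(params, n_per_group, prop_dv,
                               fold_support = fold_support,
                               seed = seed + i)
    res <- suppressWarnings(
      run_clrdv(sim$counts, sim$groups, reference = "control",
                alpha = alpha)
    )
    tested <- tidy(res)
    tested <- tested[tested$status == "ok", ]
    truth <- sim$truth[match(tested$gene_id, sim$truth$gene_id), ]
    sc <- score_calls(truth, tested$q_value < alpha)
    tibble::tibble(
      instance = i,
      n_tested = nrow(tested),
      n_called = sc$tp + sc$fp,
      fdr = sc$fdr,
      type2 = sc$type2
    )
  })
}
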