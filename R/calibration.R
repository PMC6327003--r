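#' Fisher homogeneity test of the pooled mating table
#'
#' The order-blind comparison baseline: a two-sided Fisher exact test of
#' independence on the pooled 2 x 2 female-class by male-class table of an
#' assay. Pooling across replicates matches how a homogeneity test would be
#' applied to counts in practice.
#'
#' @param x a [mating_tally()], [assay_dataset()], or 2 x 2 count matrix.
#' @return The two-sided p-value (scalar).
#' @examples
#' fisher_homogeneity_test(matrix(c(20L, 10L, 10L, 20L), 2, 2))
#' @export
fisher_homogeneity_test <- function(x) {
  m <- as_tally_matrix(x)
  if (sum(m) == 0L)
    stop("Fisher test undefined on an all-zero table", call. = FALSE)
  stats::fisher.test(m)$p.value
}

mc_se <- function(p, n) sqrt(pmax(p * (1 - p), 0) / n)

run_simulation_batch <- function(design, params, n_sims, n_replicates,
                                 alpha, fit_args = list()) {
  h_hat <- numeric(n_sims)
  lrt_p <- numeric(n_sims)
  fisher_p <- numeric(n_sims)
  sii <- numeric(n_sims)
  conv <- logical(n_sims)
  for (i in seq_len(n_sims)) {
    ds <- simulate_assay(design, params, n_replicates = n_replicates)
    fit <- do.call(esii, c(list(ds), fit_args))
    h_hat[i] <- fit$h_hat
    lrt_p[i] <- fit$p_value
    conv[i] <- fit$converged
    fisher_p[i] <- fisher_homogeneity_test(ds)
    sii[i] <- naive_sii(ds)$value
  }
  list(h_hat = h_hat, lrt_p = lrt_p, fisher_p = fisher_p, naive = sii,
       converged = conv,
       # reject at p <= alpha: exact tests have discrete p-values that can
       # equal the level (or 1), where a strict inequality would under-reject
       lrt_reject = mean(lrt_p <= alpha),
       fisher_reject = mean(fisher_p <= alpha))
}

#' Type-I error of the LRT and Fisher test under random mating
#'
#' Simulates assays at `h = 0` (no order bias) and reports the fraction
#' rejected at level `alpha` by the model's likelihood-ratio test and by the
#' Fisher homogeneity test, with Monte-Carlo standard errors. A calibrated
#' LRT should reject close to the nominal rate.
#'
#' @param design an [assay_design()]; also the assumed rates for fitting.
#' @param n_sims number of simulated assays (default 1000).
#' @param n_replicates replicates per assay (default 5).
#' @param alpha nominal level (default 0.05).
#' @param seed integer seed.
#' @return A one-row data frame: rejection rates, their Monte-Carlo SEs,
#'   mean and SD of the estimated eSII, `n_sims`, `seed`.
#' @export
type1_error_study <- function(design = assay_design(), n_sims = 1000L,
                              n_replicates = 5L, alpha = 0.05, seed = 1L) {
  res <- with_seed(seed,
    run_simulation_batch(design, model_params(h = 0), n_sims, n_replicates,
                         alpha))
  data.frame(alpha = alpha,
             lrt_rate = res$lrt_reject,
             lrt_se = mc_se(res$lrt_reject, n_sims),
             fisher_rate = res$fisher_reject,
             fisher_se = mc_se(res$fisher_reject, n_sims),
             mean_h_hat = mean(res$h_hat), sd_h_hat = stats::sd(res$h_hat),
             n_sims = n_sims, seed = seed)
}

#' Power of the LRT and Fisher test along a grid of true eSII values
#'
#' For each true `h` in `h_grid`, simulates assays (no order bias), fits the
#' model, and reports the rejection rate of the LRT and of the Fisher
#' homogeneity test at level `alpha`, plus the mean and SD of the estimated
#' eSII and of the naive index. The `h = 0` row is the type-I error.
#'
#' @param h_grid numeric vector of true coefficients in (-1, 1).
#' @inheritParams type1_error_study
#' @param n_sims simulated assays per grid point (default 500).
#' @return A data frame of class `esii_power`, one row per grid value.
#' @export
power_curve <- function(h_grid, design = assay_design(), n_sims = 500L,
                        n_replicates = 5L, alpha = 0.05, seed = 1L) {
  stopifnot(all(h_grid > -1 & h_grid < 1))
  rows <- with_seed(seed, lapply(h_grid, function(h) {
    res <- run_simulation_batch(design, model_params(h = h), n_sims,
                                n_replicates, alpha)
    data.frame(h = h,
               lrt_power = res$lrt_reject,
               lrt_se = mc_se(res$lrt_reject, n_sims),
               fisher_power = res$fisher_reject,
               fisher_se = mc_se(res$fisher_reject, n_sims),
               mean_h_hat = mean(res$h_hat), sd_h_hat = stats::sd(res$h_hat),
               mean_naive_sii = mean(res$naive),
               n_sims = n_sims)
  }))
  out <- do.call(rbind, rows)
  out$alpha <- alpha
  out$seed <- seed
  class(out) <- c("esii_power", class(out))
  out
}

#' @export
plot.esii_power <- function(x, ...) {
  ord <- order(x$h)
  graphics::matplot(x$h[ord], cbind(x$lrt_power, x$fisher_power)[ord, ],
                    type = "b", pch = c(19, 1), lty = c(1, 2),
                    col = c("black", "grey40"), xlab = "true eSII (h)",
                    ylab = sprintf("power at alpha = %.2g", x$alpha[1]),
                    ylim = c(0, 1), ...)
  graphics::legend("bottomright", c("LRT (sequential model)", "Fisher"),
                   pch = c(19, 1), lty = c(1, 2), col = c("black", "grey40"),
                   bty = "n")
  invisible(x)
}

#' Correction of spurious isolation signals caused by mating-order bias
#'
#' Simulates assays with random mating (`h = 0`) but a shared per-class
#' mating-order bias (class-A females and males both mate earlier by a factor
#' `b`). Early matings are then enriched for A x A pairs and late ones for
#' B x B pairs, so the naive SII is inflated above 0 even though mating is
#' random; the sequential model, which estimates the biases jointly with
#' `h`, should recover an eSII near 0.
#'
#' @param bias_grid positive bias multipliers `b` applied to both sexes.
#' @inheritParams type1_error_study
#' @param n_sims simulated assays per bias value (default 500).
#' @return A data frame, one row per bias value, with the mean naive SII
#'   (the spurious signal), mean and SD of the corrected eSII, and the LRT
#'   rejection rate at `alpha`.
#' @export
bias_correction_study <- function(bias_grid, design = assay_design(),
                                  n_sims = 500L, n_replicates = 5L,
                                  alpha = 0.05, seed = 1L) {
  stopifnot(all(bias_grid > 0))
  rows <- with_seed(seed, lapply(bias_grid, function(b) {
    res <- run_simulation_batch(
      design, model_params(h = 0, b_female = b, b_male = b),
      n_sims, n_replicates, alpha)
    data.frame(bias = b,
               mean_naive_sii = mean(res$naive),
               se_naive_sii = stats::sd(res$naive) / sqrt(n_sims),
               mean_h_hat = mean(res$h_hat),
               se_h_hat = stats::sd(res$h_hat) / sqrt(n_sims),
               lrt_rate = res$lrt_reject,
               n_sims = n_sims)
  }))
  out <- do.call(rbind, rows)
  out$alpha <- alpha
  out$seed <- seed
  out
}
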