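#' The classical (naive) Sexual Isolation Index
#'
#' Computes the order-blind isolation index of Malogolowkin-Cohen and
#' colleagues, `SII = (nho - nhe) / N`, where `nho` counts homogamic matings
#' (female and male of the same class), `nhe` heterogamic matings, and `N`
#' their total. The index runs from -1 (complete preference for unlikes)
#' through 0 (random mating) to +1 (complete preference for likes). In
#' finite-partner assays it is biased by mating-order effects; [esii()]
#' provides the order-corrected estimate.
#'
#' @param x a [mating_tally()], an [assay_dataset()], or a 2 x 2 count matrix.
#' @param by for datasets: `"pooled"` (default; one index over summed counts)
#'   or `"replicate"` (one index per replicate).
#' @param ... passed between methods.
#' @return An object of class `naive_sii` with elements `value`, `nho`,
#'   `nhe`, `N` — or a data frame of per-replicate indices when
#'   `by = "replicate"`.
#' @examples
#' tal <- matrix(c(10L, 2L, 2L, 10L), 2, 2)
#' naive_sii(tal)
#' @export
naive_sii <- function(x, ...) UseMethod("naive_sii")

#' @rdname naive_sii
#' @export
naive_sii.default <- function(x, ...) {
  m <- as_tally_matrix(x)
  if (any(m < 0)) stop("mating counts must be non-negative", call. = FALSE)
  nho <- sum(diag(m))
  nhe <- sum(m) - nho
  N <- nho + nhe
  if (N == 0L)
    stop("the Sexual Isolation Index is undefined for zero matings",
         call. = FALSE)
  structure(list(value = (nho - nhe) / N, nho = nho, nhe = nhe, N = N),
            class = "naive_sii")
}

#' @rdname naive_sii
#' @export
naive_sii.assay_dataset <- function(x, by = c("pooled", "replicate"), ...) {
  by <- match.arg(by)
  if (by == "pooled") return(naive_sii(mating_tally(x)))
  tabs <- mating_tally(x, by = "replicate")
  out <- do.call(rbind, lapply(names(tabs), function(r) {
    s <- naive_sii(tabs[[r]])
    data.frame(replicate = r, sii = s$value, nho = s$nho, nhe = s$nhe,
               N = s$N, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.naive_sii <- function(x, ...) {
  cat(sprintf("naive SII = %.4f  (homogamic %d, heterogamic %d, N = %d)\n",
              x$value, x$nho, x$nhe, x$N))
  invisible(x)
}
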