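#' Tally matings into a 2 x 2 female-class by male-class table
#'
#' Collapses ordered mating events into the classical contingency table of
#' counts by (female class, male class). The diagonal holds homogamic
#' matings, the off-diagonal heterogamic ones. Tallying is order-blind and
#' additive over replicates.
#'
#' @param x an [assay_dataset()], or a data frame of events with
#'   `female_class` and `male_class` columns.
#' @param design required when `x` is a bare data frame, to fix the label
#'   order of the table.
#' @param by `"pooled"` (one table over all events) or `"replicate"` (a named
#'   list of per-replicate tables).
#' @param ... passed between methods.
#' @return An integer matrix of class `mating_tally` (rows = female class,
#'   columns = male class), or a list of them when `by = "replicate"`.
#' @examples
#' d <- assay_design(c("A", "B"), n_females = 2, n_males = 2)
#' ev <- data.frame(replicate = 1, order = 1:4,
#'                  female_class = c("A", "A", "B", "B"),
#'                  male_class = c("A", "B", "A", "B"))
#' mating_tally(assay_dataset(ev, d))
#' @export
mating_tally <- function(x, ...) UseMethod("mating_tally")

#' @rdname mating_tally
#' @export
mating_tally.assay_dataset <- function(x, by = c("pooled", "replicate"), ...) {
  by <- match.arg(by)
  if (by == "pooled")
    return(mating_tally.data.frame(x$events, design = x$design))
  reps <- split(x$events, x$events$replicate)
  lapply(reps, mating_tally.data.frame, design = x$design)
}

#' @rdname mating_tally
#' @export
mating_tally.data.frame <- function(x, design, ...) {
  stopifnot(inherits(design, "assay_design"))
  tab <- table(female = factor(x$female_class, levels = design$labels),
               male = factor(x$male_class, levels = design$labels))
  m <- matrix(as.integer(tab), 2L, 2L,
              dimnames = list(female = design$labels, male = design$labels))
  class(m) <- c("mating_tally", class(m))
  m
}

#' @export
print.mating_tally <- function(x, ...) {
  cat("Mating tally (female class x male class)\n")
  print(unclass(x))
  cat(sprintf("homogamic %d, heterogamic %d, N = %d\n",
              sum(diag(unclass(x))), sum(x) - sum(diag(unclass(x))), sum(x)))
  invisible(x)
}

as_tally_matrix <- function(x, design = NULL) {
  if (inherits(x, "mating_tally")) return(unclass(x))
  if (inherits(x, "assay_dataset")) return(unclass(mating_tally(x)))
  if (is.matrix(x) && all(dim(x) == 2L)) {
    storage.mode(x) <- "integer"
    return(x)
  }
  stop("expected a mating_tally, assay_dataset, or 2x2 matrix", call. = FALSE)
}
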