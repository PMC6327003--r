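#' Describe the layout of a multiple-choice mating assay
#'
#' An assay places two classes of flies (semispecies, treatment groups, ...)
#' of both sexes together in one chamber and records copulations in sequence.
#' The design fixes the class labels, how many females and males of each
#' class enter the chamber, and the remating rates assumed by the
#' likelihood: the weight with which an already-mated individual re-enters
#' the pool of available partners.
#'
#' The defaults mirror the classical layout: 12 females and 12 males per
#' class (24 matings per replicate when observed to exhaustion), a male
#' remating rate of 0.5, and a near-zero female remating rate of 0.001 that
#' acts purely as a numerical smoother in the likelihood (females are never
#' allowed to remate in simulated data).
#'
#' @param labels character vector of exactly two class labels. The first
#'   label plays the role of "class A" for the order-bias parameters.
#' @param n_females,n_males number of flies per class and sex (>= 1).
#' @param r_male,r_female remating rates in \[0, 1\].
#' @return An object of class `assay_design`.
#' @examples
#' assay_design(c("wt", "kd"))
#' @export
assay_design <- function(labels = c("A", "B"), n_females = 12L,
                         n_males = 12L, r_male = 0.5, r_female = 0.001) {
  labels <- as.character(labels)
  if (length(labels) != 2L || anyDuplicated(labels) || any(!nzchar(labels)))
    stop("`labels` must be two distinct non-empty class labels", call. = FALSE)
  n_females <- as.integer(n_females)
  n_males <- as.integer(n_males)
  if (is.na(n_females) || n_females < 1L || is.na(n_males) || n_males < 1L)
    stop("`n_females` and `n_males` must be integers >= 1", call. = FALSE)
  for (r in list(r_male = r_male, r_female = r_female)) {
    if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0 || r > 1)
      stop("remating rates must be single numbers in [0, 1]", call. = FALSE)
  }
  structure(
    list(labels = labels, n_females = n_females, n_males = n_males,
         r_male = r_male, r_female = r_female),
    class = "assay_design"
  )
}

#' @export
print.assay_design <- function(x, ...) {
  cat("Multiple-choice assay design\n")
  cat(sprintf("  classes: %s (class A) vs %s\n", x$labels[1], x$labels[2]))
  cat(sprintf("  per class: %d females, %d males\n", x$n_females, x$n_males))
  cat(sprintf("  remating rates: male %.3g, female %.3g\n",
              x$r_male, x$r_female))
  invisible(x)
}

#' Model parameters of the sequential mate-choice model
#'
#' Bundles the assortative-mating coefficient `h` (the eSII) with the two
#' mating-order bias multipliers. A homogamic pair carries base weight
#' (1 + h)/2 and a heterogamic pair (1 - h)/2; the weight is further
#' multiplied by `b_female` when the female belongs to class A (the first
#' design label) and by `b_male` when the male does. `h = 0` with unit
#' biases is random mating.
#'
#' @param h assortative-mating coefficient in (-1, 1); the closed endpoints
#'   are accepted for limit-case evaluation (complete isolation/heterogamy).
#' @param b_female,b_male positive order-bias multipliers for class-A
#'   females and males.
#' @return An object of class `model_params`.
#' @examples
#' model_params(h = 0.6)
#' @export
model_params <- function(h = 0, b_female = 1, b_male = 1) {
  if (!is.numeric(h) || length(h) != 1L || is.na(h) || h < -1 || h > 1)
    stop("`h` must be a single number in [-1, 1]", call. = FALSE)
  if (!is.numeric(b_female) || b_female <= 0 || !is.numeric(b_male) ||
      b_male <= 0)
    stop("bias multipliers must be positive", call. = FALSE)
  structure(list(h = h, b_female = b_female, b_male = b_male),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("mate-choice parameters: h = %.4g, b_female = %.4g, b_male = %.4g\n",
              x$h, x$b_female, x$b_male))
  invisible(x)
}

as_model_params <- function(params) {
  if (inherits(params, "model_params")) return(params)
  if (is.list(params) && all(c("h", "b_female", "b_male") %in% names(params)))
    return(model_params(params$h, params$b_female, params$b_male))
  stop("`params` must be a model_params object", call. = FALSE)
}
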