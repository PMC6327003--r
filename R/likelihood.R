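#' Effective availability of partners during an assay
#'
#' As an assay proceeds, each copulation removes its female and male from the
#' pool of fresh partners. A mated individual of class `c` re-enters the pool
#' down-weighted by the remating rate of its sex, giving the effective
#' availability `max(N_c - k_c, 0) + r * min(k_c, N_c)` where `k_c` counts
#' matings so far by that sex-class. With `r = 0` this is sampling without
#' replacement; with `r = 1` the pool never depletes.
#'
#' @param design an [assay_design()] (provides initial counts and rates).
#' @param female_mated,male_mated length-2 counts of matings so far by each
#'   class (ordered as `design$labels`).
#' @return An object of class `availability_state` with per-sex-per-class
#'   effective availabilities.
#' @examples
#' availability_state(assay_design(), female_mated = c(3, 0))
#' @export
availability_state <- function(design, female_mated = c(0L, 0L),
                               male_mated = c(0L, 0L)) {
  stopifnot(inherits(design, "assay_design"),
            length(female_mated) == 2L, length(male_mated) == 2L,
            all(female_mated >= 0), all(male_mated >= 0))
  fa <- effective_avail(design$n_females, female_mated, design$r_female)
  ma <- effective_avail(design$n_males, male_mated, design$r_male)
  structure(
    list(design = design,
         female_mated = as.numeric(female_mated),
         male_mated = as.numeric(male_mated),
         avail_female = stats::setNames(fa, design$labels),
         avail_male = stats::setNames(ma, design$labels)),
    class = "availability_state"
  )
}

effective_avail <- function(n, k, r) {
  pmax(n - k, 0) + r * pmin(k, n)
}

#' @export
print.availability_state <- function(x, ...) {
  cat("Effective availabilities\n")
  print(rbind(female = x$avail_female, male = x$avail_male))
  invisible(x)
}

#' Relative weight of one pair type
#'
#' The sequential model weights a homogamic pair (same class) by
#' `(1 + h) / 2` and a heterogamic pair by `(1 - h) / 2`; the weight is then
#' multiplied by `b_female` when the female is class A (first design label)
#' and by `b_male` when the male is. `h = 0` with unit biases gives every
#' pair weight 1/2 (random mating); `h = 1` annihilates heterogamic pairs.
#'
#' @param female_class,male_class class labels.
#' @param params a [model_params()].
#' @param design an [assay_design()] fixing which label is class A.
#' @return A non-negative scalar weight.
#' @examples
#' d <- assay_design(c("A", "B"))
#' pair_weight("A", "A", model_params(h = 0.5, b_female = 2), d)  # 1.5
#' @export
pair_weight <- function(female_class, male_class, params, design) {
  params <- as_model_params(params)
  stopifnot(inherits(design, "assay_design"),
            female_class %in% design$labels, male_class %in% design$labels)
  w <- if (identical(female_class, male_class)) (1 + params$h) / 2
       else (1 - params$h) / 2
  if (female_class == design$labels[1]) w <- w * params$b_female
  if (male_class == design$labels[1]) w <- w * params$b_male
  w
}

#' Conditional distribution of the next mating pair
#'
#' Given the current availabilities, the probability that the next observed
#' copulation is of pair type (f, m) is proportional to
#' `avail_female(f) * avail_male(m) * pair_weight(f, m)`. Pair types whose
#' availability product is zero have probability zero.
#'
#' @param state an [availability_state()].
#' @param params a [model_params()].
#' @return Named probability vector over the four pair types, named
#'   `"<female class>:<male class>"`, summing to 1.
#' @examples
#' st <- availability_state(assay_design())
#' step_probabilities(st, model_params())  # 0.25 each
#' @export
step_probabilities <- function(state, params) {
  stopifnot(inherits(state, "availability_state"))
  params <- as_model_params(params)
  d <- state$design
  lab <- d$labels
  w <- numeric(4L)
  i <- 0L
  nm <- character(4L)
  for (f in lab) for (m in lab) {
    i <- i + 1L
    w[i] <- state$avail_female[f] * state$avail_male[m] *
      pair_weight(f, m, params, d)
    nm[i] <- paste(f, m, sep = ":")
  }
  total <- sum(w)
  if (total <= 0)
    stop("assay exhausted: no pair type has positive availability weight",
         call. = FALSE)
  stats::setNames(w / total, nm)
}

## ------------------------------------------------------------------
## Vectorized likelihood machinery.
##
## Availabilities at each step depend only on the observed sequence and the
## fixed remating rates, never on (h, b_female, b_male). They are therefore
## precomputed once per dataset; each likelihood evaluation is then a handful
## of vector operations, and the gradient is analytic.
## ------------------------------------------------------------------

prepare_replicate <- function(events, design, r_male, r_female) {
  A <- design$labels[1]
  f <- events$female_class == A   # female is class A
  m <- events$male_class == A     # male is class A
  K <- nrow(events)
  before <- function(x) c(0, cumsum(x))[seq_len(K)]
  aFA <- effective_avail(design$n_females, before(f), r_female)
  aFB <- effective_avail(design$n_females, before(!f), r_female)
  aMA <- effective_avail(design$n_males, before(m), r_male)
  aMB <- effective_avail(design$n_males, before(!m), r_male)
  n_obs <- ifelse(f, aFA, aFB) * ifelse(m, aMA, aMB)
  list(nAA = aFA * aMA, nAB = aFA * aMB, nBA = aFB * aMA, nBB = aFB * aMB,
       s = ifelse(f == m, 1, -1), fA = as.numeric(f), mA = as.numeric(m),
       log_nobs = log(n_obs), impossible = any(n_obs <= 0))
}

prepare_dataset <- function(dataset, r_male, r_female) {
  ev <- dataset$events
  parts <- lapply(split(ev, ev$replicate), prepare_replicate,
                  design = dataset$design, r_male = r_male,
                  r_female = r_female)
  out <- list()
  for (fld in c("nAA", "nAB", "nBA", "nBB", "s", "fA", "mA", "log_nobs"))
    out[[fld]] <- unlist(lapply(parts, `[[`, fld), use.names = FALSE)
  out$impossible <- any(vapply(parts, `[[`, logical(1), "impossible"))
  out$n <- length(out$s)
  out
}

## theta = (h, log b_female, log b_male)
loglik_theta <- function(theta, prep) {
  if (prep$n == 0L) return(0)
  if (prep$impossible) return(-Inf)
  h <- theta[1]; u <- theta[2]; v <- theta[3]
  wAA <- (1 + h) / 2 * exp(u + v)
  wAB <- (1 - h) / 2 * exp(u)
  wBA <- (1 - h) / 2 * exp(v)
  wBB <- (1 + h) / 2
  D <- prep$nAA * wAA + prep$nAB * wAB + prep$nBA * wBA + prep$nBB * wBB
  logw <- log((1 + prep$s * h) / 2) + prep$fA * u + prep$mA * v
  sum(prep$log_nobs + logw - log(D))
}

grad_theta <- function(theta, prep) {
  h <- theta[1]; u <- theta[2]; v <- theta[3]
  wAA <- (1 + h) / 2 * exp(u + v)
  wAB <- (1 - h) / 2 * exp(u)
  wBA <- (1 - h) / 2 * exp(v)
  wBB <- (1 + h) / 2
  tAA <- prep$nAA * wAA; tAB <- prep$nAB * wAB
  tBA <- prep$nBA * wBA; tBB <- prep$nBB * wBB
  D <- tAA + tAB + tBA + tBB
  dh <- sum(prep$s / (1 + prep$s * h) -
              ((tAA + tBB) / (1 + h) - (tAB + tBA) / (1 - h)) / D)
  du <- sum(prep$fA - (tAA + tAB) / D)
  dv <- sum(prep$mA - (tAA + tBA) / D)
  c(dh, du, dv)
}

#' Log-likelihood of one replicate's mating sequence
#'
#' Walks the observed events in order; each contributes the log of its
#' conditional step probability (see [step_probabilities()]), after which the
#' mated female and male are booked into the availability state. An event
#' that is impossible under the parameters (probability zero, e.g. a
#' heterogamic mating at `h = 1`) yields `-Inf` rather than an error.
#'
#' @param events data frame of one replicate's events (columns
#'   `female_class`, `male_class`, ordered), or an [assay_dataset()] with a
#'   single replicate.
#' @param design an [assay_design()]; its remating rates are used.
#' @param params a [model_params()].
#' @return The log-likelihood (scalar, possibly `-Inf`).
#' @export
sequence_loglik <- function(events, design, params) {
  if (inherits(events, "assay_dataset")) {
    design <- events$design
    events <- events$events
  }
  stopifnot(inherits(design, "assay_design"))
  params <- as_model_params(params)
  prep <- prepare_replicate(events, design, design$r_male, design$r_female)
  ll <- loglik_theta(c(params$h, log(params$b_female), log(params$b_male)),
                     c(prep, n = nrow(events)))
  if (is.nan(ll)) -Inf else ll
}

#' Log-likelihood of a whole assay dataset
#'
#' Replicate chambers are independent and share one parameter set; each
#' replicate starts from a fresh availability state, and the dataset
#' log-likelihood is the sum over replicates of [sequence_loglik()].
#'
#' @param dataset an [assay_dataset()].
#' @param params a [model_params()].
#' @param r_male,r_female optional overrides of the design's remating rates.
#' @return The log-likelihood (scalar, possibly `-Inf`).
#' @export
dataset_loglik <- function(dataset, params, r_male = NULL, r_female = NULL) {
  stopifnot(inherits(dataset, "assay_dataset"))
  params <- as_model_params(params)
  prep <- prepare_dataset(dataset,
                          r_male %||% dataset$design$r_male,
                          r_female %||% dataset$design$r_female)
  ll <- loglik_theta(c(params$h, log(params$b_female), log(params$b_male)),
                     prep)
  if (is.nan(ll)) -Inf else ll
}
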