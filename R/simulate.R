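get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  expr
}

#' Simulate one replicate's mating sequence
#'
#' Draws copulations one at a time from the sequential model: at each step
#' the next pair type is sampled with probability proportional to
#' `avail_female(f) * avail_male(m) * pair_weight(f, m)`, after which the
#' availabilities are updated. Males re-enter the pool down-weighted by the
#' design's male remating rate; females are removed outright (realized
#' female remating is excluded), so the chamber is exhausted after exactly
#' `2 * n_females` events — every female mates once, emulating assays
#' observed until all flies have copulated.
#'
#' @param design an [assay_design()]; `design$r_male` is the true male
#'   remating rate of the simulation.
#' @param params true [model_params()].
#' @param replicate_id identifier stored in the `replicate` column.
#' @param seed optional integer seed (the caller's RNG state is restored).
#' @return A data frame of events (`replicate`, `order`, `female_class`,
#'   `male_class`) that validates against `design`.
#' @examples
#' simulate_sequence(assay_design(), model_params(h = 1), seed = 1)
#' @export
simulate_sequence <- function(design, params = model_params(),
                              replicate_id = "1", seed = NULL) {
  stopifnot(inherits(design, "assay_design"))
  params <- as_model_params(params)
  with_seed(seed, {
    lab <- design$labels
    # pair types indexed AA, AB, BA, BB (female class then male class)
    w_pair <- c((1 + params$h) / 2 * params$b_female * params$b_male,
                (1 - params$h) / 2 * params$b_female,
                (1 - params$h) / 2 * params$b_male,
                (1 + params$h) / 2)
    kF <- c(0, 0)  # matings so far by female class A, B
    kM <- c(0, 0)
    K <- 2L * design$n_females
    f_idx <- integer(K)
    m_idx <- integer(K)
    for (t in seq_len(K)) {
      aF <- pmax(design$n_females - kF, 0)          # females never remate
      aM <- effective_avail(design$n_males, kM, design$r_male)
      w <- c(aF[1] * aM[1], aF[1] * aM[2], aF[2] * aM[1], aF[2] * aM[2]) *
        w_pair
      type <- sample.int(4L, 1L, prob = w)
      f_idx[t] <- if (type <= 2L) 1L else 2L
      m_idx[t] <- if (type %in% c(1L, 3L)) 1L else 2L
      kF[f_idx[t]] <- kF[f_idx[t]] + 1
      kM[m_idx[t]] <- kM[m_idx[t]] + 1
    }
    data.frame(replicate = rep(as.character(replicate_id), K),
               order = seq_len(K),
               female_class = lab[f_idx], male_class = lab[m_idx],
               stringsAsFactors = FALSE)
  })
}

#' Simulate a complete multiple-choice assay
#'
#' Generates `n_replicates` independent replicate chambers under one design
#' and parameter set. With the standard design (12 + 12 females, 5
#' replicates) an assay comprises 120 mating events from 240 flies.
#'
#' @inheritParams simulate_sequence
#' @param n_replicates number of replicate chambers (default 5).
#' @param assay_id identifier for the resulting dataset.
#' @param seed optional integer seed; the same seed reproduces the dataset
#'   exactly.
#' @return A validated [assay_dataset()].
#' @examples
#' sim <- simulate_assay(assay_design(), model_params(h = 0.5), seed = 42)
#' n_events(sim)  # 120
#' @export
simulate_assay <- function(design, params = model_params(),
                           n_replicates = 5L, assay_id = "sim",
                           seed = NULL) {
  stopifnot(inherits(design, "assay_design"), n_replicates >= 0)
  with_seed(seed, {
    reps <- lapply(seq_len(n_replicates), function(i)
      simulate_sequence(design, params, replicate_id = as.character(i)))
    ev <- if (length(reps)) do.call(rbind, reps) else
      data.frame(replicate = character(), order = integer(),
                 female_class = character(), male_class = character(),
                 stringsAsFactors = FALSE)
    assay_dataset(ev, design, assay_id = assay_id)
  })
}

#' Simulate a grid of scenarios reproducibly
#'
#' Runs [simulate_assay()] for every scenario in a list, deriving one
#' sub-seed per scenario from a single master seed before any simulation
#' starts, so the output is identical regardless of evaluation order.
#'
#' @param scenarios list of scenario lists; each may contain `design`,
#'   `params`, `n_replicates`, `assay_id` (defaults: standard design, random
#'   mating, 5 replicates).
#' @param master_seed integer master seed.
#' @return A list of elements `list(scenario =, seed =, dataset =)`, one per
#'   scenario, in input order.
#' @export
simulate_scenarios <- function(scenarios, master_seed = 1L) {
  stopifnot(is.list(scenarios))
  if (!length(scenarios)) return(list())
  seeds <- with_seed(master_seed,
                     sample.int(.Machine$integer.max - 1L, length(scenarios)))
  lapply(seq_along(scenarios), function(i) {
    sc <- scenarios[[i]]
    ds <- simulate_assay(sc$design %||% assay_design(),
                         sc$params %||% model_params(),
                         n_replicates = sc$n_replicates %||% 5L,
                         assay_id = sc$assay_id %||% paste0("scenario", i),
                         seed = seeds[i])
    list(scenario = sc, seed = seeds[i], dataset = ds)
  })
}
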