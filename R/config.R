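#' Read a run configuration file
#'
#' A configuration is a JSON object that can hold the assay-design fields
#' (`labels`, `n_females`, `n_males`, `r_male`, `r_female`), a master `seed`,
#' an `alpha` level, an `r_male_grid`, and simulation scenario settings
#' (`n_replicates`, `h_grid`, `bias_grid`, `n_sims`). Missing fields fall
#' back to the standard design defaults. Used by the bundled command-line
#' script; programmatic users can call the functions directly.
#'
#' @param path path to a JSON file.
#' @return A list with elements `design` (an [assay_design()]) plus the
#'   remaining scalar/vector settings.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  design <- assay_design(
    labels = cfg$labels %||% c("A", "B"),
    n_females = cfg$n_females %||% 12L,
    n_males = cfg$n_males %||% 12L,
    r_male = cfg$r_male %||% 0.5,
    r_female = cfg$r_female %||% 0.001)
  list(design = design,
       seed = as.integer(cfg$seed %||% 1L),
       alpha = cfg$alpha %||% 0.05,
       n_replicates = as.integer(cfg$n_replicates %||% 5L),
       n_sims = as.integer(cfg$n_sims %||% 500L),
       h = cfg$h %||% 0,
       h_grid = cfg$h_grid %||% c(0, 0.3, 0.6, 0.9),
       bias_grid = cfg$bias_grid %||% c(1, 3),
       r_male_grid = cfg$r_male_grid %||% c(0, 0.25, 0.5, 0.75, 1))
}
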