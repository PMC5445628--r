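#' Configuration for the synthetic expression generator
#'
#' The generator emulates the statistical structure the profiling method
#' assumes: per-gene Gaussian control baselines, and a planted disease
#' module of which each case perturbs its own random subset, on top of a
#' floor of private background perturbations shared by cases and controls
#' alike. Defaults describe a moderately heterogeneous disease: 5000 genes,
#' 25 controls, 40 cases, a 200-gene module of which each case perturbs
#' half, 100 private background perturbations per subject, and 4-sd effect
#' sizes.
#'
#' @param n_genes Universe size G.
#' @param n_controls,n_cases Group sizes.
#' @param module_size Number of genes in the planted disease module (M).
#' @param case_module_fraction Fraction f of module genes each case
#'   perturbs, drawn independently per case, in (0, 1\].
#' @param background_peep_size Number b of private non-module perturbations
#'   per subject (cases and controls).
#' @param effect_size Shift delta applied to perturbed genes, in units of
#'   that gene's control sd (>= 0).
#' @param direction_mode `"consistent"`: each module gene has one fixed
#'   perturbation direction shared by all cases; `"mixed"`: direction drawn
#'   per case and gene. Background perturbations always have random signs.
#' @param baseline_mean_range,baseline_sd_range Ranges for the per-gene
#'   baseline mean and sd (log2-intensity scale).
#' @param seed Integer seed.
#' @return Object of class `sim_config`.
#' @export
simulation_config <- function(n_genes = 5000, n_controls = 25, n_cases = 40,
                              module_size = 200, case_module_fraction = 0.5,
                              background_peep_size = 100, effect_size = 4,
                              direction_mode = c("consistent", "mixed"),
                              baseline_mean_range = c(4, 12),
                              baseline_sd_range = c(0.25, 1),
                              seed = 1) {
  direction_mode <- match.arg(direction_mode)
  stopifnot(n_genes >= 1, n_controls >= 2, n_cases >= 1,
            module_size >= 1, module_size <= n_genes,
            case_module_fraction > 0, case_module_fraction <= 1,
            background_peep_size >= 0,
            background_peep_size <= n_genes - module_size,
            effect_size >= 0,
            diff(baseline_mean_range) >= 0, baseline_sd_range[1] > 0)
  structure(list(n_genes = n_genes, n_controls = n_controls,
                 n_cases = n_cases, module_size = module_size,
                 case_module_fraction = case_module_fraction,
                 background_peep_size = background_peep_size,
                 effect_size = effect_size, direction_mode = direction_mode,
                 baseline_mean_range = baseline_mean_range,
                 baseline_sd_range = baseline_sd_range, seed = seed),
            class = "sim_config")
}

#' Simulate an expression dataset with a planted disease module
#'
#' Controls are drawn from per-gene Gaussian baselines. Each case perturbs a
#' random `case_module_fraction` of the planted module plus
#' `background_peep_size` random non-module genes; controls receive the same
#' number of background perturbations (the heterogeneity noise floor).
#' Perturbation shifts a value by `effect_size` control sds.
#'
#' @param config A [simulation_config()].
#' @return Object of class `peep_simulation`: list with `data` (a
#'   [peep_dataset()]), `module` (planted gene ids), `perturbed` (named list
#'   per subject of the deliberately perturbed gene ids), `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- config$n_genes
  genes <- sprintf("g%0*d", nchar(G), seq_len(G))
  ctrl_ids <- sprintf("ctrl%02d", seq_len(config$n_controls))
  case_ids <- sprintf("case%02d", seq_len(config$n_cases))
  mu <- stats::runif(G, config$baseline_mean_range[1],
                     config$baseline_mean_range[2])
  sigma <- stats::runif(G, config$baseline_sd_range[1],
                        config$baseline_sd_range[2])
  n <- config$n_controls + config$n_cases
  values <- matrix(stats::rnorm(G * n, mu, sigma), G, n,
                   dimnames = list(genes, c(ctrl_ids, case_ids)))
  module <- sample(genes, config$module_size)
  mod_dir <- stats::setNames(sample(c(-1, 1), config$module_size,
                                    replace = TRUE), module)
  n_mod <- round(config$case_module_fraction * config$module_size)
  background <- setdiff(genes, module)
  perturbed <- list()
  for (s in c(ctrl_ids, case_ids)) {
    hit <- character(0)
    if (s %in% case_ids && n_mod > 0) {
      mg <- sample(module, n_mod)
      dir <- if (config$direction_mode == "consistent") mod_dir[mg]
             else sample(c(-1, 1), n_mod, replace = TRUE)
      values[mg, s] <- values[mg, s] + dir * config$effect_size * sigma[
        match(mg, genes)]
      hit <- mg
    }
    if (config$background_peep_size > 0) {
      bg <- sample(background, config$background_peep_size)
      dir <- sample(c(-1, 1), length(bg), replace = TRUE)
      values[bg, s] <- values[bg, s] + dir * config$effect_size * sigma[
        match(bg, genes)]
      hit <- c(hit, bg)
    }
    perturbed[[s]] <- hit
  }
  labels <- stats::setNames(rep(c("control", "case"),
                                c(config$n_controls, config$n_cases)),
                            c(ctrl_ids, case_ids))
  structure(list(data = peep_dataset(values, labels), module = module,
                 perturbed = perturbed, config = config),
            class = "peep_simulation")
}

#' @export
print.peep_simulation <- function(x, ...) {
  cat(sprintf(
    "peep_simulation: %d genes, %d controls + %d cases, module %d (f = %g, b = %d, delta = %g, %s)\n",
    x$config$n_genes, x$config$n_controls, x$config$n_cases,
    x$config$module_size, x$config$case_module_fraction,
    x$config$background_peep_size, x$config$effect_size,
    x$config$direction_mode))
  invisible(x)
}

#' Draw profiles from the uniform random null
#'
#' Each of `n` subjects receives a uniform random `g`-subset of the `G`-gene
#' universe — the null model underlying the occupancy expectation and the
#' pool threshold. Used to calibrate [occupancy_histogram()] and
#' [solve_x_rand()].
#'
#' @param G Universe size.
#' @param n Number of subjects.
#' @param g Genes per subject (g <= G).
#' @param seed Integer seed.
#' @param universe Optional gene ids (default `sprintf("g%d", 1:G)`).
#' @return Named list of `n` character vectors, with the universe attached
#'   as attribute `"universe"`.
#' @export
simulate_null_peeps <- function(G, n, g, seed = 1, universe = NULL) {
  if (g > G) stop("g must not exceed G")
  if (is.null(universe)) universe <- sprintf("g%d", seq_len(G))
  stopifnot(length(universe) == G)
  set.seed(seed)
  sets <- lapply(seq_len(n), function(i) sample(universe, g))
  names(sets) <- sprintf("s%d", seq_len(n))
  attr(sets, "universe") <- universe
  sets
}

#' Precision and recall of a recovered pool against the planted module
#'
#' @param pool A [build_pool()] result (or character vector of genes).
#' @param module Character vector of planted module gene ids.
#' @return Named numeric: `precision`, `recall` (NA precision if the pool
#'   is empty).
#' @export
pool_recovery <- function(pool, module) {
  genes <- if (inherits(pool, "disease_pool")) pool$genes else pool
  tp <- length(intersect(genes, module))
  c(precision = if (length(genes)) tp / length(genes) else NA_real_,
    recall = tp / length(module))
}
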