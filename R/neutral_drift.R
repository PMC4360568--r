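# Neutral-mutation kinetics: survival and copy number of a new neutral
# allele under critical branching (drift in a stable population), and
# the mutation-clock arithmetic.

simulate_branching <- function(n, reps, seed = NULL,
                               offspring = c("poisson", "binomial")) {
  offspring <- match.arg(offspring)
  if (n < 1) abort_domain("`n` must be >= 1 generations")
  if (reps < 1e3) abort_domain("`reps` must be >= 1000")
  if (!is.null(seed)) set.seed(seed)
  copies <- rep(1L, reps)
  for (g in seq_len(n)) {
    alive <- copies > 0L
    if (!any(alive)) break
    copies[alive] <- if (offspring == "poisson") {
      # Each copy leaves Poisson(1) descendants; their sum over a
      # lineage's copies is Poisson(copies).
      stats::rpois(sum(alive), copies[alive])
    } else {
      # Two-child families: each copy transmitted to each child with
      # probability 1/2 -> Binomial(2 * copies, 1/2) descendants.
      stats::rbinom(sum(alive), 2L * copies[alive], 0.5)
    }
  }
  copies
}

#' Survival probability of a new neutral mutation
#'
#' A new neutral allele in a stable population follows a critical
#' branching process: each copy leaves on average one descendant copy.
#' Most lineages die out by chance; the survival probability after `n`
#' generations is close to `2 / (sigma^2 * n)` for large `n`, where
#' `sigma^2` is the offspring variance — `2/n` for the default
#' unit-mean Poisson offspring model. The two-children family model
#' (each copy transmitted to each of two children with probability 1/2,
#' so 25% lost / 50% one copy / 25% both) has `sigma^2 = 1/2` and
#' decays correspondingly more slowly.
#'
#' @param n Generations (>= 1).
#' @param reps Simulated lineages (>= 1000).
#' @param seed Optional integer seed.
#' @param offspring `"poisson"` (default, stable population) or
#'   `"binomial"` (two-child families).
#' @return List with `estimate`, `se` (binomial standard error),
#'   `n`, `reps`, `offspring`.
#' @examples
#' branching_survival(1, reps = 10000, seed = 1)$estimate  # ~ 1 - exp(-1)
#' @export
branching_survival <- function(n, reps = 1e5, seed = NULL,
                               offspring = c("poisson", "binomial")) {
  copies <- simulate_branching(n, reps, seed, offspring)
  p <- mean(copies > 0L)
  list(estimate = p, se = sqrt(p * (1 - p) / reps), n = n, reps = reps,
       offspring = match.arg(offspring))
}

#' Mean copy number of a surviving neutral mutation
#'
#' Conditional on a neutral lineage still being present after `n`
#' generations, its expected copy number is close to `sigma^2 * n / 2`
#' (`n/2` under the Poisson offspring model): survival and abundance
#' balance so that the unconditional mean stays at one copy.
#'
#' @inheritParams branching_survival
#' @return List with `estimate` (conditional mean), `se`,
#'   `n_surviving`, `n`, `reps`, `offspring`.
#' @examples
#' copies_given_survival(10, reps = 20000, seed = 1)$estimate  # ~ 5
#' @export
copies_given_survival <- function(n, reps = 1e5, seed = NULL,
                                  offspring = c("poisson", "binomial")) {
  copies <- simulate_branching(n, reps, seed, offspring)
  surv <- copies[copies > 0L]
  if (length(surv) == 0L)
    abort_solver(sprintf(
      "no lineage survived %d generations in %g replicates; increase `reps`",
      n, reps))
  list(estimate = mean(surv),
       se = stats::sd(surv) / sqrt(length(surv)),
       n_surviving = length(surv), n = n, reps = reps,
       offspring = match.arg(offspring))
}

#' Base miscopies per mitotic division
#'
#' The genome-wide expected number of copying errors each time a cell
#' divides: mutation rate per base pair per division times the diploid
#' genome size — three per division at the default rates.
#'
#' @param params A [model_params()] object.
#' @return Expected miscopied bases per division.
#' @examples
#' per_division_mutations(model_params())   # 3
#' @export
per_division_mutations <- function(params) {
  params <- as_model_params(params)
  params$mu_per_bp_div * params$genome_bp_diploid
}

#' New base changes per zygote from parental gametogenesis
#'
#' Multiplies the per-division miscopy count by the germ-line division
#' counts of the two parental lineages and halves it, because each
#' gamete transmits one of the two strands carrying a lineage's diploid
#' miscopies. At the defaults (3 per division; 40 maternal and 60
#' paternal divisions) this gives 150 new base changes per zygote.
#'
#' @param clock A [clock_params()] object.
#' @param params A [model_params()] object.
#' @return Expected new base changes per zygote.
#' @examples
#' new_mutations_per_zygote(clock_params(), model_params())   # 150
#' @export
new_mutations_per_zygote <- function(clock = clock_params(),
                                     params = model_params()) {
  if (!inherits(clock, "clock_params"))
    abort_contract("`clock` must be clock_params")
  per_division_mutations(params) *
    (clock$divisions_maternal + clock$divisions_paternal) / 2
}

#' Divergence clock: generations and years behind the standing variation
#'
#' If homologous strands differ at a density `divergence` (about 1 in
#' 300 bases) and each generation adds `new_per_generation` base changes
#' per individual, the accumulation has been running for
#' `divergence * haploid_bp / new_per_generation` generations — 100,000
#' at the defaults, or 2.5 million years at 25 years per generation.
#'
#' @param clock A [clock_params()] object.
#' @param params A [model_params()] object (supplies the generation
#'   time).
#' @return List with `generations` and `years`.
#' @examples
#' divergence_clock()   # 100,000 generations, 2.5e6 years
#' @export
divergence_clock <- function(clock = clock_params(),
                             params = model_params()) {
  if (!inherits(clock, "clock_params"))
    abort_contract("`clock` must be clock_params")
  params <- as_model_params(params)
  gens <- clock$divergence * clock$haploid_bp / clock$new_per_generation
  list(generations = gens, years = gens * params$generation_years)
}
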