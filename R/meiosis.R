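# Forward-in-time simulator of synergistic selection: deleterious
# mutations are counted per essential genetic system; meiosis thins each
# parent's counts binomially, gametogenesis adds Poisson(N) new
# mutations, and viability depends on the worst per-system count.

#' Partition of the conserved genome into essential genetic systems
#'
#' The synergy model groups conserved genes into large complex systems
#' of hundreds to thousands of genes; a system fails when it accumulates
#' too many deleterious mutations. The default architecture is ten equal
#' essential systems of 2,000 genes, covering the 20,000-gene haploid
#' set.
#'
#' @param n_systems Number of systems (>= 1).
#' @param system_sizes Genes per system, haploid scale; recycled to
#'   `n_systems`.
#' @param essential_flags Logical per system: does the viability rule
#'   apply to it? Recycled to `n_systems`.
#' @param L_haploid Upper bound on total genes (default 20,000).
#'
#' @return An object of class `genome_architecture` with fields
#'   `n_systems`, `system_sizes`, `essential_flags` and the derived
#'   `share` (size proportions used to place new mutations).
#' @examples
#' genome_architecture()                      # 10 x 2000 genes
#' genome_architecture(4, c(4000, 3000, 2000, 1000))
#' @export
genome_architecture <- function(n_systems = 10,
                                system_sizes = rep(2000L, n_systems),
                                essential_flags = rep(TRUE, n_systems),
                                L_haploid = 20000) {
  stopifnot_scalar_number(n_systems, "n_systems", min = 1)
  system_sizes <- rep_len(system_sizes, n_systems)
  essential_flags <- rep_len(as.logical(essential_flags), n_systems)
  if (any(system_sizes < 1)) abort_domain("system sizes must be >= 1")
  if (sum(system_sizes) > L_haploid)
    abort_domain("system sizes exceed the haploid gene count")
  structure(
    list(n_systems = as.integer(n_systems),
         system_sizes = system_sizes,
         essential_flags = essential_flags,
         share = system_sizes / sum(system_sizes)),
    class = "genome_architecture"
  )
}

#' Per-system viability rule for synergistic selection
#'
#' Encodes the graded cost of co-occurring deleterious mutations within
#' one essential system: four or more in any essential system is lethal
#' at (or shortly after) conception; three leaves a fragile system with
#' death probability `q3` in infancy or childhood; two gives a milder
#' risk `q2`; one or none is safe. The defaults `q3 = 0.3`, `q2 = 0.05`
#' quantify the model's ordinal statements and can be swept.
#'
#' @param lethal_threshold Per-system count causing conception loss
#'   (default 4).
#' @param q3 Postnatal death probability at a per-system count of 3.
#' @param q2 Postnatal death probability at a per-system count of 2.
#'
#' @return An object of class `selection_rule`.
#' @examples
#' selection_rule()                 # threshold 4, q3 = 0.3, q2 = 0.05
#' selection_rule(lethal_threshold = Inf, q3 = 0, q2 = 0)  # no selection
#' @export
selection_rule <- function(lethal_threshold = 4, q3 = 0.3, q2 = 0.05) {
  if (!(is.numeric(lethal_threshold) && length(lethal_threshold) == 1L &&
        (is.infinite(lethal_threshold) || lethal_threshold >= 1)))
    abort_domain("`lethal_threshold` must be >= 1 (Inf disables it)")
  stopifnot_scalar_number(q3, "q3", min = 0, max = 1)
  stopifnot_scalar_number(q2, "q2", min = 0, max = 1)
  if (q2 > q3)
    abort_domain("postnatal death probability must be nondecreasing in count (q2 <= q3)")
  structure(
    list(lethal_threshold = lethal_threshold, q3 = q3, q2 = q2),
    class = "selection_rule"
  )
}

# Death probability given the worst essential-system count (vectorised).
postnatal_death_prob <- function(max_count, rule) {
  ifelse(max_count >= 3, rule$q3, ifelse(max_count == 2, rule$q2, 0))
}

#' Construct an individual for the synergy simulator
#'
#' @param per_system_counts Deleterious mutations per system.
#' @param sex `"male"` or `"female"`.
#' @param x_count Deleterious mutations on the X chromosome.
#' @return An object of class `sim_individual`.
#' @export
sim_individual <- function(per_system_counts, sex = c("female", "male"),
                           x_count = 0L) {
  sex <- match.arg(sex)
  if (any(per_system_counts < 0) || x_count < 0)
    abort_domain("mutation counts must be nonnegative")
  structure(
    list(per_system_counts = as.integer(per_system_counts), sex = sex,
         x_count = as.integer(x_count),
         total_load = sum(per_system_counts)),
    class = "sim_individual"
  )
}

#' Meiotic transmission: draw one gamete from a parent
#'
#' Each deleterious mutation is passed on independently with probability
#' one half, so per-system gamete counts are binomial thinnings of the
#' parental counts; the X-linked side-count is thinned the same way.
#' Uses the current R random stream (`set.seed()` for reproducibility).
#'
#' @param parent A [sim_individual()].
#' @return A list with `per_system_counts` (haploid) and `x_count`.
#' @examples
#' set.seed(1)
#' transmit_gamete(sim_individual(c(4, 2, 0)))
#' @export
transmit_gamete <- function(parent) {
  if (!inherits(parent, "sim_individual"))
    abort_contract("`parent` must be a sim_individual")
  list(
    per_system_counts = stats::rbinom(length(parent$per_system_counts),
                                      parent$per_system_counts, 0.5),
    x_count = stats::rbinom(1L, parent$x_count, 0.5)
  )
}

#' Form a zygote from two gametes
#'
#' Sums the gametes' per-system counts, adds a Poisson(`N`) number of
#' new deleterious mutations — each assigned to a system with
#' probability proportional to system size — assigns sex 1:1, and
#' maintains the X-linked side-count by binomial thinning of the new
#' mutations at rate `x_fraction_haploid / 2`.
#'
#' @param gamete_a,gamete_b Gametes from [transmit_gamete()] (same
#'   architecture).
#' @param params A [model_params()] object (`N`, `x_fraction_haploid`).
#' @param arch A [genome_architecture()].
#' @return A [sim_individual()].
#' @export
form_zygote <- function(gamete_a, gamete_b, params, arch) {
  params <- as_model_params(params)
  if (length(gamete_a$per_system_counts) != arch$n_systems ||
      length(gamete_b$per_system_counts) != arch$n_systems)
    abort_contract("gametes do not match the genome architecture")
  counts <- gamete_a$per_system_counts + gamete_b$per_system_counts
  n_new <- stats::rpois(1L, params$N)
  if (n_new > 0) {
    sys <- sample.int(arch$n_systems, n_new, replace = TRUE,
                      prob = arch$share)
    counts <- counts + tabulate(sys, nbins = arch$n_systems)
  }
  x_new <- stats::rbinom(1L, n_new, params$x_fraction_haploid / 2)
  sim_individual(counts,
                 sex = if (stats::runif(1) < 0.5) "male" else "female",
                 x_count = gamete_a$x_count + gamete_b$x_count + x_new)
}

#' Classify a zygote's fate under a viability rule
#'
#' Lethal at conception if any essential system carries at least
#' `lethal_threshold` mutations; otherwise dies postnatally with the
#' probability the rule attaches to the worst essential-system count;
#' otherwise survives to adulthood.
#'
#' @param ind A [sim_individual()].
#' @param rule A [selection_rule()].
#' @param arch A [genome_architecture()] giving the essential flags;
#'   defaults to all-essential.
#' @return One of `"lethal_conception"`, `"postnatal_death"`,
#'   `"survivor"`.
#' @examples
#' classify_viability(sim_individual(c(4, 0)), selection_rule())
#' @export
classify_viability <- function(ind, rule, arch = NULL) {
  if (!inherits(rule, "selection_rule"))
    abort_contract("`rule` must be a selection_rule")
  ess <- if (is.null(arch)) rep(TRUE, length(ind$per_system_counts))
         else arch$essential_flags
  counts <- ind$per_system_counts[ess]
  if (length(counts) && max(counts) >= rule$lethal_threshold)
    return("lethal_conception")
  pd <- postnatal_death_prob(if (length(counts)) max(counts) else 0L, rule)
  if (pd > 0 && stats::runif(1) < pd) "postnatal_death" else "survivor"
}

# Vectorised generation step over count matrices (pop x n_systems).
sample_zygote_batch <- function(adults_counts, adults_x, n_zygotes,
                                params, arch) {
  S <- arch$n_systems
  pop <- nrow(adults_counts)
  pa <- sample.int(pop, n_zygotes, replace = TRUE)
  pb <- sample.int(pop, n_zygotes, replace = TRUE)
  gam <- function(idx) {
    m <- adults_counts[idx, , drop = FALSE]
    matrix(stats::rbinom(n_zygotes * S, as.vector(m), 0.5),
           nrow = n_zygotes)
  }
  counts <- gam(pa) + gam(pb)
  # Poisson(N) split multinomially by size share == independent
  # Poisson(N * share_s) per system.
  new_counts <- matrix(
    stats::rpois(n_zygotes * S, rep(params$N * arch$share,
                                    each = n_zygotes)),
    nrow = n_zygotes
  )
  counts <- counts + new_counts
  x <- stats::rbinom(n_zygotes, adults_x[pa], 0.5) +
       stats::rbinom(n_zygotes, adults_x[pb], 0.5) +
       stats::rbinom(n_zygotes, rowSums(new_counts),
                     params$x_fraction_haploid / 2)
  list(counts = counts, x = x,
       sex = ifelse(stats::runif(n_zygotes) < 0.5, "male", "female"))
}

#' Iterate the synergy model over generations
#'
#' Simulates a constant-size population under the per-system viability
#' rule: random mating with replacement, binomial meiotic transmission,
#' Poisson(`N`) mutational input, lethal and postnatal selection, and
#' regulation by sampling survivors back to `pop_size`. Under the
#' default rule the mean adult load settles into a stationary
#' mutation-selection balance; with selection disabled it grows by `N`
#' per generation.
#'
#' @param params A [model_params()] object; `M` sets the founding load.
#' @param arch A [genome_architecture()].
#' @param rule A [selection_rule()].
#' @param pop_size Number of adults per generation (>= 100).
#' @param n_generations Generations to simulate (>= 1).
#' @param seed Integer seed; recorded in the result.
#'
#' @return A data frame of class `generation_stats` with one row per
#'   generation: `generation`, `mean_adult_load`,
#'   `zygote_loss_fraction` (conception-stage, of zygotes formed),
#'   `postnatal_death_fraction` (of zygotes formed) and
#'   `population_size`. Attributes record `seed`, `params`, `arch`,
#'   `rule`. Extinction raises a solver error carrying the partial
#'   series in its `diagnostics`.
#' @examples
#' s <- run_generations(model_params(M = 4, N = 1), genome_architecture(),
#'                      selection_rule(), pop_size = 200,
#'                      n_generations = 5, seed = 1)
#' s$mean_adult_load
#' @export
run_generations <- function(params, arch = genome_architecture(),
                            rule = selection_rule(), pop_size = 1000,
                            n_generations = 100, seed = 1) {
  params <- as_model_params(params)
  if (pop_size < 100) abort_domain("`pop_size` must be >= 100")
  if (n_generations < 1) abort_domain("`n_generations` must be >= 1")
  set.seed(seed)
  S <- arch$n_systems
  ess <- arch$essential_flags
  # Founding adults: load M spread over systems by size share.
  counts <- matrix(
    stats::rpois(pop_size * S, rep(params$M * arch$share, each = pop_size)),
    nrow = pop_size
  )
  x <- stats::rbinom(pop_size, rowSums(counts),
                     params$x_fraction_haploid / 2)
  stats <- vector("list", n_generations)
  for (g in seq_len(n_generations)) {
    n_z <- 0L; n_lethal <- 0L; n_post <- 0L
    surv_counts <- NULL; surv_x <- NULL
    for (attempt in 1:20) {
      batch_n <- max(2L * pop_size, 200L)
      z <- sample_zygote_batch(counts, x, batch_n, params, arch)
      ess_counts <- z$counts[, ess, drop = FALSE]
      max_ess <- if (ncol(ess_counts)) do.call(pmax, c(
        lapply(seq_len(ncol(ess_counts)), function(j) ess_counts[, j]),
        list(0L))) else integer(batch_n)
      lethal <- max_ess >= rule$lethal_threshold
      pd <- postnatal_death_prob(max_ess, rule)
      postnatal <- !lethal & (stats::runif(batch_n) < pd)
      keep <- !lethal & !postnatal
      n_z <- n_z + batch_n
      n_lethal <- n_lethal + sum(lethal)
      n_post <- n_post + sum(postnatal)
      surv_counts <- rbind(surv_counts, z$counts[keep, , drop = FALSE])
      surv_x <- c(surv_x, z$x[keep])
      if (nrow(surv_counts) >= pop_size) break
    }
    if (nrow(surv_counts) == 0L) {
      partial <- do.call(rbind, stats[seq_len(g - 1L)])
      abort_solver(sprintf("population extinct at generation %d", g),
                   diagnostics = list(partial_stats = partial, seed = seed))
    }
    idx <- if (nrow(surv_counts) >= pop_size)
      sample.int(nrow(surv_counts), pop_size)
    else
      sample.int(nrow(surv_counts), pop_size, replace = TRUE)
    counts <- surv_counts[idx, , drop = FALSE]
    x <- surv_x[idx]
    stats[[g]] <- data.frame(
      generation = g,
      mean_adult_load = mean(rowSums(counts)),
      zygote_loss_fraction = n_lethal / n_z,
      postnatal_death_fraction = n_post / n_z,
      population_size = pop_size
    )
  }
  out <- do.call(rbind, stats)
  attr(out, "seed") <- seed
  attr(out, "params") <- params
  attr(out, "arch") <- arch
  attr(out, "rule") <- rule
  class(out) <- c("generation_stats", "data.frame")
  out
}

#' Summarise the equilibrium reached by a simulated series
#'
#' Averages the mean adult load, the conception-stage loss fraction and
#' the postnatal death fraction over the final third of the series,
#' where the population has settled; Monte-Carlo standard errors are the
#' between-generation standard deviations scaled by the window length.
#'
#' @param series A `generation_stats` data frame of at least 100
#'   generations.
#' @return A list with `M_eq`, `loss_eq`, `postnatal_eq` and matching
#'   `*_se` standard errors, plus the window used.
#' @export
equilibrium_summary <- function(series) {
  if (!is.data.frame(series) || nrow(series) < 100)
    abort_contract("`series` must cover at least 100 generations")
  n <- nrow(series)
  win <- series[seq.int(n - floor(n / 3) + 1L, n), ]
  m <- nrow(win)
  se <- function(v) stats::sd(v) / sqrt(m)
  list(
    M_eq = mean(win$mean_adult_load), M_eq_se = se(win$mean_adult_load),
    loss_eq = mean(win$zygote_loss_fraction),
    loss_eq_se = se(win$zygote_loss_fraction),
    postnatal_eq = mean(win$postnatal_death_fraction),
    postnatal_eq_se = se(win$postnatal_death_fraction),
    window = c(start = win$generation[1], end = win$generation[m])
  )
}

#' Sweep the zygote loss fraction over viability-rule settings
#'
#' Runs short seeded simulations across a grid of `q3`/`q2` settings
#' (and optionally lethal thresholds) and reports the equilibrium loss
#' fractions, quantifying how the conception-stage loss depends on the
#' graded part of the synergy rule.
#'
#' @param params A [model_params()] object.
#' @param q3_values,q2_values Grids for the postnatal probabilities.
#' @param lethal_thresholds Grid of lethal thresholds.
#' @param pop_size,n_generations,seed Simulation settings.
#' @return A data frame with one row per grid point: the rule settings,
#'   `M_eq`, `loss_eq`, `postnatal_eq`.
#' @export
sweep_loss_fraction <- function(params = model_params(),
                                q3_values = c(0.1, 0.3, 0.5),
                                q2_values = 0.05,
                                lethal_thresholds = 4,
                                pop_size = 1000, n_generations = 120,
                                seed = 1) {
  grid <- expand.grid(q3 = q3_values, q2 = q2_values,
                      lethal_threshold = lethal_thresholds)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    rule <- selection_rule(grid$lethal_threshold[i], grid$q3[i], grid$q2[i])
    s <- run_generations(params, genome_architecture(), rule,
                         pop_size = pop_size,
                         n_generations = n_generations, seed = seed + i)
    eq <- equilibrium_summary(s)
    cbind(grid[i, , drop = FALSE],
          data.frame(M_eq = eq$M_eq, loss_eq = eq$loss_eq,
                     postnatal_eq = eq$postnatal_eq))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
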