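#' Global parameters of the genomic-load model
#'
#' Bundles the constants the analytic and simulation machinery share:
#' the mean deleterious load of adults, the mutational input per
#' generation, gene and genome sizes, the per-division copying error
#' rate, the X-chromosome share of the genome and the generation time.
#'
#' All loads are counted on the diploid germ line: `M` is the mean
#' number of heterozygous deleterious mutations an adult carries across
#' both chromosome sets, and `N` the mean number of new ones a zygote
#' receives from parental gametogenesis. `L_haploid` counts conserved
#' functioning genes per haploid set, so the diploid complement holds
#' `2 * L_haploid` genes.
#'
#' @param M Mean deleterious mutations per adult diploid germ line
#'   (count, >= 0).
#' @param N Mean new deleterious mutations per zygote per generation
#'   (count, >= 0).
#' @param L_haploid Conserved functioning genes per haploid set.
#' @param genome_bp_diploid Base pairs in the diploid genome.
#' @param mu_per_bp_div Mutation rate per base pair per mitotic division.
#' @param x_fraction_haploid Fraction of the haploid genome carried by
#'   the X chromosome, in `[0, 1]`.
#' @param generation_years Years per human generation.
#'
#' @return An object of class `model_params`: a named list of the seven
#'   validated fields.
#' @examples
#' p <- model_params()            # M = 7, N = 1 defaults
#' model_params(M = 4, N = 0.5)
#' @export
model_params <- function(M = 7, N = 1, L_haploid = 20000,
                         genome_bp_diploid = 6e9, mu_per_bp_div = 5e-10,
                         x_fraction_haploid = 0.05, generation_years = 25) {
  stopifnot_scalar_number(M, "M", min = 0)
  stopifnot_scalar_number(N, "N", min = 0)
  stopifnot_scalar_number(L_haploid, "L_haploid", min = 0)
  stopifnot_scalar_number(genome_bp_diploid, "genome_bp_diploid", min = 0)
  stopifnot_scalar_number(mu_per_bp_div, "mu_per_bp_div", min = 0)
  stopifnot_scalar_number(x_fraction_haploid, "x_fraction_haploid",
                          min = 0, max = 1)
  stopifnot_scalar_number(generation_years, "generation_years", min = 0)
  structure(
    list(M = M, N = N, L_haploid = L_haploid,
         genome_bp_diploid = genome_bp_diploid,
         mu_per_bp_div = mu_per_bp_div,
         x_fraction_haploid = x_fraction_haploid,
         generation_years = generation_years),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("Genomic-load model parameters\n")
  cat(sprintf("  adult mean load M           : %g\n", x$M))
  cat(sprintf("  new mutations/zygote N      : %g\n", x$N))
  cat(sprintf("  zygote mean load M + N      : %g\n", x$M + x$N))
  cat(sprintf("  conserved genes (haploid)   : %g\n", x$L_haploid))
  cat(sprintf("  diploid genome (bp)         : %g\n", x$genome_bp_diploid))
  cat(sprintf("  mutation rate /bp/division  : %g\n", x$mu_per_bp_div))
  cat(sprintf("  X fraction of haploid genome: %g\n", x$x_fraction_haploid))
  cat(sprintf("  generation time (years)     : %g\n", x$generation_years))
  invisible(x)
}

as_model_params <- function(x) {
  if (inherits(x, "model_params")) return(x)
  if (is.list(x)) return(do.call(model_params, x))
  abort_domain("cannot interpret `params` as model_params")
}

#' Parameters of the neutral-mutation clock
#'
#' Constants for the divergence-clock arithmetic: the pairwise base
#' difference density between homologous strands, the number of new base
#' changes per individual per generation, the aligned haploid length and
#' the germ-line division counts of the two parental lineages.
#'
#' @param divergence Pairwise difference density between two homologous
#'   strands (per bp). Default 1/300.
#' @param new_per_generation New base changes per individual per
#'   generation entering the clock denominator.
#' @param haploid_bp Aligned haploid length in base pairs.
#' @param divisions_maternal Mitotic divisions from zygote to oocyte.
#' @param divisions_paternal Mitotic divisions from zygote to spermatozoon.
#'
#' @return An object of class `clock_params`.
#' @examples
#' clock_params()
#' @export
clock_params <- function(divergence = 1 / 300, new_per_generation = 100,
                         haploid_bp = 3e9, divisions_maternal = 40,
                         divisions_paternal = 60) {
  stopifnot_scalar_number(divergence, "divergence", min = 0)
  stopifnot_scalar_number(new_per_generation, "new_per_generation", min = 0)
  if (new_per_generation <= 0)
    abort_domain("`new_per_generation` must be positive")
  stopifnot_scalar_number(haploid_bp, "haploid_bp", min = 0)
  stopifnot_scalar_number(divisions_maternal, "divisions_maternal", min = 0)
  stopifnot_scalar_number(divisions_paternal, "divisions_paternal", min = 0)
  structure(
    list(divergence = divergence, new_per_generation = new_per_generation,
         haploid_bp = haploid_bp, divisions_maternal = divisions_maternal,
         divisions_paternal = divisions_paternal),
    class = "clock_params"
  )
}

#' Parameters of the first-cousin autozygosity model
#'
#' @param shared_grandparents Number of grandparents the two cousins
#'   share (1 or 2; 2 for ordinary first cousins).
#' @param transmission_steps Meioses a grandparental allele must survive
#'   to reach the focal child down both paths (6 for first cousins).
#' @param disease_fraction Observed proportion of first-cousin offspring
#'   with at least one recessive disease, in `[0, 1)`; `NA` if unknown.
#'
#' @return An object of class `cousin_params`.
#' @examples
#' cousin_params(disease_fraction = 0.10)
#' @export
cousin_params <- function(shared_grandparents = 2, transmission_steps = 6,
                          disease_fraction = NA_real_) {
  if (!shared_grandparents %in% c(1, 2))
    abort_domain("`shared_grandparents` must be 1 or 2")
  stopifnot_scalar_number(transmission_steps, "transmission_steps", min = 1)
  if (!is.na(disease_fraction)) {
    stopifnot_scalar_number(disease_fraction, "disease_fraction", min = 0)
    if (disease_fraction >= 1)
      abort_domain("`disease_fraction` must be < 1")
  }
  structure(
    list(shared_grandparents = shared_grandparents,
         transmission_steps = transmission_steps,
         disease_fraction = disease_fraction),
    class = "cousin_params"
  )
}
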