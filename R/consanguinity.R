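# First-cousin autozygosity: the probability that a heterozygous
# deleterious allele in a shared grandparent surfaces homozygous in a
# cousin-marriage child, the disease burden that implies as a function
# of the mean load M, and the inversion estimating M from an observed
# disease fraction.

# A pedigree is a named list: founders map to NULL, non-founders to
# c(father_id, mother_id), listed in topological order.
builtin_pedigrees <- function(kind) {
  switch(kind,
    first_cousin = list(
      gpA = NULL, gpB = NULL, sp1 = NULL, sp2 = NULL,
      par1 = c("gpA", "gpB"), par2 = c("gpA", "gpB"),
      cous1 = c("par1", "sp1"), cous2 = c("par2", "sp2"),
      child = c("cous1", "cous2")
    ),
    sibling = list(
      pa = NULL, pb = NULL,
      sib1 = c("pa", "pb"), sib2 = c("pa", "pb"),
      child = c("sib1", "sib2")
    ),
    unrelated = list(
      pa = NULL, pb = NULL, pc = NULL, pd = NULL,
      par1 = c("pa", "pb"), par2 = c("pc", "pd"),
      child = c("par1", "par2")
    ),
    abort_domain(sprintf("unknown pedigree kind '%s'", kind))
  )
}

# Exhaustive gene dropping: tag one allele of `tagged` and enumerate
# every Mendelian transmission outcome (4 equiprobable per meiosis
# pair), returning the probability `focal` carries the tag on both
# chromosomes.
pedigree_autozygosity <- function(members, tagged, focal) {
  ids <- names(members)
  is_founder <- vapply(members, is.null, logical(1))
  geno <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids[is_founder])
    geno[[id]] <- if (id == tagged) c(1L, 0L) else c(0L, 0L)
  nonf <- ids[!is_founder]
  recurse <- function(i, geno) {
    if (i > length(nonf)) {
      g <- geno[[focal]]
      return(as.numeric(g[1] == 1L && g[2] == 1L))
    }
    id <- nonf[i]
    fg <- geno[[members[[id]][1]]]
    mg <- geno[[members[[id]][2]]]
    tot <- 0
    for (fa in 1:2) {
      for (ma in 1:2) {
        geno[[id]] <- c(fg[fa], mg[ma])
        tot <- tot + recurse(i + 1L, geno)
      }
    }
    tot / 4
  }
  recurse(1L, geno)
}

#' Per-allele autozygosity probability for a mating type
#'
#' Probability that one heterozygous allele in a shared ancestor
#' becomes homozygous by descent in the focal child, computed by
#' exhaustive gene-dropping enumeration over every Mendelian
#' transmission outcome of the pedigree. For first cousins the allele
#' must survive six meioses — down both branches to the two cousins and
#' on to their child — giving (1/2)^6 = 1/64; a sibling mating needs
#' four, giving 1/16; unrelated parents give zero.
#'
#' @param pedigree_kind `"first_cousin"`, `"sibling"` or `"unrelated"`.
#' @return The autozygosity probability for a single tagged allele.
#' @examples
#' per_allele_autozygosity("first_cousin")   # 0.015625
#' @export
per_allele_autozygosity <- function(pedigree_kind = c("first_cousin",
                                                      "sibling",
                                                      "unrelated")) {
  if (length(pedigree_kind) == 1L && !pedigree_kind %in%
      c("first_cousin", "sibling", "unrelated"))
    abort_domain(sprintf("unknown pedigree kind '%s'", pedigree_kind))
  pedigree_kind <- match.arg(pedigree_kind)
  members <- builtin_pedigrees(pedigree_kind)
  tagged <- names(members)[1]
  pedigree_autozygosity(members, tagged, "child")
}

#' Expected autozygous deleterious load in a cousin-marriage child
#'
#' Each shared grandparent carries on average `M` heterozygous
#' deleterious mutations, and each becomes homozygous in the focal
#' child with the per-allele autozygosity probability; the expectation
#' is their product summed over shared grandparents — `M/32` for
#' ordinary first cousins. New mutations arising in the cousins' own
#' gametes are ignored: they cannot be identical by descent.
#'
#' @param M Mean deleterious mutations per adult diploid germ line.
#' @param cousin A [cousin_params()] object.
#' @return Expected count of autozygous deleterious loci.
#' @examples
#' expected_autozygous_load(7)   # 7/32 = 0.21875
#' @export
expected_autozygous_load <- function(M, cousin = cousin_params()) {
  stopifnot_scalar_number(M, "M", min = 0)
  cousin$shared_grandparents * M * 0.5^cousin$transmission_steps
}

#' Recessive-disease fraction implied by a mean load M
#'
#' Autozygous deleterious loci in a first-cousin child are rare and
#' independent, so their count is Poisson with mean
#' `expected_autozygous_load(M)`; a child has a recognizable recessive
#' disease when at least one such locus is present (and penetrant),
#' giving `1 - exp(-penetrance * M/32)` at the defaults.
#'
#' @param M Mean deleterious mutations per adult diploid germ line.
#' @param cousin A [cousin_params()] object.
#' @param penetrance Probability an autozygous deleterious locus causes
#'   recognizable disease; default 1.
#' @param linear If `TRUE` return the small-`M` linear approximation
#'   `penetrance * M/32` instead of the Poisson form.
#' @return Expected proportion of first-cousin offspring with at least
#'   one recessive disease.
#' @examples
#' disease_fraction_from_M(7)    # 1 - exp(-7/32) = 0.1966
#' @export
disease_fraction_from_M <- function(M, cousin = cousin_params(),
                                    penetrance = 1, linear = FALSE) {
  stopifnot_scalar_number(M, "M", min = 0)
  stopifnot_scalar_number(penetrance, "penetrance", min = 0, max = 1)
  lambda <- penetrance * cousin$shared_grandparents * M *
    0.5^cousin$transmission_steps
  if (linear) lambda else 1 - exp(-lambda)
}

#' Estimate the mean load M from a cousin-offspring disease fraction
#'
#' Exact inverse of [disease_fraction_from_M()]: observing a fraction
#' `D` of first-cousin offspring with recessive disease implies
#' `M = -32 * log(1 - D)` under the Poisson autozygosity model at the
#' default pedigree. A 10% disease fraction — the complement of the
#' observation that over 90% of cousin-marriage children are healthy —
#' gives an estimate near 3.4, comfortably below the single-figure
#' bound on M.
#'
#' @param disease_fraction Observed proportion in `[0, 1)`.
#' @param cousin A [cousin_params()] object.
#' @param penetrance As in [disease_fraction_from_M()].
#' @return The estimated mean load `M`.
#' @examples
#' estimate_M(0.10)   # -32 * log(0.9) = 3.372
#' @export
estimate_M <- function(disease_fraction, cousin = cousin_params(),
                       penetrance = 1) {
  stopifnot_scalar_number(disease_fraction, "disease_fraction", min = 0)
  if (disease_fraction >= 1)
    abort_domain("`disease_fraction` must be < 1")
  stopifnot_scalar_number(penetrance, "penetrance", min = 0, max = 1)
  if (penetrance == 0) abort_domain("`penetrance` must be positive")
  -log(1 - disease_fraction) /
    (penetrance * cousin$shared_grandparents * 0.5^cousin$transmission_steps)
}

# Vectorised gene-drop of all grandparental alleles for n offspring:
# each allele runs `steps` independent meioses and is autozygous when
# every one transmits it. Returns the per-offspring autozygous counts.
drop_autozygous_counts <- function(M, n, cousin) {
  loads <- stats::rpois(cousin$shared_grandparents * n, M)
  per_offspring <- colSums(matrix(loads, nrow = cousin$shared_grandparents))
  total <- sum(per_offspring)
  if (total == 0) return(integer(n))
  steps <- cousin$transmission_steps
  flips <- matrix(stats::rbinom(total * steps, 1L, 0.5), ncol = steps)
  autoz <- rowSums(flips) == steps
  tabulate(rep(seq_len(n), per_offspring)[autoz], nbins = n)
}

#' Monte-Carlo check of the cousin-marriage disease fraction
#'
#' Simulates grandparental loads as Poisson(`M`), gene-drops every
#' allele through the first-cousin pedigree meiosis by meiosis, and
#' scores offspring carrying at least one autozygous deleterious locus.
#' Validates the closed forms in [disease_fraction_from_M()].
#'
#' @param M Mean deleterious mutations per adult diploid germ line.
#' @param reps Number of simulated offspring (>= 1000).
#' @param seed Optional integer seed.
#' @param cousin A [cousin_params()] object.
#' @return List with `fraction`, `se`, `reps` and the closed-form
#'   `expected`.
#' @examples
#' cousin_gene_drop_mc(7, reps = 5000, seed = 1)
#' @export
cousin_gene_drop_mc <- function(M, reps = 1e4, seed = NULL,
                                cousin = cousin_params()) {
  stopifnot_scalar_number(M, "M", min = 0)
  if (reps < 1e3) abort_domain("`reps` must be >= 1000")
  if (!is.null(seed)) set.seed(seed)
  counts <- drop_autozygous_counts(M, reps, cousin)
  frac <- mean(counts >= 1L)
  list(fraction = frac, se = sqrt(frac * (1 - frac) / reps), reps = reps,
       expected = disease_fraction_from_M(M, cousin))
}
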