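# Analytic Poisson-load machinery: the zygote load distribution, the
# hard-truncation selection equilibrium, the post-selection adult
# distribution and the X-chromosome share of the load.

new_load_distribution <- function(pmf, truncated) {
  k <- seq_along(pmf) - 1L
  structure(
    list(pmf = pmf, k = k, mean = sum(k * pmf),
         truncated = truncated, k_max = k[length(k)]),
    class = "load_distribution"
  )
}

#' @export
print.load_distribution <- function(x, ...) {
  cat(sprintf("Load distribution over k = 0..%d (%s)\n", x$k_max,
              if (x$truncated) "post-selection" else "zygote"))
  cat(sprintf("  mean load: %.6f\n", x$mean))
  cat(sprintf("  P(k = 0) : %.4f   P(k > mean): %.4f\n",
              x$pmf[1], sum(x$pmf[x$k > x$mean])))
  invisible(x)
}

#' Poisson distribution of deleterious mutations in zygotes
#'
#' Meiosis distributes the parental deleterious mutations at random into
#' gametes, so the number of deleterious mutations a zygote carries is
#' Poisson with mean `M + N`: the adult mean load plus the mean
#' mutational input of one round of gametogenesis.
#'
#' The support is truncated at `k_max`, auto-extended until the excluded
#' upper tail holds less than 1e-14 probability, and renormalised, so
#' the returned mass function sums to one to machine accuracy.
#'
#' @param params A [model_params()] object (fields `M` and `N` are used).
#' @param k_max Optional support bound; extended automatically if the
#'   tail mass beyond it exceeds 1e-14.
#'
#' @return A `load_distribution`: list with `pmf` (probabilities for
#'   `k = 0..k_max`), `k`, `mean`, `truncated = FALSE`, `k_max`.
#' @examples
#' d <- zygote_load_pmf(model_params(M = 7, N = 1))
#' d$mean   # 8
#' @export
zygote_load_pmf <- function(params, k_max = NULL) {
  params <- as_model_params(params)
  lambda <- params$M + params$N
  if (lambda == 0) return(new_load_distribution(1, truncated = FALSE))
  km <- as.integer(stats::qpois(1e-14, lambda, lower.tail = FALSE)) + 2L
  if (!is.null(k_max)) km <- max(km, as.integer(k_max))
  while (stats::ppois(km, lambda, lower.tail = FALSE) >= 1e-14)
    km <- km + 10L
  pmf <- stats::dpois(0:km, lambda)
  new_load_distribution(pmf / sum(pmf), truncated = FALSE)
}

#' Solve the mutation-selection truncation equilibrium
#'
#' At equilibrium the mean load of zygotes is `M + N` but the mean load
#' of the adults they become is back to `M`: selection must remove the
#' mutational input each generation, and it acts on the upper end of the
#' Poisson distribution. This solver finds the minimal such scheme —
#' hard truncation: all zygotes with load below a threshold `k_star`
#' survive, a fraction `accept_at_k_star` of those exactly at the
#' threshold survive, and none above it do — whose survivors have mean
#' load exactly `M`.
#'
#' With `M = 7, N = 1` the solution removes about 19% of zygotes
#' (`k_star = 10`, boundary acceptance 0.93). Graded synergistic
#' selection spread over several load classes removes more — richer
#' multi-system models put the loss near 30% — so the truncation answer
#' is a lower bound on the zygote loss; see
#' [run_generations()] for the graded model.
#'
#' @param params A [model_params()] object.
#' @param tol Tolerance on the post-selection mean (> 0).
#'
#' @return An object of class `selection_solution`: list with `k_star`,
#'   `accept_at_k_star`, `loss_fraction`, `mean_zygote`, `mean_adult`.
#'   When `N = 0` the population is already at equilibrium and the
#'   identity solution (`k_star = Inf`, zero loss) is returned.
#' @examples
#' sol <- solve_truncation_equilibrium(model_params(M = 7, N = 1))
#' sol$loss_fraction   # about 0.19
#' @export
solve_truncation_equilibrium <- function(params, tol = 1e-9) {
  params <- as_model_params(params)
  if (!is.numeric(tol) || length(tol) != 1L || tol <= 0)
    abort_domain("`tol` must be a single positive number")
  M <- params$M
  if (params$N == 0) {
    return(structure(
      list(k_star = Inf, accept_at_k_star = 1, loss_fraction = 0,
           mean_zygote = M, mean_adult = M),
      class = "selection_solution"
    ))
  }
  dist <- zygote_load_pmf(params)
  p <- dist$pmf
  k <- dist$k
  # Survivors: all k < K plus fraction a of k = K. The conditional mean
  # of the fully truncated distribution increases with K towards M + N,
  # so the smallest K whose truncated mean reaches M admits a boundary
  # acceptance a in [0, 1] hitting M exactly.
  cum_p <- cumsum(p)
  cum_kp <- cumsum(k * p)
  sol <- NULL
  for (K in k[-1]) {
    S0 <- cum_p[K]          # mass of k < K (indices 1..K are k = 0..K-1)
    S1 <- cum_kp[K]
    pK <- p[K + 1]
    if (pK <= 0 || K == M) next
    a <- (M * S0 - S1) / (pK * (K - M))
    if (is.finite(a) && a >= 0 && a <= 1) {
      surv <- S0 + a * pK
      mean_adult <- (S1 + a * K * pK) / surv
      if (abs(mean_adult - M) <= tol) {
        sol <- list(k_star = K, accept_at_k_star = a,
                    loss_fraction = 1 - surv,
                    mean_zygote = dist$mean, mean_adult = mean_adult)
        break
      }
    }
  }
  if (is.null(sol))
    abort_solver("truncation equilibrium did not converge",
                 diagnostics = list(M = M, N = params$N, tol = tol,
                                    k_max = dist$k_max))
  structure(sol, class = "selection_solution")
}

#' @export
print.selection_solution <- function(x, ...) {
  cat("Truncation-selection equilibrium\n")
  if (is.infinite(x$k_star)) {
    cat("  identity solution (N = 0): no zygotes removed\n")
  } else {
    cat(sprintf("  threshold k*        : %d\n", x$k_star))
    cat(sprintf("  acceptance at k*    : %.6f\n", x$accept_at_k_star))
    cat(sprintf("  zygote loss fraction: %.6f\n", x$loss_fraction))
  }
  cat(sprintf("  mean load, zygotes  : %.6f\n", x$mean_zygote))
  cat(sprintf("  mean load, adults   : %.6f\n", x$mean_adult))
  invisible(x)
}

#' Apply a truncation-selection solution to a zygote load distribution
#'
#' Removes the mass above `k_star`, keeps the fraction
#' `accept_at_k_star` of the boundary class, and renormalises — giving
#' the load distribution of adults.
#'
#' @param dist A `load_distribution` from [zygote_load_pmf()].
#' @param sol A `selection_solution` from
#'   [solve_truncation_equilibrium()], produced for the same parameters.
#'
#' @return A `load_distribution` with `truncated = TRUE` and support
#'   ending at `k_star`. The identity solution returns `dist` unchanged.
#' @examples
#' p <- model_params(M = 7, N = 1)
#' adult <- apply_selection(zygote_load_pmf(p), solve_truncation_equilibrium(p))
#' adult$mean   # 7
#' @export
apply_selection <- function(dist, sol) {
  if (!inherits(dist, "load_distribution"))
    abort_contract("`dist` must be a load_distribution")
  if (!inherits(sol, "selection_solution"))
    abort_contract("`sol` must be a selection_solution")
  if (is.infinite(sol$k_star)) return(dist)
  if (sol$k_star > dist$k_max)
    abort_contract("selection solution support exceeds distribution support")
  K <- sol$k_star
  pmf <- dist$pmf[seq_len(K + 1L)]
  pmf[K + 1L] <- pmf[K + 1L] * sol$accept_at_k_star
  new_load_distribution(pmf / sum(pmf), truncated = TRUE)
}

#' Expected deleterious load on the X chromosome
#'
#' The X carries about 5% of the haploid genome; among the `M`
#' deleterious mutations spread over the diploid complement, the single
#' X-chromosome share is `M * x_fraction / 2` — about `M / 40` at the
#' default 5%. Deleterious X alleles that are lethal in males are never
#' observed in male carriers, so a male-viability factor below one
#' scales the expectation down for male cohorts.
#'
#' @param params A [model_params()] object.
#' @param male_viability Fraction of X-linked deleterious alleles
#'   compatible with male survival, in `[0, 1]`; default 1.
#'
#' @return Expected count of deleterious mutations on one X chromosome.
#' @examples
#' x_linked_expected_load(model_params(M = 7))   # 0.175 = 7/40
#' @export
x_linked_expected_load <- function(params, male_viability = 1.0) {
  params <- as_model_params(params)
  stopifnot_scalar_number(male_viability, "male_viability", min = 0, max = 1)
  params$M * params$x_fraction_haploid / 2 * male_viability
}

#' Export zygote and adult load distributions as a TSV table
#'
#' Writes columns `k`, `p_zygote`, `p_adult` (the adult column padded
#' with zeros above the truncation point).
#'
#' @param zygote,adult `load_distribution` objects on the same model.
#' @param file Path to write; `""` writes to stdout.
#' @return The exported data frame, invisibly.
#' @export
export_load_distributions <- function(zygote, adult, file = "") {
  if (!inherits(zygote, "load_distribution") ||
      !inherits(adult, "load_distribution"))
    abort_contract("inputs must be load_distribution objects")
  km <- max(zygote$k_max, adult$k_max)
  pad <- function(d) c(d$pmf, rep(0, km - d$k_max))
  out <- data.frame(k = 0:km, p_zygote = pad(zygote), p_adult = pad(adult))
  utils::write.table(out, file = file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}
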