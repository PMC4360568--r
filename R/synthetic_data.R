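# Seeded generators of the synthetic cohorts the estimators are
# validated on: populations with Poisson loads, first-cousin offspring
# with gene-dropped autozygous counts, and X-linked case/control
# cohorts. Every cohort echoes its full generating parameters
# (including the seed) so it can be regenerated bit-identically.

new_cohort <- function(records, kind, params) {
  structure(records, kind = kind, generator_params = params,
            class = c("synthetic_cohort", "data.frame"))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  p <- attr(x, "generator_params")
  cat(sprintf("Synthetic cohort '%s': %d records\n", attr(x, "kind"),
              nrow(x)))
  cat("  params:", paste(names(p), unlist(p), sep = "=", collapse = ", "),
      "\n")
  if (nrow(x)) print(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' Simulate a population with Poisson deleterious loads
#'
#' Draws `n` adults whose diploid deleterious load is Poisson(`M`),
#' with sex assigned 1:1 and the X-linked portion of each load thinned
#' out binomially at rate `x_fraction_haploid / 2` (expectation `M/40`
#' at the defaults).
#'
#' @param params A [model_params()] object.
#' @param n Number of individuals (>= 0).
#' @param seed Integer seed.
#' @return A `synthetic_cohort` data frame with columns `id`, `load`,
#'   `sex`, `x_count`.
#' @examples
#' simulate_population(model_params(), n = 5, seed = 1)
#' @export
simulate_population <- function(params = model_params(), n, seed = 1) {
  params <- as_model_params(params)
  stopifnot_scalar_number(n, "n", min = 0)
  set.seed(seed)
  n <- as.integer(n)
  load <- stats::rpois(n, params$M)
  records <- data.frame(
    id = seq_len(n),
    load = load,
    sex = ifelse(stats::runif(n) < 0.5, "male", "female"),
    x_count = stats::rbinom(n, load, params$x_fraction_haploid / 2)
  )
  new_cohort(records, "population",
             list(M = params$M,
                  x_fraction_haploid = params$x_fraction_haploid,
                  n = n, seed = seed))
}

#' Simulate first-cousin offspring by pedigree gene dropping
#'
#' For each offspring, the two shared grandparents receive independent
#' Poisson(`M`) heterozygous deleterious loads and every allele is
#' dropped through the six meioses of the first-cousin pedigree; the
#' autozygous count is the number of alleles surviving all six, and the
#' disease flag marks offspring with at least one.
#'
#' @param M Mean deleterious mutations per adult diploid germ line.
#' @param n Number of offspring (>= 1).
#' @param seed Integer seed.
#' @param cousin A [cousin_params()] object.
#' @return A `synthetic_cohort` data frame with columns `id`,
#'   `autozygous_load`, `disease`.
#' @examples
#' simulate_cousin_cohort(7, n = 10, seed = 1)
#' @export
simulate_cousin_cohort <- function(M, n, seed = 1,
                                   cousin = cousin_params()) {
  stopifnot_scalar_number(M, "M", min = 0)
  stopifnot_scalar_number(n, "n", min = 1)
  set.seed(seed)
  n <- as.integer(n)
  counts <- drop_autozygous_counts(M, n, cousin)
  records <- data.frame(id = seq_len(n), autozygous_load = counts,
                        disease = counts >= 1L)
  new_cohort(records, "cousin_offspring",
             list(M = M, n = n, seed = seed,
                  shared_grandparents = cousin$shared_grandparents,
                  transmission_steps = cousin$transmission_steps))
}

#' Simulate an X-linked case/control cohort
#'
#' Draws carrier flags for male cases and control males under the
#' attribution model of the carrier-risk algebra: controls carry the
#' mutation at the population prevalence `p`, cases at
#' `rr * p / (1 + p * (rr - 1))` — the same expression
#' [case_carrier_fraction()] evaluates, called here so the two modules
#' share one source of truth.
#'
#' @param p Population carrier prevalence among males, in `[0, 1]`.
#' @param rr Relative risk of death for carrier males (>= 1).
#' @param n_cases,n_controls Cohort sizes.
#' @param seed Integer seed.
#' @return A `synthetic_cohort` data frame with columns `id`, `group`
#'   (`"case"`/`"control"`) and `carrier` (logical).
#' @examples
#' simulate_case_control(0.25, 3, 100, 100, seed = 1)
#' @export
simulate_case_control <- function(p, rr, n_cases, n_controls, seed = 1) {
  stopifnot_scalar_number(p, "p", min = 0, max = 1)
  stopifnot_scalar_number(rr, "rr", min = 1)
  stopifnot_scalar_number(n_cases, "n_cases", min = 0)
  stopifnot_scalar_number(n_controls, "n_controls", min = 0)
  sex_ratio <- implied_sex_ratio(p, rr)
  case_rate <- if (rr > 1 && p > 0)
    case_carrier_fraction(rr, sex_ratio = sex_ratio)
  else p                                  # null model: groups exchangeable
  if (case_rate > 1) abort_domain("infeasible case carrier rate")
  set.seed(seed)
  n_cases <- as.integer(n_cases); n_controls <- as.integer(n_controls)
  records <- data.frame(
    id = seq_len(n_cases + n_controls),
    group = rep(c("case", "control"), c(n_cases, n_controls)),
    carrier = c(stats::runif(n_cases) < case_rate,
                stats::runif(n_controls) < p)
  )
  new_cohort(records, "case_control",
             list(p = p, rr = rr, n_cases = n_cases,
                  n_controls = n_controls, seed = seed))
}

#' Write a synthetic cohort as a self-describing TSV
#'
#' The file opens with a commented header block (`# key: value`)
#' echoing the cohort kind and every generator parameter including the
#' seed, followed by a tab-separated table, so the cohort can be
#' regenerated exactly from the file alone.
#'
#' @param cohort A `synthetic_cohort`.
#' @param file Path to write.
#' @return `file`, invisibly.
#' @export
write_cohort <- function(cohort, file) {
  if (!inherits(cohort, "synthetic_cohort"))
    abort_contract("`cohort` must be a synthetic_cohort")
  p <- attr(cohort, "generator_params")
  header <- c(sprintf("# kind: %s", attr(cohort, "kind")),
              sprintf("# %s: %s", names(p), vapply(p, format, character(1))))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(as.data.frame(cohort), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a synthetic cohort written by [write_cohort()]
#'
#' @param file Path to a cohort TSV.
#' @return A `synthetic_cohort` with the parameters restored from the
#'   header.
#' @export
read_cohort <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^# ", lines)
  meta <- sub("^# ", "", lines[hdr])
  keys <- sub(":.*$", "", meta)
  vals <- sub("^[^:]*: *", "", meta)
  params <- lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (is.na(num)) v else num
  })
  names(params) <- keys
  records <- utils::read.delim(textConnection(lines[-hdr]))
  kind <- params$kind
  params$kind <- NULL
  new_cohort(records, kind, params)
}
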