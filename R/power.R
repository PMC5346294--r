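#' Noncentrality parameter of the 1-df association test
#'
#' Under an additive genetic model explaining little phenotypic variance,
#' the standard association test statistic is chi-squared with one degree of
#' freedom and noncentrality parameter (NCP)
#' `2 N f (1 - f) b^2` for a quantitative trait, where `N` is the sample
#' size, `f` the minor allele frequency and `b` the additive effect of the
#' minor allele in phenotypic s.d. units. For a case-control design the NCP
#' is `2 N f (1 - f) r (1 - r) b^2`, where `N` is cases plus controls, `r`
#' the case proportion and `b` the additive effect on the log-odds
#' (`b = log(OR)`).
#'
#' @param n Total sample size.
#' @param maf Minor allele frequency in (0, 0.5].
#' @param beta Additive effect size; for case-control, the log odds ratio
#'   (alternatively supply `or`).
#' @param trait `"quantitative"` or `"case_control"`.
#' @param case_prop Proportion of cases (case-control only).
#' @param or Odds ratio; converted to `beta = log(or)`.
#' @return The noncentrality parameter (nonnegative scalar).
#' @export
assoc_ncp <- function(n, maf, beta = NULL,
                      trait = c("quantitative", "case_control"),
                      case_prop = NULL, or = NULL) {
  trait <- match.arg(trait)
  if (is.null(beta)) {
    if (is.null(or)) stop("supply beta or or")
    beta <- log(or)
  }
  stopifnot(n >= 1, maf > 0, maf <= 0.5, is.finite(beta))
  ncp <- 2 * n * maf * (1 - maf) * beta^2
  if (trait == "case_control") {
    if (is.null(case_prop))
      stop("case_prop is required for case-control queries")
    stopifnot(case_prop > 0, case_prop < 1)
    ncp <- ncp * case_prop * (1 - case_prop)
  }
  ncp
}

#' Association power under the noncentral chi-square model
#'
#' Power is the probability that a 1-df noncentral chi-square variable with
#' the NCP of [assoc_ncp()] exceeds the central chi-square critical value at
#' `alpha`. For one degree of freedom this equals
#' `pnorm(sqrt(ncp) - sqrt(crit)) + pnorm(-sqrt(ncp) - sqrt(crit))`.
#'
#' @inheritParams assoc_ncp
#' @param alpha Significance level; defaults to genome-wide 5e-8.
#' @return A list of class `power_result`: `ncp`, `critical`, `power`.
#' @export
assoc_power <- function(n, maf, beta = NULL,
                        trait = c("quantitative", "case_control"),
                        case_prop = NULL, or = NULL, alpha = 5e-8) {
  stopifnot(alpha > 0, alpha < 1)
  trait <- match.arg(trait)
  ncp <- assoc_ncp(n, maf, beta, trait, case_prop, or)
  critical <- qchisq(alpha, df = 1, lower.tail = FALSE)
  structure(list(ncp = ncp, critical = critical,
                 power = pchisq(critical, df = 1, ncp = ncp,
                                lower.tail = FALSE)),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  ## display truncates to whole percent; full precision kept in the object
  cat(sprintf("ncp = %.3f, critical = %.3f, power = %d%%\n",
              x$ncp, x$critical, trunc(100 * x$power)))
  invisible(x)
}

#' Smallest sample size reaching a target power
#'
#' Bisection over integer `N` exploiting monotonicity of power in `N`; the
#' returned `N` satisfies `power(N) >= target_power` and
#' `power(N - 1) < target_power`.
#'
#' @inheritParams assoc_power
#' @param target_power Desired power, in `(alpha, 1)`.
#' @return Minimal integer sample size.
#' @export
required_n <- function(maf, beta = NULL,
                       trait = c("quantitative", "case_control"),
                       case_prop = NULL, or = NULL, alpha = 5e-8,
                       target_power = 0.8) {
  trait <- match.arg(trait)
  stopifnot(target_power > alpha, target_power < 1)
  pw <- function(n) assoc_power(n, maf, beta, trait, case_prop, or, alpha)$power
  if (pw(1) >= target_power) return(1L)
  if (assoc_ncp(1, maf, beta, trait, case_prop, or) <= 0)
    stop("zero effect size: target power is unreachable")
  hi <- 2
  while (pw(hi) < target_power) {
    hi <- hi * 2
    if (hi > 2^40) stop("target power unreachable at any realistic N")
  }
  lo <- hi %/% 2   # pw(lo) < target <= pw(hi)
  while (hi - lo > 1) {
    mid <- (lo + hi) %/% 2
    if (pw(mid) >= target_power) hi <- mid else lo <- mid
  }
  as.integer(hi)
}

#' Equivalent sample size in a second population
#'
#' The sample size `N2` needed in population 2 for the same association
#' power as `N1` individuals in population 1, assuming equal effect size and
#' case proportion: `N2 = N1 * f1 (1 - f1) / (f2 (1 - f2))`. The two
#' designs' NCPs are then identical by construction, so for a variant
#' enriched to twice the frequency (small `f`), roughly half the sample is
#' needed.
#'
#' @param n1 Sample size in population 1.
#' @param f1,f2 Minor allele frequencies in populations 1 and 2, in (0, 0.5].
#' @return Real-valued equivalent sample size `N2`.
#' @export
equivalent_n <- function(n1, f1, f2) {
  stopifnot(n1 > 0, f1 > 0, f1 <= 0.5, f2 > 0, f2 <= 0.5)
  n1 * f1 * (1 - f1) / (f2 * (1 - f2))
}
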