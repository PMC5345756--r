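# Stopping boundaries for group sequential tests.
#
# The sequential z statistics (Z_1, ..., Z_K) at information fractions
# t_1 < ... < t_K = 1 are jointly normal with cor(Z_i, Z_j) = sqrt(t_i/t_j)
# and E[Z_k] = drift * sqrt(t_k).  First-crossing probabilities of a
# two-sided boundary are obtained by the classic stagewise recursion over
# the density of the score process S_k = Z_k * sqrt(t_k), whose increments
# are independent N(drift * dt, dt).

#' Per-stage boundary crossing probabilities
#'
#' Computes, for each stage, the probability that a sequence of correlated
#' standardized test statistics first crosses the two-sided boundary
#' `|Z_k| >= z_bounds[k]` at that stage.  With `drift = 0` the result gives
#' the stagewise type I error contributions of the boundary.
#'
#' The recursion integrates the sub-density of the score process over the
#' continuation region with a Gauss-Legendre rule (`nodes` nodes per stage),
#' which reproduces published group sequential constants to at least four
#' decimals with the default 256 nodes.
#'
#' @param z_bounds Positive finite boundary values on the z scale, one per stage.
#' @param schedule A [stage_schedule()] (or cumulative n vector) with the same
#'   number of stages.
#' @param drift Mean of the final-stage z statistic, `E[Z_K]`.  For a
#'   two-group comparison with standardized effect d and final per-group
#'   size n, `drift = d * sqrt(n / 2)`.
#' @param nodes Number of Gauss-Legendre nodes per stage.
#' @return Numeric vector of per-stage first-crossing probabilities; the sum
#'   over stages is at most 1.
#' @examples
#' sched <- stage_schedule(c(6, 12, 18))
#' crossing_probability(c(3.47, 2.45, 2.00), sched)
#' @export
crossing_probability <- function(z_bounds, schedule, drift = 0, nodes = 256L) {
  schedule <- as_schedule(schedule)
  K <- schedule$n_stages
  if (!is.numeric(z_bounds) || length(z_bounds) != K ||
      any(!is.finite(z_bounds)) || any(z_bounds <= 0)) {
    abort_domain("`z_bounds` must be positive finite values, one per stage.")
  }
  if (!is.numeric(drift) || length(drift) != 1L || !is.finite(drift)) {
    abort_domain("`drift` must be a single finite number.")
  }
  tfrac <- schedule$information_fractions
  b <- z_bounds * sqrt(tfrac) # bounds on the score scale

  gl <- pracma::gaussLegendre(as.integer(nodes), -1, 1)
  out <- numeric(K)

  # stage 1: mass inside the continuation region
  x <- gl$x * b[1]
  w <- gl$w * b[1]
  g <- dnorm(x, mean = drift * tfrac[1], sd = sqrt(tfrac[1])) * w
  out[1] <- 1 - sum(g)

  if (K > 1L) {
    for (k in 2:K) {
      dt_k <- tfrac[k] - tfrac[k - 1]
      x_new <- gl$x * b[k]
      w_new <- gl$w * b[k]
      inc <- dnorm(outer(x_new, x, "-"), mean = drift * dt_k, sd = sqrt(dt_k))
      g_new <- as.vector(inc %*% g) * w_new
      out[k] <- sum(g) - sum(g_new)
      x <- x_new
      g <- g_new
    }
  }
  pmax(out, 0)
}

new_gs_boundary <- function(stage, tfrac, z_bound, family, overall_alpha,
                            constant, attained_alpha) {
  out <- tibble::tibble(
    stage = stage,
    information_fraction = tfrac,
    z_bound = z_bound,
    nominal_level = 2 * pnorm(-z_bound)
  )
  structure(out,
    class = c("gs_boundary", class(out)),
    family = family, overall_alpha = overall_alpha,
    constant = constant, attained_alpha = attained_alpha
  )
}

# bisection for the boundary-family constant c such that the total
# two-sided crossing probability equals `overall_alpha` (drift 0)
solve_boundary_constant <- function(shape, schedule, overall_alpha,
                                    interval = c(1, 6), tol = 1e-6,
                                    nodes = 256L) {
  total <- function(cc) {
    sum(crossing_probability(shape(cc), schedule, drift = 0, nodes = nodes))
  }
  lo <- interval[1]
  hi <- interval[2]
  f_lo <- total(lo) - overall_alpha
  f_hi <- total(hi) - overall_alpha
  if (is.na(f_lo) || is.na(f_hi) || f_lo * f_hi > 0) {
    abort_numerical("Root search for the boundary constant does not bracket the target overall alpha.")
  }
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    f_mid <- total(mid) - overall_alpha
    if (abs(f_mid) <= tol || (hi - lo) / 2 < 1e-9) break
    if (f_lo * f_mid <= 0) {
      hi <- mid
      f_hi <- f_mid
    } else {
      lo <- mid
      f_lo <- f_mid
    }
  }
  mid
}

boundary_family <- function(family, K, overall_alpha, schedule, nodes = 256L) {
  if (is.null(schedule)) schedule <- equal_fraction_schedule(K)
  schedule <- as_schedule(schedule)
  if (schedule$n_stages != K) {
    abort_schedule("`schedule` must have exactly `K` stages.")
  }
  if (!is_probability(overall_alpha) || overall_alpha >= 0.5) {
    abort_domain("`overall_alpha` must lie in (0, 0.5).")
  }
  kk <- seq_len(K)
  shape <- switch(family,
    obf = function(cc) cc * sqrt(K / kk),
    pocock = function(cc) rep(cc, K)
  )
  cc <- solve_boundary_constant(shape, schedule, overall_alpha, nodes = nodes)
  zb <- shape(cc)
  attained <- sum(crossing_probability(zb, schedule, 0, nodes = nodes))
  new_gs_boundary(kk, schedule$information_fractions, zb, family,
                  overall_alpha, cc, attained)
}

# a helper schedule with equal information fractions (unit sizes 1..K
# scaled); only the fractions matter for boundary computation
equal_fraction_schedule <- function(K) {
  stage_schedule(2L * seq_len(K))
}

#' O'Brien-Fleming stopping boundary
#'
#' Finds the constant `c` such that the boundary `z_k = c * sqrt(K / k)`
#' has total two-sided crossing probability `overall_alpha` under the null,
#' and returns the per-stage boundary together with the nominal two-sided
#' significance levels `2 * (1 - pnorm(z_k))`.  The O'Brien-Fleming family
#' is very conservative at early looks and spends almost the full alpha at
#' the final analysis.
#'
#' @param K Number of stages (>= 1).
#' @param overall_alpha Target overall two-sided type I error, in (0, 0.5).
#' @param schedule Optional [stage_schedule()]; defaults to equally spaced
#'   information fractions.
#' @param nodes Gauss-Legendre nodes per stage for the crossing recursion.
#' @return A `gs_boundary` tibble with columns `stage`,
#'   `information_fraction`, `z_bound`, `nominal_level`, and attributes
#'   `family`, `overall_alpha`, `constant` and `attained_alpha`.
#' @examples
#' obf_levels(K = 2, overall_alpha = 0.05)
#' @export
obf_levels <- function(K, overall_alpha = 0.05, schedule = NULL, nodes = 256L) {
  if (K == 1L) {
    return(single_stage_boundary("obf", overall_alpha))
  }
  boundary_family("obf", K, overall_alpha, schedule, nodes)
}

#' Pocock stopping boundary
#'
#' Constant z boundary across stages: the same nominal significance level is
#' applied at every analysis, chosen so that the total two-sided crossing
#' probability under the null equals `overall_alpha`.
#'
#' @inheritParams obf_levels
#' @return A `gs_boundary` tibble; see [obf_levels()].
#' @examples
#' pocock_levels(K = 3, overall_alpha = 0.05)
#' @export
pocock_levels <- function(K, overall_alpha = 0.05, schedule = NULL, nodes = 256L) {
  if (K == 1L) {
    return(single_stage_boundary("pocock", overall_alpha))
  }
  boundary_family("pocock", K, overall_alpha, schedule, nodes)
}

single_stage_boundary <- function(family, overall_alpha) {
  if (!is_probability(overall_alpha) || overall_alpha >= 0.5) {
    abort_domain("`overall_alpha` must lie in (0, 0.5).")
  }
  z <- qnorm(1 - overall_alpha / 2)
  new_gs_boundary(1L, 1, z, family, overall_alpha, z, overall_alpha)
}

#' Haybittle-Peto stopping boundary
#'
#' All interim analyses use the stringent nominal level 0.001; the final
#' analysis uses the unadjusted `overall_alpha`.  No recalibration is
#' applied, so the attained overall type I error slightly exceeds
#' `overall_alpha` (by construction less than `overall_alpha + (K-1)/1000`).
#'
#' @param K Number of stages (>= 2).
#' @param overall_alpha Final-stage nominal level (default 0.05).
#' @param interim_level Nominal level at each interim analysis.
#' @param schedule Optional [stage_schedule()]; defaults to equally spaced
#'   information fractions.
#' @return A `gs_boundary` tibble; see [obf_levels()].
#' @examples
#' haybittle_peto_levels(K = 3)
#' @export
haybittle_peto_levels <- function(K, overall_alpha = 0.05,
                                  interim_level = 0.001, schedule = NULL) {
  if (!is.numeric(K) || length(K) != 1L || K < 2L) {
    abort_domain("Haybittle-Peto boundaries need at least two stages (K >= 2).")
  }
  K <- as.integer(K)
  if (is.null(schedule)) schedule <- equal_fraction_schedule(K)
  schedule <- as_schedule(schedule)
  levels <- c(rep(interim_level, K - 1L), overall_alpha)
  zb <- qnorm(1 - levels / 2)
  attained <- sum(crossing_probability(zb, schedule, 0))
  new_gs_boundary(seq_len(K), schedule$information_fractions, zb,
                  "haybittle_peto", overall_alpha, NA_real_, attained)
}

#' Custom stopping boundary from nominal levels
#'
#' Wraps an arbitrary set of per-stage two-sided nominal significance levels
#' (for example levels taken from a published design) as a `gs_boundary`,
#' computing the attained overall type I error by the crossing recursion.
#'
#' @param nominal_levels Per-stage two-sided nominal levels, each in (0, 1).
#' @param schedule Optional [stage_schedule()]; defaults to equally spaced
#'   information fractions.
#' @param overall_alpha The design's stated overall alpha (annotation only).
#' @return A `gs_boundary` tibble; see [obf_levels()].
#' @examples
#' custom_levels(c(0.0006, 0.0151, 0.0471))
#' @export
custom_levels <- function(nominal_levels, schedule = NULL, overall_alpha = 0.05) {
  if (!is_probability(nominal_levels)) {
    abort_domain("`nominal_levels` must all lie in (0, 1).")
  }
  K <- length(nominal_levels)
  if (is.null(schedule)) schedule <- equal_fraction_schedule(K)
  schedule <- as_schedule(schedule)
  if (schedule$n_stages != K) {
    abort_schedule("`schedule` length must match `nominal_levels`.")
  }
  zb <- qnorm(1 - nominal_levels / 2)
  attained <- sum(crossing_probability(zb, schedule, 0))
  new_gs_boundary(seq_len(K), schedule$information_fractions, zb, "custom",
                  overall_alpha, NA_real_, attained)
}

#' @export
print.gs_boundary <- function(x, ...) {
  cat("<gs_boundary> family = ", attr(x, "family"),
      ", overall alpha = ", attr(x, "overall_alpha"),
      ", attained alpha = ", signif(attr(x, "attained_alpha"), 4), "\n", sep = "")
  NextMethod()
}

#' @method tidy gs_boundary
#' @export
tidy.gs_boundary <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::mutate(
      family = attr(x, "family"),
      overall_alpha = attr(x, "overall_alpha"),
      .before = 1
    )
}

#' @method glance gs_boundary
#' @export
glance.gs_boundary <- function(x, ...) {
  tibble::tibble(
    family = attr(x, "family"),
    n_stages = nrow(x),
    overall_alpha = attr(x, "overall_alpha"),
    attained_alpha = attr(x, "attained_alpha"),
    constant = attr(x, "constant")
  )
}

#' Export a boundary as JSON records
#'
#' Writes one record per stage with fields `family`, `alpha`, `stage`,
#' `z_bound` and `nominal_level`.
#'
#' @param x A `gs_boundary`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_boundary_json <- function(x, path) {
  stopifnot(inherits(x, "gs_boundary"))
  recs <- tibble::as_tibble(x) |>
    dplyr::transmute(
      family = attr(x, "family"),
      alpha = attr(x, "overall_alpha"),
      stage = .data$stage,
      z_bound = .data$z_bound,
      nominal_level = .data$nominal_level
    )
  jsonlite::write_json(recs, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
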