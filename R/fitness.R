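#' Sigmoid clone-growth model and closed-form clonal fitness
#'
#' Clone size is tracked as the variant allele frequency (VAF) of a
#' heterozygous autosomal somatic mutation, so a fully clonal clone has
#' VAF 1/2. Growth over time is modelled as a sigmoid
#' \deqn{v(t) = \frac{1}{2}\,\frac{1}{1 + A e^{-st}}}
#' where \eqn{t} is time in years, \eqn{s} is the clonal fitness (per year)
#' and \eqn{A} is a constant fixed so that \eqn{v(0)} equals the VAF at the
#' first timepoint. Because the model has a single free rate parameter, two
#' serial observations determine \eqn{s} in closed form (see
#' [fit_fitness()]).
#'
#' @name sigmoid-model
#' @keywords internal
NULL

#' Intercept constant of the sigmoid clone-growth model
#'
#' Returns the constant \eqn{A} such that the sigmoid
#' \eqn{v(t) = \tfrac12 (1 + A e^{-st})^{-1}} satisfies \eqn{v(0) = v_0}:
#' \eqn{A = 1/(2 v_0) - 1}.
#'
#' @param v0 Numeric vector of VAF fractions, each in the open interval
#'   (0, 0.5). Callers must clamp boundary values first; see [fit_fitness()].
#' @return Numeric vector of positive constants \eqn{A}.
#' @examples
#' solve_A(0.25) # 1
#' solve_A(0.05) # 9
#' @export
solve_A <- function(v0) {
  if (any(!is.finite(v0)) || any(v0 <= 0) || any(v0 >= 0.5)) {
    stop("v0 must lie in the open interval (0, 0.5); clamp first", call. = FALSE)
  }
  1 / (2 * v0) - 1
}

#' Evaluate the sigmoid clone-size model
#'
#' @param t Time in years (vector).
#' @param v0 VAF at t = 0, in (0, 0.5).
#' @param s Clonal fitness per year.
#' @return VAF fraction at each time, always in (0, 0.5).
#' @export
sigmoid_vaf <- function(t, v0, s) {
  A <- solve_A(v0)
  0.5 / (1 + A * exp(-s * t))
}

#' Simulate a true VAF trajectory under piecewise-constant fitness
#'
#' Propagates a clone's true VAF through consecutive treatment phases, each
#' with its own fitness. Within a phase the trajectory follows the sigmoid
#' model; at a phase boundary the next phase re-anchors its intercept
#' constant at the previous phase's end VAF, so the trajectory is continuous.
#'
#' @param v0 True VAF fraction at time 0, in (0, 0.5).
#' @param s_by_phase Either a single numeric fitness (one phase of unbounded
#'   duration) or a two-column structure of phases: a list of
#'   `c(duration_years, s)` pairs or a data.frame with columns `duration`
#'   and `s`. Durations must be non-negative; the final phase is extended
#'   to cover any evaluation time beyond the listed durations.
#' @param eval_times Numeric vector of times (years, >= 0) at which to
#'   evaluate the trajectory.
#' @return Numeric vector of true VAF fractions, one per evaluation time.
#' @examples
#' simulate_trajectory(0.05, log(6), eval_times = 1) # 0.20
#' @export
simulate_trajectory <- function(v0, s_by_phase, eval_times) {
  if (!is.finite(v0) || v0 <= 0 || v0 >= 0.5) {
    stop("v0 must lie in the open interval (0, 0.5)", call. = FALSE)
  }
  phases <- .normalize_phases(s_by_phase)
  if (any(phases$duration < 0)) stop("phase durations must be >= 0", call. = FALSE)
  if (any(eval_times < 0)) stop("eval_times must be >= 0", call. = FALSE)

  starts <- cumsum(c(0, phases$duration[-nrow(phases)]))
  # VAF at the start of each phase, obtained by chaining phase endpoints
  v_start <- numeric(nrow(phases))
  v_start[1] <- v0
  if (nrow(phases) > 1) {
    for (k in seq_len(nrow(phases) - 1)) {
      v_start[k + 1] <- sigmoid_vaf(phases$duration[k], v_start[k], phases$s[k])
    }
  }
  vapply(eval_times, function(t) {
    k <- findInterval(t, starts)    # last phase whose start <= t
    sigmoid_vaf(t - starts[k], v_start[k], phases$s[k])
  }, numeric(1))
}

.normalize_phases <- function(s_by_phase) {
  if (is.numeric(s_by_phase) && length(s_by_phase) == 1 && is.null(dim(s_by_phase))) {
    return(data.frame(duration = Inf, s = s_by_phase))
  }
  if (is.data.frame(s_by_phase)) {
    stopifnot(all(c("duration", "s") %in% names(s_by_phase)))
    return(s_by_phase[, c("duration", "s")])
  }
  if (is.list(s_by_phase)) {
    m <- do.call(rbind, s_by_phase)
    return(data.frame(duration = m[, 1], s = m[, 2]))
  }
  stop("s_by_phase must be a single fitness, a list of (duration, s) pairs, ",
       "or a data.frame with columns duration and s", call. = FALSE)
}

#' Growth category from a fitness estimate
#'
#' Clones are categorized as `increasing` if the fitness exceeds +0.25 per
#' year, `decreasing` below -0.25 per year, and `stable` otherwise. The
#' boundaries are strict inequalities, so s = +/-0.25 exactly is `stable`.
#'
#' @param s Numeric vector of fitness values (per year).
#' @param threshold Category half-width in per-year units (default 0.25).
#' @return Character vector in `c("increasing", "stable", "decreasing")`.
#' @export
categorize_fitness <- function(s, threshold = 0.25) {
  stopifnot(is.numeric(s), threshold >= 0)
  out <- rep("stable", length(s))
  out[s > threshold] <- "increasing"
  out[s < -threshold] <- "decreasing"
  out[!is.finite(s)] <- NA_character_
  out
}

#' Closed-form clonal fitness from two serial VAF observations
#'
#' Inverts the sigmoid clone-growth model for a pair of serial VAFs:
#' \deqn{s = \frac{1}{\Delta t}\,\ln\frac{1/(2 v_0) - 1}{1/(2 v_1) - 1}.}
#' Observed VAFs are clamped into `[floor, ceiling]` before inversion; the
#' lower bound is the 0.1% detection floor of error-corrected variant
#' calling and the upper bound keeps the estimate away from the VAF = 0.5
#' singularity (VAFs at or above 50% arise under loss of heterozygosity and
#' are outside the heterozygous model). Estimates that needed clamping at
#' either endpoint are flagged `censored`.
#'
#' @param v0,v1 Observed VAF fractions at the first and second timepoint
#'   (vectors, recycled to common length).
#' @param dt_years Positive time between the observations, in years.
#' @param floor,ceiling Clamping bounds (defaults 0.001 and 0.499).
#' @param threshold Category half-width passed to [categorize_fitness()].
#' @return A data.frame with columns `s` (per year), `A` (intercept constant
#'   at the first timepoint), `category` and `censored`.
#' @examples
#' fit_fitness(0.05, 0.20, 1)$s # log(6)
#' @export
fit_fitness <- function(v0, v1, dt_years, floor = 0.001, ceiling = 0.499,
                        threshold = 0.25) {
  if (any(dt_years <= 0)) stop("dt_years must be > 0", call. = FALSE)
  n <- max(length(v0), length(v1), length(dt_years))
  v0 <- rep_len(v0, n); v1 <- rep_len(v1, n); dt_years <- rep_len(dt_years, n)
  censored <- v0 < floor | v0 > ceiling | v1 < floor | v1 > ceiling
  v0c <- pmin(pmax(v0, floor), ceiling)
  v1c <- pmin(pmax(v1, floor), ceiling)
  A0 <- solve_A(v0c)
  A1 <- solve_A(v1c)
  s <- log(A0 / A1) / dt_years
  data.frame(
    s = s,
    A = A0,
    category = categorize_fitness(s, threshold),
    censored = censored
  )
}

#' Per-phase fitness decomposition over a three-timepoint trajectory
#'
#' Splits a three-timepoint VAF trajectory (treatment start, maintenance
#' start, end of treatment) into two phase-wise fitness estimates: the
#' chemotherapy (carboplatin) phase between the first two timepoints and
#' the maintenance (PARP inhibitor) phase between the last two. Each phase
#' is fit independently, re-anchoring the intercept constant at its own
#' start VAF.
#'
#' @param times Numeric vector of three strictly increasing times (years).
#' @param vafs Numeric vector of three observed VAF fractions.
#' @param ... Passed to [fit_fitness()] (clamping bounds, threshold).
#' @return A two-row data.frame with column `phase`
#'   (`"carboplatin"`, `"maintenance"`) followed by the [fit_fitness()]
#'   columns.
#' @export
phase_fitness <- function(times, vafs, ...) {
  stopifnot(length(times) == 3, length(vafs) == 3)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  carbo <- fit_fitness(vafs[1], vafs[2], times[2] - times[1], ...)
  maint <- fit_fitness(vafs[2], vafs[3], times[3] - times[2], ...)
  cbind(phase = c("carboplatin", "maintenance"), rbind(carbo, maint))
}

#' Count clones crossing the CH detection threshold
#'
#' Tallies, per gene, clones that emerged during treatment (start VAF below
#' the threshold, end VAF at or above it) and clones that vanished (the
#' reverse). The default threshold is the 1% VAF bound conventionally used
#' to call clonal hematopoiesis.
#'
#' @param estimates data.frame with columns `gene`, `v_start`, `v_end`.
#' @param threshold VAF fraction defining the boundary (default 0.01).
#' @return data.frame with columns `gene`, `emerging`, `vanishing`.
#' @export
count_threshold_crossings <- function(estimates, threshold = 0.01) {
  stopifnot(all(c("gene", "v_start", "v_end") %in% names(estimates)))
  emerging <- estimates$v_start < threshold & estimates$v_end >= threshold
  vanishing <- estimates$v_start >= threshold & estimates$v_end < threshold
  genes <- sort(unique(estimates$gene))
  data.frame(
    gene = genes,
    emerging = vapply(genes, function(g) sum(emerging[estimates$gene == g]), integer(1)),
    vanishing = vapply(genes, function(g) sum(vanishing[estimates$gene == g]), integer(1)),
    row.names = NULL
  )
}
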