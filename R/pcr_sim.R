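#' Build a mock-community clone table
#'
#' The default mirrors a five-clone artificial community of oral taxa mixed
#' at gene-copy ratio A9:C10:F10:E3:E9 = 1:3:8:2:10, with per-template
#' per-cycle amplification efficiencies as free inputs (efficiencies are not
#' predictable from primer mismatch counts, so they are parameters, not
#' derived quantities).
#'
#' @param id Clone identifiers.
#' @param copies Input gene copies per clone (positive).
#' @param efficiency Per-cycle duplication probability per clone, in
#'   \[0, 1\].
#' @return Tibble with `id`, `copies`, `efficiency`.
#' @export
clone_templates <- function(id = c("A9", "C10", "F10", "E3", "E9"),
                            copies = c(1, 3, 8, 2, 10) * 1e5,
                            efficiency = c(0.95, 0.70, 0.90, 0.85, 0.80)) {
  if (any(copies <= 0)) abort("copies must be positive")
  if (any(efficiency < 0 | efficiency > 1)) abort("efficiency must lie in [0, 1]")
  tibble(id = id, copies = copies, efficiency = efficiency)
}

#' Amplify templates over PCR cycles
#'
#' Deterministic mode applies the closed form
#' `copies * (1 + efficiency)^cycles` exactly. Stochastic mode duplicates
#' each molecule independently with probability `efficiency` per cycle
#' (binomial per template per cycle); above 1e9 molecules a normal
#' approximation to the binomial is used, which leaves the mean and variance
#' unchanged.
#'
#' @param templates Tibble with `id`, `copies`, `efficiency` (see
#'   [clone_templates()]).
#' @param cycles Number of PCR cycles, >= 0.
#' @param mode `"deterministic"` or `"stochastic"`.
#' @param seed Optional seed for stochastic mode.
#' @return The input tibble with `copies_initial`, `cycles` and updated
#'   `copies`.
#' @examples
#' amplify(clone_templates(), cycles = 10)
#' @export
amplify <- function(templates, cycles, mode = c("deterministic", "stochastic"),
                    seed = NULL) {
  mode <- match.arg(mode)
  if (cycles < 0) abort("cycles must be >= 0")
  if (any(templates$copies < 0)) abort("copies must be non-negative")
  if (any(templates$efficiency < 0 | templates$efficiency > 1)) {
    abort("efficiency must lie in [0, 1]")
  }
  run <- function() {
    if (mode == "deterministic") {
      out <- templates$copies * (1 + templates$efficiency)^cycles
    } else {
      out <- vapply(seq_len(nrow(templates)), function(i) {
        x <- templates$copies[i]
        e <- templates$efficiency[i]
        for (cyc in seq_len(cycles)) {
          dup <- if (x > 1e9) {
            max(0, round(rnorm(1, mean = x * e, sd = sqrt(x * e * (1 - e)))))
          } else {
            rbinom(1, size = as.integer(round(x)), prob = e)
          }
          x <- x + dup
        }
        x
      }, numeric(1))
    }
    dplyr::mutate(templates, copies_initial = templates$copies,
                  cycles = cycles, copies = out)
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

#' Ten-fold (or other) serial dilution series
#'
#' @param high Highest copy number.
#' @param low Lowest copy number, reachable from `high` by an integer number
#'   of `fold` dilutions.
#' @param fold Dilution factor per step, > 1.
#' @return Descending vector of copy numbers from `high` to `low` inclusive.
#' @examples
#' dilution_series(1e8, 1e3, 10)  # the six-point standard-curve series
#' @export
dilution_series <- function(high = 1e8, low = 1e3, fold = 10) {
  if (fold <= 1) abort("fold must be > 1")
  if (high < low) abort("high must be >= low")
  steps <- log(high / low) / log(fold)
  if (abs(steps - round(steps)) > 1e-9) {
    abort("low is not reachable from high by whole dilution steps")
  }
  high / fold^(0:round(steps))
}

#' Construct a standard curve from known parameters
#'
#' A qPCR standard curve is the line `Ct = intercept + slope * log10(copies)`;
#' a slope of `-1/log10(2) = -3.3219` corresponds to perfect doubling (100%
#' efficiency).
#'
#' @param slope Ct change per log10 copies (negative for a valid curve).
#' @param intercept Ct at a single copy.
#' @param r_squared Optional coefficient of determination.
#' @return A `standard_curve` object.
#' @export
standard_curve <- function(slope, intercept, r_squared = NA_real_) {
  structure(
    list(
      slope = slope, intercept = intercept, r_squared = r_squared,
      efficiency_percent = (10^(-1 / slope) - 1) * 100,
      # a near-zero slope means Ct carries no copy-number signal
      valid = is.finite(slope) && slope < -1e-6,
      n_points = NA_integer_, model = NULL
    ),
    class = "standard_curve"
  )
}

#' Fit a qPCR standard curve
#'
#' Least-squares regression of Ct on log10 copies over a dilution series.
#' Noise-free points recover the generating slope and intercept exactly with
#' an R-squared of 1. Amplification efficiency is derived from the slope as
#' `(10^(-1/slope) - 1) * 100` percent.
#'
#' @param points Tibble with `copies` and `ct` columns; at least two
#'   distinct copy levels.
#' @return A `standard_curve` object (slope, intercept, `r_squared`,
#'   `efficiency_percent`, `valid`, underlying `lm` fit).
#' @examples
#' pts <- tibble::tibble(copies = dilution_series())
#' pts$ct <- ct_from_copies(pts$copies, standard_curve(-3.3219, 35))
#' fit_standard_curve(pts)
#' @export
fit_standard_curve <- function(points) {
  if (length(unique(points$copies)) < 2) {
    abort("need at least two distinct copy levels")
  }
  if (any(points$copies <= 0)) abort("copies must be positive")
  fit <- lm(ct ~ log10(copies), data = points)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (!is.finite(r2)) r2 <- NA_real_
  out <- standard_curve(slope, intercept, r2)
  out$n_points <- nrow(points)
  out$model <- fit
  out
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> Ct = %.4f %+.4f * log10(copies) | R^2 = %s | efficiency %.1f%%%s\n",
    x$intercept, x$slope,
    if (is.na(x$r_squared)) "NA" else sprintf("%.4f", x$r_squared),
    x$efficiency_percent,
    if (x$valid) "" else " [INVALID: non-negative slope]"
  ))
  invisible(x)
}

#' @rdname fit_standard_curve
#' @param x A `standard_curve` object.
#' @param ... Unused.
#' @method tidy standard_curve
#' @export
tidy.standard_curve <- function(x, ...) {
  tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @rdname fit_standard_curve
#' @method glance standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  tibble(
    slope = x$slope, intercept = x$intercept, r_squared = x$r_squared,
    efficiency_percent = x$efficiency_percent, valid = x$valid,
    n_points = x$n_points
  )
}

#' Simulate the qPCR read-out for a copy number
#'
#' `Ct = intercept + slope * log10(copies)` plus optional Gaussian
#' instrument noise. Vectorised over `copies`.
#'
#' @param copies Positive copy numbers.
#' @param curve A `standard_curve`.
#' @param noise_sd Standard deviation of Ct noise; 0 for deterministic.
#' @param seed Optional seed.
#' @return Ct values.
#' @export
ct_from_copies <- function(copies, curve, noise_sd = 0, seed = NULL) {
  if (any(copies <= 0)) abort("copies must be positive")
  run <- function() {
    ct <- curve$intercept + curve$slope * log10(copies)
    if (noise_sd > 0) ct <- ct + rnorm(length(ct), 0, noise_sd)
    ct
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

#' Absolute quantification from a standard curve
#'
#' Inverse of [ct_from_copies()] at zero noise:
#' `copies = 10^((ct - intercept) / slope)`.
#'
#' @param ct Ct values.
#' @param curve A valid `standard_curve` (negative slope).
#' @return Copy numbers.
#' @export
quantify <- function(ct, curve) {
  if (!curve$valid) abort("invalid standard curve (slope must be negative)")
  10^((ct - curve$intercept) / curve$slope)
}

#' Normalise copy numbers to their minimum
#'
#' Expresses a set of abundances as a ratio with the smallest member mapped
#' to 1 (the convention used for reporting mock-community mixtures).
#'
#' @param copies Positive numbers.
#' @return `copies / min(copies)`.
#' @examples
#' normalize_ratio(c(1e6, 3e6, 8e6, 2e6, 1e7))
#' @export
normalize_ratio <- function(copies) {
  if (any(copies <= 0)) abort("copies must be positive")
  copies / min(copies)
}

#' Simulate the mock-community PCR-bias experiment end to end
#'
#' For each cycle arm, amplifies the clone mixture with per-template
#' efficiencies, reads each product out by qPCR (Ct from a clone-agnostic
#' standard curve plus instrument noise), quantifies absolutely back to
#' copies, and normalises to the smallest clone within each replicate. The
#' replicate structure is biological x experimental (3 x 3 by default).
#'
#' @param templates Clone table from [clone_templates()].
#' @param cycles Cycle arms, default `c(10, 20, 30)`.
#' @param curve Standard curve used for quantification.
#' @param noise_sd Ct noise standard deviation per assay.
#' @param n_biological,n_experimental Replicate counts.
#' @param mode Amplification mode passed to [amplify()].
#' @param seed Seed governing all randomness.
#' @return A `mock_community_sim` tibble: one row per clone x cycle arm x
#'   replicate with `copies_initial`, `ratio_initial`, `copies_post`, `ct`,
#'   `copies_quantified`, `ratio` (normalised within replicate).
#' @export
simulate_mock_community <- function(templates = clone_templates(),
                                    cycles = c(10, 20, 30),
                                    curve = standard_curve(-1 / log10(2), 35),
                                    noise_sd = 0.15,
                                    n_biological = 3, n_experimental = 3,
                                    mode = c("deterministic", "stochastic"),
                                    seed = 1) {
  mode <- match.arg(mode)
  ratio0 <- normalize_ratio(templates$copies)
  run <- function() {
    grid <- tidyr::expand_grid(
      cycles = cycles,
      biological = seq_len(n_biological),
      experimental = seq_len(n_experimental)
    )
    rows <- purrr::pmap(grid, function(cycles, biological, experimental) {
      post <- amplify(templates, cycles, mode = mode)
      ct <- ct_from_copies(post$copies, curve, noise_sd = noise_sd)
      quant <- quantify(ct, curve)
      tibble(
        clone = templates$id,
        cycles = cycles, biological = biological, experimental = experimental,
        copies_initial = templates$copies,
        ratio_initial = ratio0,
        efficiency = templates$efficiency,
        copies_post = post$copies,
        ct = ct,
        copies_quantified = quant,
        ratio = normalize_ratio(quant)
      )
    })
    dplyr::bind_rows(rows)
  }
  out <- withr::with_seed(seed, run())
  class(out) <- c("mock_community_sim", class(out))
  out
}

#' Summarise a mock-community simulation per clone and cycle arm
#'
#' @param sim Result of [simulate_mock_community()].
#' @return Tibble with mean and standard error of the normalised ratio per
#'   clone and cycle arm.
#' @export
summarise_mock_ratios <- function(sim) {
  sim |>
    dplyr::group_by(.data$clone, .data$cycles) |>
    dplyr::summarise(
      ratio_initial = .data$ratio_initial[1],
      ratio_mean = mean(.data$ratio),
      ratio_se = stats::sd(.data$ratio) / sqrt(dplyr::n()),
      .groups = "drop"
    )
}
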