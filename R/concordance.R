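#' Subspecies shares from qPCR Ct values (delta-delta Ct)
#'
#' Replicate Ct values are averaged per target; the fold ratio between the
#' two targets is `2^-(Ct_A - Ct_B)` (one cycle of difference doubles the
#' ratio), converted to shares `(fold / (1 + fold), 1 / (1 + fold))` that
#' sum to 1. Targets are taken in sorted order, so target A is the
#' alphabetically first; swapping the target labels swaps the shares
#' exactly. Optional per-target amplification efficiencies replace the base
#' 2 when primer efficiency correction is wanted (off by default).
#'
#' @param table Ct table (see [read_ct_table()]).
#' @param sample_id sample to compute shares for.
#' @param efficiency named numeric vector of per-target amplification
#'   factors; default `2` for both targets.
#' @return named numeric vector of two shares, ordered by target name.
#' @export
ddct_ratio <- function(table, sample_id, efficiency = NULL) {
  rows <- filter(table, .data$sample_id == !!sample_id)
  targets <- sort(unique(table$target))
  if (length(targets) != 2)
    abort("Ct table must contain exactly two targets")
  for (tg in targets)
    if (!tg %in% rows$target)
      abort(sprintf("sample %s has no Ct for target %s", sample_id, tg))
  mean_ct <- rows |>
    group_by(.data$target) |>
    summarise(ct = mean(.data$ct), .groups = "drop")
  ct <- setNames(mean_ct$ct, mean_ct$target)[targets]
  eff <- efficiency %||% setNames(c(2, 2), targets)
  # amount of each target scales as efficiency^(-Ct)
  fold <- eff[[targets[1]]]^(-ct[[1]]) / eff[[targets[2]]]^(-ct[[2]])
  setNames(c(fold / (1 + fold), 1 / (1 + fold)), targets)
}

#' Delta-delta Ct shares for every sample in a Ct table
#'
#' @inheritParams ddct_ratio
#' @return tibble `sample_id`, `target`, `share`.
#' @export
ddct_shares <- function(table, efficiency = NULL) {
  map_dfr(unique(table$sample_id), function(sid) {
    sh <- ddct_ratio(table, sid, efficiency)
    tibble(sample_id = sid, target = names(sh), share = unname(sh))
  })
}

#' Agreement between computational and qPCR subspecies estimates
#'
#' Ordinary least squares of the qPCR share on the computational share over
#' the shared samples, with the two-sided t-test p-value on the slope. This
#' is the reusable form of the validation that regresses marker-based
#' subspecies estimates on delta-delta Ct ratios.
#'
#' @param computational tibble/data frame with columns `sample_id` and
#'   `fraction` (or `share`).
#' @param qpcr same shape, qPCR-derived fractions.
#' @return an `agreement` object with `slope`, `intercept`, `r_squared`,
#'   `p_value`, `n`; [tidy()] and [glance()] methods apply.
#' @export
agreement <- function(computational, qpcr) {
  comp <- standardize_fraction(computational, "computational")
  qp <- standardize_fraction(qpcr, "qpcr")
  shared <- inner_join(comp, qp, by = "sample_id",
                       suffix = c("_comp", "_qpcr"))
  if (nrow(shared) < 3) abort("need at least 3 shared samples")
  if (length(unique(shared$fraction_comp)) == 1)
    abort("degenerate regression: computational fractions have zero variance")
  fit <- lm(fraction_qpcr ~ fraction_comp, data = shared)
  sm <- summary(fit)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2, 4],
                 n = nrow(shared), fit = fit, data = as_tibble(shared)),
            class = "agreement")
}

standardize_fraction <- function(x, what) {
  x <- as_tibble(x)
  if ("share" %in% names(x) && !"fraction" %in% names(x))
    x <- rename(x, fraction = "share")
  if (!all(c("sample_id", "fraction") %in% names(x)))
    abort(sprintf("%s table needs columns sample_id and fraction", what))
  select(x, "sample_id", "fraction")
}

#' @export
print.agreement <- function(x, ...) {
  cat(sprintf(
    "<agreement> n = %d, slope = %.4f, intercept = %.4f, R^2 = %.4f, p = %.3g\n",
    x$n, x$slope, x$intercept, x$r_squared, x$p_value))
  invisible(x)
}

#' @describeIn agreement coefficient-level summary of the regression.
#' @param x an `agreement` object.
#' @param ... unused.
#' @export
tidy.agreement <- function(x, ...) {
  sm <- unname(summary(x$fit)$coefficients)
  tibble(term = c("intercept", "slope"),
         estimate = sm[, 1], std.error = sm[, 2],
         statistic = sm[, 3], p.value = sm[, 4])
}

#' @describeIn agreement one-row model summary.
#' @export
glance.agreement <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, r_squared = x$r_squared,
         p_value = x$p_value, n = x$n)
}
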