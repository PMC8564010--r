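#' Predict a population-level thermal performance curve
#'
#' Returns survival probability at the requested temperatures for one
#' embryogenesis group: random effects set to zero on the logit scale,
#' fertilization levels averaged with equal weights on the logit scale,
#' probability = inverse logit of the resulting cubic.
#'
#' @param fit A [fit_tpc_glmm()] or [fit_tpc_glm()] result.
#' @param embryo_temp Embryogenesis temperature identifying the group.
#' @param temps Numeric vector of assay temperatures (degC).
#' @return Numeric vector of survival probabilities.
#' @export
predict_curve <- function(fit, embryo_temp, temps) {
  stopifnot(inherits(fit, "tpc_fit"))
  a <- embryo_curve_coefs(fit, embryo_temp)
  stats::plogis(cubic_eta(pad4(a), temps))
}

## Raw monomial coefficients (a0..ad) of the embryogenesis-level logit
## curve, via the basis-coefficient map and exact basis-to-monomial change.
embryo_curve_coefs <- function(fit, embryo_temp) {
  L <- embryo_coef_map(fit, embryo_temp)
  basis_to_monomial(fit$basis, drop(L %*% fit$beta))
}

pad4 <- function(a) c(a, rep(0, 4 - length(a)))[1:4]

descriptor_names <- c("Pmax", "Topt", "Tbr", "Tbr_lo", "Tbr_hi", "CTmin", "CTmax")

#' Extract curve descriptors analytically from a fitted model
#'
#' Computes, for one or all embryogenesis groups: peak survival `Pmax` and
#' its temperature `Topt` (stationary points of the cubic by the quadratic
#' formula, compared with the search-range endpoints); thermal breadth
#' `Tbr` = width of the interval where survival is at least
#' `breadth_fraction` of the peak; and critical limits `CTmin` / `CTmax`
#' where survival falls to `limit_fraction` of the peak. Fractions of peak
#' are taken on the probability scale. Threshold crossings are the nearest
#' roots on each side of `Topt`, searched up to `extrapolation_margin` degC
#' beyond the range and refined to 1e-9 degC; values outside the range are
#' flagged `extrapolated`, and sides with no crossing are `censored` at the
#' search limit (and excluded from bootstrap CIs downstream). An
#' endpoint-peaked curve gets a `boundary` flag on `Topt`; flat-curve ties
#' resolve to the smallest temperature.
#'
#' @param fit A converged [fit_tpc_glmm()] or [fit_tpc_glm()] result.
#' @param embryo_temp Group to extract, or `NULL` (default) for all groups.
#' @param search_range Length-2 numeric: temperature window for the peak
#'   search (defaults to the assay range of the fitted data).
#' @param breadth_fraction Fraction of peak defining thermal breadth
#'   (default 0.5).
#' @param limit_fraction Fraction of peak defining critical limits
#'   (default 0.05); must be below `breadth_fraction`.
#' @param extrapolation_margin degC beyond `search_range` in which
#'   threshold crossings may still be located (default 10).
#' @return Object of class `tpc_descriptors`: data frame with one row per
#'   group and columns `embryo_temp`, `Pmax`, `Topt`, `Tbr`, `Tbr_lo`,
#'   `Tbr_hi`, `CTmin`, `CTmax`, `thermal_tolerance` (= CTmax - CTmin,
#'   derived convenience), and `flag_*` status columns with values in
#'   `interior`, `boundary`, `extrapolated`, `censored`.
#' @examples
#' # closed-form check: eta(T) = 2 - 0.05 (T - 19)^2 peaks at 19 degC
#' @export
extract_descriptors <- function(fit, embryo_temp = NULL,
                                search_range = NULL,
                                breadth_fraction = 0.5,
                                limit_fraction = 0.05,
                                extrapolation_margin = 10) {
  stopifnot(inherits(fit, "tpc_fit"))
  groups <- if (is.null(embryo_temp)) embryo_levels(fit) else embryo_temp
  search_range <- search_range %||% range(fit$basis$temps)
  rows <- lapply(groups, function(e) {
    a <- pad4(embryo_curve_coefs(fit, e))
    d <- cubic_descriptors(a, search_range, breadth_fraction,
                           limit_fraction, extrapolation_margin)
    cbind(data.frame(embryo_temp = e), descriptor_row(d))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("tpc_descriptors", "data.frame")
  out
}

descriptor_row <- function(d) {
  df <- as.data.frame(as.list(d$values))
  df$thermal_tolerance <- df$CTmax - df$CTmin
  for (nm in names(d$flags)) df[[paste0("flag_", nm)]] <- d$flags[[nm]]
  df
}

## Core analytic extraction on a raw cubic eta(T) = a0 + a1 T + a2 T^2 + a3 T^3.
cubic_descriptors <- function(a, search_range, breadth_fraction = 0.5,
                              limit_fraction = 0.05, margin = 10) {
  stopifnot(length(a) == 4, length(search_range) == 2)
  if (breadth_fraction <= 0 || breadth_fraction >= 1 ||
      limit_fraction <= 0 || limit_fraction >= 1)
    stop_validation("fractions must lie strictly in (0,1)")
  if (limit_fraction >= breadth_fraction)
    stop_validation("limit_fraction must be below breadth_fraction")
  lo <- min(search_range); hi <- max(search_range)
  eta <- function(t) cubic_eta(a, t)

  ## stationary points: roots of a1 + 2 a2 t + 3 a3 t^2
  stat <- real_quadratic_roots(3 * a[4], 2 * a[3], a[2])
  cand <- sort(unique(c(lo, hi, stat[stat >= lo & stat <= hi])))
  vals <- eta(cand)
  topt <- cand[which(vals >= max(vals) - 1e-12)][1]   # first-hit tie-break
  topt_flag <- if ((abs(topt - lo) < 1e-12 || abs(topt - hi) < 1e-12) &&
                   !any(abs(stat - topt) < 1e-9)) "boundary" else "interior"
  pmax_ <- stats::plogis(eta(topt))

  cross <- function(fraction) {
    thr <- stats::qlogis(fraction * pmax_)
    g <- c(a[1] - thr, a[2], a[3], a[4])
    roots <- real_cubic_roots(g)
    left <- roots[roots < topt - 1e-12 & roots >= lo - margin]
    right <- roots[roots > topt + 1e-12 & roots <= hi + margin]
    side <- function(x, default, which_side) {
      if (!length(x)) {
        list(value = default, flag = "censored")
      } else {
        v <- if (which_side == "left") max(x) else min(x)
        v <- polish_root(g, v)
        flag <- if (v >= lo && v <= hi) "interior" else "extrapolated"
        list(value = v, flag = flag)
      }
    }
    list(lo = side(left, lo - margin, "left"),
         hi = side(right, hi + margin, "right"))
  }
  br <- cross(breadth_fraction)
  ct <- cross(limit_fraction)

  values <- c(Pmax = pmax_, Topt = topt,
              Tbr = br$hi$value - br$lo$value,
              Tbr_lo = br$lo$value, Tbr_hi = br$hi$value,
              CTmin = ct$lo$value, CTmax = ct$hi$value)
  flags <- list(Pmax = topt_flag, Topt = topt_flag,
                Tbr = worst_flag(br$lo$flag, br$hi$flag),
                Tbr_lo = br$lo$flag, Tbr_hi = br$hi$flag,
                CTmin = ct$lo$flag, CTmax = ct$hi$flag)
  list(values = values, flags = flags)
}

worst_flag <- function(...) {
  f <- c(...)
  for (lev in c("censored", "extrapolated", "boundary")) if (lev %in% f) return(lev)
  "interior"
}

real_quadratic_roots <- function(A, B, C) {
  if (abs(A) < 1e-14) {
    if (abs(B) < 1e-14) return(numeric(0))
    return(-C / B)
  }
  disc <- B^2 - 4 * A * C
  if (disc < 0) return(numeric(0))
  s <- sqrt(disc)
  sort(c((-B - s) / (2 * A), (-B + s) / (2 * A)))
}

## real roots of g1 + g2 t + g3 t^2 + g4 t^3 (ascending coefficients)
real_cubic_roots <- function(g) {
  nz <- max(which(abs(g) > 1e-14 * max(abs(g), 1)), 1)
  if (nz == 1) return(numeric(0))
  r <- polyroot(g[seq_len(nz)])
  Re(r[abs(Im(r)) < 1e-7 * (1 + abs(Re(r)))])
}

## Newton polish of a polynomial root to ~1e-12
polish_root <- function(g, x) {
  dg <- g[-1] * seq_len(length(g) - 1)
  for (i in 1:4) {
    f <- sum(g * x^(seq_along(g) - 1))
    fp <- sum(dg * x^(seq_along(dg) - 1))
    if (abs(fp) < 1e-14) break
    x <- x - f / fp
  }
  x
}

#' Brute-force grid extraction of curve descriptors
#'
#' Same definitions as [extract_descriptors()] evaluated on a dense grid:
#' `Topt` is the grid argmax over the search range (first hit on ties), and
#' each threshold crossing is the first grid point past the threshold
#' moving outward from `Topt`. Intended as an independent oracle for the
#' analytic extraction; not meant for production use.
#'
#' @inheritParams extract_descriptors
#' @param step Grid spacing in degC (default 0.001).
#' @return A `tpc_descriptors` data frame, as for [extract_descriptors()].
#' @export
grid_descriptors <- function(fit, embryo_temp = NULL, search_range = NULL,
                             breadth_fraction = 0.5, limit_fraction = 0.05,
                             extrapolation_margin = 10, step = 0.001) {
  stopifnot(inherits(fit, "tpc_fit"))
  groups <- if (is.null(embryo_temp)) embryo_levels(fit) else embryo_temp
  search_range <- search_range %||% range(fit$basis$temps)
  rows <- lapply(groups, function(e) {
    a <- pad4(embryo_curve_coefs(fit, e))
    d <- grid_descriptors_cubic(a, search_range, breadth_fraction,
                                limit_fraction, extrapolation_margin, step)
    cbind(data.frame(embryo_temp = e), descriptor_row(d))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("tpc_descriptors", "data.frame")
  out
}

grid_descriptors_cubic <- function(a, search_range, breadth_fraction = 0.5,
                                   limit_fraction = 0.05, margin = 10,
                                   step = 0.001) {
  lo <- min(search_range); hi <- max(search_range)
  grid <- seq(lo - margin, hi + margin, by = step)
  eta <- cubic_eta(a, grid)
  inside <- grid >= lo - step / 2 & grid <= hi + step / 2
  gi <- grid[inside]; ei <- eta[inside]
  i_top <- which.max(ei)                      # which.max is first-hit
  topt <- gi[i_top]
  topt_flag <- if (i_top == 1L || i_top == length(gi)) "boundary" else "interior"
  pmax_ <- stats::plogis(ei[i_top])
  i0 <- which(inside)[i_top]                  # index of Topt in full grid

  cross <- function(fraction) {
    thr <- stats::qlogis(fraction * pmax_)
    below <- eta < thr
    left_hits <- which(below[seq_len(i0)])
    right_hits <- which(below[i0:length(grid)])
    list(lo = if (length(left_hits)) list(value = grid[max(left_hits)],
                                          flag = flag_for(grid[max(left_hits)], lo, hi))
              else list(value = lo - margin, flag = "censored"),
         hi = if (length(right_hits)) list(value = grid[i0 - 1 + min(right_hits)],
                                           flag = flag_for(grid[i0 - 1 + min(right_hits)], lo, hi))
              else list(value = hi + margin, flag = "censored"))
  }
  flag_for <- function(v, lo, hi) if (v >= lo && v <= hi) "interior" else "extrapolated"
  br <- cross(breadth_fraction)
  ct <- cross(limit_fraction)
  values <- c(Pmax = pmax_, Topt = topt,
              Tbr = br$hi$value - br$lo$value,
              Tbr_lo = br$lo$value, Tbr_hi = br$hi$value,
              CTmin = ct$lo$value, CTmax = ct$hi$value)
  flags <- list(Pmax = topt_flag, Topt = topt_flag,
                Tbr = worst_flag(br$lo$flag, br$hi$flag),
                Tbr_lo = br$lo$flag, Tbr_hi = br$hi$flag,
                CTmin = ct$lo$flag, CTmax = ct$hi$flag)
  list(values = values, flags = flags)
}

#' @export
print.tpc_descriptors <- function(x, ...) {
  cat("Thermal performance curve descriptors (per embryogenesis group):\n")
  print(as.data.frame(x), digits = 5)
  invisible(x)
}
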