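# Unit fertilization efficiency (UFE): fertilized-egg output normalized by
# total gamete cost, and its sensitivity to deviations k from the
# fertilization unit. Overuse (k > 1) leaves fertilization saturated while
# sperm cost scales with k; underuse (k < 1) additionally scales fertilized
# output linearly with k.

#' Gamete cost model for efficiency analysis
#'
#' Parameterizes the efficiency calculation either by raw quantities and
#' prices -- sperm price `Ps` and count `S`, egg price `Pe` and count `E`,
#' and the target number of fertilized eggs `FE` -- or directly by the sperm
#' cost share `r = Ps*S / (Ps*S + Pe*E)`, the single parameter the percent
#' deviation statistic actually depends on. When only `cost_share_sperm` is
#' given, a canonical unit-cost representation is synthesized (total cost 1,
#' one egg, one fertilized egg), which leaves every deviation statistic
#' unchanged. When both parameterizations are given they must agree to
#' within 1e-9 relative.
#'
#' @param price_per_sperm Currency per sperm cell (`Ps`, >= 0).
#' @param price_per_egg Currency per egg (`Pe`, >= 0).
#' @param sperm_used Sperm cells used at the fertilization unit (`S`, > 0).
#' @param eggs_used Eggs used (`E`, > 0).
#' @param target_fertilized Target number of fertilized eggs (`FE`, > 0,
#'   at most `E`).
#' @param cost_share_sperm Sperm share of total gamete cost, in \[0, 1).
#' @return An object of class `gamete_cost_model`.
#' @examples
#' gamete_cost_model(cost_share_sperm = 1 / 3)
#' gamete_cost_model(price_per_sperm = 1e-6, price_per_egg = 0.01,
#'                   sperm_used = 1.485e9, eggs_used = 1.1e4,
#'                   target_fertilized = 7370)
#' @export
gamete_cost_model <- function(price_per_sperm = NULL, price_per_egg = NULL,
                              sperm_used = NULL, eggs_used = NULL,
                              target_fertilized = NULL,
                              cost_share_sperm = NULL) {
  raw_args <- list(price_per_sperm = price_per_sperm,
                   price_per_egg = price_per_egg,
                   sperm_used = sperm_used, eggs_used = eggs_used,
                   target_fertilized = target_fertilized)
  raw_given <- !vapply(raw_args, is.null, logical(1))
  if (any(raw_given) && !all(raw_given)) {
    stop(sprintf("incomplete price parameterization: missing '%s'",
                 names(raw_args)[!raw_given][[1L]]), call. = FALSE)
  }
  if (!any(raw_given) && is.null(cost_share_sperm)) {
    stop("supply either the five price/quantity fields or cost_share_sperm",
         call. = FALSE)
  }

  if (!any(raw_given)) {
    r <- .check_cost_share(cost_share_sperm)
    # canonical representation: total cost 1, one egg used and fertilized
    raw_args <- list(price_per_sperm = r, price_per_egg = 1 - r,
                     sperm_used = 1, eggs_used = 1, target_fertilized = 1)
  }
  for (nm in names(raw_args)) {
    v <- raw_args[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop(sprintf("'%s' must be a single non-negative finite number", nm),
           call. = FALSE)
    }
  }
  with(raw_args, {
    if (sperm_used <= 0) stop("sperm_used must be > 0", call. = FALSE)
    if (eggs_used <= 0) stop("eggs_used must be > 0", call. = FALSE)
    if (target_fertilized <= 0) {
      stop("target_fertilized must be > 0", call. = FALSE)
    }
    if (target_fertilized > eggs_used) {
      stop("target_fertilized cannot exceed eggs_used", call. = FALSE)
    }
  })
  sperm_cost <- raw_args$price_per_sperm * raw_args$sperm_used
  total_cost <- sperm_cost + raw_args$price_per_egg * raw_args$eggs_used
  if (total_cost <= 0) {
    stop("total gamete cost must be positive (both prices are zero)",
         call. = FALSE)
  }
  r <- sperm_cost / total_cost
  if (r >= 1) {
    stop("cost_share_sperm must be below 1 (egg cost cannot be zero)",
         call. = FALSE)
  }
  if (!is.null(cost_share_sperm)) {
    supplied <- .check_cost_share(cost_share_sperm)
    if (abs(supplied - r) > 1e-9 * max(1, abs(r))) {
      stop(sprintf(
        "supplied cost_share_sperm (%.12g) disagrees with prices (%.12g)",
        supplied, r), call. = FALSE)
    }
  }
  structure(c(raw_args, list(cost_share_sperm = r)),
            class = "gamete_cost_model")
}

.check_cost_share <- function(r) {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r < 0 || r >= 1) {
    stop("cost_share_sperm must be a fraction in [0, 1)", call. = FALSE)
  }
  as.numeric(r)
}

#' Unit fertilization efficiency
#'
#' Fertilized eggs per unit of total gamete cost:
#' `FE / (Ps*S + Pe*E)`.
#'
#' @param model A [gamete_cost_model()].
#' @return Efficiency in fertilized eggs per currency unit.
#' @export
ufe <- function(model) {
  stopifnot(inherits(model, "gamete_cost_model"))
  model$target_fertilized /
    (model$price_per_sperm * model$sperm_used +
       model$price_per_egg * model$eggs_used)
}

#' Efficiency at a deviation k from the fertilization unit
#'
#' Multiplying the sperm dose by `k` scales the sperm cost term by `k` in
#' both directions. Overuse (`k > 1`) leaves the fertilized output at its
#' saturated target; underuse (`k < 1`) scales fertilized output linearly
#' with `k`. The two branches coincide at `k = 1`, where the value equals
#' [ufe()].
#'
#' @param model A [gamete_cost_model()].
#' @param k Deviation factor (> 0); `k = 0.5` means half the recommended
#'   sperm dose.
#' @return Efficiency at deviation `k`.
#' @export
ufe_at_k <- function(model, k) {
  stopifnot(inherits(model, "gamete_cost_model"))
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0) {
    stop("k must be a single positive number", call. = FALSE)
  }
  cost_k <- model$price_per_sperm * k * model$sperm_used +
    model$price_per_egg * model$eggs_used
  if (k >= 1) {
    model$target_fertilized / cost_k
  } else {
    k * model$target_fertilized / cost_k
  }
}

#' Percent change in efficiency at deviation k
#'
#' `|UFE - UFE_k| / UFE * 100`: the percent loss of cost-normalized
#' fertilization efficiency from deviating by factor `k` from the unit.
#' Zero exactly at `k = 1`; bounded in \[0, 100) for `k > 0` and sperm cost
#' share below 1.
#'
#' @inheritParams ufe_at_k
#' @return Percent change (non-negative).
#' @examples
#' m <- gamete_cost_model(cost_share_sperm = 1 / 3)
#' delta_ufe_percent(m, 2)  # 25
#' delta_ufe_percent(m, 10) # 75
#' @export
delta_ufe_percent <- function(model, k) {
  base <- ufe(model)
  abs(base - ufe_at_k(model, k)) / base * 100
}

#' Sweep the efficiency deviation curve over a k grid
#'
#' Evaluates [ufe_at_k()] and [delta_ufe_percent()] on a grid of deviation
#' factors, log-spaced by default, with `k = 1` inserted exactly whenever it
#' lies in range so the curve is anchored at zero deviation.
#'
#' @param model A [gamete_cost_model()].
#' @param k_min,k_max Grid range, `0 < k_min < k_max`.
#' @param points Number of grid points (>= 2) before the `k = 1` insertion.
#' @param spacing `"log"` (default) or `"linear"`.
#' @return A data frame of class `ufe_sweep` with columns `k`, `ufe_k`,
#'   `delta_percent`, sorted by `k`.
#' @examples
#' s <- ufe_sweep(gamete_cost_model(cost_share_sperm = 1 / 3))
#' s[s$k == 1, ]
#' @export
ufe_sweep <- function(model, k_min = 0.01, k_max = 10, points = 200,
                      spacing = c("log", "linear")) {
  spacing <- match.arg(spacing)
  if (!is.numeric(k_min) || !is.numeric(k_max) || length(k_min) != 1L ||
      length(k_max) != 1L || !is.finite(k_min) || !is.finite(k_max) ||
      k_min <= 0 || k_min >= k_max) {
    stop("require 0 < k_min < k_max", call. = FALSE)
  }
  if (!is.numeric(points) || length(points) != 1L || points < 2 ||
      points != floor(points)) {
    stop("points must be a whole number >= 2", call. = FALSE)
  }
  grid <- if (spacing == "log") {
    exp(seq(log(k_min), log(k_max), length.out = points))
  } else {
    seq(k_min, k_max, length.out = points)
  }
  if (k_min <= 1 && k_max >= 1) grid <- c(grid, 1)
  grid <- sort(unique(grid))
  out <- data.frame(
    k = grid,
    ufe_k = vapply(grid, function(k) ufe_at_k(model, k), numeric(1)),
    delta_percent = vapply(grid, function(k) delta_ufe_percent(model, k),
                           numeric(1))
  )
  class(out) <- c("ufe_sweep", "data.frame")
  out
}

#' Calibrate the sperm cost share from one observed deviation
#'
#' Inverts the deviation statistic: given that deviating by `k_obs` produced
#' a `delta_obs_percent` percent efficiency change, recovers the sperm cost
#' share `r`. On the overuse side (`k > 1`) the statistic is
#' `d = 1 - 1/(1 + r (k - 1))`, giving `r = d / ((1 - d)(k - 1))`; on the
#' underuse side (`k < 1`) it is `d = 1 - k/(1 - r (1 - k))`, giving
#' `r = (1 - k/(1 - d)) / (1 - k)`. The result round-trips through
#' [delta_ufe_percent()].
#'
#' This entry point exists because published deviation curves typically
#' print percent losses, not the underlying gamete prices.
#'
#' @param k_obs Observed deviation factor (> 0, not 1).
#' @param delta_obs_percent Observed percent change in \[0, 100).
#' @return Sperm cost share `r` in \[0, 1).
#' @examples
#' calibrate_cost_share(2, 25) # 1/3
#' @export
calibrate_cost_share <- function(k_obs, delta_obs_percent) {
  if (!is.numeric(k_obs) || length(k_obs) != 1L || !is.finite(k_obs) ||
      k_obs <= 0) {
    stop("k_obs must be a single positive number", call. = FALSE)
  }
  if (k_obs == 1) {
    stop("k_obs = 1 carries no information about the cost share",
         call. = FALSE)
  }
  if (!is.numeric(delta_obs_percent) || length(delta_obs_percent) != 1L ||
      !is.finite(delta_obs_percent) || delta_obs_percent < 0 ||
      delta_obs_percent >= 100) {
    stop("delta_obs_percent must lie in [0, 100)", call. = FALSE)
  }
  d <- delta_obs_percent / 100
  r <- if (k_obs > 1) {
    d / ((1 - d) * (k_obs - 1))
  } else {
    (1 - k_obs / (1 - d)) / (1 - k_obs)
  }
  if (!is.finite(r) || r < 0 || r >= 1) {
    stop(sprintf(
      "observation (k = %g, delta = %g%%) implies cost share %.4g outside [0, 1)",
      k_obs, delta_obs_percent, r), call. = FALSE)
  }
  r
}

#' @export
print.gamete_cost_model <- function(x, ...) {
  cat("Gamete cost model\n")
  cat(sprintf("  sperm: price %g x %g cells = %g\n",
              x$price_per_sperm, x$sperm_used,
              x$price_per_sperm * x$sperm_used))
  cat(sprintf("  eggs:  price %g x %g eggs  = %g\n",
              x$price_per_egg, x$eggs_used, x$price_per_egg * x$eggs_used))
  cat(sprintf("  target fertilized  %g\n", x$target_fertilized))
  cat(sprintf("  sperm cost share r %.6g\n", x$cost_share_sperm))
  cat(sprintf("  UFE at k = 1       %.6g per currency unit\n", ufe(x)))
  invisible(x)
}
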