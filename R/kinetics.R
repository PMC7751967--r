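# 1:1 Langmuir SPR kinetics: closed-form sensorgram model and global
# nonlinear least-squares fitting of kon, koff and Rmax across a
# concentration series, with KD = koff/kon.

#' Closed-form 1:1 Langmuir sensorgram response
#'
#' Association: `R(t) = Req * (1 - exp(-(kon*C + koff) * t))` with
#' `Req = rmax * kon * C / (kon*C + koff)`. Dissociation (time measured from
#' the start of dissociation): `R(t) = R0 * exp(-koff * t)` where `R0` is
#' the response at the end of a `assoc_duration`-second association phase.
#'
#' @param t Time in seconds (within the phase), `t >= 0`.
#' @param kon Association rate, 1/(M*s), positive.
#' @param koff Dissociation rate, 1/s, positive.
#' @param rmax Maximal response, RU, positive.
#' @param concentration Analyte concentration, M.
#' @param phase `"association"` or `"dissociation"`.
#' @param assoc_duration Association length in seconds (needed for the
#'   dissociation phase to locate `R0`).
#' @return Response in RU, vectorized over `t`.
#' @export
langmuir_response <- function(t, kon, koff, rmax, concentration,
                              phase = c("association", "dissociation"),
                              assoc_duration = NULL) {
  phase <- match.arg(phase)
  if (kon <= 0 || koff <= 0 || rmax <= 0) {
    stop("kon, koff and rmax must all be positive")
  }
  if (any(t < 0)) stop("t must be non-negative")
  kobs <- kon * concentration + koff
  req <- rmax * kon * concentration / kobs
  if (phase == "association") {
    req * (1 - exp(-kobs * t))
  } else {
    if (is.null(assoc_duration)) {
      stop("assoc_duration is required for the dissociation phase")
    }
    r0 <- req * (1 - exp(-kobs * assoc_duration))
    r0 * exp(-koff * t)
  }
}

predict_sensorgram <- function(sg, kon, koff, rmax) {
  out <- numeric(nrow(sg))
  for (conc in unique(sg$conc_M)) {
    sel <- sg$conc_M == conc
    assoc <- sel & sg$phase == "association"
    diss <- sel & sg$phase == "dissociation"
    t_assoc <- if (any(assoc)) max(sg$time_s[assoc]) else max(sg$time_s[diss])
    if (any(assoc)) {
      out[assoc] <- langmuir_response(
        sg$time_s[assoc], kon, koff, rmax, conc, "association"
      )
    }
    if (any(diss)) {
      out[diss] <- langmuir_response(
        sg$time_s[diss], kon, koff, rmax, conc, "dissociation",
        assoc_duration = t_assoc
      )
    }
  }
  out
}

init_koff <- function(sg, bounds) {
  ests <- c()
  for (conc in unique(sg$conc_M)) {
    dd <- sg[sg$conc_M == conc & sg$phase == "dissociation", ]
    dd <- dd[dd$ru > 0, ]
    if (nrow(dd) < 4) next
    dd <- dd[dd$time_s >= stats::median(dd$time_s), ] # decay tail
    if (nrow(dd) < 3 || length(unique(dd$time_s)) < 2) next
    sl <- coef(lm(log(dd$ru) ~ dd$time_s))[2]
    if (is.finite(sl) && sl < 0) ests <- c(ests, -sl)
  }
  if (length(ests) == 0) {
    return(sqrt(prod(bounds)))
  }
  min(max(stats::median(ests), bounds[1]), bounds[2])
}

init_kon <- function(sg, koff0, bounds) {
  kobs <- c()
  concs <- c()
  for (conc in unique(sg$conc_M)) {
    aa <- sg[sg$conc_M == conc & sg$phase == "association", ]
    if (nrow(aa) < 5) next
    plateau <- max(aa$ru) * 1.05 + 1e-9
    y <- 1 - aa$ru / plateau
    keep <- y > 0.02
    if (sum(keep) < 3 || length(unique(aa$time_s[keep])) < 2) next
    sl <- coef(lm(log(y[keep]) ~ aa$time_s[keep]))[2]
    if (is.finite(sl) && sl < 0) {
      kobs <- c(kobs, -sl)
      concs <- c(concs, conc)
    }
  }
  if (length(kobs) >= 2 && length(unique(concs)) >= 2) {
    sl <- coef(lm(kobs ~ concs))[2]
    if (is.finite(sl) && sl > 0) {
      return(min(max(sl, bounds[1]), bounds[2]))
    }
  }
  # fall back: kobs at the top concentration
  if (length(kobs) >= 1) {
    k <- max(kobs) / max(concs)
    return(min(max(k, bounds[1]), bounds[2]))
  }
  sqrt(prod(bounds))
}

#' Globally fit the 1:1 Langmuir model to a concentration series
#'
#' Fits a single (kon, koff, rmax) triple to all sensorgrams of one clone by
#' Levenberg-Marquardt least squares (rates on a log10 scale), the standard
#' practice for Biacore-style evaluation. `KD = koff/kon` exactly.
#' Initialization follows the usual diagnostics: koff from a log-linear
#' regression of the dissociation tail, kon from the observed-rate versus
#' concentration slope.
#'
#' @param sensorgrams data.frame with columns `conc_M`, `phase`
#'   (`"association"`/`"dissociation"`, time measured from the phase start),
#'   `time_s`, `ru`; at least 3 concentrations with both phases.
#' @param kon_bounds,koff_bounds Box constraints (defaults `[1e2, 1e8]`
#'   1/(M*s) and `[1e-6, 1]` 1/s).
#' @param per_curve If `TRUE`, additionally returns per-concentration fits
#'   for diagnostics.
#' @return Object of class `kinetic_fit`: `kon`, `koff`, `rmax`, `kd` (M),
#'   `kd_nM`, `residual_rms` (RU), `converged`, `well_determined` (`FALSE`
#'   when every analyte concentration sits below the fitted KD) and
#'   optionally `per_curve`. Non-convergence is flagged (with a warning),
#'   never silent.
#' @export
fit_one_to_one <- function(sensorgrams,
                           kon_bounds = c(1e2, 1e8),
                           koff_bounds = c(1e-6, 1),
                           per_curve = FALSE) {
  sg <- sensorgrams
  stopifnot(all(c("conc_M", "phase", "time_s", "ru") %in% names(sg)))
  concs <- unique(sg$conc_M)
  if (length(concs) < 3) stop("need at least 3 analyte concentrations")
  if (!all(c("association", "dissociation") %in% sg$phase)) {
    stop("both association and dissociation phases are required")
  }

  koff0 <- init_koff(sg, koff_bounds)
  kon0 <- init_kon(sg, koff0, kon_bounds)
  rmax0 <- max(sg$ru) * 1.2 + 1e-6

  resid_fn <- function(par) {
    predict_sensorgram(sg, 10^par[1], 10^par[2], par[3]) - sg$ru
  }
  fit <- minpack.lm::nls.lm(
    par = c(log10(kon0), log10(koff0), rmax0),
    fn = resid_fn,
    lower = c(log10(kon_bounds[1]), log10(koff_bounds[1]), 1e-6),
    upper = c(log10(kon_bounds[2]), log10(koff_bounds[2]), 10 * rmax0),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  kon <- 10^fit$par[1]
  koff <- 10^fit$par[2]
  rmax <- fit$par[3]
  converged <- fit$info %in% 1:3
  if (!converged) {
    warning("1:1 Langmuir fit did not converge (info = ", fit$info, ")")
  }
  # identifiability: when every analyte concentration sits far below the
  # fitted KD the surface never approaches saturation and Rmax/kon are only
  # jointly determined
  well_determined <- max(concs) >= koff / kon
  if (!well_determined) {
    warning("fit poorly identified: all concentrations below the fitted KD")
  }
  res <- structure(
    list(
      kon = kon, koff = koff, rmax = rmax,
      kd = koff / kon, kd_nM = koff / kon * 1e9,
      residual_rms = sqrt(mean(fit$fvec^2)),
      converged = converged,
      well_determined = well_determined,
      n_concentrations = length(concs)
    ),
    class = "kinetic_fit"
  )
  if (per_curve) {
    res$per_curve <- lapply(setNames(concs, signif(concs, 4)), function(cc) {
      sub <- sg[sg$conc_M == cc, ]
      tryCatch(
        fit_single_curve(sub, kon, koff, rmax, kon_bounds, koff_bounds),
        error = function(e) NULL
      )
    })
  }
  res
}

fit_single_curve <- function(sg, kon0, koff0, rmax0, kon_bounds, koff_bounds) {
  fit <- minpack.lm::nls.lm(
    par = c(log10(kon0), log10(koff0), rmax0),
    fn = function(par) predict_sensorgram(sg, 10^par[1], 10^par[2], par[3]) - sg$ru,
    lower = c(log10(kon_bounds[1]), log10(koff_bounds[1]), 1e-6),
    upper = c(log10(kon_bounds[2]), log10(koff_bounds[2]), 10 * rmax0 + 10),
    control = minpack.lm::nls.lm.control(maxiter = 100)
  )
  c(kon = 10^fit$par[1], koff = 10^fit$par[2], rmax = fit$par[3])
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf(
    "<kinetic_fit> kon=%.3g 1/(M*s)  koff=%.3g 1/s  Rmax=%.1f RU  KD=%.4g nM  rms=%.2f RU%s\n",
    x$kon, x$koff, x$rmax, x$kd_nM, x$residual_rms,
    if (x$converged) "" else "  [NOT CONVERGED]"
  ))
  invisible(x)
}

#' Fit kinetics for every clone in a sensorgram table
#'
#' @param sensorgrams data.frame with a `clone_id` column plus the columns
#'   of [fit_one_to_one()].
#' @param ... Passed to [fit_one_to_one()].
#' @return data.frame of per-clone fits (`clone_id`, `kon`, `koff`, `rmax`,
#'   `kd_nM`, `residual_rms`, `converged`).
#' @export
fit_kinetics_table <- function(sensorgrams, ...) {
  ids <- unique(sensorgrams$clone_id)
  rows <- lapply(ids, function(id) {
    f <- fit_one_to_one(sensorgrams[sensorgrams$clone_id == id, ], ...)
    data.frame(
      clone_id = id, kon = f$kon, koff = f$koff, rmax = f$rmax,
      kd_nM = f$kd_nM, residual_rms = f$residual_rms, converged = f$converged,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
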