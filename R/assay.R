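# Enzyme-assay analysis: four-parameter-logistic potency, luminescent
# (UDP-Glo-style) signal simulation, and Cheng-Prusoff inhibition-mode
# prediction.

#' Four-parameter logistic response
#'
#' GraphPad-style inhibition convention: `response = bottom + (top -
#' bottom) / (1 + (dose/ic50)^hill)`, so hill > 0 means the response
#' falls with dose and `dose = ic50` gives the exact midpoint.
#'
#' @param dose Dose(s), uM, strictly positive.
#' @param bottom,top Lower/upper response asymptotes (fraction of the
#'   uninhibited, vehicle-normalized activity).
#' @param ic50 Half-maximal dose, uM, strictly positive.
#' @param hill Hill slope.
#' @return Response value(s).
#' @export
fourpl_response <- function(dose, bottom, top, ic50, hill) {
  if (any(dose <= 0)) stop("doses must be strictly positive", call. = FALSE)
  if (ic50 <= 0) stop("ic50 must be strictly positive", call. = FALSE)
  bottom + (top - bottom) / (1 + (dose / ic50)^hill)
}

#' The dose grid of the potency experiment
#'
#' Eight log-spaced doses spanning 0.25-500 uM, the range used for the
#' inhibitor dose-response measurements.
#'
#' @return Numeric vector of doses, uM.
#' @export
default_dose_grid <- function() {
  round(exp(seq(log(0.25), log(500), length.out = 8)), 3)
}

#' The UDP-GlcNAc substrate grid of the inhibition-mode experiment
#'
#' @return Numeric vector of substrate concentrations, uM.
#' @export
default_substrate_grid <- function() {
  c(2, 10, 25, 50, 100, 200, 400)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Bounded Levenberg-Marquardt least squares over (bottom, top, ic50,
#' hill) with a deterministic start heuristic: top/bottom from the
#' extreme-dose means, ic50 from the dose pair bracketing the
#' half-maximal response, hill 1. A curve that is flat within noise (no
#' detectable decline) is flagged right-censored with the ic50 bounded
#' below by the top tested dose rather than fitted.
#'
#' @param data Tibble with columns `dose_uM` and `response` (replicate
#'   rows allowed; an optional `replicate` column is ignored by the
#'   fit).
#' @param bottom_bounds,top_bounds,hill_bounds Parameter bounds.
#' @param ic50_bounds Default `c(min dose / 10, max dose * 10)`.
#' @return A `fourpl_fit`: estimates, standard errors, convergence and
#'   censoring flags, residual summary, and the data fitted. Supports
#'   [generics::tidy()], [generics::glance()], [ggplot2::autoplot()].
#' @export
fit_4pl <- function(data,
                    bottom_bounds = c(-0.1, 0.5),
                    top_bounds = c(0.5, 1.5),
                    ic50_bounds = NULL,
                    hill_bounds = c(0.1, 10)) {
  stopifnot(all(c("dose_uM", "response") %in% names(data)))
  data <- dplyr::filter(data, is.finite(.data$response))
  doses <- sort(unique(data$dose_uM))
  if (length(doses) < 4) stop("need >= 4 distinct doses", call. = FALSE)
  if (any(doses <= 0)) stop("doses must be strictly positive", call. = FALSE)
  if (is.null(ic50_bounds)) ic50_bounds <- c(min(doses) / 10, max(doses) * 10)

  mean_by_dose <- data |>
    dplyr::summarise(m = mean(.data$response), .by = "dose_uM") |>
    dplyr::arrange(.data$dose_uM)
  top0 <- mean_by_dose$m[1]
  bottom0 <- mean_by_dose$m[nrow(mean_by_dose)]
  decline <- top0 - bottom0
  noise <- stats::sd(data$response - mean_by_dose$m[match(data$dose_uM, mean_by_dose$dose_uM)])
  if (!is.finite(noise)) noise <- 0

  # flat-curve policy: no decline detectable within noise -> right-censored
  if (decline <= max(0.05, 2 * noise)) {
    fit <- structure(
      list(bottom = NA_real_, top = mean(data$response), ic50 = max(doses),
           hill = NA_real_, se = c(bottom = NA, top = NA, ic50 = NA, hill = NA),
           converged = FALSE, right_censored = TRUE,
           sigma = noise, n = nrow(data), data = data),
      class = "fourpl_fit"
    )
    return(fit)
  }

  half <- (top0 + bottom0) / 2
  below <- which(mean_by_dose$m <= half)
  ic50_0 <- if (length(below)) mean_by_dose$dose_uM[below[1]] else stats::median(doses)
  ic50_0 <- min(max(ic50_0, ic50_bounds[1]), ic50_bounds[2])
  start <- c(bottom = min(max(bottom0, bottom_bounds[1]), bottom_bounds[2]),
             top = min(max(top0, top_bounds[1]), top_bounds[2]),
             log_ic50 = log(ic50_0), hill = 1)
  lower <- c(bottom_bounds[1], top_bounds[1], log(ic50_bounds[1]), hill_bounds[1])
  upper <- c(bottom_bounds[2], top_bounds[2], log(ic50_bounds[2]), hill_bounds[2])

  resid_fn <- function(p, d) {
    d$response - (p[1] + (p[2] - p[1]) /
                    (1 + (d$dose_uM / exp(p[3]))^p[4]))
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = start, lower = lower, upper = upper,
      fn = resid_fn, d = data,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)
    ),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$info %in% 1:4) {
    return(structure(
      list(bottom = NA_real_, top = NA_real_, ic50 = NA_real_,
           hill = NA_real_, se = c(bottom = NA, top = NA, ic50 = NA, hill = NA),
           converged = FALSE, right_censored = FALSE,
           sigma = NA_real_, n = nrow(data), data = data),
      class = "fourpl_fit"
    ))
  }
  cf <- fit$par
  df_resid <- max(nrow(data) - 4, 1)
  sigma <- sqrt(fit$deviance / df_resid)
  se <- tryCatch(
    sqrt(diag(solve(fit$hessian)) * fit$deviance / df_resid),
    error = function(e) rep(NA_real_, 4)
  )
  names(se) <- names(cf)
  ic50 <- exp(cf[["log_ic50"]])
  ic50_se <- if (!is.na(se[["log_ic50"]])) ic50 * se[["log_ic50"]] else NA_real_
  structure(
    list(bottom = cf[["bottom"]], top = cf[["top"]], ic50 = ic50,
         hill = cf[["hill"]],
         se = c(bottom = unname(se[["bottom"]]), top = unname(se[["top"]]),
                ic50 = unname(ic50_se), hill = unname(se[["hill"]])),
         converged = TRUE, right_censored = FALSE,
         sigma = sigma, n = nrow(data), data = data),
    class = "fourpl_fit"
  )
}

#' @export
print.fourpl_fit <- function(x, ...) {
  if (x$right_censored) {
    cat(sprintf(
      "<fourpl_fit> flat response: right-censored, IC50 > %.3g uM (n = %d)\n",
      x$ic50, x$n))
  } else if (!x$converged) {
    cat("<fourpl_fit> fit did not converge\n")
  } else {
    cat(sprintf(
      "<fourpl_fit> IC50 = %.3g uM (se %.2g), hill = %.2f, top = %.2f, bottom = %.2f (n = %d)\n",
      x$ic50, x$se[["ic50"]], x$hill, x$top, x$bottom, x$n))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_4pl
#' @param x A `fourpl_fit`.
#' @param ... Unused.
#' @method tidy fourpl_fit
#' @export
tidy.fourpl_fit <- function(x, ...) {
  tibble::tibble(
    term = c("bottom", "top", "ic50", "hill"),
    estimate = c(x$bottom, x$top, x$ic50, x$hill),
    std.error = unname(x$se[c("bottom", "top", "ic50", "hill")])
  )
}

#' @rdname fit_4pl
#' @method glance fourpl_fit
#' @export
glance.fourpl_fit <- function(x, ...) {
  tibble::tibble(
    ic50 = x$ic50, hill = x$hill, sigma = x$sigma, nobs = x$n,
    converged = x$converged, right_censored = x$right_censored
  )
}

#' Inhibition-mode model
#'
#' Michaelis-Menten kinetics under a chosen reversible inhibition
#' mechanism. Defaults reflect the UDP-Glo kinetic analysis: substrate
#' is UDP-GlcNAc with an assumed Km of 20 uM, Ki 10 uM.
#'
#' @param mode One of `"competitive"`, `"noncompetitive"`,
#'   `"uncompetitive"`, `"mixed"`.
#' @param Ki Inhibition constant, uM.
#' @param Km Substrate Michaelis constant, uM.
#' @param Vmax Maximal rate (arbitrary units).
#' @param alpha Mixed-mode factor (only used for `mode = "mixed"`).
#' @return An `inhibition_model` list.
#' @export
inhibition_model <- function(mode = c("competitive", "noncompetitive",
                                      "uncompetitive", "mixed"),
                             Ki = 10, Km = 20, Vmax = 1, alpha = 1) {
  mode <- match.arg(mode)
  stopifnot(Ki > 0, Km > 0, Vmax > 0, alpha > 0)
  structure(list(mode = mode, Ki = Ki, Km = Km, Vmax = Vmax, alpha = alpha),
            class = "inhibition_model")
}

#' Closed-form IC50 at a given substrate concentration
#'
#' Cheng-Prusoff relations: competitive `Ki (1 + S/Km)`; uncompetitive
#' `Ki (1 + Km/S)`; noncompetitive `Ki`; mixed
#' `Ki (S + Km) / (Km + S/alpha)`.
#'
#' @param model An [inhibition_model()].
#' @param S Substrate concentration(s), uM.
#' @return Predicted IC50(s), uM.
#' @export
predicted_ic50 <- function(model, S) {
  stopifnot(inherits(model, "inhibition_model"))
  switch(model$mode,
    competitive = model$Ki * (1 + S / model$Km),
    uncompetitive = {
      if (any(S == 0)) stop("S = 0 undefined for uncompetitive IC50",
                            call. = FALSE)
      model$Ki * (1 + model$Km / S)
    },
    noncompetitive = rep(model$Ki, length(S)),
    mixed = model$Ki * (S + model$Km) / (model$Km + S / model$alpha)
  )
}

#' Michaelis-Menten rate under inhibition
#'
#' Standard forms: competitive `Vmax S / (Km (1 + I/Ki) + S)`;
#' noncompetitive `Vmax S / ((Km + S)(1 + I/Ki))`; uncompetitive
#' `Vmax S / (Km + S (1 + I/Ki))`; mixed
#' `Vmax S / (Km (1 + I/Ki) + S (1 + I/(alpha Ki)))`. With `I = 0` all
#' reduce to plain Michaelis-Menten.
#'
#' @param S Substrate concentration(s), uM (> 0).
#' @param model An [inhibition_model()].
#' @param I Inhibitor concentration, uM (>= 0).
#' @return Rate(s).
#' @export
inhibited_rate <- function(S, model, I = 0) {
  stopifnot(inherits(model, "inhibition_model"), all(S > 0), all(I >= 0))
  with(model, switch(mode,
    competitive = Vmax * S / (Km * (1 + I / Ki) + S),
    noncompetitive = Vmax * S / ((Km + S) * (1 + I / Ki)),
    uncompetitive = Vmax * S / (Km + S * (1 + I / Ki)),
    mixed = Vmax * S / (Km * (1 + I / Ki) + S * (1 + I / (alpha * Ki)))
  ))
}

#' Simulate a dose-response experiment
#'
#' Responses are the fractional activity (vehicle-normalized, as a
#' UDP-Glo luminescence readout proportional to turnover) of either a
#' 4PL curve (`params`) or a mechanistic [inhibition_model()] at
#' substrate concentration `S`, multiplied by lognormal noise at the
#' stated coefficient of variation. Reproducible for a fixed seed.
#'
#' @param doses Inhibitor doses, uM (default [default_dose_grid()]).
#' @param params 4PL parameter list `(bottom, top, ic50, hill)`; or
#'   `NULL` to use `model`.
#' @param model An [inhibition_model()] (used when `params` is `NULL`).
#' @param S Substrate concentration for the mechanistic curve, uM.
#' @param replicates Replicates per dose (default 3).
#' @param cv Multiplicative noise coefficient of variation (default
#'   0.05).
#' @param seed Integer seed.
#' @return Tibble: `dose_uM`, `replicate`, `response`.
#' @export
simulate_dose_response <- function(doses = default_dose_grid(),
                                   params = list(bottom = 0, top = 1,
                                                 ic50 = 21.8, hill = 1),
                                   model = NULL, S = 40,
                                   replicates = 3, cv = 0.05, seed = 1) {
  stopifnot(replicates >= 1, cv >= 0)
  if (is.null(params)) {
    stopifnot(inherits(model, "inhibition_model"))
    v0 <- inhibited_rate(S, model, 0)
    mu <- vapply(doses, function(d) inhibited_rate(S, model, d) / v0,
                 numeric(1))
  } else {
    mu <- fourpl_response(doses, params$bottom, params$top,
                          params$ic50, params$hill)
  }
  grid <- tidyr::expand_grid(dose_uM = doses,
                             replicate = seq_len(replicates))
  mu_all <- rep(mu, each = replicates)
  noise <- withr_seed(seed, {
    if (cv > 0) {
      sdlog <- sqrt(log(1 + cv^2))
      stats::rlnorm(nrow(grid), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else rep(1, nrow(grid))
  })
  dplyr::mutate(grid, response = mu_all * noise)
}

# run code under a local RNG seed without touching the global stream
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
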