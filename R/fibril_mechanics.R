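# Worm-like-chain mechanics: trace measurement, the 2D WLC end-to-end
# relation, persistence-length fitting and bending rigidity.

#' Measure contour length and end-to-end distance of a trace
#'
#' @param trace a `fibril_trace` (or any data frame with `x_nm`, `y_nm`).
#' @return named numeric `c(L_nm, D_nm)`: contour length (sum of segment
#'   lengths) and end-to-end distance (first to last vertex), both in
#'   nanometres. `D <= L` always.
#' @examples
#' measure_trace(fibril_trace(c(0, 1, 1), c(0, 0, 1)))
#' @export
measure_trace <- function(trace) {
  if (is.null(trace$x_nm) || is.null(trace$y_nm) || nrow(trace) < 2) {
    stop("measure_trace: need a trace with >= 2 vertices")
  }
  seg <- sqrt(diff(trace$x_nm)^2 + diff(trace$y_nm)^2)
  L <- sum(seg)
  D <- sqrt((trace$x_nm[nrow(trace)] - trace$x_nm[1])^2 +
            (trace$y_nm[nrow(trace)] - trace$y_nm[1])^2)
  c(L_nm = L, D_nm = D)
}

#' Measure an ensemble of traces
#'
#' @param traces list of `fibril_trace` objects.
#' @return data frame with one row per fibril: `fibril_id`, `L_um`,
#'   `D_um` (micrometres — the unit the persistence-length fit works in).
#' @export
measure_traces <- function(traces) {
  rows <- lapply(traces, function(tr) {
    m <- measure_trace(tr)
    data.frame(fibril_id = attr(tr, "fibril_id") %||% NA_character_,
               L_um = m[["L_nm"]] / 1000,
               D_um = m[["D_nm"]] / 1000,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Expected squared end-to-end distance of a 2D worm-like chain
#'
#' Evaluates the surface-equilibrated (two-dimensional) worm-like-chain
#' relation
#' \deqn{\langle D^2\rangle = 4PL\left[1 - \frac{2P}{L}
#'   \left(1 - e^{-L/2P}\right)\right]}
#' for contour length L and persistence length P. In the rigid limit
#' (L << P) this tends to L^2; in the flexible limit (L >> P) to 4PL.
#'
#' @param L contour length (micrometres), > 0. Vectorized.
#' @param P persistence length (micrometres), > 0.
#' @return expected squared end-to-end distance (micrometres squared),
#'   strictly between 0 and L^2.
#' @examples
#' wlc_expected_sq_end_to_end(6.7, 6.7)
#' @export
wlc_expected_sq_end_to_end <- function(L, P) {
  if (any(L <= 0) || any(P <= 0)) {
    stop("wlc_expected_sq_end_to_end: L and P must be > 0")
  }
  x <- L / (2 * P)
  # expm1 keeps the rigid limit (x -> 0) accurate
  4 * P * L * (1 + expm1(-x) / x)
}

#' Fit the persistence length to (L, D) observations
#'
#' Least-squares fit of per-fibril squared end-to-end distance D^2
#' against contour length L under the 2D worm-like-chain relation
#' (see [wlc_expected_sq_end_to_end()]), one observation per fibril.
#'
#' D^2 observations are strongly heteroscedastic — their variance grows
#' roughly like the squared model value — so the default is relative
#' (inverse-squared-model-weighted) least squares, solved by iterative
#' reweighting: an unweighted fit seeds the weights, which are then
#' refreshed from the fitted curve over two passes. This keeps the fit
#' from being dominated by the noisiest (longest) fibrils and removes
#' most of the small-sample bias of the unweighted fit. `weights =
#' "none"` gives the plain unweighted fit of the D^2-vs-L plot.
#'
#' The uncertainty is reported two ways, since either convention occurs
#' in the literature: the asymptotic standard error of the nonlinear
#' least-squares fit and the standard deviation of fits over bootstrap
#' resamples of the fibrils (seeded).
#'
#' Straight-fibril degeneracy: when every D equals L the relation has no
#' finite optimum; the fit is bounded above at `p_cap` and a fit that
#' lands on the cap is flagged `converged = FALSE`.
#'
#' @param observations data frame with columns `L_um` and `D_um`
#'   (micrometres; >= 2 rows, `0 < D <= L`), e.g. from [measure_traces()].
#' @param temperature temperature in kelvin for the bending-rigidity
#'   conversion (default 300).
#' @param n_bootstrap bootstrap resamples for the uncertainty (default
#'   1000; 0 disables).
#' @param seed seed for the bootstrap resampling.
#' @param weights `"relative"` (default; inverse-squared-model weights,
#'   iteratively reweighted) or `"none"` (unweighted).
#' @param p_cap upper bound on P (micrometres, default 1000) guarding the
#'   rigid-limit degeneracy.
#' @return object of class `wlc_fit`: list with `P_um`, `P_se_um`
#'   (asymptotic), `P_se_boot_um` (bootstrap, `NA` if disabled),
#'   `B_Nm2` (bending rigidity, `P * kB * T`), `temperature_K`,
#'   `kB` (1.380649e-23 J/K), `n_fibrils`, `converged`.
#' @examples
#' obs <- data.frame(L_um = c(1, 2, 4, 8),
#'                   D_um = sqrt(wlc_expected_sq_end_to_end(c(1, 2, 4, 8), 2)))
#' fit_persistence_length(obs, n_bootstrap = 0)
#' @export
fit_persistence_length <- function(observations, temperature = 300,
                                   n_bootstrap = 1000, seed = 42L,
                                   weights = c("relative", "none"),
                                   p_cap = 1000) {
  weights <- match.arg(weights)
  obs <- as.data.frame(observations)
  if (nrow(obs) < 2) stop("fit_persistence_length: need >= 2 observations")
  if (any(obs$L_um <= 0) || any(obs$D_um <= 0)) {
    stop("fit_persistence_length: L and D must be positive")
  }
  if (any(obs$D_um > obs$L_um * (1 + 1e-9))) {
    stop("fit_persistence_length: D must not exceed L")
  }
  fit_once <- function(df) {
    p0 <- min(max(max(df$D_um^2) / (4 * max(df$L_um)), 0.01), 100)
    dat <- data.frame(L = df$L_um, D2 = df$D_um^2)
    fit <- minpack.lm::nlsLM(
      D2 ~ wlc_expected_sq_end_to_end(L, P),
      data = dat, start = list(P = p0), lower = 1e-4, upper = p_cap,
      control = minpack.lm::nls.lm.control(maxiter = 200))
    if (weights == "relative") {
      for (pass in 1:2) {
        w <- 1 / wlc_expected_sq_end_to_end(dat$L, coef(fit)[["P"]])^2
        fit <- minpack.lm::nlsLM(
          D2 ~ wlc_expected_sq_end_to_end(L, P),
          data = dat, start = list(P = coef(fit)[["P"]]),
          weights = w, lower = 1e-4, upper = p_cap,
          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }
    fit
  }
  fit <- tryCatch(fit_once(obs), error = function(e) {
    stop("fit_persistence_length: fit failed to converge: ",
         conditionMessage(e))
  })
  P <- unname(coef(fit)[["P"]])
  se <- tryCatch(summary(fit)$coefficients["P", "Std. Error"],
                 error = function(e) NA_real_)
  boot_se <- NA_real_
  if (n_bootstrap > 0) {
    set.seed(seed)
    pb <- vapply(seq_len(n_bootstrap), function(i) {
      idx <- sample.int(nrow(obs), replace = TRUE)
      tryCatch(unname(coef(fit_once(obs[idx, , drop = FALSE]))[["P"]]),
               error = function(e) NA_real_)
    }, numeric(1))
    boot_se <- sd(pb, na.rm = TRUE)
  }
  converged <- P < p_cap * (1 - 1e-6)
  if (!converged) {
    warning("fit_persistence_length: P at the rigid-limit cap (",
            p_cap, " um); data are consistent with straight fibrils")
  }
  structure(list(P_um = P, P_se_um = unname(se), P_se_boot_um = boot_se,
                 B_Nm2 = bending_rigidity(P, temperature),
                 temperature_K = temperature, kB = .kB,
                 n_fibrils = nrow(obs), converged = converged),
            class = "wlc_fit")
}

#' @export
print.wlc_fit <- function(x, ...) {
  cat(sprintf(
    "worm-like-chain fit (n = %d fibrils)\n  P = %.3g um (fit se %.2g, bootstrap se %.2g)\n  B = %.4g N m^2 at T = %g K\n",
    x$n_fibrils, x$P_um, x$P_se_um, x$P_se_boot_um, x$B_Nm2,
    x$temperature_K))
  if (!x$converged) cat("  WARNING: fit hit the rigid-limit cap\n")
  invisible(x)
}

#' Bending rigidity from persistence length
#'
#' Converts a persistence length to a bending rigidity via
#' `B = P * kB * T`, with P converted from micrometres to metres and kB
#' the exact CODATA Boltzmann constant 1.380649e-23 J/K.
#'
#' @param P persistence length in micrometres (>= 0).
#' @param T_K temperature in kelvin (> 0, default 300).
#' @return bending rigidity in N m^2.
#' @examples
#' bending_rigidity(6.7, 300)
#' @export
bending_rigidity <- function(P, T_K = 300) {
  if (any(P < 0)) stop("bending_rigidity: P must be >= 0")
  if (any(T_K <= 0)) stop("bending_rigidity: T must be > 0")
  (P * 1e-6) * .kB * T_K
}
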