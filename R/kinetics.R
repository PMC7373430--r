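#' FRAP / iFRAP trace container
#'
#' Raw intensities of a photobleaching experiment on the post-bleach
#' timebase (t = 0 at the first post-bleach frame).
#'
#' @param t Time in seconds, strictly increasing, starting at 0.
#' @param I_roi Bleached-ROI intensity per frame, a.u.
#' @param I_unbleached Reference (unbleached P body) intensity per frame,
#'   a.u.; corrects for photobleaching by image acquisition.
#' @param I_background Background intensity, a.u. (scalar).
#' @param I_cyto_before,I_cyto_after Mean cytoplasm intensity before the
#'   bleach pulse and in the first post-bleach frame, a.u.
#' @param I_prebleach Pre-bleach ROI intensity, a.u.
#' @param mode `"recovery"` (FRAP) or `"decay"` (iFRAP).
#' @return An object of class `frap_trace`.
#' @export
frap_trace <- function(t, I_roi, I_unbleached, I_background,
                       I_cyto_before = NA_real_, I_cyto_after = NA_real_,
                       I_prebleach = NA_real_,
                       mode = c("recovery", "decay")) {
  mode <- match.arg(mode)
  if (length(t) < 3L || any(diff(t) <= 0)) {
    stop("t must be strictly increasing with >= 3 samples", call. = FALSE)
  }
  if (length(I_roi) != length(t) || length(I_unbleached) != length(t)) {
    stop("intensity channels must match the timebase length", call. = FALSE)
  }
  structure(list(t = as.numeric(t), I_roi = as.numeric(I_roi),
                 I_unbleached = as.numeric(I_unbleached),
                 I_background = I_background,
                 I_cyto_before = I_cyto_before, I_cyto_after = I_cyto_after,
                 I_prebleach = I_prebleach, mode = mode),
            class = "frap_trace")
}

#' Normalize a FRAP recovery trace
#'
#' Double normalization: the background-subtracted ROI is divided by the
#' background-subtracted unbleached reference at each frame (removing
#' acquisition photobleaching), multiplied by the cytoplasm after/before
#' ratio (accounting for partial bleaching of the cytoplasmic pool), and
#' rescaled so the pre-bleach level equals one. The pre-bleach scaling uses
#' the first post-bleach reference frame, since pre-bleach cytoplasm is by
#' definition unbleached.
#'
#' @param trace A [frap_trace()] with `mode = "recovery"`.
#' @param cyto_mode `"after_over_before"` (default) multiplies by
#'   (I_cyto_after - bg)/(I_cyto_before - bg); `"before_over_after"` is the
#'   alternative reading of the normalization.
#' @return Numeric vector of normalized intensities, ~1 pre-bleach.
#' @export
normalize_frap <- function(trace, cyto_mode = c("after_over_before",
                                                "before_over_after")) {
  stopifnot(inherits(trace, "frap_trace"))
  cyto_mode <- match.arg(cyto_mode)
  if (trace$mode != "recovery") {
    stop("normalize_frap expects a recovery-mode trace", call. = FALSE)
  }
  bg <- trace$I_background
  ref <- trace$I_unbleached - bg
  roi <- trace$I_roi - bg
  if (any(ref <= 0)) stop("unbleached reference is not above background",
                          call. = FALSE)
  cb <- trace$I_cyto_before - bg
  ca <- trace$I_cyto_after - bg
  cfac <- if (is.finite(cb) && is.finite(ca) && cb > 0 && ca > 0) {
    if (cyto_mode == "after_over_before") ca / cb else cb / ca
  } else 1
  pre <- trace$I_prebleach - bg
  if (!is.finite(pre) || pre <= 0) {
    stop("pre-bleach intensity must exceed background", call. = FALSE)
  }
  # rescale so the pre-bleach level is 1: the pre-bleach expression has no
  # cytoplasm factor and an unbleached reference equal to ref[1]
  (roi / ref) * cfac / (pre / ref[1])
}

#' Normalize an iFRAP decay trace
#'
#' Bleach-corrected intensities scaled to the first post-bleach frame:
#' \eqn{I_t = [(I - bg)/(I_{unbleached} - bg)] / [(I_{pre} - bg) /
#' (I_{unbleached,1} - bg)]} so that \eqn{I_t(0) = 1}, where \eqn{I_{pre}}
#' is the first post-bleach ROI reading.
#'
#' @param trace A [frap_trace()] with `mode = "decay"`.
#' @return Numeric vector of normalized intensities, 1 at t = 0.
#' @export
normalize_ifrap <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  if (trace$mode != "decay") {
    stop("normalize_ifrap expects a decay-mode trace", call. = FALSE)
  }
  bg <- trace$I_background
  ref <- trace$I_unbleached - bg
  roi <- trace$I_roi - bg
  if (any(ref <= 0)) stop("unbleached reference is not above background",
                          call. = FALSE)
  corr <- roi / ref
  if (corr[1] <= 0) stop("first post-bleach frame is not above background",
                         call. = FALSE)
  corr / corr[1]
}

#' Fit a single-exponential recovery
#'
#' Least squares of \eqn{I(t) = I_\infty + (I_0 - I_\infty) e^{-kt}} with
#' k constrained non-negative. Starting values: I0 from the first point,
#' I_inf from the mean of the last three, k from a log-linear regression on
#' the normalized approach to the plateau; five multi-starts with k jittered
#' by factors in [0.5, 2] guard against local minima. The fractional
#' recovery is \eqn{F = (I_\infty - I_0)/(1 - I_0)}.
#'
#' @param t Time in seconds.
#' @param I_t Normalized intensities from [normalize_frap()].
#' @return An `exp_fit`: `I0`, `Iinf`, `k`, `frac`, `residual_sd`,
#'   `converged`, `k_identifiable`.
#' @export
fit_recovery <- function(t, I_t) {
  fit_exponential(t, I_t, mode = "recovery")
}

#' Fit a single-exponential decay
#'
#' As [fit_recovery()] but for iFRAP decays; the fractional decay is
#' \eqn{F = I_0 - I_\infty}.
#'
#' @inheritParams fit_recovery
#' @param I_t Normalized intensities from [normalize_ifrap()].
#' @return An `exp_fit`.
#' @export
fit_decay <- function(t, I_t) {
  fit_exponential(t, I_t, mode = "decay")
}

fit_exponential <- function(t, I_t, mode) {
  stopifnot(length(t) >= 4L, length(I_t) == length(t), all(is.finite(I_t)))
  frac_of <- function(I0, Iinf) {
    if (mode == "recovery") (Iinf - I0) / (1 - I0) else I0 - Iinf
  }
  # degenerate: flat trace, k unidentifiable
  if (stats::sd(I_t) < 1e-12 * max(abs(I_t), 1)) {
    return(structure(list(I0 = I_t[1], Iinf = I_t[1], k = 0,
                          frac = 0, residual_sd = 0, converged = TRUE,
                          k_identifiable = FALSE), class = "exp_fit"))
  }
  I0_s <- I_t[1]
  Iinf_s <- mean(utils::tail(I_t, 3))
  k_s <- initial_rate_guess(t, I_t, I0_s, Iinf_s)
  best <- NULL
  for (jit in c(1, 0.5, 2, 0.7071, 1.4142)) {
    st <- list(I0 = I0_s, Iinf = Iinf_s, k = max(k_s * jit, 1e-6))
    fit <- try(minpack.lm::nlsLM(
      I_t ~ Iinf + (I0 - Iinf) * exp(-k * t),
      data = data.frame(t = t, I_t = I_t), start = st,
      lower = c(I0 = -Inf, Iinf = -Inf, k = 0),
      control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-12,
                                           ptol = 1e-12)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    sse <- sum(stats::resid(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) {
    return(structure(list(I0 = I0_s, Iinf = Iinf_s, k = NA_real_,
                          frac = NA_real_, residual_sd = NA_real_,
                          converged = FALSE, k_identifiable = FALSE),
                     class = "exp_fit"))
  }
  cf <- stats::coef(best$fit)
  n <- length(t)
  structure(list(
    I0 = unname(cf["I0"]), Iinf = unname(cf["Iinf"]), k = unname(cf["k"]),
    frac = frac_of(unname(cf["I0"]), unname(cf["Iinf"])),
    residual_sd = sqrt(best$sse / max(n - 3, 1)),
    converged = TRUE,
    k_identifiable = abs(cf["Iinf"] - cf["I0"]) >
      1e-6 * max(abs(cf[c("I0", "Iinf")]), 1)),
    class = "exp_fit")
}

# log-linear slope of the normalized distance to the plateau
initial_rate_guess <- function(t, I_t, I0, Iinf) {
  y <- (Iinf - I_t) / (Iinf - I0)
  ok <- is.finite(y) & y > 1e-6
  if (sum(ok) < 2L) return(1 / max(t[t > 0], 1))
  sl <- stats::coef(stats::lm(log(y[ok]) ~ t[ok]))[2]
  max(-unname(sl), 1e-6)
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf(
    "exponential fit: k = %.4g /s, I0 = %.4g, Iinf = %.4g, F = %.4g (%s)\n",
    x$k, x$I0, x$Iinf, x$frac,
    if (isTRUE(x$converged)) "converged" else "NOT converged"))
  if (!isTRUE(x$k_identifiable)) cat("  note: k is unidentifiable (flat trace)\n")
  invisible(x)
}

#' Read / write FRAP traces as CSV
#'
#' Columns `t_s`, `I_roi`, `I_unbleached`; scalars (`I_background`,
#' `I_cyto_before`, `I_cyto_after`, `I_prebleach`, `mode`) travel in
#' commented header lines `# key: value`.
#'
#' @param trace A [frap_trace()]. @param path File path.
#' @return `read_frap_trace` returns a [frap_trace()].
#' @export
write_frap_trace <- function(trace, path) {
  stopifnot(inherits(trace, "frap_trace"))
  hdr <- c(sprintf("# I_background: %.10g", trace$I_background),
           sprintf("# I_cyto_before: %.10g", trace$I_cyto_before),
           sprintf("# I_cyto_after: %.10g", trace$I_cyto_after),
           sprintf("# I_prebleach: %.10g", trace$I_prebleach),
           sprintf("# mode: %s", trace$mode))
  writeLines(hdr, path)
  suppressWarnings(utils::write.table(
    data.frame(t_s = trace$t, I_roi = trace$I_roi,
               I_unbleached = trace$I_unbleached),
    path, sep = ",", row.names = FALSE, append = TRUE, quote = FALSE))
  invisible(path)
}

#' @rdname write_frap_trace
#' @export
read_frap_trace <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key, default = NA_real_) {
    m <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(m)) return(default)
    sub(paste0("^# ", key, ":\\s*"), "", m[1])
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  frap_trace(t = df$t_s, I_roi = df$I_roi, I_unbleached = df$I_unbleached,
             I_background = as.numeric(get("I_background", "0")),
             I_cyto_before = as.numeric(get("I_cyto_before")),
             I_cyto_after = as.numeric(get("I_cyto_after")),
             I_prebleach = as.numeric(get("I_prebleach")),
             mode = get("mode", "recovery"))
}
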