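# Biexponential logicle scale (Parks-Roeder-Moore parameterization).
#
# The scale is defined through its inverse: on the relative scale
# y in [0, 1],
#     B(y) = alpha * exp(beta * y) - gamma * exp(-delta * y) - f
# with the constants fixed so that B(x1) = 0 and B(1) = t, and with the
# curve reflected about x1 for y < x1 (the negative tail).  Constants are
# derived from (w, t, m, a):
#     relW = w / (m + a);  x2 = a / (m + a);  x1 = x2 + relW;
#     x0 = x2 + 2 * relW;  beta = (m + a) * ln(10)
# and delta solves 2 * ln(delta / beta) + relW * (delta + beta) = 0.
# The forward transform is obtained by root finding (monotone, so a
# bracketed search converges; absolute tolerance 1e-10 on the relative
# scale, well inside the 1e-8 contract on the decade scale).
logicleConstants <- function(params) {
    w <- params@w; t <- params@t; m <- params@m; a <- params@a
    denom <- m + a
    relW <- w / denom
    x2 <- a / denom
    x1 <- x2 + relW
    x0 <- x2 + 2 * relW
    beta <- denom * log(10)
    if (relW == 0) {
        delta <- beta   # pure log scale limit
    } else {
        delta <- stats::uniroot(
            function(d) 2 * log(d / beta) + relW * (d + beta),
            lower = beta * 1e-12, upper = beta, tol = 1e-14
        )$root
    }
    ca <- exp(x0 * (beta + delta))
    fa <- exp(beta * x1) - ca * exp(-delta * x1)
    alpha <- t / (exp(beta) - fa - ca * exp(-delta))
    list(alpha = alpha, beta = beta, delta = delta,
         gamma = ca * alpha, f = fa * alpha, x1 = x1, denom = denom,
         a = a)
}

biexpRelative <- function(y, k) {
    refl <- y < k$x1
    yy <- ifelse(refl, 2 * k$x1 - y, y)
    v <- k$alpha * exp(k$beta * yy) - k$gamma * exp(-k$delta * yy) - k$f
    ifelse(refl, -v, v)
}

logicleScalar <- function(x, k) {
    # bracket on the relative scale; the data range [B(-0.5), B(1.5)]
    # comfortably covers any finite cytometry intensity
    lo <- -0.5; hi <- 1.5
    while (biexpRelative(lo, k) > x) lo <- lo * 2
    while (biexpRelative(hi, k) < x) hi <- hi * 2
    stats::uniroot(function(y) biexpRelative(y, k) - x,
                   lower = lo, upper = hi, tol = 1e-10)$root
}

#' Logicle transformation of cytometry intensities
#'
#' Maps raw intensities through the standard biexponential logicle scale:
#' approximately logarithmic for large values, linear in a region of width
#' \code{w} decades around zero, with \code{a} additional negative decades.
#' Output is in display decades: the top of scale \code{t} maps to \code{m}
#' and zero maps to \code{w} (for any \code{a}), so binning downstream sees
#' values in roughly [0, m].  The transform is strictly monotone, hence the
#' equal-frequency binning of the pipeline is invariant to it; it matters
#' only for interpretability of mean-intensity profiles and plots.
#'
#' @param sample a [CellSample-class] (or a bare numeric vector).
#' @param params a [LogicleParams-class]; defaults w = 0.5, t = 262144,
#'   m = 4.5, a = 0 (typical 18-bit flow cytometry).
#' @param markers optional character vector restricting which columns are
#'   transformed; default all.
#' @return The sample with transformed intensities (or a numeric vector).
#' @examples
#' p <- logicleParams(w = 0.25, t = 16409, m = 4.5, a = 0)
#' logicleTransform(c(0, 100, 16409), p)
#' @export
logicleTransform <- function(sample, params = logicleParams(),
                             markers = NULL) {
    stopifnot(is(params, "LogicleParams"))
    validObject(params)
    k <- logicleConstants(params)
    tf <- function(v) {
        (vapply(v, logicleScalar, numeric(1), k = k) * k$denom) - k$a
    }
    if (is.numeric(sample)) return(tf(sample))
    stopifnot(is(sample, "CellSample"))
    x <- intensities(sample)
    if (is.null(markers)) markers <- colnames(x)
    missing <- setdiff(markers, colnames(x))
    if (length(missing)) {
        stop("markers not present: ", paste(missing, collapse = ", "))
    }
    x[, markers] <- apply(x[, markers, drop = FALSE], 2, tf)
    cellSample(x, sampleId = sampleId(sample),
               groupLabel = groupLabel(sample))
}

#' Inverse logicle (display decades back to raw intensity)
#'
#' @param y numeric vector on the decade scale produced by
#'   [logicleTransform()].
#' @param params a [LogicleParams-class].
#' @return numeric vector of raw-scale intensities.
#' @export
inverseLogicle <- function(y, params = logicleParams()) {
    stopifnot(is(params, "LogicleParams"))
    k <- logicleConstants(params)
    biexpRelative((y + k$a) / k$denom, k)
}
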