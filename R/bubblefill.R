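# BubbleFill baseline estimation.
#
# The autofluorescence background under tissue Raman spectra is broad and
# smooth while the Raman bands are narrow. BubbleFill exploits this scale
# separation geometrically: circles ("bubbles") are grown from below the
# spectrum in span-normalized coordinates; each bubble is lifted until it
# touches the data, the touch point splits the span, and the recursion
# continues until spans are narrower than the smallest allowed bubble.
# The upper envelope of all bubble arcs, lightly smoothed, is the baseline.
# Bubbles wider than the Raman bands cannot enter the peaks, so the bands
# survive in the residual.
#
# Implementation notes (the algorithm's published description is not
# reproduced here, so this is a faithful reconstruction): the linear trend
# through the spectrum endpoints is removed before growing bubbles and
# restored afterwards, which makes the method exact on straight-line
# baselines; spans touching a spectrum boundary grow edge-aligned bubbles
# (apex at the boundary, radius = span width); outside the outermost touch
# points the envelope is replaced by the chord to the spectrum endpoints,
# which are treated as background anchors (the fingerprint range is chosen
# so that no Raman band sits at its extremes).

#' BubbleFill baseline removal
#'
#' Estimates the smooth background of a spectrum by recursive bubble
#' growing and returns both components. The decomposition is conservative:
#' `baseline + raman` reconstructs the input exactly.
#'
#' @param s A [RamanSpectrum-class] (typically at stage `"calibrated"`).
#' @param minBubbleWidth Smallest bubble width in cm^-1 (default 50); must
#'   exceed the axis spacing. Bands narrower than this survive in the
#'   Raman component.
#' @param smoothWidth Width (cm^-1) of the moving-average smoothing applied
#'   to the bubble envelope; default `minBubbleWidth / 4`.
#' @param preSmooth If `TRUE`, bubbles are grown against a lightly
#'   smoothed copy of the spectrum (same width as `smoothWidth`) so that
#'   under heavy noise the envelope tracks the local mean rather than the
#'   lower envelope of the noise; the returned decomposition is still of
#'   the raw input. Default `FALSE`.
#' @return A list of class `"BaselineFit"` with elements `baseline`,
#'   `raman` (both length-P numeric) and `minBubbleWidth`.
#' @examples
#' ax <- seq(600, 1800)
#' y <- exp(-(ax - 600) / 500) * 100 + exp(-(ax - 1004)^2 / 18)
#' fit <- bubbleFill(RamanSpectrum(ax, y))
#' stopifnot(all(abs(fit$baseline + fit$raman - y) < 1e-12))
#' @export
bubbleFill <- function(s, minBubbleWidth = 50,
                       smoothWidth = minBubbleWidth / 4,
                       preSmooth = FALSE) {
    stopifnot(is(s, "RamanSpectrum"))
    x <- s@wavenumber
    y <- s@intensity
    n <- length(y)
    dx <- mean(diff(x))
    if (minBubbleWidth <= dx)
        stop("minBubbleWidth (", minBubbleWidth,
             " cm-1) must exceed the axis spacing (", signif(dx, 3), " cm-1)")
    if ((x[n] - x[1]) < minBubbleWidth)
        stop("spectrum span is shorter than one bubble width")

    .movavg <- function(z, k) {
        if (k < 3L || k >= n) return(z)
        if (k %% 2 == 0) k <- k + 1L
        pad <- (k - 1L) %/% 2L
        zp <- c(rep(z[1], pad), z, rep(z[length(z)], pad))
        as.numeric(stats::filter(zp, rep(1 / k, k),
                                 sides = 2))[(pad + 1):(pad + length(z))]
    }

    # remove the endpoint-to-endpoint linear trend
    trend <- y[1] + (y[n] - y[1]) * (x - x[1]) / (x[n] - x[1])
    y0 <- y - trend
    if (preSmooth) y0 <- .movavg(y0, round(smoothWidth / dx))
    rng <- diff(range(y0))
    if (rng == 0) {
        return(structure(list(baseline = y, raman = numeric(n),
                              minBubbleWidth = minBubbleWidth),
                         class = "BaselineFit"))
    }

    # square-normalized coordinates
    u <- (x - x[1]) / (x[n] - x[1])
    v <- (y0 - min(y0)) / rng
    wmin <- minBubbleWidth / (x[n] - x[1])

    env <- rep(min(v), n)      # infinite-radius initial bubble
    touched <- logical(n)
    k0 <- which.min(v)
    touched[k0] <- TRUE

    # explicit DFS stack of spans: columns i, j, alignment
    # (0 center, 1 left edge, 2 right edge)
    stk <- matrix(0L, nrow = 3L, ncol = 64L)
    top <- 0L
    push <- function(i, j, al) {
        if (j - i >= 2L && (u[j] - u[i]) >= wmin) {
            top <<- top + 1L
            if (top > ncol(stk))
                stk <<- cbind(stk, matrix(0L, 3L, ncol(stk)))
            stk[, top] <<- c(i, j, al)
        }
    }
    push(1L, k0, 1L)
    push(k0, n, 2L)

    while (top > 0L) {
        i <- stk[1L, top]; j <- stk[2L, top]; al <- stk[3L, top]
        top <- top - 1L
        w <- u[j] - u[i]
        uc <- if (al == 1L) u[i] else if (al == 2L) u[j] else (u[i] + u[j]) / 2
        r <- if (al == 0L) w / 2 else w
        uu <- u[i:j]
        arc <- sqrt(pmax(r^2 - (uu - uc)^2, 0))
        rel <- v[i:j] - arc
        kk <- which.min(rel)
        arc <- arc + rel[kk]
        seg <- i:j
        env[seg] <- pmax(env[seg], arc)
        k <- i - 1L + kk
        touched[k] <- TRUE
        if (k > i && k < j) {      # strictly interior touch splits the span
            push(i, k, if (i == 1L) 1L else 0L)
            push(k, j, if (j == n) 2L else 0L)
        }
    }

    # anchor the edges: replace the envelope outside the outermost touch
    # points by the chord to the spectrum endpoints
    t1 <- which(touched)[1]
    t2 <- which(touched)[sum(touched)]
    if (t1 > 1L) {
        idx <- 1:t1
        env[idx] <- v[1] + (env[t1] - v[1]) * (u[idx] - u[1]) / (u[t1] - u[1])
    }
    if (t2 < n) {
        idx <- t2:n
        env[idx] <- env[t2] + (v[n] - env[t2]) * (u[idx] - u[t2]) /
            (u[n] - u[t2])
    }

    baseline <- env * rng + min(y0) + trend
    # light smoothing of the envelope (edges handled by padding)
    k <- max(3L, round(smoothWidth / dx))
    if (k %% 2 == 0) k <- k + 1L
    if (k < n) {
        pad <- (k - 1L) %/% 2L
        bp <- c(rep(baseline[1], pad), baseline, rep(baseline[n], pad))
        baseline <- as.numeric(stats::filter(bp, rep(1 / k, k),
                                             sides = 2))[(pad + 1):(pad + n)]
    }
    structure(list(baseline = baseline, raman = y - baseline,
                   minBubbleWidth = minBubbleWidth),
              class = "BaselineFit")
}
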