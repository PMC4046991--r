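# Independent oracles and fixture builders used across the suite.

# Naive double-loop moment-ellipse computation (area-matched, 1/12 pixel
# term), deliberately written scalar-wise and solving the eigenproblem via
# the characteristic polynomial rather than the half/disc form the package
# uses.
bruteEllipse <- function(pix) {
    pix <- as.matrix(pix)
    n <- nrow(pix)
    mr <- 0; mc <- 0
    for (i in seq_len(n)) {
        mr <- mr + pix[i, 1]
        mc <- mc + pix[i, 2]
    }
    mr <- mr / n; mc <- mc / n
    srr <- 0; scc <- 0; src <- 0
    for (i in seq_len(n)) {
        dr <- pix[i, 1] - mr; dc <- pix[i, 2] - mc
        srr <- srr + dr * dr
        scc <- scc + dc * dc
        src <- src + dr * dc
    }
    mrr <- srr / n + 1 / 12
    mcc <- scc / n + 1 / 12
    mrc <- src / n
    tr <- mrr + mcc
    dt <- mrr * mcc - mrc * mrc
    l1 <- tr / 2 + sqrt(tr * tr / 4 - dt)
    l2 <- tr / 2 - sqrt(tr * tr / 4 - dt)
    q <- sqrt(l1 / l2)
    c(major = 2 * sqrt(n * q / pi), minor = 2 * sqrt(n / (q * pi)))
}

# pixel sets of rasterized shapes (pixel-center inclusion)
rasterDisc <- function(radius, center = c(0, 0)) {
    g <- expand.grid(row = floor(center[1] - radius - 2):ceiling(center[1] + radius + 2),
                     col = floor(center[2] - radius - 2):ceiling(center[2] + radius + 2))
    sel <- (g$row - center[1])^2 + (g$col - center[2])^2 <= radius^2
    as.matrix(g[sel, ])
}

rasterEllipse <- function(a, b, angleDeg = 0, center = c(0, 0)) {
    th <- angleDeg * pi / 180
    m <- max(a, b) + 2
    g <- expand.grid(row = floor(center[1] - m):ceiling(center[1] + m),
                     col = floor(center[2] - m):ceiling(center[2] + m))
    x <- g$col - center[2]
    y <- -(g$row - center[1])           # y axis up, angle CCW from col axis
    u <- x * cos(th) + y * sin(th)
    v <- -x * sin(th) + y * cos(th)
    as.matrix(g[(u / a)^2 + (v / b)^2 <= 1, ])
}

# Otsu's criterion evaluated exhaustively on a 256-bin histogram
oracleOtsu <- function(values, levels = 256L) {
    breaks <- seq(0, 1, length.out = levels + 1L)
    h <- hist(values, breaks = breaks, plot = FALSE)$counts
    n <- sum(h)
    best <- -Inf; bestT <- 0
    for (k in seq_len(levels - 1L)) {
        w0 <- sum(h[1:k]); w1 <- n - w0
        if (w0 == 0 || w1 == 0) next
        mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
        m0 <- sum(h[1:k] * mids[1:k]) / w0
        m1 <- sum(h[(k + 1):levels] * mids[(k + 1):levels]) / w1
        v <- w0 * w1 * (m0 - m1)^2
        if (v > best) {
            best <- v
            bestT <- breaks[k + 1L]
        }
    }
    bestT
}

# closed-form two-pass OLS with R^2
oracleOls <- function(x, y) {
    xb <- mean(x); yb <- mean(y)
    slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
    intercept <- yb - slope * xb
    fitted <- slope * x + intercept
    r2 <- 1 - sum((y - fitted)^2) / sum((y - yb)^2)
    c(slope = slope, intercept = intercept, r2 = r2)
}

# numerical-integration oracle for the continuous capsule's moment-ellipse
# major axis (fine grid over the region; no pixel term)
oracleCapsuleMajor <- function(L, W, h = 0.0005) {
    r <- W / 2
    half <- L / 2
    x <- seq(-half, half, by = h)
    y <- seq(-r, r, by = h)
    g <- expand.grid(x = x, y = y)
    d <- pmax(abs(g$x) - (half - r), 0)
    inside <- d^2 + g$y^2 <= r^2
    gx <- g$x[inside]; gy <- g$y[inside]
    A <- length(gx) * h^2
    mxx <- mean((gx - mean(gx))^2)
    myy <- mean((gy - mean(gy))^2)
    q <- sqrt(mxx / myy)
    2 * sqrt(A * q / pi)
}

# compact scene for end-to-end tests (full physics, small field of view)
smallScene <- function(lengthMm = 0.8, seed = 1, rows = 300, cols = 400,
                       ...) {
    generateScene(SceneConfig(lengthMm, seed = seed,
                              imageSizePx = c(rows, cols), ...))
}

# calibration that corrects the capsule's ellipse bias, fitted on the
# closed-form M(L) relation for a given width
capsuleCalibration <- function(widthMm = 0.25) {
    L <- seq(0.3, 2.5, length.out = 100)
    M <- capsuleMomentMajor(L, widthMm)
    f <- stats::lm(L ~ M)
    CalibrationModel(unname(coef(f)[2]), unname(coef(f)[1]))
}
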