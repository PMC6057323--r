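# Independent brute-force oracles: literal per-pixel / per-pair / per-run
# enumeration, kept deliberately loop-based and separate from the package's
# vectorized implementations.

oracleQuantize <- function(g, levels = 16L) {
  q <- matrix(0L, nrow(g), ncol(g))
  for (i in seq_len(nrow(g))) for (j in seq_len(ncol(g))) {
    q[i, j] <- min(levels, 1L + g[i, j] %/% (256L / levels))
  }
  q
}

# GLCM by enumerating every ordered pixel pair in each direction.
oracleGLCM <- function(px, mk, directions = c("deg0", "deg45", "deg90",
                                              "deg135"), levels = 16L) {
  q <- oracleQuantize(px, levels)
  offs <- list(deg0 = c(0, 1), deg45 = c(-1, 1), deg90 = c(-1, 0),
               deg135 = c(-1, -1))
  counts <- matrix(0, levels, levels)
  for (d in directions) {
    dr <- offs[[d]][1]; dc <- offs[[d]][2]
    for (sgn in c(1, -1)) {       # both directions (symmetric matrix)
      for (i in seq_len(nrow(q))) for (j in seq_len(ncol(q))) {
        i2 <- i + sgn * dr; j2 <- j + sgn * dc
        if (i2 < 1 || j2 < 1 || i2 > nrow(q) || j2 > ncol(q)) next
        if (!mk[i, j] || !mk[i2, j2]) next
        counts[q[i, j], q[i2, j2]] <- counts[q[i, j], q[i2, j2]] + 1
      }
    }
  }
  counts / sum(counts)
}

# The 13 co-occurrence features by literal double loops over the matrix.
oracleGLCMFeatures <- function(P) {
  Ng <- nrow(P)
  lg <- function(x) if (x > 0) log(x) else 0
  px <- numeric(Ng); py <- numeric(Ng)
  for (i in 1:Ng) for (j in 1:Ng) {
    px[i] <- px[i] + P[i, j]; py[j] <- py[j] + P[i, j]
  }
  mx <- sum((1:Ng) * px); my <- sum((1:Ng) * py)
  sx <- sqrt(sum((1:Ng - mx)^2 * px)); sy <- sqrt(sum((1:Ng - my)^2 * py))
  psum <- numeric(2 * Ng); pdif <- numeric(Ng)
  for (i in 1:Ng) for (j in 1:Ng) {
    psum[i + j] <- psum[i + j] + P[i, j]
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + P[i, j]
  }
  ASM <- 0; IDM <- 0; ENT <- 0; SSQ <- 0; CORnum <- 0
  for (i in 1:Ng) for (j in 1:Ng) {
    ASM <- ASM + P[i, j]^2
    IDM <- IDM + P[i, j] / (1 + (i - j)^2)
    ENT <- ENT - P[i, j] * lg(P[i, j])
    SSQ <- SSQ + (i - mx)^2 * P[i, j]
    CORnum <- CORnum + i * j * P[i, j]
  }
  CON <- 0
  for (n in 0:(Ng - 1)) CON <- CON + n^2 * pdif[n + 1]
  COR <- if (sx * sy == 0) 0 else (CORnum - mx * my) / (sx * sy)
  SAVE <- 0; SENT <- 0
  for (k in 2:(2 * Ng)) {
    SAVE <- SAVE + k * psum[k]
    SENT <- SENT - psum[k] * lg(psum[k])
  }
  SVAR <- 0
  for (k in 2:(2 * Ng)) SVAR <- SVAR + (k - SENT)^2 * psum[k]
  mud <- 0
  for (n in 0:(Ng - 1)) mud <- mud + n * pdif[n + 1]
  DVAR <- 0; DENT <- 0
  for (n in 0:(Ng - 1)) {
    DVAR <- DVAR + (n - mud)^2 * pdif[n + 1]
    DENT <- DENT - pdif[n + 1] * lg(pdif[n + 1])
  }
  HX <- -sum(sapply(px, function(x) x * lg(x)))
  HY <- -sum(sapply(py, function(x) x * lg(x)))
  HXY1 <- 0; HXY2 <- 0
  for (i in 1:Ng) for (j in 1:Ng) {
    HXY1 <- HXY1 - P[i, j] * lg(px[i] * py[j])
    HXY2 <- HXY2 - px[i] * py[j] * lg(px[i] * py[j])
  }
  ICM1 <- if (max(HX, HY) == 0) 0 else (ENT - HXY1) / max(HX, HY)
  ICM2 <- sqrt(max(0, 1 - exp(-2 * (HXY2 - ENT))))
  c(ASM, CON, IDM, ENT, COR, SSQ, SAVE, SENT, SVAR, DVAR, DENT, ICM1, ICM2)
}

# Run-length features by tracing every scan line pixel by pixel.
oracleRLM <- function(px, mk, directions = c("deg0", "deg45", "deg90",
                                             "deg135"), levels = 16L) {
  q <- oracleQuantize(px, levels)
  nr <- nrow(q); nc <- ncol(q)
  P <- sum(mk)
  steps <- list(deg0 = c(0, 1), deg45 = c(-1, 1), deg90 = c(1, 0),
                deg135 = c(1, 1))
  starts <- function(d) {
    s <- list()
    for (i in 1:nr) for (j in 1:nc) {
      prev <- c(i, j) - d
      if (prev[1] < 1 || prev[1] > nr || prev[2] < 1 || prev[2] > nc)
        s[[length(s) + 1]] <- c(i, j)
    }
    s
  }
  perDir <- sapply(directions, function(dn) {
    d <- steps[[dn]]
    runs <- list()
    for (s0 in starts(d)) {
      cur <- s0; runLevel <- NA; runLen <- 0
      while (cur[1] >= 1 && cur[1] <= nr && cur[2] >= 1 && cur[2] <= nc) {
        lev <- if (mk[cur[1], cur[2]]) q[cur[1], cur[2]] else NA
        if (!is.na(lev) && !is.na(runLevel) && lev == runLevel) {
          runLen <- runLen + 1
        } else {
          if (!is.na(runLevel)) runs[[length(runs) + 1]] <- c(runLevel, runLen)
          runLevel <- lev; runLen <- if (is.na(lev)) 0 else 1
        }
        cur <- cur + d
      }
      if (!is.na(runLevel)) runs[[length(runs) + 1]] <- c(runLevel, runLen)
    }
    R <- do.call(rbind, runs)
    tot <- nrow(R)
    sre <- sum(1 / R[, 2]^2) / tot
    lre <- sum(R[, 2]^2) / tot
    glnu <- sum(tapply(rep(1, tot), R[, 1], sum)^2) / tot
    rlnu <- sum(tapply(rep(1, tot), R[, 2], sum)^2) / tot
    c(sre, lre, glnu, rlnu, tot / P)
  })
  rowMeans(perDir)
}

# LBP codes pixel by pixel, neighbor by neighbor.
oracleLBP <- function(px, mk) {
  nr <- nrow(px); nc <- ncol(px)
  codes <- c()
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mk[i, j]) next
    if (i < 2 || j < 2 || i > nr - 1 || j > nc - 1) next
    code <- 0
    for (p in 0:7) {
      a <- 2 * pi * p / 8
      rr <- i + sin(a); cc <- j + cos(a)
      r0 <- floor(rr); c0 <- floor(cc)
      fr <- rr - r0; fc <- cc - c0
      r1 <- min(r0 + 1, nr); c1 <- min(c0 + 1, nc)
      gp <- (1 - fr) * (1 - fc) * px[r0, c0] + (1 - fr) * fc * px[r0, c1] +
        fr * (1 - fc) * px[r1, c0] + fr * fc * px[r1, c1]
      if (gp - px[i, j] >= -1e-7) code <- code + 2^p
    }
    codes <- c(codes, code)
  }
  c(mean(codes), sqrt(mean((codes - mean(codes))^2)))
}

# Daubechies-2 DWT by direct evaluation of the analysis equations.
oracleDwt1 <- function(x, f) {
  n <- length(x)
  ext <- c(x[min(3, n)], x[min(2, n)], x[1], x, x[n], x[max(n - 1, 1)],
           x[max(n - 2, 1)])
  K <- (n + 3) %/% 2
  y <- numeric(K)
  for (k in 1:K) {
    acc <- 0
    for (m in 1:4) acc <- acc + f[m] * ext[2 * k - 2 + m]
    y[k] <- acc
  }
  y
}

oracleDwt2 <- function(M) {
  s3 <- sqrt(3)
  h <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
  lo <- rev(h); hi <- h * c(-1, 1, -1, 1)
  rowPass <- function(M, f) {
    out <- NULL
    for (i in seq_len(nrow(M))) out <- rbind(out, oracleDwt1(M[i, ], f))
    out
  }
  colPass <- function(M, f) t(rowPass(t(M), f))
  L <- rowPass(M, lo); H <- rowPass(M, hi)
  list(a = colPass(L, lo), h = colPass(L, hi),
       v = colPass(H, lo), d = colPass(H, hi))
}

oracleWaveletStats <- function(px) {
  l2 <- oracleDwt2(oracleDwt2(px)$a)
  st <- function(w) {
    v <- as.numeric(w); m <- mean(v); md <- median(v)
    c(m, md, max(v), min(v), max(v) - min(v), sd(v),
      median(abs(v - md)), mean(abs(v - m)))
  }
  c(st(l2$h), st(l2$d), st(l2$v))
}

# Tamura by per-pixel window sums.
oracleTamura <- function(px, mk, kRange = 0:5) {
  nr <- nrow(px); nc <- ncol(px)
  A <- function(i, j, w) {
    lo <- -(w %/% 2) + 1; hi <- w %/% 2 + (w %% 2)
    rs <- max(i + lo - 1, 1):min(i + hi - 1, nr)
    cs <- max(j + lo - 1, 1):min(j + hi - 1, nc)
    mean(px[rs, cs])
  }
  clamp <- function(v, n) min(max(v, 1), n)
  Sbest <- matrix(0, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    bestE <- -Inf; bestK <- kRange[1]
    for (k in kRange) {
      w <- 2^k; d <- max(1, 2^(k - 1))
      Eh <- abs(A(i, clamp(j + d, nc), w) - A(i, clamp(j - d, nc), w))
      Ev <- abs(A(clamp(i + d, nr), j, w) - A(clamp(i - d, nr), j, w))
      E <- max(Eh, Ev)
      if (E > bestE) { bestE <- E; bestK <- k }
    }
    Sbest[i, j] <- 2^bestK
  }
  sb <- Sbest[mk]
  crs1 <- mean(sb)
  breaks <- seq(2^min(kRange), 2^max(kRange), length.out = 4)
  h <- c(sum(sb <= breaks[2]), sum(sb > breaks[2] & sb <= breaks[3]),
         sum(sb > breaks[3])) / length(sb) * 100
  v <- px[mk]; m <- mean(v); sig <- sqrt(mean((v - m)^2))
  con <- if (sig == 0) 0 else sig / (mean((v - m)^4) / sig^4)^(1 / 4)
  c(crs1, h, con, crs1 + con)
}

# Exact two-sided rank-sum p by enumerating all group assignments.
oracleWilcoxonExact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  ranks <- rank(c(x, y))
  wObs <- sum(ranks[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  ws <- apply(combos, 2, function(ix) sum(ranks[ix]) - nx * (nx + 1) / 2)
  mu <- nx * ny / 2
  mean(abs(ws - mu) >= abs(wObs - mu) - 1e-12)
}

# BH step-up by hand.
oracleBH <- function(p, m = length(p)) {
  n <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(n)
  for (i in seq_len(n)) {
    adj[i] <- min(1, min(m * ps[i:n] / (i:n)))
  }
  out <- numeric(n)
  out[ord] <- adj
  out
}

# Point-biserial via the textbook mean-difference formula.
oraclePointBiserial <- function(values, labels) {
  n <- length(values)
  n1 <- sum(labels == 1); n0 <- n - n1
  m1 <- mean(values[labels == 1]); m0 <- mean(values[labels == 0])
  sn <- sqrt(mean((values - mean(values))^2))
  (m1 - m0) / sn * sqrt(n1 * n0 / n^2)
}
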