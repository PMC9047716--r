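# Independent brute-force reimplementation of every catalogue feature.
# Deliberately naive: scalar loops, explicit matrix walks, its own marching
# tetrahedra and percentile code. Shares no code path with the package
# internals; used to pin the fast implementations down to 1e-9 relative.

DIRS13 <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1), c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, -1, 1), c(1, 1, -1), c(-1, 1, 1)
)

oracle_bins_array <- function(coords, bins) {
  mn <- c(min(coords[, 1]), min(coords[, 2]), min(coords[, 3]))
  arr <- array(
    0L,
    dim = c(
      max(coords[, 1]) - mn[1] + 1, max(coords[, 2]) - mn[2] + 1,
      max(coords[, 3]) - mn[3] + 1
    )
  )
  for (r in seq_len(nrow(coords))) {
    arr[
      coords[r, 1] - mn[1] + 1, coords[r, 2] - mn[2] + 1,
      coords[r, 3] - mn[3] + 1
    ] <- bins[r]
  }
  arr
}

o_at <- function(arr, i, j, k) {
  d <- dim(arr)
  if (i < 1 || i > d[1] || j < 1 || j > d[2] || k < 1 || k > d[3]) {
    return(0L)
  }
  arr[i, j, k]
}

o_xlog2 <- function(p) if (p > 0) p * log2(p) else 0

## ---- first order -------------------------------------------------------

# linear interpolation between order statistics, written from the
# definition (R type-7 convention)
oracle_percentile <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

oracle_firstorder <- function(x, bins, n_levels, voxvol) {
  n <- length(x)
  hist <- rep(0, n_levels)
  for (b in bins) hist[b] <- hist[b] + 1
  p <- hist / n
  ent <- 0
  unif <- 0
  for (q in p) {
    ent <- ent - o_xlog2(q)
    unif <- unif + q^2
  }
  m <- sum(x) / n
  m2 <- sum((x - m)^2) / n
  m3 <- sum((x - m)^3) / n
  m4 <- sum((x - m)^4) / n
  p10 <- oracle_percentile(x, 0.1)
  p90 <- oracle_percentile(x, 0.9)
  rob <- x[x >= p10 & x <= p90]
  c(
    Energy = sum(x^2),
    TotalEnergy = voxvol * sum(x^2),
    Entropy = ent,
    Minimum = min(x),
    TenthPercentile = p10,
    NinetiethPercentile = p90,
    Maximum = max(x),
    Mean = m,
    Median = oracle_percentile(x, 0.5),
    InterquartileRange = oracle_percentile(x, 0.75) - oracle_percentile(x, 0.25),
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = sum(abs(x - m)) / n,
    RobustMeanAbsoluteDeviation = mean(abs(rob - mean(rob))),
    RootMeanSquared = sqrt(sum(x^2) / n),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2,
    Uniformity = unif
  )
}

## ---- GLCM --------------------------------------------------------------

oracle_glcm <- function(coords, bins, n_levels) {
  arr <- oracle_bins_array(coords, bins)
  d <- dim(arr)
  feats <- NULL
  ndir <- 0
  for (dd in seq_len(13)) {
    cm <- matrix(0, n_levels, n_levels)
    for (i in seq_len(d[1])) {
      for (j in seq_len(d[2])) {
        for (k in seq_len(d[3])) {
          a <- arr[i, j, k]
          if (a == 0) next
          b <- o_at(arr, i + DIRS13[dd, 1], j + DIRS13[dd, 2], k + DIRS13[dd, 3])
          if (b == 0) next
          cm[a, b] <- cm[a, b] + 1
          cm[b, a] <- cm[b, a] + 1 # symmetric
        }
      }
    }
    if (sum(cm) == 0) next
    ndir <- ndir + 1
    f <- oracle_glcm_formulas(cm / sum(cm))
    feats <- if (is.null(feats)) f else feats + f
  }
  if (ndir == 0) {
    p <- matrix(0, n_levels, n_levels)
    p[bins[1], bins[1]] <- 1
    return(oracle_glcm_formulas(p))
  }
  feats / ndir
}

oracle_glcm_formulas <- function(p) {
  ng <- nrow(p)
  px <- rep(0, ng)
  for (i in 1:ng) for (j in 1:ng) px[i] <- px[i] + p[i, j]
  mu <- 0
  for (i in 1:ng) mu <- mu + i * px[i]
  s2 <- 0
  for (i in 1:ng) s2 <- s2 + (i - mu)^2 * px[i]
  pd <- rep(0, ng) # |i-j| = 0..ng-1
  ps <- rep(0, 2 * ng - 1) # i+j = 2..2ng
  ac <- cp <- cs <- ct <- con <- id <- idm <- idmn <- idn <- iv <- 0
  je <- hxy <- mp <- 0
  hxy1 <- hxy2 <- 0
  for (i in 1:ng) {
    for (j in 1:ng) {
      q <- p[i, j]
      pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + q
      ps[i + j - 1] <- ps[i + j - 1] + q
      ac <- ac + i * j * q
      cp <- cp + (i + j - 2 * mu)^4 * q
      cs <- cs + (i + j - 2 * mu)^3 * q
      ct <- ct + (i + j - 2 * mu)^2 * q
      con <- con + (i - j)^2 * q
      id <- id + q / (1 + abs(i - j))
      idm <- idm + q / (1 + (i - j)^2)
      idmn <- idmn + q / (1 + (i - j)^2 / ng^2)
      idn <- idn + q / (1 + abs(i - j) / ng)
      if (i != j) iv <- iv + q / (i - j)^2
      je <- je + q^2
      hxy <- hxy - o_xlog2(q)
      if (q > mp) mp <- q
      pp <- px[i] * px[j]
      if (q > 0 && pp > 0) hxy1 <- hxy1 - q * log2(pp)
      hxy2 <- hxy2 - o_xlog2(pp)
    }
  }
  hx <- 0
  for (i in 1:ng) hx <- hx - o_xlog2(px[i])
  da <- 0
  for (k in 1:ng) da <- da + (k - 1) * pd[k]
  de <- dv <- 0
  for (k in 1:ng) {
    de <- de - o_xlog2(pd[k])
    dv <- dv + ((k - 1) - da)^2 * pd[k]
  }
  se <- 0
  for (k in seq_along(ps)) se <- se - o_xlog2(ps[k])
  c(
    Autocorrelation = ac,
    ClusterProminence = cp,
    ClusterShade = cs,
    ClusterTendency = ct,
    Contrast = con,
    Correlation = if (s2 > 0) (ac - mu^2) / s2 else 1,
    DifferenceAverage = da,
    DifferenceEntropy = de,
    DifferenceVariance = dv,
    Id = id, Idm = idm, Idmn = idmn, Idn = idn,
    Imc1 = if (hx > 0) (hxy - hxy1) / hx else 0,
    Imc2 = sqrt(max(1 - 2^(-2 * (hxy2 - hxy)), 0)),
    InverseVariance = iv,
    JointAverage = mu,
    JointEnergy = je,
    JointEntropy = hxy,
    MaximumProbability = mp,
    SumEntropy = se,
    SumSquares = s2
  )
}

## ---- GLRLM -------------------------------------------------------------

oracle_glrlm <- function(coords, bins, n_levels) {
  arr <- oracle_bins_array(coords, bins)
  d <- dim(arr)
  np <- nrow(coords)
  feats <- NULL
  ndir <- 0
  for (dd in seq_len(13)) {
    dx <- DIRS13[dd, 1]
    dy <- DIRS13[dd, 2]
    dz <- DIRS13[dd, 3]
    runs <- list()
    for (i in seq_len(d[1])) {
      for (j in seq_len(d[2])) {
        for (k in seq_len(d[3])) {
          g <- arr[i, j, k]
          if (g == 0) next
          if (o_at(arr, i - dx, j - dy, k - dz) == g) next # not a run start
          len <- 1
          while (o_at(arr, i + len * dx, j + len * dy, k + len * dz) == g) {
            len <- len + 1
          }
          runs[[length(runs) + 1]] <- c(g, len)
        }
      }
    }
    if (length(runs) == 0) next
    ndir <- ndir + 1
    rl <- do.call(rbind, runs)
    cm <- matrix(0, n_levels, max(rl[, 2]))
    for (r in seq_len(nrow(rl))) {
      cm[rl[r, 1], rl[r, 2]] <- cm[rl[r, 1], rl[r, 2]] + 1
    }
    f <- oracle_rl_formulas(cm, np)
    feats <- if (is.null(feats)) f else feats + f
  }
  feats / ndir
}

oracle_rl_formulas <- function(cm, np) {
  nr <- sum(cm)
  ng <- nrow(cm)
  nl <- ncol(cm)
  sre <- lre <- glv <- rv <- re <- lglre <- hglre <- 0
  srl <- srh <- lrl <- lrh <- 0
  mu_i <- mu_j <- 0
  for (i in 1:ng) {
    for (j in 1:nl) {
      q <- cm[i, j] / nr
      mu_i <- mu_i + i * q
      mu_j <- mu_j + j * q
    }
  }
  for (i in 1:ng) {
    for (j in 1:nl) {
      q <- cm[i, j] / nr
      sre <- sre + q / j^2
      lre <- lre + q * j^2
      glv <- glv + (i - mu_i)^2 * q
      rv <- rv + (j - mu_j)^2 * q
      re <- re - o_xlog2(q)
      lglre <- lglre + q / i^2
      hglre <- hglre + q * i^2
      srl <- srl + q / (i^2 * j^2)
      srh <- srh + q * i^2 / j^2
      lrl <- lrl + q * j^2 / i^2
      lrh <- lrh + q * i^2 * j^2
    }
  }
  gln <- 0
  for (i in 1:ng) gln <- gln + sum(cm[i, ])^2
  rln <- 0
  for (j in 1:nl) rln <- rln + sum(cm[, j])^2
  c(
    ShortRunEmphasis = sre, LongRunEmphasis = lre,
    GrayLevelNonUniformity = gln / nr,
    GrayLevelNonUniformityNormalized = gln / nr^2,
    RunLengthNonUniformity = rln / nr,
    RunLengthNonUniformityNormalized = rln / nr^2,
    RunPercentage = nr / np,
    GrayLevelVariance = glv, RunVariance = rv, RunEntropy = re,
    LowGrayLevelRunEmphasis = lglre, HighGrayLevelRunEmphasis = hglre,
    ShortRunLowGrayLevelEmphasis = srl, ShortRunHighGrayLevelEmphasis = srh,
    LongRunLowGrayLevelEmphasis = lrl, LongRunHighGrayLevelEmphasis = lrh
  )
}

## ---- GLSZM -------------------------------------------------------------

oracle_glszm <- function(coords, bins, n_levels) {
  arr <- oracle_bins_array(coords, bins)
  d <- dim(arr)
  np <- nrow(coords)
  seen <- array(FALSE, dim = d)
  zones <- list()
  for (i0 in seq_len(d[1])) {
    for (j0 in seq_len(d[2])) {
      for (k0 in seq_len(d[3])) {
        g <- arr[i0, j0, k0]
        if (g == 0 || seen[i0, j0, k0]) next
        queue <- list(c(i0, j0, k0))
        seen[i0, j0, k0] <- TRUE
        size <- 0
        while (length(queue) > 0) {
          v <- queue[[1]]
          queue <- queue[-1]
          size <- size + 1
          for (di in -1:1) {
            for (dj in -1:1) {
              for (dk in -1:1) {
                if (di == 0 && dj == 0 && dk == 0) next
                ii <- v[1] + di
                jj <- v[2] + dj
                kk <- v[3] + dk
                if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] ||
                  kk < 1 || kk > d[3]) {
                  next
                }
                if (!seen[ii, jj, kk] && arr[ii, jj, kk] == g) {
                  seen[ii, jj, kk] <- TRUE
                  queue[[length(queue) + 1]] <- c(ii, jj, kk)
                }
              }
            }
          }
        }
        zones[[length(zones) + 1]] <- c(g, size)
      }
    }
  }
  zm <- do.call(rbind, zones)
  cm <- matrix(0, n_levels, max(zm[, 2]))
  for (r in seq_len(nrow(zm))) cm[zm[r, 1], zm[r, 2]] <- cm[zm[r, 1], zm[r, 2]] + 1
  nz <- sum(cm)
  sae <- lae <- glv <- zv <- ze <- lgl <- hgl <- 0
  sal <- sah <- lal <- lah <- 0
  mu_i <- mu_j <- 0
  ng <- nrow(cm)
  ns <- ncol(cm)
  for (i in 1:ng) {
    for (s in 1:ns) {
      q <- cm[i, s] / nz
      mu_i <- mu_i + i * q
      mu_j <- mu_j + s * q
    }
  }
  for (i in 1:ng) {
    for (s in 1:ns) {
      q <- cm[i, s] / nz
      sae <- sae + q / s^2
      lae <- lae + q * s^2
      glv <- glv + (i - mu_i)^2 * q
      zv <- zv + (s - mu_j)^2 * q
      ze <- ze - o_xlog2(q)
      lgl <- lgl + q / i^2
      hgl <- hgl + q * i^2
      sal <- sal + q / (s^2 * i^2)
      sah <- sah + q * i^2 / s^2
      lal <- lal + q * s^2 / i^2
      lah <- lah + q * s^2 * i^2
    }
  }
  gln <- 0
  for (i in 1:ng) gln <- gln + sum(cm[i, ])^2
  szn <- 0
  for (s in 1:ns) szn <- szn + sum(cm[, s])^2
  c(
    SmallAreaEmphasis = sae, LargeAreaEmphasis = lae,
    GrayLevelNonUniformity = gln / nz,
    GrayLevelNonUniformityNormalized = gln / nz^2,
    SizeZoneNonUniformity = szn / nz,
    SizeZoneNonUniformityNormalized = szn / nz^2,
    ZonePercentage = nz / np,
    GrayLevelVariance = glv, ZoneVariance = zv, ZoneEntropy = ze,
    LowGrayLevelZoneEmphasis = lgl, HighGrayLevelZoneEmphasis = hgl,
    SmallAreaLowGrayLevelEmphasis = sal,
    SmallAreaHighGrayLevelEmphasis = sah,
    LargeAreaLowGrayLevelEmphasis = lal,
    LargeAreaHighGrayLevelEmphasis = lah
  )
}

## ---- GLDM --------------------------------------------------------------

oracle_gldm <- function(coords, bins, n_levels) {
  arr <- oracle_bins_array(coords, bins)
  d <- dim(arr)
  cm <- matrix(0, n_levels, 27)
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      for (k in seq_len(d[3])) {
        g <- arr[i, j, k]
        if (g == 0) next
        dep <- 0
        for (di in -1:1) {
          for (dj in -1:1) {
            for (dk in -1:1) {
              if (di == 0 && dj == 0 && dk == 0) next
              if (o_at(arr, i + di, j + dj, k + dk) == g) dep <- dep + 1
            }
          }
        }
        cm[g, dep + 1] <- cm[g, dep + 1] + 1
      }
    }
  }
  nz <- sum(cm)
  ng <- nrow(cm)
  nd <- ncol(cm)
  sde <- lde <- glv <- dv <- de <- lgl <- hgl <- 0
  sdl <- sdh <- ldl <- ldh <- 0
  mu_i <- mu_j <- 0
  for (i in 1:ng) {
    for (j in 1:nd) {
      q <- cm[i, j] / nz
      mu_i <- mu_i + i * q
      mu_j <- mu_j + j * q
    }
  }
  for (i in 1:ng) {
    for (j in 1:nd) {
      q <- cm[i, j] / nz
      sde <- sde + q / j^2
      lde <- lde + q * j^2
      glv <- glv + (i - mu_i)^2 * q
      dv <- dv + (j - mu_j)^2 * q
      de <- de - o_xlog2(q)
      lgl <- lgl + q / i^2
      hgl <- hgl + q * i^2
      sdl <- sdl + q / (j^2 * i^2)
      sdh <- sdh + q * i^2 / j^2
      ldl <- ldl + q * j^2 / i^2
      ldh <- ldh + q * i^2 * j^2
    }
  }
  gln <- 0
  for (i in 1:ng) gln <- gln + sum(cm[i, ])^2
  dn <- 0
  for (j in 1:nd) dn <- dn + sum(cm[, j])^2
  c(
    SmallDependenceEmphasis = sde, LargeDependenceEmphasis = lde,
    GrayLevelNonUniformity = gln / nz,
    DependenceNonUniformity = dn / nz,
    DependenceNonUniformityNormalized = dn / nz^2,
    GrayLevelVariance = glv, DependenceVariance = dv, DependenceEntropy = de,
    LowGrayLevelEmphasis = lgl, HighGrayLevelEmphasis = hgl,
    SmallDependenceLowGrayLevelEmphasis = sdl,
    SmallDependenceHighGrayLevelEmphasis = sdh,
    LargeDependenceLowGrayLevelEmphasis = ldl,
    LargeDependenceHighGrayLevelEmphasis = ldh
  )
}

## ---- shape -------------------------------------------------------------

# naive marching tetrahedra on a scalar field (same stated convention as
# the package, coded independently with R loops)
oracle_march_tets <- function(field, spacing, level = 0.5) {
  d <- dim(field)
  val_at <- function(i, j, k) { # 0-based voxel index
    if (i < 0 || i >= d[1] || j < 0 || j >= d[2] || k < 0 || k >= d[3]) {
      return(0)
    }
    field[i + 1, j + 1, k + 1]
  }
  tets <- list(
    c(0, 1, 3, 7), c(0, 1, 5, 7), c(0, 2, 3, 7),
    c(0, 2, 6, 7), c(0, 4, 5, 7), c(0, 4, 6, 7)
  )
  corner_off <- function(c) c(bitwAnd(c, 1), bitwAnd(bitwShiftR(c, 1), 1), bitwAnd(bitwShiftR(c, 2), 1))
  cross_pt <- function(p1, v1, p2, v2) {
    t <- if (v2 == v1) 0.5 else (level - v1) / (v2 - v1)
    t <- min(max(t, 0), 1)
    p1 + t * (p2 - p1)
  }
  area <- 0
  vol6 <- 0
  add_tri <- function(a, b, cc, inside_pt) {
    nrm <- pracma_cross(b - a, cc - a)
    if (sum(nrm * ((a + b + cc) / 3 - inside_pt)) < 0) {
      tmp <- b
      b <- cc
      cc <- tmp
      nrm <- -nrm
    }
    area <<- area + sqrt(sum(nrm^2)) / 2
    vol6 <<- vol6 + sum(a * pracma_cross(b, cc))
  }
  for (k in -1:(d[3] - 1)) {
    for (j in -1:(d[2] - 1)) {
      for (i in -1:(d[1] - 1)) {
        vals <- numeric(8)
        pos <- matrix(0, 8, 3)
        for (c in 0:7) {
          off <- corner_off(c)
          vals[c + 1] <- val_at(i + off[1], j + off[2], k + off[3])
          pos[c + 1, ] <- (c(i, j, k) + off + 0.5) * spacing
        }
        ins <- vals > level
        if (!any(ins) || all(ins)) next
        for (tt in tets) {
          tv <- vals[tt + 1]
          tp <- pos[tt + 1, , drop = FALSE]
          tin <- tv > level
          nin <- sum(tin)
          if (nin == 0 || nin == 4) next
          iw <- which(tin)
          ow <- which(!tin)
          if (nin == 1 || nin == 3) {
            apex <- if (nin == 1) iw[1] else ow[1]
            oth <- if (nin == 1) ow else iw
            m <- lapply(oth, function(o) {
              cross_pt(tp[apex, ], tv[apex], tp[o, ], tv[o])
            })
            ip <- if (nin == 1) tp[iw[1], ] else colMeans(tp[iw, , drop = FALSE])
            add_tri(m[[1]], m[[2]], m[[3]], ip)
          } else {
            m00 <- cross_pt(tp[iw[1], ], tv[iw[1]], tp[ow[1], ], tv[ow[1]])
            m01 <- cross_pt(tp[iw[1], ], tv[iw[1]], tp[ow[2], ], tv[ow[2]])
            m11 <- cross_pt(tp[iw[2], ], tv[iw[2]], tp[ow[2], ], tv[ow[2]])
            m10 <- cross_pt(tp[iw[2], ], tv[iw[2]], tp[ow[1], ], tv[ow[1]])
            ip <- (tp[iw[1], ] + tp[iw[2], ]) / 2
            add_tri(m00, m01, m11, ip)
            add_tri(m00, m11, m10, ip)
          }
        }
      }
    }
  }
  list(area = area, volume = vol6 / 6)
}

pracma_cross <- function(u, v) {
  c(
    u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1]
  )
}

oracle_smooth3 <- function(field, sigma) {
  r <- ceiling(3 * sigma)
  k <- exp(-0.5 * (-r:r)^2 / sigma^2)
  k <- k / sum(k)
  d <- dim(field)
  out <- field
  for (ax in 1:3) {
    nxt <- array(0, dim = d)
    for (i in seq_len(d[1])) {
      for (j in seq_len(d[2])) {
        for (kk in seq_len(d[3])) {
          acc <- 0
          for (dd in -r:r) {
            q <- c(i, j, kk)
            q[ax] <- q[ax] + dd
            if (q[ax] < 1 || q[ax] > d[ax]) next
            acc <- acc + k[dd + r + 1] * out[q[1], q[2], q[3]]
          }
          nxt[i, j, kk] <- acc
        }
      }
    }
    out <- nxt
  }
  out
}

oracle_shape <- function(coords, spacing) {
  n <- nrow(coords)
  mn <- apply(coords, 2, min)
  loc <- sweep(coords, 2, mn)
  d <- apply(loc, 2, max) + 1
  mask <- array(0, dim = d)
  for (r in seq_len(n)) mask[loc[r, 1] + 1, loc[r, 2] + 1, loc[r, 3] + 1] <- 1
  mb <- oracle_march_tets(mask, spacing)
  v <- mb$volume
  pad <- 3
  padded <- array(0, dim = d + 2 * pad)
  padded[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <- mask
  sm <- oracle_smooth3(padded, 1)
  a <- if (max(sm) > 0.5) oracle_march_tets(sm, spacing)$area else mb$area
  a <- max(a, (36 * pi * v^2)^(1 / 3))

  # diameters by brute force over all voxel corner points
  corners <- NULL
  for (cx in 0:1) {
    for (cy in 0:1) {
      for (cz in 0:1) {
        corners <- rbind(corners, sweep(coords + rep(c(cx, cy, cz), each = n),
          2, spacing, `*`
        ))
      }
    }
  }
  corners <- unique(corners)
  dmax <- function(pts) {
    best <- 0
    m <- nrow(pts)
    for (a1 in seq_len(m - 1)) {
      dx <- pts[(a1 + 1):m, , drop = FALSE]
      dif <- sweep(dx, 2, pts[a1, ])
      best <- max(best, max(rowSums(dif^2)))
    }
    sqrt(best)
  }
  in_plane <- function(fix_ax) {
    best <- 0
    vals <- unique(coords[, fix_ax])
    for (vv in vals) {
      sel <- coords[, fix_ax] == vv
      pts <- NULL
      pl <- setdiff(1:3, fix_ax)
      sub <- coords[sel, pl, drop = FALSE]
      for (c1 in 0:1) {
        for (c2 in 0:1) {
          pts <- rbind(pts, sweep(
            sub + rep(c(c1, c2), each = nrow(sub)), 2,
            spacing[pl], `*`
          ))
        }
      }
      pts <- unique(pts)
      if (nrow(pts) == 1) next
      best <- max(best, dmax(pts))
    }
    best
  }

  phys <- sweep(coords + 0.5, 2, spacing, `*`)
  mu <- colMeans(phys)
  cv <- matrix(0, 3, 3)
  for (r in seq_len(n)) cv <- cv + tcrossprod(phys[r, ] - mu)
  cv <- cv / n + diag(spacing^2 / 12)
  lam <- sort(pmax(eigen(cv, symmetric = TRUE)$values, 0), decreasing = TRUE)

  c(
    MeshVolume = v,
    VoxelVolume = n * prod(spacing),
    SurfaceArea = a,
    SurfaceVolumeRatio = a / v,
    Sphericity = (36 * pi * v^2)^(1 / 3) / a,
    Maximum3DDiameter = dmax(corners),
    Maximum2DDiameterSlice = in_plane(3),
    Maximum2DDiameterColumn = in_plane(2),
    Maximum2DDiameterRow = in_plane(1),
    MajorAxisLength = 4 * sqrt(lam[1]),
    MinorAxisLength = 4 * sqrt(lam[2]),
    LeastAxisLength = 4 * sqrt(lam[3]),
    Elongation = sqrt(lam[2] / lam[1]),
    Flatness = sqrt(lam[3] / lam[1])
  )
}

## ---- full vector -------------------------------------------------------

oracle_feature_vector <- function(x, coords, spacing = c(1, 1, 1),
                                  bin_width = 25) {
  bins <- floor((x - min(x)) / bin_width) + 1
  ng <- max(bins)
  pre <- function(v, fam) stats::setNames(v, paste0(fam, "_", names(v)))
  c(
    pre(oracle_shape(coords, spacing), "shape"),
    pre(oracle_firstorder(x, bins, ng, prod(spacing)), "firstorder"),
    pre(oracle_glcm(coords, bins, ng), "glcm"),
    pre(oracle_glrlm(coords, bins, ng), "glrlm"),
    pre(oracle_glszm(coords, bins, ng), "glszm"),
    pre(oracle_gldm(coords, bins, ng), "gldm")
  )
}
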