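# Independent brute-force oracles used to validate the implementations.
# These deliberately share no code with the package internals.

# GLCM by exhaustive enumeration of every pixel pair.
glcm_oracle <- function(region, levels, offsets, symmetric = TRUE,
                        range = c(0, 1), mask = NULL) {
  H <- nrow(region); W <- ncol(region)
  if (is.null(mask)) mask <- matrix(TRUE, H, W)
  if (is.null(range)) range <- base::range(region)
  q <- matrix(0L, H, W)
  for (r in 1:H) for (c in 1:W) {
    v <- region[r, c]
    b <- if (range[2] <= range[1]) 1L else
      floor((v - range[1]) / (range[2] - range[1]) * levels) + 1
    q[r, c] <- min(max(b, 1), levels)
  }
  out <- array(0, c(levels, levels, nrow(offsets)))
  for (k in seq_len(nrow(offsets))) {
    dy <- offsets[k, 1]; dx <- offsets[k, 2]
    M <- matrix(0, levels, levels)
    for (r in 1:H) for (c in 1:W) {
      r2 <- r + dy; c2 <- c + dx
      if (r2 >= 1 && r2 <= H && c2 >= 1 && c2 <= W &&
          mask[r, c] && mask[r2, c2]) {
        M[q[r, c], q[r2, c2]] <- M[q[r, c], q[r2, c2]] + 1
        if (symmetric) M[q[r2, c2], q[r, c]] <- M[q[r2, c2], q[r, c]] + 1
      }
    }
    out[, , k] <- M / sum(M)
  }
  out
}

# Texture features by explicit double loops over matrix cells.
features_oracle <- function(P) {
  L <- nrow(P)
  en <- con <- hom <- mui <- muj <- 0
  for (i in 1:L) for (j in 1:L) {
    en <- en + P[i, j]^2
    con <- con + (i - j)^2 * P[i, j]
    hom <- hom + P[i, j] / (1 + (i - j)^2)
    mui <- mui + i * P[i, j]
    muj <- muj + j * P[i, j]
  }
  si <- sj <- cc <- 0
  for (i in 1:L) for (j in 1:L) {
    si <- si + (i - mui)^2 * P[i, j]
    sj <- sj + (j - muj)^2 * P[i, j]
    cc <- cc + (i - mui) * (j - muj) * P[i, j]
  }
  corr <- if (sqrt(si) * sqrt(sj) < 1e-12) 1 else cc / (sqrt(si) * sqrt(sj))
  c(energy = en, contrast = con, correlation = corr, homogeneity = hom)
}

# AUC as the Mann-Whitney pair count (half credit for ties).
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (n in neg) s <- s + (p > n) + 0.5 * (p == n)
  s / (length(pos) * length(neg))
}

# Youden cutoff by exhaustive search over all candidate thresholds.
youden_oracle <- function(scores, labels) {
  cands <- c(Inf, sort(unique(scores), decreasing = TRUE))
  best <- NULL
  for (t in cands) {
    pred <- as.integer(scores >= t)
    sens <- sum(pred == 1 & labels == 1) / sum(labels == 1)
    spec <- sum(pred == 0 & labels == 0) / sum(labels == 0)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && spec > best$spec + 1e-12)) {
      best <- list(cutoff = t, sens = sens, spec = spec, j = j)
    }
  }
  best
}

# Polygon area by counting sub-pixel grid points (quarter-pixel lattice).
area_oracle_px2 <- function(polygon, step = 0.25) {
  xs <- seq(min(polygon[, 1]) - 1, max(polygon[, 1]) + 1, by = step)
  ys <- seq(min(polygon[, 2]) - 1, max(polygon[, 2]) + 1, by = step)
  g <- expand.grid(x = xs, y = ys)
  # even-odd test written out directly to stay independent of the package
  n <- nrow(polygon)
  ins <- rep(FALSE, nrow(g))
  j <- n
  for (i in seq_len(n)) {
    xi <- polygon[i, 1]; yi <- polygon[i, 2]
    xj <- polygon[j, 1]; yj <- polygon[j, 2]
    cr <- ((yi > g$y) != (yj > g$y)) &
      (g$x < (xj - xi) * (g$y - yi) / (yj - yi) + xi)
    ins <- xor(ins, cr)
    j <- i
  }
  sum(ins) * step^2
}

# Convex polygon with n vertices, random radius, for area tests.
random_convex_polygon <- function(n, radius = 30, center = c(50, 50)) {
  ang <- sort(stats::runif(n, 0, 2 * pi))
  r <- radius * (0.6 + 0.4 * stats::runif(n))
  cbind(center[1] + r * cos(ang), center[2] + r * sin(ang))
}

# Interarytenoid profiles + labels for a generated cohort.
cohort_profiles <- function(cohort, region = "interarytenoid",
                            params = glcm_params()) {
  profs <- lapply(cohort, function(e) {
    ann <- region_annotation(region, e$scene$truth$regions[[region]])
    region_profiles(e$scene$image, ann, params)
  })
  list(profiles = profs,
       labels = vapply(cohort, function(e) e$label, character(1)))
}
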