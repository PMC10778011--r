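# Shared geometry helpers for the test suite.

grid_mask <- function(n, inside) {
  x <- matrix(rep(seq_len(n), n), nrow = n)
  y <- t(x)
  (inside(x, y)) * 1L
}

disk_mask <- function(n, r, cx = (n + 1) / 2, cy = cx) {
  grid_mask(n, function(x, y) (x - cx)^2 + (y - cy)^2 <= r^2)
}

square_mask <- function(n, side, x0) {
  grid_mask(n, function(x, y) {
    x >= x0 & x < x0 + side & y >= x0 & y < x0 + side
  })
}

# star-convex random blob with fixed-amplitude, random-phase harmonics
blob_mask <- function(n, radius, amp, seed) {
  set.seed(seed)
  k <- 2:8
  a <- amp / sqrt(k)
  ph <- runif(length(k), 0, 2 * pi)
  c0 <- (n + 1) / 2
  grid_mask(n, function(x, y) {
    th <- atan2(y - c0, x - c0)
    r <- sqrt((x - c0)^2 + (y - c0)^2)
    rb <- radius * pmax(
      1 + Reduce(`+`, lapply(seq_along(k), function(i) a[i] * cos(k[i] * th + ph[i]))),
      0.25
    )
    r <= rb
  })
}

rotate90 <- function(mask) t(mask)[ncol(mask):1, ]

rotate_nn <- function(mask, deg) {
  n <- nrow(mask)
  c0 <- (n + 1) / 2
  th <- deg * pi / 180
  x <- matrix(rep(seq_len(n), n), nrow = n)
  y <- t(x)
  xs <- round(c0 + cos(th) * (x - c0) + sin(th) * (y - c0))
  ys <- round(c0 - sin(th) * (x - c0) + cos(th) * (y - c0))
  out <- matrix(0L, n, n)
  ok <- xs >= 1 & xs <= n & ys >= 1 & ys <= n
  out[ok] <- mask[cbind(xs[ok], ys[ok])]
  out
}

# Independent convex hull area oracle: gift-wrapping hull + shoelace area,
# sharing no code with the package implementation.
hull_area_oracle <- function(points) {
  pts <- unique(points)
  np <- nrow(pts)
  if (np < 3) {
    return(0)
  }
  start <- which.min(pts[, 1] + pts[, 2] * 1e-9)
  hull <- start
  repeat {
    cur <- hull[length(hull)]
    cand <- if (1 == cur) 2 else 1
    for (j in seq_len(np)) {
      if (j == cur) next
      cross <- (pts[cand, 1] - pts[cur, 1]) * (pts[j, 2] - pts[cur, 2]) -
        (pts[cand, 2] - pts[cur, 2]) * (pts[j, 1] - pts[cur, 1])
      if (cross < 0 ||
        (cross == 0 &&
          sum((pts[j, ] - pts[cur, ])^2) > sum((pts[cand, ] - pts[cur, ])^2))) {
        cand <- j
      }
    }
    if (cand == start) break
    hull <- c(hull, cand)
    if (length(hull) > np) stop("hull did not close")
  }
  hx <- pts[hull, 1]
  hy <- pts[hull, 2]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

# kappa recomputed from first principles on raw label pairs
kappa_oracle <- function(truth, pred) {
  lv <- union(unique(truth), unique(pred))
  tb <- table(factor(truth, lv), factor(pred, lv))
  n <- sum(tb)
  po <- sum(diag(tb)) / n
  pe <- sum(rowSums(tb) * colSums(tb)) / n^2
  (po - pe) / (1 - pe)
}

# binary kappa of one category from a reconstructed confusion structure
one_vs_rest_kappa <- function(rec, k) {
  tp <- rec$diagonal[k]
  fn <- rec$fn[k]
  fp <- rec$fp[k]
  tn <- rec$n_total - tp - fn - fp
  class_metrics(tp, fn, fp, tn)$kappa
}

# expand a confusion matrix (rows = truth) into paired label vectors
labels_from_matrix <- function(cm) {
  lv <- breslow_levels()
  truth <- rep(lv[rep(1:3, each = 3)], times = as.vector(t(cm)))
  pred <- rep(lv[rep(1:3, times = 3)], times = as.vector(t(cm)))
  list(truth = truth, pred = pred)
}
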