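# Independent brute-force oracles. Everything here is written as explicit
# per-pixel / per-point loops, sharing no code with the package internals,
# so agreement is evidence rather than tautology.

# --- eight depth metrics by naive loops ------------------------------------
oracle_metrics <- function(pred, label, mask) {
  d2 <- 0; adiff <- 0; sqr <- 0; dl <- c()
  n <- 0; hit <- c(0, 0, 0)
  for (r in seq_len(nrow(label))) {
    for (c in seq_len(ncol(label))) {
      if (!mask[r, c]) next
      p <- pred[r, c]; g <- label[r, c]
      n <- n + 1
      adiff <- adiff + abs(p - g) / g
      d2 <- d2 + (p - g)^2
      sqr <- sqr + ((p - g) / g)^2
      dl <- c(dl, log(p) - log(g))
      ratio <- max(g / p, p / g)
      for (k in 1:3) if (ratio < 1.25^k) hit[k] <- hit[k] + 1
    }
  }
  list(abs_rel = 100 * adiff / n,
       rmse = sqrt(d2 / n),
       silog = sum(dl^2) / n - (sum(dl) / n)^2,
       silog_printed = sum(dl^2) / n + (sum(dl) / n)^2,
       delta1 = 100 * hit[1] / n, delta2 = 100 * hit[2] / n,
       delta3 = 100 * hit[3] / n,
       rmse_log = sqrt(sum(dl^2) / n),
       sq_rel = sqr / n,
       n = n)
}

oracle_chamfer <- function(a, b, squared = TRUE) {
  f <- function(p, q) {
    tot <- 0
    for (i in seq_len(nrow(p))) {
      best <- Inf
      for (j in seq_len(nrow(q))) {
        d <- sum((p[i, ] - q[j, ])^2)
        if (d < best) best <- d
      }
      tot <- tot + if (squared) best else sqrt(best)
    }
    tot / nrow(p)
  }
  f(a, b) + f(b, a)
}

# --- banded navigation-point extraction by explicit double loop ------------
oracle_nav_points <- function(labels, n_bands) {
  out <- NULL
  for (id in sort(unique(labels[labels > 0]))) {
    vs <- c(); us <- c()
    for (r in seq_len(nrow(labels)))
      for (c in seq_len(ncol(labels)))
        if (labels[r, c] == id) { vs <- c(vs, r - 1); us <- c(us, c - 1) }
    v_min <- min(vs); extent <- max(vs) - v_min + 1
    for (b in 0:(n_bands - 1)) {
      sel <- floor((vs - v_min) * n_bands / extent) == b
      if (!any(sel)) next
      out <- rbind(out, data.frame(instance_id = id, band = b,
                                   u = mean(us[sel]), v = mean(vs[sel])))
    }
  }
  out
}

# --- closed-form ground-plane range oracle ---------------------------------
# Distance along the optical axis at which the ray through pixel (u, v)
# meets a horizontal plane `h` below a camera pitched down by `pitch`,
# derived via explicit 3D vectors in a world frame (Y down, Z forward).
oracle_ground_depth <- function(u, v, k, h, pitch) {
  dir_cam <- c((u - k$cx) / k$fx, (v - k$cy) / k$fy, 1)
  x_axis <- c(1, 0, 0)
  y_axis <- c(0, cos(pitch), -sin(pitch))
  z_axis <- c(0, sin(pitch), cos(pitch))
  dir_world <- dir_cam[1] * x_axis + dir_cam[2] * y_axis + dir_cam[3] * z_axis
  if (dir_world[2] <= 0) return(0)          # ray never descends to the plane
  t <- h / dir_world[2]                     # dir_cam z-component is 1, so
  t                                          # t is the optical-axis depth
}

# --- random blob masks for property tests ----------------------------------
# Union of a few random filled rectangles per instance; instances disjoint.
random_blob_mask <- function(h, w, n_instances = 2) {
  labels <- matrix(0L, h, w)
  for (id in seq_len(n_instances)) {
    for (rect in seq_len(sample(1:3, 1))) {
      r1 <- sample(seq_len(h), 1); r2 <- min(h, r1 + sample(1:max(2, h %/% 2), 1))
      c1 <- sample(seq_len(w), 1); c2 <- min(w, c1 + sample(1:max(2, w %/% 3), 1))
      patch <- labels[r1:r2, c1:c2]
      patch[patch == 0L] <- id
      labels[r1:r2, c1:c2] <- patch
    }
  }
  labels
}

random_masked_pair <- function(h = 100, w = 100, dropout = 0.3) {
  label <- matrix(runif(h * w, 0.5, 19), h, w)
  label[runif(h * w) < dropout] <- 0
  if (all(label == 0)) label[1, 1] <- 5
  pred <- matrix(runif(h * w, 0.5, 19), h, w)
  list(pred = pred, label = label)
}
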