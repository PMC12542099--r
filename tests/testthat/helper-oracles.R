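# Independent brute-force oracles used to validate the implementation.
# These deliberately use different algorithms from the package internals.

# Connected components by iterative min-label propagation (8-connectivity):
# every TRUE cell starts with a unique label and repeatedly adopts the
# minimum label in its 8-neighbourhood until a fixed point is reached.
oracle_label_components <- function(mask) {
  mask <- mask != 0
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  lab[mask] <- seq_len(sum(mask))
  pad <- function(m) rbind(0L, cbind(0L, m, 0L), 0L)
  repeat {
    p <- pad(lab)
    neigh <- array(0L, c(h, w, 8L))
    k <- 0L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      k <- k + 1L
      neigh[, , k] <- p[(2:(h + 1)) + dr, (2:(w + 1)) + dc]
    }
    neigh[neigh == 0L] <- .Machine$integer.max
    mn <- pmin(apply(neigh, c(1, 2), min), ifelse(lab > 0L, lab,
                                                  .Machine$integer.max))
    newlab <- ifelse(mask, mn, 0L)
    if (all(newlab == lab)) break
    lab <- newlab
  }
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  lapply(ids, function(id) {
    idx <- which(lab == id, arr.ind = TRUE)
    idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  })
}

# Hole count of a single component: 4-connected components of the
# complement within a 1-cell padded bounding box, minus the one touching
# the pad.
oracle_hole_count <- function(cells) {
  r <- cells[, 1L] - min(cells[, 1L]) + 2L
  cc <- cells[, 2L] - min(cells[, 2L]) + 2L
  h <- max(r) + 1L; w <- max(cc) + 1L
  m <- matrix(TRUE, h, w)   # complement
  m[cbind(r, cc)] <- FALSE
  # 4-connected labelling of the complement by min-label propagation
  lab <- matrix(0L, h, w)
  lab[m] <- seq_len(sum(m))
  repeat {
    p <- rbind(0L, cbind(0L, lab, 0L), 0L)
    mn <- lab
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      nb <- p[(2:(h + 1)) + d[1], (2:(w + 1)) + d[2]]
      take <- m & nb > 0L & (mn == 0L | nb < mn)
      mn[take] <- nb[take]
    }
    if (all(mn == lab)) break
    lab <- mn
  }
  hole_ids <- setdiff(unique(as.vector(lab)), c(0L, lab[1L, 1L]))
  list(n = length(hole_ids),
       cells = sum(lab %in% hole_ids))
}

# Convex-hull cell count by supporting half-planes: a candidate centre is
# in the hull iff it lies on the inner side of every line through two
# component cells that supports the whole component.
oracle_convex_area <- function(cells) {
  pts <- unique(cbind(cells[, 2L], cells[, 1L]))  # (x, y)
  n <- nrow(pts)
  if (n <= 2L) return(nrow(cells))
  xr <- range(pts[, 1L]); yr <- range(pts[, 2L])
  cand <- as.matrix(expand.grid(x = xr[1]:xr[2], y = yr[1]:yr[2]))
  cross_all <- function(a, b, px, py)
    (b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1])
  collinear <- TRUE
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a <- pts[i, ]; b <- pts[j, ]
    s <- cross_all(a, b, pts[, 1L], pts[, 2L])
    if (any(s > 1e-9) && any(s < -1e-9)) { collinear <- FALSE; next }
    collinear <- collinear && all(abs(s) < 1e-9)
    if (all(s >= -1e-9)) {       # supporting line, component on + side
      sq <- cross_all(a, b, cand[, 1L], cand[, 2L])
      keep <- keep & sq >= -1e-9
    }
  }
  if (collinear) {
    # integer points on the segment between the extremes
    return(nrow(cells))
  }
  sum(keep)
}

# AUC by exhaustive pair enumeration (ties get half credit)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Two-sided Fisher exact p by exhaustive enumeration over all tables with
# the observed margins, summing hypergeometric probabilities no larger
# than the observed one (with a relative tolerance for float safety).
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  lp <- function(x) lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)
  support <- max(0L, c1 - r2):min(r1, c1)
  probs <- exp(lp(support))
  sum(probs[probs <= exp(lp(a)) * (1 + 1e-7)])
}

# small deterministic random mask factory for property tests
random_mask <- function(h, w, p = 0.35) {
  matrix(stats::runif(h * w) < p, h, w)
}

# minimal hand-built patient for pipeline tests that bypass the generator
make_patient <- function(id, labels, pcr, er = 1, pr = pcr,
                         her2 = 3, ris = ifelse(pcr == 1, 0, 1.5)) {
  structure(list(patient_id = id, ts = ts_image(labels, id),
                 er = er, er_pct = er * 50, pr = pr, pr_pct = pr * 50,
                 her2_cep17 = her2, pcr = pcr, ris_cm = ris),
            class = "synthetic_patient")
}
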