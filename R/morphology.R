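#' Connected-component morphometry of tissue-segmentation images
#'
#' Tools to label 8-connected components of a compartment mask at tile
#' resolution, compute 11 shape descriptors per component, and aggregate them
#' under the all-region (AR), largest-region (LR) and significant-region (SR)
#' strategies into 46 features per compartment.
#'
#' @name morphology
NULL

#' The 11 base shape descriptors
#'
#' Descriptor order is fixed and shared by every aggregation strategy:
#' `area`, `filled_area`, `convex_area`, `major_axis_length`,
#' `minor_axis_length`, `eccentricity`, `euler_number`, `extent`, `solidity`,
#' `perimeter`, `orientation`. Areas are in tiles, axis lengths in tile
#' units, perimeter in exposed tile edges, orientation in radians.
#'
#' @return Character vector of the 11 descriptor names.
#' @export
descriptor_names <- function() {
  c("area", "filled_area", "convex_area", "major_axis_length",
    "minor_axis_length", "eccentricity", "euler_number", "extent",
    "solidity", "perimeter", "orientation")
}

#' Canonical names of the 46 per-compartment features
#'
#' The all-region (AR) strategy contributes the component count plus the mean
#' of each descriptor over all components (12 features); the largest-region
#' (LR) strategy contributes the 11 descriptors of the single largest
#' component; the significant-region (SR) strategy contributes the count of
#' significant components plus the mean and standard deviation of each
#' descriptor over them (23 features).
#'
#' @param compartment Optional compartment prefix (e.g. `"stil"`); when given,
#'   names are prefixed `<compartment>__`.
#' @return Character vector of 46 feature names.
#' @export
feature_names <- function(compartment = NULL) {
  d <- descriptor_names()
  nm <- c("ar__n_components", paste0("ar__", d, "__mean"),
          paste0("lr__", d),
          "sr__n_regions", paste0("sr__", d, "__mean"),
          paste0("sr__", d, "__std"))
  stopifnot(length(nm) == 46L)
  if (!is.null(compartment)) nm <- paste0(compartment, "__", nm)
  nm
}

#' Label 8-connected components of a binary mask
#'
#' Components are maximal sets of TRUE cells connected through any of the 8
#' neighbours (diagonals included). The returned list is ordered by the
#' (minimum row, minimum column) of each component, which makes labelling
#' deterministic.
#'
#' @param mask Logical or 0/1 matrix (rows x columns of the tile grid).
#' @return List of components; each is an integer matrix with columns
#'   `row`, `col` (1-based grid coordinates).
#' @export
label_components <- function(mask) {
  mask <- mask_as_logical(mask)
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  comps <- list()
  nxt <- 0L
  # neighbour offsets, 8-connectivity
  dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  for (c0 in seq_len(w)) for (r0 in seq_len(h)) {
    if (!mask[r0, c0] || lab[r0, c0] > 0L) next
    nxt <- nxt + 1L
    # iterative flood fill with an explicit stack
    stack_r <- integer(256L); stack_c <- integer(256L)
    stack_r[1L] <- r0; stack_c[1L] <- c0; top <- 1L
    lab[r0, c0] <- nxt
    cells_r <- integer(0L); cells_c <- integer(0L)
    while (top > 0L) {
      r <- stack_r[top]; cc <- stack_c[top]; top <- top - 1L
      cells_r <- c(cells_r, r); cells_c <- c(cells_c, cc)
      for (k in 1:8) {
        rr <- r + dr[k]; ccn <- cc + dc[k]
        if (rr >= 1L && rr <= h && ccn >= 1L && ccn <= w &&
            mask[rr, ccn] && lab[rr, ccn] == 0L) {
          lab[rr, ccn] <- nxt
          top <- top + 1L
          if (top > length(stack_r)) {
            stack_r <- c(stack_r, integer(length(stack_r)))
            stack_c <- c(stack_c, integer(length(stack_c)))
          }
          stack_r[top] <- rr; stack_c[top] <- ccn
        }
      }
    }
    comps[[nxt]] <- cbind(row = cells_r, col = cells_c)
  }
  if (length(comps) == 0L) return(list())
  ord <- order(vapply(comps, function(m) min(m[, 1L]), 0),
               vapply(comps, function(m) min(m[, 2L]), 0))
  comps[ord]
}

mask_as_logical <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  if (is.logical(mask)) return(mask)
  mask != 0
}

#' Compute the 11 shape descriptors of one component
#'
#' Descriptors follow the regionprops conventions used in digital-pathology
#' morphometry, computed on the tile-resolution mask:
#' * `area`: number of tiles.
#' * `filled_area`: area with interior holes filled (holes are 4-connected
#'   background regions not reaching the bounding-box border).
#' * `convex_area`: tiles whose centres lie in the convex hull of the
#'   component's tile centres (hull boundary counts as inside).
#' * `major_axis_length`, `minor_axis_length`: axes of the ellipse with the
#'   same second central moments as the component, each tile treated as a
#'   unit square (adds 1/12 to the diagonal of the covariance); lengths are
#'   `4 * sqrt(eigenvalue)`.
#' * `eccentricity`: `sqrt(1 - (minor/major)^2)`, in `[0, 1]`.
#' * `euler_number`: 1 minus the number of holes (single component).
#' * `extent`: area / bounding-box area.
#' * `solidity`: area / convex_area.
#' * `perimeter`: number of exposed 4-neighbour tile edges.
#' * `orientation`: angle in radians between the column axis and the major
#'   axis, in `(-pi/2, pi/2]`.
#'
#' @param cells Integer matrix with columns `row`, `col`, as produced by
#'   [label_components()].
#' @return Named numeric vector of length 11 (see [descriptor_names()]).
#' @export
compute_descriptors <- function(cells) {
  if (is.null(dim(cells)) || nrow(cells) == 0L)
    stop("component must be non-empty")
  r <- cells[, 1L]; cc <- cells[, 2L]
  n <- length(r)
  rmin <- min(r); rmax <- max(r); cmin <- min(cc); cmax <- max(cc)
  bh <- rmax - rmin + 1L; bw <- cmax - cmin + 1L
  local <- matrix(FALSE, bh, bw)
  local[cbind(r - rmin + 1L, cc - cmin + 1L)] <- TRUE

  holes <- hole_components(local)
  filled_area <- n + sum(vapply(holes, nrow, 0L))
  euler <- 1L - length(holes)

  conv <- convex_area_cells(r, cc)

  # second central moments; each tile is a unit square (uniform density),
  # which contributes 1/12 to each diagonal term
  mr <- mean(r); mc <- mean(cc)
  mu_rr <- mean((r - mr)^2) + 1 / 12
  mu_cc <- mean((cc - mc)^2) + 1 / 12
  mu_rc <- mean((r - mr) * (cc - mc))
  tr2 <- (mu_cc + mu_rr) / 2
  det_sqrt <- sqrt(((mu_cc - mu_rr) / 2)^2 + mu_rc^2)
  l1 <- tr2 + det_sqrt; l2 <- max(tr2 - det_sqrt, 0)
  major <- 4 * sqrt(l1); minor <- 4 * sqrt(l2)
  ecc <- if (l1 > 0) sqrt(max(1 - l2 / l1, 0)) else 0
  orient <- 0.5 * atan2(2 * mu_rc, mu_cc - mu_rr)

  # exposed 4-neighbour edges
  adj_h <- sum(local[, -1L, drop = FALSE] & local[, -bw, drop = FALSE])
  adj_v <- sum(local[-1L, , drop = FALSE] & local[-bh, , drop = FALSE])
  perim <- 4L * n - 2L * (adj_h + adj_v)

  c(area = n,
    filled_area = filled_area,
    convex_area = conv,
    major_axis_length = major,
    minor_axis_length = minor,
    eccentricity = ecc,
    euler_number = euler,
    extent = n / (bh * bw),
    solidity = n / conv,
    perimeter = perim,
    orientation = orient)
}

# 4-connected background regions inside the bounding box that do not touch
# its border: the holes of the component
hole_components <- function(local) {
  bh <- nrow(local); bw <- ncol(local)
  bg <- !local
  reach <- matrix(FALSE, bh, bw)
  # flood the border-connected background (4-connectivity)
  stack <- which(bg & (row(bg) == 1L | row(bg) == bh |
                       col(bg) == 1L | col(bg) == bw))
  reach[stack] <- TRUE
  dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  while (length(stack) > 0L) {
    idx <- stack[length(stack)]; stack <- stack[-length(stack)]
    r <- ((idx - 1L) %% bh) + 1L; cc <- ((idx - 1L) %/% bh) + 1L
    for (k in 1:4) {
      rr <- r + dr[k]; ccn <- cc + dc[k]
      if (rr >= 1L && rr <= bh && ccn >= 1L && ccn <= bw &&
          bg[rr, ccn] && !reach[rr, ccn]) {
        reach[rr, ccn] <- TRUE
        stack <- c(stack, (ccn - 1L) * bh + rr)
      }
    }
  }
  hole_mask <- bg & !reach
  if (!any(hole_mask)) return(list())
  label_components_4(hole_mask)
}

# 4-connected labelling (used for holes only)
label_components_4 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  comps <- list(); nxt <- 0L
  dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  for (c0 in seq_len(w)) for (r0 in seq_len(h)) {
    if (!mask[r0, c0] || lab[r0, c0] > 0L) next
    nxt <- nxt + 1L
    stack <- list(c(r0, c0)); lab[r0, c0] <- nxt
    cells <- NULL
    while (length(stack) > 0L) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      cells <- rbind(cells, p)
      for (k in 1:4) {
        rr <- p[1L] + dr[k]; ccn <- p[2L] + dc[k]
        if (rr >= 1L && rr <= h && ccn >= 1L && ccn <= w &&
            mask[rr, ccn] && lab[rr, ccn] == 0L) {
          lab[rr, ccn] <- nxt
          stack[[length(stack) + 1L]] <- c(rr, ccn)
        }
      }
    }
    comps[[nxt]] <- cbind(row = cells[, 1L], col = cells[, 2L])
  }
  comps
}

# number of grid cells whose centres lie inside (or on) the convex hull of
# the component's cell centres; collinear components degenerate to their area
convex_area_cells <- function(r, cc) {
  n <- length(r)
  if (n <= 2L) return(n)
  pts <- unique(cbind(cc, r))
  if (nrow(pts) <= 2L) return(n)
  # collinearity check via the rank of centred coordinates
  ctr <- scale(pts, scale = FALSE)
  if (abs(ctr[, 1L] %*% ctr[, 2L])^2 >=
      (sum(ctr[, 1L]^2) * sum(ctr[, 2L]^2)) * (1 - 1e-12)) {
    return(n)
  }
  hull <- grDevices::chull(pts)
  hx <- pts[hull, 1L]; hy <- pts[hull, 2L]
  cand_c <- rep(seq(min(cc), max(cc)), each = max(r) - min(r) + 1L)
  cand_r <- rep(seq(min(r), max(r)), times = max(cc) - min(cc) + 1L)
  inside <- pracma::inpolygon(cand_c, cand_r, hx, hy, boundary = TRUE)
  sum(inside)
}

#' Select the significant components of a compartment
#'
#' A component is significant when its area strictly exceeds
#' `threshold` times the largest component area in the same compartment
#' ("exceeding" is a strict inequality, so a component at exactly the
#' threshold is dropped). The largest component is always significant.
#'
#' @param components List of components from [label_components()].
#' @param threshold Proportion of the largest area, in `(0, 1)`; default 0.05.
#' @return Subset of `components`, in the original order.
#' @export
significant_components <- function(components, threshold = 0.05) {
  if (length(components) == 0L) return(list())
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)")
  areas <- vapply(components, nrow, 0L)
  components[areas > threshold * max(areas)]
}

#' Extract the 46 morphological features of one compartment mask
#'
#' @param mask Logical matrix of the compartment at tile resolution.
#' @param threshold Significant-region threshold (see
#'   [significant_components()]).
#' @param compartment Optional prefix for the feature names.
#' @return Named numeric vector of length 46. An empty mask yields all `NA`
#'   (the missing-compartment sentinel, imputed downstream with training-set
#'   medians).
#' @export
compartment_features <- function(mask, threshold = 0.05, compartment = NULL) {
  comps <- label_components(mask)
  nm <- feature_names(compartment)
  if (length(comps) == 0L) {
    out <- rep(NA_real_, 46L); names(out) <- nm
    return(out)
  }
  desc <- t(vapply(comps, compute_descriptors, numeric(11L)))
  areas <- desc[, "area"]
  ar <- c(length(comps), colMeans(desc))
  lr <- desc[which.max(areas), ]
  sig <- desc[areas > threshold * max(areas), , drop = FALSE]
  sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
  sr <- c(nrow(sig), colMeans(sig), apply(sig, 2L, sd_pop))
  out <- c(ar, lr, sr)
  names(out) <- nm
  out
}

#' Extract morphological features for the TME compartments of a TS-image
#'
#' Computes, per compartment, the 46 features described in [feature_names()].
#' Compartments are tumor (code 1), stroma (2), intratumoral lymphocytes
#' (iTIL, 4), stromal lymphocytes (sTIL, 5) and their union TIL (4 or 5).
#' Necrosis is segmented by the cascade but is not a feature compartment.
#'
#' @param ts A `ts_image` (see [ts_image()]).
#' @param threshold Significant-region threshold, default 0.05.
#' @param compartments Character subset of
#'   `c("tumor", "stroma", "itil", "stil", "til")`.
#' @return Named numeric vector with `46 * length(compartments)` entries,
#'   names prefixed by compartment.
#' @export
extract_features <- function(ts, threshold = 0.05,
                             compartments = c("tumor", "stroma", "itil",
                                              "stil", "til")) {
  stopifnot(inherits(ts, "ts_image"))
  compartments <- match.arg(compartments, several.ok = TRUE)
  lab <- ts$labels
  masks <- list(tumor = lab == 1L, stroma = lab == 2L, itil = lab == 4L,
                stil = lab == 5L, til = lab == 4L | lab == 5L)
  out <- lapply(compartments, function(cp)
    compartment_features(masks[[cp]], threshold, cp))
  unlist(out)
}
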