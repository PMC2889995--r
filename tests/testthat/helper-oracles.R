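# Independent brute-force oracles used to cross-check the implementation.
# Each deliberately takes a different computational route from the package.

# Minimal-angle color classification, one pixel at a time via acos().
oracle_classify <- function(v) {
  corners <- rbind(c(255, 0, 0), c(0, 255, 0), c(0, 0, 255),
                   c(255, 255, 0), c(255, 0, 255), c(0, 255, 255),
                   c(255, 255, 255))
  apply(v, 1L, function(px) {
    if (all(px == 0)) return(0L)
    ang <- apply(corners, 1L, function(e)
      acos(min(1, sum(px * e) / sqrt(sum(px^2) * sum(e^2)))))
    which.min(ang)
  })
}

# Is any pair of edge angles tied for the minimum (within tol, radians)?
oracle_is_tied <- function(px, tol = 1e-7) {
  corners <- rbind(c(255, 0, 0), c(0, 255, 0), c(0, 0, 255),
                   c(255, 255, 0), c(255, 0, 255), c(0, 255, 255),
                   c(255, 255, 255))
  ang <- apply(corners, 1L, function(e)
    acos(min(1, sum(px * e) / sqrt(sum(px^2) * sum(e^2)))))
  sum(ang <= min(ang) + tol) > 1L
}

# Windowed mean / sample sd by explicit per-pixel window extraction.
oracle_box_stats <- function(m, w) {
  h <- (w - 1L) %/% 2L
  pad <- function(n) c(h:1, 1:n, n:(n - h + 1L))
  p <- m[pad(nrow(m)), pad(ncol(m))]
  mu <- matrix(0, nrow(m), ncol(m)); sg <- mu
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    win <- p[i:(i + 2L * h), j:(j + 2L * h)]
    mu[i, j] <- mean(win)
    sg[i, j] <- stats::sd(win)
  }
  list(mean = mu, sd = sg)
}

# Connected-component labelling by iterative minimum-label propagation.
oracle_label <- function(mask, connectivity = "face") {
  d <- dim(mask)
  off <- if (connectivity == "face") {
    rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
          c(0, 0, -1), c(0, 0, 1))
  } else {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    g[rowSums(g != 0) > 0, , drop = FALSE]
  }
  lab <- array(0, d)
  fg <- which(mask)
  lab[fg] <- seq_along(fg)
  co <- arrayInd(fg, d)
  repeat {
    changed <- FALSE
    for (i in seq_along(fg)) {
      for (k in seq_len(nrow(off))) {
        nb <- co[i, ] + off[k, ]
        if (any(nb < 1) || any(nb > d)) next
        if (!mask[nb[1], nb[2], nb[3]]) next
        nl <- lab[nb[1], nb[2], nb[3]]
        if (nl < lab[fg[i]]) { lab[fg[i]] <- nl; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  # relabel compactly
  u <- sort(unique(lab[lab > 0]))
  lab[lab > 0] <- match(lab[lab > 0], u)
  lab
}

# All-pairs percent co-localization straight from voxel-set intersections.
oracle_percent <- function(ref, target, thr = 0.30) {
  events <- 0L
  for (p in ref$puncta) {
    for (q in target$puncta) {
      if (length(intersect(p$voxels, q$voxels)) /
          min(p$n, q$n) > thr) { events <- events + 1L; break }
    }
  }
  100 * events / length(ref$puncta)
}

# Brute-force triple count: ref puncta pairwise co-localized with some
# member of each other set.
oracle_triple <- function(a, b, cc, thr = 0.30) {
  hit <- function(p, set) any(vapply(set$puncta, function(q)
    length(intersect(p$voxels, q$voxels)) / min(p$n, q$n) > thr,
    logical(1)))
  sum(vapply(a$puncta, function(p) hit(p, b) && hit(p, cc), logical(1)))
}

# Grayscale opening (erosion then dilation) with a disc mask, by loops.
oracle_opening_residue <- function(m, radius) {
  sz <- 2L * as.integer(ceiling(radius)) + 1L
  br <- EBImage::makeBrush(sz, shape = "disc")
  h <- (sz - 1L) %/% 2L
  filt <- function(x, f) {
    out <- x
    for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
      vals <- c()
      for (a in -h:h) for (b in -h:h) {
        if (br[a + h + 1L, b + h + 1L] == 0) next
        ii <- i + a; jj <- j + b
        if (ii < 1 || ii > nrow(x) || jj < 1 || jj > ncol(x)) next
        vals <- c(vals, x[ii, jj])
      }
      out[i, j] <- f(vals)
    }
    out
  }
  pmax(m - filt(filt(m, min), max), 0)
}

# Dominant-axis line rasterization with floating-point stepping.
oracle_line <- function(p0, p1) {
  dy <- p1[1] - p0[1]; dx <- p1[2] - p0[2]
  n <- max(abs(dy), abs(dx))
  if (n == 0) return(matrix(p0, 1L, 2L))
  t(vapply(0:n, function(i)
    c(p0[1] + round(i * dy / n), p0[2] + round(i * dx / n)), numeric(2)))
}

# Minimal synthetic puncta builders for the co-localization unit tests.
make_pset <- function(channel, voxlist, dim = c(1L, 32L, 32L)) {
  puncta <- lapply(seq_along(voxlist), function(i)
    list(id = i, channel = channel, voxels = voxlist[[i]],
         n = length(voxlist[[i]]),
         centroid = c(z = 1, y = 1, x = 1), peak = 1))
  structure(list(puncta = puncta, channel = channel, dim = dim,
                 params = list()),
            class = "puncta_set")
}

make_punctum <- function(channel, voxels, id = 1L) {
  list(id = id, channel = channel, voxels = voxels, n = length(voxels))
}

# Detect puncta in every channel of a simulated stack with one call.
detect_all <- function(stack, window = 31L, min_size = 4L) {
  out <- lapply(names(stack$channels), function(nm) {
    ch <- stack$channels[[nm]]
    detect_puncta(ch, estimate_local_background(ch, window),
                  min_size = min_size, channel_name = nm)
  })
  names(out) <- names(stack$channels)
  out
}
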