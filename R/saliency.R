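# Adaptive initial-contour extraction: SLIC-style superpixels ->
# cellular-automata saliency propagation -> mean filtering -> Otsu
# binarisation -> morphological cleanup -> largest connected component.
# The optic disc is the brightest compact structure in the cropped ROI,
# so it surfaces as the most salient object and its component boundary
# becomes the initial contour for the level-set evolution.

# sRGB (0..1 triples) -> CIELAB
srgb_to_lab <- function(rgb01) {
  grDevices::convertColor(rgb01, from = "sRGB", to = "Lab")
}

#' Compute a superpixel partition
#'
#' SLIC-style oversegmentation: k-means in combined CIELAB colour +
#' spatial coordinates, initialised on a regular grid with spacing
#' \eqn{S = \sqrt{N/K}}, followed by a connectivity pass that absorbs
#' stray fragments into an adjacent segment, so every returned segment
#' is 4-connected. Deterministic.
#'
#' @param image Numeric matrix in [0, 255] (grayscale), or an
#'   height x width x 3 array (RGB in [0, 255]).
#' @param n_segments Target number of superpixels (>= 2, <= pixel
#'   count); the realised count can differ slightly.
#' @param compactness Spatial regularisation weight (SLIC \eqn{m});
#'   larger values give squarer segments.
#' @param n_iter Assignment/update sweeps.
#' @return A \code{superpixel_partition}: \code{labels} (matrix of ids
#'   \code{1..n_segments}), \code{n_segments}, \code{adjacency}
#'   (symmetric logical matrix), \code{mean_color} (CIELAB per
#'   segment), \code{centroid} (per-segment (x, y) normalised to
#'   [0, 1]), \code{border} (segments touching the image border).
#' @export
compute_superpixels <- function(image, n_segments = 200, compactness = 10,
                                n_iter = 10) {
  if (is.matrix(image)) {
    check_gray_image(image)
    nr <- nrow(image); nc <- ncol(image)
    g <- pmin(pmax(as.vector(image) / 255, 0), 1)
    lab <- srgb_to_lab(cbind(g, g, g))
  } else if (is.array(image) && length(dim(image)) == 3L && dim(image)[3L] == 3L) {
    nr <- dim(image)[1L]; nc <- dim(image)[2L]
    rgb01 <- pmin(pmax(cbind(as.vector(image[, , 1L]), as.vector(image[, , 2L]),
                             as.vector(image[, , 3L])) / 255, 0), 1)
    lab <- srgb_to_lab(rgb01)
  } else {
    stop("`image` must be a matrix or an h x w x 3 array", call. = FALSE)
  }
  npix <- nr * nc
  if (n_segments < 2 || n_segments > npix)
    stop("`n_segments` must be in [2, pixel count]", call. = FALSE)

  S <- sqrt(npix / n_segments)
  # centre grid sized to the image aspect so even tiny n_segments get
  # the requested number of seeds
  nx <- max(1L, as.integer(ceiling(sqrt(n_segments * nc / nr))))
  ny <- max(1L, as.integer(ceiling(n_segments / nx)))
  ci <- (seq_len(nx) - 0.5) * nc / nx - 0.5
  ri <- (seq_len(ny) - 0.5) * nr / ny - 0.5
  centres <- cbind(rep(ri, times = nx), rep(ci, each = ny))
  cfeat <- lab[pmin(pmax(round(centres[, 1L]) + 1, 1), nr) +
               (pmin(pmax(round(centres[, 2L]) + 1, 1), nc) - 1) * nr, ,
               drop = FALSE]
  cen <- cbind(centres, cfeat)

  labels <- NULL
  for (it in seq_len(n_iter)) {
    labels <- .slic_assign_c(lab, cen, nr, nc, S, compactness)
    lv <- as.vector(labels)
    cnt <- tabulate(lv, nbins = nrow(cen))
    rows <- matrix(rep(seq_len(nr) - 1L, times = nc), nr, nc)
    cols <- matrix(rep(seq_len(nc) - 1L, each = nr), nr, nc)
    keep <- cnt > 0
    sums <- rowsum(cbind(as.vector(rows), as.vector(cols), lab), lv)
    ids <- as.integer(rownames(sums))
    cen_new <- cen
    cen_new[ids, ] <- sums / cnt[ids]
    cen <- cen_new[keep, , drop = FALSE]
    if (!all(keep) && it < n_iter) next
  }
  labels <- .slic_assign_c(lab, cen, nr, nc, S, compactness)

  labels <- enforce_connectivity(labels)
  build_partition(labels, lab, nr, nc)
}

# absorb 4-connected fragments that are not their label's largest piece
enforce_connectivity <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  repeat {
    changed <- FALSE
    for (l in sort(unique(as.vector(labels)))) {
      comp <- EBImage::bwlabel((labels == l) + 0)
      ncomp <- max(comp)
      if (ncomp <= 1) next
      sizes <- tabulate(comp[comp > 0], nbins = ncomp)
      main <- which.max(sizes)
      for (k in seq_len(ncomp)) {
        if (k == main) next
        idx <- which(comp == k, arr.ind = TRUE)
        # neighbouring labels of the fragment
        nb <- integer(0)
        for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
          rr <- idx[, 1L] + d[1L]; cc <- idx[, 2L] + d[2L]
          ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
          nb <- c(nb, labels[cbind(rr[ok], cc[ok])])
        }
        nb <- nb[nb != l]
        if (length(nb) == 0L) next
        tgt <- as.integer(names(which.max(table(nb))))
        labels[idx] <- tgt
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # relabel contiguously from 1
  u <- sort(unique(as.vector(labels)))
  matrix(match(labels, u), nrow(labels), ncol(labels))
}

build_partition <- function(labels, lab, nr, nc) {
  K <- max(labels)
  lv <- as.vector(labels)
  cnt <- tabulate(lv, nbins = K)
  mean_color <- rowsum(lab, lv) / cnt
  rows <- rep(seq_len(nr) - 1L, times = nc)
  cols <- rep(seq_len(nc) - 1L, each = nr)
  cy <- rowsum(rows, lv)[, 1L] / cnt
  cx <- rowsum(cols, lv)[, 1L] / cnt
  centroid <- cbind(x = cx / max(nc - 1L, 1L), y = cy / max(nr - 1L, 1L))
  adj <- matrix(FALSE, K, K)
  pair_on <- function(a, b) {
    sel <- a != b
    if (any(sel)) adj[cbind(a[sel], b[sel])] <<- TRUE
  }
  pair_on(labels[-nr, ], labels[-1L, ])
  pair_on(labels[, -nc], labels[, -1L])
  pair_on(labels[-nr, -nc], labels[-1L, -1L])
  pair_on(labels[-nr, -1L], labels[-1L, -nc])
  adj <- adj | t(adj)
  diag(adj) <- FALSE
  border <- sort(unique(c(labels[1L, ], labels[nr, ], labels[, 1L], labels[, nc])))
  structure(list(labels = labels, n_segments = K, adjacency = adj,
                 mean_color = mean_color, centroid = centroid,
                 border = seq_len(K) %in% border),
            class = "superpixel_partition")
}

#' Cellular-automata saliency over a superpixel partition
#'
#' Each superpixel is a cell whose saliency is updated synchronously
#' from its neighbours. The initial state contrasts every segment's
#' CIELAB colour against the border segments (the background prior),
#' weighted by spatial proximity. The impact-factor matrix is
#' \eqn{f_{ij} = \exp(-d_{lab}(i,j)/\sigma^2)} over the neighbour graph
#' (adjacent segments, segments sharing a neighbour, and all pairs of
#' border segments), row-normalised; the coherence of each cell is
#' inversely related to its strongest neighbour similarity and rescaled
#' to \code{coherence_range}. The update is
#' \eqn{S \leftarrow C S + (I - C) F^* S} for \code{n_steps} steps, and
#' the result is min-max normalised to [0, 1] and broadcast to pixels.
#' Deterministic.
#'
#' @param partition A \code{superpixel_partition}.
#' @param n_steps Number of synchronous automaton updates.
#' @param sigma2 Colour-similarity bandwidth on max-normalised CIELAB
#'   distances.
#' @param coherence_range Two values in (0, 1): range the coherence
#'   diagonal is rescaled to.
#' @param sigma_spatial Bandwidth of the spatial weighting (normalised
#'   centroid coordinates) in the background-contrast initial state.
#' @return Saliency matrix in [0, 1], congruent with the image.
#' @export
cellular_automata_saliency <- function(partition, n_steps = 20, sigma2 = 0.1,
                                       coherence_range = c(0.6, 0.9),
                                       sigma_spatial = 0.25) {
  stopifnot(inherits(partition, "superpixel_partition"), n_steps >= 1)
  K <- partition$n_segments
  if (K < 2)
    stop("saliency propagation needs at least two superpixels", call. = FALSE)

  colr <- partition$mean_color
  D <- as.matrix(stats::dist(colr))
  dmax <- max(D)
  # guard: on a (near-)constant image the pairwise colour distances are
  # floating-point noise; normalising by their maximum would amplify
  # that noise to full scale, so keep the map flat instead
  if (dmax > 1e-8) D <- D / dmax
  pos <- partition$centroid
  Ds <- as.matrix(stats::dist(pos))

  # background-contrast initial state
  bidx <- which(partition$border)
  w <- exp(-Ds[, bidx, drop = FALSE] / sigma_spatial)
  s0 <- rowSums(w * D[, bidx, drop = FALSE]) / rowSums(w)
  s0 <- minmax01(s0)

  # neighbour graph: adjacency, shared-neighbour pairs, border clique
  A <- partition$adjacency
  G <- A | ((A %*% A) > 0)
  G[bidx, bidx] <- TRUE
  diag(G) <- FALSE

  Fsim <- exp(-D / sigma2) * G
  rs <- rowSums(Fsim)
  Fstar <- Fsim / ifelse(rs > 0, rs, 1)
  cmax <- apply(ifelse(G, Fsim, NA), 1L, max, na.rm = TRUE)
  cmax[!is.finite(cmax)] <- 1
  craw <- 1 / pmax(cmax, 1e-10)
  lo <- coherence_range[1L]; hi <- coherence_range[2L]
  if (diff(range(craw)) > 0) {
    cvec <- lo + (craw - min(craw)) / diff(range(craw)) * (hi - lo)
  } else {
    cvec <- rep((lo + hi) / 2, K)
  }

  s <- s0
  for (i in seq_len(n_steps)) {
    s <- cvec * s + (1 - cvec) * drop(Fstar %*% s)
  }
  s <- minmax01(s)
  matrix(s[partition$labels], nrow(partition$labels), ncol(partition$labels))
}

minmax01 <- function(x) {
  r <- range(x)
  if (r[2L] - r[1L] > 1e-9) (x - r[1L]) / (r[2L] - r[1L]) else x - r[1L]
}

#' Mean-filter a saliency map
#'
#' Arithmetic mean over a square window with edge-replicating padding;
#' smooths superpixel blockiness before thresholding.
#'
#' @param map Matrix with values in [0, 1].
#' @param kernel Odd window side (>= 1, <= min image dimension).
#' @return Smoothed map, still within [0, 1].
#' @export
smooth_saliency <- function(map, kernel = 5) {
  stopifnot(is.matrix(map))
  kernel <- as.integer(kernel)
  if (kernel < 1L || kernel %% 2L == 0L || kernel > min(dim(map)))
    stop("`kernel` must be odd, >= 1 and <= min(image dimensions)",
         call. = FALSE)
  if (kernel == 1L) return(map)
  out <- box_sum(map, kernel) / kernel^2
  pmin(pmax(out, 0), 1)
}

#' Otsu threshold of a saliency map
#'
#' The threshold maximising between-class variance over a 256-bin
#' histogram of the map values in [0, 1]. Candidate cuts are the 255
#' interior bin edges k/256; the earliest maximiser wins on ties.
#'
#' @param map Matrix with values in [0, 1] and at least two distinct
#'   values.
#' @return Scalar threshold in (0, 1).
#' @export
otsu_threshold <- function(map) {
  stopifnot(is.matrix(map))
  v <- as.vector(map)
  if (any(v < 0 | v > 1))
    stop("`map` values must lie in [0, 1]", call. = FALSE)
  if (length(unique(v)) < 2L)
    stop("degenerate histogram: map is constant", call. = FALSE)
  h <- tabulate(pmin(floor(v * 256) + 1L, 256L), nbins = 256L)
  mid <- (seq_len(256L) - 0.5) / 256
  w <- cumsum(h)
  m <- cumsum(h * mid)
  tot <- w[256L]; mtot <- m[256L]
  k <- 1:255
  w0 <- w[k]; w1 <- tot - w0
  ok <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, 255L)
  bcv[ok] <- (mtot * w0[ok] - m[k][ok] * tot)^2 / (w0[ok] * w1[ok])
  which.max(bcv) / 256
}

# 8-connected labelling: 4-connected EBImage::bwlabel plus union-find
# merging of diagonally adjacent labels
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n <= 1) return(lab)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  unite <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  diag_pairs <- function(a, b) {
    sel <- a > 0 & b > 0 & a != b
    unique(cbind(a[sel], b[sel]))
  }
  prs <- rbind(diag_pairs(lab[-nr, -nc], lab[-1L, -1L]),
               diag_pairs(lab[-nr, -1L], lab[-1L, -nc]))
  if (nrow(prs) > 0)
    for (i in seq_len(nrow(prs))) unite(prs[i, 1L], prs[i, 2L])
  roots <- vapply(seq_len(n), find, integer(1))
  u <- sort(unique(roots))
  newlab <- match(roots, u)
  out <- lab
  out[lab > 0] <- newlab[lab[lab > 0]]
  out
}

#' Largest 8-connected foreground component
#'
#' Keeps only the 8-connected foreground component with the most
#' pixels; on ties, the component whose first pixel comes earliest in
#' raster-scan (row-major) order wins.
#'
#' @param mask A {0,1} matrix with at least one foreground pixel.
#' @return A {0,1} matrix containing only the winning component.
#' @export
largest_connected_object <- function(mask) {
  check_binary_mask(mask)
  if (sum(mask) == 0)
    stop("initialization failure: mask has no foreground pixels",
         call. = FALSE)
  lab <- label8(mask)
  n <- max(lab)
  sizes <- tabulate(lab[lab > 0], nbins = n)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # raster order: scan rows top to bottom, left to right
    nr <- nrow(lab); nc <- ncol(lab)
    raster <- (matrix(rep(seq_len(nr), times = nc), nr, nc) - 1L) * nc +
      matrix(rep(seq_len(nc), each = nr), nr, nc)
    first <- vapply(best, function(k) min(raster[lab == k]), numeric(1))
    best <- best[which.min(first)]
  }
  (lab == best[1L]) + 0
}

# signed "distance" level set from a mask: positive inside, negative
# outside (Euclidean distance transform on each side)
mask_to_levelset <- function(mask) {
  check_binary_mask(mask)
  inside <- EBImage::distmap(mask)
  outside <- EBImage::distmap(1 - mask)
  m <- inside - outside
  matrix(as.numeric(m), nrow(mask), ncol(mask))
}

#' Extract the adaptive initial contour
#'
#' Runs the full initialisation pipeline: cellular-automata saliency on
#' a superpixel partition, mean filtering, Otsu binarisation, binary
#' closing (3x3) with hole filling, and largest-connected-component
#' selection. The component mask is converted to an initial level set
#' \eqn{\phi^0} (positive inside, negative outside, signed Euclidean
#' distance). If the saliency stage degenerates (e.g. a constant
#' image), the initialisation falls back to a centred circle of radius
#' \code{min(height, width)/4} and emits a message.
#'
#' @param image Numeric matrix in [0, 255].
#' @param config A [lifo_config()] supplying \code{n_segments},
#'   \code{ca_steps} and \code{mean_kernel}.
#' @return List with \code{mask} ({0,1} matrix) and \code{phi}
#'   (initial level set).
#' @export
make_initial_contour <- function(image, config = lifo_config()) {
  check_gray_image(image)
  mask <- tryCatch({
    part <- compute_superpixels(image, n_segments = config$n_segments)
    sal <- cellular_automata_saliency(part, n_steps = config$ca_steps)
    sal <- smooth_saliency(sal, kernel = config$mean_kernel)
    th <- otsu_threshold(sal)
    bw <- (sal > th) + 0
    bw <- EBImage::closing(bw, EBImage::makeBrush(config$morph_kernel,
                                                  shape = "disc"))
    bw <- EBImage::fillHull(bw)
    bw <- matrix(as.numeric(bw > 0), nrow(image), ncol(image))
    largest_connected_object(bw)
  }, error = function(e) {
    message("adaptive initialization failed (", conditionMessage(e),
            "); falling back to a centered circle")
    fallback_circle(dim(image))
  })
  list(mask = mask, phi = mask_to_levelset(mask))
}

fallback_circle <- function(dim) {
  nr <- dim[1L]; nc <- dim[2L]
  r <- min(nr, nc) / 4
  g <- coord_grids(dim)
  ((g$x - (nc - 1) / 2)^2 + (g$y - (nr - 1) / 2)^2 <= r^2) + 0
}
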