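# 3D object segmentation, voxel-overlap colocalization and the van Steensel
# cross-correlation randomness test.

# Neighbour offsets (half set, to build each undirected adjacency once).
.half_offsets <- function(connectivity) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  if (connectivity == 6L)  off <- off[rowSums(abs(off)) == 1, , drop = FALSE]
  if (connectivity == 18L) off <- off[rowSums(abs(off)) <= 2, , drop = FALSE]
  # keep lexicographically positive half
  keep <- off[, 3] > 0 | (off[, 3] == 0 & off[, 2] > 0) |
    (off[, 3] == 0 & off[, 2] == 0 & off[, 1] > 0)
  off[keep, , drop = FALSE]
}

#' Segment 3D puncta by thresholding and connected components
#'
#' Voxels with intensity strictly above `threshold` (inside the optional
#' nuclear `mask`) are grouped into connected components (26-connectivity
#' by default; 6 and 18 also supported). Components smaller than
#' `min_voxels` are discarded as background — the conventional 10-voxel
#' cutoff for STED/confocal puncta. Per object the voxel count, summed
#' intensity, centroid (um) and length (um) are reported; length is the
#' extent of the voxel centres projected on the object's first principal
#' axis plus the projection of one voxel, so a single voxel has length
#' equal to the voxel size along that axis.
#'
#' @param vol 3D numeric array of intensities.
#' @param threshold Absolute intensity threshold (voxels `> threshold` are
#'   foreground), or a string `"P<q>"` (e.g. `"P99"`) meaning the q-th
#'   percentile of in-mask intensities.
#' @param min_voxels Minimum component size kept. Default 10.
#' @param voxel_size Numeric length-3, um per voxel along each axis.
#' @param mask Optional 3D logical array of the analysed region (same
#'   shape); must contain at least one `TRUE` voxel.
#' @param connectivity One of 6, 18, 26.
#' @param channel Label stored with each object.
#' @return `data.frame` with one row per object (`object_id`, `channel`,
#'   `voxel_count`, `intensity_sum`, `length_um`, `centroid_x/y/z` in um)
#'   and attributes `voxels` (list of linear voxel indices per object) and
#'   `vol_dim` (volume shape) used by [coloc_by_voxel_overlap()].
#' @export
segment_objects <- function(vol, threshold, min_voxels = 10L,
                            voxel_size = c(1, 1, 1), mask = NULL,
                            connectivity = 26L, channel = "A") {
  stopifnot(length(dim(vol)) == 3L, connectivity %in% c(6L, 18L, 26L),
            length(voxel_size) == 3L, all(voxel_size > 0))
  dims <- dim(vol)
  if (!is.null(mask)) {
    if (!identical(dim(mask), dims)) stop("mask shape must equal volume shape")
    if (!any(mask)) stop("empty mask")
  }
  if (is.character(threshold)) {
    q <- as.numeric(sub("^[Pp]", "", threshold))
    pool <- if (is.null(mask)) vol else vol[mask]
    threshold <- stats::quantile(pool, q / 100, names = FALSE, type = 7)
  }
  fg <- vol > threshold
  if (!is.null(mask)) fg <- fg & mask
  idx <- which(fg)
  empty <- data.frame(object_id = character(), channel = character(),
                      voxel_count = integer(), intensity_sum = numeric(),
                      length_um = numeric(), centroid_x = numeric(),
                      centroid_y = numeric(), centroid_z = numeric())
  if (length(idx) == 0L)
    return(structure(empty, voxels = list(), vol_dim = dims))

  coords <- arrayInd(idx, dims)
  pos <- seq_along(idx)                       # vertex id per foreground voxel
  off <- .half_offsets(connectivity)
  edges <- vector("list", nrow(off))
  for (k in seq_len(nrow(off))) {
    nb <- coords + matrix(off[k, ], nrow(coords), 3, byrow = TRUE)
    inb <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
           nb[, 2] >= 1 & nb[, 2] <= dims[2] &
           nb[, 3] >= 1 & nb[, 3] <= dims[3]
    lin <- nb[inb, 1] + (nb[inb, 2] - 1L) * dims[1] +
      (nb[inb, 3] - 1L) * dims[1] * dims[2]
    m <- match(lin, idx)
    hit <- !is.na(m)
    if (any(hit)) edges[[k]] <- cbind(pos[inb][hit], m[hit])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0)
    g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership

  keep_ids <- which(tabulate(comp) >= min_voxels)
  if (length(keep_ids) == 0L)
    return(structure(empty, voxels = list(), vol_dim = dims))
  rows <- vector("list", length(keep_ids))
  voxl <- vector("list", length(keep_ids))
  for (j in seq_along(keep_ids)) {
    sel <- comp == keep_ids[j]
    xyz_um <- sweep(coords[sel, , drop = FALSE], 2, voxel_size, `*`)
    # first principal axis of voxel centres (falls back to x for 1 voxel)
    if (sum(sel) > 1L) {
      pc1 <- eigen(stats::cov(xyz_um), symmetric = TRUE)$vectors[, 1]
    } else pc1 <- c(1, 0, 0)
    proj <- xyz_um %*% pc1
    len <- (max(proj) - min(proj)) + sum(abs(pc1) * voxel_size)
    rows[[j]] <- data.frame(
      object_id = sprintf("%s_%04d", channel, j), channel = channel,
      voxel_count = sum(sel), intensity_sum = sum(vol[idx[sel]]),
      length_um = len,
      centroid_x = mean(xyz_um[, 1]), centroid_y = mean(xyz_um[, 2]),
      centroid_z = mean(xyz_um[, 3]))
    voxl[[j]] <- idx[sel]
  }
  structure(do.call(rbind, rows), voxels = voxl, vol_dim = dims)
}

#' Object-based colocalization by voxel overlap
#'
#' A channel-B object colocalizes iff it shares at least one voxel with any
#' channel-A object. The summary percentage is taken over all B objects
#' (e.g. the percent of R-loop puncta sharing voxels with a remodeller
#' stain, relative to all R-loop puncta).
#'
#' @param objects_a,objects_b Outputs of [segment_objects()] from two
#'   volumes of identical shape.
#' @return List with `flags` (`object_id`, `coloc` per B object) and
#'   `summary` (`n_objects_b`, `n_coloc`, `pct_coloc`).
#' @export
coloc_by_voxel_overlap <- function(objects_a, objects_b) {
  da <- attr(objects_a, "vol_dim"); db <- attr(objects_b, "vol_dim")
  if (is.null(da) || is.null(db) || !identical(da, db))
    stop("objects must come from volumes of identical shape")
  vox_a <- unlist(attr(objects_a, "voxels"), use.names = FALSE)
  vb <- attr(objects_b, "voxels")
  coloc <- vapply(vb, function(v) any(v %in% vox_a), logical(1))
  n_b <- nrow(objects_b)
  list(flags = data.frame(object_id = objects_b$object_id, coloc = coloc),
       summary = list(n_objects_b = n_b, n_coloc = sum(coloc),
                      pct_coloc = if (n_b > 0) 100 * sum(coloc) / n_b
                                  else NA_real_))
}

#' Compare properties of colocalizing vs non-colocalizing objects
#'
#' For each of `intensity_sum`, `voxel_count` and `length_um`, reports
#' group means and SDs (colocalizing vs not) and a classical one-way
#' ANOVA p-value. If either group is empty the statistics for that
#' property are flagged `NA`.
#'
#' @param objects_b Output of [segment_objects()] for the B channel.
#' @param flags Logical vector (or the `flags` data frame from
#'   [coloc_by_voxel_overlap()]) marking colocalizing B objects.
#' @return `data.frame` with one row per property: group means/SDs/ns,
#'   ANOVA `f` and `p_value`.
#' @export
compare_object_properties <- function(objects_b, flags) {
  if (is.data.frame(flags)) flags <- flags$coloc
  stopifnot(length(flags) == nrow(objects_b))
  props <- c("intensity_sum", "voxel_count", "length_um")
  out <- lapply(props, function(p) {
    x <- objects_b[[p]]
    g1 <- x[flags]; g0 <- x[!flags]
    row <- data.frame(property = p,
                      mean_coloc = mean(g1), sd_coloc = stats::sd(g1),
                      n_coloc = length(g1),
                      mean_noncoloc = mean(g0), sd_noncoloc = stats::sd(g0),
                      n_noncoloc = length(g0),
                      f = NA_real_, p_value = NA_real_)
    if (length(g1) >= 2 && length(g0) >= 2 && stats::sd(x) > 0) {
      fit <- stats::oneway.test(x ~ factor(flags), var.equal = TRUE)
      row$f <- unname(fit$statistic); row$p_value <- fit$p.value
    }
    row
  })
  do.call(rbind, out)
}

#' Van Steensel cross-correlation function between two channels
#'
#' Computes the Pearson correlation between channel A and channel B
#' translated voxel-wise along one lateral axis, for every shift in
#' `[-max_shift, max_shift]`. `r[d] = cor(A[x], B[x + d])` over the
#' overlapping (in-mask) region, so the peak sits at the shift that
#' realigns B with A. A genuine colocalization signal peaks at zero shift;
#' random overlap gives a flat profile. The `verdict` is `"nonrandom"` iff
#' r at zero shift is the global maximum of the profile and exceeds the
#' mean + 3 SD of the baseline correlations at `|d| > max_shift / 2` —
#' a documented operational criterion for flagging non-random overlap.
#'
#' @param vol_a,vol_b 3D numeric arrays of identical shape.
#' @param max_shift Maximum shift in voxels, less than the axis extent.
#' @param axis Axis along which to translate (1, 2 or 3). Default 1.
#' @param mask Optional 3D logical array; correlations are restricted to
#'   voxel pairs whose both positions are in the mask.
#' @return List with `shifts`, `r`, `peak_shift`, `r_zero`, `verdict`.
#' @export
ccf_van_steensel <- function(vol_a, vol_b, max_shift, axis = 1L, mask = NULL) {
  stopifnot(identical(dim(vol_a), dim(vol_b)), length(dim(vol_a)) == 3L,
            axis %in% 1:3)
  dims <- dim(vol_a)
  if (max_shift >= dims[axis]) stop("max_shift must be below the axis extent")
  if (!is.null(mask) && !identical(dim(mask), dims))
    stop("mask shape must equal volume shape")
  shifts <- -max_shift:max_shift
  slice_idx <- function(from, to) {
    ix <- lapply(dims, seq_len)
    ix[[axis]] <- from:to
    ix
  }
  n_ax <- dims[axis]
  r <- vapply(shifts, function(d) {
    # overlap of x and x + d along `axis`
    a_rng <- c(max(1L, 1L - d), min(n_ax, n_ax - d))
    ia <- slice_idx(a_rng[1], a_rng[2])
    ib <- slice_idx(a_rng[1] + d, a_rng[2] + d)
    av <- do.call(`[`, c(list(vol_a), ia, list(drop = FALSE)))
    bv <- do.call(`[`, c(list(vol_b), ib, list(drop = FALSE)))
    if (!is.null(mask)) {
      ma <- do.call(`[`, c(list(mask), ia, list(drop = FALSE)))
      mb <- do.call(`[`, c(list(mask), ib, list(drop = FALSE)))
      sel <- ma & mb
      if (sum(sel) < 3L) return(NA_real_)
      av <- av[sel]; bv <- bv[sel]
    }
    if (stats::sd(av) == 0 || stats::sd(bv) == 0) return(NA_real_)
    stats::cor(as.vector(av), as.vector(bv))
  }, numeric(1))
  ok <- is.finite(r)
  peak_shift <- shifts[ok][which.max(r[ok])]
  r_zero <- r[shifts == 0]
  base <- r[abs(shifts) > max_shift / 2 & ok]
  nonrandom <- isTRUE(peak_shift == 0L) && length(base) >= 2 &&
    isTRUE(r_zero > mean(base) + 3 * stats::sd(base))
  list(shifts = shifts, r = r, peak_shift = peak_shift, r_zero = r_zero,
       verdict = if (nonrandom) "nonrandom" else "random")
}

#' Normalize intensities to the median of a reference population
#'
#' Divides every value by the median of the reference sample (typically the
#' control condition of the same staining batch), putting all conditions on
#' a common relative scale.
#'
#' @param values Numeric vector of intensities.
#' @param reference Numeric vector; its median must be positive.
#' @return `values / median(reference)`.
#' @export
normalize_nuclear_intensity <- function(values, reference) {
  if (length(reference) == 0L) stop("reference population is empty")
  m <- stats::median(reference)
  if (!is.finite(m) || m <= 0) stop("reference median must be positive")
  values / m
}
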