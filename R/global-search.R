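#' @include methods.R utils.R tensor-field.R
NULL

#' Neighbor offset sets for the search grid
#'
#' The default 74-direction set comprises all integer offsets in
#' \{-2..2\}^3 minus the origin, minus offsets collinear with a shorter
#' offset, minus the (2, 2, 1) class: 26 + 24 + 24 = 74 unique directions
#' on a cubic grid.  The finer 98-direction set adds the (2, 2, 1) class
#' back, raising the angular resolution.
#'
#' @param set `"74"` or `"98"`.
#' @return integer matrix, one offset per row.
#' @examples
#' nrow(neighborOffsets("74"))
#' @export
neighborOffsets <- function(set = c("74", "98")) {
    set <- match.arg(set)
    u <- -2:2
    off <- as.matrix(expand.grid(i = u, j = u, k = u))
    off <- off[rowSums(abs(off)) > 0L, , drop = FALSE]
    # drop offsets collinear with a shorter one (their direction repeats)
    doubled <- apply(off, 1L, function(o) {
        h <- o / 2
        all(h == round(h)) && any(h != 0)
    })
    off <- off[!doubled, , drop = FALSE]
    if (set == "74") {
        cls221 <- apply(off, 1L, function(o) all(sort(abs(o)) == c(1, 2, 2)))
        off <- off[!cls221, , drop = FALSE]
    }
    dimnames(off) <- NULL
    storage.mode(off) <- "integer"
    off
}

#' Build the structured search grid
#'
#' An axis-aligned lattice covering the bounding box (or the whole field)
#' with spacing chosen so that the mean neighbor step over the offset set
#' equals the configured average step length.  Lattice nodes outside the
#' box or outside the field are never expanded.
#'
#' @param field a [TensorField-class].
#' @param bbox optional 2x3 world-mm box (rows lo, hi).
#' @param params a [GSParams-class].
#' @return a [SearchGrid-class].
#' @export
buildGrid <- function(field, bbox = NULL, params = gsParams()) {
    d <- dim(field)
    corners <- .voxel2world(field@affine, as.matrix(expand.grid(
        i = c(0, d[1] - 1L), j = c(0, d[2] - 1L), k = c(0, d[3] - 1L))))
    fieldBox <- rbind(apply(corners, 2L, min), apply(corners, 2L, max))
    box <- fieldBox
    if (!is.null(bbox)) {
        bbox <- rbind(pmin(bbox[1, ], bbox[2, ]), pmax(bbox[1, ], bbox[2, ]))
        box <- rbind(pmax(fieldBox[1, ], bbox[1, ]),
                     pmin(fieldBox[2, ], bbox[2, ]))
        if (any(box[1, ] >= box[2, ]))
            stop("bounding box does not intersect the field")
    }
    off <- neighborOffsets(params@offsetSet)
    norms <- sqrt(rowSums(off^2))
    spacing <- params@avgStep / mean(norms)
    dims <- pmax(2L, as.integer(floor((box[2, ] - box[1, ]) / spacing)) + 1L)
    new("SearchGrid", origin = box[1, ], spacing = spacing, dims = dims,
        offsets = off, offDirs = off / norms, offLen = norms * spacing,
        bbox = if (is.null(bbox)) NULL else box)
}

#' Directional propagation probability of a tensor
#'
#' The diffusion profile along `v` with the tensor's isotropic fraction
#' subtracted, normalized by the largest eigenvalue:
#' `p(v) = max(0, (v' D v - lambda3) / lambda1)`.  Zero in every direction
#' on an isotropic tensor (no bias towards isotropic tensors), maximal
#' (`1 - lambda3/lambda1`) along the principal direction.
#'
#' @param tensor length-6 tensor (xx, yy, zz, xy, xz, yz).
#' @param v unit direction.
#' @return value >= 0; 0 when the largest eigenvalue is non-positive.
#' @export
propagationProbability <- function(tensor, v) {
    e <- tensorEigen(tensor)
    l1 <- e$values[1]
    l3 <- e$values[3]
    if (l1 <= 0) return(0)
    D <- matrix(c(tensor[1], tensor[4], tensor[5],
                  tensor[4], tensor[2], tensor[6],
                  tensor[5], tensor[6], tensor[3]), 3L, 3L)
    max(0, (drop(t(v) %*% D %*% v) - l3) / l1)
}

#' Divergence factor from the principal diffusion direction
#'
#' For linear tensor shapes the cosine of the angle between `v` and the
#' first eigenvector; for planar and spherical shapes (where the principal
#' direction is ill-defined) the cosine of the angle between `v` and the
#' plane spanned by the first two eigenvectors.
#'
#' @param eig eigen-system as returned by [tensorEigen()].
#' @param shape shape coefficients as returned by [westinShape()].
#' @param v unit direction.
#' @return value in [0, 1].
#' @export
divergenceFactor <- function(eig, shape, v) {
    if (shape$shapeClass == "linear") {
        abs(sum(v * eig$vectors[, 1]))
    } else {
        sqrt(max(0, 1 - sum(v * eig$vectors[, 3])^2))
    }
}

#' Cost of one path segment
#'
#' `cost = length * (1 - p(v) * d(v) * FA)`, clipped to
#' `[epsilon * length, length]`: near the floor only when propagation
#' probability, direction agreement and anisotropy are all maximal, the
#' full length on isotropic tensors, and monotone non-increasing in each
#' affinity term.  Segments whose tensor FA falls below the threshold are
#' forbidden (infinite cost).
#'
#' @param tensor length-6 tensor at the segment midpoint.
#' @param v unit segment direction.
#' @param length segment length, mm.
#' @param params a [GSParams-class] (FA threshold and epsilon floor).
#' @return segment cost, or `Inf` for a forbidden segment.
#' @examples
#' iso <- c(1, 1, 1, 0, 0, 0) * 1e-3
#' stepCost(iso, c(1, 0, 0), 2, gsParams(faThreshold = 0))   # = length
#' @export
stepCost <- function(tensor, v, length, params = gsParams()) {
    cpp_step_cost(tensor, v, length, params@faThreshold, params@epsilon)
}

# one start node per mask voxel: the lattice node nearest to each voxel
# center.  Anchoring starts at voxels (and qualifying them on the FA at the
# voxel center) keeps the emitted tract independent of the lattice density.
.start_nodes <- function(grid, mask, affine) {
    vox <- which(mask, arr.ind = TRUE) - 1L
    ctr <- .voxel2world(affine, vox)
    nodes <- round(t((t(ctr) - grid@origin) / grid@spacing))
    nodes <- pmin(pmax(nodes, 0L), matrix(rep(grid@dims - 1L, each = nrow(nodes)),
                                          ncol = 3L))
    keep <- !duplicated(nodes)
    list(nodes = nodes[keep, , drop = FALSE],
         centers = ctr[keep, , drop = FALSE])
}

# grid nodes (0-based index rows) whose world position lies in a mask voxel
.grid_nodes_in_mask <- function(grid, mask, affine) {
    dims <- grid@dims
    idx <- as.matrix(expand.grid(i = 0:(dims[1] - 1L), j = 0:(dims[2] - 1L),
                                 k = 0:(dims[3] - 1L)))
    pts <- t(t(idx * grid@spacing) + grid@origin)
    idx[.points_in_mask(pts, mask, affine), , drop = FALSE]
}

.node_world <- function(grid, nodes) {
    t(t(nodes * grid@spacing) + grid@origin)
}

# logical vector over all grid nodes: expandable (inside field domain)
.grid_expandable <- function(grid, field) {
    dims <- grid@dims
    idx <- as.matrix(expand.grid(i = 0:(dims[1] - 1L), j = 0:(dims[2] - 1L),
                                 k = 0:(dims[3] - 1L)))
    pts <- .node_world(grid, idx)
    v <- .world2voxel(field@affine, pts)
    fd <- dim(field)
    v[, 1] >= 0 & v[, 1] <= fd[1] - 1L &
    v[, 2] >= 0 & v[, 2] <= fd[2] - 1L &
    v[, 3] >= 0 & v[, 3] <= fd[3] - 1L
}

# goal membership per grid node
.grid_goal <- function(grid, mask, affine) {
    dims <- grid@dims
    idx <- as.matrix(expand.grid(i = 0:(dims[1] - 1L), j = 0:(dims[2] - 1L),
                                 k = 0:(dims[3] - 1L)))
    .points_in_mask(.node_world(grid, idx), mask, affine)
}

#' A* minimum-cost path search between two ROIs
#'
#' Expands a search tree over (node, arrival-offset) states so the
#' bending-angle constraint between adjacent segments is exact; edges
#' whose midpoint FA falls below the threshold are never expanded.  The
#' admissible, consistent heuristic is `epsilon` times the Euclidean
#' distance to the nearest goal node, so the returned path cost is the
#' true minimum over all feasible paths.  Priority ties break in
#' insertion order, making runs deterministic.
#'
#' @param grid a [SearchGrid-class].
#' @param field a [TensorField-class].
#' @param roiA,roiB logical voxel masks; the search starts at a node
#'   inside `roiA` and stops at any node inside `roiB`.
#' @param params a [GSParams-class].
#' @param start optional 0-based grid node (length-3 integer) overriding
#'   the default start (first qualifying `roiA` node).
#' @return a [Fiber-class] on success, otherwise a list with
#'   `found = FALSE`.
#' @export
astarSearch <- function(grid, field, roiA, roiB, params = gsParams(),
                        start = NULL) {
    if (is.null(start)) {
        cand <- .grid_nodes_in_mask(grid, roiA, field@affine)
        if (nrow(cand) == 0L)
            stop("roi_a contains no grid node")
        fa <- interpolateFA(field, .node_world(grid, cand))
        cand <- cand[!is.na(fa) & fa >= params@faThreshold, , drop = FALSE]
        if (nrow(cand) == 0L)
            return(list(found = FALSE, reason = "no start node above FA threshold"))
        start <- cand[1L, ]
    }
    goal <- .grid_goal(grid, roiB, field@affine)
    if (!any(goal))
        stop("roi_b contains no grid node")
    goalIdx <- which(goal) - 1L
    goalNodes <- cbind(goalIdx %% grid@dims[1],
                       (goalIdx %/% grid@dims[1]) %% grid@dims[2],
                       goalIdx %/% (grid@dims[1] * grid@dims[2]))
    r <- cpp_astar(field@tensors, dim(field), solve(field@affine),
                   grid@origin, grid@spacing, grid@dims,
                   grid@offsets, grid@offDirs, grid@offLen,
                   as.integer(start), goal, .node_world(grid, goalNodes),
                   .grid_expandable(grid, field),
                   params@faThreshold, cos(params@bendingAngle * pi / 180),
                   params@epsilon, params@maxExpansions)
    if (!isTRUE(r$found))
        return(list(found = FALSE, expansions = r$expansions))
    if (nrow(r$points) < 2L)       # start already inside roi_b
        return(list(found = TRUE, points = r$points, cost = r$cost,
                    degenerate = TRUE))
    fiber(r$points, provenance = list(method = "gs", start = start,
                                      cost = r$cost,
                                      faThreshold = params@faThreshold))
}

#' Global-search pathway reconstruction between two ROIs
#'
#' Finds, for every qualifying start node in `roiA` (one lattice node per
#' ROI voxel, snapped to the voxel center, with FA at or above the
#' threshold), the minimum-cost feasible path to `roiB` — the same path a
#' per-start [astarSearch()] returns.  Anchoring the start set at ROI
#' voxels keeps the emitted tract independent of the lattice density.  Since
#' all start nodes share one goal set and one edge cost model, the
#' per-start searches are computed in a single multi-goal sweep over the
#' (node, arrival-offset) state space.  Identical node paths are
#' deduplicated; on global failure the search is retried once with the
#' fallback FA threshold.  All returned fibers start in `roiA` and end in
#' `roiB`; ROI padding is never applied here.
#'
#' @param field a [TensorField-class].
#' @param roiA,roiB logical voxel masks.
#' @param bbox optional 2x3 world-mm search bounding box.
#' @param params a [GSParams-class].
#' @return a [FiberTract-class]; empty (with `provenance$failed = TRUE`)
#'   when both thresholds fail.
#' @export
reconstructPathway <- function(field, roiA, roiB, bbox = NULL,
                               params = gsParams()) {
    grid <- buildGrid(field, bbox, params)
    goal <- .grid_goal(grid, roiB, field@affine)
    if (!any(goal)) stop("roi_b contains no grid node")
    expandable <- .grid_expandable(grid, field)
    run_at <- function(thr) {
        st <- .start_nodes(grid, roiA, field@affine)
        if (nrow(st$nodes) == 0L) return(list())
        fa <- interpolateFA(field, st$centers)
        cand <- st$nodes[!is.na(fa) & fa >= thr, , drop = FALSE]
        if (nrow(cand) == 0L) return(list())
        res <- cpp_gs_reverse(field@tensors, dim(field), solve(field@affine),
                              grid@origin, grid@spacing, grid@dims,
                              grid@offsets, grid@offDirs, grid@offLen,
                              cand, goal, expandable, thr,
                              cos(params@bendingAngle * pi / 180),
                              params@epsilon, params@maxExpansions * 100)
        out <- list()
        for (i in seq_along(res)) {
            r <- res[[i]]
            if (!isTRUE(r$found) || is.null(r$points) || nrow(r$points) < 2L)
                next
            out[[length(out) + 1L]] <- fiber(
                r$points,
                provenance = list(method = "gs", start = cand[i, ],
                                  cost = r$cost, faThreshold = thr))
        }
        out
    }
    fibs <- run_at(params@faThreshold)
    usedThr <- params@faThreshold
    if (length(fibs) == 0L && params@faFallback < params@faThreshold) {
        fibs <- run_at(params@faFallback)
        usedThr <- params@faFallback
    }
    # deduplicate identical node paths
    if (length(fibs) > 1L) {
        key <- vapply(fibs, function(f)
            paste(signif(t(f@points), 10), collapse = ","), character(1))
        fibs <- fibs[!duplicated(key)]
    }
    prov <- list(method = "gs", faThreshold = usedThr,
                 offsetSet = params@offsetSet, avgStep = params@avgStep,
                 bendingAngle = params@bendingAngle,
                 failed = length(fibs) == 0L)
    fiberTract(fibs, provenance = prov)
}
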