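# SWC morphology: parsing, validation, and the somato-dendritic morphometrics
# (lengths, branching counts, areas, Sholl profile, branch-order diameters).
#
# Conventions (the source tooling leaves them unstated, so they are documented
# package choices): soma area is the projected disc pi * r^2 with r the
# largest soma-node radius; total surface is the soma sphere 4 pi r^2 plus the
# lateral frustum areas of the dendritic segments (a config switch reduces it
# to the sphere alone); axon nodes (SWC type 2) are ignored by all metrics.

#' Construct a morphology from an SWC node table
#'
#' @param nodes data.frame with columns \code{id, type, x, y, z, radius,
#'   parent} (standard 7-column SWC).
#' @param cell_id,group optional labels.
#' @return object of class \code{morphology}.
#' @export
new_morphology <- function(nodes, cell_id = NA_character_,
                           group = NA_character_) {
  need <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(need %in% names(nodes)))
    stopf("nodes must have columns %s", paste(need, collapse = ", "))
  m <- structure(list(nodes = nodes[, need], cell_id = cell_id, group = group),
                 class = "morphology")
  validate_morphology(m)
}

#' Validate a morphology tree
#'
#' Checks the SWC invariants: unique ids, exactly one root (parent -1),
#' parents defined and preceding their children (hence no cycles), positive
#' radii, finite coordinates, soma nodes contiguous at the root.  Violations
#' are reported with the offending node lines.  Nodes with more than two
#' children are permitted but flagged via the \code{"trifurcations"}
#' attribute (each such node counts as multiple bifurcations in the Euler
#' identity).
#'
#' @param m a \code{morphology}.
#' @return \code{m}, invisibly, on success.
#' @export
validate_morphology <- function(m) {
  nd <- m$nodes
  if (anyDuplicated(nd$id))
    stopf("duplicated node ids at lines: %s",
          paste(which(duplicated(nd$id)), collapse = ", "))
  roots <- which(nd$parent == -1)
  if (length(roots) != 1L)
    stopf("expected exactly one root (parent -1), found %d", length(roots))
  if (roots != 1L) stopf("root must be the first node")
  idx <- match(nd$parent, nd$id)
  bad <- which(nd$parent != -1 & is.na(idx))
  if (length(bad))
    stopf("undefined parent ids at lines: %s", paste(bad, collapse = ", "))
  fwd <- which(nd$parent != -1 & idx >= seq_len(nrow(nd)))
  if (length(fwd))
    stopf("parent does not precede child at lines: %s (cycles are impossible only in topological order)",
          paste(fwd, collapse = ", "))
  if (any(nd$radius <= 0))
    stopf("non-positive radius at lines: %s",
          paste(which(nd$radius <= 0), collapse = ", "))
  if (!all(is.finite(as.matrix(nd[, c("x", "y", "z")]))))
    stopf("non-finite coordinates")
  soma <- which(nd$type == 1)
  if (length(soma) && any(diff(soma) != 1L))
    warnf("soma nodes are not contiguous at the root")
  nch <- tabulate(idx[!is.na(idx)], nbins = nrow(nd))
  tri <- which(nch > 2 & nd$type == 3)
  attr(m, "trifurcations") <- tri
  invisible(m)
}

#' @export
print.morphology <- function(x, ...) {
  nd <- x$nodes
  cat(sprintf("<morphology> %s: %d nodes (%d soma, %d dendrite)\n",
              x$cell_id %||% "?", nrow(nd), sum(nd$type == 1),
              sum(nd$type == 3)))
  invisible(x)
}

#' Read / write standard SWC files
#'
#' Seven whitespace-separated columns (\code{id type x y z radius parent}),
#' \code{#} comments.  \code{write_swc} followed by \code{read_swc} is the
#' identity up to whitespace.
#'
#' @param path file path.
#' @param m a \code{morphology}.
#' @param cell_id,group labels attached to the parsed object.
#' @return \code{read_swc}: a validated \code{morphology}.
#' @export
read_swc <- function(path, cell_id = NA_character_, group = NA_character_) {
  nd <- tryCatch(
    utils::read.table(path, comment.char = "#",
                      col.names = c("id", "type", "x", "y", "z", "radius",
                                    "parent")),
    error = function(e) stopf("cannot parse SWC file '%s': %s", path,
                              conditionMessage(e)))
  new_morphology(nd, cell_id = cell_id, group = group)
}

#' @rdname read_swc
#' @export
write_swc <- function(m, path) {
  stopifnot(inherits(m, "morphology"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# id type x y z radius parent", con)
  nd <- m$nodes
  writeLines(sprintf("%d %d %.9g %.9g %.9g %.9g %d", nd$id, nd$type, nd$x,
                     nd$y, nd$z, nd$radius, nd$parent), con)
  invisible(path)
}

# ---- internal geometry helpers ----------------------------------------------

# dendritic segments: one row per node of type 3 with a defined parent;
# includes the soma->stem segment (its length is part of the dendritic length)
dendrite_segments <- function(m) {
  nd <- m$nodes
  pidx <- match(nd$parent, nd$id)
  child <- which(nd$type == 3 & nd$parent != -1)
  p <- pidx[child]
  data.frame(
    child = child, parent = p,
    x0 = nd$x[p], y0 = nd$y[p], z0 = nd$z[p],
    x1 = nd$x[child], y1 = nd$y[child], z1 = nd$z[child],
    r0 = nd$radius[p], r1 = nd$radius[child],
    len = sqrt((nd$x[child] - nd$x[p])^2 + (nd$y[child] - nd$y[p])^2 +
                 (nd$z[child] - nd$z[p])^2)
  )
}

n_children <- function(m) {
  nd <- m$nodes
  pidx <- match(nd$parent, nd$id)
  dend <- which(nd$type == 3)
  tabulate(pidx[dend][!is.na(pidx[dend])], nbins = nrow(nd))
}

#' Scalar morphometrics of a reconstruction
#'
#' Computes the somato-dendritic quantities compared across GPe groups:
#' total dendritic length (sum of parent-child Euclidean segment lengths over
#' dendrite nodes), mean dendrite length per primary subtree, bifurcation and
#' termination counts, number of primary dendrites (dendritic children of the
#' soma), soma area (projected disc), and total surface area (soma sphere
#' plus dendritic frustum lateral areas).
#'
#' @param m a \code{morphology}.
#' @param soma_surface \code{"sphere"} (default, 4 pi r^2 in the total
#'   surface) or \code{"disc"} (pi r^2).
#' @return named list of metrics; zeros with attribute \code{flag =
#'   "no_dendrites"} when the tree has no dendrite nodes.
#' @export
morpho_metrics <- function(m, soma_surface = c("sphere", "disc")) {
  soma_surface <- match.arg(soma_surface)
  nd <- m$nodes
  r_s <- max(nd$radius[nd$type == 1])
  soma_area <- pi * r_s^2
  soma_surf <- if (soma_surface == "sphere") 4 * pi * r_s^2 else pi * r_s^2
  seg <- dendrite_segments(m)
  if (nrow(seg) == 0) {
    out <- list(total_dendritic_length = 0, mean_dendrite_length = 0,
                bifurcation_count = 0L, termination_count = 0L,
                primary_dendrite_count = 0L, soma_area = soma_area,
                total_surface_area = soma_surf)
    attr(out, "flag") <- "no_dendrites"
    return(out)
  }
  nch <- n_children(m)
  dend <- which(nd$type == 3)
  primary <- sum(nd$type[seg$parent] == 1)
  bif <- sum(pmax(0L, nch[dend] - 1L))
  term <- sum(nch[dend] == 0L)
  lateral <- sum(pi * (seg$r0 + seg$r1) *
                   sqrt(seg$len^2 + (seg$r0 - seg$r1)^2))
  total_len <- sum(seg$len)
  list(total_dendritic_length = total_len,
       mean_dendrite_length = total_len / primary,
       bifurcation_count = as.integer(bif),
       termination_count = as.integer(term),
       primary_dendrite_count = as.integer(primary),
       soma_area = soma_area,
       total_surface_area = soma_surf + lateral)
}

#' Sholl profile
#'
#' Counts dendritic segment crossings of concentric spheres centred at the
#' radius-weighted soma centroid, at radii \code{step, 2 step, ...}.  A point
#' at distance exactly r is resolved to the outer side, so a dendrite ending
#' exactly on a sphere still counts as crossing it; a segment dipping through
#' a sphere and back counts twice (the squared distance along a straight
#' segment is a convex quadratic, so each segment crosses a given sphere at
#' most twice).
#'
#' @param m a \code{morphology}.
#' @param step sphere spacing in um (> 0).
#' @return data.frame with columns \code{radius}, \code{intersections}.
#' @export
sholl <- function(m, step = 10) {
  if (step <= 0) stopf("step must be > 0")
  nd <- m$nodes
  soma <- nd[nd$type == 1, ]
  w <- soma$radius / sum(soma$radius)
  ctr <- c(sum(soma$x * w), sum(soma$y * w), sum(soma$z * w))
  seg <- dendrite_segments(m)
  if (nrow(seg) == 0)
    return(data.frame(radius = step, intersections = 0L))
  ax <- seg$x0 - ctr[1]; ay <- seg$y0 - ctr[2]; az <- seg$z0 - ctr[3]
  dx <- seg$x1 - seg$x0; dy <- seg$y1 - seg$y0; dz <- seg$z1 - seg$z0
  # squared distance along segment: q(t) = qa t^2 + qb t + qc, t in [0, 1]
  qa <- dx^2 + dy^2 + dz^2
  qb <- 2 * (ax * dx + ay * dy + az * dz)
  qc <- ax^2 + ay^2 + az^2
  d0 <- qc
  d1 <- qa + qb + qc
  tv <- ifelse(qa > 0, pmin(pmax(-qb / (2 * qa), 0), 1), 0)
  dv <- qa * tv^2 + qb * tv + qc
  maxd <- sqrt(max(d0, d1))
  radii <- seq(step, ceiling(maxd / step) * step, by = step)
  cross <- vapply(radii, function(r) {
    r2 <- r^2
    inside0 <- d0 < r2; insidev <- dv < r2; inside1 <- d1 < r2
    sum((inside0 != insidev) + (insidev != inside1))
  }, numeric(1))
  data.frame(radius = radii, intersections = as.integer(cross))
}

#' Branch-order diameters
#'
#' Assigns a centrifugal branch order to every dendritic segment (order 1
#' from the soma to the first bifurcation, incrementing at each bifurcation)
#' and returns the length-weighted mean diameter (2 x child-node radius) for
#' the order classes 1, 2 and > 2, plus the per-segment diameter versus
#' path-distance series.
#'
#' @param m a \code{morphology}.
#' @return list with \code{order_diameters} (named numeric, NA for an empty
#'   class, with attribute \code{empty_classes}) and \code{profile}
#'   (data.frame \code{path_dist}, \code{diameter}, \code{order}).
#' @export
branch_order_diameters <- function(m) {
  nd <- m$nodes
  seg <- dendrite_segments(m)
  if (nrow(seg) == 0)
    return(list(order_diameters = c(order1 = NA_real_, order2 = NA_real_,
                                    order_gt2 = NA_real_),
                profile = data.frame(path_dist = numeric(0),
                                     diameter = numeric(0),
                                     order = integer(0))))
  nch <- n_children(m)
  ord <- integer(nrow(nd))
  path <- numeric(nrow(nd))
  # nodes are in topological order, so one forward pass suffices
  for (k in seq_len(nrow(seg))) {
    ch <- seg$child[k]; p <- seg$parent[k]
    if (nd$type[p] == 1) {
      ord[ch] <- 1L
      path[ch] <- seg$len[k]
    } else {
      ord[ch] <- ord[p] + if (nch[p] >= 2L) 1L else 0L
      path[ch] <- path[p] + seg$len[k]
    }
  }
  seg$order <- ord[seg$child]
  seg$diam <- 2 * seg$r1
  cls <- cut(seg$order, c(0, 1, 2, Inf), labels = c("order1", "order2",
                                                    "order_gt2"))
  wmean <- function(i) if (!any(i)) NA_real_ else
    sum(seg$diam[i] * seg$len[i]) / sum(seg$len[i])
  od <- c(order1 = wmean(cls == "order1"),
          order2 = wmean(cls == "order2"),
          order_gt2 = wmean(cls == "order_gt2"))
  attr(od, "empty_classes") <- names(od)[is.na(od)]
  list(order_diameters = od,
       profile = data.frame(path_dist = path[seg$child],
                            diameter = seg$diam, order = seg$order))
}
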