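# Synthetic dendritic trees: a stochastic binary branching process with
# radially biased growth and linear radius taper, emitted as standard SWC.
# Each branch section grows outward in ~10 um pieces, then either bifurcates
# (with the cell's bifurcation probability, up to 6 branch orders) or
# terminates, which reproduces the branching statistics the morphometry
# module quantifies (Euler identity, Sholl profiles, order-wise taper).

#' Generate a synthetic SWC reconstruction for a cell
#'
#' Builds one soma node (type 1, radius \code{soma_radius}) with
#' \code{n_primary} dendritic stems.  Section lengths are log-normal around
#' \code{mean_segment_len}; at the end of each section the branch bifurcates
#' with probability \code{bifurcation_prob} while its order is below 6,
#' otherwise it terminates.  Radii taper linearly with path length
#' (\code{taper} um of radius per um of path, floored at 0.1 um) from
#' \code{base_diameter / 2}.  Growth direction performs a radially biased
#' random walk so path distance from the soma increases nearly monotonically.
#'
#' @param params a \code{cell_params} (its \code{soma_radius} and
#'   \code{dendrite_geometry} are used).
#' @param rng_seed optional seed.
#' @param max_order maximum branch order (default 6).
#' @return a validated \code{morphology}.
#' @export
generate_swc <- function(params, rng_seed = NULL, max_order = 6L) {
  stopifnot(inherits(params, "cell_params"))
  g <- params$dendrite_geometry
  with_seed(rng_seed, {
    rows <- list(data.frame(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                            radius = params$soma_radius, parent = -1L))
    next_id <- 2L
    base_r <- g$base_diameter / 2
    piece <- 10

    grow <- function(parent_id, pos, dir, order, path_len) {
      sec_len <- stats::rlnorm(1, log(g$mean_segment_len) - 0.02, 0.2)
      n_sub <- max(1L, round(sec_len / piece))
      sub_len <- sec_len / n_sub
      radial <- unit_vector(pos)
      for (i in seq_len(n_sub)) {
        dir <- unit_vector(dir + 0.15 * stats::rnorm(3) + 0.10 * radial)
        pos <- pos + dir * sub_len
        path_len <- path_len + sub_len
        r <- max(0.1, base_r - g$taper * path_len)
        id <- next_id
        rows[[length(rows) + 1L]] <<- data.frame(
          id = id, type = 3L, x = pos[1], y = pos[2], z = pos[3],
          radius = r, parent = parent_id)
        next_id <<- next_id + 1L
        parent_id <- id
        radial <- unit_vector(pos)
      }
      if (order < max_order && stats::runif(1) < g$bifurcation_prob) {
        perp <- unit_vector(perp_vector(dir))
        ang <- 0.6  # ~35 degree half-angle between daughters
        d1 <- unit_vector(dir * cos(ang) + perp * sin(ang))
        d2 <- unit_vector(dir * cos(ang) - perp * sin(ang))
        grow(parent_id, pos, d1, order + 1L, path_len)
        grow(parent_id, pos, d2, order + 1L, path_len)
      }
      invisible(NULL)
    }

    for (s in seq_len(g$n_primary)) {
      dir <- unit_vector(stats::rnorm(3))
      start <- dir * params$soma_radius
      grow(1L, start, dir, 1L, 0)
    }
    nodes <- do.call(rbind, rows)
    new_morphology(nodes, cell_id = attr(params, "cell_id") %||% NA_character_,
                   group = params$group)
  })
}

# a random unit vector perpendicular to v
perp_vector <- function(v) {
  w <- stats::rnorm(3)
  w <- w - sum(w * v) * v
  if (sqrt(sum(w^2)) < 1e-8) w <- c(-v[2], v[1], 0)
  w
}

#' Expected bifurcation count of the branching process
#'
#' Closed-form expectation of the number of bifurcations per tree for the
#' generator's truncated binary branching process: a branch of order k
#' bifurcates with probability p while k < max_order, so
#' \eqn{b_k = p (1 + 2 b_{k+1})}, \eqn{b_{max} = 0}, and the tree expectation
#' is \code{n_primary * b_1}.
#'
#' @param p bifurcation probability.
#' @param n_primary number of stems.
#' @param max_order maximum branch order.
#' @return expected bifurcation count.
#' @export
expected_bifurcations <- function(p, n_primary, max_order = 6L) {
  b <- 0
  for (k in seq(max_order - 1L, 1L)) b <- p * (1 + 2 * b)
  n_primary * b
}
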