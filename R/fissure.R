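#' Weights of the heuristic fissure-search cost
#'
#' The per-step cost of the fissure search is a weighted sum of four terms:
#' turning angle against the previous step (`lambda_a`), angle against the
#' direction toward the leg's goal vertex (`lambda_b`), normalized distance
#' back to the leg's start (`lambda_c`), and normalized curvature difference
#' across the step (`lambda_d`). The defaults follow the values established
#' for molar fissure tracing.
#'
#' @param lambda_a,lambda_b,lambda_c,lambda_d non-negative weights.
#' @return An object of class `heuristic_weights`.
#' @export
heuristic_weights <- function(lambda_a = 0.75, lambda_b = 0.85,
                              lambda_c = 0.85, lambda_d = 0.55) {
  w <- c(lambda_a = lambda_a, lambda_b = lambda_b,
         lambda_c = lambda_c, lambda_d = lambda_d)
  if (any(!is.finite(w)) || any(w < 0)) stop("weights must be finite and >= 0")
  structure(as.list(w), class = "heuristic_weights")
}

#' Search state of the fissure path search
#'
#' @param current current vertex index.
#' @param start,goal endpoints of the current search leg.
#' @param previous vertex visited before `current`, or `NA` at the start
#'   (the turning-angle term is then zero).
#' @param cost accumulated path cost up to `current`.
#' @return An object of class `search_state`.
#' @export
search_state <- function(current, start, goal, previous = NA_integer_,
                         cost = 0) {
  structure(list(current = as.integer(current), previous = as.integer(previous),
                 start = as.integer(start), goal = as.integer(goal),
                 cost = cost),
            class = "search_state")
}

# scale factors that make the four cost terms commensurate:
# angles are already in [0, pi]; distances are divided by the bounding-box
# diagonal; curvature differences by the 95th percentile of |dk| over edges.
fissure_normalizers <- function(mesh, curvature) {
  e <- mesh_edges(mesh)
  dk <- abs(curvature[e[, 1]] - curvature[e[, 2]])
  q <- stats::quantile(dk, 0.95, names = FALSE)
  list(diag = bbox_diagonal(mesh), kappa_scale = if (q > 0) q else 1)
}

unit_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  m / pmax(n, 1e-30)
}

# vectorized step cost from (previous -> current) to each candidate.
# `previous` may be NA (first step). Returns the per-candidate cost.
step_cost_impl <- function(v, curvature, weights, norms,
                           previous, current, candidates, start, goal) {
  cur <- v[current, ]
  cand <- v[candidates, , drop = FALSE]
  dir_new <- unit_rows(cand - matrix(cur, nrow(cand), 3, byrow = TRUE))
  # turning angle w.r.t. the previous step
  if (is.na(previous)) {
    f1 <- numeric(nrow(cand))
  } else {
    dp <- unit_rows(matrix(cur - v[previous, ], 1))[1, ]
    d1 <- rowSums(dir_new * matrix(dp, nrow(cand), 3, byrow = TRUE))
    f1 <- acos(pmin(pmax(d1, -1), 1))
  }
  # angle between the step and the pull toward the goal
  to_goal <- matrix(v[goal, ], nrow(cand), 3, byrow = TRUE) - cand
  gl <- sqrt(rowSums(to_goal^2))
  f2 <- ifelse(gl < 1e-30, 0,
               acos(pmin(pmax(rowSums(dir_new * to_goal) / pmax(gl, 1e-30), -1), 1)))
  # normalized distance back to the leg start
  f3 <- sqrt(rowSums((cand - matrix(v[start, ], nrow(cand), 3, byrow = TRUE))^2)) /
    norms$diag
  # normalized curvature jump across the step
  f4 <- abs(curvature[candidates] - curvature[current]) / norms$kappa_scale
  weights$lambda_a * f1 + weights$lambda_b * f2 +
    weights$lambda_c * f3 + weights$lambda_d * f4
}

#' Per-step cost of the heuristic fissure search
#'
#' Evaluates the weighted four-term cost of stepping from `state$current` to
#' an adjacent `candidate` vertex: turning angle, goal-direction angle,
#' normalized distance to the leg start, and normalized curvature difference.
#'
#' @param state a [search_state].
#' @param candidate vertex index adjacent to `state$current`.
#' @param mesh a [triangle_mesh].
#' @param curvature per-vertex curvature, e.g. from [vertex_curvature()].
#' @param weights a [heuristic_weights].
#' @return Single non-negative cost (dimensionless).
#' @export
step_cost <- function(state, candidate, mesh, curvature,
                      weights = heuristic_weights()) {
  stopifnot(inherits(state, "search_state"))
  adj <- mesh_adjacency(mesh)
  if (!(candidate %in% adj[[state$current]])) {
    stop("candidate vertex ", candidate, " is not adjacent to vertex ",
         state$current)
  }
  norms <- fissure_normalizers(mesh, curvature)
  step_cost_impl(mesh$vertices, curvature, weights, norms,
                 state$previous, state$current, candidate,
                 state$start, state$goal)[1]
}

#' Minimum-cost path between two mesh vertices
#'
#' Uniform-cost (Dijkstra) search over directed states `(previous, current)`,
#' needed because the turning-angle term couples consecutive steps. Ties on
#' accumulated cost are broken toward the lowest candidate vertex index, so
#' results are reproducible.
#'
#' @inheritParams step_cost
#' @param start,goal distinct vertex indices.
#' @return An open [feature_curve()] with the vertex sequence and total cost.
#' @export
min_cost_path <- function(mesh, start, goal, weights = heuristic_weights(),
                          curvature = vertex_curvature(mesh)) {
  if (start == goal) stop("start and goal must differ")
  nv <- nrow(mesh$vertices)
  if (start < 1 || start > nv || goal < 1 || goal > nv) {
    stop("start/goal vertex index out of range")
  }
  adj <- mesh_adjacency(mesh)
  norms <- fissure_normalizers(mesh, curvature)
  res <- dijkstra_states(mesh$vertices, adj, curvature, weights, norms,
                         start, goal)
  if (is.null(res)) {
    stop("no path between vertices ", start, " and ", goal)
  }
  feature_curve(res$path, closed = FALSE, total_cost = res$cost)
}

# Dijkstra over states (previous -> current). State 1 is the virtual start
# (no incoming direction); states 2..(1+nE2) are directed edges.
dijkstra_states <- function(v, adj, curvature, weights, norms, start, goal) {
  deg <- lengths(adj)
  heads <- rep.int(seq_along(adj), deg)     # directed edge a -> b
  tails <- unlist(adj, use.names = FALSE)
  ne <- length(heads)
  if (ne == 0) return(NULL)
  # id of directed edge (a -> b): lookup via ordering by (a, b)
  first_out <- c(1L, cumsum(deg) + 1L)      # adj is sorted per vertex
  edge_id <- function(a, b) {
    # adj[[a]] is sorted; position by binary-free match (small degree)
    first_out[a] + match(b, adj[[a]]) - 1L
  }
  n_states <- ne + 1L
  dist <- rep(Inf, n_states)
  parent <- integer(n_states)
  done <- logical(n_states)

  # binary heap keyed by (cost, tie = current vertex index)
  h_key <- numeric(256); h_tie <- numeric(256); h_id <- integer(256)
  h_n <- 0L
  less <- function(i, j) {
    h_key[i] < h_key[j] || (h_key[i] == h_key[j] && h_tie[i] < h_tie[j])
  }
  push <- function(key, tie, id) {
    h_n <<- h_n + 1L
    if (h_n > length(h_key)) {
      h_key <<- c(h_key, numeric(length(h_key)))
      h_tie <<- c(h_tie, numeric(length(h_tie)))
      h_id <<- c(h_id, integer(length(h_id)))
    }
    h_key[h_n] <<- key; h_tie[h_n] <<- tie; h_id[h_n] <<- id
    i <- h_n
    while (i > 1L) {
      p <- i %/% 2L
      if (less(i, p)) {
        tmp <- h_key[i]; h_key[i] <<- h_key[p]; h_key[p] <<- tmp
        tmp <- h_tie[i]; h_tie[i] <<- h_tie[p]; h_tie[p] <<- tmp
        tmpi <- h_id[i]; h_id[i] <<- h_id[p]; h_id[p] <<- tmpi
        i <- p
      } else break
    }
  }
  state_cur <- c(start, tails)             # current vertex of each state
  state_prev <- c(NA_integer_, heads)      # previous vertex (NA for start)

  dist[1L] <- 0
  push(0, start, 1L)
  result <- NULL
  while (h_n > 0L) {
    top_id <- h_id[1L]; top_key <- h_key[1L]
    # remove root and restore the heap
    h_key[1L] <- h_key[h_n]; h_tie[1L] <- h_tie[h_n]; h_id[1L] <- h_id[h_n]
    h_n <- h_n - 1L
    i <- 1L
    while (TRUE) {
      l <- 2L * i; r <- l + 1L
      if (l > h_n) break
      m <- if (r <= h_n && less(r, l)) r else l
      if (less(m, i)) {
        tmp <- h_key[i]; h_key[i] <- h_key[m]; h_key[m] <- tmp
        tmp <- h_tie[i]; h_tie[i] <- h_tie[m]; h_tie[m] <- tmp
        tmpi <- h_id[i]; h_id[i] <- h_id[m]; h_id[m] <- tmpi
        i <- m
      } else break
    }
    if (done[top_id]) next
    done[top_id] <- TRUE
    cur <- state_cur[top_id]
    if (cur == goal) {
      result <- top_id
      break
    }
    prev <- state_prev[top_id]
    cands <- adj[[cur]]
    if (length(cands) == 0) next
    costs <- step_cost_impl(v, curvature, weights, norms,
                            prev, cur, cands, start, goal)
    for (k in seq_along(cands)) {
      sid <- edge_id(cur, cands[k]) + 1L
      g <- dist[top_id] + costs[k]
      if (g < dist[sid]) {
        dist[sid] <- g
        parent[sid] <- top_id
        push(g, cands[k], sid)
      }
    }
  }
  if (is.null(result)) return(NULL)
  # reconstruct the vertex path
  path <- integer(0)
  s <- result
  while (s != 1L) {
    path <- c(state_cur[s], path)
    s <- parent[s]
  }
  path <- c(start, path)
  list(path = path, cost = dist[result])
}

#' Ordered feature curve on a mesh
#'
#' @param vertex_indices ordered vertex indices; consecutive entries share a
#'   mesh edge. For a closed curve, first equals last.
#' @param closed logical closure flag.
#' @param total_cost accumulated search cost of the curve.
#' @return An object of class `feature_curve`.
#' @export
feature_curve <- function(vertex_indices, closed = FALSE, total_cost = NA_real_) {
  vertex_indices <- as.integer(vertex_indices)
  if (closed && vertex_indices[1] != vertex_indices[length(vertex_indices)]) {
    stop("closed curve must end where it starts")
  }
  structure(list(vertex_indices = vertex_indices, closed = closed,
                 total_cost = total_cost),
            class = "feature_curve")
}

#' @export
print.feature_curve <- function(x, ...) {
  cat(sprintf("<feature_curve: %d vertices, %s, cost %.4f>\n",
              length(x$vertex_indices),
              if (x$closed) "closed" else "open", x$total_cost))
  invisible(x)
}

#' Extract a closed pit-and-fissure loop through seed vertices
#'
#' Chains [min_cost_path()] legs between consecutive seed vertices and from
#' the last seed back to the first, removing duplicated junction vertices.
#' The goal-direction and distance-to-start terms of the cost pull each leg
#' toward its endpoints, which keeps the concatenated curve closed and close
#' to the fissure valley.
#'
#' @inheritParams min_cost_path
#' @param seed_vertices at least 3 distinct vertex indices on the mesh,
#'   ordered around the fissure.
#' @return A closed [feature_curve()].
#' @export
extract_fissure_loop <- function(mesh, seed_vertices,
                                 weights = heuristic_weights(),
                                 curvature = vertex_curvature(mesh)) {
  seeds <- as.integer(seed_vertices)
  if (length(seeds) < 3) stop("need at least 3 seed vertices")
  if (anyDuplicated(seeds)) stop("seed vertices must be distinct")
  loop <- integer(0)
  total <- 0
  pairs <- cbind(seeds, c(seeds[-1], seeds[1]))
  for (i in seq_len(nrow(pairs))) {
    leg <- tryCatch(
      min_cost_path(mesh, pairs[i, 1], pairs[i, 2], weights, curvature),
      error = function(e) {
        stop("leg ", i, " (", pairs[i, 1], " -> ", pairs[i, 2], ") failed: ",
             conditionMessage(e))
      }
    )
    seqv <- leg$vertex_indices
    if (i > 1) seqv <- seqv[-1]            # drop duplicated junction
    loop <- c(loop, seqv)
    total <- total + leg$total_cost
  }
  feature_curve(loop, closed = TRUE, total_cost = total)
}
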