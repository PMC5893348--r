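#' Earth Mover's Distance between two histograms, closed form
#'
#' For two equal-mass 1-D histograms on the same bins with unit cost |i - j|
#' per moved unit, the minimum transport cost equals the L1 distance between
#' the cumulative mass functions; the EMD is that cost normalized by the total
#' mass. This is the production path: O(n) and exactly equal to the linear
#' program's optimum.
#'
#' @param s,c `region_histogram` objects or numeric mass vectors of equal
#'   length whose totals agree within `tol`.
#' @param tol Relative tolerance on the equal-mass precondition (default 1e-9).
#' @return EMD in bin units (dimensionless).
#' @export
emd_closed_form <- function(s, c, tol = 1e-9) {
  ms <- hist_masses(s); mc <- hist_masses(c)
  check_emd_pre(ms, mc, tol)
  sum(abs(cumsum(ms) - cumsum(mc))) / sum(ms)
}

check_emd_pre <- function(ms, mc, tol) {
  if (length(ms) != length(mc)) stop("histograms have different bin counts")
  ts <- sum(ms); tc <- sum(mc)
  if (ts <= 0 || tc <= 0) stop("histograms must carry positive mass")
  if (abs(ts - tc) > tol * max(ts, tc)) {
    stop(sprintf("unequal total masses: %.12g vs %.12g", ts, tc))
  }
  if (any(ms < 0) || any(mc < 0)) stop("negative histogram mass")
}

#' Earth Mover's Distance via the transportation linear program
#'
#' Solves min sum_ij |i-j| x_ij subject to row sums <= S_i, column sums >= C_j,
#' x_ij >= 0 (with equality at the optimum for equal-mass inputs), by the
#' transportation simplex: a north-west-corner basic feasible start followed by
#' MODI (dual) optimality checks with cycle pivoting. Exists as the exact
#' reference for [emd_closed_form()] and for transport-plan inspection.
#'
#' @inheritParams emd_closed_form
#' @return list with `distance` (normalized total cost), and `plan`: a list
#'   with `moves` (n x n flow matrix), `total_cost` and `total_mass`.
#' @export
emd_lp <- function(s, c, tol = 1e-9) {
  ms <- hist_masses(s); mc <- hist_masses(c)
  check_emd_pre(ms, mc, tol)
  n <- length(ms)
  # balance totals exactly (they agree within tol)
  mc <- mc * (sum(ms) / sum(mc))
  I <- which(ms > 0); J <- which(mc > 0)
  sol <- transport_simplex(ms[I], mc[J], abs(outer(I - 1L, J - 1L, "-")))
  moves <- matrix(0, n, n)
  moves[cbind(I[sol$cells[, 1L]], J[sol$cells[, 2L]])] <- sol$flow
  total_mass <- sum(sol$flow)
  total_cost <- sum(abs(outer(seq_len(n) - 1L, seq_len(n) - 1L, "-")) * moves)
  list(
    distance = total_cost / total_mass,
    plan = list(moves = moves, total_cost = total_cost, total_mass = total_mass)
  )
}

# Transportation simplex for supplies a (length n), demands b (length m),
# cost matrix C (n x m), sum(a) == sum(b). Returns the basic cells and flows
# at the optimum. Degenerate bases (zero-flow basic cells) are handled.
transport_simplex <- function(a, b, C, max_iter = 10000L) {
  n <- length(a); m <- length(b)
  eps <- 1e-12 * sum(a)
  # --- north-west corner start: exactly n + m - 1 basic cells ---
  arem <- a; brem <- b
  bi <- integer(n + m - 1L); bj <- integer(n + m - 1L); bx <- numeric(n + m - 1L)
  i <- 1L; j <- 1L; k <- 0L
  repeat {
    k <- k + 1L
    x <- min(arem[i], brem[j])
    bi[k] <- i; bj[k] <- j; bx[k] <- x
    arem[i] <- arem[i] - x; brem[j] <- brem[j] - x
    if (i == n && j == m) break
    if (arem[i] <= eps && i < n) i <- i + 1L else j <- j + 1L
  }
  bi <- bi[seq_len(k)]; bj <- bj[seq_len(k)]; bx <- bx[seq_len(k)]

  for (iter in seq_len(max_iter)) {
    # --- duals from the basis spanning tree (u_i + v_j = C_ij on basis) ---
    u <- rep(NA_real_, n); v <- rep(NA_real_, m)
    u[1L] <- 0
    repeat {
      progress <- FALSE
      ku <- !is.na(u[bi]) & is.na(v[bj])
      if (any(ku)) { v[bj[ku]] <- C[cbind(bi[ku], bj[ku])] - u[bi[ku]]; progress <- TRUE }
      kv <- is.na(u[bi]) & !is.na(v[bj])
      if (any(kv)) { u[bi[kv]] <- C[cbind(bi[kv], bj[kv])] - v[bj[kv]]; progress <- TRUE }
      if (!anyNA(u) && !anyNA(v)) break
      if (!progress) stop("internal error: disconnected transportation basis")
    }
    # --- reduced costs; optimal when all >= -tol ---
    rc <- C - outer(u, v, "+")
    rc[cbind(bi, bj)] <- 0
    ent <- arrayInd(which.min(rc), dim(rc))
    if (rc[ent] >= -1e-9) break
    ei <- ent[1L]; ej <- ent[2L]
    # --- unique cycle: path in the basis tree from row-node ei to col-node ej
    path <- basis_path(bi, bj, ei, ej, n)
    # signs along the cycle: entering cell +, then alternate - , + , ...
    minus <- path[seq(1L, length(path), by = 2L)]
    theta_idx <- minus[which.min(bx[minus])]
    theta <- bx[theta_idx]
    plus <- if (length(path) >= 2L) path[seq(2L, length(path), by = 2L)] else integer(0)
    bx[minus] <- bx[minus] - theta
    bx[plus] <- bx[plus] + theta
    # leaving cell out, entering cell in (flow theta)
    bi[theta_idx] <- ei; bj[theta_idx] <- ej; bx[theta_idx] <- theta
  }
  list(cells = cbind(bi, bj), flow = bx)
}

# Path of basic-cell indices from row node `ei` to column node `ej` through the
# bipartite basis tree, ordered starting with the cell incident to column ej.
basis_path <- function(bi, bj, ei, ej, n) {
  # nodes: rows 1..n, cols n+1..n+m ; edges k connect bi[k] and n + bj[k]
  from <- c(bi, n + bj)
  to <- c(n + bj, bi)
  edge <- c(seq_along(bi), seq_along(bi))
  target <- n + ej
  parent_edge <- integer(0)
  visited <- ei
  parents <- list()  # node -> c(prev_node, edge_index)
  frontier <- ei
  repeat {
    nxt <- integer(0)
    for (node in frontier) {
      hit <- which(from == node)
      for (h in hit) {
        nb <- to[h]
        if (!(nb %in% visited)) {
          visited <- c(visited, nb)
          parents[[as.character(nb)]] <- c(node, edge[h])
          nxt <- c(nxt, nb)
        }
      }
    }
    if (target %in% visited) break
    if (length(nxt) == 0L) stop("internal error: no cycle found in basis")
    frontier <- nxt
  }
  # walk back from target to ei collecting edges
  path <- integer(0)
  node <- target
  while (node != ei) {
    p <- parents[[as.character(node)]]
    path <- c(path, p[2L])
    node <- p[1L]
  }
  path
}

#' Pairwise EMD matrix between aligned histograms
#'
#' @param hists List of `region_histogram` (all same bin count, unit mass).
#' @return Symmetric matrix of closed-form EMDs.
#' @export
emd_pairwise <- function(hists) {
  n <- length(hists)
  M <- matrix(0, n, n)
  cdfs <- lapply(hists, function(h) cumsum(hist_masses(h)))
  tots <- vapply(hists, function(h) sum(hist_masses(h)), numeric(1))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    M[i, j] <- M[j, i] <- sum(abs(cdfs[[i]] - cdfs[[j]])) / tots[i]
  }
  dimnames(M) <- list(names(hists), names(hists))
  M
}
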