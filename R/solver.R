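# Exact branch-and-bound solver ---------------------------------------------
#
# Every variant of the planning MILP reduces to: pick one management option
# per decision cell, subject to a handful of farm-level linear resource
# constraints a_k . x <= b_k. Upper bounds come from Lagrangian relaxation:
# for any lambda >= 0,
#
#   sum_c max_i (p_ci - sum_k lambda_k a_kci) + sum_k lambda_k b_k
#
# bounds the constrained optimum from above, for *any* lambda; lambda only
# affects pruning strength, never correctness. Depth-first branch and bound
# closes the gap exactly (to a relative tie tolerance used when comparing
# candidate objectives).
#
# Two problem shapes are handled:
#  * "merged"   - seed and irrigation decisions share one partition, so each
#                 decision cell picks a full option i = (r, s): a
#                 multiple-choice knapsack (bb_mckp).
#  * "two-sided"- independent seed / irrigation partitions (Model III): the
#                 search branches over per-irrigation-block frequencies, and
#                 each completed frequency assignment leaves an exact
#                 multiple-choice knapsack over seed blocks (bb_two_sided).

#' Solver control parameters
#'
#' @param node_cap abort with an error if the branch-and-bound tree exceeds
#'   this many nodes.
#' @param tol relative tolerance for comparing candidate objectives (also
#'   the guaranteed relative optimality of the returned solution).
#' @param feas_tol relative feasibility slack for resource constraints.
#' @param dual_iter iterations of the dual search that sharpens the
#'   Lagrangian bound before branching.
#' @return a list of class `solver_control`.
#' @export
solver_control <- function(node_cap = 5e7, tol = 1e-9, feas_tol = 1e-7,
                           dual_iter = 120) {
  structure(
    list(
      node_cap = node_cap, tol = tol, feas_tol = feas_tol,
      dual_iter = dual_iter
    ),
    class = "solver_control"
  )
}

row_max <- function(m) do.call(pmax, lapply(seq_len(ncol(m)), function(j) m[, j]))
row_min <- function(m) do.call(pmin, lapply(seq_len(ncol(m)), function(j) m[, j]))

# Generic Lagrangian dual search. `geval(lambda)` must return list(g =
# bound value, sg = subgradient b - usage). Returns a lambda >= 0 with a
# small (near-minimal) bound; any return value yields a valid bound.
lag_dual <- function(geval, b, profit_scale, control) {
  m <- length(b)
  if (m == 0L) return(numeric(0))
  if (m == 1L && b >= 0) {
    # one-dimensional dual: usage of the relaxed argmax is nonincreasing in
    # lambda, so bisect for the smallest lambda with usage <= b
    if (geval(0)$sg >= 0) return(0)
    lo <- 0
    hi <- max(1e-6, profit_scale / max(abs(b), 1))
    ok <- FALSE
    for (t in 1:80) {
      if (geval(hi)$sg >= 0) { ok <- TRUE; break }
      lo <- hi
      hi <- hi * 2
    }
    if (!ok) return(hi)
    for (t in 1:60) {
      mid <- (lo + hi) / 2
      if (geval(mid)$sg >= 0) hi <- mid else lo <- mid
    }
    return(hi)
  }
  # projected subgradient with clipped, diminishing steps
  scale <- pmax(abs(b), 1)
  lam <- rep(0, m)
  cur <- geval(lam)
  best_g <- cur$g
  best_lam <- lam
  for (t in seq_len(control$dual_iter)) {
    step <- profit_scale / (2 * t)
    dir <- pmax(pmin(cur$sg / scale, 1), -1)
    lam <- pmax(0, lam - step * dir / scale)
    cur <- geval(lam)
    if (cur$g < best_g) {
      best_g <- cur$g
      best_lam <- lam
    }
  }
  best_lam
}

# Greedy warm start for the multiple-choice knapsack: take the
# reduced-profit argmax, repair violated constraints by the cheapest
# per-unit swaps, then polish with first-improvement local search.
# Returns NULL when repair fails (B&B then starts cold).
mckp_warm_start <- function(prof, usage, b, red, feas_tol) {
  C <- nrow(prof)
  I <- ncol(prof)
  m <- length(b)
  choice <- max.col(red, ties.method = "first")
  repaired <- FALSE
  for (pass in seq_len(C * m + 1L)) {
    idx <- cbind(seq_len(C), choice)
    used <- vapply(usage, function(U) sum(U[idx]), 0)
    viol <- which(used > b + feas_tol)
    if (length(viol) == 0L) {
      repaired <- TRUE
      break
    }
    k <- viol[which.max((used - b)[viol])]
    U <- usage[[k]]
    alt <- max.col(-U, ties.method = "first") # min-usage option per cell
    gain <- U[idx] - U[cbind(seq_len(C), alt)]
    loss <- prof[idx] - prof[cbind(seq_len(C), alt)]
    cand <- which(gain > 1e-12 & alt != choice)
    if (length(cand) == 0L) return(NULL)
    pick <- cand[which.min(loss[cand] / gain[cand])]
    choice[pick] <- alt[pick]
  }
  if (!repaired) return(NULL)
  if (m == 1L) {
    # classic fill greedy for one resource: from the feasible reduced-cost
    # argmax, apply profit-per-resource-ranked upgrades while they fit
    U <- usage[[1L]]
    used1 <- sum(U[cbind(seq_len(C), choice)])
    repeat {
      slack <- b - used1
      dp <- prof - prof[cbind(seq_len(C), choice)]
      du <- U - U[cbind(seq_len(C), choice)]
      ok <- which(dp > 1e-12 & du > 1e-12 & du <= slack + feas_tol)
      if (length(ok) == 0L) break
      pick <- ok[which.max(dp[ok] / du[ok])]
      cc <- (pick - 1L) %% C + 1L
      oo <- (pick - 1L) %/% C + 1L
      choice[cc] <- oo
      used1 <- used1 + du[pick]
    }
  }
  # local search: single-cell swaps that raise profit and stay feasible
  used <- vapply(usage, function(U) sum(U[cbind(seq_len(C), choice)]), 0)
  for (pass in 1:25) {
    improved <- FALSE
    for (cc in seq_len(C)) {
      cur <- choice[cc]
      better <- which(prof[cc, ] > prof[cc, cur] + 1e-12)
      for (o in better[order(prof[cc, better], decreasing = TRUE)]) {
        du <- vapply(usage, function(U) U[cc, o] - U[cc, cur], 0)
        if (all(used + du <= b + feas_tol)) {
          choice[cc] <- o
          used <- used + du
          improved <- TRUE
          break
        }
      }
    }
    if (!improved) break
  }
  idx <- cbind(seq_len(C), choice)
  list(choice = choice, value = sum(prof[idx]))
}

# Exact multiple-choice knapsack: maximize sum_c prof[c, x_c] subject to
# sum_c usage_k[c, x_c] <= b_k. Returns the option chosen per cell.
# Dispatches on constraint structure: the common single-resource case gets
# LP-bounded branch and bound over dominance-reduced option frontiers; the
# general case falls back to Lagrangian bounding.
bb_mckp <- function(prof, usage, b, control, node_env = NULL) {
  C <- nrow(prof)
  I <- ncol(prof)
  m <- length(b)
  if (is.null(node_env)) node_env <- new.env(parent = emptyenv())
  if (is.null(node_env$nodes)) node_env$nodes <- 0L

  if (m == 0L) {
    choice <- max.col(prof, ties.method = "first")
    val <- sum(prof[cbind(seq_len(C), choice)])
    node_env$nodes <- node_env$nodes + 1L
    return(list(
      status = "optimal", choice = choice, value = val,
      bound = val, nodes = node_env$nodes
    ))
  }
  if (m == 1L && b[1] >= 0 && min(usage[[1L]]) >= 0) {
    return(bb_mckp_single(prof, usage[[1L]], b[1], control, node_env))
  }
  bb_mckp_lagrangian(prof, usage, b, control, node_env)
}

# Single non-negative resource: handled by the compiled exact solver
# (src/mckp.cpp): LP-bounded branch and bound over dominance-reduced
# option frontiers with duplicate-cell symmetry breaking. The warm start
# computed here seeds its incumbent.
bb_mckp_single <- function(prof, U, b, control, node_env) {
  ws <- mckp_warm_start(prof, list(U), b, prof, control$feas_tol * max(1, b))
  warm <- if (is.null(ws)) integer(0) else as.integer(ws$choice)
  res <- .mckp_single_cpp(prof, U, b, control$tol, control$feas_tol,
    control$node_cap - node_env$nodes, warm)
  node_env$nodes <- node_env$nodes + res$nodes
  res$nodes <- node_env$nodes
  res
}

# General constraint sets: Lagrangian-bounded depth-first search.
bb_mckp_lagrangian <- function(prof, usage, b, control, node_env) {
  C <- nrow(prof)
  I <- ncol(prof)
  m <- length(b)

  profit_scale <- max(1, max(abs(prof)))
  geval <- function(lam) {
    red <- prof
    for (k in seq_len(m)) red <- red - lam[k] * usage[[k]]
    amax <- max.col(red, ties.method = "first")
    idx <- cbind(seq_len(C), amax)
    list(
      g = sum(red[idx]) + sum(lam * b),
      sg = b - vapply(usage, function(U) sum(U[idx]), 0)
    )
  }
  lambda <- lag_dual(geval, b, profit_scale, control)

  red <- prof
  for (k in seq_len(m)) red <- red - lambda[k] * usage[[k]]
  cmax <- row_max(red)
  ub_root <- sum(cmax) + sum(lambda * b)
  tie_tol <- control$tol * max(1, abs(ub_root))
  feas_tol <- control$feas_tol * pmax(1, abs(b))

  # Interchangeable-cell symmetry breaking: cells with identical profit and
  # usage rows admit an optimum in which their options appear in a fixed
  # (preference-ranked) order, so the search only visits sorted
  # assignments within each duplicate group.
  key <- apply(do.call(cbind, c(list(prof), usage)), 1, paste, collapse = "\r")
  group <- match(key, unique(key))
  opt_ord_g <- lapply(split(seq_len(C), group), function(cells) {
    order(red[cells[1L], ], decreasing = TRUE)
  })
  second <- vapply(seq_len(C), function(cc) {
    if (I > 1L) red[cc, opt_ord_g[[group[cc]]][2L]] else -Inf
  }, 0)
  grp_regret <- tapply(cmax - second, group, max)
  ord <- order(-grp_regret[group], group) # duplicate cells consecutive

  # minimum achievable remaining usage, for infeasibility pruning
  minu <- vapply(usage, row_min, numeric(C)) # C x m
  sufmin <- matrix(0, m, C + 1L)
  for (d in rev(seq_len(C))) sufmin[, d] <- sufmin[, d + 1L] + minu[ord[d], ]
  same_as_prev <- c(FALSE, group[ord[-1L]] == group[ord[-C]])

  state <- new.env(parent = emptyenv())
  state$best_val <- -Inf
  state$best_choice <- NULL
  ws <- mckp_warm_start(prof, usage, b, red, max(feas_tol))
  if (!is.null(ws)) {
    state$best_val <- ws$value
    state$best_choice <- ws$choice
  }

  choice <- integer(C)
  ucell <- function(cc, o) vapply(usage, function(U) U[cc, o], 0)

  recurse <- function(depth, ub, used, acc, min_pos) {
    node_env$nodes <- node_env$nodes + 1L
    if (node_env$nodes > control$node_cap) {
      stop("branch-and-bound node cap exceeded (", control$node_cap, " nodes)",
        call. = FALSE)
    }
    if (depth > C) {
      if (acc > state$best_val + tie_tol) {
        state$best_val <- acc
        state$best_choice <- choice
      }
      return(invisible(NULL))
    }
    cc <- ord[depth]
    oord <- opt_ord_g[[group[cc]]]
    for (pos in min_pos:I) {
      o <- oord[pos]
      ub_child <- ub - cmax[cc] + red[cc, o]
      if (ub_child <= state$best_val + tie_tol) break # options ranked: rest are worse
      used2 <- used + ucell(cc, o)
      if (any(used2 + sufmin[, depth + 1L] > b + feas_tol)) next
      choice[cc] <<- o
      next_min <- if (depth < C && same_as_prev[depth + 1L]) pos else 1L
      recurse(depth + 1L, ub_child, used2, acc + prof[cc, o], next_min)
    }
    invisible(NULL)
  }
  recurse(1L, ub_root, numeric(m), 0, 1L)

  if (!is.finite(state$best_val)) {
    return(list(
      status = "infeasible", choice = NULL, value = NA_real_,
      bound = ub_root, nodes = node_env$nodes
    ))
  }
  list(
    status = "optimal", choice = state$best_choice, value = state$best_val,
    bound = ub_root, nodes = node_env$nodes
  )
}

# Exact solver for independent seed / irrigation partitions. P3 and each
# usage3[[k]] are C x R x S arrays over refinement cells; irr_block /
# seed_block map cells to their irrigation / seed decision units.
# Dispatches to the compiled solver (src/mckp.cpp) for the common
# single-resource case, warm-started from the common-coarsening solution
# (uniform decisions over the join of both partitions are feasible for
# the independent-partition model); general constraint sets fall back to
# the Lagrangian-bounded search below.
bb_two_sided <- function(P3, usage3, b, irr_block, seed_block, control) {
  m <- length(b)
  single <- m == 0L || (m == 1L && b[1] >= 0 && min(usage3[[1L]]) >= 0)
  if (!single) {
    return(bb_two_sided_lagrangian(P3, usage3, b, irr_block, seed_block, control))
  }
  dims <- dim(P3)
  C <- dims[1]; R <- dims[2]; S <- dims[3]
  Q <- max(irr_block)
  Pn <- max(seed_block)
  U3 <- if (m == 1L) usage3[[1L]] else array(0, dims)
  b1 <- if (m == 1L) b[1] else 1e15

  # common coarsening of the two partitions (label propagation to the
  # fixed point): one (r, s) per join component is feasible here
  lab <- seq_len(C)
  repeat {
    new <- as.integer(ave(lab, irr_block, FUN = min))
    new <- as.integer(ave(new, seed_block, FUN = min))
    if (identical(new, lab)) break
    lab <- new
  }
  jl <- match(lab, sort(unique(lab)))
  agg_p <- rowsum(matrix(P3, C, R * S), jl) # columns: r fastest, then s
  agg_u <- rowsum(matrix(U3, C, R * S), jl)
  warm_r <- integer(0)
  warm_s <- integer(0)
  ws <- bb_mckp(agg_p, if (m == 1L) list(agg_u) else list(), b[seq_len(m)],
    control)
  if (ws$status == "optimal") {
    r_join <- (ws$choice - 1L) %% R + 1L
    s_join <- (ws$choice - 1L) %/% R + 1L
    cell_join <- jl
    warm_r <- integer(Q)
    warm_s <- integer(Pn)
    warm_r[irr_block] <- r_join[cell_join]
    warm_s[seed_block] <- s_join[cell_join]
  }
  res <- .two_sided_cpp(
    as.numeric(P3), as.numeric(U3), b1, as.integer(irr_block),
    as.integer(seed_block), R, S, control$tol, control$feas_tol,
    control$node_cap, as.integer(warm_r), as.integer(warm_s)
  )
  res
}

# Lagrangian-bounded fallback for general constraint sets.
bb_two_sided_lagrangian <- function(P3, usage3, b, irr_block, seed_block, control) {
  dims <- dim(P3)
  C <- dims[1]; R <- dims[2]; S <- dims[3]
  Q <- max(irr_block)
  Pn <- max(seed_block)
  m <- length(b)
  node_env <- new.env(parent = emptyenv())
  node_env$nodes <- 0L
  sb <- factor(seed_block, levels = seq_len(Pn))

  profit_scale <- max(1, max(abs(P3)))
  cellmax_rs <- function(red3) {
    # C x S matrix: per cell, best frequency for each seed
    mat <- red3[, 1, ]
    if (R > 1L) for (r in 2:R) mat <- pmax(mat, red3[, r, ])
    matrix(mat, nrow = C)
  }
  geval <- function(lam) {
    red3 <- P3
    for (k in seq_len(m)) red3 <- red3 - lam[k] * usage3[[k]]
    Mfree <- cellmax_rs(red3)
    rs <- rowsum(Mfree, sb)
    sstar <- max.col(rs, ties.method = "first")
    g <- sum(rs[cbind(seq_len(Pn), sstar)]) + sum(lam * b)
    scell <- sstar[seed_block]
    rstar <- vapply(seq_len(C), function(cc) which.max(red3[cc, , scell[cc]]), 0L)
    idx <- cbind(seq_len(C), rstar, scell)
    sg <- b - vapply(usage3, function(U) sum(U[idx]), 0)
    list(g = g, sg = sg)
  }
  lambda <- if (m > 0L) lag_dual(geval, b, profit_scale, control) else numeric(0)

  red3 <- P3
  for (k in seq_len(m)) red3 <- red3 - lambda[k] * usage3[[k]]
  Mfree <- cellmax_rs(red3)
  lam_b <- sum(lambda * b)

  block_cells <- split(seq_len(C), irr_block)
  bord <- order(lengths(block_cells), decreasing = TRUE)

  rs0 <- rowsum(Mfree, sb)
  bound0 <- sum(row_max(rs0)) + lam_b
  tie_tol <- control$tol * max(1, abs(bound0))

  state <- new.env(parent = emptyenv())
  state$best_val <- -Inf
  state$best_r <- NULL
  state$best_s <- NULL
  assigned <- integer(Q)

  leaf_solve <- function() {
    rsel <- assigned[irr_block]
    gather <- function(A) {
      vapply(seq_len(S), function(s) A[cbind(seq_len(C), rsel, rep.int(s, C))], numeric(C))
    }
    PP <- rowsum(matrix(gather(P3), nrow = C), sb)
    UU <- lapply(usage3, function(U) rowsum(matrix(gather(U), nrow = C), sb))
    res <- bb_mckp(PP, UU, b, control, node_env = node_env)
    if (res$status == "optimal" && res$value > state$best_val + tie_tol) {
      state$best_val <- res$value
      state$best_r <- assigned
      state$best_s <- res$choice
    }
    invisible(NULL)
  }

  recurse <- function(depth, Mcur, rs) {
    node_env$nodes <- node_env$nodes + 1L
    if (node_env$nodes > control$node_cap) {
      stop("branch-and-bound node cap exceeded (", control$node_cap, " nodes)",
        call. = FALSE)
    }
    if (depth > Q) {
      leaf_solve()
      return(invisible(NULL))
    }
    q <- bord[depth]
    cells <- block_cells[[q]]
    aff <- sort(unique(seed_block[cells]))
    sub <- factor(seed_block[cells], levels = aff)
    old_contrib <- rowsum(Mcur[cells, , drop = FALSE], sub)
    kids <- vector("list", R)
    kb <- numeric(R)
    for (r in seq_len(R)) {
      newrows <- matrix(red3[cells, r, ], ncol = S)
      rs_new <- rs
      rs_new[aff, ] <- rs[aff, , drop = FALSE] - old_contrib +
        rowsum(newrows, sub)
      kb[r] <- sum(row_max(rs_new)) + lam_b
      kids[[r]] <- list(newrows = newrows, rs_new = rs_new)
    }
    for (r in order(kb, decreasing = TRUE)) {
      if (kb[r] <= state$best_val + tie_tol) break
      assigned[q] <<- r
      Mnew <- Mcur
      Mnew[cells, ] <- kids[[r]]$newrows
      recurse(depth + 1L, Mnew, kids[[r]]$rs_new)
    }
    assigned[q] <<- 0L
    invisible(NULL)
  }
  recurse(1L, Mfree, rs0)

  if (!is.finite(state$best_val)) {
    return(list(
      status = "infeasible", r_choice = NULL, s_choice = NULL,
      value = NA_real_, bound = bound0, nodes = node_env$nodes
    ))
  }
  list(
    status = "optimal", r_choice = state$best_r, s_choice = state$best_s,
    value = state$best_val, bound = bound0, nodes = node_env$nodes
  )
}
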