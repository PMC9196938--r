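#' Solve a linear program with a two-phase simplex method
#'
#' Minimizes `obj %*% x` subject to `A x (<=|=|>=) rhs` and `lb <= x <= ub`.
#' This is the LP subroutine behind every relaxation solved by the
#' branch-and-bound search.  It is a dense tableau implementation: lower
#' bounds are shifted out, finite upper bounds become explicit rows, rows
#' and columns are equilibrated, and a two-phase scheme with artificial
#' variables finds a basic optimal solution.  Pivoting is deterministic
#' (Dantzig rule, lowest column index on ties, lowest basic index on
#' ratio-test ties); after a run of degenerate pivots the rule switches to
#' Bland's anti-cycling rule in place until the objective moves again, so
#' the method terminates on degenerate programs without sacrificing speed
#' on ordinary ones.  Identical inputs always return identical solutions.
#'
#' Problem sizes in this package are a few hundred rows and columns at
#' most, for which a dense tableau is fast and easy to audit.
#'
#' @param obj numeric objective coefficients (length n).
#' @param A constraint matrix (m x n), dense or a `Matrix` sparse matrix.
#' @param sense character vector of `"<="`, `"="`, `">="` per row.
#' @param rhs numeric right-hand sides (length m).
#' @param lb,ub variable bounds; `lb` defaults to 0 and must be finite,
#'   `ub` defaults to `Inf`.
#' @param maximize if `TRUE` maximizes instead.
#' @param tol pivot / feasibility tolerance on the equilibrated tableau.
#' @return List with `status` (`"optimal"`, `"infeasible"`, `"unbounded"` or
#'   `"iterlimit"`), `x` (solution in original variable space), `objective`,
#'   and `basis` (indices of structural variables basic at the optimum; a
#'   warm-start descriptor — informational).
#' @export
lp_solve <- function(obj, A, sense, rhs, lb = NULL, ub = NULL,
                     maximize = FALSE, tol = 1e-9) {
  n <- length(obj)
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  m0 <- nrow(A)
  stopifnot(ncol(A) == n, length(rhs) == m0, length(sense) == m0,
            all(sense %in% c("<=", "=", ">=")))
  if (is.null(lb)) lb <- rep(0, n)
  if (is.null(ub)) ub <- rep(Inf, n)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)))
    stop("all lower bounds must be finite")
  if (any(ub < lb - 1e-12))
    return(list(status = "infeasible", x = rep(NA_real_, n),
                objective = NA_real_, basis = integer()))

  cvec <- if (maximize) -as.numeric(obj) else as.numeric(obj)

  # shift lower bounds to zero
  rhs2 <- as.numeric(rhs - A %*% lb)
  ubs <- pmax(ub - lb, 0)

  # finite upper bounds become explicit rows
  fin <- which(is.finite(ubs))
  if (length(fin)) {
    Aub <- matrix(0, length(fin), n)
    Aub[cbind(seq_along(fin), fin)] <- 1
    A2 <- rbind(A, Aub)
    sense2 <- c(sense, rep("<=", length(fin)))
    rhs2 <- c(rhs2, ubs[fin])
  } else {
    A2 <- A
    sense2 <- sense
  }

  res <- simplex_core(cvec, A2, sense2, rhs2, tol = tol)
  if (res$status == "optimal") {
    x <- lb + res$x[seq_len(n)]
    objective <- sum(cvec * x)  # recompute in original space for accuracy
    list(status = "optimal", x = x,
         objective = if (maximize) -objective else objective,
         basis = res$basis[res$basis <= n])
  } else {
    list(status = res$status, x = rep(NA_real_, n), objective = NA_real_,
         basis = integer())
  }
}

# two-phase dense tableau simplex for: min c'x, A x (sense) b, x >= 0.
# Returns list(status, x, basis).
simplex_core <- function(cvec, A, sense, rhs, tol = 1e-9,
                         max_iter = 50000L) {
  m <- nrow(A); n <- ncol(A)

  # equilibration: rows, then columns, then rows again; keeps tableau
  # entries near unit magnitude so fixed tolerances behave across the
  # kg / vehicle-count / binary variable scales of this model family
  rmax <- pmax(apply(abs(A), 1L, max), 1e-300)
  A <- A / rmax
  rhs <- rhs / rmax
  cmax <- pmax(apply(abs(A), 2L, max), 1e-300)
  cmax[cmax < 1e-12] <- 1
  A <- sweep(A, 2L, cmax, `/`)
  rmax2 <- pmax(apply(abs(A), 1L, max), 1e-300)
  A <- A / rmax2
  rhs <- rhs / rmax2
  # objective in column-scaled space (affects only internal tolerances)
  cvec_s <- cvec / cmax
  cscale <- max(abs(cvec_s), 1)
  cs <- cvec_s / cscale

  # orient rows so rhs >= 0
  neg <- rhs < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    rhs[neg] <- -rhs[neg]
    sense[neg] <- c("<=" = ">=", ">=" = "<=", "=" = "=")[sense[neg]]
  }

  n_le <- sum(sense == "<=")
  n_ge <- sum(sense == ">=")
  n_eq <- sum(sense == "=")
  n_art <- n_ge + n_eq
  ncols <- n + n_le + n_ge + n_art

  # column layout: [structural | slack(<=) | surplus(>=) | artificial(>=,=)]
  Tb <- matrix(0, m + 2L, ncols + 1L)   # +2 cost rows, +1 rhs column
  Tb[seq_len(m), seq_len(n)] <- A
  Tb[seq_len(m), ncols + 1L] <- rhs
  basis <- integer(m)

  sl <- n; su <- n + n_le; ar <- n + n_le + n_ge
  i_le <- which(sense == "<="); i_ge <- which(sense == ">=")
  i_eq <- which(sense == "=")
  for (r in seq_along(i_le)) {
    Tb[i_le[r], sl + r] <- 1
    basis[i_le[r]] <- sl + r
  }
  for (r in seq_along(i_ge)) Tb[i_ge[r], su + r] <- -1
  art_rows <- c(i_ge, i_eq)
  for (r in seq_along(art_rows)) {
    Tb[art_rows[r], ar + r] <- 1
    basis[art_rows[r]] <- ar + r
  }
  art_cols <- if (n_art) (ar + 1L):ncols else integer()

  crow2 <- m + 1L   # phase-2 (true) objective row
  crow1 <- m + 2L   # phase-1 (artificial) objective row
  Tb[crow2, seq_len(n)] <- cs
  if (n_art) {
    # phase-1 reduced costs: -(sum of artificial-basic rows)
    Tb[crow1, ] <- -colSums(Tb[art_rows, , drop = FALSE])
    Tb[crow1, art_cols] <- 0
  }

  env <- new.env(parent = emptyenv())
  env$Tb <- Tb; env$basis <- basis
  allowed <- rep(TRUE, ncols)

  if (n_art) {
    st1 <- simplex_iterate(env, crow1, allowed, m, ncols, tol, max_iter)
    if (st1 != "optimal")
      return(list(status = if (st1 == "unbounded") "infeasible" else st1,
                  x = NULL, basis = integer()))
    if (-env$Tb[crow1, ncols + 1L] > 1e-7 * max(1, max(abs(rhs))))
      return(list(status = "infeasible", x = NULL, basis = integer()))
    # drive remaining basic artificials out, or drop redundant rows
    drop_rows <- integer()
    for (r in which(env$basis %in% art_cols)) {
      cand <- which(abs(env$Tb[r, seq_len(n + n_le + n_ge)]) > tol * 10)
      if (length(cand)) simplex_pivot(env, r, cand[1L])
      else drop_rows <- c(drop_rows, r)   # linearly dependent row
    }
    if (length(drop_rows)) {
      keep <- setdiff(seq_len(m), drop_rows)
      env$Tb <- env$Tb[c(keep, crow2, crow1), , drop = FALSE]
      env$basis <- env$basis[keep]
      m <- length(keep)
      crow2 <- m + 1L
    }
  }

  allowed[art_cols] <- FALSE
  st2 <- simplex_iterate(env, crow2, allowed, m, ncols, tol, max_iter)
  if (st2 != "optimal")
    return(list(status = st2, x = NULL, basis = integer()))
  x <- numeric(ncols)
  x[env$basis] <- env$Tb[seq_len(m), ncols + 1L]
  list(status = "optimal", x = pmax(x[seq_len(n)] / cmax, 0),
       basis = env$basis)
}

# pivot the tableau held in env at (row pr, column jc)
simplex_pivot <- function(env, pr, jc) {
  Tb <- env$Tb
  piv <- Tb[pr, jc]
  Tb[pr, ] <- Tb[pr, ] / piv
  fac <- Tb[, jc]
  fac[pr] <- 0
  nz <- which(fac != 0)
  if (length(nz))
    Tb[nz, ] <- Tb[nz, , drop = FALSE] - outer(fac[nz], Tb[pr, ])
  Tb[, jc] <- 0
  Tb[pr, jc] <- 1
  env$Tb <- Tb
  env$basis[pr] <- jc
  invisible(NULL)
}

# run simplex iterations on the tableau in env, minimizing cost row `crow`.
# Dantzig pricing with lowest-index ties; after `stall_limit` consecutive
# degenerate pivots, Bland's rule takes over until the objective improves.
# The ratio test only accepts pivot elements above `ptol` (the tableau is
# equilibrated, so genuine entries are O(1)) and, among near-minimal
# ratios, prefers the largest pivot element for numerical stability.
simplex_iterate <- function(env, crow, allowed, m, ncols, tol, max_iter,
                            stall_limit = 60L, ptol = 1e-7) {
  it <- 0L; stall <- 0L; bland <- FALSE
  last_obj <- env$Tb[crow, ncols + 1L]
  rows <- seq_len(m)
  skip <- rep(FALSE, ncols)   # columns with only near-zero pivots, per basis
  repeat {
    it <- it + 1L
    if (it > max_iter) return("iterlimit")
    red <- env$Tb[crow, seq_len(ncols)]
    red[!allowed | skip] <- 0
    if (bland) {
      cand <- which(red < -tol)
      if (!length(cand)) return("optimal")
      jc <- cand[1L]
    } else {
      jc <- which.min(red)
      if (red[jc] >= -tol) return("optimal")
    }
    col <- env$Tb[rows, jc]
    pos <- col > ptol
    if (!any(pos)) {
      if (any(col > tol)) {
        skip[jc] <- TRUE  # unusable pivot column under the current basis
        next
      }
      return("unbounded")
    }
    skip[] <- FALSE       # basis is about to change; re-admit all columns
    ratio <- rep(Inf, m)
    ratio[pos] <- env$Tb[rows, ncols + 1L][pos] / col[pos]
    rmin <- min(ratio)
    ties <- which(ratio <= rmin + ptol * max(1, abs(rmin)))
    pr <- if (bland) ties[which.min(env$basis[ties])]
    else {
      big <- ties[col[ties] >= 0.5 * max(col[ties])]
      big[which.min(env$basis[big])]
    }
    simplex_pivot(env, pr, jc)
    obj <- env$Tb[crow, ncols + 1L]
    if (abs(obj - last_obj) > tol * max(1, abs(last_obj))) {
      stall <- 0L; bland <- FALSE; last_obj <- obj
    } else {
      stall <- stall + 1L
      if (stall >= stall_limit) bland <- TRUE
    }
  }
}
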