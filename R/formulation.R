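#' Build the mixed-integer linear formulation of an instance
#'
#' Translates a [ppe_instance()] into a MILP over the variable catalog
#' `[z_i | x_hijm | y_hijkm]` (binary DC openings, integer vehicle counts,
#' continuous kg shipped).  The capacity/demand constraints become `<=` rows;
#' the coverage restriction is applied by fixing the upper bound of `x` to 0
#' on every path longer than the coverage radius (tighter than a big-M row);
#' integer `x` receives the finite bound `min(U_hm, P_im)` so the search tree
#' is finite.  Both objectives are precomputed as linear coefficient vectors
#' over the catalog: the waiting cost `lambda_k(e_m * D_hij)` of each route
#' is a constant once distances are fixed, so the loss objective G1 is linear
#' in the shipped quantities with constant offset `sum(w_k d_jk lambda_max_k)`.
#'
#' @param instance a [ppe_instance()].
#' @return An object of class `milp_formulation`: variable catalog
#'   (`data.frame` with name, kind, lb, ub), dense constraint matrix `A` with
#'   `sense`/`rhs`/`tag` row metadata, objective vectors `obj_G1`, `obj_G2`
#'   and constants `const_G1`, `const_G2`.
#' @export
build_formulation <- function(instance) {
  stopifnot(inherits(instance, "ppe_instance"))
  bad <- !vapply(instance[c("distance", "vehicle_supply", "ppe_supply",
                            "dc_vehicle_cap", "dc_ppe_cap", "demand",
                            "unit_cost", "unit_time", "rent", "ppe_weight",
                            "vehicle_capacity")],
                 function(p) all(is.finite(p)), TRUE)
  if (any(bad))
    stop("non-finite parameter in field(s): ",
         paste(names(bad)[bad], collapse = ", "))

  nH <- length(instance$reserve_ids); nI <- length(instance$dc_ids)
  nJ <- length(instance$area_ids); nK <- length(instance$ppe_ids)
  nM <- length(instance$vehicle_ids)
  nX <- nH * nI * nJ * nM
  nY <- nH * nI * nJ * nK * nM
  nvar <- nI + nX + nY
  off_x <- nI; off_y <- nI + nX

  # linear index -> subscripts, column-major (h fastest), matching as.vector()
  xi <- arrayInd(seq_len(nX), c(nH, nI, nJ, nM))
  yi <- arrayInd(seq_len(nY), c(nH, nI, nJ, nK, nM))

  # variable catalog
  x_ub <- pmin(instance$vehicle_supply[xi[, c(1L, 4L), drop = FALSE]],
               instance$dc_vehicle_cap[xi[, c(2L, 4L), drop = FALSE]])
  x_ub[as.vector(instance$distance)[xi[, 1L] + nH * (xi[, 2L] - 1L) +
                                      nH * nI * (xi[, 3L] - 1L)] >
         instance$coverage] <- 0  # constraint (5) as a bound
  catalog <- data.frame(
    name = c(paste0("z[", instance$dc_ids, "]"),
             paste0("x[", instance$reserve_ids[xi[, 1L]], ",",
                    instance$dc_ids[xi[, 2L]], ",",
                    instance$area_ids[xi[, 3L]], ",",
                    instance$vehicle_ids[xi[, 4L]], "]"),
             paste0("y[", instance$reserve_ids[yi[, 1L]], ",",
                    instance$dc_ids[yi[, 2L]], ",",
                    instance$area_ids[yi[, 3L]], ",",
                    instance$ppe_ids[yi[, 4L]], ",",
                    instance$vehicle_ids[yi[, 5L]], "]")),
    kind = c(rep("binary", nI), rep("integer", nX), rep("continuous", nY)),
    lb = rep(0, nvar),
    ub = c(rep(1, nI), x_ub, rep(Inf, nY)),
    stringsAsFactors = FALSE)

  # constraint rows (6)-(11), all "<="
  n6 <- nH * nM; n7 <- nH * nK; n8 <- nI * nM; n9 <- nI * nK
  n10 <- nX; n11 <- nJ * nK
  o6 <- 0L; o7 <- n6; o8 <- n6 + n7; o9 <- o8 + n8; o10 <- o9 + n9
  o11 <- o10 + n10
  nrow_tot <- o11 + n11

  trip_i <- c(
    o6 + xi[, 1L] + nH * (xi[, 4L] - 1L),                    # (6) x
    o7 + yi[, 1L] + nH * (yi[, 4L] - 1L),                    # (7) y
    o8 + xi[, 2L] + nI * (xi[, 4L] - 1L),                    # (8) x
    o8 + rep(seq_len(nI), nM) + nI * (rep(seq_len(nM), each = nI) - 1L),  # (8) z
    o9 + yi[, 2L] + nI * (yi[, 4L] - 1L),                    # (9) y
    o9 + rep(seq_len(nI), nK) + nI * (rep(seq_len(nK), each = nI) - 1L),  # (9) z
    o10 + seq_len(nX),                                       # (10) x
    o10 + yi[, 1L] + nH * (yi[, 2L] - 1L) + nH * nI * (yi[, 3L] - 1L) +
      nH * nI * nJ * (yi[, 5L] - 1L),                        # (10) y
    o11 + yi[, 3L] + nJ * (yi[, 4L] - 1L))                   # (11) y
  trip_j <- c(
    off_x + seq_len(nX),
    off_y + seq_len(nY),
    off_x + seq_len(nX),
    rep(seq_len(nI), nM),
    off_y + seq_len(nY),
    rep(seq_len(nI), nK),
    off_x + seq_len(nX),
    off_y + seq_len(nY),
    off_y + seq_len(nY))
  trip_v <- c(
    rep(1, nX),
    rep(1, nY),
    rep(1, nX),
    -as.vector(instance$dc_vehicle_cap),
    rep(1, nY),
    -as.vector(instance$dc_ppe_cap),
    -instance$vehicle_capacity[xi[, 4L]],
    rep(1, nY),
    rep(1, nY))

  A <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_v,
                            dims = c(nrow_tot, nvar))
  rhs <- c(as.vector(instance$vehicle_supply),   # (6)
           as.vector(instance$ppe_supply),       # (7)
           rep(0, n8), rep(0, n9), rep(0, n10),
           as.vector(instance$demand))           # (11)
  sense <- rep("<=", nrow_tot)
  tag <- c(rep("(6)", n6), rep("(7)", n7), rep("(8)", n8), rep("(9)", n9),
           rep("(10)", n10), rep("(11)", n11))

  # objective vectors
  plateau <- vapply(instance$curves, `[[`, 0, "plateau")
  lam <- unit_loss_array(instance)                           # [H,I,J,K,M]
  wk <- instance$ppe_weight
  obj_G1 <- numeric(nvar)
  obj_G1[off_y + seq_len(nY)] <- wk[yi[, 4L]] *
    (as.vector(lam) - plateau[yi[, 4L]])
  const_G1 <- sum(sweep(instance$demand, 2L, plateau * wk, `*`))

  obj_G2 <- numeric(nvar)
  obj_G2[seq_len(nI)] <- instance$rent
  obj_G2[off_x + seq_len(nX)] <- as.vector(instance$distance)[
    xi[, 1L] + nH * (xi[, 2L] - 1L) + nH * nI * (xi[, 3L] - 1L)] *
    instance$unit_cost[xi[, 4L]]

  structure(list(instance = instance, catalog = catalog,
                 A = as.matrix(A), sense = sense, rhs = rhs, tag = tag,
                 obj_G1 = obj_G1, const_G1 = const_G1,
                 obj_G2 = obj_G2, const_G2 = 0,
                 nvar = nvar, n_z = nI, n_x = nX, n_y = nY,
                 theta = NULL),
            class = "milp_formulation")
}

#' Evaluate an objective on a solution vector
#'
#' @param formulation a `milp_formulation`.
#' @param x solution vector over the variable catalog.
#' @param which `"G1"` (waiting loss) or `"G2"` (logistics cost).
#' @return Objective value in yuan (coefficients plus constant offset).
#' @export
eval_objective <- function(formulation, x, which = c("G1", "G2")) {
  which <- match.arg(which)
  if (which == "G1") sum(formulation$obj_G1 * x) + formulation$const_G1
  else sum(formulation$obj_G2 * x) + formulation$const_G2
}

#' Embed an allocation plan as a catalog vector
#'
#' @param formulation a `milp_formulation`.
#' @param plan an [allocation_plan()].
#' @return Numeric vector over the variable catalog (inverse of
#'   [extract_plan()]).
#' @export
embed_plan <- function(formulation, plan) {
  stopifnot(inherits(plan, "allocation_plan"))
  v <- c(as.numeric(plan$open_dc), as.vector(plan$vehicles),
         as.vector(plan$shipped))
  if (!is.null(formulation$theta)) v <- c(v, numeric(4L))
  v
}

#' Recover an allocation plan from a solution vector
#'
#' Integer variables are rounded if within `int_tol` of an integer; a larger
#' fractional residue is an error (the vector does not describe a plan).
#'
#' @param formulation a `milp_formulation`.
#' @param x solution vector over the variable catalog (goal deviation
#'   variables, if present, are ignored).
#' @param int_tol integrality tolerance for rounding.
#' @return An [allocation_plan()].
#' @export
extract_plan <- function(formulation, x, int_tol = 1e-6) {
  inst <- formulation$instance
  n_z <- formulation$n_z; n_x <- formulation$n_x; n_y <- formulation$n_y
  if (length(x) < n_z + n_x + n_y)
    stop("solution vector shorter than the variable catalog")
  zv <- x[seq_len(n_z)]
  xv <- x[n_z + seq_len(n_x)]
  yv <- x[n_z + n_x + seq_len(n_y)]
  if (any(abs(c(zv, xv) - round(c(zv, xv))) > int_tol))
    stop(sprintf("fractional integer variable beyond tolerance %g", int_tol))
  nH <- length(inst$reserve_ids); nI <- length(inst$dc_ids)
  nJ <- length(inst$area_ids); nK <- length(inst$ppe_ids)
  nM <- length(inst$vehicle_ids)
  allocation_plan(inst, round(zv),
                  array(round(xv), c(nH, nI, nJ, nM)),
                  array(pmax(yv, 0), c(nH, nI, nJ, nK, nM)))
}

#' Goal-programming specification
#'
#' Ideal levels and preemptive priorities for the two objectives.  The
#' waiting-loss objective dominates the cost objective; "dominates" is
#' realized either lexicographically (stage-wise solves, the default) or by
#' a weighted single objective with a large priority ratio.
#'
#' @param ideals numeric length 2: ideal levels `R_1`, `R_2` in yuan.
#' @param priorities numeric length 2, positive; used by weighted mode.
#' @param mode `"lexicographic"` or `"weighted"`.
#' @param min_ratio smallest admissible `priorities[1]/priorities[2]` in
#'   weighted mode.
#' @return An object of class `goal_spec`.
#' @export
goal_spec <- function(ideals, priorities = c(1e6, 1),
                      mode = c("lexicographic", "weighted"),
                      min_ratio = 1e3) {
  mode <- match.arg(mode)
  stopifnot(length(ideals) == 2L, is.numeric(ideals),
            length(priorities) == 2L, all(priorities > 0))
  if (any(!is.finite(ideals))) stop("ideal levels must be finite")
  if (mode == "weighted" && priorities[1L] / priorities[2L] < min_ratio)
    stop(sprintf("weighted mode requires priorities[1]/priorities[2] >= %g",
                 min_ratio))
  structure(list(ideals = as.numeric(ideals),
                 priorities = as.numeric(priorities), mode = mode),
            class = "goal_spec")
}

#' Attach deviation variables and goal rows to a formulation
#'
#' Appends non-negative deviation variables `theta_n^-`, `theta_n^+` and the
#' two equality rows `G_n + theta_n^- - theta_n^+ = R_n`.  The complementarity
#' condition `theta_n^- * theta_n^+ = 0` is nonlinear and is *not* added as a
#' row: with both deviations non-negative, appearing in a single equality and
#' only `theta^+` penalized, an optimal basic solution never carries both
#' positive; the property is verified post hoc by the solver.
#'
#' @param base a `milp_formulation` from [build_formulation()].
#' @param spec a [goal_spec()].
#' @return A `milp_formulation` with `theta` index bookkeeping and a
#'   `goal_objective` vector (`priorities[1] * theta_1^+ +
#'   priorities[2] * theta_2^+`, used directly in weighted mode).
#' @export
attach_goal <- function(base, spec) {
  stopifnot(inherits(base, "milp_formulation"), inherits(spec, "goal_spec"))
  if (!is.null(base$theta)) stop("goal rows already attached")
  nvar <- base$nvar
  th <- nvar + 1:4  # th1m, th1p, th2m, th2p
  g <- base
  g$catalog <- rbind(base$catalog, data.frame(
    name = c("theta1-", "theta1+", "theta2-", "theta2+"),
    kind = "continuous", lb = 0, ub = Inf, stringsAsFactors = FALSE))
  g$nvar <- nvar + 4L
  A <- cbind(base$A, matrix(0, nrow(base$A), 4L))
  row1 <- c(base$obj_G1, 1, -1, 0, 0)
  row2 <- c(base$obj_G2, 0, 0, 1, -1)
  g$A <- rbind(A, row1, row2)
  rownames(g$A) <- NULL
  g$sense <- c(base$sense, "=", "=")
  g$rhs <- c(base$rhs, spec$ideals[1L] - base$const_G1,
             spec$ideals[2L] - base$const_G2)
  g$tag <- c(base$tag, "(16.1)", "(16.2)")
  g$obj_G1 <- c(base$obj_G1, numeric(4L))
  g$obj_G2 <- c(base$obj_G2, numeric(4L))
  g$theta <- list(th1m = th[1L], th1p = th[2L], th2m = th[3L], th2p = th[4L])
  g$goal_spec <- spec
  gobj <- numeric(g$nvar)
  gobj[th[2L]] <- spec$priorities[1L]
  gobj[th[4L]] <- spec$priorities[2L]
  g$goal_objective <- gobj
  g
}

#' Write a formulation as LP-format text (debugging aid)
#'
#' Standard LP-file dialect with fixed decimal notation; objective defaults
#' to the cost objective G2.
#'
#' @param formulation a `milp_formulation`.
#' @param path output file path.
#' @param objective coefficient vector to use as the objective (default
#'   `obj_G2`).
#' @return `path`, invisibly.
#' @export
write_lp_format <- function(formulation, path,
                            objective = formulation$obj_G2) {
  f <- formulation
  nm <- gsub("[^A-Za-z0-9_]", "_", f$catalog$name)
  term <- function(coefs) {
    idx <- which(abs(coefs) > 0)
    paste(sprintf("%+.12f %s", coefs[idx], nm[idx]), collapse = " ")
  }
  lines <- c("Minimize", paste(" obj:", term(objective)), "Subject To")
  senses <- c("<=" = "<=", "=" = "=", ">=" = ">=")
  for (r in seq_along(f$rhs))
    lines <- c(lines, sprintf(" c%d: %s %s %.12f", r, term(f$A[r, ]),
                              senses[[f$sense[r]]], f$rhs[r]))
  lines <- c(lines, "Bounds")
  for (v in seq_len(f$nvar)) {
    ubtxt <- if (is.finite(f$catalog$ub[v]))
      sprintf("%.12f", f$catalog$ub[v]) else "+inf"
    lines <- c(lines, sprintf(" %.12f <= %s <= %s", f$catalog$lb[v], nm[v],
                              ubtxt))
  }
  gen <- nm[f$catalog$kind == "integer"]
  bin <- nm[f$catalog$kind == "binary"]
  if (length(gen)) lines <- c(lines, "General", paste("", gen))
  if (length(bin)) lines <- c(lines, "Binary", paste("", bin))
  lines <- c(lines, "End")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.milp_formulation <- function(x, ...) {
  cat(sprintf("MILP formulation: %d variables (%d binary, %d integer, %d continuous), %d rows\n",
              x$nvar, sum(x$catalog$kind == "binary"),
              sum(x$catalog$kind == "integer"),
              sum(x$catalog$kind == "continuous"), length(x$rhs)))
  if (!is.null(x$theta)) cat("  goal rows attached\n")
  invisible(x)
}
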