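# Geometry kernel: initial ion estimate, binding-atom selection,
# Levenberg-Marquardt refinement of the ion position against ideal
# coordination distances, imidazole orientation angles, optimal rigid
# superposition, and chi2 rotamer sampling for histidines.

IDEAL_DIST_DEFAULT <- 2.15  # Angstrom, all ligand atoms except Cys S
IDEAL_DIST_CYS_SG <- 2.32   # Angstrom, Cys SG

.vnorm <- function(v) sqrt(sum(v * v))
.unit <- function(v) v / .vnorm(v)
.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
.angle_deg <- function(a, b) {
  cosv <- sum(a * b) / (.vnorm(a) * .vnorm(b))
  acos(max(-1, min(1, cosv))) * 180 / pi
}

#' Ideal coordination distance for a ligand atom
#'
#' 2.15 Angstrom for all coordinating atoms except the Cys sulfur,
#' for which 2.32 Angstrom is used.
#'
#' @param res_type 3-letter residue type.
#' @param atom Atom name.
#' @return Ideal zinc-ligand distance in Angstrom.
#' @export
ideal_distance <- function(res_type, atom) {
  ifelse(res_type == "CYS" & atom == "SG",
         IDEAL_DIST_CYS_SG, IDEAL_DIST_DEFAULT)
}

#' Initial estimate of the ion position for a candidate site
#'
#' For sites with four or more residues the centroid of the binding points is
#' used.  For three-residue sites two symmetric starting points are returned,
#' offset from the centroid along the unit normal of the plane of the three
#' binding points.  Side "A" is the +normal side, with the normal computed
#' from the residues sorted by (chain, seq_id, icode).
#'
#' @param binding_points List (or 3-column matrix rows) of binding-point
#'   coordinates, in residue order sorted by (chain, seq_id).
#' @param offset Off-plane displacement for 3-residue sites (Angstrom).
#' @return A list of one (>=4 residues) or two (3 residues, sides A then B)
#'   length-3 coordinates.
#' @export
initial_zinc_estimate <- function(binding_points, offset = 1.5) {
  pts <- do.call(rbind, binding_points)
  stopifnot(nrow(pts) >= 3L)
  centroid <- colMeans(pts)
  if (nrow(pts) >= 4L) return(list(centroid))
  n <- .cross(pts[2, ] - pts[1, ], pts[3, ] - pts[1, ])
  if (.vnorm(n) < 1e-6) {
    stop("degenerate geometry: three binding points are (nearly) collinear")
  }
  n <- .unit(n)
  list(centroid + offset * n, centroid - offset * n)
}

#' Select the binding atom of each residue nearest to an ion estimate
#'
#' Residues with two candidate coordinating atoms (His, Asp, Glu) contribute
#' the listed atom closest to the estimated ion position; single-atom
#' residues contribute their atom.  Exact ties resolve to the
#' lexicographically first atom name.
#'
#' @param residues List of binding-residue objects
#'   (see [extract_binding_residues()]).
#' @param estimate Length-3 ion position estimate.
#' @return List per residue: `list(res_type, atom, coord, d_ideal)`.
#' @export
select_binding_atoms <- function(residues, estimate) {
  dict <- binding_atom_dictionary()
  lapply(residues, function(r) {
    cand <- dict[[r$res_type]]
    coords <- lapply(cand, .atom_coord, residue = r)
    ok <- !vapply(coords, is.null, TRUE)
    cand <- cand[ok]
    coords <- coords[ok]
    if (length(cand) == 0L) {
      stop("no binding atom present for residue ", r$key)
    }
    d <- vapply(coords, function(p) .vnorm(p - estimate), 0)
    i <- order(d, cand)[1]
    list(res_type = r$res_type, atom = cand[i], coord = coords[[i]],
         d_ideal = ideal_distance(r$res_type, cand[i]))
  })
}

#' Refine the ion position by damped least squares
#'
#' Minimises sum_i (d_i - d_ideal_i)^2 over the ion position, where d_i is
#' the distance to chosen ligand atom i, using the Levenberg-Marquardt
#' method started from `start`.  Convergence when the step norm drops below
#' `tol` or after `max_iter` iterations.
#'
#' @param chosen_atoms Output of [select_binding_atoms()].
#' @param start Length-3 starting position.
#' @param tol Step-norm convergence tolerance.
#' @param max_iter Iteration cap.
#' @return `PlacementResult` list: `zinc_coord`, `chosen_atoms`, `distances`,
#'   `d_ideal`, `drmsd`, `objective`, `converged`, `side` (filled by caller).
#' @export
refine_zinc_position <- function(chosen_atoms, start, tol = 1e-8,
                                 max_iter = 200L) {
  P <- do.call(rbind, lapply(chosen_atoms, `[[`, "coord"))
  ideal <- vapply(chosen_atoms, `[[`, 0, "d_ideal")
  x <- as.numeric(start)
  resid_fun <- function(x) {
    d <- sqrt(rowSums(sweep(P, 2, x)^2))
    list(r = d - ideal, d = d)
  }
  lambda <- 1e-3
  rf <- resid_fun(x)
  obj <- sum(rf$r^2)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # Jacobian of residuals d_i - ideal_i wrt x: (x - p_i)/d_i
    d_safe <- pmax(rf$d, 1e-12)
    J <- -sweep(P, 2, x) / d_safe   # row i: (x - p_i) / d_i
    g <- crossprod(J, rf$r)
    H <- crossprod(J)
    step_ok <- FALSE
    for (k in 1:30) {
      A <- H + lambda * diag(3)
      delta <- tryCatch(solve(A, -g), error = function(e) NULL)
      if (is.null(delta)) { lambda <- lambda * 10; next }
      x_new <- x + as.numeric(delta)
      rf_new <- resid_fun(x_new)
      obj_new <- sum(rf_new$r^2)
      if (obj_new <= obj) {
        x <- x_new; rf <- rf_new
        step_norm <- .vnorm(delta)
        decrease <- obj - obj_new
        obj <- obj_new
        lambda <- max(lambda / 10, 1e-12)
        step_ok <- TRUE
        break
      }
      lambda <- lambda * 10
    }
    if (!step_ok) { converged <- TRUE; break }
    if (step_norm < tol || decrease < tol^2 * (1 + obj)) {
      converged <- TRUE; break
    }
  }
  if (!converged) {
    warning("ion placement did not converge within ", max_iter, " iterations")
  }
  d <- rf$d
  list(zinc_coord = x, chosen_atoms = chosen_atoms, distances = d,
       d_ideal = ideal, drmsd = sqrt(mean((d - ideal)^2)),
       objective = obj, converged = converged, side = "n/a")
}

# Ring geometry bookkeeping: the flanking carbons C1/C2 for each candidate
# nitrogen of the imidazole.
.his_flanking <- list(NE2 = c("CD2", "CE1"), ND1 = c("CE1", "CG"))

#' Imidazole orientation angles of a histidine relative to a placed ion
#'
#' alpha ("angle to plane") is the elevation of the coordination bond vector
#' out of the imidazole plane: 90 degrees minus the angle between the plane
#' normal and the bond vector, folded into [0, 90].  beta ("angle to m->N")
#' is the in-plane angle between the projection of the bond vector and the
#' extension of the midpoint-to-nitrogen axis, where the midpoint m is taken
#' between the two ring carbons flanking the coordinating nitrogen
#' (CD2/CE1 for NE2; CE1/CG for ND1).
#'
#' @param his Residue object of type HIS with ring atoms CG, ND1, CD2, CE1,
#'   NE2 present.
#' @param zinc Length-3 ion coordinate.
#' @param nitrogen `"ND1"` or `"NE2"`: the coordinating nitrogen.
#' @return List `alpha`, `beta` (degrees), `nitrogen`.
#' @export
imidazole_angles <- function(his, zinc, nitrogen = c("NE2", "ND1")) {
  nitrogen <- match.arg(nitrogen)
  ring_names <- c("CG", "ND1", "CD2", "CE1", "NE2")
  ring <- lapply(ring_names, .atom_coord, residue = his)
  if (any(vapply(ring, is.null, TRUE))) {
    stop("missing imidazole ring atom in residue ", his$key)
  }
  names(ring) <- ring_names
  R <- do.call(rbind, ring)
  ctr <- colMeans(R)
  Rc <- sweep(R, 2, ctr)
  # plane normal: smallest principal axis of the ring atoms
  n <- svd(Rc)$v[, 3]
  N <- ring[[nitrogen]]
  bond <- zinc - N
  gamma <- .angle_deg(n, bond)
  alpha <- abs(90 - gamma)
  flank <- .his_flanking[[nitrogen]]
  m <- (ring[[flank[1]]] + ring[[flank[2]]]) / 2
  axis <- N - m                       # extension of m->N beyond N
  proj <- bond - sum(bond * n) * n    # projection onto ring plane
  beta <- if (.vnorm(proj) < 1e-9) 0 else .angle_deg(proj, axis)
  list(alpha = alpha, beta = beta, nitrogen = nitrogen)
}

# Angles for every His in a site against a given placement; the nitrogen is
# the one chosen during atom selection when it is a ring nitrogen, otherwise
# the nearer of ND1/NE2.
.site_his_angles <- function(residues, chosen_atoms, zinc) {
  out <- list()
  for (i in seq_along(residues)) {
    r <- residues[[i]]
    if (r$res_type != "HIS") next
    nit <- chosen_atoms[[i]]$atom
    if (!nit %in% c("ND1", "NE2")) nit <- "NE2"
    out[[length(out) + 1L]] <- imidazole_angles(r, zinc, nit)
  }
  out
}

#' Pick the favourable side of a three-residue placement
#'
#' Three-residue sites admit two mirror-symmetric ion positions.  When the
#' site contains histidine(s) the side with the lower imidazole-angle score
#' wins; otherwise side A (the +normal side under the deterministic residue
#' ordering) is kept.  Equal scores also resolve to side A.
#'
#' @param placements List of two `PlacementResult`s (sides A, B).
#' @param angle_scores Numeric length-2 imidazole-angle scores, or NULL for
#'   His-free sites.
#' @return The selected placement with `side` set.
#' @export
choose_three_residue_side <- function(placements, angle_scores = NULL) {
  sel <- 1L
  if (!is.null(angle_scores) && length(angle_scores) == 2L &&
      is.finite(angle_scores[2]) && angle_scores[2] < angle_scores[1]) {
    sel <- 2L
  }
  p <- placements[[sel]]
  p$side <- c("A", "B")[sel]
  p
}

#' Minimal RMSD under optimal rigid superposition
#'
#' Kabsch superposition of two equally sized coordinate sets after centroid
#' removal; correspondence is optimised by enumerating permutations within
#' groups of identical residue types.
#'
#' @param coords_a,coords_b Matrices (n x 3) of corresponding coordinates.
#' @param types_a,types_b Character vectors of residue types per row; when
#'   given, rows of `coords_b` are permuted within equal-type groups and the
#'   minimum RMSD over all such permutations is returned.
#' @return RMSD in Angstrom.
#' @export
superimpose_rmsd <- function(coords_a, coords_b,
                             types_a = NULL, types_b = NULL) {
  A <- as.matrix(coords_a)
  B <- as.matrix(coords_b)
  if (nrow(A) != nrow(B)) stop("coordinate sets differ in size")
  if (is.null(types_a)) {
    return(.kabsch_rmsd(A, B))
  }
  if (!identical(sort(types_a), sort(types_b))) {
    stop("residue-type multisets differ between site and template")
  }
  # enumerate permutations of B rows within equal-type groups
  perms_for <- function(n) {
    if (n == 1L) return(list(1L))
    out <- list()
    rec <- function(prefix, rest) {
      if (length(rest) == 0L) { out[[length(out) + 1L]] <<- prefix; return() }
      for (i in seq_along(rest)) rec(c(prefix, rest[i]), rest[-i])
    }
    rec(integer(), seq_len(n))
    out
  }
  groups <- split(seq_along(types_b), types_b)
  # B rows must be matched to A rows of the same type, group by group
  a_groups <- split(seq_along(types_a), types_a)
  best <- Inf
  group_perms <- lapply(groups, function(idx) perms_for(length(idx)))
  combo_iter <- function(gi, b_order) {
    if (gi > length(groups)) {
      idx_b <- unlist(b_order)
      idx_a <- unlist(a_groups)
      r <- .kabsch_rmsd(A[idx_a, , drop = FALSE], B[idx_b, , drop = FALSE])
      if (r < best) best <<- r
      return()
    }
    g <- groups[[gi]]
    for (p in group_perms[[gi]]) {
      combo_iter(gi + 1L, c(b_order, list(g[p])))
    }
  }
  combo_iter(1L, list())
  best
}

.kabsch_rmsd <- function(A, B) {
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  s <- svd(crossprod(Bc, Ac))
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  diff <- Ac - Bc %*% t(R)
  sqrt(sum(diff^2) / nrow(A))
}

# Rotate points about the axis through `origin` with unit direction `axis`.
.rotate_about_axis <- function(P, origin, axis, theta_deg) {
  th <- theta_deg * pi / 180
  k <- .unit(axis)
  t(apply(P, 1, function(p) {
    v <- p - origin
    v_rot <- v * cos(th) + .cross(k, v) * sin(th) + k * sum(k * v) * (1 - cos(th))
    origin + v_rot
  }))
}

#' Sample histidine chi2 rotamers to improve imidazole orientation
#'
#' Greedily explores joint rotations of the imidazole ring(s) about the
#' CB-CG axis in 15-degree increments (proposals of -step/0/+step per His
#' each round), re-selecting the coordinating nitrogen and re-refining the
#' ion position for every new configuration, and keeping the configuration
#' with the lowest imidazole-angle score.  The search stops when the
#' cumulative rotation of every His reaches +/- span, when a round proposes
#' no unvisited configuration, or when no proposal improves the score.
#' At most the four His nearest the ion are sampled.
#'
#' @param residues Binding-residue list of the site (sorted order).
#' @param placement Current `PlacementResult`.
#' @param step Rotation increment (degrees).
#' @param span Maximum cumulative rotation per His (degrees).
#' @return List: `residues` (possibly with rotated His ring atoms),
#'   `placement` (re-refined), `angles` (per-His angle list), `score`
#'   (imidazole-angle score), `n_evaluations`.
#' @export
sample_his_rotamers <- function(residues, placement, step = 15, span = 180) {
  his_idx <- which(vapply(residues, function(r) r$res_type == "HIS", TRUE))
  if (length(his_idx) == 0L) {
    ang <- list()
    return(list(residues = residues, placement = placement, angles = ang,
                score = NA_real_, n_evaluations = 0L))
  }
  if (length(his_idx) > 4L) {
    dists <- vapply(his_idx, function(i)
      .vnorm(residues[[i]]$bp - placement$zinc_coord), 0)
    his_idx <- his_idx[order(dists)][1:4]
  }
  h <- length(his_idx)
  ring_names <- c("ND1", "CD2", "CE1", "NE2")

  apply_rotation <- function(res_list, angles_vec) {
    for (j in seq_len(h)) {
      if (angles_vec[j] == 0) next
      r <- res_list[[his_idx[j]]]
      cb <- .atom_coord(r, "CB"); cg <- .atom_coord(r, "CG")
      if (is.null(cb) || is.null(cg)) next
      sel <- r$atoms$atom %in% ring_names
      P <- as.matrix(r$atoms[sel, c("x", "y", "z")])
      P2 <- .rotate_about_axis(P, cg, cg - cb, angles_vec[j])
      r$atoms[sel, c("x", "y", "z")] <- P2
      # refresh cached binding point
      r$bp <- tryCatch(binding_point(r), error = function(e) r$bp)
      res_list[[his_idx[j]]] <- r
    }
    res_list
  }

  evaluate <- function(res_list, start) {
    chosen <- select_binding_atoms(res_list, start)
    # intermediate proposals may fail to converge; only the configuration
    # finally selected warrants a warning (flag kept on the result)
    pl <- withCallingHandlers(
      refine_zinc_position(chosen, start),
      warning = function(w) {
        if (grepl("did not converge", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    ang <- .site_his_angles(res_list, chosen, pl$zinc_coord)
    sc <- his_angles_score(vapply(ang, `[[`, 0, "alpha"),
                           vapply(ang, `[[`, 0, "beta"))
    list(placement = pl, angles = ang, score = sc)
  }

  base <- evaluate(residues, placement$zinc_coord)
  cur_state <- rep(0, h)
  visited <- new.env(parent = emptyenv())
  assign(paste(cur_state, collapse = ","), TRUE, envir = visited)
  best <- list(state = cur_state, residues = residues, eval = base)
  n_eval <- 1L

  deltas <- as.matrix(expand.grid(rep(list(c(-step, 0, step)), h)))
  repeat {
    improved <- FALSE
    any_new <- FALSE
    round_best <- NULL
    for (k in seq_len(nrow(deltas))) {
      cand_state <- best$state + deltas[k, ]
      if (any(abs(cand_state) > span)) next
      key <- paste(cand_state, collapse = ",")
      if (exists(key, envir = visited, inherits = FALSE)) next
      assign(key, TRUE, envir = visited)
      any_new <- TRUE
      res_cand <- apply_rotation(residues, cand_state)
      ev <- evaluate(res_cand, best$eval$placement$zinc_coord)
      n_eval <- n_eval + 1L
      if (is.null(round_best) || ev$score < round_best$eval$score) {
        round_best <- list(state = cand_state, residues = res_cand, eval = ev)
      }
    }
    if (!any_new) break
    if (!is.null(round_best) && round_best$eval$score < best$eval$score) {
      best <- round_best
      improved <- TRUE
    }
    if (!improved) break
  }
  if (!isTRUE(best$eval$placement$converged)) {
    warning("selected rotamer configuration: ion placement did not converge")
  }
  list(residues = best$residues, placement = best$eval$placement,
       angles = best$eval$angles, score = best$eval$score,
       n_evaluations = n_eval)
}
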