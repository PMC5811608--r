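# Solvent-accessible surface areas by the Shrake-Rupley sphere-point method.

# Near-uniform unit sphere points via the golden-spiral (Fibonacci) lattice.
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area per atom (Shrake-Rupley)
#'
#' Rolls a probe sphere over the structure: each atom's accessible area is
#' the fraction of `n_sphere_points` test points on its expanded sphere
#' (radius vdW + probe) not buried inside any neighbour's expanded sphere,
#' times the full sphere area.
#'
#' @param model A [structure_model()].
#' @param probe Probe radius in Angstrom (default 1.4, a water molecule).
#' @param n_sphere_points Test points per atom (default 960).
#' @param subset Optional logical/integer index of atoms to evaluate (the
#'   whole structure still occludes).
#' @return Numeric vector of per-atom areas in Angstrom^2 (for `subset`
#'   atoms when given); `sum()` of it is the total SASA.
#' @export
sasa <- function(model, probe = 1.4, n_sphere_points = 960, subset = NULL) {
  at <- model$atoms
  xyz <- atom_xyz(model)
  rr <- at$radius + probe
  n <- nrow(xyz)
  idx <- if (is.null(subset)) seq_len(n) else seq_len(n)[subset]
  sp <- sphere_points(n_sphere_points)
  out <- numeric(length(idx))
  max_rr <- max(rr)
  for (q in seq_along(idx)) {
    i <- idx[q]
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (rr + rr[i])^2 & d2 > 0)
    pts <- sweep(sp * rr[i], 2, xyz[i, ], "+")
    if (length(nb)) {
      free <- rep(TRUE, n_sphere_points)
      for (j in nb) {
        if (!any(free)) break
        dj2 <- rowSums(sweep(pts[free, , drop = FALSE], 2, xyz[j, ])^2)
        free[free] <- dj2 > rr[j]^2
      }
      frac <- sum(free) / n_sphere_points
    } else frac <- 1
    out[q] <- frac * 4 * pi * rr[i]^2
  }
  out
}

#' Buried surface area between two residue groups
#'
#' Total accessible area lost when the two groups are in contact:
#' \deqn{BSA = SASA(A) + SASA(B) - SASA(A \cup B)}
#' evaluated with each group extracted in isolation. This is the
#' two-sided (total) convention; the one-sided value per group is also
#' returned. The kringle-1 / protease-domain interface of closed
#' prothrombin buries about 1253 A^2 by this measure.
#'
#' @param model A [structure_model()].
#' @param group_a,group_b Residue ranges (2-vectors) or explicit residue
#'   number vectors; must not overlap.
#' @param probe,n_sphere_points Passed to [sasa()].
#' @return List: `bsa` (total, A^2), `buried_a`, `buried_b` (one-sided),
#'   `sasa_a`, `sasa_b`, `sasa_ab`.
#' @export
buried_surface_area <- function(model, group_a, group_b, probe = 1.4,
                                n_sphere_points = 960) {
  expand <- function(g) if (length(g) == 2) seq(g[1], g[2]) else g
  ra <- expand(group_a); rb <- expand(group_b)
  if (length(intersect(ra, rb)))
    stop_config("residue groups overlap")
  sel_a <- model$atoms$resno %in% ra
  sel_b <- model$atoms$resno %in% rb
  if (!any(sel_a) || !any(sel_b))
    stop_config("a residue group selects no atoms")
  sub <- function(sel) structure_model(model$atoms[sel, , drop = FALSE],
                                       model$domains)
  m_a <- sub(sel_a); m_b <- sub(sel_b); m_ab <- sub(sel_a | sel_b)
  s_a <- sum(sasa(m_a, probe, n_sphere_points))
  s_b <- sum(sasa(m_b, probe, n_sphere_points))
  ab <- sasa(m_ab, probe, n_sphere_points)
  in_a <- m_ab$atoms$resno %in% ra
  s_ab <- sum(ab)
  list(bsa = s_a + s_b - s_ab,
       buried_a = s_a - sum(ab[in_a]),
       buried_b = s_b - sum(ab[!in_a]),
       sasa_a = s_a, sasa_b = s_b, sasa_ab = s_ab)
}
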