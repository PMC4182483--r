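# Shared in-code fixtures: tiny PDB texts and toy templates.

pdb_atom_line <- function(serial, name, resid, chain, resno, x, y, z,
                          occ = 1, alt = " ", icode = " ", elesy = NULL) {
  if (is.null(elesy)) elesy <- substr(gsub("[0-9]", "", name), 1, 1)
  sprintf("ATOM  %5d %s%s%-3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial,
          ifelse(nchar(name) >= 4, substr(name, 1, 4),
                 sprintf(" %-3s", name)),
          alt, resid, chain, resno, icode, x, y, z, occ, 0, elesy)
}

# One serine residue (N, CA, CB, OG): the minimal parse fixture.
ser_pdb_text <- function() {
  c(pdb_atom_line(1, "N",  "SER", "A", 1, 0.000, 0.000, 0.000),
    pdb_atom_line(2, "CA", "SER", "A", 1, 1.458, 0.000, 0.000),
    pdb_atom_line(3, "CB", "SER", "A", 1, 2.000, 1.400, 0.000),
    pdb_atom_line(4, "OG", "SER", "A", 1, 2.100, 2.500, 0.500),
    "END")
}

# A toy template with hand-placed coordinates and given one-letter types.
toy_template <- function(types = c("E", "D", "K"), id = "TOY",
                         shift = 0, family = id) {
  n <- length(types)
  ca <- cbind(seq_len(n) * 7, rep(0, n), rep(0, n)) + shift
  fa <- ca + cbind(rep(0, n), rep(3, n), seq_len(n))
  pts <- data.frame(chain = "A", resno = seq_len(n) * 10L, icode = "",
                    aa = types,
                    ca_x = ca[, 1], ca_y = ca[, 2], ca_z = ca[, 3],
                    fa_x = fa[, 1], fa_y = fa[, 2], fa_z = fa[, 3],
                    fa_atom = "XX", fa_present = TRUE,
                    stringsAsFactors = FALSE)
  class(pts) <- c("residue_points", "data.frame")
  sitematch:::new_template(id, pts, source_structure = id, family_id = family)
}

# Apply a rigid rotation + translation to a template's coordinates.
transform_template <- function(t, angle = 0.7, axis = c(0, 0, 1),
                               shift = c(5, -3, 2), id = t$template_id) {
  axis <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + s_ * K + (1 - c_) * (K %*% K)
  pts <- t$points
  ca <- as.matrix(pts[, c("ca_x", "ca_y", "ca_z")]) %*% t(R)
  fa <- as.matrix(pts[, c("fa_x", "fa_y", "fa_z")]) %*% t(R)
  pts[, c("ca_x", "ca_y", "ca_z")] <- sweep(ca, 2, shift, `+`)
  pts[, c("fa_x", "fa_y", "fa_z")] <- sweep(fa, 2, shift, `+`)
  sitematch:::new_template(id, pts, source_structure = t$source_structure,
                           family_id = t$family_id)
}

# Independent superposition oracle: direct minimization over Euler angles
# (multiple starts), no SVD.
rmsd_rotation_oracle <- function(a, b) {
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  rot_euler <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(ang) {
    sqrt(sum((ac - bc %*% t(rot_euler(ang)))^2) / nrow(a))
  }
  starts <- as.matrix(expand.grid(seq(0, 2 * pi, length.out = 5)[-5],
                                  seq(0, pi, length.out = 4),
                                  seq(0, 2 * pi, length.out = 5)[-5]))
  best <- Inf
  for (i in seq_len(nrow(starts))) {
    r <- stats::optim(starts[i, ], obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    if (r$value < best) best <- r$value
  }
  best
}

# Independent enumeration oracle: full Cartesian product, then filter
# distinctness.
enumeration_oracle <- function(cands) {
  grid <- do.call(expand.grid, rev(cands))
  grid <- as.matrix(grid[, rev(seq_along(cands)), drop = FALSE])
  keep <- apply(grid, 1, function(r) !anyDuplicated(r))
  sum(keep)
}
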