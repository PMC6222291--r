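# Shared helpers: deterministic random rotations and small PDB fixtures
# written on the fly.

randomRotation <- function() {
  # uniform-ish random proper rotation from a random axis/angle
  axis <- stats::rnorm(3)
  rotationAboutAxis(axis, stats::runif(1, 0, 360))
}

# apply a rigid transform (rotation about origin + translation) to all
# models of a structure, returning a new structure
transformStructure <- function(structure, R, t = c(0, 0, 0)) {
  coords <- lapply(seq_len(nModels(structure)), function(i)
    sweep(modelCoords(structure, i) %*% t(R), 2L, -as.numeric(t)))
  proteinStructure(identifier(structure), atomData(structure), coords)
}

transformMembrane <- function(membrane, R, t = c(0, 0, 0)) {
  membraneModel(as.numeric(R %*% membraneCenter(membrane)) + t,
                as.numeric(R %*% membraneNormal(membrane)),
                membraneThickness(membrane))
}

writeMiniPdb <- function(path, lines) {
  writeLines(c(lines, "END"), path)
  path
}

pdbAtomLine <- function(serial, name, resn, chain, resno, x, y, z,
                        record = "ATOM") {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00",
          record, serial, name, "", resn, chain, resno, "", x, y, z)
}

# independent numerical-minimization oracle for the optimal superposition
# RMSD: optimises Euler angles + translation with stats::optim
rmsdOracle <- function(mobile, reference) {
  rotFromEuler <- function(e) {
    rotationAboutAxis(c(0, 0, 1), e[1] * 180 / pi) %*%
      rotationAboutAxis(c(0, 1, 0), e[2] * 180 / pi) %*%
      rotationAboutAxis(c(1, 0, 0), e[3] * 180 / pi)
  }
  obj <- function(par) {
    R <- rotFromEuler(par[1:3])
    moved <- sweep(mobile %*% t(R), 2L, -par[4:6])
    sqrt(mean(rowSums((moved - reference)^2)))
  }
  best <- Inf
  for (start in list(rep(0, 6), c(pi / 2, 0.3, -0.4, 0, 0, 0),
                     c(-1, 1.2, 2.5, 1, -1, 1))) {
    fit <- stats::optim(start, obj, method = "BFGS",
                        control = list(maxit = 2000, reltol = 1e-14))
    fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-15))
    best <- min(best, fit$value)
  }
  best
}
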