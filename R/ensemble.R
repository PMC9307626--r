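# Bondi van der Waals radii (Angstrom); unknown elements fall back to 1.7
# with a warning.
.bondiRadii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
                 P = 1.80, S = 1.80, CL = 1.75, BR = 1.85, I = 1.98,
                 MG = 1.73, ZN = 1.39, K = 2.75, NA. = 2.27)

.vdwRadius <- function(elements, table = .bondiRadii) {
  el <- toupper(trimws(elements))
  el[el == "NA"] <- "NA."
  r <- unname(table[el])
  if (anyNA(r)) {
    warning("unknown element(s) ",
            paste(unique(elements[is.na(r)]), collapse = ", "),
            "; using 1.7 A van der Waals radius")
    r[is.na(r)] <- 1.7
  }
  r
}

#' Specification of a sphere-seeded volume grid
#'
#' Defines the inclusion region (the union of spheres centred on the seed
#' points, by default nascent-chain Calpha positions) and the exclusion
#' rule (grid points too close to a structure atom) for
#' [tunnelVolume()]. The defaults follow the tunnel-volume protocol:
#' 20 A spheres, 2.0 A grid spacing, 1.09 A distance cutoff.
#'
#' @param seedPoints numeric matrix (n x 3) of sphere centres, Angstrom.
#' @param sphereRadius inclusion sphere radius, Angstrom.
#' @param gridSpacing cubic grid pitch, Angstrom.
#' @param distanceCutoff exclusion padding, Angstrom.
#' @param mode `"vdw"` removes grid points within (vdW radius +
#'   `distanceCutoff`) of an atom centre; `"center"` uses the plain
#'   centre distance `distanceCutoff` without vdW radii.
#' @param vdwTable named vector of van der Waals radii by element.
#' @return list of class `"VolumeGridSpec"`.
#' @examples
#' volumeGridSpec(matrix(0, 1, 3))
#' @export
volumeGridSpec <- function(seedPoints, sphereRadius = 20, gridSpacing = 2.0,
                           distanceCutoff = 1.09, mode = c("vdw", "center"),
                           vdwTable = .bondiRadii) {
  seedPoints <- as.matrix(seedPoints)
  if (!nrow(seedPoints) || ncol(seedPoints) != 3)
    stop("seedPoints must be a non-empty n x 3 matrix", call. = FALSE)
  if (gridSpacing <= 0 || sphereRadius <= gridSpacing)
    stop("need gridSpacing > 0 and sphereRadius > gridSpacing",
         call. = FALSE)
  structure(list(seedPoints = seedPoints, sphereRadius = sphereRadius,
                 gridSpacing = gridSpacing, distanceCutoff = distanceCutoff,
                 mode = match.arg(mode), vdwTable = vdwTable),
            class = "VolumeGridSpec")
}

.volumeGrid <- function(spec) {
  lo <- apply(spec$seedPoints, 2, min) - spec$sphereRadius
  hi <- apply(spec$seedPoints, 2, max) + spec$sphereRadius
  ax <- lapply(1:3, function(d) seq(lo[d], hi[d], by = spec$gridSpacing))
  grid <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]],
                                KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- NULL
  keep <- cppAnyWithin(grid, spec$seedPoints, spec$sphereRadius)
  grid[keep, , drop = FALSE]
}

#' Effective volume enclosed by seeded spheres after atom exclusion
#'
#' Lays a cubic grid over the bounding box of the seed spheres, keeps
#' points within the sphere radius of any seed point, deletes points
#' closer to any structure atom than its van der Waals radius plus the
#' distance cutoff (or the plain centre distance in `"center"` mode), and
#' returns the retained count times the grid-cell volume. With an empty
#' atom set the unoccluded union volume is returned with a warning.
#'
#' @param atoms data.frame with columns `x`, `y`, `z` and optionally
#'   `element` (defaults to carbon radii), e.g. from [atomFrame()]; or a
#'   numeric n x 3 matrix.
#' @param spec a [volumeGridSpec()].
#' @return volume in cubic Angstrom.
#' @examples
#' spec <- volumeGridSpec(matrix(0, 1, 3))
#' tunnelVolume(data.frame(x = numeric(), y = numeric(), z = numeric()),
#'              spec) # ~ 4/3 pi 20^3
#' @export
tunnelVolume <- function(atoms, spec) {
  stopifnot(inherits(spec, "VolumeGridSpec"))
  if (is.matrix(atoms)) atoms <- data.frame(x = atoms[, 1], y = atoms[, 2],
                                            z = atoms[, 3])
  grid <- .volumeGrid(spec)
  if (!nrow(atoms)) {
    warning("empty atom set: returning the unoccluded sphere-union volume")
    return(nrow(grid) * spec$gridSpacing^3)
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  alive <- rep(TRUE, nrow(grid))
  if (spec$mode == "center") {
    alive <- !cppAnyWithin(grid, xyz, spec$distanceCutoff)
  } else {
    el <- if (is.null(atoms$element)) rep("C", nrow(atoms)) else
      atoms$element
    rad <- .vdwRadius(el, spec$vdwTable)
    for (r in unique(rad)) {
      sub <- xyz[rad == r, , drop = FALSE]
      hit <- cppAnyWithin(grid[alive, , drop = FALSE], sub,
                          r + spec$distanceCutoff)
      alive[alive] <- !hit
    }
  }
  sum(alive) * spec$gridSpacing^3
}

#' Tunnel-volume difference between two structures on a shared grid
#'
#' Both volumes are evaluated on the identical grid defined by the single
#' `spec` (same seeds and spacing), so the difference isolates the effect
#' of the structural change.
#'
#' @param mutantAtoms,wtAtoms atom tables as in [tunnelVolume()].
#' @param spec the shared [volumeGridSpec()].
#' @return `volume(mutant) - volume(wt)` in cubic Angstrom.
#' @export
volumeDifference <- function(mutantAtoms, wtAtoms, spec) {
  stopifnot(inherits(spec, "VolumeGridSpec"))
  tunnelVolume(mutantAtoms, spec) - tunnelVolume(wtAtoms, spec)
}

#' Atom table of one ensemble frame
#'
#' @param ens a [StructureEnsemble-class].
#' @param frame frame index.
#' @param heavyOnly drop hydrogens?
#' @return data.frame with `x`, `y`, `z`, `element`, `role`, `resno`,
#'   `name`.
#' @export
atomFrame <- function(ens, frame = 1L, heavyOnly = TRUE) {
  xyz <- frameCoords(ens, frame)
  df <- data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   element = ens@atoms$element, role = ens@atoms$role,
                   resno = ens@atoms$resno, name = ens@atoms$name,
                   stringsAsFactors = FALSE)
  if (heavyOnly) df <- df[toupper(df$element) != "H", ]
  df
}

#' Nascent-chain contact frequencies across an ensemble
#'
#' For every nascent-chain residue and every ribosomal component (chain
#' role other than `"NC"`), the percentage of frames in which any
#' heavy-atom pair is closer than the cutoff. Hydrogens are ignored by
#' default since deposited structures may lack them.
#'
#' @param ens a [StructureEnsemble-class] with at least one `"NC"` atom.
#' @param cutoff heavy-atom contact distance, Angstrom (4.5 by default, a
#'   common heavy-atom contact convention).
#' @param partners optional character vector restricting the components.
#' @param includeHydrogens include hydrogen atoms in the distance checks?
#' @return data.frame with columns `nc_residue`, `component`, `frequency`
#'   (percent of frames).
#' @examples
#' ens <- simulateEnsemble(ensembleSpec(nFrames = 5, ncLength = 6))
#' head(contactFrequencies(ens))
#' @export
contactFrequencies <- function(ens, cutoff = 4.5, partners = NULL,
                               includeHydrogens = FALSE) {
  stopifnot(is(ens, "StructureEnsemble"))
  at <- ens@atoms
  heavy <- if (includeHydrogens) rep(TRUE, nrow(at)) else
    toupper(at$element) != "H"
  ncIdx <- which(at$role == "NC" & heavy)
  if (!length(ncIdx))
    stop("no nascent-chain (role 'NC') atoms present", call. = FALSE)
  comps <- setdiff(unique(at$role), "NC")
  if (!is.null(partners)) comps <- intersect(comps, partners)
  resnos <- sort(unique(at$resno[ncIdx]))
  nf <- nFrames(ens)
  counts <- matrix(0L, length(resnos), length(comps),
                   dimnames = list(resnos, comps))
  for (f in seq_len(nf)) {
    xyz <- ens@coords[, , f, drop = TRUE]
    for (ci in seq_along(comps)) {
      pIdx <- which(at$role == comps[ci] & heavy)
      if (!length(pIdx)) next
      hit <- cppAnyWithin(xyz[ncIdx, , drop = FALSE],
                          xyz[pIdx, , drop = FALSE], cutoff)
      res <- unique(at$resno[ncIdx][hit])
      counts[match(res, resnos), ci] <- counts[match(res, resnos), ci] + 1L
    }
  }
  out <- expand.grid(nc_residue = resnos, component = comps,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$frequency <- 100 * as.vector(counts) / nf
  out
}

#' S2 order parameters of backbone carbonyl bond vectors
#'
#' For each nascent-chain residue carrying both atoms of the bond vector
#' (C -> O by default) in every frame, the generalised order parameter is
#' computed from the second moments of the unit vector u over frames:
#' `S2 = (3 (<x2>^2 + <y2>^2 + <z2>^2 + 2<xy>^2 + 2<xz>^2 + 2<yz>^2) - 1) / 2`.
#' The frame of reference is fixed (the ribosome is frozen across
#' frames), so no alignment is performed. S2 is 1 for a rigid vector and
#' tends to 0 for isotropic reorientation.
#'
#' @param ens a [StructureEnsemble-class].
#' @param vector length-2 character, the atom names spanning the bond
#'   (from, to).
#' @return data.frame with columns `residue` and `s2`. Residues missing
#'   either atom are skipped with a warning.
#' @examples
#' ens <- simulateEnsemble(ensembleSpec(nFrames = 10, ncLength = 6,
#'   mobility = rep(0, 6)))
#' orderParameters(ens)$s2 # all 1
#' @export
orderParameters <- function(ens, vector = c("C", "O")) {
  stopifnot(is(ens, "StructureEnsemble"), length(vector) == 2L)
  at <- ens@atoms
  ncRes <- sort(unique(at$resno[at$role == "NC"]))
  skipped <- integer(0)
  out <- data.frame(residue = integer(0), s2 = numeric(0))
  for (r in ncRes) {
    iFrom <- which(at$role == "NC" & at$resno == r & at$name == vector[1])
    iTo <- which(at$role == "NC" & at$resno == r & at$name == vector[2])
    if (length(iFrom) != 1L || length(iTo) != 1L) {
      skipped <- c(skipped, r)
      next
    }
    v <- ens@coords[iTo, , , drop = TRUE] - ens@coords[iFrom, , , drop = TRUE]
    v <- if (is.null(dim(v))) matrix(v, nrow = 3) else v  # 3 x nFrames
    u <- sweep(v, 2, sqrt(colSums(v^2)), "/")
    m <- tcrossprod(u) / ncol(u)  # 3x3 matrix of <u_a u_b>
    s2 <- (3 * (m[1, 1]^2 + m[2, 2]^2 + m[3, 3]^2 +
                  2 * m[1, 2]^2 + 2 * m[1, 3]^2 + 2 * m[2, 3]^2) - 1) / 2
    out <- rbind(out, data.frame(residue = r, s2 = s2))
  }
  if (length(skipped))
    warning("residue(s) without a complete bond vector skipped: ",
            paste(skipped, collapse = ", "))
  out
}

#' Write an ensemble as a multi-model PDB file
#'
#' Standard fixed-column ATOM records inside MODEL/ENDMDL blocks; model
#' numbers define the frame order.
#'
#' @param ens a [StructureEnsemble-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEnsemblePdb <- function(ens, path) {
  stopifnot(is(ens, "StructureEnsemble"))
  at <- ens@atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nFrames(ens))) {
    xyz <- ens@coords[, , f, drop = TRUE]
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf(
      "ATOM  %5d  %-3s%4s%2s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      at$eleno, at$name, at$resname, at$chain, at$resno,
      xyz[, 1], xyz[, 2], xyz[, 3], at$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a (multi-model) PDB file into a StructureEnsemble
#'
#' Parsed with `bio3d`; MODEL numbers define the frame order. Chain roles
#' (nascent chain vs ribosomal components) are assigned from the
#' chain-to-role map.
#'
#' @param path PDB file path.
#' @param roles named character vector mapping chain identifiers to roles
#'   (e.g. `c(N = "NC", W = "rRNA:wall")`); unmapped chains keep their
#'   chain id as role, with a warning.
#' @return A [StructureEnsemble-class].
#' @export
readEnsemblePdb <- function(path, roles = NULL) {
  p <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- p$atom
  nAtoms <- nrow(at)
  xyz <- p$xyz
  nf <- nrow(xyz)
  coords <- array(NA_real_, c(nAtoms, 3L, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  role <- at$chain
  if (!is.null(roles)) {
    known <- at$chain %in% names(roles)
    role[known] <- unname(roles[at$chain[known]])
    if (!all(known))
      warning("chain(s) without a role mapping: ",
              paste(unique(at$chain[!known]), collapse = ", "))
  }
  atoms <- data.frame(eleno = at$eleno, name = at$elety, resno = at$resno,
                      resname = at$resid, chain = at$chain,
                      element = at$elesy, role = role,
                      stringsAsFactors = FALSE)
  new("StructureEnsemble", atoms = atoms, coords = coords)
}
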