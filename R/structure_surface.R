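# Structural comparison and surface analysis: PDB parsing, Kabsch
# superposition of paired alpha carbons, unaligned-residue detection,
# Shrake-Rupley solvent-accessible surface area with a deterministic
# spiral point set, surface-residue selection and surface group counts.

#' Construct a structure model from an atom table
#'
#' @param atoms Data.frame with columns \code{resno}, \code{resname},
#'   \code{atom}, \code{element}, \code{x}, \code{y}, \code{z}.
#' @param radii Named per-element radius table in Angstrom (Bondi van der
#'   Waals set by default).
#' @return A \code{structure_model}.
#' @export
structure_model <- function(atoms, radii = ELEMENT_RADIUS) {
  need <- c("resno", "resname", "atom", "element", "x", "y", "z")
  stopifnot(all(need %in% names(atoms)))
  if (nrow(atoms) == 0) stop("structure has no atoms", call. = FALSE)
  if (is.unsorted(atoms$resno)) {
    stop("residue indices must be non-decreasing", call. = FALSE)
  }
  r <- radii[toupper(atoms$element)]
  r[is.na(r)] <- ELEMENT_RADIUS_DEFAULT
  atoms$radius <- as.numeric(r)
  stopifnot(all(atoms$radius > 0))
  structure(list(atoms = atoms), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: %d atoms, %d residues\n",
              nrow(x$atoms), length(unique(x$atoms$resno))))
  invisible(x)
}

#' Read a protein structure from a PDB file
#'
#' ATOM and HETATM records are parsed via bio3d; waters are dropped and
#' alternate locations are resolved to the highest-occupancy conformer.
#'
#' @param path Path to a PDB file.
#' @param keep_hetatm Keep non-water HETATM records (default FALSE).
#' @return A \code{structure_model}.
#' @export
read_structure <- function(path, keep_hetatm = FALSE) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  at <- at[at$resid != "HOH", , drop = FALSE]
  if (!keep_hetatm) at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in ", path, call. = FALSE)
  # resolve altLoc: keep the highest-occupancy conformer per atom slot
  alt <- at$alt
  alt[is.na(alt)] <- ""
  if (any(nzchar(alt))) {
    key <- paste(at$chain, at$resno, at$insert, at$elety)
    occ <- at$o
    occ[is.na(occ)] <- 1
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(idx) {
      idx[which.max(occ[idx])]
    }), use.names = FALSE)
    at <- at[sort(keep), , drop = FALSE]
  }
  element <- at$elesy
  bad <- is.na(element) | !nzchar(trimws(element))
  element[bad] <- substr(trimws(at$elety[bad]), 1, 1)
  structure_model(data.frame(
    resno = at$resno, resname = at$resid, atom = trimws(at$elety),
    element = trimws(element), x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE))
}

#' Least-squares rigid superposition of paired coordinates
#'
#' Optimal rotation by the orthogonal-Procrustes (Kabsch) solution with
#' reflection excluded, plus translation, over >= 3 paired points.
#'
#' @param mobile,target Paired coordinate matrices (n x 3, same n >= 3),
#'   e.g. alpha carbons.
#' @return A \code{superposition}: list with \code{rotation} (3 x 3,
#'   applied as \code{x \%*\% rotation}), \code{translation}, \code{rmsd},
#'   \code{distances} (per-pair post-superposition Euclidean distances) and
#'   \code{fitted} (transformed mobile coordinates).
#' @export
superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile)
  target <- as.matrix(target)
  if (nrow(mobile) != nrow(target)) stop("unequal pair counts",
                                         call. = FALSE)
  if (nrow(mobile) < 3) stop("need >= 3 pairs", call. = FALSE)
  cm <- colMeans(mobile)
  ct <- colMeans(target)
  a <- sweep(mobile, 2, cm)
  b <- sweep(target, 2, ct)
  sv_a <- svd(a)$d
  if (sv_a[2] < 1e-9 * max(sv_a[1], 1)) {
    warning("degenerate (collinear) mobile configuration", call. = FALSE)
  }
  h <- t(a) %*% b
  sv <- svd(h)
  d <- sign(det(sv$u) * det(sv$v))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- sweep(a %*% rot, 2, ct, `+`)
  dists <- sqrt(rowSums((fitted - target)^2))
  structure(list(rotation = rot, translation = ct - as.numeric(cm %*% rot),
                 rmsd = sqrt(mean(dists^2)), distances = dists,
                 fitted = fitted),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition over %d pairs: RMSD %.3f A\n",
              length(x$distances), x$rmsd))
  invisible(x)
}

# Needleman-Wunsch global alignment (match/mismatch/gap = 1/-1/-2) used to
# pair residues for superposition when explicit pairs are not supplied.
align_pairs_nw <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  score <- matrix(0, n + 1, m + 1)
  score[, 1] <- gap * (0:n)
  score[1, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (a[i] == b[j]) match else mismatch
      score[i + 1, j + 1] <- max(score[i, j] + s, score[i, j + 1] + gap,
                                 score[i + 1, j] + gap)
    }
  }
  pairs <- matrix(0L, 0, 2)
  i <- n; j <- m
  while (i > 0 && j > 0) {
    s <- if (a[i] == b[j]) match else mismatch
    if (score[i + 1, j + 1] == score[i, j] + s) {
      pairs <- rbind(c(i, j), pairs)
      i <- i - 1; j <- j - 1
    } else if (score[i + 1, j + 1] == score[i, j + 1] + gap) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  pairs
}

#' Superpose two structures on their paired alpha carbons
#'
#' Pairs residues either explicitly or through a global sequence alignment
#' of the one-letter CA sequences (match/mismatch/gap = 1/-1/-2), then runs
#' [superpose()].
#'
#' @param mobile,target \code{structure_model}s with CA atoms.
#' @param pairs Optional integer matrix (k x 2) of paired residue numbers
#'   (mobile, target); aligned automatically when NULL.
#' @return A \code{superposition} with an extra \code{pairs} element of
#'   paired residue numbers.
#' @export
superpose_structures <- function(mobile, target, pairs = NULL) {
  ca_m <- ca_table(mobile)
  ca_t <- ca_table(target)
  if (is.null(pairs)) {
    ali <- align_pairs_nw(paste(ca_m$code, collapse = ""),
                          paste(ca_t$code, collapse = ""))
    pairs <- cbind(ca_m$resno[ali[, 1]], ca_t$resno[ali[, 2]])
  }
  im <- match(pairs[, 1], ca_m$resno)
  it <- match(pairs[, 2], ca_t$resno)
  if (anyNA(im) || anyNA(it)) stop("pair without CA atom", call. = FALSE)
  sup <- superpose(as.matrix(ca_m[im, c("x", "y", "z")]),
                   as.matrix(ca_t[it, c("x", "y", "z")]))
  sup$pairs <- pairs
  sup
}

ca_table <- function(structure) {
  at <- structure$atoms
  ca <- at[at$atom == "CA", , drop = FALSE]
  if (nrow(ca) == 0) stop("structure has no CA atoms", call. = FALSE)
  code <- AA_THREE_TO_ONE[toupper(ca$resname)]
  code[is.na(code)] <- "X"
  cbind(ca, code = code, stringsAsFactors = FALSE)
}

#' Split residue pairs into aligned and unaligned at a distance threshold
#'
#' @param distances Per-pair post-superposition distances (Angstrom).
#' @param threshold Distance above which (strictly) a pair counts as
#'   unaligned; default 2.0.
#' @param ids Optional pair labels (defaults to indices).
#' @return List with \code{aligned} (labels) and \code{unaligned}
#'   (data.frame of label and distance).
#' @export
unaligned_residues <- function(distances, threshold = 2.0, ids = NULL) {
  stopifnot(all(distances >= 0))
  if (is.null(ids)) ids <- seq_along(distances)
  un <- distances > threshold
  list(aligned = ids[!un],
       unaligned = data.frame(id = ids[un], distance = distances[un],
                              stringsAsFactors = FALSE, row.names = NULL))
}

# Deterministic generalized-spiral lattice on the unit sphere.
spiral_points <- function(n) {
  k <- seq_len(n)
  z <- 1 - (2 * k - 1) / n
  phi <- k * base::pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Structure-intrinsic orthonormal frame (principal axes of the atom cloud,
# signs fixed against the first off-centroid atom, right-handed via a cross
# product). Orienting the point lattice in this frame makes the
# deterministic SASA exactly invariant under rigid motion of the whole
# structure. Near-isotropic clouds fall back to the identity frame.
intrinsic_frame <- function(xyz) {
  n <- nrow(xyz)
  if (n < 3) return(diag(3))
  x <- sweep(xyz, 2, colMeans(xyz))
  eg <- eigen(crossprod(x), symmetric = TRUE)
  if (eg$values[1] < 1e-8) return(diag(3))
  v <- eg$vectors
  # fix axis signs against the atoms in their stored order (the first atom
  # with a clear projection decides), which is invariant under rigid motion
  for (j in 1:2) {
    for (i in seq_len(n)) {
      s <- sum(v[, j] * x[i, ])
      if (abs(s) > 1e-6) {
        if (s < 0) v[, j] <- -v[, j]
        break
      }
    }
  }
  v[, 3] <- c(v[2, 1] * v[3, 2] - v[3, 1] * v[2, 2],
              v[3, 1] * v[1, 2] - v[1, 1] * v[3, 2],
              v[1, 1] * v[2, 2] - v[2, 1] * v[1, 2])
  v
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Classic sphere-point SASA: each atom's solvent-expanded sphere
#' (vdW radius + probe) is sampled with a point lattice and points buried
#' in any neighbour's expanded sphere are discarded; accessible area is the
#' surviving fraction of the analytic sphere area, summed per residue.
#' The default point set is a deterministic spiral lattice so results are
#' seed-free; \code{mode = "random"} draws seeded uniform sphere points for
#' cross-checking.
#'
#' @param structure A \code{structure_model}.
#' @param probe Probe radius in Angstrom; default 1.4 (water).
#' @param n_points Sphere points per atom (>= 92); default 960.
#' @param mode \code{"spiral"} (deterministic, default) or
#'   \code{"random"}.
#' @param seed Seed for random mode.
#' @return A \code{sasa_report} data.frame with per-residue \code{resno},
#'   \code{resname}, \code{sasa} (Angstrom^2); per-atom values in the
#'   \code{atom_sasa} attribute.
#' @export
shrake_rupley_sasa <- function(structure, probe = 1.4, n_points = 960L,
                               mode = c("spiral", "random"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(probe > 0, n_points >= 92)
  at <- structure$atoms
  if (mode == "spiral") {
    pts <- spiral_points(n_points) %*%
      t(intrinsic_frame(as.matrix(at[, c("x", "y", "z")])))
  } else {
    set.seed(derive_seed(seed, "sasa"))
    v <- matrix(stats::rnorm(3 * n_points), n_points, 3)
    pts <- v / sqrt(rowSums(v^2))
  }
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rad <- at$radius + probe
  n_atoms <- nrow(at)
  atom_area <- numeric(n_atoms)
  for (i in seq_len(n_atoms)) {
    pi_pts <- sweep(pts * rad[i], 2, xyz[i, ], `+`)
    dd <- sqrt(rowSums(sweep(xyz, 2, xyz[i, ])^2))
    nb <- which(dd < rad[i] + rad & seq_len(n_atoms) != i)
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      d2 <- rowSums(sweep(pi_pts, 2, xyz[j, ])^2)
      exposed <- exposed & d2 >= rad[j]^2
      if (!any(exposed)) break
    }
    atom_area[i] <- sum(exposed) / n_points * 4 * base::pi * rad[i]^2
  }
  res_area <- tapply(atom_area, at$resno, sum)
  resno <- as.integer(names(res_area))
  resname <- at$resname[match(resno, at$resno)]
  out <- data.frame(resno = resno, resname = resname,
                    sasa = as.numeric(res_area),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "atom_sasa") <- atom_area
  class(out) <- c("sasa_report", "data.frame")
  out
}

#' Select surface residues by SASA cutoff
#'
#' @param sasa A \code{sasa_report} from [shrake_rupley_sasa()].
#' @param cutoff Residues with SASA at or above this (Angstrom^2) are
#'   surface; default 30.
#' @return Integer vector of surface residue numbers.
#' @export
surface_residues <- function(sasa, cutoff = 30) {
  stopifnot(cutoff >= 0)
  sasa$resno[sasa$sasa >= cutoff]
}

#' Side-chain group counts over surface residues
#'
#' @param structure A \code{structure_model}.
#' @param surface Integer vector of surface residue numbers (present in the
#'   structure).
#' @param table Group table; default [aa_dichotomy_table()].
#' @return Named integer vector of counts per group label.
#' @export
surface_group_composition <- function(structure, surface,
                                      table = aa_dichotomy_table()) {
  at <- structure$atoms
  missing <- setdiff(surface, at$resno)
  if (length(missing) > 0) {
    stop("surface residue(s) absent from structure: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  resname <- at$resname[match(surface, at$resno)]
  code <- AA_THREE_TO_ONE[toupper(resname)]
  if (anyNA(code)) {
    warning("skipping non-canonical residue(s): ",
            paste(unique(resname[is.na(code)]), collapse = ", "),
            call. = FALSE)
    code <- code[!is.na(code)]
  }
  vapply(table, function(g) sum(code %in% g), 0L)
}

#' Write a structure model as a minimal PDB file
#'
#' @param structure A \code{structure_model}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_structure <- function(structure, path) {
  at <- structure$atoms
  lines <- sprintf(
    "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(at)),
    ifelse(nchar(at$atom) < 4, paste0(" ", at$atom), at$atom),
    at$resname, at$resno, at$x, at$y, at$z, at$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
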