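# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: path sums walk the tree edge list directly,
# the rotation oracle grids over Euler angles, the pI oracle scans a pH
# grid, and the two-sphere SASA case uses the spherical-cap closed form.

# Leaf-to-leaf path-length matrix by breadth-first walks over the edge
# list of an ape phylo object.
brute_force_cophenetic <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- max(tree$edge)
  adj <- vector("list", nnode)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]
    b <- tree$edge[e, 2]
    w <- tree$edge.length[e]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  d <- matrix(0, ntip, ntip,
              dimnames = list(tree$tip.label, tree$tip.label))
  for (start in seq_len(ntip)) {
    dist_to <- rep(NA_real_, nnode)
    dist_to[start] <- 0
    queue <- start
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      for (k in seq_len(NROW(adj[[v]]))) {
        nb <- adj[[v]][k, 1]
        if (is.na(dist_to[nb])) {
          dist_to[nb] <- dist_to[v] + adj[[v]][k, 2]
          queue <- c(queue, nb)
        }
      }
    }
    d[start, ] <- dist_to[seq_len(ntip)]
  }
  d
}

# Best RMSD over a grid of ZYZ Euler rotations (with local refinement),
# used to validate the Kabsch solution on small toys.
rotation_grid_rmsd <- function(mobile, target, coarse = 24) {
  mob <- sweep(mobile, 2, colMeans(mobile))
  tgt <- sweep(target, 2, colMeans(target))
  rot_zyz <- function(a, b, c) {
    rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0,
                               0, 0, 1), 3, 3)
    ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0,
                               sin(t), 0, cos(t)), 3, 3)
    rz(a) %*% ry(b) %*% rz(c)
  }
  eval_rmsd <- function(ang) {
    r <- rot_zyz(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((mob %*% r - tgt)^2)))
  }
  best <- c(0, 0, 0)
  best_val <- eval_rmsd(best)
  grid <- seq(0, 2 * pi, length.out = coarse + 1)[-(coarse + 1)]
  bgrid <- seq(0, pi, length.out = coarse / 2 + 1)
  for (a in grid) for (b in bgrid) for (c in grid) {
    v <- eval_rmsd(c(a, b, c))
    if (v < best_val) {
      best_val <- v
      best <- c(a, b, c)
    }
  }
  opt <- stats::optim(best, eval_rmsd, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

# pI by exhaustive pH-grid scan at 1e-4 resolution over the same charge
# function contract (re-derived here, not calling the package internals).
grid_pi <- function(sequence) {
  pka_neg <- c(D = 4.05, E = 4.45, C = 9.00, Y = 10.00)
  pka_pos <- c(H = 5.98, K = 10.00, R = 12.00)
  nterm_tab <- c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82,
                 V = 7.44, E = 7.70)
  chars <- strsplit(sequence, "")[[1]]
  nterm <- nterm_tab[chars[1]]
  if (is.na(nterm)) nterm <- 7.5
  pos <- c(nterm, pka_pos[chars[chars %in% names(pka_pos)]])
  neg <- c(3.55, pka_neg[chars[chars %in% names(pka_neg)]])
  grid <- seq(0, 14, by = 1e-4)
  q <- vapply(grid, function(p) {
    sum(1 / (1 + 10^(p - pos))) - sum(1 / (1 + 10^(neg - p)))
  }, 0.0)
  grid[which.min(abs(q))]
}

# Total accessible area of two equal spheres (radius r, centre distance d)
# from the spherical-cap closed form: each sphere loses a cap of height
# h = r - d/2.
two_sphere_area <- function(r, d) {
  if (d >= 2 * r) return(2 * 4 * pi * r^2)
  h <- r - d / 2
  2 * (4 * pi * r^2 - 2 * pi * r * h)
}

# Random additive (tree) metric over n taxa: build a random topology with
# known branch lengths, return its path metric.
random_additive_metric <- function(n, seed) {
  set.seed(seed)
  tree <- ape::rtree(n, tip.label = paste0("t", seq_len(n)))
  tree$edge.length <- stats::runif(nrow(tree$edge), 0.2, 2)
  list(tree = tree, d = brute_force_cophenetic(tree))
}

make_toy_structure_df <- function(xyz, resname = "GLY", element = "C") {
  data.frame(resno = seq_len(nrow(xyz)), resname = resname, atom = "CA",
             element = element, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}
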