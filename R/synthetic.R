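# Synthetic benchmark generator. Emulates the statistical structure of a
# small curated laccase benchmark: a two-class (acidic / alkaline) pH
# mixture, sequences whose side-chain group composition shifts linearly
# with the label (the planted signal), class-conditional habitats, a
# docking-rank feature with missingness, ss2 profiles, and a random tree
# over all records. Labels are regenerated from the realized compositions,
# so the planted linear model is exactly true on the emitted data.

#' Synthetic benchmark configuration
#'
#' @param n_records Number of records; default 55.
#' @param seed Integer seed; every draw derives from it.
#' @param acidic_fraction Probability a record belongs to the acidic
#'   class; default 0.7 (most characterized basidiomycete laccases are
#'   acidic).
#' @param acidic_mean,acidic_sd,alkaline_mean,alkaline_sd Class-conditional
#'   pH mixture parameters; defaults 4.0/0.8 and 8.5/1.0.
#' @param beta0,beta Planted linear model: pH = beta0 + beta . (group
#'   fractions) + noise, with \code{beta} over the five side-chain groups
#'   of [aa_group_table()].
#' @param noise_sd Label noise standard deviation in pH units; default 0.5.
#' @param docking_missing_prob Probability the docking rank is missing;
#'   default 0.2.
#' @param habitat_levels Habitat vocabulary.
#' @param habitat_probs Class-conditional habitat probabilities: 2-row
#'   matrix (acidic, alkaline) x levels.
#' @param seq_len_range Sequence length range (uniform integer draw).
#' @param label_linked_branches When TRUE, terminal tree branches grow with
#'   |pH - 7| so the cophenetic filter has signal to exploit.
#' @return A \code{synthetic_config} list.
#' @export
synthetic_config <- function(n_records = 55L, seed = 1L,
                             acidic_fraction = 0.7,
                             acidic_mean = 4.0, acidic_sd = 0.8,
                             alkaline_mean = 8.5, alkaline_sd = 1.0,
                             beta0 = 2.875,
                             beta = c(acidic = -62.5, basic = 62.5,
                                      aromatic = 0, polar = 0,
                                      nonpolar = 0),
                             noise_sd = 0.5,
                             docking_missing_prob = 0.2,
                             habitat_levels = c("wood", "soil", "litter"),
                             habitat_probs = rbind(
                               acidic = c(0.5, 0.3, 0.2),
                               alkaline = c(0.2, 0.3, 0.5)),
                             seq_len_range = c(300L, 500L),
                             label_linked_branches = FALSE) {
  stopifnot(n_records >= 2, noise_sd > 0,
            acidic_fraction >= 0, acidic_fraction <= 1,
            docking_missing_prob >= 0, docking_missing_prob <= 1,
            length(beta) == 5, all(habitat_probs >= 0),
            ncol(habitat_probs) == length(habitat_levels))
  structure(list(
    n_records = as.integer(n_records), seed = as.integer(seed),
    acidic_fraction = acidic_fraction, acidic_mean = acidic_mean,
    acidic_sd = acidic_sd, alkaline_mean = alkaline_mean,
    alkaline_sd = alkaline_sd, beta0 = beta0, beta = beta,
    noise_sd = noise_sd, docking_missing_prob = docking_missing_prob,
    habitat_levels = habitat_levels, habitat_probs = habitat_probs,
    seq_len_range = as.integer(seq_len_range),
    label_linked_branches = label_linked_branches),
    class = "synthetic_config")
}

# Residue sampling probabilities whose group fractions move the planted
# linear predictor to the intended pH t. Direction u = beta / |beta|^2
# guarantees beta . g(t) = t - beta0 for any beta; within a group the
# residue probabilities scale uniformly.
composition_probs <- function(t, config) {
  groups <- aa_group_table()
  p0 <- stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
  g0 <- vapply(groups, function(g) sum(p0[g]), 0.0)
  u <- config$beta / sum(config$beta^2)
  shift <- (t - config$beta0 - sum(config$beta * g0)) * u
  g_target <- g0 + shift
  if (any(g_target < 0)) {
    stop("infeasible composition shift for beta = (",
         paste(config$beta, collapse = ", "), ") at pH ", round(t, 2),
         call. = FALSE)
  }
  p <- p0
  for (k in seq_along(groups)) {
    p[groups[[k]]] <- p0[groups[[k]]] * g_target[k] / g0[k]
  }
  p / sum(p)
}

random_ss2 <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  state <- sample(c("C", "H", "E"), n, replace = TRUE,
                  prob = c(0.45, 0.30, 0.25))
  p_win <- stats::runif(n, 0.5, 0.95)
  rest <- (1 - p_win) * stats::runif(n)
  states <- c("C", "H", "E")
  probs <- matrix(0, n, 3, dimnames = list(NULL, states))
  win_col <- match(state, states)
  other1 <- ifelse(win_col == 1, 2, 1)
  other2 <- ifelse(win_col == 3, 2, 3)
  probs[cbind(seq_len(n), win_col)] <- p_win
  probs[cbind(seq_len(n), other1)] <- rest
  probs[cbind(seq_len(n), other2)] <- 1 - p_win - rest
  prof <- data.frame(index = seq_len(n), residue = chars, state = state,
                     p_coil = probs[, "C"], p_helix = probs[, "H"],
                     p_strand = probs[, "E"], stringsAsFactors = FALSE)
  class(prof) <- c("ss2_profile", "data.frame")
  prof
}

#' Generate a synthetic labeled benchmark
#'
#' Draws class labels from the two-component pH mixture, samples each
#' sequence residue-by-residue from a composition whose group fractions
#' shift linearly with the intended label, then regenerates the label from
#' the realized group fractions through the planted linear model plus
#' Gaussian noise (clipped to \[0, 14\], with the clipping recorded).
#' Habitats are drawn class-conditionally, docking ranks are present with
#' probability 1 - missingness, ss2 profiles are sampled per sequence, and
#' a random bifurcating tree with exponential branch lengths spans all
#' records. Everything is reproducible from the config seed.
#'
#' @param config A \code{synthetic_config}.
#' @param out_dir Optional directory; when given, writes
#'   \code{sequences.fasta}, \code{metadata.csv}, \code{tree.nwk} and an
#'   \code{ss2/} directory in the formats the pipeline consumes.
#' @return A \code{laccase_benchmark}: list with \code{records}
#'   (labeled \code{protein_records}), \code{intended_ph}, \code{clipped},
#'   \code{group_fractions}, \code{ss2} (named profile list), \code{tree}
#'   (ape \code{phylo}) and \code{config}.
#' @export
generate_benchmark <- function(config = synthetic_config(),
                               out_dir = NULL) {
  set.seed(config$seed)
  n <- config$n_records
  ids <- sprintf("lac%03d", seq_len(n))
  acidic <- NULL
  for (try in 1:100) {
    acidic <- stats::runif(n) < config$acidic_fraction
    if (any(acidic) && any(!acidic)) break
  }
  if (!any(acidic) || !any(!acidic)) {
    stop("could not draw both classes", call. = FALSE)
  }
  intended <- ifelse(acidic,
                     stats::rnorm(n, config$acidic_mean, config$acidic_sd),
                     stats::rnorm(n, config$alkaline_mean,
                                  config$alkaline_sd))
  intended <- pmin(pmax(intended, 0.5), 13.5)
  lens <- sample(config$seq_len_range[1]:config$seq_len_range[2], n,
                 replace = TRUE)
  sequences <- character(n)
  gfrac <- matrix(NA_real_, n, 5,
                  dimnames = list(ids, names(aa_group_table())))
  ph <- numeric(n)
  clipped <- logical(n)
  for (i in seq_len(n)) {
    p <- composition_probs(intended[i], config)
    sequences[i] <- paste(sample(AA_ALPHABET, lens[i], replace = TRUE,
                                 prob = p), collapse = "")
    comp <- aa_composition(sequences[i])
    gfrac[i, ] <- comp[21:25]
    raw_ph <- config$beta0 + sum(config$beta * gfrac[i, ]) +
      stats::rnorm(1, 0, config$noise_sd)
    clipped[i] <- raw_ph < 0 || raw_ph > 14
    ph[i] <- min(max(raw_ph, 0), 14)
  }
  class_row <- ifelse(acidic, 1L, 2L)
  habitat <- vapply(seq_len(n), function(i) {
    sample(config$habitat_levels, 1,
           prob = config$habitat_probs[class_row[i], ])
  }, "")
  has_rank <- stats::runif(n) >= config$docking_missing_prob
  rank <- ifelse(has_rank, sample(0:10, n, replace = TRUE), NA_integer_)
  records <- protein_records(
    id = ids, sequence = sequences, species = "synthetic",
    is_mature = TRUE, habitat = habitat, docking_rank = rank,
    ph_optimum = ph)
  ss2 <- stats::setNames(lapply(sequences, random_ss2), ids)
  tree <- ape::rtree(n, tip.label = ids)
  if (config$label_linked_branches) {
    ntip <- length(tree$tip.label)
    tip_edges <- match(seq_len(ntip), tree$edge[, 2])
    tree$edge.length[tip_edges] <-
      0.1 + 0.15 * abs(ph[match(tree$tip.label, ids)] - 7)
  }
  bench <- structure(list(records = records, intended_ph = intended,
                          clipped = clipped, group_fractions = gfrac,
                          ss2 = ss2, tree = tree, config = config),
                     class = "laccase_benchmark")
  if (!is.null(out_dir)) write_benchmark(bench, out_dir)
  bench
}

#' @export
print.laccase_benchmark <- function(x, ...) {
  ph <- x$records$ph_optimum
  cat(sprintf(
    "synthetic laccase benchmark: %d records (%d acidic, %d alkaline)\n",
    nrow(x$records), sum(ph < 7), sum(ph >= 7)))
  cat(sprintf("  pH range %.2f-%.2f; %d clipped label(s)\n", min(ph),
              max(ph), sum(x$clipped)))
  invisible(x)
}

#' Write benchmark artifacts to disk
#'
#' @param bench A \code{laccase_benchmark}.
#' @param out_dir Output directory (created if needed).
#' @return \code{out_dir}, invisibly.
#' @export
write_benchmark <- function(bench, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(bench$records, file.path(out_dir, "sequences.fasta"))
  meta <- data.frame(id = bench$records$id,
                     species = bench$records$species,
                     habitat = bench$records$habitat,
                     docking_rank = bench$records$docking_rank,
                     ph_optimum = bench$records$ph_optimum,
                     cleavage_pos = NA_integer_)
  utils::write.csv(meta, file.path(out_dir, "metadata.csv"),
                   row.names = FALSE, na = "")
  ss2_dir <- file.path(out_dir, "ss2")
  dir.create(ss2_dir, showWarnings = FALSE)
  for (id in names(bench$ss2)) {
    write_ss2(bench$ss2[[id]], file.path(ss2_dir, paste0(id, ".ss2")))
  }
  ape::write.tree(bench$tree, file.path(out_dir, "tree.nwk"))
  invisible(out_dir)
}

#' Split a benchmark into training and validation sets
#'
#' Seeded random split into partitions of sizes (n - v, v), resampled (up
#' to \code{max_retries} times) until both partitions contain at least one
#' acidic (pH < 7) and one alkaline (pH >= 7) record.
#'
#' @param records Labeled \code{protein_records}.
#' @param validation_size Validation partition size; default 5.
#' @param seed Integer seed.
#' @param max_retries Bounded resampling attempts; default 100.
#' @return List with \code{train} and \code{validation} record sets.
#' @export
benchmark_split <- function(records, validation_size = 5L, seed = 1L,
                            max_retries = 100L) {
  n <- nrow(records)
  stopifnot(validation_size >= 1, validation_size < n)
  ph <- records$ph_optimum
  if (anyNA(ph)) stop("all records must be labeled", call. = FALSE)
  both_classes <- function(v) any(v < 7) && any(v >= 7)
  if (!both_classes(ph)) {
    stop("both classes must be present before splitting", call. = FALSE)
  }
  set.seed(derive_seed(seed, "split"))
  for (try in seq_len(max_retries)) {
    val_idx <- sort(sample.int(n, validation_size))
    if (both_classes(ph[val_idx]) && both_classes(ph[-val_idx])) {
      return(list(train = records[-val_idx, , drop = FALSE],
                  validation = records[val_idx, , drop = FALSE]))
    }
  }
  stop("could not satisfy the both-classes guarantee after ",
       max_retries, " retries", call. = FALSE)
}

#' Generate an ideal-geometry toy structure
#'
#' A CA-trace backbone with the standard 3.8 Angstrom consecutive spacing:
#' helical rise/twist (1.5 Angstrom, 100 degrees per residue) in helix
#' mode, a flat zigzag in extended mode. One pseudo-atom (the CA) per
#' residue; the matching random sequence is returned alongside.
#'
#' @param n_residues Number of residues (>= 3).
#' @param geometry \code{"helix"} or \code{"extended"}.
#' @param seed Integer seed for the sequence draw.
#' @return List with \code{structure} (a \code{structure_model}) and
#'   \code{sequence}.
#' @export
generate_toy_structure <- function(n_residues, geometry = c("helix",
                                                            "extended"),
                                   seed = 1L) {
  geometry <- match.arg(geometry)
  if (n_residues < 3) stop("need >= 3 residues", call. = FALSE)
  k <- seq_len(n_residues)
  if (geometry == "helix") {
    rise <- 1.5
    twist <- 100 * base::pi / 180
    radius <- sqrt((3.8^2 - rise^2) / (2 * (1 - cos(twist))))
    xyz <- cbind(radius * cos(k * twist), radius * sin(k * twist),
                 rise * k)
  } else {
    dx <- sqrt(3.8^2 - 1)
    xyz <- cbind(dx * k, (k %% 2), 0)
  }
  set.seed(derive_seed(seed, "toy-structure"))
  seq1 <- sample(AA_ALPHABET, n_residues, replace = TRUE)
  three <- names(AA_THREE_TO_ONE)[match(seq1, AA_THREE_TO_ONE)]
  atoms <- data.frame(resno = k, resname = three, atom = "CA",
                      element = "C", x = xyz[, 1], y = xyz[, 2],
                      z = xyz[, 3], stringsAsFactors = FALSE)
  list(structure = structure_model(atoms),
       sequence = paste(seq1, collapse = ""))
}
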