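# Substrate-binding residue identification (5-Angstrom ligand proximity on a
# reference structure) and projection of the reference positions through the
# MSA onto every other sequence, followed by side-chain group counting.

#' Residues with an atom near the ligand
#'
#' A residue is selected when at least one of its atoms lies strictly within
#' \code{radius} Angstrom (minimum Euclidean distance) of at least one
#' ligand atom.
#'
#' @param structure A \code{structure_model} (see [read_structure()]).
#' @param ligand_xyz Numeric matrix of ligand atom coordinates (n x 3).
#' @param radius Proximity cutoff in Angstrom; default 5.
#' @return Sorted integer vector of residue numbers.
#' @export
residues_near_ligand <- function(structure, ligand_xyz, radius = 5.0) {
  stopifnot(radius > 0)
  atoms <- structure$atoms
  if (nrow(atoms) == 0) stop("empty structure", call. = FALSE)
  ligand_xyz <- matrix(as.numeric(ligand_xyz), ncol = 3)
  if (nrow(ligand_xyz) == 0) stop("empty ligand", call. = FALSE)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  near <- logical(nrow(atoms))
  for (k in seq_len(nrow(ligand_xyz))) {
    dd <- sqrt(rowSums((xyz - matrix(ligand_xyz[k, ], nrow(xyz), 3,
                                     byrow = TRUE))^2))
    near <- near | dd < radius
  }
  sort(unique(atoms$resno[near]))
}

#' Read ligand coordinates from PDB HETATM records or an xyz CSV
#'
#' @param path Path to a PDB file (HETATM records are used) or a CSV with
#'   columns \code{x}, \code{y}, \code{z}.
#' @return Numeric matrix of coordinates (n x 3).
#' @export
read_ligand_xyz <- function(path) {
  first <- readLines(path, n = 50)
  if (any(grepl("^(HETATM|ATOM)", first))) {
    pdb <- bio3d::read.pdb(path)
    het <- pdb$atom[pdb$atom$type == "HETATM" & pdb$atom$resid != "HOH", ]
    if (nrow(het) == 0) stop("no HETATM records in ", path, call. = FALSE)
    return(as.matrix(het[, c("x", "y", "z")]))
  }
  tab <- utils::read.csv(path)
  stopifnot(all(c("x", "y", "z") %in% names(tab)))
  as.matrix(tab[, c("x", "y", "z")])
}

#' Project reference binding-site positions through an MSA
#'
#' Each reference (ungapped, 1-based) position is converted to its alignment
#' column; for every other sequence the residue occupying that column is
#' reported with its own ungapped position, or marked absent when the column
#' holds a gap.
#'
#' @param alignment Alignment matrix from [as_alignment()].
#' @param reference_id Row name of the reference sequence.
#' @param reference_positions Integer vector of ungapped positions in the
#'   reference sequence.
#' @return A \code{binding_site_map}: list with \code{reference_id},
#'   \code{reference_positions}, \code{columns} (alignment columns), and
#'   \code{sites} — a named list per sequence of data.frames with
#'   \code{position} (\code{NA} = absent) and \code{residue} per slot.
#' @export
map_reference_positions <- function(alignment, reference_id,
                                    reference_positions) {
  if (!(reference_id %in% rownames(alignment))) {
    stop("reference id not in alignment: ", reference_id, call. = FALSE)
  }
  ref_row <- alignment[reference_id, ]
  ref_cols <- which(ref_row != "-")
  reference_positions <- as.integer(reference_positions)
  if (any(reference_positions < 1 |
          reference_positions > length(ref_cols))) {
    stop("reference position outside ungapped reference length",
         call. = FALSE)
  }
  columns <- ref_cols[reference_positions]
  if (any(ref_row[columns] == "-")) {
    stop("reference position maps to a gap in the reference row",
         call. = FALSE)
  }
  sites <- lapply(rownames(alignment), function(id) {
    row <- alignment[id, ]
    ungapped_upto <- cumsum(row != "-")
    res <- row[columns]
    pos <- ifelse(res == "-", NA_integer_, ungapped_upto[columns])
    data.frame(column = columns, position = as.integer(pos),
               residue = ifelse(res == "-", NA_character_, res),
               stringsAsFactors = FALSE)
  })
  names(sites) <- rownames(alignment)
  structure(list(reference_id = reference_id,
                 reference_positions = reference_positions,
                 columns = columns, sites = sites),
            class = "binding_site_map")
}

#' Count projected binding residues per side-chain group
#'
#' Counts occurrences over the six dichotomy labels (a residue may
#' contribute to several dichotomies); absent slots contribute nothing.
#'
#' @param residues Character vector of one-letter residues (\code{NA} =
#'   absent slot).
#' @param table Group table; defaults to [aa_dichotomy_table()]. The
#'   collapsed five-class scheme of [aa_group_table()] may be supplied
#'   instead.
#' @return Named integer vector of counts, one per group label.
#' @export
binding_group_counts <- function(residues, table = aa_dichotomy_table()) {
  residues <- residues[!is.na(residues)]
  bad <- setdiff(residues, AA_ALPHABET)
  if (length(bad) > 0) {
    stop("non-canonical residue(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  vapply(table, function(g) sum(residues %in% g), 0L)
}

#' Binding group counts for every sequence of a binding-site map
#'
#' @param map A \code{binding_site_map} from [map_reference_positions()].
#' @param table Group table (see [binding_group_counts()]).
#' @return Data.frame with \code{id} plus one \code{bind_*} column per group
#'   label.
#' @export
binding_feature_table <- function(map, table = aa_dichotomy_table()) {
  rows <- lapply(names(map$sites), function(id) {
    counts <- binding_group_counts(map$sites[[id]]$residue, table)
    as.data.frame(c(list(id = id), as.list(counts)),
                  stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[-1] <- paste0("bind_", names(table))
  out
}

#' Export a binding-site map as TSV
#'
#' @param map A \code{binding_site_map}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_binding_site_map <- function(map, path) {
  rows <- do.call(rbind, lapply(names(map$sites), function(id) {
    df <- map$sites[[id]]
    data.frame(id = id, reference_position = map$reference_positions,
               column = df$column,
               position = ifelse(is.na(df$position), "ABSENT",
                                 df$position),
               residue = ifelse(is.na(df$residue), "ABSENT", df$residue),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
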