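# Sequence and metadata I/O plus preprocessing (deduplication,
# signal-peptide removal). Records are kept in a plain data.frame with one
# row per protein so downstream code can use ordinary subsetting.

#' Construct a set of protein records
#'
#' @param id Character vector of unique record identifiers.
#' @param sequence Uppercase amino-acid sequences (canonical residues plus
#'   \code{"X"}).
#' @param species Optional species tag per record.
#' @param is_mature Logical; whether the signal peptide has been removed.
#' @param habitat Optional habitat category per record.
#' @param docking_rank Optional non-negative integer docking rank
#'   (0 = docked outside the binding area); \code{NA} = missing.
#' @param ph_optimum Optional experimentally determined pH optimum in
#'   \[0, 14\]; \code{NA} = unlabeled.
#'
#' @return A \code{protein_records} data.frame.
#' @export
protein_records <- function(id, sequence, species = NA_character_,
                            is_mature = FALSE, habitat = NA_character_,
                            docking_rank = NA_integer_,
                            ph_optimum = NA_real_) {
  recs <- data.frame(
    id = as.character(id), species = as.character(species),
    sequence = toupper(as.character(sequence)),
    is_mature = as.logical(is_mature), habitat = as.character(habitat),
    docking_rank = as.integer(docking_rank),
    ph_optimum = as.numeric(ph_optimum),
    stringsAsFactors = FALSE)
  validate_protein_records(recs)
  class(recs) <- c("protein_records", "data.frame")
  recs
}

validate_protein_records <- function(recs) {
  if (anyDuplicated(recs$id)) {
    stop("duplicate record id(s): ",
         paste(unique(recs$id[duplicated(recs$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(recs$sequence))) {
    stop("empty sequence for record(s): ",
         paste(recs$id[!nzchar(recs$sequence)], collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(recs))) {
    assert_canonical(recs$sequence[i], sprintf("record '%s'", recs$id[i]),
                     allow_x = TRUE)
  }
  bad_ph <- !is.na(recs$ph_optimum) &
    (recs$ph_optimum < 0 | recs$ph_optimum > 14)
  if (any(bad_ph)) {
    stop("ph_optimum outside [0, 14] for record(s): ",
         paste(recs$id[bad_ph], collapse = ", "), call. = FALSE)
  }
  bad_rank <- !is.na(recs$docking_rank) & recs$docking_rank < 0
  if (any(bad_rank)) stop("negative docking_rank", call. = FALSE)
  invisible(recs)
}

#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased; residues outside the 20 canonical amino acids
#' plus \code{"X"} raise an error naming the record and the offending
#' character. The record id is the first whitespace-delimited token of the
#' header; any remainder is stored as the species tag.
#'
#' @param path Path to a FASTA file.
#' @return A \code{protein_records} data.frame.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  headers <- names(set)
  if (any(!nzchar(headers))) stop("malformed FASTA header", call. = FALSE)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, "", 1)
  rest <- sub("^\\S+\\s*", "", headers)
  species <- ifelse(nzchar(rest), rest, NA_character_)
  protein_records(id = ids, sequence = as.character(set), species = species)
}

#' Write protein records as FASTA (60-column wrap)
#'
#' @param records A \code{protein_records} data.frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- ifelse(is.na(records$species), records$id,
                       paste(records$id, records$species))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Remove exact-duplicate sequences
#'
#' Keeps the first occurrence of each distinct sequence; order is otherwise
#' preserved (the behaviour of a seqkit-style rmdup step).
#'
#' @param records A \code{protein_records} data.frame.
#' @return The deduplicated records.
#' @export
dedupe_sequences <- function(records) {
  records[!duplicated(records$sequence), , drop = FALSE]
}

#' Strip an N-terminal signal peptide from one record
#'
#' @param record A one-row \code{protein_records} data.frame.
#' @param cleavage_pos 1-based position of the last signal-peptide residue;
#'   the mature sequence starts at \code{cleavage_pos + 1}.
#' @return The record with the mature sequence and \code{is_mature = TRUE}.
#' @export
strip_signal_peptide <- function(record, cleavage_pos) {
  stopifnot(nrow(record) == 1)
  if (isTRUE(record$is_mature)) {
    stop(sprintf("record '%s' is already mature", record$id), call. = FALSE)
  }
  n <- nchar(record$sequence)
  cleavage_pos <- as.integer(cleavage_pos)
  if (is.na(cleavage_pos) || cleavage_pos < 1 || cleavage_pos >= n) {
    stop(sprintf(
      "cleavage_pos %s out of range [1, %d) for record '%s'",
      cleavage_pos, n, record$id), call. = FALSE)
  }
  record$sequence <- substring(record$sequence, cleavage_pos + 1L)
  record$is_mature <- TRUE
  record
}

#' Strip signal peptides for many records from a cleavage table
#'
#' @param records A \code{protein_records} data.frame.
#' @param cleavage Data.frame with columns \code{id} and \code{cleavage_pos}
#'   (e.g. from [read_metadata()]); records without an entry (or with a
#'   missing position) are returned unchanged.
#' @return Updated records.
#' @export
strip_signal_peptides <- function(records, cleavage) {
  stopifnot(all(c("id", "cleavage_pos") %in% names(cleavage)))
  for (i in seq_len(nrow(records))) {
    j <- match(records$id[i], cleavage$id)
    if (!is.na(j) && !is.na(cleavage$cleavage_pos[j])) {
      records[i, ] <- strip_signal_peptide(records[i, , drop = FALSE],
                                           cleavage$cleavage_pos[j])
    }
  }
  records
}

#' Read the tabular metadata file
#'
#' Expects a CSV with header
#' \code{id,species,habitat,docking_rank,ph_optimum,cleavage_pos};
#' empty cells are missing values.
#'
#' @param path Path to the CSV file.
#' @return A data.frame with typed columns.
#' @export
read_metadata <- function(path) {
  meta <- utils::read.csv(path, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  need <- c("id", "species", "habitat", "docking_rank", "ph_optimum",
            "cleavage_pos")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols) > 0) {
    stop("metadata lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  meta$docking_rank <- as.integer(meta$docking_rank)
  meta$ph_optimum <- as.numeric(meta$ph_optimum)
  meta$cleavage_pos <- as.integer(meta$cleavage_pos)
  meta
}

#' Attach metadata columns to protein records by id
#'
#' @param records A \code{protein_records} data.frame.
#' @param meta Metadata data.frame from [read_metadata()].
#' @return Records with habitat, docking rank and pH optimum filled in.
#' @export
merge_metadata <- function(records, meta) {
  j <- match(records$id, meta$id)
  for (col in intersect(c("species", "habitat", "docking_rank", "ph_optimum"),
                        names(meta))) {
    hit <- !is.na(j)
    records[[col]][hit] <- meta[[col]][j[hit]]
  }
  validate_protein_records(records)
  records
}

#' Read a PSIPRED ss2 secondary-structure profile
#'
#' Skips comment/header lines (leading \code{#} or blank), then parses
#' whitespace-separated rows of (index, residue, state, three state
#' probabilities). States must be C (coil), H (helix) or E (strand) and
#' indices contiguous from 1.
#'
#' @param path Path to an ss2 file.
#' @return An \code{ss2_profile} data.frame with columns \code{index},
#'   \code{residue}, \code{state}, \code{p_coil}, \code{p_helix},
#'   \code{p_strand}.
#' @export
read_ss2 <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("ss2 file has no data rows: ", path,
                               call. = FALSE)
  fields <- strsplit(lines, "\\s+")
  n_fields <- lengths(fields)
  if (any(n_fields != 6)) {
    stop("malformed ss2 row: ", lines[which(n_fields != 6)[1]],
         call. = FALSE)
  }
  m <- do.call(rbind, fields)
  prof <- data.frame(
    index = as.integer(m[, 1]), residue = m[, 2], state = m[, 3],
    p_coil = as.numeric(m[, 4]), p_helix = as.numeric(m[, 5]),
    p_strand = as.numeric(m[, 6]), stringsAsFactors = FALSE)
  if (!identical(prof$index, seq_len(nrow(prof)))) {
    stop("ss2 indices are not contiguous from 1", call. = FALSE)
  }
  bad_state <- setdiff(unique(prof$state), c("C", "H", "E"))
  if (length(bad_state) > 0) {
    stop("ss2 state outside {C, H, E}: ",
         paste(bad_state, collapse = ", "), call. = FALSE)
  }
  probs <- as.matrix(prof[, c("p_coil", "p_helix", "p_strand")])
  if (any(probs < 0 | probs > 1)) {
    stop("ss2 probability outside [0, 1]", call. = FALSE)
  }
  class(prof) <- c("ss2_profile", "data.frame")
  prof
}

#' Write an ss2 profile in PSIPRED dialect
#'
#' @param profile An \code{ss2_profile} data.frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_ss2 <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# PSIPRED VFORMAT (ss2)", con)
  writeLines("", con)
  writeLines(sprintf("%4d %s %s  %6.3f %6.3f %6.3f", profile$index,
                     profile$residue, profile$state, profile$p_coil,
                     profile$p_helix, profile$p_strand), con)
  invisible(path)
}
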