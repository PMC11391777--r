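# Per-sequence numeric features: 25-dimensional composition vector,
# theoretical molecular weight and isoelectric point, N-glycosylation sequon
# flag, secondary-structure fractions, and assembly of the encoded feature
# table (one-hot categoricals, -1 missing sentinel).

#' Amino-acid and side-chain group composition
#'
#' The 25-dimensional sequence representation: components 1-20 are relative
#' abundances of the canonical amino acids in fixed alphabetical one-letter
#' order; components 21-25 are the side-chain group fractions over the
#' disjoint five-class partition of [aa_group_table()]. Each block sums to 1.
#'
#' @param sequence Non-empty canonical amino-acid sequence.
#' @param groups Side-chain partition, a named list of residue vectors that
#'   together cover each canonical residue exactly once.
#' @return Named numeric vector of length 25.
#' @export
aa_composition <- function(sequence, groups = aa_group_table()) {
  if (!nzchar(sequence)) stop("empty sequence", call. = FALSE)
  chars <- assert_canonical(sequence)
  counts <- table(factor(chars, levels = AA_ALPHABET))
  frac <- as.numeric(counts) / length(chars)
  names(frac) <- paste0("f_", AA_ALPHABET)
  cover <- sort(unlist(groups, use.names = FALSE))
  if (!identical(cover, sort(AA_ALPHABET))) {
    stop("group table must partition the 20 canonical residues",
         call. = FALSE)
  }
  grp <- vapply(groups, function(g) sum(frac[paste0("f_", g)]), 0.0)
  names(grp) <- paste0("grp_", names(groups))
  c(frac, grp)
}

#' Theoretical molecular weight
#'
#' Sum of average residue masses plus one water (18.0153 Da).
#'
#' @param sequence Canonical amino-acid sequence.
#' @return Mass in Da.
#' @export
molecular_weight <- function(sequence) {
  if (!nzchar(sequence)) stop("empty sequence", call. = FALSE)
  chars <- assert_canonical(sequence)
  sum(AA_RESIDUE_MASS[chars]) + WATER_MASS
}

# Net charge at a given pH: Henderson-Hasselbalch sum over the N-terminus,
# C-terminus and ionizable side chains. Strictly decreasing in pH.
protein_net_charge <- function(sequence, ph) {
  chars <- assert_canonical(sequence)
  nterm_pka <- PKA_NTERM[chars[1]]
  if (is.na(nterm_pka)) nterm_pka <- PKA_NTERM_DEFAULT
  pos_pka <- c(nterm_pka, PKA_SIDE_POS[chars[chars %in% names(PKA_SIDE_POS)]])
  neg_pka <- c(PKA_CTERM, PKA_SIDE_NEG[chars[chars %in% names(PKA_SIDE_NEG)]])
  vapply(ph, function(p) {
    sum(1 / (1 + 10^(p - pos_pka))) - sum(1 / (1 + 10^(neg_pka - p)))
  }, 0.0)
}

#' Theoretical isoelectric point
#'
#' Unique root of the monotone net-charge function over the Bjellqvist pKa
#' set (N-terminus, C-terminus, side chains D, E, C, Y, H, K, R), found by
#' bisection on \[0, 14\].
#'
#' @param sequence Canonical amino-acid sequence.
#' @param tol Bisection tolerance in pH units.
#' @return The pI.
#' @export
isoelectric_point <- function(sequence, tol = 1e-3) {
  if (!nzchar(sequence)) stop("empty sequence", call. = FALSE)
  lo <- 0; hi <- 14
  if (protein_net_charge(sequence, lo) < 0) return(lo)
  if (protein_net_charge(sequence, hi) > 0) return(hi)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (protein_net_charge(sequence, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' N-glycosylation sequon feature
#'
#' Deterministic scan for the N-X-\[S/T\] sequon with X != P. This is a
#' motif-based stand-in for neural-network sequon scoring: it flags
#' candidate sites, not experimentally validated glycosylation.
#'
#' @param sequence Canonical amino-acid sequence.
#' @return List with \code{feature} (1 if any sequon found, else 0) and
#'   \code{positions} (1-based positions of the N of each sequon).
#' @export
nglyc_feature <- function(sequence) {
  chars <- assert_canonical(sequence)
  n <- length(chars)
  pos <- integer(0)
  if (n >= 3) {
    for (i in seq_len(n - 2)) {
      if (chars[i] == "N" && chars[i + 1] != "P" &&
          chars[i + 2] %in% c("S", "T")) {
        pos <- c(pos, i)
      }
    }
  }
  list(feature = as.integer(length(pos) > 0), positions = pos)
}

#' Secondary-structure state percentages
#'
#' @param profile An \code{ss2_profile} from [read_ss2()].
#' @return Named numeric vector \code{c(coil, helix, strand)} of percentages
#'   summing to 100.
#' @export
ss_fractions <- function(profile) {
  if (nrow(profile) == 0) stop("empty ss2 profile", call. = FALSE)
  counts <- table(factor(profile$state, levels = c("C", "H", "E")))
  out <- 100 * as.numeric(counts) / nrow(profile)
  names(out) <- c("coil", "helix", "strand")
  out
}

#' Define a feature schema
#'
#' An ordered inventory of feature descriptors. Categorical descriptors
#' carry their category vocabulary; every descriptor carries a feature-type
#' tag used later for interpretation summaries.
#'
#' @param name Character vector of unique descriptor names.
#' @param kind \code{"numeric"} or \code{"categorical"} per descriptor.
#' @param feature_type One of \code{composition}, \code{group_composition},
#'   \code{host}, \code{biochemical}, \code{secondary_structure},
#'   \code{phylogenetic}, \code{binding} per descriptor.
#' @param categories List of category vocabularies (character vectors;
#'   \code{NULL} for numeric descriptors).
#' @return A \code{feature_schema} object.
#' @export
feature_schema <- function(name, kind, feature_type,
                           categories = vector("list", length(name))) {
  stopifnot(length(kind) == length(name),
            length(feature_type) == length(name),
            length(categories) == length(name))
  if (anyDuplicated(name)) stop("duplicate descriptor names", call. = FALSE)
  if (!all(kind %in% c("numeric", "categorical"))) {
    stop("kind must be 'numeric' or 'categorical'", call. = FALSE)
  }
  ok_types <- c("composition", "group_composition", "host", "biochemical",
                "secondary_structure", "phylogenetic", "binding")
  if (!all(feature_type %in% ok_types)) {
    stop("unknown feature_type tag", call. = FALSE)
  }
  n_cat <- vapply(categories, length, 0L)
  if (any(kind == "categorical" & n_cat < 2)) {
    stop("every categorical descriptor needs >= 2 categories", call. = FALSE)
  }
  structure(list(name = name, kind = kind, feature_type = feature_type,
                 categories = categories), class = "feature_schema")
}

#' Default schema for the laccase feature set
#'
#' 20 residue fractions + 5 group fractions, molecular weight, pI,
#' N-glycosylation flag, docking rank, habitat (one-hot), three
#' secondary-structure percentages, the phylogenetic leaf branch length, and
#' six substrate-binding group counts.
#'
#' @param habitat_levels Category vocabulary for the habitat descriptor.
#' @return A \code{feature_schema}.
#' @export
default_feature_schema <- function(habitat_levels = c("wood", "soil",
                                                      "litter")) {
  groups <- names(aa_group_table())
  dich <- names(aa_dichotomy_table())
  name <- c(paste0("f_", AA_ALPHABET), paste0("grp_", groups),
            "mw", "pi", "nglyc", "docking_rank", "habitat",
            "ss_coil", "ss_helix", "ss_strand", "leaf_branch_length",
            paste0("bind_", dich))
  kind <- rep("numeric", length(name))
  kind[name == "habitat"] <- "categorical"
  feature_type <- c(rep("composition", 20), rep("group_composition", 5),
                    "biochemical", "biochemical", "biochemical",
                    "biochemical", "host",
                    rep("secondary_structure", 3), "phylogenetic",
                    rep("binding", 6))
  categories <- vector("list", length(name))
  categories[[which(name == "habitat")]] <- habitat_levels
  feature_schema(name, kind, feature_type, categories)
}

#' Encode raw features into the numeric feature table
#'
#' Categorical descriptors expand to one-hot blocks over the schema
#' vocabulary (an observed category sets one column to 1; a missing value
#' yields an all-zero block). Missing numeric values are replaced by the
#' sentinel -1. Column order is deterministic: schema order, categories in
#' declared order.
#'
#' @param raw Data.frame with an \code{id} column plus one column per schema
#'   descriptor (numeric, or character for categoricals; \code{NA} =
#'   missing).
#' @param schema A \code{feature_schema}.
#' @return A \code{feature_table}: list with \code{ids}, numeric
#'   \code{matrix}, per-column \code{feature_type}, and the \code{schema}.
#' @export
encode_feature_table <- function(raw, schema) {
  stopifnot(inherits(schema, "feature_schema"), "id" %in% names(raw))
  if (anyDuplicated(raw$id)) stop("duplicate row id", call. = FALSE)
  missing_desc <- setdiff(schema$name, names(raw))
  if (length(missing_desc) > 0) {
    stop("raw features lack descriptor(s): ",
         paste(missing_desc, collapse = ", "), call. = FALSE)
  }
  n <- nrow(raw)
  cols <- list()
  types <- character(0)
  for (k in seq_along(schema$name)) {
    nm <- schema$name[k]
    if (schema$kind[k] == "numeric") {
      v <- as.numeric(raw[[nm]])
      v[!is.finite(v)] <- -1
      cols[[nm]] <- v
      types <- c(types, schema$feature_type[k])
    } else {
      vocab <- schema$categories[[k]]
      v <- as.character(raw[[nm]])
      bad <- !is.na(v) & !(v %in% vocab)
      if (any(bad)) {
        stop(sprintf("category value(s) outside vocabulary of '%s': %s", nm,
                     paste(unique(v[bad]), collapse = ", ")), call. = FALSE)
      }
      for (cat in vocab) {
        cols[[paste0(nm, "=", cat)]] <-
          as.numeric(!is.na(v) & v == cat)
        types <- c(types, schema$feature_type[k])
      }
    }
  }
  mat <- do.call(cbind, cols)
  rownames(mat) <- raw$id
  stopifnot(!anyNA(mat))
  structure(list(ids = raw$id, matrix = mat, feature_type = types,
                 schema = schema), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d records x %d encoded columns\n",
              nrow(x$matrix), ncol(x$matrix)))
  tab <- table(x$feature_type)
  cat("  feature types:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Assemble raw (pre-encoding) features for a record set
#'
#' Computes the composition block, molecular weight, pI and the sequon flag
#' from each sequence, and joins externally supplied secondary-structure,
#' phylogenetic and binding features. Records whose sequence contains the
#' ambiguity code \code{X} get missing composition/weight/pI values (encoded
#' as -1 downstream) with a warning, since their masses are undefined.
#'
#' @param records A \code{protein_records} data.frame.
#' @param ss2 Optional named list of \code{ss2_profile}s keyed by record id.
#' @param leaf_lengths Optional named numeric vector of terminal branch
#'   lengths keyed by record id.
#' @param binding_counts Optional data.frame with an \code{id} column and
#'   the six \code{bind_*} dichotomy count columns.
#' @return Data.frame of raw features, one row per record.
#' @export
build_raw_features <- function(records, ss2 = NULL, leaf_lengths = NULL,
                               binding_counts = NULL) {
  n <- nrow(records)
  comp_names <- c(paste0("f_", AA_ALPHABET),
                  paste0("grp_", names(aa_group_table())))
  comp <- matrix(NA_real_, n, 25, dimnames = list(records$id, comp_names))
  mw <- pi_ <- rep(NA_real_, n)
  ngl <- rep(NA_real_, n)
  has_x <- grepl("X", records$sequence, fixed = TRUE)
  if (any(has_x)) {
    warning("record(s) with ambiguous residue 'X' excluded from ",
            "composition/MW/pI features: ",
            paste(records$id[has_x], collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(n)) {
    if (!has_x[i]) {
      comp[i, ] <- aa_composition(records$sequence[i])
      mw[i] <- molecular_weight(records$sequence[i])
      pi_[i] <- isoelectric_point(records$sequence[i])
      ngl[i] <- nglyc_feature(records$sequence[i])$feature
    }
  }
  raw <- data.frame(id = records$id, comp, mw = mw, pi = pi_, nglyc = ngl,
                    docking_rank = as.numeric(records$docking_rank),
                    habitat = records$habitat, stringsAsFactors = FALSE)
  ss_cols <- c("ss_coil", "ss_helix", "ss_strand")
  raw[ss_cols] <- NA_real_
  if (!is.null(ss2)) {
    for (id in intersect(records$id, names(ss2))) {
      raw[raw$id == id, ss_cols] <- as.list(ss_fractions(ss2[[id]]))
    }
  }
  raw$leaf_branch_length <- if (is.null(leaf_lengths)) NA_real_ else
    as.numeric(leaf_lengths[records$id])
  bind_cols <- paste0("bind_", names(aa_dichotomy_table()))
  raw[bind_cols] <- NA_real_
  if (!is.null(binding_counts)) {
    j <- match(records$id, binding_counts$id)
    for (bc in bind_cols) {
      raw[[bc]][!is.na(j)] <- binding_counts[[bc]][j[!is.na(j)]]
    }
  }
  rownames(raw) <- NULL
  raw
}
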