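#' Construct a mutation set
#'
#' A mutation set describes a variant as point substitutions relative to the
#' wild type, in the conventional `I77L` notation (wild-type residue, 1-based
#' position, mutant residue). The empty set denotes the wild type itself.
#'
#' @param wt Character vector of wild-type residues (one-letter codes).
#' @param pos Integer vector of 1-based positions.
#' @param mut Character vector of mutant residues.
#' @return A data frame of class `mutation_set` with columns `wt`, `pos`,
#'   `mut`, sorted by position.
#' @export
mutation_set <- function(wt = character(0), pos = integer(0), mut = character(0)) {
  stopifnot(length(wt) == length(pos), length(pos) == length(mut))
  wt <- toupper(as.character(wt))
  mut <- toupper(as.character(mut))
  pos <- as.integer(pos)
  if (any(pos < 1L)) stop("mutation positions must be >= 1", call. = FALSE)
  if (!all(wt %in% STANDARD_RESIDUES) || !all(mut %in% STANDARD_RESIDUES)) {
    stop("mutations must use standard one-letter residue codes", call. = FALSE)
  }
  silent <- wt == mut
  if (any(silent)) {
    stop("silent substitution ", wt[silent][1L], pos[silent][1L],
         mut[silent][1L], " (wild-type and mutant residue identical)",
         call. = FALSE)
  }
  df <- data.frame(wt = wt, pos = pos, mut = mut, stringsAsFactors = FALSE)
  df <- unique(df)
  if (anyDuplicated(df$pos)) {
    p <- df$pos[duplicated(df$pos)][1L]
    stop("conflicting substitutions at position ", p, call. = FALSE)
  }
  df <- df[order(df$pos), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("mutation_set", "data.frame")
  df
}

#' Parse mutation notation
#'
#' Parses underscore-joined point-mutation tokens such as `"I77L_H210N"` into
#' a [mutation_set()]. The empty string and `"WT"` (any case) denote the wild
#' type. Token order is irrelevant and duplicate tokens collapse; the same
#' position with two different substitutions is an error, as is a silent
#' substitution like `"I77I"`.
#'
#' @param text Single string, e.g. `"I77L"`, `"I77L_H210N"`, `""`, `"WT"`.
#' @return A `mutation_set`.
#' @export
parse_variant_spec <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text) || toupper(text) == "WT") return(mutation_set())
  tokens <- strsplit(text, "_", fixed = TRUE)[[1L]]
  tokens <- tokens[nzchar(tokens)]
  m <- regmatches(tokens, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", tokens))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) {
    stop("malformed mutation token '", tokens[bad][1L], "' in '", text, "'",
         call. = FALSE)
  }
  mutation_set(
    wt = vapply(m, `[`, character(1), 2L),
    pos = as.integer(vapply(m, `[`, character(1), 3L)),
    mut = vapply(m, `[`, character(1), 4L)
  )
}

#' Render a mutation set as its canonical signature
#'
#' The inverse of [parse_variant_spec()]: mutations joined by underscores in
#' position order; the empty set renders as `"WT"`.
#'
#' @param mutations A `mutation_set`.
#' @return A single string.
#' @export
format_variant_spec <- function(mutations) {
  stopifnot(inherits(mutations, "mutation_set"))
  if (nrow(mutations) == 0L) return("WT")
  paste0(mutations$wt, mutations$pos, mutations$mut, collapse = "_")
}

#' Apply mutations to a wild-type sequence
#'
#' @param wt Wild-type protein sequence (string or character vector).
#' @param mutations A `mutation_set`.
#' @param validate_wt If `TRUE` (default), every mutation's stated wild-type
#'   residue must match the sequence at that position; a mismatch almost
#'   always means the sequence and the variant table disagree.
#' @return The mutated sequence as a single string (same length as `wt`).
#' @export
apply_variant <- function(wt, mutations, validate_wt = TRUE) {
  stopifnot(inherits(mutations, "mutation_set"))
  residues <- as_residue_vector(wt)
  n <- length(residues)
  if (nrow(mutations) > 0L) {
    out_of_range <- mutations$pos > n
    if (any(out_of_range)) {
      stop("mutation position ", mutations$pos[out_of_range][1L],
           " exceeds sequence length ", n, call. = FALSE)
    }
    if (validate_wt) {
      found <- residues[mutations$pos]
      mism <- found != mutations$wt
      if (any(mism)) {
        i <- which(mism)[1L]
        stop("wild-type residue mismatch at position ", mutations$pos[i],
             ": expected ", mutations$wt[i], ", found ", found[i],
             call. = FALSE)
      }
    }
    residues[mutations$pos] <- mutations$mut
  }
  paste(residues, collapse = "")
}

#' Enumerate the full combinatorial library of a mutation set
#'
#' Since each of the `n` point mutations is either present or absent, they
#' span `2^n` variants, from the wild type (no mutations) to the full
#' combination. The output order is deterministic: by subset size, then by
#' the position-sorted mutation signature.
#'
#' @param mutations A `mutation_set` with `n` mutations (pairwise-distinct
#'   positions, enforced by the class).
#' @return A named list of `2^n` `mutation_set` objects (class
#'   `variant_library`); names are the canonical signatures (`"WT"` for the
#'   empty subset).
#' @export
enumerate_library <- function(mutations) {
  stopifnot(inherits(mutations, "mutation_set"))
  n <- nrow(mutations)
  if (n > 24L) stop("refusing to enumerate 2^", n, " variants", call. = FALSE)
  masks <- 0:(2^n - 1)
  subsets <- lapply(masks, function(mask) {
    keep <- bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L
    ms <- mutations[keep, , drop = FALSE]
    class(ms) <- c("mutation_set", "data.frame")
    ms
  })
  sizes <- vapply(subsets, nrow, integer(1))
  sigs <- vapply(subsets, format_variant_spec, character(1))
  ord <- order(sizes, sigs)
  out <- subsets[ord]
  names(out) <- sigs[ord]
  class(out) <- "variant_library"
  out
}

#' @export
print.variant_library <- function(x, ...) {
  cat("<variant_library> ", length(x), " variants: ",
      paste(utils::head(names(x), 5L), collapse = ", "),
      if (length(x) > 5L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Read a variant/activity table
#'
#' Reads a delimited (CSV or TSV; the delimiter is sniffed from the header
#' line unless forced) table with columns `variant_id`, `mutations` and
#' `activity`. The `mutations` column uses the underscore notation of
#' [parse_variant_spec()]; a blank `mutations` cell (or `"WT"`) is the wild
#' type. A blank `activity` marks an unlabeled, prediction-only row. An
#' optional `activity_sd` column carries experimental uncertainties; it is
#' stored but never used in fitting (models are fitted to the reported mean
#' activities).
#'
#' @param file Path or connection.
#' @param delim `NULL` (sniff), `","` or `"\t"`.
#' @return A data frame of class `activity_table` with columns `variant_id`,
#'   `mutations` (canonical signature string), `activity` (numeric, `NA` when
#'   unlabeled), `labeled` (logical) and, when present in the input,
#'   `activity_sd`. The parsed `mutation_set` objects are attached as the
#'   `"mutation_sets"` attribute (a named list keyed by `variant_id`).
#' @export
read_variant_table <- function(file, delim = NULL) {
  first <- if (is.character(file) && length(file) == 1L && !grepl("\n", file)) {
    readLines(file, n = 1L, warn = FALSE)
  } else {
    NA_character_
  }
  if (is.null(delim)) {
    delim <- if (!is.na(first) && grepl("\t", first)) "\t" else ","
  }
  df <- utils::read.delim(file, sep = delim, header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = "character", strip.white = TRUE)
  names(df) <- tolower(names(df))
  required <- c("variant_id", "mutations", "activity")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("variant table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    out <- data.frame(variant_id = character(0), mutations = character(0),
                      activity = numeric(0), labeled = logical(0),
                      stringsAsFactors = FALSE)
    attr(out, "mutation_sets") <- list()
    class(out) <- c("activity_table", "data.frame")
    return(out)
  }

  sets <- vector("list", nrow(df))
  sigs <- character(nrow(df))
  act <- rep(NA_real_, nrow(df))
  for (i in seq_len(nrow(df))) {
    sets[[i]] <- tryCatch(
      parse_variant_spec(df$mutations[i]),
      error = function(e) {
        stop("row ", i, " ('", df$variant_id[i], "'): ", conditionMessage(e),
             call. = FALSE)
      }
    )
    sigs[i] <- format_variant_spec(sets[[i]])
    a <- trimws(df$activity[i])
    if (nzchar(a)) {
      v <- suppressWarnings(as.numeric(a))
      if (is.na(v)) {
        stop("row ", i, " ('", df$variant_id[i],
             "'): unparseable activity '", a, "'", call. = FALSE)
      }
      act[i] <- v
    }
  }
  out <- data.frame(
    variant_id = df$variant_id,
    mutations = sigs,
    activity = act,
    labeled = !is.na(act),
    stringsAsFactors = FALSE
  )
  if ("activity_sd" %in% names(df)) {
    out$activity_sd <- suppressWarnings(as.numeric(df$activity_sd))
  }
  names(sets) <- df$variant_id
  attr(out, "mutation_sets") <- sets
  class(out) <- c("activity_table", "data.frame")
  out
}

#' Write a variant/activity table
#'
#' @param table An `activity_table` (or compatible data frame).
#' @param file Path or connection; comma-separated output.
#' @return Invisibly, `table`.
#' @export
write_variant_table <- function(table, file) {
  cols <- intersect(c("variant_id", "mutations", "activity", "activity_sd"),
                    names(table))
  utils::write.csv(as.data.frame(table)[, cols, drop = FALSE], file,
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(table)
}

#' Write an enumerated library as multi-record FASTA
#'
#' @param wt Wild-type sequence.
#' @param library A `variant_library` from [enumerate_library()].
#' @param file Output path.
#' @return Invisibly, the named character vector of sequences.
#' @export
write_library_fasta <- function(wt, library, file) {
  stopifnot(inherits(library, "variant_library"))
  seqs <- vapply(library, function(ms) apply_variant(wt, ms), character(1))
  seqinr::write.fasta(
    sequences = lapply(seqs, function(s) strsplit(s, "")[[1L]]),
    names = names(library),
    file.out = file
  )
  invisible(seqs)
}

#' Read a protein sequence from a FASTA file
#'
#' @param file FASTA path.
#' @param id Optional record name to select; by default the first record is
#'   used.
#' @return The sequence as a single uppercase string.
#' @export
read_protein_fasta <- function(file, id = NULL) {
  recs <- seqinr::read.fasta(file, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  if (length(recs) == 0L) stop("no sequences in '", file, "'", call. = FALSE)
  if (!is.null(id)) {
    if (!(id %in% names(recs))) {
      stop("no record named '", id, "' in '", file, "'", call. = FALSE)
    }
    recs <- recs[id]
  }
  toupper(as.character(recs[[1L]]))
}
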