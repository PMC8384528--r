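#' Construct an amino-acid index
#'
#' An amino-acid index (an "AAindex" entry) maps each of the 20 standard
#' residues to one real number describing a physicochemical or biochemical
#' property (hydrophobicity, helix propensity, volume, ...). It is the
#' encoding table that turns a protein sequence into a numeric signal.
#'
#' @param accession Single string, the unique identifier of the index
#'   (e.g. `"NAGK730101"`).
#' @param values Named numeric vector of length 20; names must be exactly the
#'   20 standard one-letter residue codes. All values must be finite.
#' @param description Free-text description of the property.
#'
#' @return An object of class `aa_index`: a list with elements `accession`,
#'   `description` and `values` (the value map, stored in alphabetical residue
#'   order `ACDEFGHIKLMNPQRSTVWY`).
#'
#' @examples
#' idx <- aa_index("TOY0000001", setNames(1:20, sort(c(
#'   "A","R","N","D","C","Q","E","G","H","I",
#'   "L","K","M","F","P","S","T","W","Y","V"))))
#' idx$values[["A"]]
#' @export
aa_index <- function(accession, values, description = "") {
  if (!is.character(accession) || length(accession) != 1L || !nzchar(accession)) {
    stop("'accession' must be a single non-empty string", call. = FALSE)
  }
  if (is.null(names(values)) || !setequal(names(values), STANDARD_RESIDUES)) {
    stop(
      "'values' must be named with exactly the 20 standard residues (",
      paste(STANDARD_RESIDUES, collapse = ""), ")",
      call. = FALSE
    )
  }
  values <- as.numeric(values[STANDARD_RESIDUES])
  names(values) <- STANDARD_RESIDUES
  if (any(!is.finite(values))) {
    stop("index '", accession, "' contains non-finite values", call. = FALSE)
  }
  structure(
    list(
      accession = accession,
      description = as.character(description)[1L],
      values = values
    ),
    class = "aa_index"
  )
}

#' @export
print.aa_index <- function(x, ...) {
  cat("<aa_index>", x$accession, "\n")
  if (nzchar(x$description)) cat("  ", x$description, "\n", sep = "")
  print(round(x$values, 4))
  invisible(x)
}

#' Parse an AAindex1 flat file
#'
#' Reads a database of amino-acid indices in the AAindex1 flat-file format:
#' records introduced by an `H <accession>` line, an optional `D` description,
#' an `I` header line and two data lines of ten whitespace-separated values in
#' the standard column order (`A R N D C Q E G H I` on the first line,
#' `L K M F P S T W Y V` on the second), each record terminated by `//`.
#'
#' Entries whose 20 values do not all parse as finite numbers (e.g. contain
#' `NA`) are excluded -- not imputed -- and reported via a message; their
#' accessions are returned in the `"excluded"` attribute so that
#' `length(result) + length(attr(result, "excluded"))` equals the number of
#' records in the file.
#'
#' @param file Path to an AAindex1 file, a connection, or a character vector
#'   of lines (when `length(file) > 1` or `file` contains a newline).
#'
#' @return Named list of [aa_index] objects (names are accessions), with
#'   attribute `excluded`: character vector of accessions dropped for missing
#'   or unparseable values.
#'
#' @seealso [write_aaindex_db()] for the inverse operation.
#' @export
parse_aaindex_db <- function(file) {
  lines <- if (is.character(file) && (length(file) != 1L || grepl("\n", file[1L]))) {
    unlist(strsplit(file, "\n", fixed = TRUE))
  } else {
    readLines(file, warn = FALSE)
  }

  # split into records on "//" terminator lines, tracking line offsets
  records <- list()
  start <- 1L
  for (i in seq_along(lines)) {
    if (grepl("^//", lines[i])) {
      block <- lines[start:i]
      if (any(nzchar(trimws(block[-length(block)])))) {
        records[[length(records) + 1L]] <- list(lines = block, offset = start)
      }
      start <- i + 1L
    }
  }
  if (start <= length(lines) && any(nzchar(trimws(lines[start:length(lines)])))) {
    # trailing content without a "//" terminator: treat as a (malformed) record
    records[[length(records) + 1L]] <- list(lines = lines[start:length(lines)],
                                            offset = start)
  }

  parsed <- list()
  excluded <- character(0)
  for (rec in records) {
    entry <- parse_aaindex_record(rec$lines, rec$offset)
    if (is.null(entry$index)) {
      message("parse_aaindex_db: excluding '", entry$accession,
              "' (missing or unparseable values)")
      excluded <- c(excluded, entry$accession)
    } else {
      if (entry$accession %in% names(parsed)) {
        stop("duplicate accession '", entry$accession, "' at line ",
             rec$offset, call. = FALSE)
      }
      parsed[[entry$accession]] <- entry$index
    }
  }
  structure(parsed, excluded = excluded)
}

# Parse one AAindex1 record (lines up to and including the "//" terminator).
# Returns list(accession=, index = aa_index or NULL if values unusable).
# Structural problems (no H, no I, wrong token counts) are errors that name
# the offending line.
parse_aaindex_record <- function(block, offset) {
  h <- grep("^H\\s", block)
  if (length(h) == 0L) {
    stop("malformed AAindex record starting at line ", offset,
         ": no 'H' accession line", call. = FALSE)
  }
  accession <- trimws(sub("^H\\s+", "", block[h[1L]]))
  if (!nzchar(accession)) {
    stop("malformed AAindex record at line ", offset + h[1L] - 1L,
         ": empty accession", call. = FALSE)
  }

  d <- grep("^D\\s", block)
  description <- if (length(d) > 0L) {
    # description may continue on following lines indented with whitespace
    desc <- sub("^D\\s+", "", block[d[1L]])
    j <- d[1L] + 1L
    while (j <= length(block) && grepl("^\\s+\\S", block[j])) {
      desc <- paste(desc, trimws(block[j]))
      j <- j + 1L
    }
    desc
  } else {
    ""
  }

  i_line <- grep("^I\\b", block)
  if (length(i_line) == 0L) {
    stop("malformed AAindex record '", accession, "' starting at line ",
         offset, ": no 'I' value header", call. = FALSE)
  }
  i_at <- i_line[1L]
  if (i_at + 2L > length(block)) {
    stop("malformed AAindex record '", accession, "': 'I' header at line ",
         offset + i_at - 1L, " not followed by two value lines", call. = FALSE)
  }
  tokens <- unlist(lapply(block[i_at + 1:2], function(l) {
    strsplit(trimws(l), "\\s+")[[1L]]
  }))
  if (length(tokens) != 20L) {
    stop("malformed AAindex record '", accession, "' at line ",
         offset + i_at, ": expected 20 values, found ", length(tokens),
         call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(tokens))
  if (any(is.na(vals) | !is.finite(vals))) {
    return(list(accession = accession, index = NULL))
  }
  names(vals) <- AAINDEX_COLUMN_ORDER
  list(accession = accession,
       index = aa_index(accession, vals, description))
}

#' Write indices to an AAindex1 flat file
#'
#' Serializes [aa_index] objects back to the AAindex1 format understood by
#' [parse_aaindex_db()]; parsing the output recovers identical accessions and
#' values (round trip).
#'
#' @param indices A single `aa_index` or a list of them.
#' @param file Path or connection to write to.
#' @return Invisibly, the character vector of lines written.
#' @export
write_aaindex_db <- function(indices, file) {
  if (inherits(indices, "aa_index")) indices <- list(indices)
  lines <- unlist(lapply(indices, function(idx) {
    stopifnot(inherits(idx, "aa_index"))
    v <- idx$values[AAINDEX_COLUMN_ORDER]
    c(
      paste("H", idx$accession),
      paste("D", idx$description),
      "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
      paste0("  ", paste(formatC(v[1:10], format = "g", digits = 10), collapse = "  ")),
      paste0("  ", paste(formatC(v[11:20], format = "g", digits = 10), collapse = "  ")),
      "//"
    )
  }))
  writeLines(lines, file)
  invisible(lines)
}
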