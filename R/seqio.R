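#' Protein sequence records
#'
#' A protein record is a plain list with fields `id` (accession), `description`
#' (free text, possibly empty) and `sequence` (upper-case amino-acid string
#' using the 20 standard letters plus X/B/Z/U). Collections of records are
#' unnamed lists of such records with unique ids.
#'
#' @param id Accession string.
#' @param sequence Amino-acid string (no gaps, no whitespace).
#' @param description Optional free-text description.
#' @return An object of class `protein_record`.
#' @examples
#' protein_record("a", "MKH")
#' @export
protein_record <- function(id, sequence, description = "") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("'id' must be a single non-empty string")
  }
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1L || !nzchar(sequence)) {
    stop(sprintf("record '%s': sequence must be non-empty", id))
  }
  chars <- strsplit(sequence, "")[[1L]]
  bad <- setdiff(unique(chars), AA_ALLOWED)
  if (length(bad) > 0L) {
    stop(sprintf("record '%s': illegal sequence character(s): %s",
                 id, paste(bad, collapse = ", ")))
  }
  structure(list(id = id, description = description, sequence = sequence),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%d aa)%s\n", x$id, nchar(x$sequence),
              if (nzchar(x$description)) paste0(" - ", x$description) else ""))
  invisible(x)
}

check_unique_ids <- function(ids) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop(sprintf("duplicate sequence id(s): %s", paste(dup, collapse = ", ")))
  }
  invisible(ids)
}

#' Read protein sequences from FASTA
#'
#' Headers are split at the first whitespace into accession and description.
#' Gap characters or whitespace inside a sequence, illegal letters, duplicate
#' ids and empty files are hard errors: curation problems should surface, not
#' be silently repaired.
#'
#' @param path Path to a FASTA file.
#' @param format Input format; only `"fasta"` is supported.
#' @return List of [protein_record()] objects, input order preserved.
#' @export
read_sequences <- function(path, format = "fasta") {
  format <- match.arg(format, "fasta")
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0L) stop(sprintf("no FASTA records in %s", path))
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  check_unique_ids(ids)
  seqs <- as.character(set)
  recs <- vector("list", length(set))
  for (i in seq_along(set)) {
    if (grepl("[-. ]", seqs[[i]])) {
      stop(sprintf("record '%s': gap or whitespace characters in sequence", ids[[i]]))
    }
    recs[[i]] <- protein_record(ids[[i]], seqs[[i]], descs[[i]])
  }
  recs
}

#' Write protein records to FASTA
#'
#' @param records List of [protein_record()] objects.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(records, path, width = 70L) {
  check_unique_ids(vapply(records, `[[`, "", "id"))
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records) {
    header <- if (nzchar(rec$description)) {
      paste(rec$id, rec$description)
    } else {
      rec$id
    }
    writeLines(paste0(">", header), con)
    s <- rec$sequence
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Construct an alignment block
#'
#' @param rows Named character vector of equal-length gapped sequences
#'   ('-' gaps; '.' is normalized to '-').
#' @return An object of class `alignment_block` with fields `ids`, `rows`,
#'   `n_columns`.
#' @export
alignment_block <- function(rows) {
  if (is.null(names(rows)) || any(!nzchar(names(rows)))) {
    stop("alignment rows must be named by sequence id")
  }
  check_unique_ids(names(rows))
  rows <- toupper(gsub(".", "-", rows, fixed = TRUE))
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    stop(sprintf("ragged alignment: row lengths %s",
                 paste(unique(widths), collapse = ", ")))
  }
  bad <- setdiff(unique(strsplit(paste(rows, collapse = ""), "")[[1L]]),
                 c(AA_ALLOWED, "-"))
  if (length(bad) > 0L) {
    stop(sprintf("illegal alignment character(s): %s", paste(bad, collapse = ", ")))
  }
  structure(list(ids = names(rows), rows = rows, n_columns = unname(widths[1L])),
            class = "alignment_block")
}

#' @export
print.alignment_block <- function(x, ...) {
  cat(sprintf("<alignment_block> %d sequences x %d columns\n",
              length(x$ids), x$n_columns))
  invisible(x)
}

#' Ungap one alignment row back to its source sequence
#' @param aln An `alignment_block`.
#' @param id Sequence id.
#' @return Ungapped sequence string.
#' @export
ungap_row <- function(aln, id) {
  if (!id %in% aln$ids) stop(sprintf("unknown sequence id: %s", id))
  gsub("-", "", aln$rows[[id]], fixed = TRUE)
}

#' Read a multiple alignment
#'
#' @param path Path to the alignment file.
#' @param dialect `"aligned-fasta"` or `"clustal"`.
#' @return An [alignment_block()].
#' @export
read_alignment <- function(path, dialect = c("aligned-fasta", "clustal")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (dialect == "aligned-fasta") {
    set <- Biostrings::readBStringSet(path, format = "fasta")
    if (length(set) == 0L) stop(sprintf("no records in %s", path))
    rows <- as.character(set)
    names(rows) <- sub("\\s.*$", "", names(set))
  } else {
    rows <- parse_clustal(readLines(path))
  }
  alignment_block(rows)
}

# Minimal Clustal-dialect block parser: the header line is skipped,
# conservation rows (leading whitespace or only conservation symbols) are
# ignored, and per-name sequence chunks are concatenated across blocks.
# Optional trailing cumulative residue counts are dropped.
parse_clustal <- function(lines) {
  if (length(lines) == 0L) stop("empty alignment file")
  if (grepl("^(CLUSTAL|MUSCLE|Kalign)", lines[1L])) lines <- lines[-1L]
  rows <- list()
  order <- character(0L)
  for (line in lines) {
    if (!nzchar(trimws(line)) || grepl("^\\s", line)) next  # conservation row
    parts <- strsplit(trimws(line), "\\s+")[[1L]]
    if (length(parts) < 2L) next
    name <- parts[1L]
    chunk <- parts[2L]
    if (!name %in% order) order <- c(order, name)
    rows[[name]] <- paste0(if (is.null(rows[[name]])) "" else rows[[name]],
                           chunk)
  }
  if (length(rows) == 0L) stop("no sequence rows found in clustal file")
  stats::setNames(unlist(rows[order]), order)
}

#' Write an alignment as aligned FASTA
#' @param aln An `alignment_block`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in aln$ids) {
    writeLines(c(paste0(">", id), aln$rows[[id]]), con)
  }
  invisible(path)
}

#' Read the bundled insect-vs-human identity fixture
#'
#' Parses the machine-readable transcription of the published 54 x 6 percent
#' identity table (insect cytb561s against the six human references). The TSV
#' has columns `accession`, `species`, `group`, then the six human columns in
#' fixed order Dcytb, Lcytb, CGcytb, TScytb, CYB561D1, SDR2.
#'
#' @param path Path to the fixture TSV. Defaults to the copy shipped with the
#'   package.
#' @return A list of class `similarity_fixture` with fields `matrix`
#'   (an [identity_matrix()]), `group` (per-row labels) and `species`.
#' @export
read_similarity_fixture <- function(path = system.file("extdata",
                                                       "table1_identity.tsv",
                                                       package = "cytb561anno")) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  expected <- c("accession", "species", "group", HUMAN_REF_ORDER)
  if (!identical(colnames(df), expected)) {
    stop(sprintf("fixture columns must be: %s", paste(expected, collapse = ", ")))
  }
  if (nrow(df) != 54L) {
    stop(sprintf("fixture must have 54 rows, found %d", nrow(df)))
  }
  vals <- as.matrix(df[, HUMAN_REF_ORDER])
  if (!is.numeric(vals) || anyNA(vals)) stop("non-numeric identity cell in fixture")
  rownames(vals) <- df$accession
  mat <- identity_matrix_object(vals)
  structure(list(matrix = mat,
                 group = stats::setNames(df$group, df$accession),
                 species = stats::setNames(df$species, df$accession)),
            class = "similarity_fixture")
}

#' Look up one fixture cell
#' @param fixture A `similarity_fixture`.
#' @param accession Insect row accession.
#' @param reference Human column name (e.g. `"SDR2"`).
#' @return Percent identity.
#' @export
fixture_lookup <- function(fixture, accession, reference) {
  if (!accession %in% rownames(fixture$matrix$values)) {
    stop(sprintf("unknown accession: %s", accession))
  }
  reference <- match.arg(reference, HUMAN_REF_ORDER)
  unname(fixture$matrix$values[accession, reference])
}

#' Read a structure model from a PDB file
#'
#' Thin wrapper around [bio3d::read.pdb()] returning a flat atom table.
#' Ligands (HETATM records) are flagged; residue numbering and chain ids are
#' preserved from the file.
#'
#' @param path Path to a PDB file.
#' @return A list of class `structure_model` with a data frame `atoms`
#'   (chain, resno, resid, elety, element, x, y, z, occupancy, het).
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L) stop(sprintf("no atoms in %s", path))
  element <- toupper(trimws(a$elesy))
  missing_el <- !nzchar(element) | is.na(element)
  if (any(missing_el)) {
    # fall back to the first letter of the atom name (toy files)
    element[missing_el] <- toupper(substr(trimws(a$elety[missing_el]), 1L, 1L))
  }
  atoms <- data.frame(
    chain = a$chain, resno = a$resno, resid = a$resid, elety = trimws(a$elety),
    element = element, x = a$x, y = a$y, z = a$z,
    occupancy = if (!is.null(a$o)) a$o else 1,
    het = a$type == "HETATM",
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop(sprintf("non-finite coordinates in %s", path))
  }
  structure(list(atoms = atoms, source = path), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %d atoms (%d ligand) from %s\n",
              nrow(x$atoms), sum(x$atoms$het), x$source))
  invisible(x)
}

#' Write a toy structure model as PDB
#'
#' Minimal ATOM/HETATM writer for generated test structures.
#'
#' @param atoms Data frame with columns chain, resno, resid, elety, element,
#'   x, y, z and optionally het, occupancy.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(atoms, path) {
  het <- if (!is.null(atoms$het)) atoms$het else rep(FALSE, nrow(atoms))
  occ <- if (!is.null(atoms$occupancy)) atoms$occupancy else rep(1, nrow(atoms))
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    sprintf("%-6s%5d %-4s%4s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            if (het[i]) "HETATM" else "ATOM", i,
            substr(atoms$elety[i], 1L, 4L), substr(atoms$resid[i], 1L, 4L),
            atoms$chain[i], atoms$resno[i],
            atoms$x[i], atoms$y[i], atoms$z[i], occ[i], 0,
            atoms$element[i])
  }, character(1L))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
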